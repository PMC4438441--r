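#' Discrete character matrices with missing and polymorphic cells
#'
#' A `character_matrix` stores taxa x characters where each cell is either
#' a nonempty set of states (a single state, or several for polymorphic
#' taxa) or missing. States are labelled `0 .. k-1`, matching NEXUS symbol
#' order. Missing cells are represented by `NA`.
#'
#' @param taxa Character vector of taxon labels (ordered).
#' @param cells A list of columns; each column is a list over taxa whose
#'   elements are sorted integer vectors of states (0-based) or `NA` for
#'   missing.
#' @param k Integer vector: number of defined states per character.
#' @param char_ids Character ids; defaults to `char1, char2, ...`.
#' @param coding_set Optional tag distinguishing alternative codings of
#'   the same characters (e.g. genus-range vs species-range biogeography).
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(taxa, cells, k, char_ids = NULL,
                             coding_set = NULL) {
  nch <- length(cells)
  if (length(k) == 1) k <- rep(as.integer(k), nch)
  if (length(k) != nch) stop2("`k` must have one entry per character")
  char_ids <- char_ids %||% paste0("char", seq_len(nch))
  # taxa order is authoritative; per-column names are dropped
  cells <- lapply(cells, unname)
  for (j in seq_len(nch)) {
    col <- cells[[j]]
    if (length(col) != length(taxa))
      stop2("column ", char_ids[j], " has wrong length")
    for (i in seq_along(col)) {
      cell <- col[[i]]
      if (is_missing_cell(cell)) next
      if (length(cell) == 0)
        stop2("empty state set for taxon ", taxa[i],
              ", character ", char_ids[j])
      if (any(cell < 0 | cell >= k[j]))
        stop2("state out of range (k=", k[j], ") for taxon ", taxa[i],
              ", character ", char_ids[j])
    }
  }
  structure(list(taxa = taxa, char_ids = char_ids, k = as.integer(k),
                 cells = cells, coding_set = coding_set),
            class = "character_matrix")
}

is_missing_cell <- function(cell) length(cell) == 1 && is.na(cell[1])

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters%s\n",
              length(x$taxa), length(x$char_ids),
              if (is.null(x$coding_set)) ""
              else paste0(" (coding set: ", x$coding_set, ")")))
  invisible(x)
}

# Extract one character column as a named list of cells.
character_column <- function(cm, char) {
  j <- if (is.character(char)) match(char, cm$char_ids) else char
  if (is.na(j) || j < 1 || j > length(cm$char_ids))
    stop2("character not found: ", char)
  stats::setNames(cm$cells[[j]], cm$taxa)
}

character_k <- function(cm, char) {
  j <- if (is.character(char)) match(char, cm$char_ids) else char
  cm$k[j]
}

#' Read a NEXUS character matrix
#'
#' Wraps [ape::read.nexus.data()]; polymorphism tokens `{01}` and `(01)`
#' both become state sets, and the declared MISSING symbol (and any other
#' non-symbol token, e.g. the gap `-`) becomes missing. Per-character `k`
#' defaults to one more than the largest observed state index; pass `k`
#' to override (NEXUS declares a single global symbol list).
#'
#' @param file Path to a NEXUS file with a DATA/CHARACTERS block.
#' @param k Optional integer (scalar or per-character) state count.
#' @param coding_set Optional coding-set tag to attach.
#' @return A [character_matrix()].
#' @export
read_nexus_characters <- function(file, k = NULL, coding_set = NULL) {
  raw <- ape::read.nexus.data(file)
  txt <- toupper(paste(readLines(file), collapse = "\n"))
  symbols <- sub('.*SYMBOLS\\s*=\\s*"([^"]*)".*', "\\1", txt)
  symbols <- if (symbols == txt) as.character(0:9) else
    strsplit(gsub("\\s", "", symbols), "")[[1]]
  missing_sym <- sub(".*MISSING\\s*=\\s*(\\S).*", "\\1", txt)
  if (missing_sym == txt) missing_sym <- "?"
  taxa <- names(raw)
  nch <- length(raw[[1]])
  cells <- vector("list", nch)
  for (j in seq_len(nch)) {
    col <- vector("list", length(taxa))
    for (i in seq_along(taxa)) {
      tok <- toupper(raw[[i]][j])
      if (tok %in% c(toupper(missing_sym), tolower(missing_sym), "-")) {
        col[[i]] <- NA
        next
      }
      parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
      states <- match(parts, symbols) - 1L
      if (anyNA(states))
        stop2("symbol '", tok, "' outside SYMBOLS for taxon ", taxa[i],
              ", character ", j)
      col[[i]] <- sort(unique(states))
    }
    cells[[j]] <- col
  }
  if (is.null(k)) {
    k <- vapply(cells, function(col) {
      obs <- unlist(col[!vapply(col, is_missing_cell, TRUE)])
      if (length(obs) == 0) 2L else max(2L, max(obs) + 1L)
    }, integer(1))
  }
  character_matrix(taxa, cells, k = k, coding_set = coding_set)
}

#' Write a character matrix to NEXUS
#'
#' Polymorphic cells are written with curly braces (`{01}`), missing cells
#' with `?`.
#'
#' @param cm A [character_matrix()].
#' @param file Output path.
#' @export
write_nexus_characters <- function(cm, file) {
  kmax <- max(cm$k)
  symbols <- paste(0:(kmax - 1), collapse = "")
  fmt_cell <- function(cell) {
    if (is_missing_cell(cell)) return("?")
    if (length(cell) == 1) return(as.character(cell))
    paste0("{", paste(cell, collapse = ""), "}")
  }
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(cm$taxa), length(cm$char_ids)),
             sprintf('FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=?;',
                     symbols),
             "MATRIX")
  for (i in seq_along(cm$taxa)) {
    row <- vapply(cm$cells, function(col) fmt_cell(col[[i]]), character(1))
    lines <- c(lines, paste(cm$taxa[i], paste(row, collapse = "")))
  }
  lines <- c(lines, ";", "END;")
  writeLines(lines, file)
  invisible(file)
}

#' Export a character matrix as TSV
#'
#' Polymorphic cells are comma-joined state lists; missing cells are `?`.
#'
#' @param cm A [character_matrix()].
#' @param file Output path.
#' @export
write_characters_tsv <- function(cm, file) {
  fmt_cell <- function(cell) {
    if (is_missing_cell(cell)) "?" else paste(cell, collapse = ",")
  }
  mat <- vapply(cm$cells,
                function(col) vapply(col, fmt_cell, character(1)),
                character(length(cm$taxa)))
  df <- data.frame(taxon = cm$taxa, mat, check.names = FALSE)
  names(df) <- c("taxon", cm$char_ids)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV character matrix written by [write_characters_tsv()]
#'
#' @param file Input path.
#' @param k Optional per-character state counts (default inferred).
#' @param coding_set Optional coding-set tag.
#' @return A [character_matrix()].
#' @export
read_characters_tsv <- function(file, k = NULL, coding_set = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  taxa <- df$taxon
  char_ids <- setdiff(names(df), "taxon")
  cells <- lapply(char_ids, function(id) {
    lapply(df[[id]], function(tok) {
      if (tok == "?") NA
      else sort(unique(as.integer(strsplit(tok, "[,&]")[[1]])))
    })
  })
  if (is.null(k)) {
    k <- vapply(cells, function(col) {
      obs <- unlist(col[!vapply(col, is_missing_cell, TRUE)])
      if (length(obs) == 0) 2L else max(2L, max(obs) + 1L)
    }, integer(1))
  }
  character_matrix(taxa, cells, k = k, char_ids = char_ids,
                   coding_set = coding_set)
}

#' Tip prior from an observed cell
#'
#' Missing data get a flat prior over all `k` states; a polymorphic cell
#' spreads its mass equally over the listed states (e.g. `{0,1}` with
#' `k = 3` gives `(0.5, 0.5, 0)`); a monomorphic cell is an indicator.
#' These vectors are used directly as tip partial likelihoods.
#'
#' @param cell A state set (0-based integers) or `NA`.
#' @param k Number of states (>= 2).
#' @return Numeric vector of length `k`, summing to 1.
#' @export
tip_prior <- function(cell, k) {
  if (k < 2) stop2("k must be >= 2")
  if (is_missing_cell(cell)) return(rep(1 / k, k))
  if (length(cell) == 0) stop2("empty state set")
  if (any(cell < 0 | cell >= k)) stop2("state out of range")
  p <- numeric(k)
  p[cell + 1] <- 1 / length(cell)
  p
}

# taxa x k matrix of tip priors for one character column
tip_prior_matrix <- function(column, k) {
  m <- t(vapply(column, tip_prior, numeric(k), k = k))
  rownames(m) <- names(column)
  m
}

#' Partition characters by state count
#'
#' Groups characters by `k` (binary characters form one partition,
#' three-state characters another, ...), mirroring the convention of
#' state-count partitioning for phenotypic data. Characters observed in a
#' single state across all taxa are flagged invariant and excluded from
#' the partitions (an Mk rate is not identifiable for them).
#'
#' @param cm A [character_matrix()].
#' @return A list with `partitions` (list of `list(k, chars)`) and
#'   `invariant` (character ids excluded).
#' @export
partition_by_state_count <- function(cm) {
  inv <- vapply(seq_along(cm$char_ids), function(j) {
    obs <- unlist(cm$cells[[j]][!vapply(cm$cells[[j]], is_missing_cell, TRUE)])
    length(unique(obs)) <= 1
  }, logical(1))
  keep <- which(!inv)
  ks <- sort(unique(cm$k[keep]))
  parts <- lapply(ks, function(kk) {
    list(k = kk, chars = cm$char_ids[keep[cm$k[keep] == kk]])
  })
  list(partitions = parts, invariant = cm$char_ids[inv])
}
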