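#' Geologic intervals
#'
#' @param name Interval name.
#' @param old_Ma Old (beginning) bound, Ma.
#' @param young_Ma Young (ending) bound, Ma; `old_Ma > young_Ma >= 0`.
#' @return An object of class `geologic_interval`.
#' @export
geologic_interval <- function(name, old_Ma, young_Ma) {
  if (!(old_Ma > young_Ma && young_Ma >= 0))
    stop2("interval requires old_Ma > young_Ma >= 0 (got ",
          old_Ma, ", ", young_Ma, ")")
  structure(list(name = name, old_Ma = old_Ma, young_Ma = young_Ma),
            class = "geologic_interval")
}

#' Bundled geologic interval table
#'
#' Period, epoch, and selected stage bounds following the International
#' Commission on Stratigraphy chart. The bundled values are a snapshot;
#' pass `file` to substitute a revised table (bound revisions across
#' chart versions are a configuration concern, not code).
#'
#' @param file Optional TSV path with columns `name`, `old_Ma`,
#'   `young_Ma` overriding the bundled table.
#' @return Data frame of intervals.
#' @export
ics_intervals <- function(file = NULL) {
  file <- file %||% system.file("extdata", "ics_intervals.tsv",
                                package = "paleoasr", mustWork = TRUE)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("name", "old_Ma", "young_Ma") %in% names(tab)))
    stop2("interval table needs columns name, old_Ma, young_Ma")
  tab
}

#' Exponential calibration prior from a geologic interval
#'
#' The interval's young bound becomes the hard minimum age offset of an
#' exponential prior; the rate is chosen so that the requested mass
#' (default 95 percent) of the distribution lies between the young and
#' old bounds: `rate = -log(1 - mass) / (old - young)`. The support is
#' `[offset, Inf)`, so the hard minimum is never violated.
#'
#' @param interval A [geologic_interval()] (or list with `old_Ma`,
#'   `young_Ma`, `name`).
#' @param mass Prior mass to place inside the interval.
#' @return An object of class `calibration_prior` with `offset_Ma`,
#'   `rate_per_Myr`, `mean_excess_Myr`, `interval`.
#' @export
exponential_calibration <- function(interval, mass = 0.95) {
  if (!(mass > 0 && mass < 1)) stop2("mass must lie in (0, 1)")
  old <- interval$old_Ma; young <- interval$young_Ma
  if (old <= young) stop2("old bound must exceed young bound")
  rate <- -log(1 - mass) / (old - young)
  structure(list(interval = interval$name %||% NA_character_,
                 offset_Ma = young, old_bound_Ma = old,
                 rate_per_Myr = rate, mean_excess_Myr = 1 / rate,
                 mass = mass),
            class = "calibration_prior")
}

#' @export
print.calibration_prior <- function(x, ...) {
  cat(sprintf(
    "calibration_prior: offset %.4g Ma + Exp(rate %.4g /Myr)  [%s, %.0f%% mass by %.4g Ma]\n",
    x$offset_Ma, x$rate_per_Myr, x$interval, 100 * x$mass, x$old_bound_Ma))
  invisible(x)
}

#' Construct calibration priors from interval assignments
#'
#' @param assignments Data frame with columns `label` (node or tip
#'   label) and `interval` (interval name).
#' @param table Interval table as from [ics_intervals()].
#' @param mass Prior mass inside each interval.
#' @return Named list of [exponential_calibration()] priors.
#' @export
calibration_priors <- function(assignments, table = ics_intervals(),
                               mass = 0.95) {
  out <- lapply(seq_len(nrow(assignments)), function(i) {
    nm <- assignments$interval[i]
    row <- table[table$name == nm, ]
    if (nrow(row) == 0) stop2("unknown interval: ", nm)
    exponential_calibration(
      geologic_interval(nm, row$old_Ma[1], row$young_Ma[1]), mass = mass)
  })
  stats::setNames(out, assignments$label)
}

#' Export calibration priors as JSON
#'
#' @param priors Named list from [calibration_priors()].
#' @param file Output path.
#' @export
write_calibrations_json <- function(priors, file) {
  rec <- lapply(priors, function(p)
    list(interval = p$interval, offset_Ma = p$offset_Ma,
         old_bound_Ma = p$old_bound_Ma, rate_per_Myr = p$rate_per_Myr,
         mass = p$mass))
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' BLADJ-style even-spacing age assignment
#'
#' Scales a topology so that dated (calibrated) nodes take exactly their
#' fixed ages and undated internal nodes are placed by even spacing:
#' walking down from each dated node, the maximal run of undated nodes
#' along a descent path is spaced evenly between that dated ancestor and
#' the first dated node the path reaches (paths visited oldest
#' calibration first; a node dated by an earlier path bounds later
#' ones). Tips are
#' dated nodes: age 0 by default, overridden by `fixed_ages` for fossil
#' tips, so fossil tip calibrations participate in the spacing. The root
#' age defaults to a fixed value unless the root carries its own entry
#' in `fixed_ages`.
#'
#' @param phy A `phylo` topology (branch lengths, if any, are ignored) or
#'   a [time_tree()].
#' @param fixed_ages Named numeric vector of fixed ages (Ma); names match
#'   tip labels or internal node labels.
#' @param clade_ages Optional list of `list(taxa = <tip labels>, age)`
#'   fixing the MRCA of each taxon set (convenient when internal nodes
#'   are unlabelled).
#' @param root_age Root age (Ma), fixed unless overridden.
#' @return A [time_tree()] whose branch durations realize the assigned
#'   ages.
#' @export
bladj_scale <- function(phy, fixed_ages = NULL, clade_ages = NULL,
                        root_age = 150) {
  if (inherits(phy, "time_tree")) phy <- phy$phy
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  age <- rep(NA_real_, nnode)
  age[seq_len(ntip)] <- 0
  labels <- c(phy$tip.label,
              phy$node.label %||% rep(NA_character_, phy$Nnode))
  if (!is.null(fixed_ages)) {
    for (nm in names(fixed_ages)) {
      idx <- which(labels == nm)
      if (length(idx) == 0) stop2("no node or tip labelled ", nm)
      age[idx[1]] <- fixed_ages[[nm]]
    }
  }
  if (!is.null(clade_ages)) {
    for (ca in clade_ages) {
      v <- mrca_node(phy, ca$taxa)
      age[v] <- ca$age
    }
  }
  if (is.na(age[root])) age[root] <- root_age
  dated <- !is.na(age)
  parent <- rep(NA_integer_, nnode)
  for (i in seq_len(nrow(phy$edge)))
    parent[phy$edge[i, 2]] <- phy$edge[i, 1]
  kids <- child_list(phy)
  # consistency of the fixed ages with ancestry
  for (v in which(dated)) {
    u <- parent[v]
    while (!is.na(u)) {
      if (dated[u] && age[u] < age[v] - 1e-12)
        stop2("fixed age of ancestor node ", u, " (", age[u],
              " Ma) is younger than descendant node ", v,
              " (", age[v], " Ma)")
      u <- parent[u]
    }
  }
  # Chain spacing: walk down from each dated node; the maximal run of
  # undated nodes along a descent path is evenly spaced between the
  # dated ancestor and the first dated node the path reaches. A node
  # dated by an earlier path bounds the later ones. Paths are visited
  # in order of the oldest original calibration beneath them (ties in
  # stored child order), so each shared chain is spaced against its
  # oldest constraint first and ages stay monotone.
  oldest_below <- rep(-Inf, nnode)
  for (v in which(dated)) oldest_below[v] <- age[v]
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; c_ <- po$edge[i, 2]
    oldest_below[p] <- max(oldest_below[p], oldest_below[c_])
  }
  ordered_kids <- function(v) {
    ks <- kids[[v]]
    ks[order(-oldest_below[ks])]
  }
  fix_below <- function(anc, chain, v) {
    if (dated[v]) {
      if (length(chain) > 0) {
        m <- length(chain)
        step <- (age[anc] - age[v]) / (m + 1)
        age[chain] <<- age[anc] - step * seq_len(m)
        dated[chain] <<- TRUE
      }
      for (ch in ordered_kids(v)) fix_below(v, integer(0), ch)
    } else {
      chain2 <- c(chain, v)
      for (ch in ordered_kids(v)) {
        if (dated[v]) fix_below(v, integer(0), ch)
        else fix_below(anc, chain2, ch)
      }
    }
  }
  for (ch in ordered_kids(root)) fix_below(root, integer(0), ch)
  phy$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  if (any(phy$edge.length < -1e-9))
    stop2("age assignment produced a negative branch duration")
  phy$edge.length[phy$edge.length < 0] <- 0
  time_tree(phy, tip_ages = stats::setNames(age[seq_len(ntip)],
                                            phy$tip.label))
}
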