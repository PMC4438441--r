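#' Configuration for a factorial reconstruction study
#'
#' Describes the full design: alternative topologies, the character
#' matrix, target clades (tip sets for MRCA lookup), reconstruction
#' methods, and the shared seed. Taxa present in the matrix but absent
#' from a topology are dropped for that topology's analyses (a topology
#' without fossil tips simply analyses fewer taxa); a topology tip with
#' no matrix row is an error.
#'
#' @param topologies Named list of [time_tree()] objects (>= 1).
#' @param characters A [character_matrix()] (>= 1 character).
#' @param targets Named list of tip-label sets; each target node is the
#'   MRCA of its set on each topology.
#' @param methods Subset of `c("parsimony", "ML", "SIMMAP")` (>= 1).
#' @param nsim Stochastic-mapping replicates.
#' @param alpha Model-selection significance level.
#' @param n_restarts Optimizer restarts per Mk fit.
#' @param seed Master seed; every factorial cell derives its own stream.
#' @return An object of class `study_config`.
#' @export
study_config <- function(topologies, characters, targets,
                         methods = c("parsimony", "ML", "SIMMAP"),
                         nsim = 5000, alpha = 0.05, n_restarts = 5,
                         seed = 1) {
  if (length(topologies) < 1) stop2("need at least one topology")
  if (is.null(names(topologies)) || any(names(topologies) == ""))
    stop2("topologies must be named")
  if (!inherits(characters, "character_matrix"))
    stop2("`characters` must be a character_matrix")
  if (length(characters$char_ids) < 1) stop2("need at least one character")
  if (length(methods) < 1) stop2("need at least one method")
  bad <- setdiff(methods, c("parsimony", "ML", "SIMMAP"))
  if (length(bad) > 0) stop2("unknown method(s): ", paste(bad, collapse = ", "))
  if (length(targets) < 1 || is.null(names(targets)))
    stop2("`targets` must be a named list of tip sets")
  structure(list(topologies = topologies, characters = characters,
                 targets = targets, methods = methods, nsim = nsim,
                 alpha = alpha, n_restarts = n_restarts, seed = seed),
            class = "study_config")
}

#' Run the factorial reconstruction study
#'
#' Executes one analysis per (topology, character, method) cell: the Mk
#' model class is selected once per topology-character pair by the
#' likelihood-ratio chain (the ML and stochastic-mapping methods share
#' the selected rate matrix), each requested method is run, and results
#' are extracted at each target clade's MRCA. A reconstruction is
#' flagged FAILED at a target when it is ambiguous (all states
#' effectively equally supported). Per-cell seeds are derived from the
#' study seed, so results are reproducible and independent of cell
#' execution order.
#'
#' @param cfg A [study_config()].
#' @return An object of class `study_report`: `records` (one per cell),
#'   `summary` and `long` data frames, and `meta`.
#' @export
run_factorial <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  cm <- cfg$characters
  for (tn in names(cfg$topologies)) {
    tree <- cfg$topologies[[tn]]
    missing_rows <- setdiff(tree$phy$tip.label, cm$taxa)
    if (length(missing_rows) > 0)
      stop2("topology ", tn, " has tips without matrix rows: ",
            paste(missing_rows, collapse = ", "))
    for (tg in names(cfg$targets)) {
      absent <- setdiff(cfg$targets[[tg]], tree$phy$tip.label)
      if (length(absent) > 0)
        stop2("target ", tg, " tip ", absent[1],
              " missing from topology ", tn)
    }
  }
  records <- list()
  long <- NULL
  for (tn in names(cfg$topologies)) {
    tree <- cfg$topologies[[tn]]
    for (ch in cm$char_ids) {
      column <- character_column(cm, ch)[tree$phy$tip.label]
      names(column) <- tree$phy$tip.label
      k <- character_k(cm, ch)
      sel <- NULL
      if (any(c("ML", "SIMMAP") %in% cfg$methods)) {
        sel <- select_model(tree, column, k = k, alpha = cfg$alpha,
                            n_restarts = cfg$n_restarts,
                            seed = derive_seed(cfg$seed, tn, ch, "fit"))
      }
      for (m in cfg$methods) {
        res <- switch(m,
          parsimony = parsimony_asr(tree, column, k = k),
          ML = ml_marginal_asr(tree, column, sel$fit),
          SIMMAP = stochastic_map(tree, column, sel$fit, nsim = cfg$nsim,
                                  seed = derive_seed(cfg$seed, tn, ch, m)))
        cell <- list(topology = tn, character = ch, method = m,
                     model_class = if (is.null(sel)) NA_character_
                                   else sel$model_class,
                     targets = list())
        for (tg in names(cfg$targets)) {
          v <- mrca_node(tree, cfg$targets[[tg]])
          failed <- is_failed_reconstruction(res, v)
          if (m == "parsimony") {
            set <- res$node_sets[[v]]
            cell$targets[[tg]] <- list(node = v, mp_set = set,
                                       failed = failed)
            long <- rbind(long, data.frame(
              topology = tn, character = ch, method = m, target = tg,
              node = v, state = 0:(k - 1),
              value = as.numeric(0:(k - 1) %in% set),
              model = cell$model_class, failed = failed))
          } else {
            pv <- res$node_prob[v, ]
            cell$targets[[tg]] <- list(node = v, prob = pv,
                                       failed = failed)
            long <- rbind(long, data.frame(
              topology = tn, character = ch, method = m, target = tg,
              node = v, state = 0:(k - 1), value = round(pv, 4),
              model = cell$model_class, failed = failed))
          }
        }
        records[[length(records) + 1]] <- cell
      }
    }
  }
  summary_df <- do.call(rbind, lapply(records, function(cell) {
    do.call(rbind, lapply(names(cell$targets), function(tg) {
      t_ <- cell$targets[[tg]]
      if (cell$method == "parsimony") {
        data.frame(topology = cell$topology, character = cell$character,
                   method = cell$method, target = tg, node = t_$node,
                   model = cell$model_class,
                   best_state = paste(t_$mp_set, collapse = ","),
                   best_value = NA_real_, failed = t_$failed)
      } else {
        data.frame(topology = cell$topology, character = cell$character,
                   method = cell$method, target = tg, node = t_$node,
                   model = cell$model_class,
                   best_state = as.character(which.max(t_$prob) - 1L),
                   best_value = round(max(t_$prob), 4), failed = t_$failed)
      }
    }))
  }))
  rownames(long) <- rownames(summary_df) <- NULL
  structure(list(records = records, summary = summary_df, long = long,
                 meta = list(seed = cfg$seed, nsim = cfg$nsim,
                             alpha = cfg$alpha,
                             package_version =
                               as.character(utils::packageVersion("paleoasr")),
                             run_time = Sys.time())),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d records (%d failed target results)\n",
              length(x$records), sum(x$summary$failed)))
  invisible(x)
}

#' Write a study report to TSV and JSON
#'
#' Emits a long-format table (one row per topology, character, method,
#' target, state; probabilities at 4 decimals), a per-cell summary of
#' the best-supported ancestral state at each target, and a JSON mirror
#' of the long table keyed by target. Output bytes depend only on the
#' report content (run metadata is not serialized), so identical
#' configurations and seeds give identical files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
report_to_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- report$long
  long$value <- format_prob(long$value)
  long_path <- file.path(dir, "asr_long.tsv")
  utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_path <- file.path(dir, "asr_summary.tsv")
  s <- report$summary
  s$best_value <- ifelse(is.na(s$best_value), "NA", format_prob(s$best_value))
  utils::write.table(s, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_path <- file.path(dir, "asr_report.json")
  keyed <- split(report$long, report$long$target)
  payload <- lapply(keyed, function(df) {
    lapply(seq_len(nrow(df)), function(i)
      list(topology = df$topology[i], character = df$character[i],
           method = df$method[i], node = df$node[i], state = df$state[i],
           value = round(df$value[i], 4), model = df$model[i],
           failed = df$failed[i]))
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  c(long = long_path, summary = summary_path, json = json_path)
}
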