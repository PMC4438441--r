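#' Ancestral state reconstruction results
#'
#' Container returned by the three reconstruction methods. Probability
#' methods fill `node_prob` (rows over all nodes, tips included; ML rows
#' are proportions of total likelihood, stochastic-mapping rows are
#' posterior probabilities); parsimony fills `node_sets` (the set of
#' states attainable in at least one most-parsimonious assignment) and
#' `min_changes`. Stochastic mapping additionally reports imputed states
#' for missing/polymorphic tips and sampled change counts.
#'
#' @name asr_result
NULL

new_asr_result <- function(method, k, node_prob = NULL, node_sets = NULL,
                           min_changes = NULL, tip_imputed = NULL,
                           branch_changes = NULL, replicate_changes = NULL,
                           nsim = NULL) {
  structure(list(method = method, k = k, node_prob = node_prob,
                 node_sets = node_sets, min_changes = min_changes,
                 tip_imputed = tip_imputed, branch_changes = branch_changes,
                 replicate_changes = replicate_changes, nsim = nsim),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("asr_result: %s, k=%d%s\n", x$method, x$k,
              if (!is.null(x$min_changes))
                sprintf(", minimum changes = %d", x$min_changes) else ""))
  invisible(x)
}

#' Flag an uninformative reconstruction at a node
#'
#' A reconstruction is considered failed when it is ambiguous: for
#' probability methods the node's largest state probability does not
#' exceed 1/k (within 1e-6); for parsimony the most-parsimonious set
#' contains every state.
#'
#' @param result An [asr_result].
#' @param node Node id.
#' @return Logical.
#' @export
is_failed_reconstruction <- function(result, node) {
  if (result$method == "parsimony")
    return(length(result$node_sets[[node]]) == result$k)
  max(result$node_prob[node, ]) <= 1 / result$k + 1e-6
}

cells_as_sets <- function(column, k) {
  lapply(column, function(cell) {
    if (is_missing_cell(cell)) 0:(k - 1) else cell
  })
}

#' Parsimony ancestral states (unordered, MPR union)
#'
#' Unit-cost (Fitch-style) parsimony on a rooted, possibly multifurcating
#' tree. Polymorphic tips contribute their state set; missing tips the
#' full set. For every node the reported set contains exactly the states
#' realized by at least one assignment achieving the minimum change
#' count.
#'
#' @param tree A [time_tree()].
#' @param column Named list of cells covering the tips.
#' @param k Number of states (default inferred from the data).
#' @return An [asr_result] with `node_sets` and `min_changes`.
#' @export
parsimony_asr <- function(tree, column, k = NULL) {
  phy <- tree$phy
  column <- column[phy$tip.label]
  if (is.null(k)) {
    obs <- unlist(column[!vapply(column, is_missing_cell, TRUE)])
    k <- max(2L, max(obs) + 1L)
  }
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  sets <- cells_as_sets(column, k)
  kids <- child_list(phy)
  down <- matrix(Inf, nnode, k)
  for (i in seq_len(ntip)) down[i, sets[[i]] + 1] <- 0
  # unit-cost Sankoff transition: min_j(x_j + [s != j]) = min(x_s, min x + 1)
  trans_min <- function(x) pmin(x, min(x) + 1)
  for (v in postorder_nodes(phy)) {
    acc <- numeric(k)
    for (ch in kids[[v]]) acc <- acc + trans_min(down[ch, ])
    down[v, ] <- acc
  }
  root <- ntip + 1L
  minlen <- min(down[root, ])
  up <- matrix(Inf, nnode, k)
  up[root, ] <- 0
  pre <- rev(postorder_nodes(phy))
  for (p in pre) {
    mins <- lapply(kids[[p]], function(ch) trans_min(down[ch, ]))
    tot <- Reduce(`+`, mins)
    for (ci in seq_along(kids[[p]])) {
      ch <- kids[[p]][ci]
      other <- tot - mins[[ci]]
      base <- up[p, ] + other            # cost by parent state
      up[ch, ] <- trans_min(base)
    }
  }
  total <- down + up
  node_sets <- lapply(seq_len(nnode), function(v) {
    which(total[v, ] <= minlen + 1e-9) - 1L
  })
  new_asr_result("parsimony", k, node_sets = node_sets,
                 min_changes = as.integer(round(minlen)))
}

# Outside ("above the node") partial vectors for every node, reusing the
# pruning pieces; each row rescaled to max 1. Exact on rooted trees with
# multifurcations.
mk_outside <- function(pr) {
  phy <- pr$phy; k <- pr$k
  nnode <- nrow(pr$down)
  O <- matrix(0, nnode, k)
  O[pr$root, ] <- pr$pi
  for (p in rev(postorder_nodes(phy))) {
    eidx <- pr$kids[[p]]
    D <- lapply(eidx, function(ei) {
      ch <- phy$edge[ei, 2]
      as.vector(pr$P[[ei]] %*% pr$down[ch, ])
    })
    for (ci in seq_along(eidx)) {
      ei <- eidx[ci]
      ch <- phy$edge[ei, 2]
      other <- rep(1, k)
      for (bi in seq_along(eidx)) if (bi != ci) other <- other * D[[bi]]
      oc <- as.vector(crossprod(pr$P[[ei]], O[p, ] * other))
      m <- max(oc)
      O[ch, ] <- if (m > 0) oc / m else 0
    }
  }
  O
}

#' Maximum-likelihood marginal ancestral states
#'
#' Exact marginal posterior of the state at every node given all tip
#' data, with the rate matrix fixed at the supplied fit (the two-pass
#' inside/outside computation; for reversible generators this equals the
#' classical re-rooting construction). Rows are normalized to proportions
#' of total likelihood (PTL).
#'
#' @param tree A [time_tree()].
#' @param column Named list of cells covering the tips.
#' @param fit An [fit_mk()] result (or a `rate_matrix`).
#' @return An [asr_result] with `node_prob`.
#' @export
ml_marginal_asr <- function(tree, column, fit) {
  rm <- if (inherits(fit, "mk_fit")) fit$rate_matrix else fit
  k <- rm$k
  column <- column[tree$phy$tip.label]
  tipp <- tip_prior_matrix(column, k)
  pr <- mk_prune(tree, tipp, rm, partials = TRUE)
  if (!is.finite(pr$logL)) stop2("data have zero likelihood under this fit")
  O <- mk_outside(pr)
  raw <- O * pr$down
  prob <- raw / rowSums(raw)
  new_asr_result("ML", k, node_prob = prob)
}

# Number of real changes on a CTMC path from a to b over duration t,
# conditioned on the endpoints. Exact rejection sampling with a capped
# number of attempts, then a uniformization fallback.
sample_branch_changes <- function(Q, a, b, t, max_attempts = 1000) {
  k <- nrow(Q)
  if (t <= 0) {
    if (a != b) stop2("zero-length branch with differing endpoint states")
    return(0L)
  }
  for (att in seq_len(max_attempts)) {
    s <- a; tau <- 0; changes <- 0L
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      tau <- tau + stats::rexp(1, rate)
      if (tau >= t) break
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(k, 1, prob = probs)
      changes <- changes + 1L
    }
    if (s == b) return(changes)
  }
  uniformization_changes(Q, a, b, t)
}

uniformization_changes <- function(Q, a, b, t) {
  k <- nrow(Q)
  lam <- max(-diag(Q))
  if (lam <= 0) {
    if (a != b) stop2("absorbing generator cannot connect the endpoints")
    return(0L)
  }
  R <- diag(k) + Q / lam
  nmax <- max(4, stats::qpois(1 - 1e-12, lam * t) + 2)
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (n in seq_len(nmax)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  w <- vapply(0:nmax, function(n) {
    stats::dpois(n, lam * t) * Rpow[[n + 1]][a, b]
  }, numeric(1))
  if (sum(w) <= 0) stop2("endpoint pair unreachable under uniformization")
  n <- sample.int(nmax + 1, 1, prob = w) - 1L
  if (n == 0) return(0L)
  states <- integer(n + 1)
  states[1] <- a; states[n + 1] <- b
  if (n > 1) {
    for (m in 2:n) {
      wgt <- R[states[m - 1], ] * Rpow[[n - m + 2]][, b]
      states[m] <- sample.int(k, 1, prob = wgt)
    }
  }
  sum(diff(states) != 0)
}

#' Bayesian stochastic character mapping
#'
#' Empirical-Bayes stochastic mapping: with the rate matrix fixed at its
#' maximum-likelihood estimate, samples `nsim` full character histories
#' conditioned on the tip data. Node states are drawn from their joint
#' conditional distribution (root first, then each child given its
#' parent); each branch's substitution path is then simulated conditioned
#' on its sampled endpoints. Node posterior probabilities (PP) are the
#' sampled state frequencies; tips coded missing or polymorphic receive
#' imputed states (their most frequently sampled state). Reproducible
#' given `seed`.
#'
#' @inheritParams ml_marginal_asr
#' @param nsim Number of simulated histories (>= 1).
#' @param seed Integer seed.
#' @return An [asr_result] with `node_prob` (PP), `tip_imputed`,
#'   per-branch mean change counts and per-replicate total change counts.
#' @export
stochastic_map <- function(tree, column, fit, nsim = 5000, seed = NULL) {
  if (!is_count(nsim)) stop2("nsim must be a positive integer")
  rm <- if (inherits(fit, "mk_fit")) fit$rate_matrix else fit
  k <- rm$k
  phy <- tree$phy
  column <- column[phy$tip.label]
  tipp <- tip_prior_matrix(column, k)
  pr <- mk_prune(tree, tipp, rm, partials = TRUE)
  if (!is.finite(pr$logL)) stop2("data have zero likelihood under this fit")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  nedge <- nrow(phy$edge)
  with_seed(seed, {
    states <- matrix(0L, nnode, nsim)
    w <- pr$pi * pr$down[pr$root, ]
    states[pr$root, ] <- sample.int(k, nsim, replace = TRUE, prob = w)
    for (p in rev(postorder_nodes(phy))) {
      ps <- states[p, ]
      for (ei in pr$kids[[p]]) {
        ch <- phy$edge[ei, 2]
        # sampling kernel: rows = parent state, cols proportional to
        # P[i, j] * downstream partial of the child
        M <- pr$P[[ei]] * rep(pr$down[ch, ], each = k)
        cs <- integer(nsim)
        for (i in unique(ps)) {
          sel <- which(ps == i)
          cs[sel] <- sample.int(k, length(sel), replace = TRUE,
                                prob = M[i, ])
        }
        states[ch, ] <- cs
      }
    }
    branch_changes <- numeric(nedge)
    replicate_changes <- integer(nsim)
    Qm <- rm$Q
    for (ei in seq_len(nedge)) {
      p <- phy$edge[ei, 1]; ch <- phy$edge[ei, 2]
      t_e <- phy$edge.length[ei]
      pair_key <- paste(states[p, ], states[ch, ])
      nch <- integer(nsim)
      for (key in unique(pair_key)) {
        sel <- which(pair_key == key)
        ab <- as.integer(strsplit(key, " ")[[1]])
        nch[sel] <- vapply(sel, function(.)
          sample_branch_changes(Qm, ab[1], ab[2], t_e), integer(1))
      }
      branch_changes[ei] <- mean(nch)
      replicate_changes <- replicate_changes + nch
    }
    counts <- t(apply(states, 1, tabulate, nbins = k))
    pp <- counts / nsim
    imput <- rep(NA_integer_, ntip)
    needs <- which(vapply(column, function(cell)
      is_missing_cell(cell) || length(cell) > 1, TRUE))
    imput[needs] <- vapply(needs, function(i) which.max(pp[i, ]) - 1L,
                           integer(1))
    names(imput) <- phy$tip.label
    new_asr_result("SIMMAP", k, node_prob = pp, tip_imputed = imput,
                   branch_changes = branch_changes,
                   replicate_changes = replicate_changes, nsim = nsim)
  })
}
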