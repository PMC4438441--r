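#' Mk rate matrices
#'
#' Builds the k-state continuous-time Markov generator for discrete
#' character evolution under one of the three nested parameterizations:
#' equal rates (ER, 1 free rate), symmetric (SYM, k(k-1)/2) and
#' all-rates-different (ARD, k(k-1)). Root/stationary frequencies default
#' to equal (1/k), the Mk convention.
#'
#' @param model_class One of `"ER"`, `"SYM"`, `"ARD"`.
#' @param k Number of states (>= 2).
#' @param rates Free rate parameters, in the order documented for each
#'   class: ER a single rate; SYM the upper triangle row by row; ARD all
#'   off-diagonal entries row by row.
#' @param pi Root frequencies (default equal).
#' @return An object of class `rate_matrix` with elements `Q`,
#'   `model_class`, `rates`, `k`, `pi`.
#' @export
mk_rate_matrix <- function(model_class = c("ER", "SYM", "ARD"), k,
                           rates, pi = rep(1 / k, k)) {
  model_class <- match.arg(model_class)
  k <- as.integer(k)
  if (k < 2) stop2("k must be >= 2")
  np <- mk_n_params(model_class, k)
  if (length(rates) != np)
    stop2(model_class, " with k=", k, " needs ", np, " rate(s)")
  if (any(rates < 0)) stop2("rates must be >= 0")
  Q <- matrix(0, k, k)
  if (model_class == "ER") {
    Q[] <- rates[1]
  } else if (model_class == "SYM") {
    idx <- 1
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      Q[i, j] <- Q[j, i] <- rates[idx]
      idx <- idx + 1
    }
  } else {
    idx <- 1
    for (i in 1:k) for (j in 1:k) {
      if (i == j) next
      Q[i, j] <- rates[idx]
      idx <- idx + 1
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, model_class = model_class, rates = rates,
                 k = k, pi = pi),
            class = "rate_matrix")
}

#' Number of free rate parameters for a model class
#' @param model_class `"ER"`, `"SYM"` or `"ARD"`.
#' @param k Number of states.
#' @return Integer parameter count.
#' @export
mk_n_params <- function(model_class, k) {
  switch(model_class,
         ER = 1L,
         SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)),
         stop2("unknown model class: ", model_class))
}

as_generator <- function(Q) {
  if (inherits(Q, "rate_matrix")) Q$Q else Q
}

#' Transition probability matrix exp(Qt)
#'
#' Uses the closed form for two states, an eigendecomposition for larger
#' generators (validated against the reconstruction of Q, with a dense
#' scaling-and-squaring fallback), and returns the identity at `t = 0`.
#'
#' @param Q A generator matrix or [mk_rate_matrix()].
#' @param t Duration (Myr), `>= 0`.
#' @return A k x k stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop2("t must be >= 0")
  transition_prob_fn(as_generator(Q))(t)
}

# Factory: returns function(t) -> exp(Qt), amortizing the spectral
# decomposition across many branch lengths.
transition_prob_fn <- function(Q) {
  Q <- as_generator(Q)
  k <- nrow(Q)
  if (k == 2) {
    a <- Q[1, 2]; b <- Q[2, 1]; s <- a + b
    return(function(t) {
      if (t == 0 || s == 0) return(diag(2))
      e <- exp(-s * t)
      matrix(c((b + a * e) / s, a * (1 - e) / s,
               b * (1 - e) / s, (a + b * e) / s),
             2, 2, byrow = TRUE)
    })
  }
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- eg$vectors %*% (eg$values * Vinv)
      err <- max(Mod(recon - Q))
      use_eigen <- err < 1e-9 * max(1, max(abs(Q)))
    }
  }
  if (use_eigen) {
    V <- eg$vectors; val <- eg$values
    function(t) {
      if (t == 0) return(diag(k))
      P <- Re(V %*% (exp(val * t) * Vinv))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      if (t == 0) return(diag(k))
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P
    }
  }
}

# Per-edge transition matrices for a tree; element i corresponds to row i
# of phy$edge.
edge_prob_list <- function(phy, Q) {
  f <- transition_prob_fn(Q)
  lapply(phy$edge.length, f)
}

# Core pruning pass. tip_priors: taxa x k matrix (rownames = tip labels)
# or named list of length-k vectors. Returns log-likelihood plus, when
# partials = TRUE, the machinery reused by the ASR methods.
mk_prune <- function(tree, tip_priors, Q, pi = NULL, partials = FALSE) {
  stopifnot(inherits(tree, "time_tree"))
  phy <- tree$phy
  Qm <- as_generator(Q)
  k <- nrow(Qm)
  pi <- pi %||% (if (inherits(Q, "rate_matrix")) Q$pi else rep(1 / k, k))
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  if (is.list(tip_priors) && !is.matrix(tip_priors))
    tip_priors <- do.call(rbind, tip_priors[phy$tip.label])
  miss <- setdiff(phy$tip.label, rownames(tip_priors))
  if (length(miss) > 0)
    stop2("no tip prior for taxon: ", paste(miss, collapse = ", "))
  P <- edge_prob_list(phy, Qm)
  # edge indices grouped by parent node
  kids <- vector("list", nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], i)
  }
  L <- matrix(0, nnode, k)
  logsc <- numeric(nnode)
  L[seq_len(ntip), ] <- tip_priors[phy$tip.label, , drop = FALSE]
  for (v in postorder_nodes(phy)) {
    part <- rep(1, k)
    sc <- 0
    for (ei in kids[[v]]) {
      ch <- phy$edge[ei, 2]
      part <- part * as.vector(P[[ei]] %*% L[ch, ])
      sc <- sc + logsc[ch]
    }
    m <- max(part)
    if (m <= 0) {
      # data impossible under this Q
      L[v, ] <- 0
      logsc[v] <- -Inf
    } else {
      L[v, ] <- part / m
      logsc[v] <- sc + log(m)
    }
  }
  root <- root_node(tree)
  lik <- sum(pi * L[root, ])
  logL <- if (lik <= 0 || !is.finite(logsc[root])) -Inf
          else log(lik) + logsc[root]
  if (!partials) return(logL)
  list(logL = logL, down = L, logsc = logsc, P = P, kids = kids,
       pi = pi, k = k, root = root, phy = phy)
}

#' Felsenstein pruning log-likelihood for a discrete character
#'
#' Tip priors are used directly as tip partial-likelihood vectors, so
#' missing and polymorphic taxa enter through [tip_prior()]. The tree may
#' be multifurcating; zero-length branches contribute identity transition
#' matrices.
#'
#' @param tree A [time_tree()].
#' @param tip_priors Named list (or taxa x k matrix) of tip prior vectors
#'   covering every tip.
#' @param Q A [mk_rate_matrix()] or plain generator matrix.
#' @param pi Root frequencies; defaults to those stored in `Q` or equal.
#' @return Log-likelihood (the root partials dotted with `pi`).
#' @export
prune_likelihood <- function(tree, tip_priors, Q, pi = NULL) {
  mk_prune(tree, tip_priors, Q, pi = pi, partials = FALSE)
}

#' Maximum-likelihood fit of an Mk model to one character
#'
#' Maximizes the pruning likelihood over nonnegative rates on the log
#' scale with bounded quasi-Newton iterations and jittered restarts (ARD
#' surfaces can be multimodal). Deterministic given `seed`.
#'
#' @param tree A [time_tree()].
#' @param column Named list of cells (state sets / `NA`) covering the
#'   tips, e.g. from [character_column()].
#' @param model_class `"ER"`, `"SYM"` or `"ARD"`.
#' @param k Number of states.
#' @param n_restarts Number of optimizer starts (first deterministic,
#'   rest jittered).
#' @param seed Seed for the jittered restarts.
#' @param init Optional starting rates (recycled to the parameter count);
#'   used in addition to the default start.
#' @param pi Root frequencies (default equal).
#' @return An object of class `mk_fit`: `rate_matrix`, `logL`,
#'   `convergence`, `n_restarts`.
#' @export
fit_mk <- function(tree, column, model_class = "ER", k = NULL,
                   n_restarts = 5, seed = NULL, init = NULL, pi = NULL) {
  column <- column[tree$phy$tip.label]
  if (any(vapply(column, is.null, TRUE)))
    stop2("column must cover every tip of the tree")
  if (is.null(k)) {
    obs <- unlist(column[!vapply(column, is_missing_cell, TRUE)])
    if (length(obs) == 0) stop2("all cells missing; cannot fit")
    k <- max(2L, max(obs) + 1L)
  }
  obs <- unlist(column[!vapply(column, is_missing_cell, TRUE)])
  if (length(obs) == 0) stop2("all cells missing; cannot fit")
  n_informative <- sum(!vapply(column, is_missing_cell, TRUE))
  if (n_informative < 2) stop2("need >= 2 tips with non-missing data")
  tipp <- tip_prior_matrix(column, k)
  pi <- pi %||% rep(1 / k, k)
  np <- mk_n_params(model_class, k)
  negll <- function(logr) {
    rm <- mk_rate_matrix(model_class, k, exp(logr), pi = pi)
    -mk_prune(tree, tipp, rm, pi = pi)
  }
  r0 <- length(tree$phy$tip.label) / max(sum(tree$phy$edge.length), 1e-8)
  starts <- list(rep(log(r0), np))
  if (!is.null(init)) {
    ir <- rep_len(pmax(init, 1e-8), np)
    starts <- c(starts, list(log(ir)))
  }
  extra <- n_restarts - length(starts)
  if (extra > 0) {
    jit <- with_seed(seed %||% 1L,
                     lapply(seq_len(extra),
                            function(i) log(r0) + stats::rnorm(np, sd = 1.5)))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = log(1e-9), upper = log(1e4),
                   control = list(factr = 1e5, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop2("optimization failed for every start")
  rm <- mk_rate_matrix(model_class, k, exp(best$par), pi = pi)
  structure(list(rate_matrix = rm, logL = -best$value,
                 convergence = best$convergence == 0,
                 n_restarts = length(starts)),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("mk_fit: %s, k=%d, logL=%.4f, rates=%s\n",
              x$rate_matrix$model_class, x$rate_matrix$k, x$logL,
              paste(signif(x$rate_matrix$rates, 4), collapse = ", ")))
  invisible(x)
}

#' Serialize a fitted Mk model to JSON
#'
#' Writes the model class, free rates, root frequencies and
#' log-likelihood.
#'
#' @param fit An [fit_mk()] result.
#' @param file Output path.
#' @export
write_mk_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "mk_fit"))
  jsonlite::write_json(
    list(model_class = fit$rate_matrix$model_class,
         k = fit$rate_matrix$k,
         rates = fit$rate_matrix$rates,
         pi = fit$rate_matrix$pi,
         logL = fit$logL,
         convergence = fit$convergence),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Hierarchical Mk model selection by likelihood-ratio test
#'
#' Forward selection along the nested chain ER, SYM, ARD: at each step
#' twice the log-likelihood gain is compared with a chi-squared quantile
#' whose degrees of freedom equal the difference in free parameters, at
#' significance level `alpha`; selection stops at the first
#' non-significant step. For binary characters SYM coincides with ER, so
#' the candidate set collapses to ER vs ARD. A p-value exactly equal to
#' `alpha` retains the simpler model. Each richer model is warm-started
#' from the accepted simpler fit so nested log-likelihoods never decrease.
#'
#' @inheritParams fit_mk
#' @param alpha Significance level of each chi-squared test.
#' @return A list: `model_class` (the selection), `fit` (its [fit_mk()]
#'   object), `fits` (all fitted candidates), `tests` (data frame of LRT
#'   statistics, df and p-values).
#' @export
select_model <- function(tree, column, k = NULL, alpha = 0.05,
                         n_restarts = 5, seed = NULL) {
  if (is.null(k)) {
    obs <- unlist(column[!vapply(column, is_missing_cell, TRUE)])
    k <- max(2L, max(obs) + 1L)
  }
  chain <- if (k == 2) c("ER", "ARD") else c("ER", "SYM", "ARD")
  fits <- list()
  fits[["ER"]] <- fit_mk(tree, column, "ER", k = k,
                         n_restarts = n_restarts, seed = seed)
  current <- "ER"
  tests <- data.frame(from = character(), to = character(),
                      stat = numeric(), df = integer(), p = numeric())
  for (cand in chain[-1]) {
    warm <- expand_rates(fits[[current]]$rate_matrix, cand)
    fits[[cand]] <- fit_mk(tree, column, cand, k = k,
                           n_restarts = n_restarts,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, cand),
                           init = warm)
    stat <- max(0, 2 * (fits[[cand]]$logL - fits[[current]]$logL))
    df <- mk_n_params(cand, k) - mk_n_params(current, k)
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    tests <- rbind(tests, data.frame(from = current, to = cand,
                                     stat = stat, df = df, p = p))
    if (p < alpha) current <- cand else break
  }
  list(model_class = current, fit = fits[[current]], fits = fits,
       tests = tests)
}

# Express a fitted simpler model's rates in a richer parameterization,
# for warm starts.
expand_rates <- function(rm, target_class) {
  k <- rm$k
  Q <- rm$Q
  if (target_class == "SYM") {
    out <- numeric(0)
    for (i in 1:(k - 1)) for (j in (i + 1):k) out <- c(out, Q[i, j])
    out
  } else {
    out <- numeric(0)
    for (i in 1:k) for (j in 1:k) if (i != j) out <- c(out, Q[i, j])
    out
  }
}
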