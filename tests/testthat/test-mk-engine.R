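test_that("rate matrices respect their class structure", {
  er <- mk_rate_matrix("ER", 3, 0.4)
  expect_true(all(abs(rowSums(er$Q)) < 1e-12))
  off <- er$Q[row(er$Q) != col(er$Q)]
  expect_true(all(off == 0.4))

  sym <- mk_rate_matrix("SYM", 3, c(0.1, 0.2, 0.3))
  expect_equal(sym$Q, t(sym$Q))
  expect_true(all(abs(rowSums(sym$Q)) < 1e-12))

  ard <- mk_rate_matrix("ARD", 3, seq(0.1, 0.6, by = 0.1))
  expect_true(all(abs(rowSums(ard$Q)) < 1e-12))
  expect_error(mk_rate_matrix("SYM", 3, 1:2), "needs")
})

test_that("transition matrices: identity at t=0, closed form, stationarity", {
  Q <- mk_rate_matrix("ER", 2, 1)
  expect_equal(transition_matrix(Q, 0), diag(2))
  # two-state ER closed form (1 +/- exp(-2t))/2 at mu=1, t=1
  P <- transition_matrix(Q, 1)
  expect_equal(P[1, 1], (1 + exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(P[1, 2], (1 - exp(-2)) / 2, tolerance = 1e-12)
  # long-time limit: all entries 1/2
  expect_equal(transition_matrix(Q, 500), matrix(0.5, 2, 2),
               tolerance = 1e-10)
  expect_error(transition_matrix(Q, -1), ">= 0")
  # rows sum to one for random generators
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    rq <- mk_rate_matrix("ARD", k, runif(k * (k - 1), 0.01, 2))
    P <- transition_matrix(rq, runif(1, 0, 5))
    expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  }
})

test_that("pruning likelihood matches degenerate closed forms", {
  tr <- read_newick_time_tree("(A:0,B:0);")
  Q <- mk_rate_matrix("ER", 2, 1)
  tp <- list(A = tip_prior(0L, 2), B = tip_prior(0L, 2))
  expect_equal(prune_likelihood(tr, tp, Q), log(0.5))
  expect_error(prune_likelihood(tr, list(A = tip_prior(0L, 2)), Q), "B")
})

test_that("pruning equals exhaustive enumeration on small trees", {
  for (s in 1:6) {
    n <- sample(3:5, 1)
    k <- sample(2:3, 1)
    tr <- random_oracle_tree(n, seed = 500 + s)
    col <- random_column(tr, k, seed = 600 + s)
    tp <- t(vapply(col, tip_prior, numeric(k), k = k))
    mc <- sample(c("ER", "SYM", "ARD"), 1)
    Q <- mk_rate_matrix(mc, k, runif(mk_n_params(mc, k), 0.05, 1))
    ll <- prune_likelihood(tr, tp, Q)
    expect_equal(ll, oracle_mk_loglik(tr, tp, Q$Q, Q$pi),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is linear in tip partials and child-order invariant", {
  tr <- random_oracle_tree(6, seed = 77)
  Q <- mk_rate_matrix("ER", 3, 0.3)
  col <- random_column(tr, 3, seed = 78)
  tp <- t(vapply(col, tip_prior, numeric(3), k = 3))
  base <- prune_likelihood(tr, tp, Q)
  tp2 <- tp
  tp2[2, ] <- tp2[2, ] * 7
  expect_equal(prune_likelihood(tr, tp2, Q), base + log(7),
               tolerance = 1e-10)
  # reordering children (rotate the tree) leaves the likelihood unchanged
  phy2 <- ape::rotate(tr$phy, node = length(tr$phy$tip.label) + 1L)
  tr2 <- time_tree(phy2, tip_ages = stats::setNames(
    tr$node_age[seq_len(6)], tr$phy$tip.label))
  expect_equal(prune_likelihood(tr2, tp, Q), base, tolerance = 1e-10)
})

test_that("ER likelihood depends on branch lengths only through mu*t", {
  tr <- random_oracle_tree(8, seed = 88)
  col <- random_column(tr, 2, seed = 89)
  tp <- t(vapply(col, tip_prior, numeric(2), k = 2))
  l1 <- prune_likelihood(tr, tp, mk_rate_matrix("ER", 2, 0.8))
  phy2 <- tr$phy
  phy2$edge.length <- phy2$edge.length * 2
  tr2 <- time_tree(phy2)
  l2 <- prune_likelihood(tr2, tp, mk_rate_matrix("ER", 2, 0.4))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("fitting a no-change character drives the rate to the boundary", {
  tr <- random_oracle_tree(10, seed = 21)
  col <- stats::setNames(rep(list(1L), 10), tr$phy$tip.label)
  col[[3]] <- NA
  fit <- fit_mk(tr, col, "ER", k = 2, seed = 1)
  expect_lt(fit$rate_matrix$rates, 1e-6)
  # limit: root frequency of the shared state times the missing tip's
  # normalized flat prior (1/k)
  expect_equal(fit$logL, log(0.5) + log(0.5), tolerance = 1e-5)
})

test_that("fits are deterministic given the seed", {
  tr <- random_oracle_tree(12, seed = 31)
  col <- random_column(tr, 3, seed = 32)
  f1 <- fit_mk(tr, col, "ARD", k = 3, n_restarts = 3, seed = 7)
  f2 <- fit_mk(tr, col, "ARD", k = 3, n_restarts = 3, seed = 7)
  expect_identical(f1$rate_matrix$rates, f2$rate_matrix$rates)
  expect_error(fit_mk(tr, stats::setNames(rep(list(NA), 12),
                                          tr$phy$tip.label), "ER", k = 2),
               "missing")
})

test_that("model-selection chain has the right df and candidate sets", {
  tr <- random_oracle_tree(15, seed = 41)
  col3 <- random_column(tr, 3, seed = 42, p_missing = 0, p_poly = 0)
  sel3 <- select_model(tr, col3, k = 3, n_restarts = 2, seed = 5)
  expect_equal(sel3$tests$df[1], 2L)                  # ER -> SYM, k=3
  if (nrow(sel3$tests) > 1) expect_equal(sel3$tests$df[2], 3L)
  col2 <- random_column(tr, 2, seed = 43, p_missing = 0, p_poly = 0)
  sel2 <- select_model(tr, col2, k = 2, n_restarts = 2, seed = 6)
  expect_true(all(sel2$tests$from == "ER" & sel2$tests$to == "ARD"))
  expect_equal(sel2$tests$df, 1L)
  expect_true(sel2$model_class %in% c("ER", "ARD"))
})

test_that("fitted models serialize to JSON with rates and logL", {
  tr <- random_oracle_tree(8, seed = 61)
  col <- random_column(tr, 2, seed = 62, p_missing = 0, p_poly = 0)
  fit <- fit_mk(tr, col, "ER", k = 2, n_restarts = 2, seed = 63)
  f <- tempfile(fileext = ".json")
  write_mk_fit_json(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$model_class, "ER")
  expect_equal(back$rates, fit$rate_matrix$rates, tolerance = 1e-12)
  expect_equal(back$logL, fit$logL, tolerance = 1e-12)
})

test_that("pruning likelihood agrees with an independent implementation", {
  # cross-check against phytools' Mk likelihood machinery
  skip_if_not_installed("phytools")
  tr <- random_oracle_tree(15, seed = 51)
  col <- random_column(tr, 2, seed = 52, p_missing = 0, p_poly = 0)
  x <- stats::setNames(as.character(unlist(col)), names(col))
  pf <- phytools::fitMk(tr$phy, x, model = "ER")
  mu <- pf$rates
  ours <- prune_likelihood(tr, lapply(col, tip_prior, k = 2),
                           mk_rate_matrix("ER", 2, mu))
  expect_equal(ours, as.numeric(stats::logLik(pf)), tolerance = 1e-4)
})
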