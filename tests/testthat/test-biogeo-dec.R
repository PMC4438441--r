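test_that("dispersal matrices implement the rule weights and max rule", {
  D <- build_dispersal_matrix(quaternary_epoch())
  # multi-hop route beats the direct trans-Pacific crossing
  expect_equal(D["NorthAmerica", "Australia"], 0.1 * 0.5 * 0.5)
  expect_equal(D["NorthAmerica", "Eurasia"], 0.1)
  expect_equal(D["Eurasia", "Australia"], 0.25)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 1))

  two <- area_graph_epoch(c("X", "Y"), 0, 10,
                          data.frame(from = "X", to = "Y",
                                     class = "connected"))
  expect_equal(build_dispersal_matrix(two)["X", "Y"], 0.9)

  iso <- area_graph_epoch(c("X", "Y", "Z"), 0, 10,
                          data.frame(from = "X", to = "Y",
                                     class = "connected"))
  Diso <- build_dispersal_matrix(iso)
  expect_equal(unname(Diso["Z", c("X", "Y")]), c(0, 0))
  expect_error(area_graph_epoch(c("X", "Y"), 0, 10,
                                data.frame(from = "X", to = "Y",
                                           class = "warp")),
               "unknown separation class")
})

test_that("random graphs match the brute-force simple-path oracle", {
  classes <- names(dispersal_class_weights())
  w <- dispersal_class_weights()
  for (s in 1:6) {
    set.seed(1200 + s)
    A <- 5
    areas <- LETTERS[1:A]
    prs <- t(utils::combn(A, 2))
    df <- data.frame(from = areas[prs[, 1]], to = areas[prs[, 2]],
                     class = sample(classes, nrow(prs), replace = TRUE))
    ep <- area_graph_epoch(areas, 0, 10, df)
    D <- build_dispersal_matrix(ep)
    # oracle: enumerate every permutation-based simple path
    W <- matrix(w[ep$classes], A, A)
    diag(W) <- 0
    for (i in 1:(A - 1)) for (j in (i + 1):A) {
      best <- 0
      others <- setdiff(1:A, c(i, j))
      for (len in 0:length(others)) {
        mids <- if (len == 0) list(integer(0)) else {
          combs <- utils::combn(others, len, simplify = FALSE)
          unlist(lapply(combs, function(cm) {
            if (length(cm) == 1) list(cm)
            else apply(perms(cm), 1, identity, simplify = FALSE)
          }), recursive = FALSE)
        }
        for (mid in mids) {
          path <- c(i, mid, j)
          pr <- prod(W[cbind(path[-length(path)], path[-1])])
          best <- max(best, pr)
        }
      }
      expect_equal(D[i, j], best)
      # the path maximum dominates the best single edge
      expect_gte(D[i, j], W[i, j])
    }
  }
})

test_that("the anagenetic generator has DEC rates and zero row sums", {
  ep <- quaternary_epoch()
  m <- dec_model(ep$areas, list(ep), d = 2, e = 0.5)
  Q <- dec_generator(m, 1)
  expect_true(all(abs(rowSums(Q)) < 1e-12))
  # single-area range gains area j at d * p[i, j]
  D <- m$epochs[[1]]$D
  expect_equal(Q["NorthAmerica", "NorthAmerica+Eurasia"], 2 * D[1, 2])
  # range loss at e; single-area ranges fall to null
  expect_equal(Q["NorthAmerica", "null"], 0.5)
  expect_equal(Q["NorthAmerica+Eurasia", "Eurasia"], 0.5)
  expect_true(all(Q["null", ] == 0))

  one <- area_graph_epoch("X", 0, 10,
                          data.frame(from = character(), to = character(),
                                     class = character()))
  m1 <- dec_model("X", list(one), d = 1, e = 0)
  expect_true(all(dec_generator(m1, 1)[2, ] == 0))
})

test_that("DEC likelihood: trivial cases and stratification consistency", {
  tr <- read_newick_time_tree("(A:1,B:1);")
  one <- area_graph_epoch("X", 0, 10,
                          data.frame(from = character(), to = character(),
                                     class = character()))
  m1 <- dec_model("X", list(one), d = 0.5, e = 0)
  expect_equal(dec_likelihood(tr, list(A = 1L, B = 1L), m1), 0)
  expect_error(dec_likelihood(tr, list(A = integer(0), B = 1L), m1),
               "empty range")

  two_a <- area_graph_epoch(c("X", "Y"), 0, 0.35,
                            data.frame(from = "X", to = "Y",
                                       class = "close-islands"))
  two_b <- area_graph_epoch(c("X", "Y"), 0.35, 10,
                            data.frame(from = "X", to = "Y",
                                       class = "close-islands"))
  two <- area_graph_epoch(c("X", "Y"), 0, 10,
                          data.frame(from = "X", to = "Y",
                                     class = "close-islands"))
  m_flat <- dec_model(c("X", "Y"), list(two), d = 0.07, e = 0.03)
  m_strat <- dec_model(c("X", "Y"), list(two_a, two_b), d = 0.07, e = 0.03)
  tips <- list(A = 1L, B = 2L)
  expect_equal(dec_likelihood(tr, tips, m_strat),
               dec_likelihood(tr, tips, m_flat), tolerance = 1e-10)
})

test_that("DEC likelihood matches enumeration, stratified included", {
  two_y <- area_graph_epoch(c("X", "Y"), 0, 0.8,
                            data.frame(from = "X", to = "Y",
                                       class = "connected"))
  two_o <- area_graph_epoch(c("X", "Y"), 0.8, 50,
                            data.frame(from = "X", to = "Y",
                                       class = "pacific-class-ocean"))
  m <- dec_model(c("X", "Y"), list(two_y, two_o), d = 0.4, e = 0.15)
  for (s in 1:4) {
    tr <- random_oracle_tree(3, seed = 1300 + s)
    set.seed(1400 + s)
    tips <- stats::setNames(lapply(1:3, function(.)
      sort(sample(1:2, sample(1:2, 1)))), tr$phy$tip.label)
    expect_equal(dec_likelihood(tr, tips, m), oracle_dec(tr, tips, m),
                 tolerance = 1e-10)
  }
})

test_that("null-range absorption shrinks total nonempty mass when e > 0", {
  ep <- quaternary_epoch()
  m <- dec_model(ep$areas, list(ep), d = 0.1, e = 0.2)
  Q <- dec_generator(m, 1)
  P1 <- transition_matrix(Q, 1)
  P2 <- transition_matrix(Q, 3)
  nonnull <- 2:m$nstates
  for (si in nonnull) {
    expect_lte(sum(P2[si, nonnull]), sum(P1[si, nonnull]) + 1e-12)
  }
})

test_that("DEC rate fitting is deterministic and respects degeneracy", {
  ep <- area_graph_epoch(c("X", "Y"), 0, 1000,
                         data.frame(from = "X", to = "Y",
                                    class = "connected"))
  tr <- simulate_birth_death_tree(20, 0.2, 0, seed = 5)
  m <- dec_model(c("X", "Y"), list(ep), d = 0.05, e = 0.01)
  rr <- simulate_dec_ranges(tr, m, seed = 6)
  keep <- names(rr)[!attr(rr, "extinct")]
  tr2 <- if (length(keep) == length(rr)) tr else {
    time_tree(ape::keep.tip(tr$phy, keep),
              tip_ages = stats::setNames(
                tr$node_age[match(keep, tr$phy$tip.label)], keep))
  }
  f1 <- fit_dec(tr2, rr[keep], list(ep), c("X", "Y"))
  f2 <- fit_dec(tr2, rr[keep], list(ep), c("X", "Y"))
  expect_identical(c(f1$d, f1$e), c(f2$d, f2$e))

  same <- stats::setNames(rep(list(1L), length(keep)), keep)
  expect_warning(f3 <- fit_dec(tr2, same, list(ep), c("X", "Y"),
                               fix_e = 0), "boundary")
  expect_lt(f3$d, 1e-6)
})

test_that("ancestral range tables normalize to 100 percent", {
  tr <- read_newick_time_tree("((A:1,B:1):1,C:2);")
  one <- area_graph_epoch("X", 0, 10,
                          data.frame(from = character(), to = character(),
                                     class = character()))
  m1 <- dec_model("X", list(one), d = 0.2, e = 0)
  ar <- dec_ancestral_ranges(tr, list(A = 1L, B = 1L, C = 1L), m1)
  rng <- ar[ar$type == "range", ]
  expect_true(all(rng$label == "X"))
  expect_true(all(abs(rng$rel_prob_pct - 100) < 1e-9))

  ep <- quaternary_epoch()
  m <- dec_model(ep$areas, list(ep), d = 0.1, e = 0.05)
  set.seed(9)
  tips <- stats::setNames(lapply(1:3, function(.) sample(1:4, 1)),
                          c("A", "B", "C"))
  ar2 <- dec_ancestral_ranges(tr, tips, m)
  for (v in unique(ar2$node)) {
    expect_equal(sum(ar2$rel_prob_pct[ar2$node == v &
                                      ar2$type == "range"]), 100,
                 tolerance = 1e-6)
  }
  expect_error(dec_ancestral_ranges(tr, tips, m, node = 99), "unknown node")
})

test_that("ancestral range ranking matches the enumeration posterior", {
  two <- area_graph_epoch(c("X", "Y"), 0, 50,
                          data.frame(from = "X", to = "Y",
                                     class = "close-islands"))
  m <- dec_model(c("X", "Y"), list(two), d = 0.3, e = 0.1)
  tr <- read_newick_time_tree("(A:1,B:1.5);")
  tips <- list(A = 1L, B = 2L)
  ar <- dec_ancestral_ranges(tr, tips, m, node = 3)
  rng <- ar[ar$type == "range", ]
  # oracle: posterior over root ranges from the enumeration terms
  gens <- dec_generator(m, 1)
  P <- function(t) as.matrix(Matrix::expm(gens * t))
  PA <- P(1); PB <- P(1.5)
  ridx <- c(X = 2L, Y = 3L, `X+Y` = 4L)
  term <- function(si) {
    sp <- if (si %in% 2:3) list(c(si, si)) else {
      list(c(2L, 4L), c(4L, 2L), c(2L, 3L), c(3L, 2L),
           c(3L, 4L), c(4L, 3L), c(3L, 2L), c(2L, 3L))
    }
    # clado_splits order for X+Y: i=X -> ({X},XY),(XY,{X}),({X},{Y}),({Y},{X});
    # i=Y -> ({Y},XY),(XY,{Y}),({Y},{X}),({X},{Y})
    if (si == 4L) sp <- list(c(2L, 4L), c(4L, 2L), c(2L, 3L), c(3L, 2L),
                             c(3L, 4L), c(4L, 3L), c(3L, 2L), c(2L, 3L))
    acc <- 0
    for (pr in sp) acc <- acc + PA[pr[1], 2] * PB[pr[2], 3]
    acc / length(sp)
  }
  post <- vapply(2:4, term, numeric(1))
  post <- 100 * post / sum(post)
  got <- rng$rel_prob_pct[match(names(ridx), rng$label)]
  got[is.na(got)] <- 0
  expect_equal(got, post, tolerance = 1e-8)
})

test_that("area configs and tip-range tables round-trip", {
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c(
    "areas:",
    "  - name: NorthAmerica",
    "  - name: Eurasia",
    "  - name: IndoPacific",
    "    inhabitable: false",
    "  - name: Australia",
    "epochs:",
    "  - start_Ma: 0",
    "    end_Ma: 3",
    "    pairs:",
    "      - {from: NorthAmerica, to: Eurasia, class: atlantic-class-ocean}",
    "      - {from: Eurasia, to: IndoPacific, class: close-islands}",
    "      - {from: IndoPacific, to: Australia, class: close-islands}",
    "      - {from: NorthAmerica, to: Australia, class: pacific-class-ocean}"),
    cfgf)
  cfg <- read_area_config(cfgf)
  expect_equal(cfg$inhabitable,
               c("NorthAmerica", "Eurasia", "Australia"))
  D <- build_dispersal_matrix(cfg$epochs[[1]])
  # waypoint islands still carry the multi-hop route
  expect_equal(D["NorthAmerica", "Australia"], 0.025)

  trf <- tempfile()
  writeLines(c("taxon\tareas", "A\tNorthAmerica", "B\tEurasia,Australia"),
             trf)
  tr <- read_tip_ranges(trf, cfg$inhabitable)
  expect_equal(tr$A, 1L)
  expect_equal(tr$B, c(2L, 3L))
  expect_error(read_tip_ranges(trf, c("Eurasia")), "unknown area")
})
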