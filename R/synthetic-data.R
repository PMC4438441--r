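#' Simulate a birth-death time tree with fossil tips
#'
#' Constant-rate forward birth-death simulation conditioned on a given
#' number of extant tips: lineages branch at rate `lambda` and die at
#' rate `mu`; the clock stops at a random time after the extant count
#' first reaches `n_tips` (before the next event), so terminal branches
#' have positive length. Extinct lineages are retained as fossil tips,
#' either each independently with probability `fossil_frac` or as an
#' exact count via `n_fossils`; a fossil tip's age is its extinction
#' time. All other extinct lineages are pruned. Reproducible by seed.
#'
#' @param n_tips Number of extant tips required (>= 2).
#' @param lambda Speciation rate (per Myr); `lambda > mu`.
#' @param mu Extinction rate (per Myr, >= 0).
#' @param fossil_frac Independent retention probability per extinct
#'   lineage.
#' @param n_fossils Optional exact number of fossil tips to retain
#'   (overrides `fossil_frac`; simulation retries until at least this
#'   many extinct lineages exist).
#' @param seed Integer seed.
#' @param max_attempts Bounded retries before giving up.
#' @return A [time_tree()]; extant tips are labelled `t1, t2, ...` and
#'   fossil tips `f1, f2, ...`.
#' @export
simulate_birth_death_tree <- function(n_tips, lambda, mu = 0,
                                      fossil_frac = 0, n_fossils = NULL,
                                      seed = NULL, max_attempts = 1000) {
  if (!(lambda > mu && mu >= 0)) stop2("need lambda > mu >= 0")
  if (n_tips < 2) stop2("n_tips must be >= 2")
  with_seed(seed, {
    for (att in seq_len(max_attempts)) {
      sim <- bd_forward(n_tips, lambda, mu)
      if (is.null(sim)) next
      extinct <- which(sim$died & sim$is_tip)
      if (!is.null(n_fossils)) {
        if (length(extinct) < n_fossils) next
        fossils <- if (n_fossils == 0) integer(0)
                   else sort(sample(extinct, n_fossils))
      } else {
        fossils <- extinct[stats::runif(length(extinct)) < fossil_frac]
      }
      tree <- bd_build_tree(sim, fossils)
      if (!is.null(tree)) return(tree)
    }
    stop2("could not meet the requested tip condition after ",
          max_attempts, " attempts")
  })
}

# One forward pass; returns lineage bookkeeping or NULL on extinction.
bd_forward <- function(n_tips, lambda, mu) {
  parent <- c(NA_integer_); btime <- c(0); dtime <- c(NA_real_)
  died <- c(FALSE)
  alive <- 1L
  t <- 0
  nmax <- 50 * n_tips + 1000
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0) return(NULL)
    rate <- n_alive * (lambda + mu)
    dt <- stats::rexp(1, rate)
    if (n_alive == n_tips && length(parent) > 1) {
      # stop before the next event; survivors become extant tips
      t_end <- t + dt
      dtime[alive] <- t_end
      died[alive] <- FALSE
      is_tip <- rep(TRUE, length(parent))
      has_kids <- unique(parent[!is.na(parent)])
      is_tip[has_kids] <- FALSE
      return(list(parent = parent, btime = btime, dtime = dtime,
                  died = died, t_end = t_end, is_tip = is_tip,
                  extant = alive))
    }
    t <- t + dt
    i <- alive[sample.int(n_alive, 1)]
    if (stats::runif(1) < lambda / (lambda + mu)) {
      # birth: lineage i splits into two daughters
      dtime[i] <- t; died[i] <- FALSE
      parent <- c(parent, i, i)
      btime <- c(btime, t, t)
      dtime <- c(dtime, NA_real_, NA_real_)
      died <- c(died, FALSE, FALSE)
      alive <- c(setdiff(alive, i), length(parent) - 1L, length(parent))
    } else {
      dtime[i] <- t; died[i] <- TRUE
      alive <- setdiff(alive, i)
    }
    if (length(parent) > nmax) return(NULL)
  }
}

# Assemble the sampled tree (extant + chosen fossils) as a time_tree.
bd_build_tree <- function(sim, fossils) {
  keep_tips <- sort(c(sim$extant, fossils))
  if (length(keep_tips) < 2) return(NULL)
  labels <- character(length(sim$parent))
  labels[sim$extant] <- paste0("t", seq_along(sim$extant))
  if (length(fossils) > 0) labels[fossils] <- paste0("f", seq_along(fossils))
  kids <- vector("list", length(sim$parent))
  for (i in seq_along(sim$parent)) {
    p <- sim$parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  nw <- function(i) {
    len <- sim$dtime[i] - sim$btime[i]
    if (sim$is_tip[i]) paste0(labels[i], ":", format(len, digits = 15))
    else paste0("(", nw(kids[[i]][1]), ",", nw(kids[[i]][2]), "):",
                format(len, digits = 15))
  }
  root_lin <- 1L
  if (sim$is_tip[root_lin]) return(NULL)
  txt <- paste0("(", nw(kids[[root_lin]][1]), ",",
                nw(kids[[root_lin]][2]), ");")
  phy <- ape::read.tree(text = txt)
  phy <- ape::keep.tip(phy, labels[keep_tips])
  ages <- stats::setNames(sim$t_end - sim$dtime[keep_tips],
                          labels[keep_tips])
  ages[abs(ages) < 1e-12] <- 0
  time_tree(phy, tip_ages = ages)
}

#' Simulate one Mk character on a time tree
#'
#' The root state is drawn from `pi` and states evolve down each branch
#' under `exp(Q t)`.
#'
#' @param tree A [time_tree()].
#' @param Q A [mk_rate_matrix()] or generator matrix.
#' @param pi Root frequencies (default those in `Q`, else equal).
#' @param seed Integer seed.
#' @return Named list of monomorphic cells (0-based states) per tip.
#' @export
simulate_mk_character <- function(tree, Q, pi = NULL, seed = NULL) {
  Qm <- as_generator(Q)
  k <- nrow(Qm)
  pi <- pi %||% (if (inherits(Q, "rate_matrix")) Q$pi else rep(1 / k, k))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  with_seed(seed, {
    P <- edge_prob_list(phy, Qm)
    state <- integer(nnode)
    state[root_node(tree)] <- sample.int(k, 1, prob = pi)
    po <- ape::reorder.phylo(phy, "postorder")
    for (ei in rev(seq_len(nrow(po$edge)))) {
      p <- po$edge[ei, 1]; ch <- po$edge[ei, 2]
      which_edge <- which(phy$edge[, 1] == p & phy$edge[, 2] == ch)
      state[ch] <- sample.int(k, 1, prob = P[[which_edge]][state[p], ])
    }
    stats::setNames(lapply(state[seq_len(ntip)], function(s) s - 1L),
                    phy$tip.label)
  })
}

#' Inject missingness and polymorphism into a character column
#'
#' Randomly chosen cells become missing; other randomly chosen cells
#' become two-state polymorphic sets that always contain the original
#' true state (for binary characters the polymorphic set is necessarily
#' both states).
#'
#' @param column Named list of monomorphic cells.
#' @param missing_frac Fraction of cells to blank out.
#' @param polymorphic_frac Fraction of cells to make polymorphic.
#' @param k Number of states.
#' @param seed Integer seed.
#' @return Modified column.
#' @export
inject_uncertainty <- function(column, missing_frac, polymorphic_frac,
                               k, seed = NULL) {
  if (missing_frac < 0 || polymorphic_frac < 0 ||
      missing_frac + polymorphic_frac > 1)
    stop2("fractions must be >= 0 and sum to <= 1")
  with_seed(seed, {
    u <- stats::runif(length(column))
    out <- column
    for (i in seq_along(column)) {
      if (u[i] < missing_frac) {
        out[[i]] <- NA
      } else if (u[i] < missing_frac + polymorphic_frac) {
        true <- column[[i]][1]
        other <- setdiff(0:(k - 1), true)
        out[[i]] <- sort(c(true, if (length(other) == 1) other
                           else sample(other, 1)))
      }
    }
    out
  })
}

#' Simulate tip ranges under a (time-stratified) DEC model
#'
#' The root range is drawn uniformly from the allowed nonempty ranges;
#' anagenesis follows the epoch-stratified generator along each branch
#' and cladogenesis draws one allowed split (equal weights) at each
#' node. Lineages whose range hits the absorbing null range are recorded
#' as extinct.
#'
#' @param tree A [time_tree()] (binary or with polytomies, which are
#'   treated as simultaneous multi-way sympatry of the drawn split).
#' @param model A [dec_model()].
#' @param seed Integer seed.
#' @return Named list of area-index vectors per tip (empty vector =
#'   lineage extinct in the simulation), with attribute `extinct`.
#' @export
simulate_dec_ranges <- function(tree, model, seed = NULL) {
  btree <- dec_prepare_tree(tree)
  phy <- btree$phy
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  with_seed(seed, {
    gens <- lapply(seq_along(model$epochs), function(i)
      dec_generator(model, i))
    state <- integer(nnode)
    state[ntip + 1L] <- sample(2:model$nstates, 1)
    kids <- child_list(phy)
    for (p in rev(postorder_nodes(phy))) {
      s <- state[p]
      # cladogenesis
      sp <- clado_splits(model, s)
      pair <- if (length(sp) == 0) c(1L, 1L)  # null: descendants extinct
              else sp[[sample.int(length(sp), 1)]]
      for (ci in seq_along(kids[[p]])) {
        ch <- kids[[p]][ci]
        s0 <- pair[min(ci, 2)]
        state[ch] <- dec_sim_branch(model, gens, s0,
                                    btree$node_age[p], btree$node_age[ch])
      }
    }
    out <- lapply(seq_len(ntip), function(i) model$ranges[[state[i]]])
    names(out) <- phy$tip.label
    attr(out, "extinct") <- vapply(out, function(r) length(r) == 0,
                                   logical(1))
    out
  })
}

# Gillespie simulation of the range CTMC from age_parent down to
# age_child, switching generators at epoch boundaries.
dec_sim_branch <- function(model, gens, s0, age_parent, age_child) {
  s <- s0
  age <- age_parent
  while (age > age_child + 1e-12) {
    ei <- which(vapply(model$epochs, function(e)
      age > e$young + 1e-12 && age <= e$old + 1e-9, logical(1)))[1]
    if (is.na(ei)) ei <- 1L
    seg_end <- max(model$epochs[[ei]]$young, age_child)
    Q <- gens[[ei]]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) { age <- seg_end; break }
      dt <- stats::rexp(1, rate)
      if (age - dt <= seg_end) { age <- seg_end; break }
      age <- age - dt
      w <- Q[s, ]; w[s] <- 0
      s <- sample.int(model$nstates, 1, prob = w)
    }
  }
  s
}

#' Simulate a full comparative study dataset
#'
#' Emulates the structure of a combined-evidence ancestral-state study:
#' three alternative time-calibrated topologies over one taxon set
#' (extant plus fossil tips), a matrix of discrete ecological characters
#' evolved under Mk models with injected missingness and polymorphism,
#' and two nested target clades for reconstruction. One master seed
#' hierarchically derives every component stream.
#'
#' @param seed Master seed.
#' @param n_extant Number of extant taxa.
#' @param n_fossils Number of fossil tips per topology.
#' @param lambda,mu Birth-death rates (per Myr).
#' @param char_k Integer vector of state counts, one per character.
#' @param rate Mk rate used to evolve each character (per Myr).
#' @param missing_frac,polymorphic_frac Uncertainty injection rates.
#' @return List with `topologies` (named list of [time_tree()]),
#'   `characters` (a [character_matrix()]), and `targets` (named list of
#'   tip-label sets for MRCA lookup).
#' @export
simulate_study_dataset <- function(seed = 1,
                                   n_extant = 58, n_fossils = 15,
                                   lambda = 0.06, mu = 0.03,
                                   char_k = c(2, 3, 3, 2, 3, 2, 2, 4, 3, 2, 4),
                                   rate = 0.02,
                                   missing_frac = 0.15,
                                   polymorphic_frac = 0.05) {
  topo_names <- c("genetic", "unconstrained", "constrained")
  topologies <- lapply(topo_names, function(nm) {
    nf <- if (nm == "genetic") 0 else n_fossils
    simulate_birth_death_tree(n_extant, lambda, mu, n_fossils = nf,
                              seed = derive_seed(seed, "tree", nm))
  })
  names(topologies) <- topo_names
  gen_tree <- topologies$unconstrained
  taxa <- gen_tree$phy$tip.label
  cells <- vector("list", length(char_k))
  for (j in seq_along(char_k)) {
    Q <- mk_rate_matrix("ER", char_k[j], rate)
    col <- simulate_mk_character(gen_tree, Q,
                                 seed = derive_seed(seed, "char", j))
    col <- inject_uncertainty(col, missing_frac, polymorphic_frac,
                              k = char_k[j],
                              seed = derive_seed(seed, "noise", j))
    cells[[j]] <- col[taxa]
  }
  cm <- character_matrix(taxa, cells, k = char_k,
                         char_ids = paste0("char", seq_along(char_k)))
  # target clades: the larger root subclade of the generating topology
  # (its MRCA exists on every topology), and the full tip set
  root_kids <- child_list(gen_tree$phy)[[root_node(gen_tree)]]
  clades <- lapply(root_kids, function(v) {
    if (v <= n_tips(gen_tree)) gen_tree$phy$tip.label[v]
    else ape::extract.clade(gen_tree$phy, v)$tip.label
  })
  crown <- clades[[which.max(lengths(clades))]]
  crown <- intersect(crown, grep("^t", taxa, value = TRUE))
  # characters are shared across topologies; the genetic topology lacks
  # fossil tips, so targets use extant labels only
  list(topologies = topologies,
       characters = cm,
       targets = list(crown = crown,
                      total_group = grep("^t", taxa, value = TRUE)))
}
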