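# Independent brute-force oracles, deliberately kept free of the package's
# pruning/DP code paths: exhaustive enumeration over complete node-state
# assignments, with transition probabilities from Matrix::expm only.

# all k^n assignments as an (k^n x n) matrix of states 1..k
all_assignments <- function(k, n) {
  as.matrix(expand.grid(rep(list(seq_len(k)), n)))
}

oracle_edge_probs <- function(phy, Q) {
  lapply(phy$edge.length, function(t) {
    if (t == 0) diag(nrow(Q)) else as.matrix(Matrix::expm(Q * t))
  })
}

# Joint enumeration likelihood: sum over assignments of ALL nodes of
# pi(root) * prod_edges P * prod_tips prior.
oracle_mk_loglik <- function(tree, tip_priors, Q, pi) {
  phy <- tree$phy
  k <- nrow(Q)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  P <- oracle_edge_probs(phy, Q)
  A <- all_assignments(k, nn)
  w <- pi[A[, ntip + 1]]
  for (ei in seq_len(nrow(phy$edge))) {
    w <- w * P[[ei]][cbind(A[, phy$edge[ei, 1]], A[, phy$edge[ei, 2]])]
  }
  tp <- tip_priors[phy$tip.label, , drop = FALSE]
  for (i in seq_len(ntip)) w <- w * tp[i, A[, i]]
  log(sum(w))
}

# per-node marginal state probabilities from the same enumeration
oracle_mk_marginal <- function(tree, tip_priors, Q, pi) {
  phy <- tree$phy
  k <- nrow(Q)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  P <- oracle_edge_probs(phy, Q)
  A <- all_assignments(k, nn)
  w <- pi[A[, ntip + 1]]
  for (ei in seq_len(nrow(phy$edge)))
    w <- w * P[[ei]][cbind(A[, phy$edge[ei, 1]], A[, phy$edge[ei, 2]])]
  tp <- tip_priors[phy$tip.label, , drop = FALSE]
  for (i in seq_len(ntip)) w <- w * tp[i, A[, i]]
  out <- matrix(0, nn, k)
  for (v in seq_len(nn)) for (s in seq_len(k))
    out[v, s] <- sum(w[A[, v] == s])
  out / rowSums(out)
}

# exhaustive parsimony: minimum changes and per-node MP-state unions,
# enumerating internal assignments and resolutions of tip state sets
oracle_parsimony <- function(tree, sets, k) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  A <- all_assignments(k, nn)
  sets1 <- lapply(sets[phy$tip.label], function(s) s + 1L)
  ok <- rep(TRUE, nrow(A))
  for (i in seq_len(ntip)) ok <- ok & (A[, i] %in% sets1[[i]])
  A <- A[ok, , drop = FALSE]
  cost <- rep(0, nrow(A))
  for (ei in seq_len(nrow(phy$edge)))
    cost <- cost + (A[, phy$edge[ei, 1]] != A[, phy$edge[ei, 2]])
  mc <- min(cost)
  best <- A[cost == mc, , drop = FALSE]
  list(min_changes = mc,
       node_sets = lapply(seq_len(nn), function(v)
         sort(unique(best[, v])) - 1L))
}

# brute-force stratified DEC likelihood on a binary tree: enumeration
# over internal-node ranges and ordered cladogenetic splits
oracle_dec <- function(tree, tip_ranges, model) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  nR <- model$nstates
  gens <- lapply(seq_along(model$epochs), function(i)
    paleoasr::dec_generator(model, i))
  branch_P <- function(a_child, a_parent) {
    if (a_parent - a_child <= 1e-12) return(diag(nR))
    bounds <- sort(unique(unlist(lapply(model$epochs, function(e)
      c(e$young, e$old)))))
    cuts <- bounds[bounds > a_child + 1e-12 & bounds < a_parent - 1e-12]
    pts <- c(a_child, cuts, a_parent)
    P <- diag(nR)
    for (s in rev(seq_len(length(pts) - 1))) {
      mid <- (pts[s] + pts[s + 1]) / 2
      ei <- which(vapply(model$epochs, function(e)
        mid >= e$young & mid <= e$old, logical(1)))[1]
      P <- P %*% as.matrix(Matrix::expm(gens[[ei]] * (pts[s + 1] - pts[s])))
    }
    P
  }
  P <- lapply(seq_len(nrow(phy$edge)), function(ei)
    branch_P(tree$node_age[phy$edge[ei, 2]],
             tree$node_age[phy$edge[ei, 1]]))
  ridx <- function(r) {
    r <- sort(r)
    which(vapply(model$ranges, function(x)
      length(x) == length(r) && all(x == r), logical(1)))
  }
  splits_of <- function(si) {
    r <- model$ranges[[si]]
    if (length(r) == 0) return(list())
    if (length(r) == 1) return(list(c(si, si)))
    out <- list()
    for (i in r) {
      out <- c(out, list(c(ridx(i), si), c(si, ridx(i)),
                         c(ridx(i), ridx(setdiff(r, i))),
                         c(ridx(setdiff(r, i)), ridx(i))))
    }
    out
  }
  kids <- lapply(seq_len(nn), function(v) phy$edge[phy$edge[, 1] == v, 2])
  edge_of <- function(ch) which(phy$edge[, 2] == ch)
  tipidx <- vapply(seq_len(ntip), function(i)
    ridx(tip_ranges[[phy$tip.label[i]]]), integer(1))
  # recursive enumeration of subtree likelihood given state at top of node
  subtree_lik <- function(v, s) {
    if (v <= ntip) return(as.numeric(s == tipidx[v]))
    sp <- splits_of(s)
    if (length(sp) == 0) return(0)
    ch <- kids[[v]]
    acc <- 0
    for (pr in sp) {
      left <- 0; right <- 0
      for (s2 in seq_len(nR)) {
        left <- left + P[[edge_of(ch[1])]][pr[1], s2] * subtree_lik(ch[1], s2)
        right <- right + P[[edge_of(ch[2])]][pr[2], s2] * subtree_lik(ch[2], s2)
      }
      acc <- acc + left * right
    }
    acc / length(sp)
  }
  root <- ntip + 1L
  tot <- 0
  for (s in 2:nR) tot <- tot + subtree_lik(root, s)
  as.numeric(log(tot / (nR - 1)))
}

# Independent even-spacing age oracle: an explicit-stack preorder walk
# that tracks, for every node, the pending chain of undated ancestors
# since the last dated one; when a dated node is reached the chain is
# spaced evenly between the two dated endpoints. Nodes dated by an
# earlier branch of the walk act as chain endpoints for later branches.
oracle_bladj_ages <- function(phy, fixed, root_age) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  age <- rep(NA_real_, nn)
  age[seq_len(ntip)] <- 0
  labels <- c(phy$tip.label, phy$node.label %||% rep(NA, phy$Nnode))
  for (nm in names(fixed)) age[which(labels == nm)[1]] <- fixed[[nm]]
  if (is.na(age[ntip + 1])) age[ntip + 1] <- root_age
  oldest <- function(v) {
    below <- v
    frontier <- v
    repeat {
      frontier <- phy$edge[phy$edge[, 1] %in% frontier, 2]
      if (length(frontier) == 0) break
      below <- c(below, frontier)
    }
    suppressWarnings(max(age[below], na.rm = TRUE))
  }
  orig_oldest <- vapply(seq_len(nn), oldest, numeric(1))
  children <- function(v) {
    ks <- phy$edge[phy$edge[, 1] == v, 2]
    ks[order(-orig_oldest[ks])]
  }
  # stack entries: node, dated ancestor, chain of undated nodes between
  stack <- lapply(rev(children(ntip + 1)), function(ch)
    list(v = ch, anc = ntip + 1, chain = integer(0)))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top$v
    # an earlier branch may have dated a prefix of the pending chain;
    # the deepest such node becomes the effective ancestor
    done <- which(!is.na(age[top$chain]))
    if (length(done) > 0) {
      top$anc <- top$chain[max(done)]
      top$chain <- top$chain[-seq_len(max(done))]
    }
    if (!is.na(age[v])) {
      if (length(top$chain) > 0) {
        m <- length(top$chain)
        age[top$chain] <- age[top$anc] -
          (age[top$anc] - age[v]) * seq_len(m) / (m + 1)
      }
      for (ch in rev(children(v)))
        stack[[length(stack) + 1]] <- list(v = ch, anc = v,
                                           chain = integer(0))
    } else {
      # re-examine v after its first child path dates it
      for (ch in rev(children(v)))
        stack[[length(stack) + 1]] <- list(v = ch, anc = top$anc,
                                           chain = c(top$chain, v))
    }
  }
  age
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of a vector, one per row
perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) out <- rbind(out, cbind(x[i], perms(x[-i])))
  out
}

is_missing_cell_oracle <- function(cell) length(cell) == 1 && is.na(cell[1])

# random rooted time tree for oracle instances, built from ape::rtree so
# it shares nothing with the package's birth-death simulator
random_oracle_tree <- function(n_tips, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_tips)
  phy$edge.length <- phy$edge.length + 0.05
  time_tree(phy)
}

random_column <- function(tree, k, seed, p_missing = 0.15, p_poly = 0.15) {
  set.seed(seed)
  cells <- lapply(tree$phy$tip.label, function(.) {
    u <- stats::runif(1)
    if (u < p_missing) NA
    else if (u < p_missing + p_poly && k > 1)
      sort(sample(0:(k - 1), 2))
    else sample(0:(k - 1), 1)
  })
  stats::setNames(cells, tree$phy$tip.label)
}

quaternary_epoch <- function() {
  area_graph_epoch(
    c("NorthAmerica", "Eurasia", "IndoPacific", "Australia"), 0, 3,
    data.frame(
      from = c("NorthAmerica", "Eurasia", "IndoPacific", "NorthAmerica"),
      to = c("Eurasia", "IndoPacific", "Australia", "Australia"),
      class = c("atlantic-class-ocean", "close-islands",
                "close-islands", "pacific-class-ocean")))
}
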