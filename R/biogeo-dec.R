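#' Rule-based dispersal classes
#'
#' Relative dispersal weights for the separation class between two
#' landmasses in a given epoch: connected landmasses 0.9; close islands
#' 0.5; an ocean of Atlantic/Indian/Tethys scale 0.1; an ocean of Pacific
#' scale 0.01; no route 0.
#'
#' @return Named numeric vector of class weights.
#' @export
dispersal_class_weights <- function() {
  c("connected" = 0.9,
    "close-islands" = 0.5,
    "atlantic-class-ocean" = 0.1,
    "pacific-class-ocean" = 0.01,
    "none" = 0)
}

#' Define the area graph for one epoch
#'
#' @param areas Character vector of area labels (landmasses; may include
#'   waypoint islands that are not themselves inhabitable range areas).
#' @param start_Ma Young bound of the epoch (Ma).
#' @param end_Ma Old bound of the epoch (Ma); must exceed `start_Ma`.
#' @param classes Data frame with columns `from`, `to`, `class` giving
#'   the separation class of each area pair with a route; unlisted pairs
#'   are `"none"`. Classes are symmetric.
#' @return An object of class `area_graph_epoch`.
#' @export
area_graph_epoch <- function(areas, start_Ma, end_Ma, classes) {
  if (end_Ma <= start_Ma) stop2("epoch old bound must exceed young bound")
  w <- dispersal_class_weights()
  A <- length(areas)
  cls <- matrix("none", A, A, dimnames = list(areas, areas))
  if (nrow(classes) > 0) {
    for (r in seq_len(nrow(classes))) {
      a <- classes$from[r]; b <- classes$to[r]; cl <- classes$class[r]
      if (!cl %in% names(w)) stop2("unknown separation class: ", cl)
      if (!a %in% areas || !b %in% areas)
        stop2("unknown area in pair: ", a, " - ", b)
      cls[a, b] <- cls[b, a] <- cl
    }
  }
  structure(list(areas = areas, start_Ma = start_Ma, end_Ma = end_Ma,
                 classes = cls),
            class = "area_graph_epoch")
}

#' Build the relative dispersal matrix for an epoch
#'
#' Each area pair's relative dispersal probability is the maximum over
#' all simple paths of the product of edge weights (multi-step routes
#' multiply their step probabilities; when several routes exist the
#' highest resulting probability is used). Pairs with no route get 0; the
#' diagonal is 1. Exhaustive simple-path enumeration (intended for the
#' handful of landmasses of paleogeographic reconstructions; at most 8).
#'
#' @param epoch An [area_graph_epoch()].
#' @return Symmetric matrix of relative dispersal probabilities in
#'   `[0, 1]` with unit diagonal.
#' @export
build_dispersal_matrix <- function(epoch) {
  stopifnot(inherits(epoch, "area_graph_epoch"))
  areas <- epoch$areas
  A <- length(areas)
  if (A > 8) stop2("more than 8 areas; reduce the graph")
  w <- dispersal_class_weights()
  W <- matrix(w[epoch$classes], A, A, dimnames = list(areas, areas))
  diag(W) <- 0
  best <- matrix(0, A, A, dimnames = list(areas, areas))
  diag(best) <- 1
  # depth-first enumeration of simple paths from each source
  for (src in seq_len(A)) {
    visit <- function(v, prob, used) {
      for (u in seq_len(A)) {
        if (used[u] || W[v, u] <= 0) next
        p2 <- prob * W[v, u]
        if (p2 > best[src, u]) best[src, u] <<- p2
        used2 <- used; used2[u] <- TRUE
        visit(u, p2, used2)
      }
    }
    used <- rep(FALSE, A); used[src] <- TRUE
    visit(src, 1, used)
  }
  diag(best) <- 1
  best
}

#' Dispersal-Extinction-Cladogenesis model
#'
#' Geographic ranges are nonempty subsets of the inhabitable areas
#' (optionally capped in size), plus the absorbing empty "null" range.
#' Anagenesis: a range gains area j at rate `d` times the summed relative
#' dispersal probabilities from its occupied areas to j (epoch-specific),
#' and loses any occupied area at rate `e` (a single-area range falls
#' into the null range). Cladogenesis at nodes follows the classical
#' allowed-split set with equal weights.
#'
#' @param areas Inhabitable area labels (the range state space is built
#'   over these).
#' @param epochs List of [area_graph_epoch()] objects tiling
#'   `[0, root age]`. Their graphs may contain extra waypoint areas; the
#'   dispersal matrices are restricted to `areas` after max-product path
#'   evaluation, so waypoints still boost multi-step routes.
#' @param d Dispersal base rate (per Myr).
#' @param e Local extinction rate (per Myr).
#' @param max_range_size Optional cap on range size (required when more
#'   than 8 areas are inhabitable).
#' @return An object of class `dec_model`.
#' @export
dec_model <- function(areas, epochs, d, e, max_range_size = NULL) {
  A <- length(areas)
  if (A > 8 && is.null(max_range_size))
    stop2("more than 8 areas: supply `max_range_size` to cap the ",
          "range state space")
  if (d < 0 || e < 0) stop2("d and e must be >= 0")
  cap <- max_range_size %||% A
  ranges <- list(integer(0))  # null range first
  for (sz in seq_len(cap)) {
    combs <- utils::combn(A, sz, simplify = FALSE)
    ranges <- c(ranges, combs)
  }
  labels <- c("null", vapply(ranges[-1], function(r)
    paste(areas[r], collapse = "+"), character(1)))
  eps <- lapply(epochs, function(ep) {
    D <- build_dispersal_matrix(ep)[areas, areas, drop = FALSE]
    list(young = ep$start_Ma, old = ep$end_Ma, D = D)
  })
  ord <- order(vapply(eps, `[[`, numeric(1), "young"))
  eps <- eps[ord]
  for (i in seq_along(eps)[-1]) {
    if (abs(eps[[i]]$young - eps[[i - 1]]$old) > 1e-9)
      stop2("epochs must tile time without gaps or overlap")
  }
  structure(list(areas = areas, A = A, ranges = ranges,
                 range_labels = labels, nstates = length(ranges),
                 d = d, e = e, epochs = eps, cap = cap),
            class = "dec_model")
}

#' @export
print.dec_model <- function(x, ...) {
  cat(sprintf("dec_model: %d areas, %d range states, %d epoch(s), d=%.4g, e=%.4g\n",
              x$A, x$nstates, length(x$epochs), x$d, x$e))
  invisible(x)
}

range_index <- function(model, r) {
  r <- sort(r)
  for (i in seq_along(model$ranges)) {
    if (length(model$ranges[[i]]) == length(r) &&
        all(model$ranges[[i]] == r)) return(i)
  }
  NA_integer_
}

#' Anagenetic generator over range states for one epoch
#'
#' @param model A [dec_model()].
#' @param epoch_i Epoch index (youngest first).
#' @return Square generator matrix over the range state space (null range
#'   absorbing; rows sum to zero).
#' @export
dec_generator <- function(model, epoch_i = 1) {
  D <- model$epochs[[epoch_i]]$D
  n <- model$nstates
  Q <- matrix(0, n, n, dimnames = list(model$range_labels,
                                       model$range_labels))
  for (si in seq_len(n)) {
    r <- model$ranges[[si]]
    if (length(r) == 0) next  # null absorbing
    for (j in setdiff(seq_len(model$A), r)) {
      tgt <- range_index(model, c(r, j))
      if (is.na(tgt)) next  # beyond the range-size cap
      Q[si, tgt] <- Q[si, tgt] + model$d * sum(D[r, j])
    }
    for (i in r) {
      tgt <- if (length(r) == 1) 1L else range_index(model, setdiff(r, i))
      Q[si, tgt] <- Q[si, tgt] + model$e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Ordered allowed daughter-range pairs for a parent range (indices into
# the model's range list): single-area ranges duplicate sympatrically;
# wider ranges allow peripheral-isolate (subset) sympatry and vicariance,
# all ordered scenarios equally weighted.
clado_splits <- function(model, si) {
  r <- model$ranges[[si]]
  if (length(r) == 0) return(list())
  if (length(r) == 1) return(list(c(si, si)))
  out <- list()
  for (i in r) {
    one <- range_index(model, i)
    rest <- range_index(model, setdiff(r, i))
    out <- c(out, list(c(one, si), c(si, one)))
    if (!is.na(rest)) out <- c(out, list(c(one, rest), c(rest, one)))
  }
  out
}

# Transition matrix along a branch spanning [age_child, age_parent],
# split at epoch boundaries; forward-time (old -> young) product.
dec_branch_prob <- function(model, tp_fns, age_child, age_parent) {
  n <- model$nstates
  if (age_parent - age_child <= 1e-12) return(diag(n))
  bounds <- sort(unique(unlist(lapply(model$epochs, function(e)
    c(e$young, e$old)))))
  cuts <- bounds[bounds > age_child + 1e-12 & bounds < age_parent - 1e-12]
  pts <- c(age_child, cuts, age_parent)
  P <- diag(n)
  # oldest segment first
  for (s in rev(seq_len(length(pts) - 1))) {
    lo <- pts[s]; hi <- pts[s + 1]
    mid <- (lo + hi) / 2
    ei <- which(vapply(model$epochs, function(e)
      mid >= e$young - 1e-12 && mid <= e$old + 1e-12, logical(1)))[1]
    if (is.na(ei)) stop2("branch segment at ", mid,
                         " Ma falls outside the epoch tiling")
    P <- P %*% tp_fns[[ei]](hi - lo)
  }
  P
}

dec_tp_fns <- function(model) {
  lapply(seq_along(model$epochs), function(i)
    transition_prob_fn(dec_generator(model, i)))
}

# Binarize a time tree for DEC (polytomies -> zero-duration virtual
# splits) and carry the age bookkeeping through.
dec_prepare_tree <- function(tree) {
  phy <- tree$phy
  if (ape::is.binary(phy)) return(tree)
  phy2 <- ape::multi2di(phy, random = FALSE)
  phy2$edge.length[is.na(phy2$edge.length)] <- 0
  time_tree(phy2, tip_ages = stats::setNames(
    tree$node_age[seq_len(n_tips(tree))], phy$tip.label))
}

# Inside (pruning) pass over range states with cladogenesis. Returns
# per-node scaled partials and the pieces needed for marginals.
dec_inside <- function(tree, tip_ranges, model) {
  btree <- dec_prepare_tree(tree)
  phy <- btree$phy
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  n <- model$nstates
  tp_fns <- dec_tp_fns(model)
  # tip indicators
  L <- matrix(0, nnode, n)
  for (i in seq_len(ntip)) {
    r <- tip_ranges[[phy$tip.label[i]]]
    if (is.null(r)) stop2("no range for tip ", phy$tip.label[i])
    if (length(r) == 0) stop2("empty range for tip ", phy$tip.label[i])
    ri <- range_index(model, r)
    if (is.na(ri)) stop2("tip range outside the state space for ",
                         phy$tip.label[i])
    L[i, ri] <- 1
  }
  kids <- child_list(phy)
  P <- vector("list", nrow(phy$edge))
  for (ei in seq_len(nrow(phy$edge))) {
    p <- phy$edge[ei, 1]; ch <- phy$edge[ei, 2]
    P[[ei]] <- dec_branch_prob(model, tp_fns,
                               btree$node_age[ch], btree$node_age[p])
  }
  eidx <- vector("list", nnode)
  for (ei in seq_len(nrow(phy$edge))) {
    p <- phy$edge[ei, 1]
    eidx[[p]] <- c(eidx[[p]], ei)
  }
  splits <- lapply(seq_len(n), function(si) clado_splits(model, si))
  logsc <- numeric(nnode)
  for (v in postorder_nodes(phy)) {
    es <- eidx[[v]]
    stopifnot(length(es) == 2)
    chL <- phy$edge[es[1], 2]; chR <- phy$edge[es[2], 2]
    DL <- as.vector(P[[es[1]]] %*% L[chL, ])
    DR <- as.vector(P[[es[2]]] %*% L[chR, ])
    part <- numeric(n)
    for (si in seq_len(n)) {
      sp <- splits[[si]]
      if (length(sp) == 0) next
      acc <- 0
      for (pr in sp) acc <- acc + DL[pr[1]] * DR[pr[2]]
      part[si] <- acc / length(sp)
    }
    m <- max(part)
    if (m <= 0) {
      L[v, ] <- 0; logsc[v] <- -Inf
    } else {
      L[v, ] <- part / m
      logsc[v] <- logsc[chL] + logsc[chR] + log(m)
    }
  }
  root <- ntip + 1L
  nonempty <- 2:n
  lik <- sum(L[root, nonempty]) / length(nonempty)
  logL <- if (lik <= 0 || !is.finite(logsc[root])) -Inf
          else log(lik) + logsc[root]
  list(logL = logL, L = L, logsc = logsc, P = P, eidx = eidx,
       splits = splits, btree = btree, root = root, n = n)
}

#' DEC log-likelihood of tip ranges on a time-calibrated tree
#'
#' Pruning over range states. Branches crossing epoch boundaries are cut
#' at each boundary and use the corresponding epoch's generator on each
#' segment. Cladogenetic transitions at internal nodes allow sympatry for
#' single-area ranges and, for wider ranges, peripheral-isolate sympatry
#' and vicariance, all ordered splits equally weighted. The root range
#' distribution is flat over the allowed nonempty ranges. Polytomies are
#' resolved internally into zero-duration virtual binary splits.
#'
#' @param tree A [time_tree()].
#' @param tip_ranges Named list: per tip, an integer vector of occupied
#'   area indices (1-based into `model$areas`).
#' @param model A [dec_model()].
#' @return Log-likelihood.
#' @export
dec_likelihood <- function(tree, tip_ranges, model) {
  dec_inside(tree, tip_ranges, model)$logL
}

#' Maximum-likelihood DEC rates
#'
#' Maximizes [dec_likelihood()] over the dispersal rate `d` and
#' extinction rate `e` on the log scale from a fixed, deterministic set
#' of starting points.
#'
#' @param tree A [time_tree()].
#' @param tip_ranges Named list of tip area-index vectors.
#' @param epochs List of [area_graph_epoch()] (as for [dec_model()]).
#' @param areas Inhabitable area labels.
#' @param max_range_size Optional range-size cap.
#' @param fix_e Optional fixed extinction rate (then only `d` is free).
#' @return List with `d`, `e`, `logL`, `convergence`.
#' @export
fit_dec <- function(tree, tip_ranges, epochs, areas,
                    max_range_size = NULL, fix_e = NULL) {
  uniq <- unique(lapply(tip_ranges, sort))
  if (length(uniq) < 2) {
    warning("all tips share one range; rate estimates lie on the boundary")
  }
  obj <- function(par) {
    d <- exp(par[1])
    e <- if (is.null(fix_e)) exp(par[2]) else fix_e
    m <- dec_model(areas, epochs, d = d, e = e,
                   max_range_size = max_range_size)
    -dec_likelihood(tree, tip_ranges, m)
  }
  npar <- if (is.null(fix_e)) 2 else 1
  starts <- if (npar == 2) {
    list(log(c(0.01, 0.01)), log(c(0.1, 0.01)), log(c(0.01, 0.1)))
  } else list(log(0.01), log(0.1))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = rep(log(1e-8), npar),
                   upper = rep(log(100), npar),
                   control = list(factr = 1e7, maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop2("DEC optimization failed for every start")
  list(d = exp(best$par[1]),
       e = if (is.null(fix_e)) exp(best$par[2]) else fix_e,
       logL = -best$value, convergence = best$convergence == 0)
}

#' Ancestral range probabilities at a node
#'
#' Marginal posterior of the geographic range at a node (and the
#' cladogenetic daughter splits there), relative probabilities normalized
#' to 100 percent. Ranges and splits are listed in one ranked table:
#' range rows are marginals over all splits at the node, and split rows
#' break the same mass down by daughter pair, so each block sums to 100.
#'
#' @param tree A [time_tree()].
#' @param tip_ranges Named list of tip area-index vectors.
#' @param model A fitted or supplied [dec_model()].
#' @param node Node id in the original tree (default: every internal
#'   node; tips allowed).
#' @return Data frame with columns `node`, `type` (`"range"` or
#'   `"split"`), `label`, `rel_prob_pct`, ranked within node and type.
#' @export
dec_ancestral_ranges <- function(tree, tip_ranges, model, node = NULL) {
  ins <- dec_inside(tree, tip_ranges, model)
  btree <- ins$btree
  phy <- btree$phy
  n <- ins$n
  nnode <- length(phy$tip.label) + phy$Nnode
  # outside pass
  O <- matrix(0, nnode, n)
  O[ins$root, 2:n] <- 1 / (n - 1)
  for (p in rev(postorder_nodes(phy))) {
    es <- ins$eidx[[p]]
    chL <- phy$edge[es[1], 2]; chR <- phy$edge[es[2], 2]
    DL <- as.vector(ins$P[[es[1]]] %*% ins$L[chL, ])
    DR <- as.vector(ins$P[[es[2]]] %*% ins$L[chR, ])
    HL <- numeric(n); HR <- numeric(n)
    for (si in seq_len(n)) {
      if (O[p, si] <= 0) next
      sp <- ins$splits[[si]]
      if (length(sp) == 0) next
      wgt <- O[p, si] / length(sp)
      for (pr in sp) {
        HL[pr[1]] <- HL[pr[1]] + wgt * DR[pr[2]]
        HR[pr[2]] <- HR[pr[2]] + wgt * DL[pr[1]]
      }
    }
    oL <- as.vector(crossprod(ins$P[[es[1]]], HL))
    oR <- as.vector(crossprod(ins$P[[es[2]]], HR))
    if (max(oL) > 0) O[chL, ] <- oL / max(oL)
    if (max(oR) > 0) O[chR, ] <- oR / max(oR)
  }
  # map requested original nodes onto the binarized tree
  nodes <- node %||% ((length(tree$phy$tip.label) + 1):
                        (length(tree$phy$tip.label) + tree$phy$Nnode))
  map_node <- function(v) {
    ntip0 <- length(tree$phy$tip.label)
    if (v <= ntip0) return(match(tree$phy$tip.label[v], phy$tip.label))
    tips <- ape::extract.clade(tree$phy, v)$tip.label
    mrca_node(btree, tips)
  }
  out <- NULL
  for (v in nodes) {
    if (v < 1 || v > length(tree$phy$tip.label) + tree$phy$Nnode)
      stop2("unknown node: ", v)
    bv <- map_node(v)
    marg <- O[bv, ] * ins$L[bv, ]
    if (sum(marg) <= 0) stop2("zero posterior mass at node ", v)
    marg <- 100 * marg / sum(marg)
    df <- data.frame(node = v, type = "range",
                     label = model$range_labels, rel_prob_pct = marg)
    df <- df[df$rel_prob_pct > 0, ]
    # split breakdown for internal nodes
    es <- ins$eidx[[bv]]
    if (!is.null(es) && length(es) == 2) {
      chL <- phy$edge[es[1], 2]; chR <- phy$edge[es[2], 2]
      DL <- as.vector(ins$P[[es[1]]] %*% ins$L[chL, ])
      DR <- as.vector(ins$P[[es[2]]] %*% ins$L[chR, ])
      sl <- list()
      for (si in seq_len(n)) {
        if (O[bv, si] <= 0) next
        sp <- ins$splits[[si]]
        if (length(sp) == 0) next
        for (pr in sp) {
          val <- O[bv, si] * DL[pr[1]] * DR[pr[2]] / length(sp)
          if (val <= 0) next
          lab <- paste0(model$range_labels[si], " -> ",
                        model$range_labels[pr[1]], " | ",
                        model$range_labels[pr[2]])
          sl[[lab]] <- (sl[[lab]] %||% 0) + val
        }
      }
      if (length(sl) > 0) {
        sv <- unlist(sl)
        sv <- 100 * sv / sum(sv)
        df <- rbind(df, data.frame(node = v, type = "split",
                                   label = names(sv), rel_prob_pct = sv))
      }
    }
    df <- df[order(df$type, -df$rel_prob_pct), ]
    out <- rbind(out, df)
  }
  rownames(out) <- NULL
  out
}

#' Read an area/epoch configuration file
#'
#' YAML with top-level keys `areas` (list of `{name, inhabitable}` or
#' plain names) and `epochs` (list of `{start_Ma, end_Ma, pairs}` where
#' each pair is `{from, to, class}`).
#'
#' @param file Path to the YAML configuration.
#' @return List with `areas` (all graph vertices), `inhabitable`
#'   (range-space areas) and `epochs` (list of [area_graph_epoch()]).
#' @export
read_area_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$areas) || is.null(cfg$epochs))
    stop2("config needs `areas` and `epochs`")
  if (is.character(cfg$areas)) {
    areas <- cfg$areas
    inhab <- areas
  } else {
    areas <- vapply(cfg$areas, `[[`, character(1), "name")
    flags <- vapply(cfg$areas, function(a)
      isTRUE(a$inhabitable %||% TRUE), logical(1))
    inhab <- areas[flags]
  }
  epochs <- lapply(cfg$epochs, function(ep) {
    pairs <- if (length(ep$pairs) == 0) {
      data.frame(from = character(), to = character(), class = character())
    } else {
      do.call(rbind, lapply(ep$pairs, function(p)
        data.frame(from = p$from, to = p$to, class = p$class)))
    }
    area_graph_epoch(areas, ep$start_Ma, ep$end_Ma, pairs)
  })
  list(areas = areas, inhabitable = inhab, epochs = epochs)
}

#' Read tip ranges from TSV
#'
#' @param file TSV with columns `taxon` and `areas` (comma-joined area
#'   labels).
#' @param areas Area labels defining the index space.
#' @return Named list of 1-based area-index vectors.
#' @export
read_tip_ranges <- function(file, areas) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "areas") %in% names(tab)))
    stop2("tip-range table needs columns `taxon` and `areas`")
  out <- lapply(tab$areas, function(s) {
    labs <- strsplit(s, ",")[[1]]
    idx <- match(trimws(labs), areas)
    if (anyNA(idx)) stop2("unknown area label in: ", s)
    sort(idx)
  })
  stats::setNames(out, tab$taxon)
}
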