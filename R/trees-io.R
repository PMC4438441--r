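#' Time-calibrated trees with fossil tips
#'
#' A `time_tree` wraps an [ape::phylo] object together with node ages.
#' The coordinate convention is paleontological: ages are in Ma and
#' increase into the past; branch lengths are durations in Myr. Tips need
#' not be contemporaneous -- extinct (fossil) tips simply carry a positive
#' age. Polytomies are preserved; downstream likelihood machinery accepts
#' multifurcations.
#'
#' @param phy A rooted `phylo` object with branch lengths (Myr durations).
#' @param tip_ages Optional named numeric vector of tip ages (Ma) used to
#'   anchor the age scale. Ages of unlisted tips follow from the branch
#'   lengths. When omitted, the deepest tip is anchored at age 0.
#' @return An object of class `time_tree`: a list with elements `phy`,
#'   `node_age` (length `Ntip + Nnode`, in phylo node numbering) and
#'   `root_age`.
#' @export
time_tree <- function(phy, tip_ages = NULL) {
  if (!inherits(phy, "phylo")) stop2("`phy` must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop2("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop2("negative branch length in tree")
  if (anyDuplicated(phy$tip.label))
    stop2("duplicate tip labels: ",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                collapse = ", "))
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)  # distance from root
  if (is.null(tip_ages)) {
    root_age <- max(depth[seq_len(ntip)])
  } else {
    if (is.null(names(tip_ages)) || !all(names(tip_ages) %in% phy$tip.label))
      stop2("`tip_ages` must be named by tip labels present in the tree")
    idx <- match(names(tip_ages), phy$tip.label)
    implied <- as.numeric(tip_ages) + depth[idx]
    if (diff(range(implied)) > 1e-6 * max(1, max(implied)))
      stop2("tip ages are inconsistent with branch lengths ",
            "(implied root ages differ by more than 1e-6)")
    root_age <- mean(implied)
  }
  node_age <- root_age - depth
  # clamp age of the deepest tip against roundoff
  node_age[abs(node_age) < 1e-12] <- 0
  if (any(node_age < -1e-9))
    stop2("negative node age implied by tip ages/branch lengths")
  node_age[node_age < 0] <- 0
  structure(list(phy = phy, node_age = node_age, root_age = root_age),
            class = "time_tree")
}

#' Read a Newick tree as a time tree
#'
#' Branch lengths are mandatory and interpreted as durations in Myr.
#' Unless `tip_ages` is supplied, the deepest tip defines age 0, so tips
#' that do not reach the present are fossil tips with positive ages.
#'
#' @param text A Newick string, or `NULL` when `file` is given.
#' @param file Path to a Newick file.
#' @param tip_ages Optional named tip ages (Ma), or a path to a TSV table
#'   with columns `taxon` and `age_Ma` (see [read_tip_ages()]).
#' @return A [time_tree()].
#' @export
read_newick_time_tree <- function(text = NULL, file = NULL, tip_ages = NULL) {
  if (is.null(text) && is.null(file)) stop2("supply `text` or `file`")
  phy <- if (!is.null(text)) {
    suppressWarnings(
      tryCatch(ape::read.tree(text = text),
               error = function(e) stop2("Newick parse error: ",
                                         conditionMessage(e))))
  } else ape::read.tree(file = file)
  if (is.null(phy)) {
    # locate the first structural problem crudely for the error message
    pos <- newick_error_position(text %||% paste(readLines(file), collapse = ""))
    stop2("malformed Newick string (near character ", pos, ")")
  }
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (is.character(tip_ages) && length(tip_ages) == 1) {
    tip_ages <- read_tip_ages(tip_ages)
  }
  time_tree(phy, tip_ages = tip_ages)
}

# First position where parentheses go unbalanced, else string end.
newick_error_position <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0) return(i)
  }
  length(chars)
}

#' Read a tip-age table
#'
#' @param file TSV with columns `taxon` and `age_Ma`.
#' @return Named numeric vector of ages (Ma).
#' @export
read_tip_ages <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "age_Ma") %in% names(tab)))
    stop2("tip-age table needs columns `taxon` and `age_Ma`")
  stats::setNames(as.numeric(tab$age_Ma), tab$taxon)
}

#' Write a time tree to Newick
#'
#' @param tree A [time_tree()].
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @export
write_newick_time_tree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (is.null(file)) ape::write.tree(tree$phy)
  else ape::write.tree(tree$phy, file = file)
}

#' @export
print.time_tree <- function(x, ...) {
  ntip <- length(x$phy$tip.label)
  nfossil <- sum(x$node_age[seq_len(ntip)] > 1e-9)
  cat(sprintf("time_tree: %d tips (%d fossil), root age %.4g Ma\n",
              ntip, nfossil, x$root_age))
  invisible(x)
}

n_tips <- function(tree) length(tree$phy$tip.label)

root_node <- function(tree) length(tree$phy$tip.label) + 1L

# children of each node as a list indexed by node id
child_list <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2])
  }
  ch
}

# internal nodes ordered so children precede parents (postorder)
postorder_nodes <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  unique(po$edge[, 1])
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A [time_tree()] or `phylo`.
#' @param taxa Character vector of tip labels. A single label returns the
#'   tip itself.
#' @return Node id (phylo numbering).
#' @export
mrca_node <- function(tree, taxa) {
  phy <- if (inherits(tree, "time_tree")) tree$phy else tree
  unknown <- setdiff(taxa, phy$tip.label)
  if (length(unknown) > 0)
    stop2("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(taxa) == 0) stop2("`taxa` must be nonempty")
  if (length(unique(taxa)) == 1) return(match(taxa[1], phy$tip.label))
  ape::getMRCA(phy, taxa)
}

#' Validate the internal consistency of a time tree
#'
#' Checks the age/branch-duration bookkeeping: each parent's age equals
#' each child's age plus the connecting branch duration (to 1e-9 Myr),
#' ages are nonnegative, and tip labels are unique.
#'
#' @param tree A [time_tree()].
#' @param tol Tolerance in Myr.
#' @return Invisibly `TRUE`; errors describe the first violation.
#' @export
validate_time_tree <- function(tree, tol = 1e-9) {
  stopifnot(inherits(tree, "time_tree"))
  phy <- tree$phy
  if (anyDuplicated(phy$tip.label)) stop2("duplicate tip labels")
  if (any(tree$node_age < -tol)) stop2("negative node age")
  scale <- max(1, tree$root_age)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c_ <- phy$edge[i, 2]
    expect <- tree$node_age[c_] + phy$edge.length[i]
    if (abs(tree$node_age[p] - expect) > tol * scale)
      stop2(sprintf("age bookkeeping violated at edge %d -> %d", p, c_))
  }
  invisible(TRUE)
}
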