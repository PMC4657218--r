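#' Patristic distance matrix
#'
#' Pairwise path-length (patristic) distances between all leaves, in
#' substitutions/site. Independent of root placement.
#'
#' @param tree a `phylo` with branch lengths on every edge.
#' @return a symmetric numeric matrix with zero diagonal, rows/columns
#'   in `tree$tip.label` order.
#' @export
patristic_matrix <- function(tree) {
  check_edge_lengths(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

check_edge_lengths <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (is.null(tree$edge.length))
    stop("tree has no edge lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad) > 0)
    stop("missing edge length on edge(s) ",
         paste(apply(tree$edge[bad, , drop = FALSE], 1, paste, collapse = "->"),
               collapse = ", "))
  invisible(tree)
}

# canonical unrooted form: merge the two root-adjacent edges of a
# binary-rooted tree so edge counts and pendant lengths match the
# unrooted tree ML programs actually estimated
unrooted_form <- function(tree) {
  check_edge_lengths(tree)
  n <- length(tree$tip.label)
  if (n == 2) {
    tree$edge.length <- sum(tree$edge.length)
    tree$edge <- matrix(c(3L, 1L), 1, 2)  # degenerate single edge A--B
    return(tree)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree
}

#' Branch-length summaries of a gene tree
#'
#' Total tree length, edge count (internal and terminal branches), mean
#' edge length — the rate-of-evolution proxy used to rank loci — and the
#' pendant (terminal) branch length of every taxon. Binary-rooted trees
#' are first reduced to their unrooted form (the two root-adjacent
#' branches merge into one) so that the same ML tree gives the same
#' numbers however it was serialized.
#'
#' @param tree a `phylo` with branch lengths.
#' @return a list with `total_length`, `n_edges`, `mean_edge_length`,
#'   and `terminal_lengths` (named numeric, taxon -> pendant length).
#' @export
edge_stats <- function(tree) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) < 2)
    stop("no edges: tree must have at least 2 tips")
  tr <- unrooted_form(tree)
  ntip <- length(tr$tip.label)
  total <- sum(tr$edge.length)
  nedge <- nrow(tr$edge)
  pend <- tr$edge[, 2] <= ntip
  term <- stats::setNames(tr$edge.length[pend], tr$tip.label[tr$edge[pend, 2]])
  if (ntip == 2) term <- stats::setNames(rep(total, 2), tr$tip.label)
  list(total_length = total, n_edges = nedge,
       mean_edge_length = total / nedge,
       terminal_lengths = term[tr$tip.label])
}

#' Average nodal support of a tree
#'
#' Arithmetic mean of the numeric support values on internal nodes
#' (percent scale after [read_trees()] normalization). Nodes without a
#' numeric label are ignored; `NA` when no node carries support.
#'
#' @param tree a `phylo`.
#' @return a single numeric, or `NA_real_` when no support is present.
#' @export
average_support <- function(tree) {
  v <- suppressWarnings(as.numeric(tree$node.label))
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Flag spurious sequences by terminal branch length
#'
#' A taxon is flagged when its pendant branch is more than `factor`
#' times the mean branch length of the tree (mean over all branches,
#' the candidate included; strict inequality). With the default
#' `factor = 5` this is the screen used to discard mis-assembled or
#' non-orthologous sequences before locus curation.
#'
#' @param tree a `phylo` with branch lengths.
#' @param factor positive multiplier of the tree-wide mean branch
#'   length.
#' @return character vector of flagged taxon labels (possibly empty).
#' @export
flag_spurious <- function(tree, factor = 5) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) ||
      factor <= 0)
    stop("factor must be a positive number")
  es <- edge_stats(tree)
  thr <- factor * es$mean_edge_length
  names(es$terminal_lengths)[es$terminal_lengths > thr]
}
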