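# fixtures and independent oracles used across test files

rtree_with_lengths <- function(n, mean_edge = 0.1) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length * mean_edge / mean(tr$edge.length)
  tr
}

random_aa_alignment <- function(n_taxa, len, missing_rate = 0,
                                name = "loc") {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(sample(aa, n_taxa * len, replace = TRUE), nrow = n_taxa,
              dimnames = list(sprintf("tax%02d", seq_len(n_taxa)), NULL))
  if (missing_rate > 0) {
    hit <- runif(length(m)) < missing_rate
    m[hit] <- sample(c("-", "?", "X"), sum(hit), replace = TRUE)
  }
  alignment(m, name = name)
}

# patristic oracle: all-pairs shortest paths on the tree seen as a
# weighted graph, fully independent of cophenetic.phylo
graph_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(
    matrix(as.character(tree$edge), ncol = 2), directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g)
  tips <- as.character(seq_along(tree$tip.label))
  d <- d[tips, tips]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# textbook closed-form simple linear regression
ols_closed_form <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, r2 = r2)
}

# brute-force split enumeration: drop each edge of the unrooted tree
# from the graph and read off the connected component of one endpoint
enumerate_splits <- function(tree) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  splits <- list()
  for (e in seq_len(nrow(tr$edge))) {
    edges <- tr$edge[-e, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(as.character(edges), ncol = 2), directed = FALSE)
    g <- g + igraph::vertices(setdiff(as.character(tr$edge[e, ]),
                                      igraph::V(g)$name))
    comp <- igraph::components(g)$membership
    side_ids <- as.integer(names(comp)[comp == comp[as.character(tr$edge[e, 2])]])
    side <- tr$tip.label[side_ids[side_ids <= ntip]]
    splits[[e]] <- sort(side)
  }
  splits
}

oracle_split_support <- function(trees, side, roster) {
  hits <- vapply(trees, function(tr) {
    sp <- enumerate_splits(tr)
    comp <- sort(setdiff(roster, side))
    any(vapply(sp, function(s)
      identical(s, sort(side)) || identical(s, comp), logical(1)))
  }, logical(1))
  100 * mean(hits)
}

# a small stats table with every criterion populated, for selection tests
random_stats_table <- function(n) {
  data.frame(
    locus = sprintf("L%03d", seq_len(n)),
    n_taxa = sample(20:36, n, replace = TRUE),
    pct_missing = runif(n, 0, 50),
    rate = runif(n, 0.01, 0.5),
    sat_slope = runif(n, 0.2, 1),
    sat_r2 = runif(n, 0.3, 1),
    sat_n_pairs = rep(100L, n),
    avg_support = runif(n, 30, 100),
    n_focal_present = sample(0:4, n, replace = TRUE),
    focal_under_mode = sample(0:4, n, replace = TRUE),
    stringsAsFactors = FALSE)
}
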