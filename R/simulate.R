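# the 20 canonical amino-acid letters
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Expected substitution probability under the equal-rates 20-state model
#'
#' The simulator evolves sites under the simplest exchangeable
#' amino-acid process: all exchanges equally likely, uniform
#' stationary frequencies. On a branch of length `t` (expected
#' substitutions/site) the probability that the end states differ is
#' `(19/20) * (1 - exp(-20/19 * t))`, saturating at 0.95. This closed
#' form is what the simulator's output is validated against.
#'
#' @param t branch length in expected substitutions per site.
#' @return probability that the two ends of the branch differ.
#' @export
aa_substitution_prob <- function(t) {
  (19 / 20) * (1 - exp(-(20 / 19) * t))
}

# evolve integer-coded sequences down a tree; parents before children
simulate_sequences <- function(tree, n_sites) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- matrix(NA_integer_, nrow = ntip + nnode, ncol = n_sites)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(20L, n_sites, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    s <- seqs[par, ]
    hit <- stats::runif(n_sites) < aa_substitution_prob(t)
    nh <- sum(hit)
    if (nh > 0)  # jump uniformly to one of the 19 other states
      s[hit] <- ((s[hit] - 1L + sample.int(19L, nh, replace = TRUE)) %% 20L) + 1L
    seqs[child, ] <- s
  }
  m <- matrix(AA_LETTERS[seqs[seq_len(ntip), , drop = FALSE]],
              nrow = ntip, dimnames = list(tree$tip.label, NULL))
  m
}

#' Simulate one locus: alignment plus its true tree
#'
#' Scales the branch lengths of `tree` by `rate`, plants long branches,
#' evolves amino-acid sites independently down the scaled tree under
#' the equal-rates 20-state process, and overwrites a fraction of cells
#' with `?`. A plant of scale `s` sets the taxon's pendant branch to
#' `s` times the tree's mean branch length, so the plant severity is
#' expressed on the same scale the spurious-sequence filter tests
#' against (an 8x plant is unambiguously a long branch to a 5x filter
#' regardless of how short the pendant happened to be). The returned
#' tree carries the true scaled branch lengths (no re-inference), so
#' statistics computed from it recover the generating parameters
#' exactly.
#'
#' @param tree a rooted or unrooted `phylo` with branch lengths; at
#'   least 4 tips.
#' @param length number of alignment columns.
#' @param rate positive multiplier applied to every branch.
#' @param long_branch optional named numeric vector, taxon -> plant
#'   scale; the pendant branch becomes `scale * mean(branch length)`.
#' @param missing_cell_rate fraction of cells replaced by `?`.
#' @param name locus identifier.
#' @param seed optional integer seed for stand-alone reproducibility.
#' @return list with `alignment` ([alignment()]) and `tree` (the scaled
#'   `phylo`).
#' @export
simulate_locus <- function(tree, length, rate = 1, long_branch = NULL,
                           missing_cell_rate = 0, name = "locus",
                           seed = NULL) {
  if (length(tree$tip.label) < 4) stop("roster must have at least 4 taxa")
  if (rate < 0) stop("rate must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- tree
  tr$edge.length <- tr$edge.length * rate
  if (!is.null(long_branch) && length(long_branch) > 0) {
    ntip <- length(tr$tip.label)
    m0 <- edge_stats(tr)$mean_edge_length   # pre-plant tree average
    for (tx in names(long_branch)) {
      tip <- match(tx, tr$tip.label)
      if (is.na(tip)) stop("planted taxon '", tx, "' not in tree")
      e <- which(tr$edge[, 2] == tip)
      tr$edge.length[e] <- long_branch[[tx]] * m0
    }
  }
  m <- simulate_sequences(tr, length)
  if (missing_cell_rate > 0) {
    hit <- stats::runif(length(m)) < missing_cell_rate
    m[hit] <- "?"
  }
  list(alignment = alignment(m, name = name), tree = tr)
}

#' Random taxon roster and base tree
#'
#' A random topology (`ape::rtree`) rescaled to a given mean branch
#' length, used as the shared species tree for a simulated locus set.
#'
#' @param roster taxon labels (>= 4).
#' @param mean_edge target mean branch length in substitutions/site.
#' @return a `phylo`.
#' @export
random_base_tree <- function(roster, mean_edge = 0.1) {
  if (length(roster) < 4) stop("roster must have at least 4 taxa")
  tr <- ape::rtree(length(roster), tip.label = roster)
  tr$edge.length <- tr$edge.length * mean_edge / mean(tr$edge.length)
  tr
}

#' Simulate a collection of loci with known ground truth
#'
#' Emulates the structure of a genome-derived phylogenomic locus set:
#' many loci sharing one species tree but evolving at heterogeneous
#' rates, with variable taxon occupancy (random dropout), missing
#' cells, and optionally planted long-branch taxa in chosen loci. The
#' defaults mirror a 36-taxon, 1080-locus study design with roughly a
#' quarter of the full taxon-by-site grid missing. Everything is
#' reproducible from `seed`.
#'
#' @param roster taxon labels; default 36 taxa `t01..t36`.
#' @param n_loci number of loci (default 1080).
#' @param length_range integer range of locus lengths (columns).
#' @param base_tree shared species tree; default [random_base_tree()].
#' @param rate_multipliers per-locus positive rate multipliers; default
#'   log-normal draws (meanlog 0, sdlog 0.7).
#' @param long_branch_plants optional `data.frame` with columns
#'   `locus` (index), `taxon`, `scale`.
#' @param missing_cell_rate per-cell missingness (default 0.05).
#' @param taxon_dropout_rate per-taxon, per-locus dropout probability
#'   (default 0.2); at least 4 taxa are always kept.
#' @param node_support_range optional length-2 integer range; when set,
#'   every internal node of each locus tree gets a synthetic bootstrap
#'   label drawn uniformly from it (the truth trees are not inferred,
#'   so these labels carry no signal — they exist to exercise the
#'   support-dependent stages). Default `NULL`: no support labels.
#' @param seed integer RNG seed.
#' @return list with `loci` (named list of `list(alignment, tree)`)
#'   and `truth` (a `data.frame`: locus, length, rate_multiplier,
#'   true_rate, n_taxa, planted_taxa, plant_scale, pct_missing_true).
#' @export
simulate_locus_set <- function(roster = sprintf("t%02d", 1:36),
                               n_loci = 1080,
                               length_range = c(150, 600),
                               base_tree = NULL,
                               rate_multipliers = NULL,
                               long_branch_plants = NULL,
                               missing_cell_rate = 0.05,
                               taxon_dropout_rate = 0.2,
                               node_support_range = NULL,
                               seed = 1) {
  set.seed(as.integer(seed))
  if (is.null(base_tree)) base_tree <- random_base_tree(roster)
  if (is.null(rate_multipliers))
    rate_multipliers <- stats::rlnorm(n_loci, meanlog = 0, sdlog = 0.7)
  if (length(rate_multipliers) != n_loci)
    stop("need one rate multiplier per locus")
  if (any(rate_multipliers <= 0)) stop("rate multipliers must be positive")
  base_rate <- edge_stats(base_tree)$mean_edge_length
  nm <- sprintf("locus%04d", seq_len(n_loci))
  loci <- vector("list", n_loci); names(loci) <- nm
  truth <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    len <- sample(length_range[1]:length_range[2], 1)
    plants <- NULL
    if (!is.null(long_branch_plants)) {
      rows <- long_branch_plants[long_branch_plants$locus == i, , drop = FALSE]
      if (nrow(rows) > 0)
        plants <- stats::setNames(rows$scale, rows$taxon)
    }
    keep <- roster[stats::runif(length(roster)) >= taxon_dropout_rate]
    keep <- union(keep, names(plants))   # planted taxa never drop out
    if (length(keep) < 4)
      keep <- union(keep, sample(setdiff(roster, keep), 4 - length(keep)))
    tr <- if (length(keep) == length(roster)) base_tree else
      ape::drop.tip(base_tree, setdiff(roster, keep))
    sim <- simulate_locus(tr, len, rate = rate_multipliers[i],
                          long_branch = plants,
                          missing_cell_rate = missing_cell_rate,
                          name = nm[i])
    if (!is.null(node_support_range))
      sim$tree$node.label <- as.character(
        sample(node_support_range[1]:node_support_range[2],
               sim$tree$Nnode, replace = TRUE))
    loci[[i]] <- sim
    miss_true <- 100 * (sum(missing_mask(sim$alignment)) +
                          (length(roster) - length(keep)) * len) /
      (length(roster) * len)
    truth[[i]] <- data.frame(
      locus = nm[i], length = len, rate_multiplier = rate_multipliers[i],
      true_rate = rate_multipliers[i] * base_rate,
      n_taxa = length(keep),
      planted_taxa = if (is.null(plants)) "" else
        paste(names(plants), collapse = ","),
      plant_scale = if (is.null(plants)) NA_real_ else max(plants),
      pct_missing_true = miss_true, stringsAsFactors = FALSE)
  }
  list(loci = loci, truth = do.call(rbind, truth), base_tree = base_tree)
}

#' Write a simulated locus set to disk
#'
#' One FASTA and one Newick file per locus, plus a tab-separated truth
#' table (`truth.tsv`).
#'
#' @param set result of [simulate_locus_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_locus_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(set$loci)) {
    write_alignment(set$loci[[nm]]$alignment,
                    file.path(dir, paste0(nm, ".fasta")), "fasta")
    write_trees(set$loci[[nm]]$tree, file.path(dir, paste0(nm, ".nwk")))
  }
  utils::write.table(set$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a locus set directory into paired alignments and trees
#'
#' Expects `<locus>.fasta` + `<locus>.nwk` pairs as written by
#' [write_locus_set()].
#'
#' @param dir directory path.
#' @return named list of `list(alignment, tree)`.
#' @export
read_locus_set <- function(dir) {
  fa <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fa) == 0) stop("no .fasta loci in ", dir)
  out <- lapply(fa, function(f) {
    nm <- sub("\\.fasta$", "", basename(f))
    treef <- file.path(dir, paste0(nm, ".nwk"))
    if (!file.exists(treef)) stop("missing tree file for locus ", nm)
    list(alignment = read_alignment(f, "fasta", name = nm),
         tree = read_trees(treef)[[1]])
  })
  names(out) <- sub("\\.fasta$", "", basename(fa))
  out
}
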