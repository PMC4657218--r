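#' Uncorrected p-distance matrix
#'
#' Pairwise proportion of mismatching residues over comparable sites —
#' columns where both taxa carry a non-missing residue (pairwise
#' deletion). A pair with no comparable site gets `NA`.
#'
#' @param aln a [alignment()] with at least 2 taxa.
#' @return symmetric numeric matrix in `[0, 1]` with zero diagonal;
#'   `NA` marks pairs with zero comparable sites.
#' @export
p_distance_matrix <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("p-distance needs at least 2 taxa")
  chars <- unclass(aln)
  miss <- missing_mask(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !miss[i, ] & !miss[j, ]
      nc <- sum(ok)
      d[i, j] <- d[j, i] <-
        if (nc == 0) NA_real_ else sum(chars[i, ok] != chars[j, ok]) / nc
    }
  }
  d
}

#' Saturation regression of p-distance on patristic distance
#'
#' Ordinary least squares (intercept included) of uncorrected
#' p-distances on the patristic distances inferred from the gene tree,
#' over the unordered taxon pairs common to both matrices. Under no
#' saturation the points are linear with slope near the per-site
#' divergence rate; multiple hits flatten the curve, so a low slope
#' and poor fit (low R-squared) diagnose a saturated locus.
#'
#' @param pd p-distance matrix from [p_distance_matrix()].
#' @param patristic patristic matrix from [patristic_matrix()].
#' @return list with `slope`, `r2` and `n_pairs`.
#' @export
saturation_fit <- function(pd, patristic) {
  shared <- intersect(rownames(pd), rownames(patristic))
  if (length(shared) < 3)
    stop("insufficient pairs: matrices share fewer than 3 taxa")
  pdm <- pd[shared, shared]
  pat <- patristic[shared, shared]
  lt <- lower.tri(pdm)
  y <- pdm[lt]; x <- pat[lt]
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("insufficient pairs: fewer than 3 usable pairs")
  if (stats::var(x) == 0) stop("zero variance in patristic distances")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]), r2 = r2, n_pairs = length(y))
}

#' Taxon occupancy and missing-data fraction of a locus
#'
#' `n_taxa` counts roster taxa with at least one non-missing residue in
#' the locus. `pct_missing` is the percentage of missing cells over the
#' full roster-by-length grid: taxa absent from the alignment
#' contribute all-missing rows, so locus-level and concatenated-matrix
#' missingness add up consistently.
#'
#' @param aln a [alignment()]; its taxa must be a subset of `roster`.
#' @param roster the full taxon list of the study.
#' @return list with `n_taxa` (integer) and `pct_missing` (percent).
#' @export
occupancy <- function(aln, roster) {
  extra <- setdiff(aln_taxa(aln), roster)
  if (length(extra) > 0)
    stop("taxa in alignment but not in roster: ",
         paste(extra, collapse = ", "))
  miss <- missing_mask(aln)
  present <- rowSums(!miss) > 0
  n_cells <- length(roster) * ncol(aln)
  n_missing <- sum(miss) + (length(roster) - nrow(aln)) * ncol(aln)
  list(n_taxa = as.integer(sum(present)),
       pct_missing = if (n_cells == 0) 0 else 100 * n_missing / n_cells)
}

#' Long-branch (LB) scores of a gene tree
#'
#' For each taxon i, `PD_i` is its mean patristic distance to all other
#' taxa; the LB score is the percent deviation of `PD_i` from the
#' across-taxon average: `LB_i = (PD_i / mean(PD) - 1) * 100`. Scores
#' average to zero over taxa by construction; large positive values
#' mark long-branched taxa prone to attraction artifacts.
#'
#' @param tree a `phylo` with branch lengths and at least 3 tips.
#' @return list with `mean_distances` (PD_i, named), `grand_mean`, and
#'   `scores` (LB_i in percent, named).
#' @export
lb_scores <- function(tree) {
  if (length(tree$tip.label) < 3) stop("LB scores need at least 3 taxa")
  d <- patristic_matrix(tree)
  if (all(d == 0)) stop("degenerate tree: all patristic distances are zero")
  n <- nrow(d)
  pd <- rowSums(d) / (n - 1)
  gm <- mean(pd)
  list(mean_distances = pd, grand_mean = gm,
       scores = (pd / gm - 1) * 100)
}

#' LB-score modes of focal taxa, and per-locus counts under the mode
#'
#' Long-branch scores are taxon-specific, so loci cannot be compared by
#' raw LB values. Instead, for each focal (suspected long-branch)
#' taxon, its LB scores are pooled across all loci where it occurs and
#' the mode of their density distribution is located (Gaussian KDE,
#' Silverman bandwidth, argmax on a 512-point grid over the observed
#' range). A locus then scores one point per focal taxon it contains
#' whose LB score falls at or below that taxon's mode — loci where the
#' focal taxa are *not* long-branched score high.
#'
#' @param profiles named list (locus -> [lb_scores()] result).
#' @param focal character vector of focal taxon labels.
#' @return list with `modes` (named numeric per focal taxon) and
#'   `counts` (named integer per locus, 0 to `length(focal)`).
#' @export
lb_mode_ranking <- function(profiles, focal) {
  if (length(focal) == 0) stop("no focal taxa given")
  modes <- vapply(focal, function(f) {
    pooled <- unlist(lapply(profiles, function(p) p$scores[f]), use.names = FALSE)
    pooled <- pooled[!is.na(pooled)]
    if (length(pooled) == 0)
      stop("focal taxon '", f, "' absent from all loci")
    if (length(pooled) < 10)
      stop("focal taxon '", f, "' present in only ", length(pooled),
           " loci; mode estimate unreliable (need >= 10)")
    if (stats::var(pooled) == 0) return(pooled[1])
    dens <- stats::density(pooled, bw = "nrd0", n = 512,
                           from = min(pooled), to = max(pooled))
    dens$x[which.max(dens$y)]
  }, numeric(1))
  counts <- vapply(profiles, function(p) {
    s <- p$scores[focal]
    sum(!is.na(s) & s <= modes + 1e-9)
  }, integer(1))
  list(modes = modes, counts = counts)
}

#' Score a collection of loci
#'
#' Runs the full per-locus scorecard over paired alignments and gene
#' trees: occupancy and missing data, rate of evolution (mean branch
#' length), saturation slope and R-squared, average nodal support, and
#' — when focal taxa are supplied — the focal-under-LB-mode count and
#' the number of focal taxa present.
#'
#' @param loci named list; each element a list with components
#'   `alignment` ([alignment()]) and `tree` (`phylo`). Names are locus
#'   identifiers (falling back to the alignment names).
#' @param roster full taxon list.
#' @param focal focal taxa for LB-mode ranking (default none).
#' @return a `data.frame` with one row per locus and columns `locus`,
#'   `n_taxa`, `pct_missing`, `rate`, `sat_slope`, `sat_r2`,
#'   `sat_n_pairs`, `avg_support`, `n_focal_present`,
#'   `focal_under_mode`; the per-locus LB profiles and per-taxon modes
#'   are attached as attributes `"lb_profiles"` and `"lb_modes"`.
#' @export
score_loci <- function(loci, roster, focal = character(0)) {
  if (length(loci) == 0) stop("no loci to score")
  nm <- names(loci)
  if (is.null(nm))
    nm <- vapply(loci, function(l) aln_name(l$alignment), character(1))
  profiles <- vector("list", length(loci)); names(profiles) <- nm
  rows <- vector("list", length(loci))
  for (k in seq_along(loci)) {
    aln <- loci[[k]]$alignment; tree <- loci[[k]]$tree
    if (!setequal(aln_taxa(aln), tree$tip.label))
      stop("locus '", nm[k], "': alignment taxa and tree tips differ (",
           paste(c(setdiff(aln_taxa(aln), tree$tip.label),
                   setdiff(tree$tip.label, aln_taxa(aln))), collapse = ", "),
           ")")
    occ <- occupancy(aln, roster)
    es <- edge_stats(tree)
    sat <- saturation_fit(p_distance_matrix(aln), patristic_matrix(tree))
    profiles[[k]] <- lb_scores(tree)
    rows[[k]] <- data.frame(
      locus = nm[k], n_taxa = occ$n_taxa, pct_missing = occ$pct_missing,
      rate = es$mean_edge_length, sat_slope = sat$slope, sat_r2 = sat$r2,
      sat_n_pairs = sat$n_pairs, avg_support = average_support(tree),
      stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  if (length(focal) > 0) {
    mr <- lb_mode_ranking(profiles, focal)
    stats$n_focal_present <- vapply(profiles, function(p)
      sum(focal %in% names(p$scores)), integer(1))
    stats$focal_under_mode <- unname(mr$counts[stats$locus])
    attr(stats, "lb_modes") <- mr$modes
  } else {
    stats$n_focal_present <- NA_integer_
    stats$focal_under_mode <- NA_integer_
  }
  attr(stats, "lb_profiles") <- profiles
  stats
}

# fixed, documented column order of the stats table on disk
STATS_COLUMNS <- c("locus", "n_taxa", "pct_missing", "rate", "sat_slope",
                   "sat_r2", "sat_n_pairs", "avg_support",
                   "n_focal_present", "focal_under_mode")

#' Write / read the per-locus statistics table
#'
#' Tab-separated, fixed column order: locus, n_taxa, pct_missing, rate,
#' sat_slope, sat_r2, sat_n_pairs, avg_support, n_focal_present,
#' focal_under_mode.
#'
#' @param stats a [score_loci()] table.
#' @param path file path.
#' @return invisibly `path` (write) or the table (read).
#' @export
write_locus_stats <- function(stats, path) {
  utils::write.table(stats[, STATS_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_stats
#' @export
read_locus_stats <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
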