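#' Filter loci on threshold criteria
#'
#' Keeps the loci satisfying all set thresholds. Boundary semantics
#' follow the curation rules the thresholds come from: `min_taxa` is
#' inclusive ("at least N taxa"), `max_pct_missing` discards only loci
#' *strictly above* the threshold ("more than X% missing"), and the
#' support threshold is inclusive by default ("average bootstrap 60 or
#' more"), with `support_strict = TRUE` available for a strict
#' "higher than" reading.
#'
#' @param stats a [score_loci()] table.
#' @param min_taxa minimum occupancy, inclusive, or `NULL`.
#' @param max_pct_missing maximum percent missing; loci strictly above
#'   are discarded; or `NULL`.
#' @param min_avg_support minimum average nodal support, or `NULL`.
#' @param support_strict if `TRUE`, require support strictly above
#'   `min_avg_support`.
#' @param min_focal_present minimum number of focal taxa present, or
#'   `NULL`.
#' @return character vector of retained locus names.
#' @export
filter_loci <- function(stats, min_taxa = NULL, max_pct_missing = NULL,
                        min_avg_support = NULL, support_strict = FALSE,
                        min_focal_present = NULL) {
  if (is.null(min_taxa) && is.null(max_pct_missing) &&
      is.null(min_avg_support) && is.null(min_focal_present))
    stop("at least one criterion must be set")
  keep <- rep(TRUE, nrow(stats))
  need <- function(col) {
    v <- stats[[col]]
    if (is.null(v))
      stop("criterion references absent statistic '", col, "'")
    if (anyNA(v))
      stop("criterion references absent statistic '", col, "' for loci: ",
           paste(stats$locus[is.na(v)], collapse = ", "))
    v
  }
  if (!is.null(min_taxa)) keep <- keep & need("n_taxa") >= min_taxa
  if (!is.null(max_pct_missing))
    keep <- keep & need("pct_missing") <= max_pct_missing
  if (!is.null(min_avg_support)) {
    v <- need("avg_support")
    keep <- keep & if (support_strict) v > min_avg_support else
      v >= min_avg_support
  }
  if (!is.null(min_focal_present))
    keep <- keep & need("n_focal_present") >= min_focal_present
  stats$locus[keep]
}

# default direction of "better" for each ranking criterion
BEST_DIRECTIONS <- c(n_taxa = "higher", avg_support = "higher",
                     rate = "lower", sat_slope = "higher",
                     focal_under_mode = "higher")

#' Rank loci across criteria and select the best fraction
#'
#' Each locus is ranked on every criterion (1 = best; occupancy,
#' average support, saturation slope and focal-under-mode count rank
#' high-to-low, rate of evolution low-to-high; ties share the average
#' rank). The composite score is the (optionally weighted) sum of
#' ranks, and the `ceiling(best_fraction * n)` loci with the smallest
#' composite are selected — the construction behind a "best 10%"
#' matrix. Ties in the composite break lexicographically by locus name.
#'
#' @param stats a [score_loci()] table with all five criterion columns
#'   populated.
#' @param best_fraction fraction of loci to keep, in (0, 1].
#' @param directions named character vector overriding the per-criterion
#'   direction (`"higher"`/`"lower"` = better).
#' @param weights named numeric vector of per-criterion weights
#'   (default all 1).
#' @return character vector of selected locus names, best composite
#'   first.
#' @export
rank_and_select_best <- function(stats, best_fraction,
                                 directions = BEST_DIRECTIONS,
                                 weights = NULL) {
  if (!is.numeric(best_fraction) || best_fraction <= 0 || best_fraction > 1)
    stop("best_fraction must be in (0, 1]")
  dirs <- BEST_DIRECTIONS
  dirs[names(directions)] <- directions
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(dirs)),
                                                   names(dirs))
  comp <- rep(0, nrow(stats))
  for (crit in names(dirs)) {
    v <- stats[[crit]]
    if (is.null(v) || anyNA(v))
      stop("statistic '", crit, "' absent for loci: ",
           paste(stats$locus[is.na(stats[[crit]])], collapse = ", "))
    r <- if (dirs[crit] == "higher") rank(-v, ties.method = "average")
         else rank(v, ties.method = "average")
    comp <- comp + weights[crit] * r
  }
  n_sel <- ceiling(best_fraction * nrow(stats))
  ord <- order(comp, stats$locus)
  stats$locus[ord][seq_len(n_sel)]
}

#' Concatenate loci into a supermatrix
#'
#' Builds one row per roster taxon; a taxon absent from a locus gets a
#' block of `?`. Locus blocks are laid out in ascending order of locus
#' name (downstream partitioned analyses are order-insensitive, but a
#' fixed order makes the matrix reproducible), and a partition table
#' tiling `1..total_length` is emitted alongside.
#'
#' @param loci a named list of [alignment()] objects (names are locus
#'   identifiers; alignment `name` attributes are the fallback).
#' @param roster full taxon list defining the row set and order.
#' @param name name for the concatenated matrix.
#' @param model model label for the partition table.
#' @return list with `alignment` (the supermatrix), `table` (the
#'   [partition_table()]), `loci` (ordered names) and `roster`.
#' @export
concatenate <- function(loci, roster, name = "concat", model = "AUTO") {
  if (length(loci) == 0) stop("no loci to concatenate")
  nm <- names(loci)
  if (is.null(nm)) nm <- vapply(loci, aln_name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate locus names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(loci) <- nm
  ord <- order(nm)
  loci <- loci[ord]
  for (l in names(loci)) {
    extra <- setdiff(aln_taxa(loci[[l]]), roster)
    if (length(extra) > 0)
      stop("locus '", l, "' has taxa outside the roster: ",
           paste(extra, collapse = ", "))
  }
  lens <- vapply(loci, ncol, integer(1))
  total <- sum(lens)
  m <- matrix("?", nrow = length(roster), ncol = total,
              dimnames = list(roster, NULL))
  at <- 0L
  for (l in names(loci)) {
    aln <- loci[[l]]
    if (ncol(aln) > 0)
      m[aln_taxa(aln), (at + 1L):(at + ncol(aln))] <- unclass(aln)
    at <- at + ncol(aln)
  }
  pt <- partition_table(names(loci), lens, model = model)
  list(alignment = alignment(m, name = name), table = pt,
       loci = names(loci), roster = roster)
}

# rate-ascending locus order, ties broken by name, shared by the
# progressive series and the rate bins
rate_order <- function(stats) stats$locus[order(stats$rate, stats$locus)]

#' Progressive concatenation series of the slowest-evolving loci
#'
#' For each requested size k, the k slowest-evolving loci (rate
#' ascending, ties by name). Successive sets are nested, so the series
#' tracks how support changes as faster and faster loci are added.
#'
#' @param stats a [score_loci()] table with a `rate` column.
#' @param sizes ascending integer vector of set sizes.
#' @return named list of character vectors of locus names (one per
#'   size).
#' @export
progressive_series <- function(stats, sizes = c(5, 10, 15, 20, 30, 50,
                                                100, 200, 300, 500)) {
  if (is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be strictly ascending")
  if (max(sizes) > nrow(stats))
    stop("size ", max(sizes), " exceeds number of loci (", nrow(stats), ")")
  ord <- rate_order(stats)
  stats::setNames(lapply(sizes, function(k) ord[seq_len(k)]),
                  paste0("slowest", sizes))
}

#' Non-overlapping rate bins of loci
#'
#' Consecutive slices of the rate-sorted locus list, slowest first.
#' When `bin_size` does not divide the locus count the final bin holds
#' the remainder.
#'
#' @param stats a [score_loci()] table with a `rate` column.
#' @param bin_size loci per bin (positive integer).
#' @return named list of character vectors, `bin1` = slowest.
#' @export
rate_bins <- function(stats, bin_size) {
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be a positive integer")
  ord <- rate_order(stats)
  idx <- split(seq_along(ord), ceiling(seq_along(ord) / bin_size))
  stats::setNames(lapply(idx, function(i) ord[i]),
                  paste0("bin", seq_along(idx)))
}

#' Locus-jackknife replicates
#'
#' Draws `reps` replicates of `k` distinct loci each, uniformly without
#' replacement, fully reproducible from `seed`.
#'
#' @param loci character vector of locus names.
#' @param k loci per replicate.
#' @param reps number of replicates.
#' @param seed integer RNG seed.
#' @return named list (`rep1`, `rep2`, ...) of character vectors; the
#'   seed is attached as attribute `"seed"`.
#' @export
jackknife_replicates <- function(loci, k, reps, seed) {
  n <- length(loci)
  if (k > n) stop("k (", k, ") exceeds number of loci (", n, ")")
  if (reps < 1) stop("reps must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- stats::setNames(lapply(seq_len(reps), function(i) sample(loci, k)),
                         paste0("rep", seq_len(reps)))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write / read a jackknife replicate manifest
#'
#' Tab-separated: replicate index, seed, comma-joined locus names.
#' Byte-identical for a fixed seed.
#'
#' @param reps result of [jackknife_replicates()].
#' @param path file path.
#' @return invisibly `path` (write) or the replicate list (read).
#' @export
write_jackknife_manifest <- function(reps, path) {
  seed <- attr(reps, "seed")
  lines <- c("replicate\tseed\tloci",
             vapply(seq_along(reps), function(i)
               paste(i, seed, paste(reps[[i]], collapse = ","), sep = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_jackknife_manifest
#' @export
read_jackknife_manifest <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out <- stats::setNames(strsplit(tab$loci, ",", fixed = TRUE),
                         paste0("rep", tab$replicate))
  attr(out, "seed") <- tab$seed[1]
  out
}

# reduced amino-acid alphabets; each group is represented by its first
# letter so recoding is idempotent on already-recoded data
RECODING_SCHEMES <- list(
  dayhoff6 = c(AGPST = "A", DENQ = "D", HKR = "H", ILMV = "I",
               FWY = "F", C = "C"),
  dayhoff4 = c(AGPST = "A", DENQ = "D", HKR = "H", FWYILMV = "F",
               C = "?"),
  hp = c(ACFGILMVW = "A", DEHKNPQRSTY = "D")
)

recode_map <- function(scheme) {
  groups <- RECODING_SCHEMES[[scheme]]
  map <- character(0)
  for (g in names(groups))
    map[strsplit(g, "")[[1]]] <- groups[[g]]
  map
}

#' Recode an amino-acid alignment into a reduced alphabet
#'
#' Maps each residue to the representative letter of its group:
#' `dayhoff6` uses the six Dayhoff classes (AGPST, DENQ, HKR, ILMV,
#' FWY, C), `dayhoff4` merges the aromatic and aliphatic classes and
#' treats cysteine as missing, and `hp` reduces to
#' hydrophobic/polar. Gap and missing symbols pass through unchanged.
#' Recoding reduces across-taxon compositional heterogeneity at the
#' cost of signal.
#'
#' @param aln a [alignment()] over the 20 amino-acid letters.
#' @param scheme `"dayhoff6"`, `"dayhoff4"` or `"hp"`.
#' @return a recoded [alignment()] of identical shape and taxon set.
#' @export
recode <- function(aln, scheme = c("dayhoff6", "dayhoff4", "hp")) {
  scheme <- match.arg(scheme)
  map <- recode_map(scheme)
  m <- unclass(aln)
  miss <- missing_mask(aln)
  known <- matrix(m %in% names(map), nrow = nrow(m)) | miss
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop("residue '", m[bad[1], bad[2]], "' at taxon '",
         rownames(m)[bad[1]], "', column ", bad[2],
         " is not an amino acid or missing symbol")
  }
  out <- m
  out[!miss] <- map[m[!miss]]
  alignment(out, name = aln_name(aln))
}
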