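#' Frequency of a bipartition across a tree set
#'
#' The percentage of trees containing an edge whose removal splits the
#' leaves into `side` versus its complement (unrooted split
#' semantics). Mapping a hypothesis clade over bootstrap or jackknife
#' trees this way turns a tree set into a support value for that
#' hypothesis. Trees whose leaf set differs from the roster are
#' rejected rather than restricted, because restriction silently
#' changes what a split means.
#'
#' @param trees list of `phylo` objects, all over `roster`.
#' @param side character vector of taxa on one side of the split.
#' @param roster the full leaf set.
#' @return percent of trees containing the split (0-100).
#' @export
bipartition_support <- function(trees, side, roster) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("no trees")
  side <- unique(side)
  if (length(setdiff(side, roster)) > 0)
    stop("side contains taxa outside the roster: ",
         paste(setdiff(side, roster), collapse = ", "))
  if (length(side) < 1 || length(side) > length(roster) - 1)
    stop("side must contain between 1 and |roster|-1 taxa")
  hits <- vapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (!setequal(tr$tip.label, roster))
      stop("tree ", i, " has a different leaf set than the roster (",
           paste(c(setdiff(roster, tr$tip.label),
                   setdiff(tr$tip.label, roster)), collapse = ", "), ")")
    has_split(tr, side, roster)
  }, logical(1))
  100 * sum(hits) / length(trees)
}

has_split <- function(tree, side, roster) {
  k <- length(side)
  if (k == 1 || k == length(roster) - 1) return(TRUE)  # pendant edges
  comp <- setdiff(roster, side)
  clades <- ape::prop.part(tree)
  labs <- attr(clades, "labels")
  for (cl in clades) {
    tips <- labs[cl]
    if (setequal(tips, side) || setequal(tips, comp)) return(TRUE)
  }
  FALSE
}

# Kass & Raftery-style interpretation thresholds on 2*|log-unit diff|
BF_THRESHOLDS <- c(barely = 2, positive = 6, strong = 10)

#' Compare marginal likelihoods of a hypothesis and its negation
#'
#' Takes the marginal log-likelihood of a constrained topological
#' hypothesis and of its negation (e.g. from stepping-stone
#' integration), and reports the absolute difference in log units, a
#' supported/rejected verdict (supported iff the hypothesis has the
#' higher marginal likelihood), and a strength category from the
#' standard interpretation scale applied to twice the difference
#' (> 10: very strong; 6-10: strong; 2-6: positive; otherwise barely
#' worth mentioning).
#'
#' @param lnl_for marginal log-likelihood with the hypothesis enforced.
#' @param lnl_against marginal log-likelihood of its negation.
#' @param thresholds named ascending cutoffs on `2 * diff` separating
#'   the strength categories.
#' @return object of class `bayes_comparison`: list with `lnl_for`,
#'   `lnl_against`, `diff` (absolute, log units), `supported`
#'   (logical), `strength`, and `verdict` (e.g. "very strongly
#'   supported").
#' @export
bayes_factor_compare <- function(lnl_for, lnl_against,
                                 thresholds = BF_THRESHOLDS) {
  if (!is.finite(lnl_for) || !is.finite(lnl_against))
    stop("marginal log-likelihoods must be finite")
  diff <- abs(lnl_for - lnl_against)
  two_ln_bf <- 2 * diff
  strength <- if (two_ln_bf > thresholds["strong"]) "very strong"
    else if (two_ln_bf > thresholds["positive"]) "strong"
    else if (two_ln_bf > thresholds["barely"]) "positive"
    else "barely worth mentioning"
  supported <- lnl_for > lnl_against
  adverb <- c(`very strong` = "very strongly", strong = "strongly",
              positive = "positively",
              `barely worth mentioning` = "equivocally")[strength]
  structure(list(lnl_for = lnl_for, lnl_against = lnl_against,
                 diff = diff, supported = supported, strength = strength,
                 verdict = paste(adverb,
                                 if (supported) "supported" else "rejected")),
            class = "bayes_comparison")
}

#' @export
print.bayes_comparison <- function(x, ...) {
  cat(sprintf("marginal lnL for: %.2f  against: %.2f\n", x$lnl_for,
              x$lnl_against))
  cat(sprintf("difference: %.2f log units -> %s\n", x$diff, x$verdict))
  invisible(x)
}

#' Generations entering a stepping-stone marginal-likelihood estimate
#'
#' Bookkeeping for stepping-stone integration runs: with `steps` stones
#' of `generations_per_step` MCMC generations each and the first
#' `burnin_steps` stones discarded, the marginal likelihood is
#' estimated from `(steps - burnin_steps) * generations_per_step`
#' generations.
#'
#' @param steps number of stones.
#' @param generations_per_step MCMC generations per stone.
#' @param burnin_steps stones discarded as burn-in.
#' @return integer count of generations used in the estimate.
#' @export
steppingstone_generations <- function(steps = 50, generations_per_step = 5000,
                                      burnin_steps = 1) {
  if (burnin_steps >= steps) stop("burn-in discards every step")
  as.integer((steps - burnin_steps) * generations_per_step)
}

#' Write a bipartition support report
#'
#' Tab-separated: hypothesis label, number of trees, percent support.
#'
#' @param report data.frame with columns `hypothesis`, `n_trees`,
#'   `percent`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_support_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
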