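test_that("filter_loci applies inclusive/strict boundaries as documented", {
  set.seed(51)
  st <- random_stats_table(10)
  st$n_taxa <- c(rep(8L, 4), rep(5L, 6))
  expect_equal(filter_loci(st, min_taxa = 8), st$locus[1:4])

  st$pct_missing <- c(40, 39.9, 40.1, runif(7, 0, 39))
  kept <- filter_loci(st, max_pct_missing = 40)
  expect_true(st$locus[1] %in% kept)    # exactly 40% is retained
  expect_false(st$locus[3] %in% kept)   # "more than 40%" is discarded

  st$avg_support <- c(60, 59.9, 60.1, rep(80, 7))
  expect_true(st$locus[1] %in% filter_loci(st, min_avg_support = 60))
  expect_false(st$locus[1] %in%
                 filter_loci(st, min_avg_support = 60, support_strict = TRUE))
})

test_that("criteria conjunction equals the intersection of single runs", {
  set.seed(52)
  st <- random_stats_table(50)
  both <- filter_loci(st, min_taxa = 30, max_pct_missing = 25)
  expect_setequal(both, intersect(filter_loci(st, min_taxa = 30),
                                  filter_loci(st, max_pct_missing = 25)))
})

test_that("filter_loci is monotone under threshold relaxation", {
  set.seed(53)
  st <- random_stats_table(60)
  for (mt in c(34, 30, 26, 22)) {
    kept <- filter_loci(st, min_taxa = mt, max_pct_missing = 30)
    relaxed <- filter_loci(st, min_taxa = mt - 2, max_pct_missing = 35)
    expect_true(all(kept %in% relaxed))
  }
})

test_that("filter_loci rejects criteria on absent statistics", {
  st <- random_stats_table(5)
  st$avg_support <- NA_real_
  expect_error(filter_loci(st, min_avg_support = 60), "absent")
  expect_error(filter_loci(st), "at least one criterion")
})

test_that("rank_and_select_best returns exactly the ceiling fraction", {
  set.seed(54)
  st <- random_stats_table(100)
  expect_length(rank_and_select_best(st, 0.1), 10)
  expect_length(rank_and_select_best(st, 0.105), 11)
  expect_length(rank_and_select_best(st, 1), 100)

  # a locus ranked best on every criterion is always selected
  st$n_taxa[7] <- 40L; st$avg_support[7] <- 100
  st$rate[7] <- 0.001; st$sat_slope[7] <- 2; st$focal_under_mode[7] <- 5L
  for (f in c(0.01, 0.1, 0.5))
    expect_true(st$locus[7] %in% rank_and_select_best(st, f))
})

test_that("composite rank selection matches brute-force enumeration", {
  set.seed(55)
  for (i in 1:5) {
    st <- random_stats_table(30)
    comp <- rank(-st$n_taxa) + rank(-st$avg_support) + rank(st$rate) +
      rank(-st$sat_slope) + rank(-st$focal_under_mode)
    expected <- st$locus[order(comp, st$locus)][1:6]
    expect_equal(rank_and_select_best(st, 0.2), expected)
  }
})

test_that("concatenation lays out blocks by locus name with ? fill", {
  roster <- c("a", "b", "c")
  l1 <- alignment(c(a = strrep("A", 250), b = strrep("C", 250)))
  l2 <- alignment(c(a = strrep("D", 100), c = strrep("E", 100)))
  cc <- concatenate(list(zlocus = l1, alocus = l2), roster)
  expect_equal(ncol(cc$alignment), 350)
  expect_equal(cc$loci, c("alocus", "zlocus"))  # ascending name order
  expect_equal(cc$table$start, c(1L, 101L))
  expect_equal(cc$table$end, c(100L, 350L))
  m <- unclass(cc$alignment)
  expect_equal(unique(m["b", 1:100]), "?")      # b absent from alocus
  expect_equal(unique(m["c", 101:350]), "?")    # c absent from zlocus
  expect_equal(unique(m["a", 1:100]), "D")

  expect_error(concatenate(list(x = l1, x = l2), roster), "duplicate")
})

test_that("supermatrix missingness is the length-weighted locus mean", {
  set.seed(56)
  roster <- sprintf("tax%02d", 1:8)
  alns <- lapply(1:6, function(i) {
    a <- random_aa_alignment(sample(4:8, 1), sample(30:90, 1),
                             missing_rate = 0.1)
    alignment(unclass(a)[sample(nrow(a)), , drop = FALSE])
  })
  rn <- lapply(alns, function(a)
    alignment(`rownames<-`(unclass(a), sample(roster, nrow(a))), name = ""))
  names(rn) <- sprintf("g%d", 1:6)
  cc <- concatenate(rn, roster)
  pm <- vapply(rn, function(a) occupancy(a, roster)$pct_missing, numeric(1))
  lens <- vapply(rn, ncol, numeric(1))
  expect_equal(occupancy(cc$alignment, roster)$pct_missing,
               sum(pm * lens) / sum(lens), tolerance = 1e-12)
  expect_equal(ncol(cc$alignment), sum(lens))
  validate <- phylosieve:::validate_partition_table(cc$table)
  expect_equal(sum(validate$end - validate$start + 1), sum(lens))
})

test_that("progressive series are nested prefixes of the rate order", {
  set.seed(57)
  st <- random_stats_table(20)
  ser <- progressive_series(st, c(5, 10))
  expect_length(ser$slowest5, 5)
  expect_length(ser$slowest10, 10)
  expect_true(all(ser$slowest5 %in% ser$slowest10))
  expect_equal(ser$slowest5, st$locus[order(st$rate, st$locus)][1:5])
  expect_equal(progressive_series(st, c(2, 20))$slowest20,
               st$locus[order(st$rate, st$locus)])
  expect_error(progressive_series(st, c(5, 25)), "exceeds")
})

test_that("rate bins partition the loci, slowest first", {
  set.seed(58)
  st <- random_stats_table(50)
  bins <- rate_bins(st, 10)
  expect_length(bins, 5)
  expect_setequal(unlist(bins), st$locus)
  expect_equal(sum(lengths(bins)), 50)
  meds <- vapply(bins, function(b) median(st$rate[st$locus %in% b]),
                 numeric(1))
  expect_true(all(diff(meds) >= 0))

  # non-divisible n: remainder goes to the final, shorter bin
  rem <- rate_bins(st, 15)
  expect_equal(lengths(rem), c(bin1 = 15L, bin2 = 15L, bin3 = 15L,
                               bin4 = 5L))
  expect_error(rate_bins(st, 0), "positive")
})

test_that("jackknife replicates are seed-reproducible and distinct", {
  loci <- sprintf("g%04d", 1:100)
  a <- jackknife_replicates(loci, k = 20, reps = 30, seed = 7)
  b <- jackknife_replicates(loci, k = 20, reps = 30, seed = 7)
  expect_identical(unclass(a)[], unclass(b)[])
  c2 <- jackknife_replicates(loci, k = 20, reps = 30, seed = 8)
  expect_false(identical(unclass(a)[], unclass(c2)[]))
  expect_true(all(vapply(a, function(r) length(unique(r)) == 20, logical(1))))
  expect_error(jackknife_replicates(loci, k = 101, reps = 1, seed = 1),
               "exceeds")

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_jackknife_manifest(a, f1)
  write_jackknife_manifest(b, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  back <- read_jackknife_manifest(f1)
  expect_equal(unname(unclass(back)[]), unname(unclass(a)[]))
})

test_that("jackknife inclusion frequencies are uniform", {
  loci <- sprintf("g%02d", 1:20)
  reps <- jackknife_replicates(loci, k = 1, reps = 10000, seed = 99)
  counts <- table(factor(unlist(reps), levels = loci))
  p <- 1 / 20
  sd3 <- 3 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) <= sd3))
})

test_that("recoding maps groups to representatives and keeps shape", {
  aln <- alignment(c(a = "AGPSTC", b = "DENQHK", c = "ILMVFW", d = "Y-?XRW"))
  d6 <- recode(aln, "dayhoff6")
  m <- unclass(d6)
  expect_true(all(m["a", 1:5] == "A"))         # AGPST collapse
  expect_equal(unname(m["a", 6]), "C")         # C is its own class
  expect_equal(m["b", ], c("D", "D", "D", "D", "H", "H"))
  expect_equal(m["d", 2:4], c("-", "?", "X"))  # missing passes through
  expect_equal(dim(d6), dim(aln))
  expect_equal(aln_taxa(d6), aln_taxa(aln))

  hp <- recode(aln, "hp")
  expect_true(all(unclass(hp)["c", ] == "A"))  # all hydrophobic

  d4 <- recode(aln, "dayhoff4")
  expect_equal(unname(unclass(d4)["a", 6]), "?")  # C treated as missing

  bad <- alignment(c(a = "AB"))                # B is not an amino acid
  expect_error(recode(bad, "dayhoff6"), "column 2")
})

test_that("recoding is idempotent on the recoded alphabet", {
  set.seed(59)
  for (scheme in c("dayhoff6", "dayhoff4", "hp")) {
    aln <- random_aa_alignment(6, 40, missing_rate = 0.1)
    once <- recode(aln, scheme)
    twice <- recode(once, scheme)
    expect_identical(unclass(twice), unclass(once))
  }
})
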