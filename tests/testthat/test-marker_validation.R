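test_that("SNP region calling equals the brute-force run-length oracle", {
  # all sub-threshold -> nothing
  tr <- signal_track(1:100, rep(0, 100))
  expect_identical(nrow(call_snp_regions(tr)), 0L)

  # one 12-nt run at z = 3 -> one prediction at its argmax
  z <- rep(0, 100); z[40:51] <- 3; z[45] <- 3.7
  out <- call_snp_regions(signal_track(1:100, z))
  expect_identical(nrow(out), 1L)
  expect_identical(out$pos, 45L)
  expect_identical(c(out$start, out$end), c(40L, 51L))

  # a 9-nt run is below the minimum length
  z <- rep(0, 100); z[10:18] <- 3
  expect_identical(nrow(call_snp_regions(signal_track(1:100, z))), 0L)

  # random tracks: equivalence with the independent scanner
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(30:120, 1)
    z <- pmax(0, rnorm(n, 1.2, 1.5))
    tr <- signal_track(seq_len(n), z)
    got <- call_snp_regions(tr)
    exp <- oracle_call_regions(seq_len(n), z, 2.5, 10L)
    if (is.null(exp)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$pos, as.integer(exp[, 1]))
      expect_identical(got$start, as.integer(exp[, 2]))
      expect_identical(got$end, as.integer(exp[, 3]))
    }
  }
})

test_that("region calling is invariant to sub-threshold padding", {
  set.seed(21)
  z <- pmax(0, rnorm(60, 1.5, 1.5))
  base <- call_snp_regions(signal_track(101:160, z))
  padded <- call_snp_regions(signal_track(c(1:100, 101:160, 161:260),
                                          c(rep(0, 100), z, rep(0, 100))))
  expect_equal(base, padded)
})

test_that("WGS SNP filtering applies inclusive thresholds like the predicate oracle", {
  s <- snp_table(chrom = rep("I", 4), pos = 1:4 * 100,
                 ref = "A", alt = "C",
                 qual = c(29, 30, 60, 60), gq = c(50, 20, 19, 20),
                 zygosity = c("hom", "hom", "hom", "het"))
  out <- filter_wgs_snps(s)
  expect_identical(out$pos, 200L)  # QUAL 29 out; GQ 19 out; het out

  set.seed(22)
  for (i in 1:50) {
    s <- snp_table(chrom = "I", pos = sample(1e6, 80),
                   ref = "A", alt = "G",
                   qual = sample(20:40, 80, TRUE), gq = sample(10:30, 80, TRUE),
                   zygosity = sample(c("hom", "het"), 80, TRUE))
    keep <- s$qual >= 30 & s$gq >= 20 & s$zygosity == "hom"
    expect_identical(filter_wgs_snps(s)$pos, s$pos[keep])
  }
})

test_that("prediction matching: exact matches, FDR, and the maximum-matching oracle", {
  snps <- snp_table(chrom = "I", pos = c(100L, 200L, 300L), ref = "A",
                    alt = "C", qual = 60, gq = 60)
  preds <- data.frame(chrom = "I", pos = c(100L, 200L, 300L))
  rep0 <- match_predictions(preds, snps, window = 0)
  expect_identical(rep0$n_matched, 3L)
  expect_equal(rep0$fdr, 0)

  # empty prediction set: undefined FDR
  expect_true(is.na(match_predictions(preds[0, ], snps, 20)$fdr))

  # one-to-one consumption: two predictions cannot share one SNP
  preds2 <- data.frame(chrom = "I", pos = c(99L, 101L))
  snps1 <- snp_table("I", 100L, "A", "C", 60, 60)
  expect_identical(match_predictions(preds2, snps1, 5)$n_matched, 1L)

  # random instances <= 50 items vs exhaustive maximum-cardinality matching
  set.seed(23)
  n_diff <- 0L
  for (i in 1:200) {
    np <- sample(1:25, 1); ns <- sample(1:25, 1)
    pp <- sort(sample(500, np)); sp <- sort(sample(500, ns))
    w <- sample(c(5L, 10L, 20L), 1)
    greedy <- match_predictions(data.frame(chrom = "I", pos = pp),
                                snp_table("I", sp, "A", "C", 60, 60),
                                w)$n_matched
    opt <- oracle_max_matching(pp, sp, w)
    expect_lte(greedy, opt)
    if (greedy < opt) n_diff <- n_diff + 1L
  }
  # greedy nearest-neighbour is near-optimal; discrepancies are logged
  if (n_diff > 0)
    message("greedy vs optimal matching differed on ", n_diff, "/200 instances")
  expect_lte(n_diff, 20L)
})

test_that("matched counts are monotone in the window (5-20 bp sweep)", {
  set.seed(24)
  snps <- simulate_parental_snp_sets(300, common_fraction = 0, seed = 24)$b
  preds <- simulate_tiling_predictions(snps, jitter_sd = 6,
                                       false_positive_rate = 0.4, seed = 25)
  sweep <- match_window_sweep(preds, snps)
  expect_true(all(diff(sweep$n_matched) >= 0))
  expect_true(all(sweep$fdr >= 0 & sweep$fdr <= 1))
})

test_that("simulated tiling predictions recover the configured FDR (0.65 +- 0.03)", {
  set.seed(26)
  # 1190 true SNPs + spurious calls at FDR 0.65 gives ~3400 predictions,
  # the scale of a genome-wide tiling screen; 20 replicates of the mean
  # (single-replicate binomial SD is already 0.008 at this size)
  fdrs <- replicate(20, {
    snps <- simulate_parental_snp_sets(1190, common_fraction = 0,
                                       seed = NULL)$b
    preds <- simulate_tiling_predictions(snps, jitter_sd = 5,
                                         false_positive_rate = 0.65,
                                         seed = NULL)
    match_predictions(preds, snps, window = 20)$fdr
  })
  expect_lt(abs(mean(fdrs) - 0.65), 0.03)
})

test_that("parental origin assignment handles unique, shared and divergent sites", {
  b <- snp_table(chrom = c("I", "I", "I"), pos = c(100L, 200L, 300L),
                 ref = "A", alt = c("C", "G", "T"), qual = 60, gq = 60)
  g <- snp_table(chrom = c("I", "I"), pos = c(200L, 300L),
                 ref = "A", alt = c("G", "C"), qual = 60, gq = 60)
  expect_message(panel <- assign_parental_origin(b, g), "non-discriminating")
  # pos 100: B-only -> allele_b = alt, allele_g = ref
  expect_identical(panel$allele_b[panel$pos == 100], "C")
  expect_identical(panel$allele_g[panel$pos == 100], "A")
  # pos 200: same alt in both -> dropped
  expect_false(200 %in% panel$pos)
  # pos 300: different alts -> alt-vs-alt marker
  expect_identical(panel$allele_b[panel$pos == 300], "T")
  expect_identical(panel$allele_g[panel$pos == 300], "C")

  # simulated sets: panel size equals the symmetric-difference oracle
  sets <- simulate_parental_snp_sets(200, common_fraction = 0.5, seed = 27)
  key <- function(s) paste0(s$chrom, ":", s$pos)
  expect_identical(nrow(sets$panel),
                   length(c(setdiff(key(sets$b), key(sets$g)),
                            setdiff(key(sets$g), key(sets$b)))))
})

test_that("occurrence counting matches a manual tally and flags >k markers", {
  g <- toy_geno(rep("G", 35), sprintf("e%d", 1:7),
                sprintf("m%d", 1:5))
  occ <- count_occurrences(g)
  expect_true(all(occ$marker_counts$b_count == 0))
  expect_true(all(occ$segregant_b_proportion == 0))

  # hand-built 7x5 matrix: manual tally
  calls <- c("B","G","G","B","G",
             "B","B","G","B","G",
             "B","G","G","B","G",
             "B","B","G","B","G",
             "B","G","G","G","G",
             "G","B","G","B","G",
             "B","G","G","B","B")
  g <- toy_geno(calls, sprintf("e%d", 1:7), sprintf("m%d", 1:5))
  occ <- count_occurrences(g, k = 4L)
  expect_identical(occ$marker_counts$b_count, c(6L, 3L, 0L, 6L, 1L))
  expect_identical(occ$marker_counts$flagged, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(occ$segregant_b_proportion[1]), 2 / 5)
  expect_error(count_occurrences(g, segregants = "nope"), "not in matrix")
})

test_that("region clustering matches single-linkage at the gap threshold", {
  # single marker -> single one-member region
  m1 <- data.frame(id = "a", chrom = "I", pos = 100L)
  r <- cluster_regions(m1)
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_markers, 1L)

  # 60 kb apart with a 50 kb gap -> two regions
  m2 <- data.frame(id = c("a", "b"), chrom = "I", pos = c(100000L, 160000L))
  expect_identical(nrow(cluster_regions(m2, max_gap = 50000L)), 2L)
  expect_identical(nrow(cluster_regions(m2, max_gap = 60000L)), 1L)

  # random marker sets vs brute-force single linkage
  set.seed(28)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    mm <- data.frame(id = sprintf("m%d", 1:n),
                     chrom = sample(c("I", "II"), n, TRUE),
                     pos = sample(5e5, n))
    gap <- sample(c(10000L, 50000L), 1)
    got <- cluster_regions(mm, gap)
    exp <- oracle_cluster(mm$chrom, mm$pos, gap)
    expect_identical(nrow(got), length(exp))
    expect_identical(got$start, as.integer(vapply(exp, `[`, 1.0, 1)))
    expect_identical(got$end, as.integer(vapply(exp, `[`, 1.0, 2)))
  }
})

test_that("BED export is 0-based half-open", {
  r <- cluster_regions(data.frame(id = c("a", "b"), chrom = "IV",
                                  pos = c(953432L, 978432L)))
  f <- withr::local_tempfile(fileext = ".bed")
  regions_to_bed(r, f)
  bed <- read.delim(f, header = FALSE)
  expect_identical(bed$V2, 953431L)
  expect_identical(bed$V3, 978432L)
})

test_that("coverage-deletion detection flags contiguous low-coverage blocks", {
  genes <- c("YOR380W", "YOR381W", "FIT2", "FIT3", "FRE5", "YOR385W",
             "PHR1", "YOR387W", "YOR388C")
  cov <- data.frame(gene = genes, chrom = "XV",
                    start = seq(1060000, by = 2000, length.out = 9),
                    rpk_query = c(50, 48, 0, 0, 0, 0, 0, 0, 52),
                    rpk_ref = c(49, 50, 47, 55, 60, 44, 51, 46, 50))
  # equal coverage everywhere -> no flags
  eq <- cov; eq$rpk_query <- eq$rpk_ref
  expect_identical(nrow(detect_coverage_deletions(eq)$blocks), 0L)

  # six consecutive zero-coverage genes -> one 6-gene block
  rep <- detect_coverage_deletions(cov)
  expect_identical(nrow(rep$blocks), 1L)
  expect_identical(rep$blocks$n_genes, 6L)
  expect_identical(rep$blocks$genes,
                   "FIT2,FIT3,FRE5,YOR385W,PHR1,YOR387W")

  # random tables vs the predicate oracle
  set.seed(29)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    cv <- data.frame(gene = sprintf("g%d", 1:n), chrom = "I",
                     start = sort(sample(1e6, n)),
                     rpk_query = round(runif(n, 0, 5), 2),
                     rpk_ref = round(runif(n, 0, 60), 2))
    got <- detect_coverage_deletions(cv)$flags$deleted
    exp <- (cv$rpk_query + 0.5) / (cv$rpk_ref + 0.5) <= 0.1
    expect_identical(got, exp)
  }
})
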