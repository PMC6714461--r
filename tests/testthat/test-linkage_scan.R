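test_that("Mendelian QC reproduces the chi-square closed form", {
  # 40 B / 37 G of 77: X2 = 9/77, p ~ 0.73, passes
  g <- toy_geno(c(rep("B", 40), rep("G", 37)), sprintf("s%02d", 1:77), "m1")
  qc <- qc_genotypes(g)
  expect_equal(qc$markers$chisq, 9 / 77, tolerance = 1e-12)
  expect_equal(qc$markers$p, pchisq(9 / 77, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(qc$markers$pass)

  # total distortion fails
  g <- toy_geno(rep("B", 77), sprintf("s%02d", 1:77), "m1")
  expect_false(qc_genotypes(g)$markers$pass)

  # call-rate flags
  m <- matrix(c(rep(c("B", "G"), 10)), ncol = 2)
  m[1, 1] <- NA
  rownames(m) <- sprintf("s%02d", 1:10); colnames(m) <- c("m1", "m2")
  qc <- qc_genotypes(genotype_matrix(m))
  expect_false(qc$segregants$pass[1])
  expect_true(all(qc$segregants$pass[-1]))
  expect_error(qc_genotypes(toy_geno(c("B", "G"), c("a", "b"), "m1")),
               "at least 10")
})

test_that("null segregation fails QC at close to the exact type-I rate", {
  # oracle: exact rejection probability of the discrete chi-square at n=77
  exact <- oracle_chisq_type1(77, 0.05)
  set.seed(30)
  panel <- h4_marker_panel()
  h_b <- setNames(rep("B", 43), panel$id)
  h_g <- setNames(rep("G", 43), panel$id)
  fails <- replicate(200, {
    g <- simulate_segregants(h_b, h_g, panel, 77)
    mean(!qc_genotypes(g)$markers$pass)
  })
  rate <- mean(fails)
  n_tests <- 200 * 43
  expect_lt(abs(rate - exact), 3 * sqrt(exact * (1 - exact) / n_tests) + 0.005)
  expect_lt(abs(rate - 0.05), 0.02)  # ~5% at alpha = 0.05
})

test_that("rank-sum test agrees with exhaustive enumeration for n <= 8", {
  # B {1,2,3} vs G {4,5,6}: exact two-sided p = 0.1 (2 of 20 assignments)
  ts <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(ts$exact)
  expect_equal(ts$p.value, 0.1, tolerance = 1e-12)
  expect_equal(oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)

  # identical multisets give p = 1
  expect_equal(ranksum_test(c(1, 2, 5), c(1, 2, 5))$p.value, 1)

  # all split sizes with pooled n <= 8, random tie-free values
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    n1 <- sample(2:(n - 2), 1)
    v <- sample(1000, n)  # distinct -> tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(ranksum_test(x, y)$p.value, oracle_ranksum_p(x, y),
                 tolerance = 1e-9,
                 label = sprintf("n=%d n1=%d", n, n1))
  }
})

test_that("normal approximation tracks the permutation null at n = 77", {
  set.seed(32)
  for (i in 1:30) {
    y <- c(rnorm(40, 0.5), rnorm(37, 0))  # 0.5-SD location shift
    x <- y[1:40]; z <- y[41:77]
    p_norm <- ranksum_test(x, z)$p.value
    # permutation estimate of the two-sided p
    r <- rank(y)
    u_obs <- sum(r[1:40]) - 40 * 41 / 2
    mu <- 40 * 37 / 2
    us <- replicate(20000, sum(sample(r, 40)) - 40 * 41 / 2)
    p_perm <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    if (p_perm > 0.005 && p_perm < 0.6) {
      mc_se <- sqrt(p_perm * (1 - p_perm) / 20000)
      expect_lt(abs(p_norm - p_perm), 0.1 * p_perm + 3 * mc_se)
    }
  }
})

test_that("the scan reports directions and skips under-filled markers", {
  panel <- toy_panel()
  calls <- c("B","B","G","G","B",
             "B","B","G","G","B",
             "B","G","G","B","B",
             "G","G","B","B","B",
             "G","G","B","B","B",
             "G","B","B","G","B")
  g <- toy_geno(calls, sprintf("s%d", 1:6), panel$id)
  ph <- phenotype_table(rep(sprintf("s%d", 1:6), 2), "RS",
                        rep(c(1, 2, 3, 10, 11, 12), 2), rep(1:2, each = 6))
  scan <- wilcoxon_scan(g, ph, "RS", panel = panel)
  # marker II_400 is constant "B": skipped
  expect_false("II_400" %in% scan$marker)
  expect_true("II_400" %in% attr(scan, "skipped"))
  # B carriers at I_10 have the low RS values -> direction B
  expect_identical(scan$direction[scan$marker == "I_10"], "B")
  # constant phenotype -> p = 1
  ph2 <- phenotype_table(sprintf("s%d", 1:6), "RS", rep(5, 6))
  expect_true(all(wilcoxon_scan(g, ph2, "RS")$p == 1))
})

test_that("scan p-values are invariant to monotone trait transforms and id relabeling", {
  pop <- simulate_mapping_population(sim_config(seed = 40))
  # the scan ranks per-segregant replicate means; a monotone transform of
  # that vector must leave every p unchanged
  m <- trait_means(pop$pheno, "RS")
  ph1 <- phenotype_table(names(m), "RS", as.numeric(m))
  ph2 <- phenotype_table(names(m), "RS", exp(as.numeric(m) / 20))
  scan1 <- wilcoxon_scan(pop$geno, ph1, "RS")
  scan2 <- wilcoxon_scan(pop$geno, ph2, "RS")
  expect_equal(scan1$p, scan2$p, tolerance = 1e-12)

  # relabeling segregants jointly leaves the scan unchanged
  perm <- sample(nrow(pop$geno))
  g2 <- genotype_matrix(unclass(pop$geno)[perm, , drop = FALSE])
  scan3 <- wilcoxon_scan(g2, pop$pheno, "RS")
  expect_equal(scan1$p, scan3$p, tolerance = 1e-12)
})

test_that("single-marker permutation threshold converges to -log10(alpha)", {
  set.seed(41)
  g <- toy_geno(sample(rep(c("B", "G"), c(40, 37))), sprintf("s%02d", 1:77),
                "m1")
  ph <- phenotype_table(sprintf("s%02d", 1:77), "RS", rnorm(77, 20, 5))
  thr <- permutation_thresholds(g, ph, "RS", n_perm = 2000, seed = 42)
  expect_lt(abs(thr[["0.05"]] - (-log10(0.05))), 0.15)
  expect_lt(abs(thr[["0.1"]] - (-log10(0.10))), 0.15)
  expect_gte(thr[["0.05"]], thr[["0.1"]])
  expect_error(permutation_thresholds(g, ph, "RS", n_perm = 50), ">= 100")
})

test_that("threshold(5%) controls the genome-wide false-positive rate at 5% +- 2%", {
  # fixed genotypes; under an exchangeable null the permutation distribution
  # *is* the null distribution of the max statistic, so fresh null draws
  # scanned against one permutation threshold measure the FWER directly
  pop <- simulate_mapping_population(sim_config(seed = 50, qtl_spec = NULL))
  thr <- permutation_thresholds(pop$geno, pop$pheno, "RS", n_perm = 1000,
                                seed = 51)
  set.seed(52)
  n_null <- 500
  Y <- matrix(rnorm(77 * n_null, 20, 5), nrow = 77,
              dimnames = list(rownames(pop$geno), NULL))
  maxes <- nilqtl:::.scan_max_neglogp(pop$geno, Y)
  fwer5 <- mean(maxes >= thr[["0.05"]])
  fwer10 <- mean(maxes >= thr[["0.1"]])
  expect_lt(abs(fwer5 - 0.05), 0.02)
  expect_lt(abs(fwer10 - 0.10), 0.03)
})

test_that("permutation thresholds are reproducible and ordered", {
  pop <- simulate_mapping_population(sim_config(seed = 53))
  t1 <- permutation_thresholds(pop$geno, pop$pheno, "RS", 200, seed = 7)
  t2 <- permutation_thresholds(pop$geno, pop$pheno, "RS", 200, seed = 7)
  expect_equal(as.numeric(t1), as.numeric(t2))
  expect_gte(t1[["0.05"]], t1[["0.1"]])
})

test_that("variance decomposition recovers constructed shares exactly without noise", {
  # balanced two-locus design, y = 2 x1 + 1 x2: shares 80/20, interaction 0
  cells <- expand.grid(L1 = c("B", "G"), L2 = c("B", "G"),
                       rep = 1:5, stringsAsFactors = FALSE)
  g <- toy_geno(as.character(t(as.matrix(cells[, 1:2]))),
                sprintf("s%02d", seq_len(nrow(cells))), c("mA", "mB"))
  y <- 2 * (cells$L1 == "B") + 1 * (cells$L2 == "B")
  ph <- phenotype_table(sprintf("s%02d", seq_len(nrow(cells))), "Y", y)
  vd <- variance_explained(g, ph, "Y", c("mA", "mB"))
  expect_equal(vd$percent[vd$term == "mA"], 80, tolerance = 1e-8)
  expect_equal(vd$percent[vd$term == "mB"], 20, tolerance = 1e-8)
  expect_equal(vd$percent[vd$term == "mA:mB"], 0, tolerance = 1e-8)
  expect_identical(attr(vd, "model"), "two_locus_interaction")

  # one-way model
  vd1 <- variance_explained(g, ph, "Y", "mA")
  expect_identical(attr(vd1, "model"), "one_way")
  expect_equal(vd1$percent[1], 80, tolerance = 1e-8)

  # percentages sum to 100 with the residual
  expect_equal(sum(vd$percent), 100, tolerance = 1e-8)
})

test_that("variance decomposition is calibrated under the null", {
  set.seed(54)
  res <- t(replicate(200, {
    g <- toy_geno(sample(c("B", "G"), 80, TRUE), sprintf("s%02d", 1:40),
                  c("mA", "mB"))
    ph <- phenotype_table(sprintf("s%02d", 1:40), "Y", rnorm(40))
    vd <- variance_explained(g, ph, "Y", c("mA", "mB"),
                             with_interaction = FALSE)
    c(vd$percent[1], vd$p[1])
  }))
  expect_lt(mean(res[, 1]), 6)              # ~ 100/(n-1) ~ 2.6% under null
  frac_sig <- mean(res[, 2] < 0.05)
  expect_lt(abs(frac_sig - 0.05), 0.05)     # p roughly uniform
})

test_that("H4-like simulations recover Table-like variance shares", {
  set.seed(55)
  sh <- t(replicate(60, {
    pop <- simulate_mapping_population(sim_config(seed = NULL))
    vd <- variance_explained(pop$geno, pop$pheno, "RS",
                             c("IV_953", "VIII_464"))
    vd$percent[1:2]
  }))
  # configured shares 25.8 / 15.6 (RS truncation and ANOVA bias allow ~2)
  expect_lt(abs(mean(sh[, 1]) - 25.8), 2 + 3 * sd(sh[, 1]) / sqrt(60))
  expect_lt(abs(mean(sh[, 2]) - 15.6), 2 + 3 * sd(sh[, 2]) / sqrt(60))
})

test_that("extreme selection returns the best decile, ties broken by id", {
  pop <- simulate_mapping_population(sim_config(seed = 60))
  ext <- select_extremes(pop$pheno, "RS", fraction = 0.1)
  expect_length(ext, 7L)  # floor(0.1 * 77)
  means <- trait_means(pop$pheno, "RS")
  expect_true(max(means[ext]) <= min(means[setdiff(names(means), ext)]))

  expect_setequal(select_extremes(pop$pheno, "RS", fraction = 1),
                  rownames(pop$geno))

  # manual sort oracle on a hand-ranked table
  ph <- phenotype_table(sprintf("s%02d", 1:10), "RS",
                        c(5, 3, 9, 1, 7, 2, 8, 4, 10, 6))
  expect_identical(select_extremes(ph, "RS", 0.3), c("s04", "s06", "s02"))
  expect_identical(select_extremes(ph, "RS", 0.2, "highest"),
                   c("s09", "s03"))
})

test_that("sequential cross design maximises phenotypic distance (exhaustive oracle)", {
  set.seed(61)
  for (i in 1:20) {
    g <- toy_geno(sample(c("B", "G"), 20 * 5, TRUE, prob = c(0.6, 0.4)),
                  sprintf("s%02d", 1:20), sprintf("m%d", 1:5))
    y <- runif(20, 2, 55)
    ph <- phenotype_table(sprintf("s%02d", 1:20), "RS", y)
    qual <- rownames(g)[g[, "m1"] == "B" & g[, "m2"] == "B"]
    if (length(qual) < 2) next
    sc <- design_sequential_cross(g, ph, "RS", c("m1", "m2"))
    # exhaustive search over qualifying pairs
    best <- 0
    for (a in seq_along(qual)) for (b in seq_along(qual))
      if (a < b) best <- max(best, abs(y[match(qual[a], rownames(g))] -
                                         y[match(qual[b], rownames(g))]))
    expect_equal(sc$trait_difference, best, tolerance = 1e-9)
    # fixed loci are homozygous-identical in the pair: never heterozygous
    expect_false(any(c("m1", "m2") %in% sc$heterozygous_markers))
  }
  g <- toy_geno(rep("G", 10), sprintf("s%d", 1:5), c("m1", "m2")[1:2])
  ph <- phenotype_table(sprintf("s%d", 1:5), "RS", 1:5)
  expect_error(design_sequential_cross(g, ph, "RS", "m1"), "fewer than 2")
})

test_that("removing major QTLs raises power for the minor QTL (sequential mapping logic)", {
  panel <- h4_marker_panel()
  qtl <- h4_qtl_spec()
  set.seed(62)
  p_h4 <- p_h5 <- numeric(15)
  for (i in 1:15) {
    # H4: all three QTLs segregate in 77 segregants
    pop <- simulate_mapping_population(sim_config(seed = NULL))
    s4 <- wilcoxon_scan(pop$geno, pop$pheno, "RS")
    p_h4[i] <- s4$neglog10_p[s4$marker == "XV_1051"]

    # H5: majors fixed at B (their regions no longer segregate), n = 84,
    # single replicate
    h1 <- setNames(rep("B", 43), panel$id)
    h2 <- setNames(ifelse(panel$chrom %in% c("IV", "VIII"), "B", "G"),
                   panel$id)
    g5 <- simulate_segregants(h1, h2, panel, 84)
    ph5 <- simulate_phenotypes(g5, qtl, trait_mean = 30.3 - sum(qtl$effect[1:2]),
                               residual_sd = 6, n_replicates = 1)
    s5 <- wilcoxon_scan(g5, ph5, "RS")
    p_h5[i] <- s5$neglog10_p[s5$marker == "XV_1051"]
  }
  expect_gt(mean(p_h5), mean(p_h4))
})
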