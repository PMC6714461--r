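# Nonparametric QTL linkage scanning: Mendelian segregation QC, per-marker
# Wilcoxon-Mann-Whitney tests, genome-wide permutation thresholds
# (Churchill-Doerge max-statistic construction), ANOVA variance
# decomposition, extreme-segregant selection and sequential cross design.

#' Two-sample Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test of a location difference between two samples. The exact
#' null distribution is used when the pooled sample size is at most
#' `exact_max` and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. A pooled sample with zero
#' rank variance (e.g. a constant phenotype) yields `p = 1`.
#'
#' @param x,y numeric samples.
#' @param exact_max largest pooled n for the exact distribution (default 30).
#' @return list with `statistic` (the Mann-Whitney U of `x`), `p.value`, and
#'   `exact` (logical).
#' @export
ranksum_test <- function(x, y, exact_max = 30L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_tab <- table(r)
  has_ties <- any(tie_tab > 1L)
  if (!has_ties && n <= exact_max) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(list(statistic = u, p.value = min(1, p), exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tie_corr <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p.value = 1, exact = FALSE))
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5)   # continuity correction
  p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  list(statistic = u, p.value = min(1, p), exact = FALSE)
}

#' Genotype quality control for a backcross panel
#'
#' Per marker: a 1-df chi-square test of 1:1 Mendelian segregation on called
#' genotypes, `X2 = (nB - nG)^2 / (nB + nG)`; markers with `p < alpha` are
#' flagged as distorted, markers with no calls as uncallable. Per segregant:
#' the call rate (fraction of non-missing, homozygous-consistent calls);
#' segregants below `min_call_rate` are flagged.
#'
#' @param geno a [genotype_matrix()] with >= 10 segregants.
#' @param alpha distortion significance level (default 0.05).
#' @param min_call_rate per-segregant call-rate flag threshold (default
#'   0.99).
#' @return list of class `qc_report`: `markers` (data.frame `marker`,
#'   `n_b`, `n_g`, `chisq`, `p`, `pass`, `uncallable`), `segregants`
#'   (data.frame `segregant`, `call_rate`, `pass`) and `global_call_rate`.
#' @export
qc_genotypes <- function(geno, alpha = 0.05, min_call_rate = 0.99) {
  if (nrow(geno) < 10L) stop("at least 10 segregants are required")
  n_b <- colSums(geno == "B", na.rm = TRUE)
  n_g <- colSums(geno == "G", na.rm = TRUE)
  n <- n_b + n_g
  chisq <- ifelse(n > 0, (n_b - n_g)^2 / n, NA_real_)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  markers <- data.frame(marker = colnames(geno), n_b = as.integer(n_b),
                        n_g = as.integer(n_g), chisq = chisq, p = p,
                        pass = !is.na(p) & p >= alpha, uncallable = n == 0,
                        stringsAsFactors = FALSE, row.names = NULL)
  call_rate <- rowMeans(!is.na(geno))
  segregants <- data.frame(segregant = rownames(geno), call_rate = call_rate,
                           pass = call_rate >= min_call_rate,
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(markers = markers, segregants = segregants,
                 global_call_rate = mean(!is.na(geno)), alpha = alpha),
            class = "qc_report")
}

#' Per-marker Wilcoxon linkage scan
#'
#' For each marker, replicate-mean trait values of `B`-carriers are compared
#' with those of `G`-carriers by a two-sided rank-sum test; markers with
#' fewer than two segregants in either genotype class are skipped (recorded
#' in the `skipped` attribute). The reported direction is the allele whose
#' carriers have the lower mean trait value (for residual-sugar-like traits,
#' the improving allele).
#'
#' @param geno a [genotype_matrix()].
#' @param pheno a [phenotype_table()].
#' @param trait trait name.
#' @param panel optional [marker_panel()] supplying marker coordinates.
#' @return data.frame of class `linkage_result` with columns `marker`,
#'   `chrom`, `pos`, `trait`, `statistic`, `p`, `neglog10_p`, `direction`.
#' @export
wilcoxon_scan <- function(geno, pheno, trait, panel = NULL) {
  y <- trait_means(pheno, trait)
  segs <- intersect(rownames(geno), names(y))
  if (length(segs) < 4L) stop("too few segregants with phenotype and genotype")
  g <- geno[segs, , drop = FALSE]
  y <- y[segs]
  rows <- list(); skipped <- character(0)
  for (m in colnames(g)) {
    is_b <- !is.na(g[, m]) & g[, m] == "B"
    is_g <- !is.na(g[, m]) & g[, m] == "G"
    if (sum(is_b) < 2L || sum(is_g) < 2L) { skipped <- c(skipped, m); next }
    ts <- ranksum_test(y[is_b], y[is_g])
    dir <- if (mean(y[is_b]) <= mean(y[is_g])) "B" else "G"
    rows[[m]] <- data.frame(marker = m, trait = trait,
                            statistic = ts$statistic, p = ts$p.value,
                            neglog10_p = -log10(ts$p.value), direction = dir,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no marker had >= 2 segregants per genotype class")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(panel)) {
    idx <- match(res$marker, panel$id)
    res$chrom <- panel$chrom[idx]; res$pos <- panel$pos[idx]
  } else {
    res$chrom <- NA_character_; res$pos <- NA_integer_
  }
  res <- res[, c("marker", "chrom", "pos", "trait", "statistic", "p",
                 "neglog10_p", "direction")]
  attr(res, "skipped") <- skipped
  class(res) <- c("linkage_result", "data.frame")
  res
}

# Vectorised -log10 p for many phenotype vectors against all markers.
# Y: n x nperm matrix of trait vectors (rows aligned to rownames(geno)).
# Uses the identical normal-approximation/exact branches as ranksum_test,
# with a fast path when the matrix has no missing calls.
.scan_max_neglogp <- function(geno, Y, exact_max = 30L) {
  n <- nrow(geno)
  usable <- colnames(geno)[colSums(geno == "B", na.rm = TRUE) >= 2L &
                             colSums(geno == "G", na.rm = TRUE) >= 2L]
  if (!length(usable)) stop("no usable markers")
  no_missing <- !anyNA(geno[, usable, drop = FALSE])
  nperm <- ncol(Y)
  if (no_missing && n > exact_max) {
    R <- apply(Y, 2L, rank)
    ties_ok <- apply(Y, 2L, function(col) !any(duplicated(col)))
    tie_corr <- vapply(seq_len(nperm), function(j) {
      if (ties_ok[j]) 0 else { tt <- table(R[, j]); sum(tt^3 - tt) }
    }, 1.0)
    B <- (geno[, usable, drop = FALSE] == "B") + 0
    n1 <- colSums(B)
    U <- t(B) %*% R - n1 * (n1 + 1) / 2          # markers x nperm
    mu <- n1 * (n - n1) / 2
    sig2 <- outer(n1 * (n - n1) / 12, (n + 1) - tie_corr / (n * (n - 1)))
    Z <- abs(U - mu) - 0.5
    Z[Z < 0] <- 0
    P <- 2 * stats::pnorm(-Z / sqrt(sig2))
    P[P > 1] <- 1
    return(apply(-log10(P), 2L, max))
  }
  # general fallback: per permutation, per marker
  vapply(seq_len(nperm), function(j) {
    y <- Y[, j]
    max(vapply(usable, function(m) {
      is_b <- !is.na(geno[, m]) & geno[, m] == "B"
      is_g <- !is.na(geno[, m]) & geno[, m] == "G"
      -log10(ranksum_test(y[is_b], y[is_g], exact_max)$p.value)
    }, 1.0))
  }, 1.0)
}

#' Genome-wide permutation thresholds for the linkage scan
#'
#' The Churchill-Doerge construction: the trait vector is shuffled across
#' segregants `n_perm` times (jointly for all markers, preserving marker
#' LD), the scan is rerun, and the maximum `-log10 p` over markers is
#' recorded; the threshold at level `l` is the `(1 - l)` empirical quantile
#' of that max distribution. Output is labelled "FDR 5%/10%" by convention
#' in linkage plots, though the construction controls the family-wise error
#' rate.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno a [phenotype_table()].
#' @param trait trait name.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param levels genome-wide significance levels (default 0.05, 0.10).
#' @param seed RNG seed.
#' @return named numeric vector of thresholds in `-log10 p`, names =
#'   levels; attribute `max_stats` holds the permutation max distribution.
#' @export
permutation_thresholds <- function(geno, pheno, trait, n_perm = 1000L,
                                   levels = c(0.05, 0.10), seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  y <- trait_means(pheno, trait)
  segs <- intersect(rownames(geno), names(y))
  g <- geno[segs, , drop = FALSE]
  y <- y[segs]
  Y <- replicate(n_perm, sample(y))
  maxes <- .scan_max_neglogp(g, Y)
  thr <- stats::quantile(maxes, probs = 1 - levels, names = FALSE, type = 7)
  names(thr) <- as.character(levels)
  attr(thr, "max_stats") <- maxes
  thr
}

#' Attach permutation thresholds and significance flags to a scan
#'
#' @param result a `linkage_result` from [wilcoxon_scan()].
#' @param thresholds output of [permutation_thresholds()].
#' @return the `linkage_result` with a `thresholds` attribute and
#'   `significant5`/`significant10` columns.
#' @export
apply_thresholds <- function(result, thresholds) {
  attr(result, "thresholds") <- thresholds
  t5 <- thresholds[["0.05"]]; t10 <- thresholds[["0.1"]]
  if (is.null(t10)) t10 <- thresholds[["0.10"]]
  result$significant5 <- result$neglog10_p >= t5
  result$significant10 <- result$neglog10_p >= t10
  result
}

#' ANOVA variance decomposition at mapped loci
#'
#' Linear model of the replicate-mean trait on one or two marker genotypes
#' (`trait ~ locus1 + locus2 + locus1:locus2`), with Type-II sums of squares
#' for the main effects; the percentage of variance per term is
#' `100 * SS_term / SS_total` (SS_total includes the residual). One locus
#' gives a one-way ANOVA. An empty genotype cell drops the interaction with
#' a message.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno a [phenotype_table()].
#' @param trait trait name.
#' @param loci one or two marker ids, each called in >= 90% of segregants.
#' @param with_interaction include the interaction term (two loci only).
#' @return data.frame of class `variance_decomposition`: `term`,
#'   `ss`, `percent`, `df`, `f`, `p`; attribute `model` is
#'   `"one_way"` or `"two_locus_interaction"`.
#' @export
variance_explained <- function(geno, pheno, trait, loci,
                               with_interaction = length(loci) == 2L) {
  if (!length(loci) %in% 1:2) stop("loci must name one or two markers")
  if (!all(loci %in% colnames(geno)))
    stop("unknown locus id(s): ",
         paste(setdiff(loci, colnames(geno)), collapse = ", "))
  y <- trait_means(pheno, trait)
  segs <- intersect(rownames(geno), names(y))
  g <- geno[segs, loci, drop = FALSE]
  y <- y[segs]
  called <- colMeans(!is.na(g))
  if (any(called < 0.9))
    stop("locus called in < 90% of segregants: ",
         paste(loci[called < 0.9], collapse = ", "))
  ok <- stats::complete.cases(g)
  y <- y[ok]; g <- g[ok, , drop = FALSE]
  ss_total <- sum((y - mean(y))^2)
  df_dat <- data.frame(y = y, lapply(as.data.frame(g), factor))
  names(df_dat) <- c("y", paste0("L", seq_along(loci)))
  if (length(loci) == 1L) {
    fit <- stats::lm(y ~ L1, data = df_dat)
    a <- stats::anova(fit)
    out <- data.frame(term = c(loci, "residual"),
                      ss = a[["Sum Sq"]],
                      percent = 100 * a[["Sum Sq"]] / ss_total,
                      df = a[["Df"]], f = a[["F value"]], p = a[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
    attr(out, "model") <- "one_way"
  } else {
    if (with_interaction) {
      cells <- table(df_dat$L1, df_dat$L2)
      if (any(cells == 0L)) {
        message("empty genotype cell; interaction dropped")
        with_interaction <- FALSE
      }
    }
    rss <- function(fm) sum(stats::resid(stats::lm(fm, data = df_dat))^2)
    rss_add <- rss(y ~ L1 + L2)
    ss1 <- rss(y ~ L2) - rss_add            # Type II main effects
    ss2 <- rss(y ~ L1) - rss_add
    if (with_interaction) {
      fit_full <- stats::lm(y ~ L1 * L2, data = df_dat)
      ss_int <- rss_add - sum(stats::resid(fit_full)^2)
    } else {
      fit_full <- stats::lm(y ~ L1 + L2, data = df_dat)
      ss_int <- NA_real_
    }
    ss_res <- sum(stats::resid(fit_full)^2)
    df_res <- fit_full$df.residual
    ms_res <- ss_res / df_res
    terms <- c(loci, if (with_interaction) paste(loci, collapse = ":"),
               "residual")
    ss <- c(ss1, ss2, if (with_interaction) ss_int, ss_res)
    dfs <- c(1L, 1L, if (with_interaction) 1L, df_res)
    f <- c(ss1, ss2, if (with_interaction) ss_int) / ms_res
    p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
    out <- data.frame(term = terms, ss = ss, percent = 100 * ss / ss_total,
                      df = dfs, f = c(f, NA_real_), p = c(p, NA_real_),
                      stringsAsFactors = FALSE)
    attr(out, "model") <- "two_locus_interaction"
  }
  rownames(out) <- NULL
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Select phenotypically extreme segregants
#'
#' The best decile (by default) of a population: `floor(fraction * n)`
#' segregants with the most extreme replicate-mean trait value; ties are
#' broken by segregant id.
#'
#' @param pheno a [phenotype_table()].
#' @param trait trait name.
#' @param fraction fraction to select, in (0, 1].
#' @param direction `"lowest"` (default; best residual sugars) or
#'   `"highest"`.
#' @return character vector of segregant ids.
#' @export
select_extremes <- function(pheno, trait, fraction = 0.1,
                            direction = c("lowest", "highest")) {
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  y <- trait_means(pheno, trait)
  n_take <- max(1L, floor(fraction * length(y)))
  o <- order(if (direction == "lowest") y else -y, names(y))
  names(y)[o][seq_len(n_take)]
}

#' Design a sequential cross removing fixed major QTLs
#'
#' Among segregants homozygous for the required allele at every fixed locus,
#' returns the pair maximising the absolute trait difference (ties broken by
#' id order). The virtual hybrid of that pair is heterozygous exactly at the
#' markers where the two segregants differ, which never include the fixed
#' loci.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno a [phenotype_table()].
#' @param trait trait name.
#' @param fixed_loci marker ids to condition on.
#' @param required_allele allele required at every fixed locus (default
#'   `"B"`).
#' @return list of class `sequential_cross`: `pair` (two segregant ids),
#'   `trait_difference`, `heterozygous_markers` (ids segregating in the
#'   virtual hybrid).
#' @export
design_sequential_cross <- function(geno, pheno, trait, fixed_loci,
                                    required_allele = "B") {
  if (!all(fixed_loci %in% colnames(geno)))
    stop("unknown fixed locus id(s)")
  y <- trait_means(pheno, trait)
  segs <- intersect(rownames(geno), names(y))
  g <- geno[segs, , drop = FALSE]
  qual <- segs[apply(g[, fixed_loci, drop = FALSE] == required_allele, 1L,
                     function(r) all(!is.na(r)) && all(r))]
  if (length(qual) < 2L)
    stop("fewer than 2 segregants carry '", required_allele,
         "' at all fixed loci")
  qual <- sort(qual)
  best <- NULL; best_d <- -Inf
  for (i in seq_len(length(qual) - 1L)) for (j in (i + 1L):length(qual)) {
    d <- abs(y[qual[i]] - y[qual[j]])
    if (d > best_d) { best_d <- d; best <- c(qual[i], qual[j]) }
  }
  het <- colnames(g)[!is.na(g[best[1L], ]) & !is.na(g[best[2L], ]) &
                       g[best[1L], ] != g[best[2L], ]]
  structure(list(pair = best, trait_difference = unname(best_d),
                 heterozygous_markers = het),
            class = "sequential_cross")
}
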