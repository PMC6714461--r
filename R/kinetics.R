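# Fermentation kinetics: loess smoothing of cumulative CO2 release curves,
# extraction of the standard trait panel (CO2max, LP, T35/T50/T70,
# rate 50-70), broad-sense heritability and trait correlations.

#' Smooth a fermentation curve
#'
#' Local quadratic (loess) regression with tricube weights, evaluated at the
#' input times, then monotonised by running maximum: cumulative CO2 release
#' cannot decrease, so downward noise excursions are flattened.
#'
#' @param curve a [fermentation_curve()] with at least 5 points.
#' @param span loess span in (0, 1]; default 0.2 tracks a 150 h fermentation's
#'   sigmoidal transition to better than 0.1 g/L while still averaging noise.
#' @return a smoothed [fermentation_curve()] (attribute `smoothed = TRUE`).
#' @export
smooth_curve <- function(curve, span = 0.2) {
  if (nrow(curve) < 5L) stop("at least 5 time points are required")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  # a local quadratic needs >= 5 points in its window; floor the span on
  # sparsely sampled curves
  span <- max(span, min(1, 5 / nrow(curve)))
  fit <- stats::loess(co2_g_per_L ~ time_h, data = curve, span = span,
                      degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  sm <- cummax(stats::predict(fit, newdata = curve))
  out <- fermentation_curve(curve$time_h, sm,
                            segregant = attr(curve, "segregant"),
                            replicate = attr(curve, "replicate"),
                            temperature = attr(curve, "temperature"))
  attr(out, "smoothed") <- TRUE
  out
}

.first_crossing <- function(times, values, target) {
  above <- values >= target
  if (!any(above)) return(NA_real_)
  i <- which(above)[1L]
  if (i == 1L) return(times[1L])
  # linear interpolation between the bracketing samples
  t0 <- times[i - 1L]; t1 <- times[i]
  v0 <- values[i - 1L]; v1 <- values[i]
  if (v1 == v0) return(t1)
  t0 + (target - v0) / (v1 - v0) * (t1 - t0)
}

#' Extract kinetic traits from a CO2 curve
#'
#' Traits follow the fermentation-kinetics conventions: `co2max` is the
#' maximum CO2 observed; `lp` (lag phase) is the earliest time at which the
#' production rate first exceeds `rate_threshold`; `t35`, `t50`, `t70` are
#' the linearly interpolated first crossings of 35/50/70% of the *expected*
#' maximum (125 g/L by default, deliberately not the observed maximum);
#' `rate50_70 = 0.2 * expected_max / (t70 - t50)`. Crossings never reached
#' yield `NA`.
#'
#' The rate used for the lag phase is the central finite difference of the
#' smoothed curve. Non-monotonic input is taken as unsmoothed and smoothed
#' internally with a warning.
#'
#' @param curve a [fermentation_curve()], ideally from [smooth_curve()].
#' @param expected_max expected maximal CO2 release, g/L (default 125).
#' @param rate_threshold lag-phase rate threshold, g/L/h (default 0.05).
#' @param span span for internal smoothing if needed.
#' @return list of class `kinetic_traits` with fields `co2max`, `lp`, `t35`,
#'   `t50`, `t70`, `rate50_70`, `expected_max`.
#' @export
extract_traits <- function(curve, expected_max = 125, rate_threshold = 0.05,
                           span = 0.2) {
  stopifnot(expected_max > 0, rate_threshold > 0)
  if (!isTRUE(attr(curve, "smoothed")) && any(diff(curve$co2_g_per_L) < 0)) {
    warning("non-monotonic unsmoothed curve; smoothing internally")
    curve <- smooth_curve(curve, span = span)
  }
  tt <- curve$time_h; y <- curve$co2_g_per_L
  co2max <- max(y)
  n <- length(tt)
  rate <- numeric(n)
  rate[1L] <- (y[2L] - y[1L]) / (tt[2L] - tt[1L])
  rate[n] <- (y[n] - y[n - 1L]) / (tt[n] - tt[n - 1L])
  if (n > 2L)
    rate[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (tt[3:n] - tt[1:(n - 2L)])
  lp <- if (any(rate > rate_threshold)) tt[which(rate > rate_threshold)[1L]]
        else NA_real_
  t35 <- .first_crossing(tt, y, 0.35 * expected_max)
  t50 <- .first_crossing(tt, y, 0.50 * expected_max)
  t70 <- .first_crossing(tt, y, 0.70 * expected_max)
  rate50_70 <- if (!is.na(t50) && !is.na(t70) && t70 > t50)
    0.2 * expected_max / (t70 - t50) else NA_real_
  structure(list(co2max = co2max, lp = lp, t35 = t35, t50 = t50, t70 = t70,
                 rate50_70 = rate50_70, expected_max = expected_max),
            class = "kinetic_traits")
}

#' Kinetic traits for a set of curves, as a phenotype table
#'
#' @param curves list of [fermentation_curve()] objects; segregant and
#'   replicate are taken from curve attributes (or names).
#' @param expected_max,rate_threshold,span passed to [extract_traits()].
#' @param smooth smooth each curve first (default `TRUE`).
#' @return a [phenotype_table()] with traits `CO2max`, `LP`, `T35`, `T50`,
#'   `T70`, `rate50_70`.
#' @export
curves_to_phenotypes <- function(curves, expected_max = 125,
                                 rate_threshold = 0.05, span = 0.2,
                                 smooth = TRUE) {
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    seg <- attr(cv, "segregant")
    if (is.null(seg) || is.na(seg)) seg <- names(curves)[i]
    repl <- attr(cv, "replicate"); if (is.null(repl)) repl <- 1L
    if (smooth) cv <- smooth_curve(cv, span = span)
    tr <- extract_traits(cv, expected_max, rate_threshold, span)
    data.frame(segregant = seg,
               trait = c("CO2max", "LP", "T35", "T50", "T70", "rate50_70"),
               replicate = repl,
               value = c(tr$co2max, tr$lp, tr$t35, tr$t50, tr$t70,
                         tr$rate50_70),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  phenotype_table(df$segregant, df$trait, df$value, df$replicate)
}

#' Broad-sense heritability from replicated controls
#'
#' `h2 = 100 * (s2_progeny - s2_env) / s2_progeny`, where the environmental
#' variance `s2_env` is the mean within-genotype replicate variance of the
#' replicated control genotypes (parents and hybrid) and `s2_progeny` is the
#' variance of the progeny values. Clamped to `[0, 100]`; `NA` when the
#' progeny variance is zero.
#'
#' @param progeny_values numeric progeny trait values (one value per
#'   segregant, e.g. replicate means or single measurements).
#' @param control_replicates list of numeric vectors, one per replicated
#'   control genotype (each with >= 2 replicates).
#' @return heritability in percent, or `NA`.
#' @export
heritability <- function(progeny_values, control_replicates) {
  progeny_values <- progeny_values[!is.na(progeny_values)]
  if (length(progeny_values) < 10L)
    stop("at least 10 progeny values are required")
  if (length(control_replicates) < 2L)
    stop("at least 2 replicated control genotypes are required")
  if (any(vapply(control_replicates, length, 1L) < 2L))
    stop("each control genotype needs >= 2 replicates")
  s2_env <- mean(vapply(control_replicates, stats::var, 1.0))
  s2_prog <- stats::var(progeny_values)
  if (s2_prog == 0) return(NA_real_)
  min(100, max(0, 100 * (s2_prog - s2_env) / s2_prog))
}

#' Pairwise trait correlations with Bonferroni correction
#'
#' Pearson correlations between per-segregant trait means, pairwise-complete;
#' two-sided p-values are multiplied by the number of tested pairs (capped at
#' 1) and flagged significant at adjusted `p <= alpha`.
#'
#' @param pheno a [phenotype_table()].
#' @param alpha adjusted significance cutoff (default 0.001).
#' @return list of class `trait_correlations` with matrices `r`, `p`,
#'   `p_adjusted` and logical `significant`.
#' @export
trait_correlations <- function(pheno, alpha = 0.001) {
  traits <- unique(pheno$trait)
  k <- length(traits)
  if (k < 2L) stop("need at least two traits")
  means <- lapply(traits, function(tr) trait_means(pheno, tr))
  segs <- sort(unique(pheno$segregant))
  wide <- sapply(means, function(v) v[segs])
  colnames(wide) <- traits; rownames(wide) <- segs
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- stats::complete.cases(wide[, c(i, j)])
    if (sum(ok) < 3L) next
    if (stats::sd(wide[ok, i]) == 0 || stats::sd(wide[ok, j]) == 0) next
    ct <- stats::cor.test(wide[ok, i], wide[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  p_adj <- pmin(p * n_pairs, 1)
  diag(p_adj) <- 0
  structure(list(r = r, p = p, p_adjusted = p_adj,
                 significant = !is.na(p_adj) & p_adj <= alpha),
            class = "trait_correlations")
}
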