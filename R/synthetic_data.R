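# Synthetic populations emulating a backcrossed, fully homozygous yeast
# mapping panel: parental SNP sets, meioses under a Haldane map, recurrent
# backcrossing with phenotypic selection, additive QTL phenotypes, logistic
# CO2 kinetics, and noisy tiling-array SNP predictions.

#' S. cerevisiae chromosome lengths (sacCer3)
#'
#' Named vector of the sixteen nuclear chromosome lengths in bp, roman
#' numeral names.
#'
#' @return named integer vector.
#' @export
yeast_chrom_lengths <- function() {
  c(I = 230218L, II = 813184L, III = 316620L, IV = 1531933L, V = 576874L,
    VI = 270161L, VII = 1090940L, VIII = 562643L, IX = 439888L, X = 745751L,
    XI = 666816L, XII = 1078177L, XIII = 924431L, XIV = 784333L,
    XV = 1091291L, XVI = 948066L)
}

.roman_order <- function(chrom) {
  ord <- names(yeast_chrom_lengths())
  m <- match(chrom, ord)
  ifelse(is.na(m), rank(chrom) + length(ord), m)
}

#' Haldane recombination fraction from physical distance
#'
#' Genetic distance is taken proportional to physical distance,
#' `d(cM) = cm_per_kb * kb`, and converted with the Haldane map function
#' `r = (1 - exp(-2 d / 100)) / 2` (no interference).
#'
#' @param d_bp inter-marker distance in bp.
#' @param cm_per_kb recombination density; 0.35 cM/kb is the genome-average
#'   for S. cerevisiae.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d_bp, cm_per_kb = 0.35) {
  d_cm <- cm_per_kb * d_bp / 1000
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Simulation configuration for a backcross mapping design
#'
#' Defaults state the design this package targets: four backcross rounds,
#' 77 fully homozygous segregants, duplicate phenotyping, two major plus one
#' minor additive QTL, 0.35 cM/kb.
#'
#' @param seed RNG seed.
#' @param panel a [marker_panel()]; defaults to [h4_marker_panel()].
#' @param n_backcrosses backcross rounds after the F1 (default 4).
#' @param n_segregants mapping-population size (default 77).
#' @param n_spores_per_round spores screened per backcross round; the single
#'   best is kept (selection fraction 1/30).
#' @param n_replicates phenotype replicates per segregant (default 2).
#' @param qtl_spec data.frame with columns `marker`, `effect`, `allele`:
#'   `effect` (trait units) is added when a segregant carries `allele`.
#' @param trait_mean baseline trait mean (trait units).
#' @param residual_sd per-replicate environmental SD (trait units).
#' @param cm_per_kb recombination density.
#' @param trait trait name the QTLs act on (default `"RS"`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, panel = h4_marker_panel(),
                       n_backcrosses = 4L, n_segregants = 77L,
                       n_spores_per_round = 30L, n_replicates = 2L,
                       qtl_spec = h4_qtl_spec(), trait_mean = 30.3,
                       residual_sd = 6 * sqrt(2), cm_per_kb = 0.35,
                       trait = "RS") {
  stopifnot(n_backcrosses >= 0, n_segregants >= 1, n_spores_per_round >= 1,
            n_replicates >= 1, residual_sd >= 0, cm_per_kb > 0)
  if (!is.null(qtl_spec) && nrow(qtl_spec) &&
      !all(qtl_spec$marker %in% panel$id))
    stop("qtl_spec markers missing from panel: ",
         paste(setdiff(qtl_spec$marker, panel$id), collapse = ", "))
  if (!is.null(qtl_spec) && any(!is.finite(qtl_spec$effect)))
    stop("QTL effects must be finite")
  structure(list(seed = seed, panel = panel, n_backcrosses = n_backcrosses,
                 n_segregants = n_segregants,
                 n_spores_per_round = n_spores_per_round,
                 n_replicates = n_replicates, qtl_spec = qtl_spec,
                 trait_mean = trait_mean, residual_sd = residual_sd,
                 cm_per_kb = cm_per_kb, trait = trait),
            class = "sim_config")
}

#' QTL effect sizes for target variance shares
#'
#' For a bi-allelic locus at frequency 1/2 in a backcross panel, an additive
#' effect `a` contributes variance `a^2/4`. Given target shares `v_i` of the
#' total phenotypic variance and a residual SD, the total variance is
#' `var_res / (1 - sum(v))` and `a_i = 2 sqrt(v_i * var_tot)`.
#'
#' @param shares variance shares in (0, 1), summing to < 1.
#' @param residual_sd SD of the non-QTL variance component (on the scale the
#'   shares refer to, e.g. replicate means).
#' @return numeric effects, same length as `shares`.
#' @export
qtl_effects_for_shares <- function(shares, residual_sd) {
  stopifnot(all(shares > 0), sum(shares) < 1, residual_sd > 0)
  var_tot <- residual_sd^2 / (1 - sum(shares))
  2 * sqrt(shares * var_tot)
}

#' Default 43-marker panel in 12 introgressed regions
#'
#' Forty-three markers clustered in 12 regions on 11 chromosomes, mimicking
#' a KASP panel designed inside donor-introgressed blocks. Regions centred
#' on IV:953 kb, VIII:464 kb and XV:1051 kb carry the panel's QTL markers
#' (`IV_953`, `VIII_464`, `XV_1051`); markers within a region are spaced
#' 25 kb.
#'
#' @return a [marker_panel()] of 43 markers.
#' @export
h4_marker_panel <- function() {
  regions <- data.frame(
    chrom = c("II", "IV", "IV", "V", "VII", "VIII", "X", "XI", "XII",
              "XIII", "XV", "XVI"),
    center = c(300432, 953432, 1400432, 400432, 800432, 464432, 500432,
               300432, 700432, 600432, 1051432, 300432),
    stringsAsFactors = FALSE)
  n_markers <- rep(3L, nrow(regions))
  n_markers[seq_len(7L)] <- 4L   # 7 * 4 + 5 * 3 = 43
  chrom <- character(0); pos <- integer(0)
  for (i in seq_len(nrow(regions))) {
    k <- n_markers[i]
    offs <- (seq_len(k) - 1L - floor((k - 1) / 2)) * 25000  # centre included
    chrom <- c(chrom, rep(regions$chrom[i], k))
    pos <- c(pos, as.integer(regions$center[i] + offs))
  }
  marker_panel(chrom, pos, allele_b = "A", allele_g = "C")
}

#' Default three-QTL specification
#'
#' Two major QTLs (donor `B` allele beneficial, i.e. lowering residual
#' sugars) with variance shares 25.8% and 15.6% at `IV_953` and `VIII_464`,
#' and one minor QTL (7.4%, recipient `G` allele beneficial) at `XV_1051`;
#' shares are on the duplicate-mean scale with a 6 g/L residual SD.
#'
#' @param shares variance shares for (IV_953, VIII_464, XV_1051).
#' @param residual_sd_means residual SD on the replicate-mean scale.
#' @return data.frame with columns `marker`, `effect`, `allele`.
#' @export
h4_qtl_spec <- function(shares = c(0.258, 0.156, 0.074),
                        residual_sd_means = 6) {
  stopifnot(length(shares) <= 3L)
  a <- qtl_effects_for_shares(shares, residual_sd_means)
  k <- seq_along(shares)
  data.frame(marker = c("IV_953", "VIII_464", "XV_1051")[k],
             effect = -a, allele = c("B", "B", "G")[k],
             stringsAsFactors = FALSE)
}

#' Simulate two parental SNP sets and their discriminating marker panel
#'
#' Each strain carries `n_snps` SNPs against the reference; a fraction is
#' shared between strains and the symmetric difference defines the putative
#' bi-allelic marker panel. Defaults are sized to give ~3.4k non-common
#' positions genome-wide.
#'
#' @param n_snps SNPs per strain.
#' @param common_fraction fraction shared between the strains.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed RNG seed.
#' @return list with elements `b`, `g` (each a [snp_table()]) and `panel`
#'   (a [marker_panel()] over the non-common positions).
#' @export
simulate_parental_snp_sets <- function(n_snps = 8500, common_fraction = 0.8,
                                       chrom_lengths = yeast_chrom_lengths(),
                                       seed = NULL) {
  if (n_snps < 1) stop("at least one SNP per strain is required")
  stopifnot(common_fraction >= 0, common_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_common <- round(common_fraction * n_snps)
  n_unique <- n_snps - n_common
  n_total <- n_common + 2L * n_unique
  pos <- .sample_genome_positions(n_total, chrom_lengths)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  idx_common <- seq_len(n_common)
  idx_b <- if (n_unique) n_common + seq_len(n_unique) else integer(0)
  idx_g <- if (n_unique) n_common + n_unique + seq_len(n_unique) else integer(0)
  mk <- function(idx) snp_table(pos$chrom[idx], pos$pos[idx], ref[idx],
                                alt[idx], qual = 60, gq = 60, zygosity = "hom")
  b <- mk(c(idx_common, idx_b))
  g <- mk(c(idx_common, idx_g))
  list(b = b, g = g, panel = assign_parental_origin(b, g))
}

.sample_genome_positions <- function(n, chrom_lengths) {
  chrom <- sample(names(chrom_lengths), size = ceiling(n * 1.3), replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  pos <- vapply(chrom, function(cn) sample.int(chrom_lengths[[cn]], 1L), 1L)
  keep <- !duplicated(paste0(chrom, ":", pos))
  while (sum(keep) < n) {        # rare: resample until enough distinct sites
    extra_c <- sample(names(chrom_lengths), n, replace = TRUE,
                      prob = chrom_lengths / sum(chrom_lengths))
    extra_p <- vapply(extra_c, function(cn) sample.int(chrom_lengths[[cn]], 1L), 1L)
    chrom <- c(chrom[keep], extra_c); pos <- c(pos[keep], extra_p)
    keep <- !duplicated(paste0(chrom, ":", pos))
  }
  chrom <- chrom[keep][seq_len(n)]; pos <- pos[keep][seq_len(n)]
  o <- order(.roman_order(chrom), pos)
  list(chrom = chrom[o], pos = pos[o])
}

#' Simulate one meiosis of a homothallic diploid
#'
#' Produces one recombinant gamete from two parental haplotypes under the
#' Haldane map, then duplicates it: the returned call vector is the fully
#' homozygous diploid genotype of the self-diploidised spore (HO/HO).
#'
#' @param h1,h2 named character haplotypes over the same marker panel
#'   (values `"B"`/`"G"`, names = marker ids).
#' @param panel the [marker_panel()] the haplotypes are defined on.
#' @param cm_per_kb recombination density.
#' @return named character vector of homozygous calls.
#' @export
simulate_meiosis <- function(h1, h2, panel, cm_per_kb = 0.35) {
  if (!identical(names(h1), panel$id) || !identical(names(h2), panel$id))
    stop("haplotypes must be named by, and ordered as, the panel marker ids")
  gamete <- character(nrow(panel))
  for (cn in unique(panel$chrom)) {
    idx <- which(panel$chrom == cn)
    cur <- sample(1:2, 1L)
    gamete[idx[1L]] <- if (cur == 1L) h1[idx[1L]] else h2[idx[1L]]
    if (length(idx) > 1L) {
      r <- haldane_r(diff(panel$pos[idx]), cm_per_kb)
      sw <- stats::runif(length(r)) < r
      for (j in seq_along(r)) {
        if (sw[j]) cur <- 3L - cur
        gamete[idx[j + 1L]] <- if (cur == 1L) h1[idx[j + 1L]] else h2[idx[j + 1L]]
      }
    }
  }
  names(gamete) <- panel$id
  gamete
}

.genetic_value <- function(calls, qtl_spec, trait_mean) {
  g <- trait_mean
  if (!is.null(qtl_spec) && nrow(qtl_spec))
    for (i in seq_len(nrow(qtl_spec)))
      if (!is.na(calls[[qtl_spec$marker[i]]]) &&
          calls[[qtl_spec$marker[i]]] == qtl_spec$allele[i])
        g <- g + qtl_spec$effect[i]
  g
}

#' Simulate a recurrent backcross program
#'
#' Starting from the F1 of an all-`B` donor and an all-`G` recipient, each
#' round sporulates the current hybrid, phenotypes `n_spores_per_round`
#' homozygous spores (residual sugars; lower is better), keeps the best one
#' and crosses it back to the recipient. With `select = FALSE` a random
#' spore is kept, giving the neutral expectation of a `2^-(k+1)` donor
#' genome fraction after `k` backcrosses.
#'
#' @param config a [sim_config()].
#' @param select select the lowest-RS spore each round (default `TRUE`).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `h1`, `h2` (final hybrid haplotypes), `donor_fraction`
#'   (fraction of `B` over both haplotypes) and `log` (per-round data.frame:
#'   round, donor fraction, retained donor block count).
#' @export
simulate_backcross_program <- function(config, select = TRUE,
                                       seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  panel <- config$panel
  donor <- stats::setNames(rep("B", nrow(panel)), panel$id)
  recipient <- stats::setNames(rep("G", nrow(panel)), panel$id)
  h1 <- donor; h2 <- recipient           # F1
  log <- data.frame(round = integer(0), donor_fraction = numeric(0),
                    n_donor_blocks = integer(0))
  if (config$n_backcrosses > 0) {
    for (round in seq_len(config$n_backcrosses)) {
      spores <- replicate(config$n_spores_per_round,
                          simulate_meiosis(h1, h2, panel, config$cm_per_kb))
      if (select) {
        rs <- apply(spores, 2L, function(s)
          max(0, .genetic_value(s, config$qtl_spec, config$trait_mean) +
                stats::rnorm(1L, 0, config$residual_sd)))
        best <- which.min(rs)
      } else {
        best <- sample(ncol(spores), 1L)
      }
      h1 <- spores[, best]
      h2 <- recipient
      runs <- rle(h1 == "B")
      log <- rbind(log, data.frame(
        round = round,
        donor_fraction = mean(c(h1, h2) == "B"),
        n_donor_blocks = sum(runs$values)))
    }
  }
  list(h1 = h1, h2 = h2, donor_fraction = mean(c(h1, h2) == "B"), log = log)
}

#' Simulate a homozygous segregant population from a hybrid
#'
#' @param h1,h2 hybrid haplotypes (named by panel ids).
#' @param panel the [marker_panel()].
#' @param n_segregants population size.
#' @param cm_per_kb recombination density.
#' @param seed RNG seed.
#' @return a [genotype_matrix()] (`n_segregants` x markers), ids `S001`, ...
#' @export
simulate_segregants <- function(h1, h2, panel, n_segregants = 77,
                                cm_per_kb = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- t(replicate(n_segregants, simulate_meiosis(h1, h2, panel, cm_per_kb)))
  rownames(calls) <- sprintf("S%03d", seq_len(n_segregants))
  colnames(calls) <- panel$id
  genotype_matrix(calls)
}

#' Simulate phenotypes under an additive QTL model
#'
#' `y = mu + sum_l a_l 1[g_l = allele_l] (+ interactions) + e`, with
#' `e ~ N(0, residual_sd^2)` independent per replicate; replicates share the
#' genetic value. Residual-sugar values are truncated at zero (a fermentation
#' cannot leave negative sugar).
#'
#' @param geno a [genotype_matrix()].
#' @param qtl_spec data.frame `marker`, `effect`, `allele`.
#' @param trait_mean baseline mean.
#' @param residual_sd per-replicate environmental SD.
#' @param n_replicates replicates per segregant.
#' @param trait trait name (truncation at 0 applies when `"RS"`).
#' @param interaction_spec optional data.frame `marker1`, `marker2`,
#'   `allele1`, `allele2`, `effect`: added when both alleles are carried.
#' @param var_inflate_marker,var_inflate_allele,var_inflate_factor optional
#'   heteroscedasticity switch: segregants carrying the given allele at the
#'   given marker get their residual SD multiplied by the factor.
#' @param seed RNG seed.
#' @return a [phenotype_table()].
#' @export
simulate_phenotypes <- function(geno, qtl_spec, trait_mean, residual_sd,
                                n_replicates = 2L, trait = "RS",
                                interaction_spec = NULL,
                                var_inflate_marker = NULL,
                                var_inflate_allele = "G",
                                var_inflate_factor = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(qtl_spec) && nrow(qtl_spec)) {
    missing_m <- setdiff(qtl_spec$marker, colnames(geno))
    if (length(missing_m))
      stop("unknown QTL marker id(s): ", paste(missing_m, collapse = ", "))
  }
  n <- nrow(geno)
  gval <- rep(trait_mean, n)
  if (!is.null(qtl_spec) && nrow(qtl_spec))
    for (i in seq_len(nrow(qtl_spec)))
      gval <- gval + qtl_spec$effect[i] *
        (!is.na(geno[, qtl_spec$marker[i]]) &
           geno[, qtl_spec$marker[i]] == qtl_spec$allele[i])
  if (!is.null(interaction_spec) && nrow(interaction_spec))
    for (i in seq_len(nrow(interaction_spec)))
      gval <- gval + interaction_spec$effect[i] *
        (geno[, interaction_spec$marker1[i]] == interaction_spec$allele1[i] &
           geno[, interaction_spec$marker2[i]] == interaction_spec$allele2[i])
  sd_i <- rep(residual_sd, n)
  if (!is.null(var_inflate_marker))
    sd_i[!is.na(geno[, var_inflate_marker]) &
           geno[, var_inflate_marker] == var_inflate_allele] <-
      residual_sd * var_inflate_factor
  seg <- rep(rownames(geno), times = n_replicates)
  rep_idx <- rep(seq_len(n_replicates), each = n)
  vals <- rep(gval, times = n_replicates) +
    stats::rnorm(n * n_replicates, 0, rep(sd_i, times = n_replicates))
  if (trait == "RS") vals <- pmax(vals, 0)
  phenotype_table(seg, trait, vals, rep_idx)
}

#' Logistic kinetic model parameters
#'
#' @param co2_max asymptotic CO2 release, g/L.
#' @param t_mid inflection time, h.
#' @param k logistic slope, 1/h.
#' @param noise_sd measurement noise SD, g/L.
#' @param times sampling grid, h (strictly increasing).
#' @return list of class `kinetic_params`.
#' @export
kinetic_params <- function(co2_max = 110, t_mid = 60, k = 0.05, noise_sd = 1,
                           times = seq(0, 200, by = 4)) {
  stopifnot(co2_max > 0, k > 0, noise_sd >= 0, all(diff(times) > 0))
  structure(list(co2_max = co2_max, t_mid = t_mid, k = k, noise_sd = noise_sd,
                 times = times), class = "kinetic_params")
}

#' Simulate a CO2 release curve
#'
#' `CO2(t) = co2_max / (1 + exp(-k (t - t_mid)))` plus raw Gaussian
#' measurement noise (no clipping or monotonisation: smoothing handles it).
#'
#' @param params a [kinetic_params()].
#' @param seed RNG seed.
#' @return a [fermentation_curve()].
#' @export
simulate_co2_curve <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- params$co2_max / (1 + exp(-params$k * (params$times - params$t_mid)))
  fermentation_curve(params$times,
                     mu + stats::rnorm(length(mu), 0, params$noise_sd))
}

#' Simulate tiling-array SNP predictions
#'
#' Each true SNP is reported with probability `sensitivity`, at its position
#' plus rounded Gaussian jitter; spurious predictions are added at random
#' genomic positions (kept > 25 bp from any true SNP) so that the expected
#' false discovery rate equals `false_positive_rate`.
#'
#' @param true_snps a [snp_table()] of real inter-parental SNPs.
#' @param jitter_sd positional jitter SD in bp.
#' @param false_positive_rate target FDR in `[0, 1)`.
#' @param sensitivity per-SNP detection probability.
#' @param chrom_lengths named chromosome lengths for spurious placement.
#' @param seed RNG seed.
#' @return data.frame of class `prediction_table` with columns
#'   `chrom`, `pos`, `z`, sorted by (chrom, pos).
#' @export
simulate_tiling_predictions <- function(true_snps, jitter_sd = 5,
                                        false_positive_rate = 0.65,
                                        sensitivity = 1,
                                        chrom_lengths = yeast_chrom_lengths(),
                                        seed = NULL) {
  stopifnot(false_positive_rate >= 0, false_positive_rate < 1,
            sensitivity >= 0, sensitivity <= 1, jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(nrow(true_snps)) < sensitivity
  chrom <- true_snps$chrom[keep]
  pos <- pmax(1L, true_snps$pos[keep] +
                as.integer(round(stats::rnorm(sum(keep), 0, jitter_sd))))
  n_fp <- round(sum(keep) * false_positive_rate / (1 - false_positive_rate))
  if (n_fp > 0) {
    fp <- .sample_genome_positions(n_fp * 2L, chrom_lengths)
    true_key <- paste0(true_snps$chrom, ":",
                       floor(true_snps$pos / 50))   # coarse exclusion bins
    far <- !(paste0(fp$chrom, ":", floor(fp$pos / 50)) %in% true_key)
    take <- which(far)[seq_len(min(n_fp, sum(far)))]
    chrom <- c(chrom, fp$chrom[take])
    pos <- c(pos, fp$pos[take])
  }
  z <- 3 + abs(stats::rnorm(length(pos)))
  o <- order(chrom, pos)   # same (chrom, pos) string order as snp_table
  df <- data.frame(chrom = chrom[o], pos = as.integer(pos[o]), z = z[o],
                   stringsAsFactors = FALSE)
  class(df) <- c("prediction_table", "data.frame")
  df
}

#' Simulate a complete H4-like mapping population
#'
#' Convenience wrapper stating this package's default world: a hybrid
#' heterozygous at all 43 panel markers (the marker panel is designed inside
#' introgressed regions, which are exactly the regions still segregating),
#' 77 homozygous segregants, duplicate phenotypes with two major and one
#' minor additive QTL.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `geno` ([genotype_matrix()]) and `pheno`
#'   ([phenotype_table()]).
#' @export
simulate_mapping_population <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  panel <- config$panel
  h_b <- stats::setNames(rep("B", nrow(panel)), panel$id)
  h_g <- stats::setNames(rep("G", nrow(panel)), panel$id)
  geno <- simulate_segregants(h_b, h_g, panel, config$n_segregants,
                              config$cm_per_kb)
  pheno <- simulate_phenotypes(geno, config$qtl_spec, config$trait_mean,
                               config$residual_sd, config$n_replicates,
                               trait = config$trait)
  list(geno = geno, pheno = pheno)
}
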