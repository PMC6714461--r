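# End-to-end orchestration: simulate -> kinetics -> validate markers ->
# QC + linkage scan -> annotate, with a YAML config, stage logging and a
# reproducibility manifest (seeds, checksums, row counts).

#' Default pipeline configuration
#'
#' @return named list of the demo configuration: 77 segregants, 43 markers,
#'   three QTLs (two major, one minor), duplicate phenotyping, 1000
#'   permutations.
#' @export
default_pipeline_config <- function() {
  list(seed = 42L, n_segregants = 77L, n_replicates = 2L,
       n_permutations = 1000L, trait = "RS", expected_max = 125,
       n_snps = 2000L, snp_common_fraction = 0.8, tiling_fdr = 0.65,
       tiling_jitter_sd = 5, match_window = 20L, n_backcrosses = 4L)
}

.read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$n_permutations) || cfg$n_permutations < 100L)
    stop("config error: n_permutations must be >= 100")
  if (cfg$n_segregants < 10L)
    stop("config error: n_segregants must be >= 10")
  if (cfg$n_replicates < 1L) stop("config error: n_replicates must be >= 1")
  cfg
}

.stage_log <- function(stage, msg, verbose = TRUE) {
  if (verbose)
    message(sprintf("[%s] %-16s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: (1) simulate a backcross mapping population and per-segregant CO2
#' curves; (2) extract kinetic traits; (3) simulate parental SNP sets and
#' tiling predictions, validate markers and cluster introgressed regions;
#' (4) genotype QC, Wilcoxon linkage scan with permutation thresholds,
#' variance decomposition at the top markers; (5) annotate the two bundled
#' synthetic CDS variants. All randomness derives from the single config
#' seed via a fixed per-stage fan-out, so a rerun with the same config is
#' byte-identical.
#'
#' @param config path to a YAML config file, or a named list; see
#'   [default_pipeline_config()] for keys.
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress to stderr.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("nilqtl_run_"),
                         verbose = TRUE) {
  cfg <- .read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- cfg$seed + 1000L * (1:5)
  artifacts <- character(0)
  counts <- list()

  # stage 1: population simulation
  .stage_log("simulate", sprintf("%d segregants, seed %d", cfg$n_segregants,
                                 seeds[1]), verbose)
  sc <- sim_config(seed = seeds[1], n_segregants = cfg$n_segregants,
                   n_replicates = cfg$n_replicates,
                   n_backcrosses = cfg$n_backcrosses)
  pop <- simulate_mapping_population(sc)
  f_geno <- file.path(out_dir, "genotypes.tsv")
  f_pheno <- file.path(out_dir, "phenotypes.tsv")
  write_genotype_matrix(pop$geno, f_geno)
  write_phenotype_table(pop$pheno, f_pheno)
  artifacts <- c(artifacts, f_geno, f_pheno)
  counts$segregants <- nrow(pop$geno)
  counts$markers <- ncol(pop$geno)

  # stage 2: kinetics on simulated curves; fermentation speed tracks the
  # genetic RS value (slower fermentation <-> more residual sugar)
  .stage_log("kinetics", "simulating and reducing CO2 curves", verbose)
  set.seed(seeds[2])
  rs_mean <- trait_means(pop$pheno, cfg$trait)
  curves <- list()
  for (s in rownames(pop$geno)) for (r in seq_len(cfg$n_replicates)) {
    pars <- kinetic_params(co2_max = 125 - rs_mean[[s]] * 0.6,
                           t_mid = 55 + rs_mean[[s]] * 1.2, k = 0.05,
                           noise_sd = 1)
    cv <- simulate_co2_curve(pars)
    attr(cv, "segregant") <- s; attr(cv, "replicate") <- r
    curves[[paste(s, r, sep = "_")]] <- cv
  }
  kin <- curves_to_phenotypes(curves, expected_max = cfg$expected_max)
  f_kin <- file.path(out_dir, "kinetic_traits.tsv")
  write_phenotype_table(kin, f_kin)
  artifacts <- c(artifacts, f_kin)
  counts$curves <- length(curves)

  # stage 3: marker validation
  .stage_log("validate-markers", "tiling predictions vs WGS SNPs", verbose)
  par_sets <- simulate_parental_snp_sets(cfg$n_snps, cfg$snp_common_fraction,
                                         seed = seeds[3])
  preds <- simulate_tiling_predictions(par_sets$b,
                                       jitter_sd = cfg$tiling_jitter_sd,
                                       false_positive_rate = cfg$tiling_fdr,
                                       seed = seeds[3] + 1L)
  filtered <- filter_wgs_snps(par_sets$b)
  report <- match_predictions(preds, filtered, cfg$match_window)
  f_match <- file.path(out_dir, "match_report.json")
  jsonlite::write_json(list(n_predicted = report$n_predicted,
                            n_matched = report$n_matched,
                            window = report$window, fdr = report$fdr),
                       f_match, auto_unbox = TRUE, digits = 6)
  f_panel <- file.path(out_dir, "marker_panel.tsv")
  utils::write.table(par_sets$panel, f_panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  regions <- cluster_regions(par_sets$panel)
  f_bed <- file.path(out_dir, "introgressed_regions.bed")
  regions_to_bed(regions, f_bed)
  artifacts <- c(artifacts, f_match, f_panel, f_bed)
  counts$predicted_snps <- report$n_predicted
  counts$validated_markers <- report$n_matched

  # stage 4: QC + linkage scan
  .stage_log("scan", sprintf("Wilcoxon scan, %d permutations",
                             cfg$n_permutations), verbose)
  qc <- qc_genotypes(pop$geno)
  f_qc <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(list(global_call_rate = qc$global_call_rate,
                            n_distorted = sum(!qc$markers$pass),
                            n_flagged_segregants = sum(!qc$segregants$pass)),
                       f_qc, auto_unbox = TRUE, digits = 6)
  scan <- wilcoxon_scan(pop$geno, pop$pheno, cfg$trait, panel = sc$panel)
  thr <- permutation_thresholds(pop$geno, pop$pheno, cfg$trait,
                                n_perm = cfg$n_permutations, seed = seeds[4])
  scan <- apply_thresholds(scan, thr)
  f_scan <- file.path(out_dir, "scan.tsv")
  write_linkage_table(scan, f_scan)
  top2 <- scan$marker[order(scan$p)][1:2]
  vd <- variance_explained(pop$geno, pop$pheno, cfg$trait, sort(top2))
  f_vd <- file.path(out_dir, "variance_decomposition.tsv")
  utils::write.table(vd, f_vd, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, f_qc, f_scan, f_vd)
  counts$scanned_markers <- nrow(scan)
  counts$significant5 <- sum(scan$significant5)

  # stage 5: annotation of the bundled synthetic variants
  .stage_log("annotate", "synthetic OYE2/VHS1 stand-in variants", verbose)
  ann <- rbind(
    .consequence_row("YHR179W_OYE2_synthetic", synthetic_oye2_cds(),
                     "c.229_230delTC"),
    .consequence_row("YDR247W_VHS1_synthetic", synthetic_vhs1_cds(),
                     "c.1116C>A"))
  f_ann <- file.path(out_dir, "annotations.tsv")
  utils::write.table(ann, f_ann, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, f_ann)

  manifest <- list(
    package_version = as.character(utils::packageVersion("nilqtl")),
    config = cfg, stage_seeds = as.list(stats::setNames(
      seeds, c("simulate", "kinetics", "validate", "scan", "annotate"))),
    row_counts = counts,
    checksums = as.list(tools::md5sum(artifacts)),
    status = "ok")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8)
  .stage_log("done", out_dir, verbose)
  invisible(manifest)
}

.consequence_row <- function(gene, cds, notation) {
  cs <- consequence(cds, notation)
  data.frame(gene = gene, variant = notation, class = cs$class,
             p_notation = cs$p_notation, mutant_length = cs$mutant_length,
             reference_length = cs$reference_length,
             truncation = cs$truncation, stringsAsFactors = FALSE)
}

#' Command-line interface
#'
#' Entry point used by the `exec/nilqtl` script. Subcommands: `run`
#' (full pipeline), `simulate`, `kinetics`, `scan`, `validate-markers`,
#' `annotate`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
nilqtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: nilqtl <command> [options]",
    "  run              --config cfg.yaml --out dir/",
    "  simulate         --seed N --out dir/",
    "  kinetics         --curves dir/ --expected-max 125 --out traits.tsv",
    "  scan             --genotypes g.tsv --phenotypes p.tsv --trait RS",
    "                   --n-perm 1000 --seed N --out scan.tsv",
    "  validate-markers --predictions p.tsv --wgs b.tsv --window 20 --out r.json",
    "  annotate         --cds f.fa --variant 'c.229_230delTC'",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]
  opt <- .parse_cli_opts(args[-1L])
  get <- function(key, default = NULL) {
    if (!is.null(opt[[key]])) opt[[key]] else default
  }
  switch(cmd,
    run = {
      cfg <- if (!is.null(get("config"))) get("config") else list()
      run_pipeline(cfg, out_dir = get("out", "nilqtl_out"))
    },
    simulate = {
      out <- get("out", "nilqtl_sim"); dir.create(out, showWarnings = FALSE)
      sc <- sim_config(seed = as.integer(get("seed", 1)))
      pop <- simulate_mapping_population(sc)
      write_genotype_matrix(pop$geno, file.path(out, "genotypes.tsv"))
      write_phenotype_table(pop$pheno, file.path(out, "phenotypes.tsv"))
    },
    kinetics = {
      files <- list.files(get("curves"), pattern = "\\.csv$",
                          full.names = TRUE)
      curves <- lapply(files, read_fermentation_curve)
      names(curves) <- sub("\\.csv$", "", basename(files))
      kin <- curves_to_phenotypes(
        curves, expected_max = as.numeric(get("expected-max", 125)))
      write_phenotype_table(kin, get("out", "traits.tsv"))
    },
    scan = {
      geno <- read_genotype_matrix(get("genotypes"))
      pheno <- read_phenotype_table(get("phenotypes"))
      trait <- get("trait", "RS")
      scan <- wilcoxon_scan(geno, pheno, trait)
      thr <- permutation_thresholds(geno, pheno, trait,
                                    n_perm = as.integer(get("n-perm", 1000)),
                                    seed = as.integer(get("seed", 1)))
      write_linkage_table(apply_thresholds(scan, thr),
                          get("out", "scan.tsv"))
    },
    `validate-markers` = {
      preds <- utils::read.delim(get("predictions"))
      wgs <- filter_wgs_snps(read_snp_table(get("wgs")))
      rep <- match_predictions(preds, wgs, as.integer(get("window", 20)))
      jsonlite::write_json(list(n_predicted = rep$n_predicted,
                                n_matched = rep$n_matched, fdr = rep$fdr),
                           get("out", "match_report.json"),
                           auto_unbox = TRUE, digits = 6)
    },
    annotate = {
      cds <- read_fasta(get("cds"))[[1L]]
      cs <- consequence(cds, get("variant"))
      cat(sprintf("%s\t%s\tmutant=%d\treference=%d\n", cs$class,
                  cs$p_notation, cs$mutant_length, cs$reference_length))
    },
    { message("unknown command: ", cmd, "\n", usage); return(invisible(1L)) })
  invisible(0L)
}

.parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[[i]], "--")) {
      key <- sub("^--", "", args[[i]])
      if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
        opt[[key]] <- args[[i + 1L]]; i <- i + 2L
      } else { opt[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  opt
}
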