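# Building the validated bi-allelic marker panel: z-score region calling on
# tiling-array signal, WGS SNP quality filtering, prediction-to-SNP matching
# with FDR, parental-origin assignment, occurrence counting in extreme
# segregants, introgressed-region clustering and coverage-based deletion
# detection.

#' Construct a hybridization signal track
#'
#' @param pos 1-based positions, strictly increasing.
#' @param z z-score-transformed hybridization signal.
#' @param chrom chromosome name (single string).
#' @return data.frame of class `signal_track`.
#' @export
signal_track <- function(pos, z, chrom = "I") {
  if (length(pos) != length(z)) stop("pos and z must have equal length")
  if (length(pos) && any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  df <- data.frame(chrom = chrom, pos = as.integer(pos), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Call SNP regions from a signal track
#'
#' Maximal runs of consecutive positions with `z > z_threshold`, at least
#' `min_run` nucleotides long, are conserved; each run is reported at its
#' argmax-z position (first position on ties). Positions must be contiguous
#' (step 1 bp) to belong to one run.
#'
#' @param track a [signal_track()].
#' @param z_threshold signal threshold (default 2.5).
#' @param min_run minimum run length in nucleotides (default 10).
#' @return data.frame of class `prediction_table` with columns `chrom`,
#'   `pos` (peak), `z` (peak z), `start`, `end`.
#' @export
call_snp_regions <- function(track, z_threshold = 2.5, min_run = 10L) {
  if (!nrow(track))
    return(.empty_predictions())
  above <- track$z > z_threshold
  step1 <- c(TRUE, diff(track$pos) == 1L)
  # new run wherever signal drops below threshold or the grid jumps
  grp <- cumsum(!above | !step1)
  out <- list()
  for (g in unique(grp[above])) {
    idx <- which(grp == g & above)
    span <- track$pos[idx[length(idx)]] - track$pos[idx[1L]] + 1L
    if (span >= min_run) {
      peak <- idx[which.max(track$z[idx])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = track$chrom[peak], pos = track$pos[peak], z = track$z[peak],
        start = track$pos[idx[1L]], end = track$pos[idx[length(idx)]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_predictions())
  df <- do.call(rbind, out)
  class(df) <- c("prediction_table", "data.frame")
  df
}

.empty_predictions <- function() {
  df <- data.frame(chrom = character(), pos = integer(), z = numeric(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE)
  class(df) <- c("prediction_table", "data.frame")
  df
}

#' Filter WGS SNPs on quality thresholds
#'
#' Keeps records with `qual >= min_qual`, `gq >= min_gq` and (optionally)
#' homozygous genotype; order is preserved. Thresholds are inclusive.
#'
#' @param snps a [snp_table()].
#' @param min_qual minimum site quality (default 30).
#' @param min_gq minimum genotype quality (default 20).
#' @param require_hom keep homozygous calls only (default `TRUE`).
#' @return filtered [snp_table()].
#' @export
filter_wgs_snps <- function(snps, min_qual = 30, min_gq = 20,
                            require_hom = TRUE) {
  keep <- (!is.na(snps$qual) & snps$qual >= min_qual) &
    (!is.na(snps$gq) & snps$gq >= min_gq)
  if (require_hom) keep <- keep & snps$zygosity == "hom"
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match array predictions to sequencing SNPs
#'
#' Greedy nearest-neighbour matching within `|delta pos| <= window` on the
#' same chromosome; each WGS SNP is consumed at most once; distance ties are
#' broken toward the lower position. The false discovery rate of the
#' prediction set is `1 - n_matched / n_predicted`.
#'
#' @param predictions a `prediction_table` (columns `chrom`, `pos`).
#' @param wgs_snps a [snp_table()] of validated SNPs.
#' @param window matching window in bp (>= 0).
#' @return list of class `match_report`: `n_predicted`, `n_matched`,
#'   `window`, `fdr` (`NA` when nothing was predicted) and `matches`
#'   (data.frame `chrom`, `pred_pos`, `snp_pos`, `distance`).
#' @export
match_predictions <- function(predictions, wgs_snps, window = 20L) {
  if (window < 0) stop("window must be >= 0")
  n_pred <- nrow(predictions)
  matches <- data.frame(chrom = character(), pred_pos = integer(),
                        snp_pos = integer(), distance = integer(),
                        stringsAsFactors = FALSE)
  if (n_pred > 0 && nrow(wgs_snps) > 0) {
    for (cn in intersect(unique(predictions$chrom), unique(wgs_snps$chrom))) {
      pp <- sort(predictions$pos[predictions$chrom == cn])
      sp <- sort(wgs_snps$pos[wgs_snps$chrom == cn])
      cand <- do.call(rbind, lapply(seq_along(pp), function(i) {
        j <- which(abs(sp - pp[i]) <= window)
        if (!length(j)) return(NULL)
        data.frame(pi = i, sj = j, d = abs(sp[j] - pp[i]))
      }))
      if (is.null(cand)) next
      cand <- cand[order(cand$d, pmin(cand$pi, cand$sj), cand$pi, cand$sj), ,
                   drop = FALSE]
      used_p <- logical(length(pp)); used_s <- logical(length(sp))
      for (k in seq_len(nrow(cand))) {
        i <- cand$pi[k]; j <- cand$sj[k]
        if (!used_p[i] && !used_s[j]) {
          used_p[i] <- TRUE; used_s[j] <- TRUE
          matches <- rbind(matches, data.frame(
            chrom = cn, pred_pos = pp[i], snp_pos = sp[j], d = cand$d[k],
            stringsAsFactors = FALSE))
        }
      }
    }
    names(matches) <- c("chrom", "pred_pos", "snp_pos", "distance")
  }
  n_matched <- nrow(matches)
  structure(list(n_predicted = n_pred, n_matched = n_matched,
                 window = window,
                 fdr = if (n_pred > 0) 1 - n_matched / n_pred else NA_real_,
                 matches = matches),
            class = "match_report")
}

#' Sweep the matching window
#'
#' Runs [match_predictions()] across several windows (5-20 bp is the usual
#' range) and tabulates matched counts and FDR; matched counts are
#' monotonically non-decreasing in the window.
#'
#' @param predictions,wgs_snps as in [match_predictions()].
#' @param windows integer windows in bp.
#' @return data.frame `window`, `n_predicted`, `n_matched`, `fdr`.
#' @export
match_window_sweep <- function(predictions, wgs_snps,
                               windows = c(5L, 10L, 15L, 20L)) {
  do.call(rbind, lapply(windows, function(w) {
    rep <- match_predictions(predictions, wgs_snps, w)
    data.frame(window = w, n_predicted = rep$n_predicted,
               n_matched = rep$n_matched, fdr = rep$fdr)
  }))
}

#' Assign parental origin to discriminating SNP positions
#'
#' Positions carried as a non-reference SNP by exactly one parent become
#' markers: the allele of the donor parent (`B`) is its alt (or the ref when
#' only the recipient is variant there). Positions variant in both parents
#' with the same alt, i.e. non-discriminating, are dropped with a message;
#' both-variant positions with *different* alts are kept (alt vs alt
#' markers).
#'
#' @param parent_b [snp_table()] of the donor strain.
#' @param parent_g [snp_table()] of the recipient strain.
#' @return a [marker_panel()] with `allele_b`/`allele_g` filled in.
#' @export
assign_parental_origin <- function(parent_b, parent_g) {
  key <- function(s) paste0(s$chrom, ":", s$pos)
  kb <- key(parent_b); kg <- key(parent_g)
  common <- intersect(kb, kg)
  b_only <- parent_b[!(kb %in% common), , drop = FALSE]
  g_only <- parent_g[!(kg %in% common), , drop = FALSE]
  out <- data.frame(chrom = c(b_only$chrom, g_only$chrom),
                    pos = c(b_only$pos, g_only$pos),
                    allele_b = c(b_only$alt, g_only$ref),
                    allele_g = c(b_only$ref, g_only$alt),
                    stringsAsFactors = FALSE)
  if (length(common)) {
    bi <- parent_b[match(common, kb), ]; gi <- parent_g[match(common, kg), ]
    diff_alt <- bi$alt != gi$alt
    n_drop <- sum(!diff_alt)
    if (n_drop)
      message(n_drop, " position(s) variant in both parents with the same ",
              "alt allele dropped (non-discriminating)")
    if (any(diff_alt))
      out <- rbind(out, data.frame(chrom = bi$chrom[diff_alt],
                                   pos = bi$pos[diff_alt],
                                   allele_b = bi$alt[diff_alt],
                                   allele_g = gi$alt[diff_alt],
                                   stringsAsFactors = FALSE))
  }
  marker_panel(out$chrom, out$pos, out$allele_b, out$allele_g)
}

#' Count donor-allele occurrences across selected extreme segregants
#'
#' For every marker, counts how many of the selected segregants call the
#' donor `B` allele; markers seen in more than `k` segregants (strictly) are
#' flagged as candidate-region markers. Also reports each segregant's
#' B-proportion (B calls over all called markers).
#'
#' @param geno a [genotype_matrix()] restricted to (or containing) the
#'   selected extreme segregants.
#' @param segregants ids of the selected segregants (default: all rows).
#' @param k occurrence threshold; flag markers with count `> k` (default 4,
#'   i.e. "more than 4 of the 7").
#' @return list of class `occurrence_report`: `marker_counts` (data.frame
#'   `marker`, `b_count`, `n_called`, `flagged`) and `segregant_b_proportion`
#'   (named numeric).
#' @export
count_occurrences <- function(geno, segregants = rownames(geno), k = 4L) {
  missing_s <- setdiff(segregants, rownames(geno))
  if (length(missing_s))
    stop("segregants not in matrix: ", paste(missing_s, collapse = ", "))
  sub <- geno[segregants, , drop = FALSE]
  b_count <- colSums(sub == "B", na.rm = TRUE)
  n_called <- colSums(!is.na(sub))
  prop <- rowSums(sub == "B", na.rm = TRUE) / rowSums(!is.na(sub))
  structure(list(
    marker_counts = data.frame(marker = colnames(sub),
                               b_count = as.integer(b_count),
                               n_called = as.integer(n_called),
                               flagged = b_count > k,
                               stringsAsFactors = FALSE, row.names = NULL),
    segregant_b_proportion = prop, k = k),
    class = "occurrence_report")
}

#' Cluster flagged markers into introgressed regions
#'
#' Single-linkage clustering along the chromosome: same-chromosome markers
#' whose inter-marker gap is at most `max_gap` are merged; region bounds are
#' the min/max member positions.
#'
#' @param markers data.frame with columns `id` (or `marker`), `chrom`, `pos`.
#' @param max_gap maximum gap in bp (default 50000).
#' @return data.frame of class `introgressed_regions`: `chrom`, `start`,
#'   `end`, `n_markers`, `members` (comma-separated ids).
#' @export
cluster_regions <- function(markers, max_gap = 50000L) {
  if (!nrow(markers))
    return(structure(data.frame(chrom = character(), start = integer(),
                                end = integer(), n_markers = integer(),
                                members = character()),
                     class = c("introgressed_regions", "data.frame")))
  id_col <- if ("id" %in% names(markers)) "id" else "marker"
  m <- markers[order(.roman_order(markers$chrom), markers$pos), , drop = FALSE]
  new_region <- c(TRUE, diff(m$pos) > max_gap |
                    m$chrom[-1L] != m$chrom[-nrow(m)])
  grp <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), grp), function(idx)
    data.frame(chrom = m$chrom[idx[1L]], start = min(m$pos[idx]),
               end = max(m$pos[idx]), n_markers = length(idx),
               members = paste(m[[id_col]][idx], collapse = ","),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("introgressed_regions", "data.frame")
  out
}

#' Export introgressed regions as BED
#'
#' The only 0-based half-open surface of the package: `start` becomes
#' `start - 1`, `end` stays (1-based inclusive end equals half-open end).
#'
#' @param regions output of [cluster_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Detect gene deletions from coverage ratios
#'
#' Genes where `(rpk_query + eps) / (rpk_ref + eps) <= ratio_threshold` are
#' flagged as deleted in the query strain; runs of consecutive flagged genes
#' (in position order per chromosome) are reported as deletion blocks. The
#' pseudo-count avoids division by zero at fully uncovered genes.
#'
#' @param coverage data.frame with columns `gene`, `chrom`, `start`,
#'   `rpk_query`, `rpk_ref` (reads per kb in the query and reference
#'   strains).
#' @param ratio_threshold flagging threshold (default 0.1).
#' @param eps pseudo-count (default 0.5).
#' @return list of class `deletion_report`: `flags` (data.frame with a
#'   logical `deleted` column) and `blocks` (data.frame `chrom`, `start_gene`,
#'   `end_gene`, `n_genes`, `genes`).
#' @export
detect_coverage_deletions <- function(coverage, ratio_threshold = 0.1,
                                      eps = 0.5) {
  if (any(coverage$rpk_query < 0) || any(coverage$rpk_ref < 0))
    stop("coverage must be >= 0")
  cov <- coverage[order(.roman_order(coverage$chrom), coverage$start), ,
                  drop = FALSE]
  ratio <- (cov$rpk_query + eps) / (cov$rpk_ref + eps)
  cov$ratio <- ratio
  cov$deleted <- ratio <= ratio_threshold
  blocks <- data.frame(chrom = character(), start_gene = character(),
                       end_gene = character(), n_genes = integer(),
                       genes = character(), stringsAsFactors = FALSE)
  if (any(cov$deleted)) {
    brk <- cumsum(c(TRUE, diff(as.integer(cov$deleted)) != 0 |
                      cov$chrom[-1L] != cov$chrom[-nrow(cov)]))
    for (g in unique(brk[cov$deleted])) {
      idx <- which(brk == g & cov$deleted)
      blocks <- rbind(blocks, data.frame(
        chrom = cov$chrom[idx[1L]], start_gene = cov$gene[idx[1L]],
        end_gene = cov$gene[idx[length(idx)]], n_genes = length(idx),
        genes = paste(cov$gene[idx], collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  rownames(cov) <- NULL
  structure(list(flags = cov, blocks = blocks), class = "deletion_report")
}
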