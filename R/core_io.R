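#' @keywords internal
"_PACKAGE"

# Coordinate convention: 1-based inclusive throughout (VCF-style); the only
# 0-based half-open surface is BED export in regions_to_bed().

GENOTYPE_ALPHABET <- c("B", "G")

#' Construct a validated genotype matrix
#'
#' Segregant-by-marker calls for fully homozygous diploid segregants of a
#' backcross population. Calls are `"B"` (donor parent allele), `"G"`
#' (recipient parent allele) or `NA` (missing).
#'
#' @param calls character matrix with segregant ids as rownames and marker ids
#'   as colnames; entries in `c("B", "G", NA)`.
#' @return object of class `genotype_matrix` (a character matrix).
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("calls must be a character matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have segregant rownames and marker colnames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate segregant ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  bad <- !is.na(calls) & !(calls %in% GENOTYPE_ALPHABET)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype symbol '%s' at segregant '%s', marker '%s'",
                 calls[bad][1L], rownames(calls)[idx[1L]], colnames(calls)[idx[2L]]))
  }
  structure(calls, class = c("genotype_matrix", class(calls)))
}

#' Read a genotype matrix from TSV
#'
#' Expects a header row of marker ids, a first column of segregant ids and
#' cells in `{B, G, NA}`. Lines starting with `#` are comments.
#'
#' @param path path to a tab-separated file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  lines <- readLines(path)
  header <- lines[!startsWith(lines, "#")][1L]
  marker_ids <- strsplit(header, "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(marker_ids))  # read.delim would silently uniquify these
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = "NA")
  if (ncol(df) < 2L) stop("genotype TSV needs a segregant id column plus markers")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  colnames(m) <- marker_ids
  genotype_matrix(m)
}

#' Write a genotype matrix to TSV
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(geno, path) {
  df <- data.frame(segregant = rownames(geno), unclass(geno),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a validated SNP table
#'
#' One row per bi-allelic SNP of a strain against the reference genome.
#'
#' @param chrom chromosome names (non-empty strings).
#' @param pos 1-based positions (integer >= 1).
#' @param ref,alt reference and alternate alleles; `ref != alt` rowwise.
#' @param qual phred-scaled site quality (>= 0).
#' @param gq genotype quality.
#' @param zygosity `"hom"` or `"het"`.
#' @return `data.frame` of class `snp_table`, sorted by (chrom, pos).
#' @export
snp_table <- function(chrom, pos, ref, alt, qual = NA_real_, gq = NA_real_,
                      zygosity = "hom") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   qual = as.numeric(qual), gq = as.numeric(gq),
                   zygosity = as.character(zygosity),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(!nzchar(df$chrom))) stop("empty chromosome name")
    if (any(df$pos < 1L)) stop("positions must be >= 1 (1-based)")
    if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
    if (any(!is.na(df$qual) & df$qual < 0)) stop("qual must be >= 0")
    if (any(!df$zygosity %in% c("hom", "het"))) stop("zygosity must be hom or het")
    o <- order(df$chrom, df$pos)
    if (is.unsorted(o)) {
      # callers that require original order should sort before constructing
    }
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Read a SNP table from VCF or TSV
#'
#' Accepts a minimal single-sample VCF 4.x subset (`CHROM, POS, REF, ALT,
#' QUAL` columns plus `GQ` and `GT` in FORMAT) or a TSV with columns
#' `chrom, pos, ref, alt, qual, gq, zygosity`. Records are returned in
#' ascending (chrom, pos) order; unsorted input is sorted with a warning.
#'
#' @param path input file; format sniffed from the `##fileformat=VCF` header
#'   or a `.vcf` extension.
#' @return a [snp_table()].
#' @export
read_snp_table <- function(path) {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat=VCF", first) ||
    grepl("\\.vcf$", path, ignore.case = TRUE)
  if (is_vcf) df <- .read_vcf_subset(path) else df <- .read_snp_tsv(path)
  if (nrow(df) > 1L) {
    o <- order(df$chrom, df$pos)
    if (!identical(o, seq_len(nrow(df))))
      warning("SNP records were not sorted by (chrom, pos); sorting")
  }
  snp_table(df$chrom, df$pos, df$ref, df$alt, df$qual, df$gq, df$zygosity)
}

.read_snp_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("SNP TSV must have columns chrom, pos, ref, alt")
  if (is.null(df$qual)) df$qual <- NA_real_
  if (is.null(df$gq)) df$gq <- NA_real_
  if (is.null(df$zygosity)) df$zygosity <- "hom"
  df
}

.read_vcf_subset <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), gq = numeric(),
                      zygosity = character(), stringsAsFactors = FALSE))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 8L)) stop("malformed VCF record: fewer than 8 columns")
  get <- function(i) vapply(fields, `[[`, "", i)
  pos <- as.integer(get(2L))
  if (anyNA(pos) || any(pos < 1L)) stop("VCF POS must be integer >= 1")
  qual <- suppressWarnings(as.numeric(get(6L)))
  gq <- rep(NA_real_, length(body))
  zyg <- rep("hom", length(body))
  has_sample <- all(ncols >= 10L)
  if (has_sample) {
    fmt <- strsplit(get(9L), ":", fixed = TRUE)
    smp <- strsplit(get(10L), ":", fixed = TRUE)
    for (i in seq_along(body)) {
      j <- match("GQ", fmt[[i]])
      if (!is.na(j) && j <= length(smp[[i]]))
        gq[i] <- suppressWarnings(as.numeric(smp[[i]][[j]]))
      j <- match("GT", fmt[[i]])
      if (!is.na(j) && j <= length(smp[[i]])) {
        al <- strsplit(smp[[i]][[j]], "[/|]")[[1L]]
        zyg[i] <- if (length(unique(al)) == 1L) "hom" else "het"
      }
    }
  }
  data.frame(chrom = get(1L), pos = pos, ref = get(4L), alt = get(5L),
             qual = qual, gq = gq, zygosity = zyg, stringsAsFactors = FALSE)
}

#' Write a SNP table as TSV
#'
#' @param snps a [snp_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker id in the `<chrom>_<kb>` convention
#'
#' Marker names carry their chromosome and the kb bin of their position,
#' e.g. a marker at IV:953,432 is `IV_953`.
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return character vector of ids.
#' @export
marker_id <- function(chrom, pos) paste0(chrom, "_", floor(pos / 1000))

#' Construct a marker panel
#'
#' Validated bi-allelic markers with parental origin: `allele_b` is the base
#' carried by the donor parent, `allele_g` the base carried by the recipient.
#' Ids follow [marker_id()]; kb-bin collisions are disambiguated with a
#' `.2`, `.3`, ... suffix.
#'
#' @param chrom,pos marker coordinates (1-based).
#' @param allele_b,allele_g parental alleles.
#' @param id optional explicit ids; derived from coordinates when `NULL`.
#' @return `data.frame` of class `marker_panel`, sorted by (chrom, pos).
#' @export
marker_panel <- function(chrom, pos, allele_b = NA_character_,
                         allele_g = NA_character_, id = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   allele_b = as.character(allele_b),
                   allele_g = as.character(allele_g),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (is.null(id)) {
    id <- if (nrow(df)) marker_id(df$chrom, df$pos) else character(0)
    if (anyDuplicated(id)) {
      dup <- stats::ave(seq_along(id), id, FUN = seq_along)
      id <- ifelse(dup > 1L, paste0(id, ".", dup), id)
    }
  }
  if (anyDuplicated(id)) stop("marker ids must be unique within a panel")
  df <- cbind(data.frame(id = id, stringsAsFactors = FALSE), df)
  rownames(df) <- NULL
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Construct a phenotype table
#'
#' Long-format phenotype records: one row per (segregant, trait, replicate).
#' Canonical trait names follow the fermentation panel: `CO2max`, `LP`,
#' `T35`, `T50`, `T70`, `rate50_70`, `RS`, `Ethanol`.
#'
#' @param segregant,trait,value vectors of equal length.
#' @param replicate replicate index (default 1).
#' @return `data.frame` of class `phenotype_table`.
#' @export
phenotype_table <- function(segregant, trait, value, replicate = 1L) {
  df <- data.frame(segregant = as.character(segregant),
                   trait = as.character(trait),
                   replicate = as.integer(replicate),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  neg_time <- df$trait %in% c("LP", "T35", "T50", "T70") & !is.na(df$value) &
    df$value < 0
  if (any(neg_time)) stop("kinetic times must be >= 0")
  if (any(df$trait == "RS" & !is.na(df$value) & df$value < 0))
    stop("residual sugars must be >= 0")
  if (any(df$trait == "CO2max" & !is.na(df$value) & df$value <= 0))
    stop("CO2max must be > 0 where present")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read / write phenotype tables (TSV, long format)
#'
#' @param path file path.
#' @return [read_phenotype_table()] returns a [phenotype_table()].
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("segregant", "trait", "replicate", "value")
  if (!all(need %in% names(df)))
    stop("phenotype TSV must have columns segregant, trait, replicate, value")
  phenotype_table(df$segregant, df$trait, df$value, df$replicate)
}

#' @rdname read_phenotype_table
#' @param pheno a [phenotype_table()].
#' @export
write_phenotype_table <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-segregant trait means
#'
#' Averages replicate measurements per segregant for one trait; the linkage
#' scan and extreme-selection operations work on these means.
#'
#' @param pheno a [phenotype_table()].
#' @param trait trait name.
#' @return named numeric vector (names = segregant ids).
#' @export
trait_means <- function(pheno, trait) {
  sub <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (!nrow(sub)) stop("trait '", trait, "' not present in phenotype table")
  tapply(sub$value, sub$segregant, mean)
}

#' Construct a fermentation curve
#'
#' Cumulative CO2 release (g/L) against time (h) for one fermentation.
#'
#' @param times hours, strictly increasing.
#' @param co2 cumulative CO2 in g/L; finite.
#' @param segregant,replicate,temperature optional metadata.
#' @return `data.frame` of class `fermentation_curve` with columns
#'   `time_h`, `co2_g_per_L`.
#' @export
fermentation_curve <- function(times, co2, segregant = NA_character_,
                               replicate = 1L, temperature = 28) {
  if (length(times) != length(co2)) stop("times and co2 must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(co2))) stop("co2 values must be finite")
  df <- data.frame(time_h = as.numeric(times), co2_g_per_L = as.numeric(co2))
  attr(df, "segregant") <- segregant
  attr(df, "replicate") <- replicate
  attr(df, "temperature") <- temperature
  class(df) <- c("fermentation_curve", "data.frame")
  df
}

#' Read a fermentation curve from CSV
#'
#' Expects columns `time_h` and `co2_g_per_L`.
#'
#' @param path CSV path.
#' @return a [fermentation_curve()].
#' @export
read_fermentation_curve <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_h", "co2_g_per_L") %in% names(df)))
    stop("curve CSV must have columns time_h, co2_g_per_L")
  fermentation_curve(df$time_h, df$co2_g_per_L)
}

#' Write a linkage-scan result table
#'
#' One TSV row per (marker, trait) with the scan score and the permutation
#' thresholds at genome-wide 5% and 10%.
#'
#' @param result a `linkage_result` from [wilcoxon_scan()] (with thresholds
#'   attached by [permutation_thresholds()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linkage_table <- function(result, path) {
  if (!inherits(result, "linkage_result") || !nrow(result))
    stop("result must be a non-empty linkage_result")
  thr <- attr(result, "thresholds")
  t5 <- if (!is.null(thr)) thr[["0.05"]] else NA_real_
  t10 <- if (!is.null(thr)) thr[["0.1"]] else NA_real_
  out <- data.frame(marker = result$marker, chrom = result$chrom,
                    pos = result$pos, trait = result$trait,
                    neglog10_p = round(result$neglog10_p, 6L),
                    threshold5 = round(t5, 6L), threshold10 = round(t10, 6L),
                    significant5 = !is.na(t5) & result$neglog10_p >= t5,
                    significant10 = !is.na(t10) & result$neglog10_p >= t10,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a linkage table written by [write_linkage_table()]
#'
#' @param path TSV path.
#' @return data.frame with the written columns.
#' @export
read_linkage_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
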