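# Protein-level consequence annotation of small coding-sequence variants:
# HGVS-like c.-notation parsing, sequence editing with 3'-normalisation of
# indels, standard-code translation, and classification into synonymous /
# missense / nonsense / frameshift / no-stop calls.

GENETIC_CODE_1 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

#' Parse an HGVS-like c.-notation string
#'
#' Supported forms: `c.<pos><ref>><alt>` (substitution),
#' `c.<start>_<end>del<bases>` and `c.<pos>del<base>` (deletion),
#' `c.<pos>_<pos+1>ins<bases>` (insertion).
#'
#' @param notation e.g. `"c.229_230delTC"`, `"c.1116C>A"`.
#' @return list of class `cds_variant`: `kind`, `start`, `end`, `ref`,
#'   `alt`, `notation`.
#' @export
parse_cdot <- function(notation) {
  s <- sub("^c\\.", "", trimws(notation))
  if (grepl("^\\d+[ACGT]>[ACGT]$", s)) {
    pos <- as.integer(sub("^(\\d+).*", "\\1", s))
    ref <- sub("^\\d+([ACGT])>.*", "\\1", s)
    alt <- sub(".*>([ACGT])$", "\\1", s)
    v <- list(kind = "substitution", start = pos, end = pos, ref = ref,
              alt = alt)
  } else if (grepl("^\\d+(_\\d+)?del[ACGT]+$", s)) {
    start <- as.integer(sub("^(\\d+).*", "\\1", s))
    end <- if (grepl("_", s)) as.integer(sub("^\\d+_(\\d+).*", "\\1", s))
           else start
    ref <- sub(".*del([ACGT]+)$", "\\1", s)
    if (nchar(ref) != end - start + 1L)
      stop("deletion span and stated bases disagree in ", notation)
    v <- list(kind = "deletion", start = start, end = end, ref = ref,
              alt = "")
  } else if (grepl("^\\d+_\\d+ins[ACGT]+$", s)) {
    start <- as.integer(sub("^(\\d+).*", "\\1", s))
    end <- as.integer(sub("^\\d+_(\\d+).*", "\\1", s))
    if (end != start + 1L) stop("insertion must be between adjacent bases")
    v <- list(kind = "insertion", start = start, end = end, ref = "",
              alt = sub(".*ins([ACGT]+)$", "\\1", s))
  } else {
    stop("unsupported c. notation: ", notation)
  }
  v$notation <- paste0("c.", s)
  class(v) <- "cds_variant"
  v
}

.check_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS must start with ATG")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA"))
    stop("CDS must end with a stop codon")
  cds
}

# Shift a deletion 3' while the base following the deleted segment equals
# its first base (HGVS right-alignment within repeats); analogous rotation
# for insertions.
.normalize_3prime <- function(cds, v) {
  n <- nchar(cds)
  if (v$kind == "deletion") {
    len <- v$end - v$start + 1L
    while (v$end + 1L <= n &&
           substr(cds, v$end + 1L, v$end + 1L) ==
             substr(cds, v$start, v$start)) {
      v$start <- v$start + 1L; v$end <- v$end + 1L
    }
    v$ref <- substr(cds, v$start, v$end)
    v$notation <- if (len == 1L) sprintf("c.%ddel%s", v$start, v$ref)
                  else sprintf("c.%d_%ddel%s", v$start, v$end, v$ref)
  } else if (v$kind == "insertion") {
    while (v$start + 1L <= n &&
           substr(cds, v$start + 1L, v$start + 1L) ==
             substr(v$alt, 1L, 1L)) {
      v$alt <- paste0(substr(v$alt, 2L, nchar(v$alt)), substr(v$alt, 1L, 1L))
      v$start <- v$start + 1L; v$end <- v$end + 1L
    }
    v$notation <- sprintf("c.%d_%dins%s", v$start, v$end, v$alt)
  }
  v
}

#' Apply a coding variant to a CDS
#'
#' Verifies the stated reference bases against the CDS, right-aligns indels
#' (HGVS 3' rule) and returns the edited sequence.
#'
#' @param cds coding DNA string (ATG..stop, length divisible by 3).
#' @param variant a `cds_variant` (from [parse_cdot()]) or a c.-notation
#'   string.
#' @return the mutant DNA string.
#' @export
apply_variant <- function(cds, variant) {
  cds <- .check_cds(cds)
  if (is.character(variant)) variant <- parse_cdot(variant)
  if (variant$end > nchar(cds)) stop("variant position beyond CDS end")
  if (variant$kind != "insertion") {
    found <- substr(cds, variant$start, variant$end)
    if (found != variant$ref)
      stop(sprintf("reference mismatch at c.%d: expected %s, found %s",
                   variant$start, variant$ref, found))
  }
  variant <- .normalize_3prime(cds, variant)
  switch(variant$kind,
    substitution = paste0(substr(cds, 1L, variant$start - 1L), variant$alt,
                          substr(cds, variant$start + 1L, nchar(cds))),
    deletion = paste0(substr(cds, 1L, variant$start - 1L),
                      substr(cds, variant$end + 1L, nchar(cds))),
    insertion = paste0(substr(cds, 1L, variant$start), variant$alt,
                       substr(cds, variant$start + 1L, nchar(cds))))
}

#' Translate DNA with the standard genetic code
#'
#' Translation starts at position 1 and stops at (excluding) the first stop
#' codon. A trailing partial codon is ignored.
#'
#' @param dna DNA string, length >= 3.
#' @return character protein string; attribute `no_stop` is `TRUE` when no
#'   stop codon was encountered.
#' @export
translate_cds <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) < 3L) stop("need at least one codon")
  n_codons <- nchar(dna) %/% 3L
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(dna, starts, starts + 2L)
  aa <- GENETIC_CODE_1[codons]
  if (anyNA(aa)) stop("non-ACGT codon encountered")
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    prot <- paste(aa[seq_len(stop_at[1L] - 1L)], collapse = "")
    attr(prot, "no_stop") <- FALSE
  } else {
    prot <- paste(aa, collapse = "")
    attr(prot, "no_stop") <- TRUE
  }
  prot
}

#' Protein-level consequence of a coding variant
#'
#' Compares reference and mutant translations. Frameshift (indel length not
#' divisible by 3) is reported as `p.<Aa3><pos>fsTer<stop>`, where `<pos>`
#' is the first changed residue and `<stop>` the 1-based codon index of the
#' new stop in the mutant reading frame (the convention used for calls like
#' p.Ser77fsTer95; the mutant peptide itself is one residue shorter).
#' Substitutions creating a stop are nonsense, `p.<Aa3><pos>*`. In-frame
#' indels and other protein-changing substitutions are missense; identical
#' proteins are synonymous; a mutant translation without any stop codon is
#' classified `no_stop`.
#'
#' @param cds reference coding sequence.
#' @param variant `cds_variant` or c.-notation string.
#' @return list of class `protein_consequence`: `class`, `p_notation`,
#'   `mutant_length` (residues strictly before the stop),
#'   `reference_length`, `truncation` (residues lost), `stop_codon_index`
#'   (mutant frame; `NA` if no new stop), `mutant_protein`.
#' @export
consequence <- function(cds, variant) {
  cds <- .check_cds(cds)
  if (is.character(variant)) variant <- parse_cdot(variant)
  mut <- apply_variant(cds, variant)
  ref_prot <- translate_cds(cds)
  mut_prot <- translate_cds(mut)
  ref_len <- nchar(ref_prot)
  mut_len <- nchar(mut_prot)
  no_stop <- isTRUE(attr(mut_prot, "no_stop"))
  indel_len <- nchar(variant$alt) - nchar(variant$ref)
  is_frameshift <- variant$kind != "substitution" && indel_len %% 3L != 0L
  aa3 <- function(aa1) unname(AA_THREE[aa1])
  if (no_stop) {
    cls <- "no_stop"
    p_not <- sprintf("p.(%s...no stop)", "?")
    stop_idx <- NA_integer_
  } else if (ref_prot == mut_prot && !is_frameshift) {
    cls <- "synonymous"
    p_not <- "p.(=)"
    stop_idx <- mut_len + 1L
  } else if (is_frameshift) {
    cls <- "frameshift"
    # first residue differing between reference and mutant translations
    k <- 1L
    min_len <- min(ref_len, mut_len)
    while (k <= min_len &&
           substr(ref_prot, k, k) == substr(mut_prot, k, k)) k <- k + 1L
    stop_idx <- mut_len + 1L
    if (k > min_len && mut_len >= ref_len) {
      # frameshift that never changes a residue before the ref stop: report
      # at the first shifted codon
      k <- min_len + 1L
    }
    p_not <- sprintf("p.%s%dfsTer%d", aa3(substr(ref_prot, k, k)), k,
                     stop_idx)
  } else if (variant$kind == "substitution" && mut_len < ref_len) {
    cls <- "nonsense"
    k <- mut_len + 1L
    p_not <- sprintf("p.%s%d*", aa3(substr(ref_prot, k, k)), k)
    stop_idx <- k
  } else {
    cls <- "missense"
    stop_idx <- mut_len + 1L
    k <- 1L
    while (k <= min(ref_len, mut_len) &&
           substr(ref_prot, k, k) == substr(mut_prot, k, k)) k <- k + 1L
    if (k <= min(ref_len, mut_len))
      p_not <- sprintf("p.%s%d%s", aa3(substr(ref_prot, k, k)), k,
                       aa3(substr(mut_prot, k, k)))
    else p_not <- "p.?"
  }
  structure(list(class = cls, p_notation = p_not,
                 mutant_length = mut_len, reference_length = ref_len,
                 truncation = max(0L, ref_len - mut_len),
                 stop_codon_index = stop_idx,
                 mutant_protein = as.character(mut_prot)),
            class = "protein_consequence")
}

#' Read a single-sequence FASTA file
#'
#' Minimal FASTA reader for CDS inputs (no dependency on Biostrings at run
#' time; Biostrings is used in the test suite as an independent oracle).
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  names(seqs) <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  seqs
}
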