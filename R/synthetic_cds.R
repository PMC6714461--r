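# Synthetic stand-in coding sequences. The genuine OYE2 (YHR179W) and VHS1
# (YDR247W) CDS are not bundled; these constructors build deterministic
# SYNTHETIC sequences of the same protein lengths (400 and 461 aa) whose
# local context reproduces the documented variants exactly:
#   OYE2 stand-in: c.229_230delTC -> frameshift p.Ser77fsTer95
#   VHS1 stand-in: c.1116C>A      -> nonsense  p.Tyr372*
# They are suitable for exercising and testing the annotation machinery,
# not for any sequence-level biology.

# deterministic non-stop filler codons
.filler_codons <- function(n) {
  pool <- c("GAA", "TTG", "AAA", "GAT", "GTT", "ATT", "GCC", "CAA",
            "AGA", "GGT", "TTC", "CCA")
  rep(pool, length.out = n)
}

#' Synthetic stand-in CDS for OYE2 (YHR179W)
#'
#' A 1203-nt synthetic CDS (400 codons + stop). Codon 77 is `TCC` (Ser) at
#' positions 229-231; deleting `TC` at 229-230 (`c.229_230delTC`) shifts the
#' frame so that the first changed residue is 77 and the new stop falls at
#' mutant codon 95, i.e. `p.Ser77fsTer95`: a 94-residue peptide instead of
#' the 400-residue full-length protein.
#'
#' @return character CDS string (synthetic; see file-level note).
#' @export
synthetic_oye2_cds <- function() {
  codons <- c("ATG", .filler_codons(399), "TAA")
  codons[77] <- "TCC"   # Ser, provides the TC deleted by c.229_230delTC
  codons[78] <- "GGT"   # mutant codon 77 reads CGG (Arg != Ser)
  codons[79:94] <- "GCT" # shifted frame reads TGC (Cys) through codon 94
  codons[95] <- "GCT"   # ends in T ...
  codons[96] <- "AAG"   # ... + AA = TAA: stop at mutant codon 95
  paste(codons, collapse = "")
}

#' Synthetic stand-in CDS for VHS1 (YDR247W)
#'
#' A 1386-nt synthetic CDS (461 codons + stop). Codon 372 is `TAC` (Tyr) at
#' positions 1114-1116, so the substitution `c.1116C>A` creates a `TAA` stop
#' codon: `p.Tyr372*`, truncating the 461-residue protein to 371 residues
#' (90 C-terminal residues lost).
#'
#' @return character CDS string (synthetic; see file-level note).
#' @export
synthetic_vhs1_cds <- function() {
  codons <- c("ATG", .filler_codons(460), "TAA")
  codons[372] <- "TAC"  # Tyr; C>A at its third base makes TAA
  paste(codons, collapse = "")
}

#' Write the synthetic stand-in CDS as FASTA
#'
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_synthetic_cds_fasta <- function(dir) {
  wrap <- function(s) paste(substring(s, seq(1, nchar(s), 60),
                                      pmin(seq(60, nchar(s) + 59, 60),
                                           nchar(s))), collapse = "\n")
  p1 <- file.path(dir, "YHR179W_OYE2_synthetic_cds.fa")
  p2 <- file.path(dir, "YDR247W_VHS1_synthetic_cds.fa")
  writeLines(c(">YHR179W_OYE2_synthetic synthetic stand-in CDS",
               wrap(synthetic_oye2_cds())), p1)
  writeLines(c(">YDR247W_VHS1_synthetic synthetic stand-in CDS",
               wrap(synthetic_vhs1_cds())), p2)
  invisible(c(p1, p2))
}
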