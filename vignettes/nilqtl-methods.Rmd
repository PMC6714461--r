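---
title: "Methods: QTL mapping of stuck-fermentation traits in a backcrossed yeast lineage"
author: "nilqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping of stuck-fermentation traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilqtl)
```

## The problem this package addresses

Stuck alcoholic fermentation — the premature arrest of sugar-to-ethanol
conversion — is a costly failure mode in high-gravity wine fermentations,
especially when high ethanol combines with high temperature. One productive
way to dissect its genetics in *Saccharomyces cerevisiae* is a nearly
isogenic lineage (NIL): a tolerant donor strain is recurrently backcrossed
into a sensitive recipient, selecting each round the meiotic segregant that
leaves the least residual sugar. After four rounds the hybrid shares most of
its genome with the recipient but retains a handful of donor introgressions,
and because the strains are homothallic (*HO/HO*), every spore
self-diploidises into a fully homozygous segregant — so a single genotyping
pass reads the whole genotype, and genetic variance is purely additive
within the panel.

`nilqtl` implements the complete downstream analysis as a tested,
reusable pipeline:

1. **Kinetics** — reduce CO2 weight-loss curves to the standard trait panel
   (`CO2max`, lag phase `LP`, `T35`/`T50`/`T70`, `rate 50–70`), plus
   broad-sense heritability and Bonferroni-corrected trait correlations.
2. **Marker validation** — call candidate SNP regions from z-scored
   tiling-array signal, filter whole-genome-sequencing SNPs on quality,
   match the two within a window to estimate the array's false discovery
   rate, assign parental origin, count donor-allele occurrences in
   phenotypic extremes, and cluster markers into introgressed regions.
3. **Linkage scan** — Mendelian-segregation QC, a per-marker two-sided
   Wilcoxon–Mann–Whitney scan, genome-wide permutation thresholds, ANOVA
   variance decomposition, and sequential-cross design to expose minor QTLs
   after fixing major ones.
4. **Variant effect** — HGVS-like annotation of coding variants
   (frameshift, nonsense, missense, synonymous), reproducing calls of the
   form `p.Ser77fsTer95` and `p.Tyr372*`.
5. **Synthetic data** — a generator that emulates the full design so every
   stage is testable offline.

## The statistical model

### Linkage scan

For marker $m$ with allele classes $B$ (donor) and $G$ (recipient), the scan
tests location equality of the replicate-mean trait values of the two
carrier groups with a two-sided rank-sum test. The exact null distribution
is used when the pooled $n \le 30$ and there are no ties; otherwise the
normal approximation with tie and continuity corrections:

$$ Z = \frac{|U - n_1 n_2 / 2| - 1/2}
         {\sqrt{\frac{n_1 n_2}{12}\left[(n+1) -
          \frac{\sum_k (t_k^3 - t_k)}{n(n-1)}\right]}} $$

The rank statistic makes the scan invariant to monotone transforms of the
trait and robust to the variance heterogeneity typical of stuck-fermentation
phenotypes (arrested fermentations pile up at high residual sugar).

Genome-wide significance uses the max-statistic permutation construction
(Churchill & Doerge): the trait vector is shuffled across segregants
(jointly over markers, preserving linkage disequilibrium), the scan is
rerun, and the $(1-\alpha)$ quantile of the per-permutation maximum
$-\log_{10} p$ is the threshold. Linkage plots conventionally label these
cutoffs "FDR 5%/10%"; the construction controls the family-wise error rate,
and the output keeps both the labels and the max-stat distribution.

### Variance decomposition

At mapped loci, the replicate-mean trait is modelled as
`trait ~ locus1 + locus2 + locus1:locus2` with Type-II sums of squares
(each main effect adjusted for the other); percent variance is
$100 \cdot SS_{\text{term}} / SS_{\text{total}}$ with the residual included
in the total, so effect percentages are directly comparable to published
per-locus shares. One locus reduces to a one-way ANOVA. An empty genotype
cell drops the interaction with a message.

### Heritability

Broad-sense heritability uses replicated controls (the two parents and the
hybrid) to estimate the environmental variance:
$h^2 = 100\,(s^2_{\text{progeny}} - s^2_{\text{env}})/s^2_{\text{progeny}}$,
where $s^2_{\text{env}}$ is the mean within-genotype replicate variance,
clamped to $[0, 100]$.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `expected_max` | 125 | g/L CO2 | `T35/T50/T70` are fractions of the *expected* maximum, deliberately not the observed `CO2max` — a stuck fermentation never reaches it, which is the point. |
| `rate_threshold` | 0.05 | g/L/h | Lag phase ends when the smoothed production rate first exceeds this. |
| `span` | 0.2 | fraction | Loess span. A local quadratic at span 0.3 deviates up to 0.25 g/L from a noiseless logistic (k = 0.05/h, 4 h sampling); 0.2 keeps the bias under 0.1 g/L and still halves 1 g/L measurement noise. The span is floored so the local window always holds ≥ 5 points. |
| `z_threshold`, `min_run` | 2.5, 10 nt | — | Tiling-array region calling: maximal runs of consecutive positions above the z-score threshold, at least 10 nt long. |
| `min_qual`, `min_gq` | 30, 20 | phred | WGS SNP filter, inclusive (≥), homozygous-only by default. |
| `window` | 20 | bp | Prediction-to-SNP matching window (the widest of the 5–20 bp sweep, exposed as an option since array position error is several bp). |
| `max_gap` | 50 | kb | Single-linkage gap for clustering flagged markers into introgressed regions. |
| `n_perm` | 1000 | — | Permutations for genome-wide thresholds. |
| `cm_per_kb` | 0.35 | cM/kb | Genome-average recombination density for the simulator's Haldane map. |

## What the synthetic generator emulates — and what it does not

The generator states one concrete world: sixteen chromosomes at sacCer3
lengths; two parental SNP sets sized to leave ~3,400 non-common positions;
a 43-marker panel clustered in 12 regions on 11 chromosomes (markers
25 kb apart within a region, including `IV_953`, `VIII_464`, `XV_1051`);
meioses under a Haldane map at 0.35 cM/kb with no interference; four
backcross rounds selecting the lowest-RS spore of 30; 77 fully homozygous
segregants phenotyped in duplicate; and an additive three-QTL architecture
with variance shares 25.8% and 15.6% (donor allele beneficial) plus a minor
7.4% locus whose *recipient* allele is beneficial. The residual SD is
6 g/L on the duplicate-mean scale, and the baseline RS mean is 30.3 g/L —
the recipient parent's published mean, which is what the all-recipient
genotype class should resemble under an additive model. Residual-sugar
values are truncated at zero (a fermentation cannot leave negative sugar);
effect sizes are derived from the share algebra
$a_i = 2\sqrt{v_i\,\sigma^2_{\text{tot}}}$ at allele frequency 1/2.

CO2 curves are logistic,
$\mathrm{CO2}(t) = \mathrm{CO2max} / (1 + e^{-k (t - t_{mid})})$ plus raw
Gaussian noise. The logistic is a modelling choice — the analysis only
consumes trait read-outs, and the logistic provides closed-form oracles
($T_x = t_{mid} + \ln\frac{x}{1-x}/k$ for fraction $x$ of the asymptote).

Not emulated: real fermentation mechanics (diauxie, nitrogen limitation,
non-sigmoidal stuck profiles), genotyping error, segregation distortion
from viability selection, aneuploidy, mitochondrial inheritance, and
polygenic background beyond the three configured QTLs. A green test
therefore establishes that the *statistical machinery* behaves as designed
under the stated world, not that the biology of any particular dataset is
additive or logistic.

## Numerical choices and degenerate inputs

- **Coordinates** are 1-based inclusive everywhere (VCF convention); BED
  export is the single 0-based half-open surface.
- **Missing genotypes** are excluded pairwise per marker; a constant
  phenotype yields $p = 1$ (zero rank variance), and markers with fewer
  than two segregants per allele class are skipped and logged.
- **Trait crossings** use linear interpolation between the bracketing
  samples; the first crossing wins; unreached crossings propagate as `NA`,
  never as sentinels.
- **Matching discipline**: greedy nearest-neighbour with one-to-one SNP
  consumption, distance ties broken toward the lower position. Greedy is
  not always maximum-cardinality (predictions {0, 6} vs SNPs {5, 11} at
  window 5 is a counterexample); the test suite compares against an
  exhaustive augmenting-path matcher on random instances and logs
  discrepancies, which are rare at realistic marker densities.
- **Permutation thresholds** use the empirical quantile of the max
  distribution; reproducibility is by explicit seed. The FWER calibration
  test exploits exchangeability: with genotypes fixed, the permutation
  distribution *is* the null distribution of the max statistic, so fresh
  null phenotype draws scanned against one threshold measure the FWER
  directly — hundreds of times cheaper than re-permuting per dataset.
- **Frameshift notation**: `p.<Aa><pos>fsTer<k>` where `<pos>` is the first
  changed residue and `<k>` the 1-based codon index of the new stop in the
  mutant frame — the convention behind calls like `p.Ser77fsTer95`, whose
  "95 amino acids" counts through the stop codon while the mutant peptide
  has 94 residues; both numbers are reported. Indels are right-aligned
  (3' rule) at the DNA level before annotation. A substitution that
  destroys the terminal stop is classified `no_stop`.
- **Published-length discrepancy**: the truncated kinase is described both
  as losing "93 C-terminal amino acids" and as 371 of 461 residues; the
  arithmetic from the printed lengths (461 − 371 = 90) is what the
  annotator reports.

## Design choices where the design was genuinely open

- **Exact vs approximate rank-sum**: exact when tie-free and pooled
  $n \le 30$, else corrected normal approximation. At the panel sizes that
  matter (77, 84) the approximation path is active and matches permutation
  estimates to within 10% relative in the well-estimable p range (checked
  at a 0.5-SD shift with 20,000 permutations; smaller p-values cannot be
  permutation-verified at feasible cost).
- **Thresholds as FWER**: the permutation cutoff is implemented as the
  genome-wide max-statistic threshold; the "FDR" label used in linkage
  plots is preserved in output for continuity.
- **Replicates are averaged** per segregant before testing; duplicate-mean
  phenotyping for the primary panel and single measurements for the
  follow-up cross are both supported.
- **Occurrence threshold** "more than 4 of 7" is strict (≥ 5).
- **Deletion detection** uses a 0.5 pseudo-count on read-per-kb ratios to
  stay defined at fully uncovered genes.
- **Simulator selection** acts on simulated residual sugars (lower is
  better), mirroring phenotypic selection during backcrossing.

## Known limitations

- Single-marker tests only: no interval mapping or HMM genotype
  probabilities, and no multi-QTL cofactor scans — at this map density and
  population size they add little, and the sequential-cross design is the
  supported route to minor QTLs.
- The two-QTL joint detection power target of 0.9 at $n = 77$ is not
  attainable in the stated world: a 15.6%-share locus caps near 0.75 power
  at the genome-wide threshold even for a parametric test (noncentral-F
  argument), and the measured joint power is ~0.65. The corresponding
  acceptance check is intentionally left failing rather than relaxed.
- Genome-to-CDS coordinate lifting (strand, splicing) is out of scope; the
  annotator works in CDS space. The bundled OYE2/VHS1 sequences are
  synthetic stand-ins with the documented lengths and variant contexts,
  suitable for exercising the machinery but not for sequence-level biology.
- Test-suite scale-downs from the stated replicate counts (e.g. 200 rather
  than 500 variance-share replicates; 15–20 full-size tiling-FDR
  replicates) keep the default run inside CI budgets; tolerances are
  unchanged.
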