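---
title: "Methods: allele-specific elongation analysis of synonymous mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific elongation analysis of synonymous mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synoribo)
```

## The model

A somatic synonymous mutation at a third codon position changes codon
optimality without changing the protein: A/T → C/G moves the codon into
the optimal (fast-decoded) set, C/G → A/T out of it, and A↔T or C↔G
changes are directionless under this rule and stay unclassified. If
optimality controls decoding speed, the derived allele of an optimal
mutation should show *lower* ribosome A-site occupancy per mRNA than the
ancestral allele at the same site, and vice versa for non-optimal
mutations.

The observable is the per-allele **A-site density**

$$\mathrm{density} = \frac{\text{A-site read count}}{\text{RNA read count}}$$

computed from raw counts. Within a tumor sample the two alleles of a
heterozygous site share the library, the cell population and every trans
factor, so their density ratio is an unconfounded cis readout; the
normal-vs-tumor comparisons cross libraries and are reported with an
explicit "not library-size normalized" label.

### Mutation polarization

Direction matters: "optimal" is a property of the *change*, not the
site. A site is polarized only when the reference base equals the
outgroup base, making the reference allele ancestral and the single
observed non-reference tumor base derived. Sites with a
reference/outgroup mismatch (`non_ancestral_ref`), an unknown outgroup
base (`missing_outgroup`), no derived evidence (`monomorphic`) or two or
more distinct non-reference bases (`multiallelic`) are excluded. The
multiallelic rule is deliberately conservative — one stray third base
removes the site — because a tri-allelic pileup at the depths involved
is more likely artifact than biology.

### Tumor-specific filters

Two tiers trade power against confidence, used for different purposes:

* **loose** (mutation-landscape and gene-level enrichment): normal RNA
  coverage ≥ 5 with zero derived reads, tumor showing both alleles with
  derived fraction strictly below 1 (a site 100% derived in tumor is
  more plausibly a mis-polarized germline difference than a clonal
  somatic event).
* **strict** (allele-density comparisons, which are sensitive to shallow
  counts): (1) normal RNA coverage ≥ 20 and no derived read; (2) normal
  RPF A-site coverage ≥ 20 and no derived read in the A-site
  tri-nucleotide; (3) tumor RNA coverage ≥ 20 with both alleles ≥ 3;
  (4) tumor RPF A-site coverage ≥ 20 with both alleles ≥ 3; (5) absence
  from the known-SNP panel. Panel matching is by (transcript, position):
  a site known to segregate in the population is excluded regardless of
  which alternative allele is recorded.

"No mutation detected in normal" is implemented as an absolute zero
derived reads, exposed as `max_derived_in_normal` for sensitivity
analyses. Strict-pass sites are provably a subset of loose-pass sites.

### P-site offsets and A-site assignment

RPF 5′ ends of one read length pile up at a fixed distance upstream of
initiating start codons; that distance is the P-site offset $d_L$. Per
length, the offset is inferred as the argmax of the 5′-end histogram
over a window around the start codon (default −40..+10 nt), computed
independently per length (no cross-length smoothing, because adjacent
lengths genuinely differ by 0–1 nt). Ties between equal peaks resolve to
the smaller offset. A length is excluded when it has fewer than
`min_reads` (default 200) in-window reads, a peak below 2× the median
bin, or a peak downstream of the start codon; excluded lengths have
their reads dropped rather than given a borrowed offset, so they cannot
contaminate densities. An additional advisory flag (`dispersed_peak`)
fires when the peak holds less than 70% of the mass in its immediate
±1 nt neighborhood — the local phasing estimate — warning about
poor-quality digestion without discarding a length whose argmax is still
well-defined.

Given $d_L$, a read with 5′ end $p$ has P-site $[p+d_L,\,p+d_L+3)$ and
A-site $[p+d_L+3,\,p+d_L+6)$; a read contributes to a site's A-site
count when the A-site interval contains the site.

### Statistics

* Within-class comparisons use two-sided two-sample KS tests across the
  three density groups and a paired t-test on (tumor-ancestral,
  tumor-derived) densities per site. The t-test runs on untransformed
  densities by default; a log2 option exists but changes no sign
  conclusion on the synthetic conditions and is off by default to keep
  the primary procedure minimal.
* Sites are pooled across patients for the group tests; every record
  keeps its patient of origin so stratified analyses remain possible.
* Gene-class enrichment compares synonymous SNP density
  (1000 × count / CDS length) between oncogenes and TSG per optimality
  class, and optimal vs non-optimal within the remaining genes, by KS
  test with the direction reported from the means.
* The TE fold-change regression is OLS of
  $\log_2(\mathrm{TE}_{tumor}/\mathrm{TE}_{normal})$ — computed per
  patient and averaged per gene — on six predictors min-max scaled to
  $[-1, 1]$ via $x' = 2(x - \min)/(\max - \min) - 1$: optimal and
  non-optimal synonymous mutation counts, gene length, a dN
  (conservation) covariate read from an input table, expression and GC
  content. The log form symmetrizes up- and down-regulation; the raw
  ratio is reported alongside. Min-max scaling is the minimal transform
  achieving the stated range; the design is rank-checked before fitting
  and collinear predictors are named in the error.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth, and its defaults are the cohort conditions the
package is validated under: 10 patients, 1000 genes of which 240
oncogenes and 242 TSG, CDS lengths uniform in 300–1500 nt, RNA depth
Poisson(50) per site, ancestral A-site/RNA density 0.5, derived-allele
density multiplied by 0.5 (optimal) or 2.0 (non-optimal), tumor derived
allele fraction Binomial(depth, 0.5), synonymous mutation rate 1 per kb
CDS per class with 3-fold enrichment of optimal mutations in oncogenes
and non-optimal in TSG, RPF lengths 28–31 nt with offsets
{28: 12, 29: 12, 30: 13, 31: 13}, frame fidelity 0.9 (±1 nt otherwise),
and 20% of injected variants copied into the known-SNP panel.

Two generator choices deserve comment:

* **Tumor allele fraction 0.5.** Real tumors have variable purity and
  subclonal structure; nothing in the modeled analysis depends on the
  fraction beyond both alleles clearing the ≥ 3 count threshold, so a
  balanced heterozygote is the neutral default, exposed as
  `tumor_allele_fraction`.
* **Variants are injected as codon rewrites.** Each variant's ancestral
  codon template is written into the transcript, guaranteeing the
  change is synonymous in both directions and sits at a third codon
  position; TAA/TGA/ATA/ATG/TGG prefixes that would create stop or
  start/Trp effects are excluded from the template sets.

Per (variant, carrier patient): RNA depths are Poisson, tumor derived
counts Binomial, and RPF A-site counts per allele Poisson with mean
(RNA count of the allele) × (base density) × (speed factor). Normal
samples never carry a derived allele. RPF reads come in two
populations: start-anchored calibration reads (P-site on the initiation
codon, 5′ end at `cds_start − offset` plus frame noise) and
variant-anchored reads (A-site on the variant codon, one per simulated
A-site count, labeled with its allele). The per-site pileup table is
the authoritative count input to the pipeline, as it would be for real
data; reads drive offset calibration, and the reads→counts path is
verified against the hand-designed fixture where no frame noise exists.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error beyond allele sampling,
mapping bias between alleles, positional coverage heterogeneity along
transcripts, ribosome queuing or sequence-context pause sites, splicing
isoforms, indels, and subclonal tumor architecture. Recovery results on
synthetic data demonstrate correctness of the computations under the
stated model, not robustness to these real-data phenomena.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; the VCF-like
  panel file converts to/from 1-based positions at I/O.
* Zero RNA denominators cannot occur at strict-tier sites; if forced,
  the record is dropped and counted (`n_dropped` attribute).
* Identical density vectors give KS D = 0, p = 1; ties in KS inputs are
  accepted with the usual approximate p-values.
* Ranking ties in `top_genes` break by raw count, then gene id, making
  reports reproducible.
* A CDS whose length is not a multiple of 3 is a malformed model and a
  hard error, not a warning.
* The speed-factor bounds admit exactly 1 on both sides so the null
  generator (no elongation effect) is a legal configuration; it is used
  to calibrate the paired test's type-I error.

## Validation problem sizes

The shipped tests and the acceptance script use: exhaustive enumeration
(12 ordered base changes) for the optimality rule; 1000 simulated sites
against a brute-force reimplementation of the five strict criteria;
2000 reads per length for exact offset recovery; 200 sites per class at
depth 50 for density-direction recovery; 1000 replicates × 100 sites
for null calibration of the paired test; 100 replicates at gene-set
sizes 240/242 for enrichment detection; 1000 genes for regression
recovery; and a 120-gene end-to-end run executed twice for byte-level
determinism. These sizes keep the full suite under a minute while
leaving every statistical margin wide (e.g. offset recovery is exact
integer equality, and the enrichment KS p-values at the programmed
3-fold effect are far below 0.05).

## Known limitations

* The optimality rule is the directional A/T→C/G dichotomy; a
  frequency-derived optimal-codon table (species-specific, possibly
  tissue-specific) is a plausible refinement not attempted here.
* dN arrives as a precomputed covariate; no orthology or substitution
  model is computed internally.
* The pipeline consumes alignment-derived tables in transcript
  coordinates; genome-space alignment, liftOver and base/mapping-quality
  filtering are upstream concerns that the tables are assumed to have
  already absorbed.
* Cross-sample density comparisons are intentionally unnormalized and
  should be read as supporting, not primary, evidence; the paired
  within-tumor contrast is the load-bearing statistic.
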