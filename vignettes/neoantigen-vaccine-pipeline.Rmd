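---
title: "Neoantigen DNA vaccine design and immune monitoring with neovax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen DNA vaccine design and immune monitoring with neovax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

## The problem

Personalized neoantigen vaccines target mutant peptides that arise from
tumor-specific somatic mutations and are absent from the normal proteome.
In the adjuvant triple-negative breast cancer (TNBC) setting the pipeline
runs from tumor/normal sequencing results to a manufactured DNA vaccine and
then to immune monitoring:

1. expressed protein-altering somatic variants are turned into ~25-mer
   mutant peptide windows;
2. minimal 8–11-mer epitopes are enumerated against the patient's HLA
   class I alleles and scored by an ensemble of binding predictors;
3. candidates are filtered (ensemble median IC50, expression,
   anchor-position fold change, wild-type proteome screen) and ranked, and
   4–20 windows are selected per patient;
4. the selected windows are concatenated behind a non-cleavable mutant
   ubiquitin (G76V) into a single polyepitope open reading frame, reverse
   translated to DNA;
5. post-vaccination T-cell responses are called from ELISpot and
   intracellular cytokine staining (ICS), clonotype expansion is tested in
   CDR3β repertoires, and recurrence-free survival (RFS) is compared
   against an unvaccinated cohort.

`neovax` implements every stage as composable functions, plus a synthetic
cohort generator with known ground truth, so the full pipeline is testable
without access to protected patient-level data.

## Epitope prioritization model

Each missense variant yields a mutant window with up to 12 residues of
flank on each side of the substituted residue (≤ 25 residues total); the
matched wild-type window is taken from the reference protein at the same
coordinates. Frameshift variants contribute the up-to-12-residue upstream
flank plus the novel tail truncated to 25 residues, with no wild-type
partner. All 8–11-mer substrings overlapping the altered residue(s) are
crossed with the patient's alleles.

For every candidate the across-algorithm **median IC50** is computed for
mutant and wild-type peptides, and the fold change
`median_WT / median_MT` (> 1 means the mutant binds tighter). A candidate
passes when:

* median mutant IC50 < 500 nM (the conventional binder threshold),
* the transcript is expressed (TPM > 0) with mutant-allele RNA support
  (≥ 1 read),
* if the mutation falls on an HLA anchor position (position 2 or the
  C-terminus by default, overridable per allele), the fold change
  exceeds 1 — a mutation buried in the MHC groove changes affinity rather
  than the T-cell-facing surface, so tighter mutant binding is required
  for it to be a useful target,
* the mutant peptide does not occur verbatim in the wild-type proteome.

Ranking is a deterministic lexicographic key — passes, driver gene,
clonality (VAF ≥ 0.5 × patient maximum VAF), ascending median mutant
IC50, descending fold change, then id — rather than a weighted score: in
practice this prioritization is guided by named criteria and a human
tumor board rather than weights, and a total order is the smallest
faithful reproducible substitute. If fewer than 4 windows pass,
thresholds are relaxed stepwise (IC50 ceiling doubled, then the
mutant-read requirement dropped), mirroring the practice of relaxing
binding and expression thresholds slightly to reach a minimum vaccine
size; at most 20 windows are selected.

```{r selection-demo}
cand <- data.frame(
  window_id = c("wA", "wB", "wC"),
  median_mt_ic50 = c(120, 450, 800), fold_change = c(3, 0.8, 2),
  anchor_overlap = c(FALSE, TRUE, FALSE), tpm = c(4, 2, 5),
  rna_alt_reads = c(3, 2, 4), proteome_match = FALSE,
  driver_flag = c(FALSE, TRUE, FALSE), clonality = "clonal")
rank_and_select(cand, min_select = 1)$selection[, c("window_id", "reasons")]
```

## Construct assembly

The polyepitope protein is `Ub(G76V) + window_1 + ... + window_k` in
selection rank order, with no linkers (none are described for this
platform; a linker string is configurable). The G76V substitution removes
the C-terminal glycine needed for deubiquitination, committing the fusion
to proteasomal processing. The packaged canonical human ubiquitin is
validated (76 residues, G at 76) rather than assumed. Junction-spanning
8–11-mers are enumerated and optionally scored; the report is
informational only — reordering epitopes silently would misrepresent the
design. DNA is emitted by most-frequent-codon reverse translation from a
packaged approximate human usage table (ties alphabetical, one stop codon
appended); translating the DNA back under the standard code recovers the
protein exactly, which the tests assert.

Each window is tiled for immune monitoring with 15–16-mer overlapping
peptides (OPs) stepping by `length − 11`, lengths chosen so the last
peptide ends exactly at the window end; a 25-mer gives exactly three OPs
with 11-residue overlaps. Window lengths 17, 18 and 22 cannot be tiled
with exact 11-residue overlaps by 15/16-mers, so there the final 15-mer is
anchored to the window end (overlap > 11) and the panel is flagged
`exact_overlap = FALSE`. Full coverage of every window residue is
guaranteed and property-tested.

## Immune response calling

ELISpot wells are background-subtracted against matched no-peptide wells
(floored at zero for reported means). Calling is tiered:

* **Screening** — adjusted post-vaccination mean ≥ 50 SFC/10⁶ and ≥ 2×
  the (floored) pre-vaccination mean. The published screening step states
  no numeric rule, so both knobs are explicit arguments with these
  defaults.
* **Confirmation** — one-sided Welch t-test (post > pre) on
  background-adjusted replicate wells at α = 0.05. The underlying trial
  reran the assay physically; here the statistical rule is applied to the
  replicate wells of the panel. Individual wells are adjusted by the
  background mean without flooring so replicate variance is preserved.
  A pooled-variance variant is available; with equal replicate counts and
  equal sample variances the two coincide. Per-neoantigen calls are not
  multiplicity-adjusted (matching the per-neoantigen reporting practice);
  a Benjamini–Hochberg column is emitted alongside.

A patient is a **responder** if at least one neoantigen is confirmed.
Confirmed responses are deconvolved over the OP panel (`focused` if one OP
carries ≥ 60% of the summed adjusted signal, else `mixed`) and checked for
mutant specificity (adjusted MT-S ≥ 2× the floored WT-S signal).

The **ICS rule** is: positive iff post ≥ 2 × pre percent-positive cells
AND post ≥ 1%. The relaxed variant drops the 1% floor, so strict positives
are always a subset of relaxed positives.

## TCR clonotype expansion

Clonotypes are CDR3β amino-acid sequences. For each clonotype present in
either timepoint the package computes a frequency fold change and a
one-sided exact 2×2 test (count vs remaining depth, pre vs post),
implemented as the conditional hypergeometric tail and verified in tests
against both explicit enumeration and `fisher.test`. Calls require a
BH-adjusted q < 0.05, fold ≥ 4, and a raw frequency increase. The
pseudocount (default 0.5) substitutes for zero counts only — de novo or
vanished clones — so the fold ranking of clones observed at both
timepoints does not depend on it. A response is `monoclonal` with exactly
one expanded clonotype, `oligoclonal` with two or more.

## Outcomes

RFS runs from first vaccination to relapse or death; the unvaccinated
comparison arm is given its own time zero 4 months after surgery to
account for the vaccine manufacturing window. Kaplan–Meier estimation and
the log-rank test are delegated to the `survival` package, with Greenwood
variance and log-log confidence bands (a standard, configurable default).
Ties between events and censoring at the same time count the censored
subjects as still at risk (events first). Tests pin the estimator to
hand-worked product-limit tables and the log-rank statistic to the
textbook O−E/V formula.

## The synthetic cohort generator

The generator emulates the published cohort structure: 18 patients, a
median of 21.5 expressed protein-altering mutations per patient (Poisson
counts), 97% missense / 3% frameshift, selections of 4–20 windows, ~23%
of vaccinated epitopes truly immunogenic, no-peptide ELISpot backgrounds
with plate means in the 10–120 SFC/10⁶ range, and 2/18 expected
recurrences with a comparison arm calibrated to ~49% 36-month RFS
(exponential hazard). Where the source states no value, defaults were
chosen once on domain grounds:

* **Binding** — the toy predictor gives each allele a fixed 9-position
  weight matrix (one consensus residue per position at weight 1, two
  secondary residues, alanine pinned low as a neutral baseline);
  8/10/11-mers map onto the matrix anchor-aligned; scores map to
  IC50 = 50000^(1 − score) nM, spanning the 500 nM decision boundary.
  Four "algorithms" are fixed perturbations of the allele matrix, so the
  ensemble median is non-degenerate. This is a deterministic stand-in for
  neural binding predictors, not a model of real peptide–MHC chemistry.
* **ELISpot counts** — negative binomial (overdispersed spot counts are
  standard for this assay) with size 20, i.e. roughly 20% replicate CV at
  post-vaccination magnitudes; immunogenic effects are log-normal with
  median 600 SFC/10⁶ so cumulative post-vaccination totals span hundreds
  to tens of thousands.
* **ICS** — Gaussian percent-positive readouts around 0.2% background;
  immunogenic epitopes get CD8 means of 2.5% (CD4 1.5% half the time), so
  the strict rule is satisfied with probability > 0.9 at default noise.
* **Repertoires** — 500 clonotypes with gamma(0.5) abundance weights
  sampled to depth 10⁴; immunogenic epitopes expand 1–3 clones (chosen
  among clones with expected pre-vaccination count ≥ 5, as in vitro
  culture expands pre-existing detectable clones) by the configured
  factor (default 20×).

Every stage derives its own sub-seed from the master seed, so a config is
byte-reproducible, and assay realizations can be redrawn independently of
the (deterministic) design stage.

What passing tests on this generator do **not** show: real proteome
composition and peptide processing, binding-predictor error structure,
shared clonotypes across patients, batch effects, or informative
censoring. The generator demonstrates that the calling rules control
their error rates and recover planted signal under the stated noise
model, nothing more.

## Problem sizes and numerical choices

The test suite runs cohorts of 4–18 patients with reduced proteomes
(30–100 proteins of 60–300 residues), 12 × 18 patient-panels for the null
calibration, 200 seeds for power checks, and 20 × 1000 clonotypes for
expansion recovery — sizes chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo error well inside the asserted margins.
Degenerate inputs are contracts, not crashes: windows shorter than the
minimal peptide yield empty enumerations, empty cohorts yield reports
flagged undefined, selections can be empty (with a warning status), and
fewer than two replicate wells make a confirmatory call indeterminate
rather than significant.

## Known limitations

* The toy binding oracle is intentionally simple; interfaces accept
  external per-algorithm predictions via `score_epitopes(predictor = ...)`.
* Proximal phased variants, splice isoforms and codon-level effects are
  out of scope; variants are consumed as protein-level annotations.
* Patient-level event times from real cohorts are protected data, so no
  real survival curve ships with the package; the survival module is
  validated against oracles and simulation instead.
* MHC class II prediction and single-cell TCR processing are out of scope.
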