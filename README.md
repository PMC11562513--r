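# neovax

Design and monitoring pipeline for personalized neoantigen DNA vaccines,
aimed at the adjuvant triple-negative breast cancer setting and similar
low-mutation-burden cohorts. The package covers the full path from a
somatic variant table to a manufacturable construct and from assay
readouts to cohort-level conclusions:

* **Peptide windows** — each protein-altering variant becomes a ≤ 25-mer
  mutant window (up to 12 residues of flank per side) with a matched
  wild-type window; all minimal 8–11-mer epitopes overlapping the mutation
  are enumerated against the patient's HLA class I alleles.
* **Prioritization** — ensemble binding aggregation (across-algorithm
  median IC50 and wild-type/mutant fold change `FC = IC50_WT / IC50_MT`),
  filters (median MT IC50 < 500 nM; transcript and mutant-allele
  expression; FC > 1 required when the mutation sits on an anchor
  position, i.e. position 2 or the C-terminus; exact wild-type proteome
  screen), and a deterministic ranked selection of 4–20 windows per
  patient with stepwise threshold relaxation.
* **Construct assembly** — mutant ubiquitin (G76V, non-cleavable,
  proteasome-routing) fused N-terminally to the ordered windows; reverse
  translation with a human codon-usage table; junctional-epitope report;
  15/16-mer overlapping-peptide monitoring panels (11-residue overlaps;
  a 25-mer window tiles into exactly three peptides).
* **Immune calling** — tiered ELISpot calls (screening floor + fold rule,
  then a one-sided Welch t-test on background-subtracted replicate
  wells), responder classification, cumulative SFC, OP deconvolution, and
  the ICS rule (positive iff post ≥ 2 × pre and post ≥ 1%; relaxed
  variant drops the floor).
* **TCR expansion** — CDR3β clonotype tables, one-sided exact 2×2
  enrichment tests with Benjamini–Hochberg adjustment and a fold floor,
  monoclonal/oligoclonal classification.
* **Outcomes** — Kaplan–Meier product-limit RFS (`S(t) = Π(1 − dᵢ/nᵢ)`),
  log-rank comparison against an unvaccinated arm with its own time zero,
  and a cohort report.
* **Synthetic cohort generator** — a fully seeded simulator (proteome,
  variants, HLA, binding via a deterministic toy ensemble, assays,
  repertoires, follow-up) with known ground truth, emulating an
  18-patient cohort with a median of 21.5 expressed mutations per
  patient, 97% missense variants, ~23% truly immunogenic vaccinated
  epitopes and 2/18 recurrences.

See `vignettes/neoantigen-vaccine-pipeline.Rmd` for the model details and
design decisions.

## Worked example

Cohort statistics recomputed from the packaged per-patient trial summary
(`inst/extdata/trial_summary.tsv`):

```r
library(neovax)
d <- read_trial_summary()
cohort_report(d$n_epitopes, responder = d$immune_response,
              recurrence = d$recurrence)
#> Cohort report (n vaccinated = 18 )
#>   epitopes per vaccine: median 10, mean 11, range 4-20, total 198
#>   responders: 13/18 (72%)
#>   recurrences: 2
```

Eighteen vaccines carrying 198 epitopes in total (median 10 per patient,
range 4–20), with 2 recurrences over follow-up; the response column of
the table marks 13 responding patients.

A fully synthetic cohort, end to end:

```r
cfg <- cohort_config(seed = 7)
cohort <- simulate_cohort(cfg)
res <- analyze_cohort(cohort)
res$report
#> Cohort report (n vaccinated = 18 )
#>   epitopes per vaccine: median 10, mean 10.1111, range 6-15, total 182
#>   responders: 15/18 (83%)
#>   immunogenic epitopes: 45 (25% of vaccinated)
#>   ICS positive (strict/relaxed): 67 / 168
#>   recurrences: 1
#>   RFS at 36 months: 94.4% (95% CI 66.6-99.2%)
```

The caller recovers the planted ground truth: this cohort has 46 truly
immunogenic epitopes and the tiered ELISpot calls confirm 45 of them with
no false positives; the log-rank comparison against the higher-hazard
control arm gives p ≈ 6e-4. Monitoring panels tile each selected window:

```r
design_overlapping_peptides(cohort$designs$P01$selection$mt_sequence[1])
#>   peptide_index start length         sequence
#> 1             1     1     16 ICSAFPPIGQGSLESM
#> 2             2     6     16 PPIGQGSLESMEPSII
#> 3             3    11     15  GSLESMEPSIIMKWG
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/neovax.R run-all --seed 7 --outdir out/
```

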