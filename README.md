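# ragscan

Somatic deletions in childhood acute lymphoblastic leukemia often carry
the sequence footprint of off-target RAG recombinase activity: an
RSS-like motif (heptamer CACAGTG + 12/23-nt spacer + nonamer ACAAAAACC)
near a breakpoint, sitting interior to the deleted segment in
"excision-circle" orientation, with non-templated nucleotides (NTN) at
the repaired junction. ragscan turns that observation into a tested,
reusable pipeline for anyone with a deletion callset, a reference
genome, and patient groups to compare: it classifies each deletion as
putatively RAG-mediated or not, quantifies orientation, motif decay
with distance, and junction structure, and compares groups with
contingency statistics, bootstrap intervals, and a patient-level
random-intercept logistic model.

The core pieces:

* **Exact PWM p-values.** A window of width *w* scores
  `sum(log2(p_i(b_i)/q(b_i)))` bits under a position-weight matrix with
  background q(A)=q(T)=0.3, q(C)=q(G)=0.2; the match p-value
  `P(score >= s)` is computed exactly by dynamic programming over
  discretised score contributions (FIMO-style). Hits are windows with
  `p < 1e-4`, scanned on both strands within ±50 bp of each breakpoint.
* **RAG classification.** Full RSS (either spacer variant) at both
  breakpoints, at one, heptamer only, nonamer only, or none —
  "putatively RAG-mediated" = full RSS at ≥1 breakpoint. Off-target
  means both breakpoints >1000 bp from every Ig/TCR locus.
* **Junction analysis.** Observed junction inserts are stripped of
  templated ends; the remainder is NTN. Empty inserts resolve into
  microhomology or blunt joins.
* **Cohort statistics.** Chi-square (no continuity correction), two-sided
  Fisher, crude odds ratios with Woolf CIs, bootstrap percentile CIs,
  Wilcoxon rank-sum, OLS age associations, and a logistic mixed model
  (lme4) of per-deletion RAG status on exposure group with a per-patient
  random intercept; broom-style `tidy()`/`glance()` methods included.
* **A seeded synthetic cohort generator** that plants RSS motifs,
  orientations, decay, and NTN into a random genome under the study
  design it emulates (18 vs 17 patients, off-target RAG fractions
  0.41 vs 0.21, NTN 0.92/0.79/0.65 by class), so the entire pipeline
  runs and is testable with no access to restricted data.

## Worked example

`rag_demo()` generates a miniature cohort (5 patients per group, two
50-kb chromosomes), runs every stage, and prints a report:

```r
library(ragscan)
res <- rag_demo(seed = 1)
#> ragscan demo cohort (seed 1)
#>   10 patients, 137 deletions (75 off-target)
#>   off-target RAG-mediated: high 42.3% vs low 30.4% (chi-square p = 0.33)
#>   full RSS at both breakpoints: high 9.6% vs low 8.7% (Fisher p = 1)
#>   multilevel OR (high vs low) = 1.65 [0.47, 5.80]
#>   NTN proportion by class: full_both 0.71, full_one 0.82, other 0.63
```

The group percentages are the proportions of off-target deletions whose
breakpoint flanks contain a full RSS hit at `p < 1e-4`; at demo size the
planted high/low contrast (42% vs 30% here) is visible but, as the
printed p-values say, not significant — power arrives at the full study
size, which is what the acceptance script runs. `res$annotations` holds
the per-deletion table (target status, RAG class, per-motif indicators,
orientation flags, junction status), and the full-size equivalent is:

```r
co  <- simulate_rag_cohort(synthetic_config(), seed = 1)
ann <- annotate_deletions(co$deletions, co$genome, co$regions)
ann <- annotate_junctions(ann, co$deletions, co$genome)
ntn_by_class(ann[ann$target_status == "off_target", ])
plot_decay_profile(decay_profile(
  annotate_deletions(co$deletions, co$genome, co$regions, flank = 200)))
```

File-based workflows go through `read_deletions()` (VCF with
`SVTYPE=DEL`/`END`, BEDPE, or TSV; VAF ≤ 0.10 filtered on read),
`read_regions()` (BED), `read_pwm()` (MEME format), `read_patients()`
(TSV), and `run_rag_pipeline()`, which writes every result table plus a
JSON manifest of parameters, seed, and input checksums.

## Layout

```
R/                  scanning, annotation, junctions, k-mers, statistics,
                    generator, pipeline, plots
tests/testthat/     unit + property tests with brute-force oracles,
                    plus the cohort-level acceptance suite
scripts/acceptance.R  end-to-end reproduction script
vignettes/          methods vignette: models, conventions, design choices
```
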