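---
title: "Classifying RAG-mediated deletions from breakpoint motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying RAG-mediated deletions from breakpoint motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragscan)
```

## The biological question

During V(D)J recombination the RAG1/RAG2 recombinase cuts DNA at
recombination signal sequences (RSS): a conserved heptamer (consensus
CACAGTG), a 12- or 23-nucleotide spacer, and a nonamer (consensus
ACAAAAACC) flanking antigen-receptor gene segments. RAG can also cut at
RSS-*like* sequences outside the immunoglobulin and T-cell receptor
(Ig/TCR) loci, producing somatic deletions in lymphoid progenitors —
a recognised mutational mechanism in childhood acute lymphoblastic
leukemia. Given a set of somatic deletion calls, ragscan asks: which
deletions bear the sequence hallmarks of off-target RAG activity, and
do two patient groups differ in the proportion of such deletions?

The hallmarks scored per deletion are:

1. an RSS motif within 50 bp of a breakpoint (full RSS = strong
   evidence; heptamer or nonamer alone = weaker evidence);
2. the motif sitting *interior* to the deleted segment with the
   heptamer's CAC end facing the junction — the orientation in which a
   V(D)J-type reaction releases the signal ends as an excision circle;
3. rapid decay of motif frequency with distance from the breakpoint;
4. non-templated nucleotides (NTN) at the junction, the footprint of
   TdT acting during NHEJ repair of RAG breaks.

## Motif model and exact p-values

Motifs are position-weight matrices over A/C/G/T with the 0-order
background A/T = 0.3, C/G = 0.2. A window of width $w$ scores
$s = \sum_{i=1}^{w} \log_2 p_i(b_i)/q(b_i)$ bits; `N` contributes 0.
The match p-value is the exact FIMO-style tail probability
$P(S \ge s)$ for a window drawn from the background, computed by
dynamic programming over per-position score contributions discretised
to $10^{-3}$ bits (`score_pvalue_table()`). On a width-39 matrix the
accumulated rounding is below $4\times10^{-2}$ bits, orders of
magnitude finer than the $10^{-4}$ decision threshold; the test suite
checks the DP against full $4^7$ enumeration. A window is a hit when
$p < 10^{-4}$, scanned on both strands.

The full RSS matrix is the heptamer, `spacer_len` background columns
(12 or 23), and the nonamer concatenated (`compose_full_rss()`).
Background spacer columns contribute exactly zero bits, so the full
score decomposes into heptamer + nonamer sub-scores; both spacer
variants are scanned and either can satisfy "full RSS".

The matrices used by the published analyses of this type come from the
immunogenetics literature and are not redistributable in matrix form;
the defaults shipped here (`default_rag_pwms()`) are consensus-weighted
matrices with 0.8 on the consensus base, and any MEME-format matrices
can be substituted via `read_pwm()`.

## Per-deletion annotation

Coordinates are 0-based half-open everywhere; a deletion is
`[left_bp, right_bp)`. VCF input (`SVTYPE=DEL` with `END`) is converted
on read so that the deleted bases are the 1-based inclusive range
`[POS, END]`. Calls with VAF ≤ 0.10 are excluded at read time.

For each breakpoint, `annotate_deletions()` extracts the window
covering `flank` (default 50) bases on each side of the boundary and
scans it. Hit offsets are signed 1-based distances from the boundary to
the junction-proximal base of the match: positive interior (flush =
+1), negative exterior, 0 for boundary-straddling matches. Interior is
rightward at the left breakpoint and leftward at the right breakpoint,
which turns "motif internal to the deletion" into a sign test.

Numerical and tie-break choices:

* Overlapping hits of one motif at one breakpoint collapse to the
  single best (lowest p, then smallest |offset|, then interior
  preferred) — deletions are counted as having *a* motif, so
  multiplicity is uninformative.
* Deletions shorter than `2 * flank`: interior hits extending past the
  segment midpoint are dropped on each side, so one planted motif
  cannot satisfy both breakpoints. This is this package's resolution
  of a genuinely open convention.
* Breakpoints within `buffer` (default 1000) bp of an Ig/TCR locus are
  on-target; the buffer is inclusive (distance exactly 1000 counts as
  on-target), fixed so the boundary is testable.
* RAG classes are mutually exclusive: `full_both` > `full_one` >
  `heptamer_only` > `nonamer_only` > `none`, with heptamer evidence
  outranking nonamer evidence. "Putatively RAG-mediated" means
  `full_both` or `full_one`. Per-motif indicator columns are emitted
  alongside so heptamer-only and nonamer-only tabulations need no
  reclassification.

Orientation: an interior heptamer is in excision-circle orientation iff
it matches the plus strand at the left breakpoint or the minus strand
at the right breakpoint (`check_orientation()`). The heptamer is a
perfect palindrome apart from its central base, so orientation
discrimination rests entirely on that position — a weak but real
signal, which is why cohort-level orientation fractions sit near, not
at, 100%.

## Junction resolution

With an observed junction insert, the longest prefix matching the
reference continuation past the left breakpoint and the longest suffix
matching the reference preceding the right breakpoint are stripped
(exact matching only — no mismatch tolerance is defined for this
operation, and exactness is testable); what remains is NTN. A fully
templated insert re-normalises (left-aligns) the breakpoints. An empty
insert is classified by microhomology: the longest exact match (capped
at 25 bp, far beyond biological expectation) between the sequences
ending at the two breakpoints; zero-length means a blunt join. Missing
inserts are `unresolved` and excluded from NTN denominators.

## De novo k-mer discovery

`discover_kmers()` is a deliberately simple analogue of de novo motif
finders: canonical k-mers (k-mer + reverse complement as one unit,
default k = 7) are counted once per sequence (ZOOPS) and compared
against a background of dinucleotide-preserving shuffles of the targets
(Altschul–Erickson random Eulerian paths, 10 copies per target). The
enrichment p-value is the one-sided *conditional* binomial: with the
k-mer present in $x$ of $n_t$ targets and $b$ of $n_b$ background
sequences, $x$ is referred to $\mathrm{Binomial}(x+b,\,
n_t/(n_t+n_b))$. Conditioning on the total removes the sampling noise
of the estimated background frequency; with an unconditional binomial
against $\hat p_0 = b/n_b$, rare k-mers with $b = 0$ are
anti-conservative under a 10× background and null inputs fail a
Bonferroni screen far more often than nominal. There is no PWM
refinement or mismatch-tolerant merging — k-mer presence is the
deliverable.

## Cohort statistics

* Group contrasts of per-deletion outcomes use the Pearson chi-square
  on 2×2 tables **without** Yates continuity correction, and the
  two-sided Fisher exact test defined as the sum of hypergeometric
  probabilities of tables no more probable than the observed one.
  These are the conventions that reproduce the published p-values this
  analysis is built around; both are validated against brute-force
  enumeration in the tests.
* Crude odds ratios are $ad/bc$ with Woolf intervals
  ($\pm 1.96\sqrt{1/a+1/b+1/c+1/d}$ on the log scale);
  Haldane–Anscombe 0.5 is applied and flagged when a cell is zero.
* Per-deletion proportions get 95% bootstrap percentile intervals,
  resampling deletions (not patients) within group, B = 10,000,
  seeded.
* Per-patient count contrasts use the Wilcoxon rank-sum test: exact
  when tie-free and $n \le 20$, otherwise the tie-corrected normal
  approximation without continuity correction.
* The multilevel model is a per-deletion logistic regression on
  exposure group with a per-patient random intercept, fitted by
  lme4 with adaptive Gauss–Hermite quadrature (7 points; Laplace
  fallback). The interval is Wald on the log-odds scale — the
  published analyses of this design print asymmetric intervals that a
  Wald construction cannot reproduce, so only the point estimate is
  comparable. Complete separation is detected from the group-by-outcome
  table and handled by a Firth-penalised fixed-effects fit with a
  warning.

## The synthetic cohort generator

Restricted biospecimens mean the real WGS callsets behind this kind of
study cannot be redistributed, so the package carries a first-class
generator (`simulate_rag_cohort()`) whose defaults *are* the study
conditions the analysis assumes: 18 high- and 17 low-exposure
patients; negative-binomial deletion counts with group means 22 and 10
(dispersion 8), giving ≈566 deletions with an overall median near 12
and a real group difference in counts; 45% of deletions anchored in
one of six labelled Ig/TCR loci; off-target full-RSS (RAG) fractions
0.41 vs 0.21 by group and 0.93 on-target; full-RSS-at-both-breakpoints
fractions 0.23/0.11 of RAG deletions by group; NTN probabilities
0.92/0.79/0.65 by RAG class with geometric lengths (mean 4, minimum
1); interior offsets geometric with mean 15 bp; 30% of planted spacers
are 23-nt. Off-target deletion lengths are log-uniform on 1 kb–1 Mb;
the default genome is two 3-Mb chromosomes drawn from the scan
background, so placement and scanning stay fast while leaving room for
the length distribution.

Three generator choices deserve emphasis:

* **Detection-gated planting.** Planted instances are sampled from the
  PWM *conditional on* passing the scan threshold (bounded rejection
  sampling; `plant_min_pvalue = 1`, or `consensus_plant = TRUE`,
  disable this). The planted class fractions emulate *detected*
  fractions, and unconditional 0.8-weight sampling leaves ~16% of
  instances genuinely undetectable at $p<10^{-4}$, which would make
  the planted parameters unrecoverable by construction.
* **Orientation-unambiguous instances.** Because heptamer orientation
  hinges on the single central base, instances are required to score
  strictly better in the intended orientation than in reverse;
  otherwise a motif "planted in excision-circle orientation" would
  carry no orientation information at all.
* **Genuinely non-templated NTN.** Planted NTN end bases are resampled
  so they cannot be re-absorbed into the reference by the junction
  stripper, keeping truth labels meaningful.

Per-patient random intercepts on the logit RAG probability are
supported (`patient_intercept_sd`) but default to 0: the sequence-level
cohort keeps realized group fractions tight around their targets,
while clustering behaviour is studied with the label-level simulator
`simulate_rag_outcomes()`, which carries the true OR and intercept SD
directly.

What the generator does **not** emulate: repeat structure and GC
heterogeneity of real genomes, caller-specific breakpoint uncertainty,
non-deletion SV classes, mutational signatures, and any correlation
between deletion placement and genes. Passing recovery tests therefore
demonstrates internal consistency of scanner, classifier and
statistics under the declared generative model — not performance on
real tumor callsets.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the full pipeline on
one default cohort (~560 deletions, 6 Mb genome), 100 label-level
replicates for chi-square power, 200 replicates for multilevel OR
recovery, and 100 null runs of the k-mer screen — sizes chosen so the
whole suite completes in a few minutes on one core while keeping Monte
Carlo error well inside the 3-binomial-SD bands used for recovery
checks. Every stochastic step takes an explicit seed, cohort
generation is byte-reproducible, and `run_rag_pipeline()` records all
effective parameters in a JSON manifest whose reruns produce identical
result tables.

## Known limitations

* Heptamer-only hits at $p<10^{-4}$ under the 0.8-weight default PWM
  reduce to exact consensus matches (any mismatch falls below
  threshold), so heptamer-only classes are driven by chance matches;
  sharper literature PWMs change this and can be supplied as files.
* Strand/orientation calls for near-palindromic heptamers are
  single-base decisions; ties (central C/G) are resolved by the
  collapse order, not by evidence.
* The junction stripper is exact-match and left-aligns templated
  inserts; callers that report already-normalised breakpoints are
  unaffected, others may shift motif offsets by a few bases.
* The multilevel Wald interval understates asymmetry for small cell
  counts; profile or bootstrap intervals are out of scope.

## A two-minute tour

```{r demo, eval = FALSE}
library(ragscan)
res <- rag_demo(seed = 1)

co <- simulate_rag_cohort(synthetic_config(), seed = 1)
ann <- annotate_deletions(co$deletions, co$genome, co$regions)
ann <- annotate_junctions(ann, co$deletions, co$genome)
ntn_by_class(ann[ann$target_status == "off_target", ])
plot_decay_profile(decay_profile(
  annotate_deletions(co$deletions, co$genome, co$regions, flank = 200)))
```
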