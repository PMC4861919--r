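---
title: "Detecting domain-truncating gene amplifications from segmented copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domain-truncating gene amplifications from segmented copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truncamp)
library(dplyr)
```

## The problem

Estrogen receptor alpha (ERα), encoded by *ESR1*, drives proliferation in
hormone-dependent tumors. Its C-terminal hormone-binding domain (HBD) is
encoded by the 3' exon block (exons 5–8 in the 8-exon convention), while the
N-terminal transactivation (AF1) and DNA-binding domains sit in the 5' block
(exons 1–4 or 1–3). Somatic copy-number events that amplify only the 5' exon
block — amplifications whose 3' boundary falls *inside* the gene — produce an
amplified, HBD-truncated receptor, a lesion with the potential for
hormone-independent activity and anti-estrogen resistance. The same
functional loss can arise from a heterozygous deletion restricted to the 3'
exon block.

`truncamp` implements the full desk analysis around this phenomenon:

1. call gene-level amplifications from segmented copy-number profiles (SEG
   format, log2 ratios relative to the genome-wide average);
2. classify each amplification as *encompassing* (contains the whole gene
   footprint) or *overlapping* (intersects it partially), and as *focal*
   (strictly shorter than half the host chromosome arm) or not;
3. classify per-exon copy-number profiles into full-length amplification,
   5'-retaining truncating amplification, or 3'-block heterozygous deletion,
   and localize the intragenic breakpoint;
4. aggregate amplifications across the cohort into a binned recurrence
   profile, a minimal common region (MCR), and a binomial locus-enrichment
   test against the genome-wide rate;
5. quantify concordance with exon-level RNA-seq expression via a 5':3'
   exon-block log-ratio statistic, tested with an exact Mann-Whitney U test.

A synthetic-cohort generator with ground-truth labels supports calibration
and parameter-recovery studies; it is first-class, tested code.

## Copy-number model and decision rules

Input profiles are segmented log2 copy-number ratios (CBS/TCGA level-3
style); segmentation, normalization and germline-CNV removal are assumed
done upstream. Internally all intervals are 0-based half-open; the SEG and
exon-model dialects (1-based inclusive) are converted on read.

**Per-exon copy number.** Each exon receives the intersection-length-weighted
mean of the log2 ratios of the segments overlapping it. The weighted mean
(rather than a maximum or marker-weighted rule) is unbiased for the
within-exon mixture when a breakpoint falls inside an exon; exons in
coverage gaps are missing rather than imputed.

**Amplicons.** Maximal runs of segments with log2 ratio at or above `t_amp`,
merged across positional gaps of at most `gap_tol`. Defaults: `t_amp = 0.3`
(about 2.5 copies in a pure diploid sample, a common gain cut-off — the
analysis this models used GISTIC-derived calls whose threshold is not
stated, so the value is exposed in configuration) and `gap_tol = 0`
(CBS output is already maximal-run merged).

**Truncation calls** on the per-exon vector, in order:

* **truncating_amp** — some split $k \in [1, n-1]$ has
  $\mathrm{mean}(\log_2 \mathrm{CN}_{1..k}) \ge t_{amp}$,
  $\mathrm{mean}(\log_2 \mathrm{CN}_{k+1..n}) < t_{amp}$, and a between-block
  difference of at least `delta_min`; $k$ maximizes the difference, ties
  going to the smallest $k$. Block means tolerate single-exon noise, which a
  per-exon all-exceed rule would not; the published calls were made visually
  on segmented data, so the package commits to this explicit rule.
* **full_length_amp** — every exon at or above `t_amp`. A profile that is
  amplified throughout but steps down by at least `delta_min` across some
  split is flagged (`internal_step`), not called truncating: a within-
  amplification step leaves the 3' block amplified.
* **hbd_deletion** — no exon amplified, 3'-block mean at or below
  `t_del = -0.3` (single-copy loss attenuated by tumor impurity down to
  roughly 60% purity) while the 5'-block mean is above it.
* **none** otherwise; a mirrored 3'-retaining pattern is reported as `none`
  with a `three_prime_retained` diagnostic, because only 5'-retaining
  truncations correspond to the phenomenon modeled.

`delta_min` defaults to 0.5 log2 units. The split $k$ is free (any
$1..n-1$), not restricted to the historically observed $k = 3, 4$; the
report carries the observed $k$ per sample.

**Breakpoint localization.** For a truncating call the breakpoint must lie
in the inter-exon gap between the last retained and first lost exon
(transcript order). When exactly one segment boundary falls strictly inside
that gap the interval collapses to that point; otherwise the whole gap is
reported. Coordinates are genomic on both strands.

**Focality.** An amplicon is focal when strictly shorter than half the arm
holding its midpoint; centromere-spanning amplicons belong to the arm with
the larger share. The half-arm rule needs a single denominator, and the
midpoint/larger-share convention decides the ambiguous cases the source
analysis leaves open.

## Recurrence mapping and enrichment

The per-bin recurrence profile (default 1 Mb bins) counts samples with at
least one amplicon overlapping the bin. The MCR is the intersection of the
per-sample amplicons attached to the gene; when amplicons are disjoint the
leftmost maximal-overlap run is returned with a multiplicity flag. Locus
enrichment is a one-sided binomial tail $P(X \ge k \mid n, r)$ with $r$
estimated as the genome-wide mean per-bin amplified fraction (sex
chromosomes excluded by default — their copy-number baseline differs), with
Benjamini–Hochberg adjustment across the loci tested in the run. This is a
deliberate simplification of a GISTIC-style marker-permutation score: it
exposes the same qualitative question (is the locus amplified above the
genome-wide rate?) at desk scale.

## Exon-block expression statistic

RNA-seq exon quantifications are RPKM; exact zeros are floored to 0.1 so
log-ratios are defined, and no other normalization is applied (values are
taken as already normalized upstream; the block ratio cancels global
per-sample scaling anyway). Per sample,

$$ r_i = \mathrm{mean}_{j \in 5'}\log_2 x_{ij} - \mathrm{mean}_{j \in 3'}\log_2 x_{ij}, \qquad \mathrm{fold}_i = 2^{r_i}. $$

Group folds are geometric means, $F_g = 2^{\overline{r_i}}$, and the
headline statistic is the fold-of-folds $F = F_{trunc}/F_{ctrl}$.
Geometric means are the primary summary because arithmetic means of ratios
are scale-biased; arithmetic versions are also reported. Significance uses
a two-tailed Mann-Whitney U on the $r_i$, exact (full labeling enumeration,
tie-aware) whenever the smaller group has at most 8 samples and the
labeling count is at most $10^5$, otherwise a tie-corrected normal
approximation with 0.5 continuity correction. A within-truncated-group test
compares pooled 3'-block vs 5'-block log2 values, either per sample–exon
pair (default) or per exon mean — the appropriate sampling unit is
genuinely open, so both are exposed.

Control selection for the matched comparison mirrors the "similarly focal
amplification without intragenic breakpoint" design: focal full-length
amplified samples ranked by amplicon–gene overlap. The whole-cohort
comparison is a separate mode.

## Statistical core

* `mann_whitney_u()` — statistic $U = \#\{x > y\} + \tfrac12\#\{x = y\}$
  via midranks; exact mode enumerates every labeling of the observed values
  (so ties are exact); two-tailed $p = \min(1, 2\min(P(U \le u), P(U \ge u)))$
  in both modes. The exact cap (min group 8, $10^5$ labelings) covers the
  8-vs-8 design exactly while bounding runtime.
* `pearson_bootstrap()` — product-moment $r$, two-sided t-test on $n-2$
  df, percentile bootstrap interval (default $B = 1000$, seeded and
  recorded). "Standard bootstrapping" in statistical packages varies; the
  defaults are documented rather than claimed to match any one of them.
* `bh_fdr()` — Benjamini–Hochberg step-up, delegated to
  `stats::p.adjust(method = "BH")` behind a validated interface.

## The synthetic-cohort generator

`sim_config()` / `simulate_truth()` / `simulate_cohort()` /
`simulate_expression()` emulate the statistical structure the callers
assume:

* diploid background segments, exponential lengths (mean 20 Mb, truncated
  at arm boundaries — realistic multi-segment chromosomes without modeling
  marker noise), per-segment log2 noise $N(0, 0.1^2)$ by default;
* events at the configured prevalences, or exact per-type counts; the
  default prevalences are the published endometrial cohort structure
  (52/539 broad, 29/539 focal full-length, 7/539 truncating, 1/539
  3'-block deletion, i.e. 16.3% amplified, 6.7% focal);
* amplification levels uniform in 0.8–2.0 log2 units; deletions at −1
  (heterozygous loss in a pure sample); focal events shorter than half the
  host arm, broad events longer; truncation breakpoints uniform inside the
  inter-exon gap after exon $k$, with $k$ drawn from a distribution whose
  default mass sits on $k = 3$ and $k = 4$ (the historically observed
  retained blocks);
* exon expression from an equal per-exon baseline (20 RPKM), amplified
  exons scaled proportionally by the copy fold ($2^{\text{log2 level}}$ —
  amplification-associated expression increase with no stated model, so
  proportional coupling is the default and is overridable); in truncated
  and deletion samples the 3'-lost exons are set so the *realized* 5':3'
  expression ratio equals the implanted fold — the implanted fold is
  defined as the estimator's estimand, which is what makes parameter
  recovery interpretable; multiplicative log-normal noise (default sd 0.25
  in log2 units) and exact zeros at a configurable rate (default 1%)
  complete the matrix.

Everything is deterministic given the config seed; identical config and
seed give byte-identical SEG output.

What the generator does **not** emulate: marker-level noise, tumor purity
and subclonality mixtures, GC or batch artifacts, correlated exon baselines,
isoform switching, or fusion transcripts. Passing tests on simulated
cohorts therefore demonstrate correctness of the pipeline's logic under its
stated model, not performance on real tumor data.

## Study designs used by the bundled analyses

The parameter-recovery study simulates 200 replicate cohorts of 8 truncated
samples with an implanted 5':3' block fold of 2.1 against 8 focal
full-length-amplified controls (and separately a fold of 2.2 against a
545-sample cohort), log-normal noise sd 0.25, equal baselines, no zero
inflation, and the truncation split fixed at $k = 4$. The split is fixed at
the block boundary in this design because the implanted quantity is the
*block* fold: with $k = 3$, exon 4 would be a lost exon inside the 5'
analysis block and the implanted block effect would no longer equal the
nominal fold. Zero inflation is off because the design specifies log-normal
noise as its only expression noise source.

The deterministic truth-recovery study uses a noise-free 539-sample cohort
with exact implanted counts (52 broad, 29 focal full-length, 7 truncating,
1 deletion), on which the pipeline must reproduce every event label, split
index and breakpoint containment, and the printed-style percentages
6.7% / 19.4% / 1.5% / 16.3%.

```{r example}
cfg <- sim_config(
  n_samples = 539,
  counts = c(broad_amp = 52, focal_full_amp = 29,
             truncating_amp = 7, hbd_deletion = 1),
  noise_sd = 0, zero_rate = 0, seed = 42
)
cohort <- simulate_cohort(cfg)
expression <- simulate_expression(cohort$truth, cfg)

dir <- tempfile("cohort-")
paths <- write_fixture(cohort, expression, dir)

report <- run_pipeline(list(
  seg = paths[["segments"]],
  gene_model = system.file("extdata", "toy_gene_model.tsv", package = "truncamp"),
  gene = "ESR1",
  arms = system.file("extdata", "toy_cytoband.tsv", package = "truncamp"),
  expr = paths[["expression"]]
))
report
```

## Numerical choices and degenerate inputs

* Percentages are rounded half-up (1.484% prints as 1.5%), matching how
  cohort fractions are conventionally printed.
* Ties in the truncating-split search go to the smallest $k$; ties in the
  maximal-overlap MCR go to the leftmost run.
* Exact-test boundary handling uses a $10^{-9}$ tolerance when comparing
  enumerated U values, so midrank arithmetic cannot flip a tail.
* Samples with any missing exon value are excluded from truncation calling
  and reported with a `no_coverage` diagnostic; all-missing vectors and
  single-exon genes are errors.
* Half-open interval logic throughout: a segment touching an exon only at
  its boundary does not overlap it.
* The bundled 8-exon gene model and two-chromosome genome are fixture
  values chosen for geometric realism (a 171 Mb chromosome with a 61 Mb p
  arm, gene on the q arm), not coordinates claimed from any annotation
  release.

## Known limitations

* Segmentation, purity/ploidy correction and allele-specific copy number
  are out of scope; inputs are taken as already segmented and normalized.
* The enrichment test is a binomial simplification, not a
  marker-permutation G-score; its q-values are not comparable to
  GISTIC's.
* One canonical transcript per gene; multi-transcript gene models must be
  resolved upstream.
* Only 5'-retaining truncations are called as events; the mirrored pattern
  is surfaced via diagnostics for manual review.
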