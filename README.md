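# truncamp

Detection of hormone-binding-domain–truncating gene amplifications from
segmented somatic copy-number data, and quantification of their concordance
with exon-level mRNA expression.

## What it does, and for whom

In hormone-dependent tumors (endometrial and breast carcinoma in
particular), amplifications of *ESR1* whose 3' boundary falls *inside* the
gene amplify only the 5' exon block — the transactivation (AF1) and
DNA-binding domains — while leaving the exons encoding the hormone-binding
domain (HBD) at lower copy number. The resulting amplified, HBD-truncated
estrogen receptor is a candidate driver of hormone-independent growth and
anti-estrogen resistance. `truncamp` is for cancer-genomics analysts who
have segmented copy-number profiles (SEG format) and exon-level RPKM
matrices and want to call, localize and quantify such events cohort-wide.

The core statistics:

* **Amplification calling** — amplicons are maximal runs of segments with
  log2 ratio ≥ `t_amp` (default 0.3); calls are *encompassing* vs
  *overlapping* the gene footprint; *focal* means strictly shorter than
  half the host chromosome arm.
* **Truncation calling** — on the per-exon copy-number vector
  (intersection-length-weighted segment means), a 5'-retaining truncating
  amplification is a split `k` with block means
  `mean(log2 CN[1..k]) ≥ t_amp > mean(log2 CN[k+1..n])` and between-block
  difference ≥ `delta_min`; 3'-block heterozygous deletions use
  `t_del = -0.3`. The intragenic breakpoint is localized to the inter-exon
  gap (or the single segment boundary inside it).
* **Exon-block expression ratio** — per sample
  `r_i = mean(log2 RPKM, 5' exons) − mean(log2 RPKM, 3' exons)` on
  zero-floored (0.1) RPKM; group folds are geometric means
  `F_g = 2^mean(r_i)` and the headline fold-of-folds is
  `F = F_truncated / F_control`, tested with an exact (tie-aware,
  enumeration-based) two-tailed Mann-Whitney U test.
* **Recurrence mapping** — binned amplification frequency, minimal common
  region, target-gene nomination and a binomial locus-enrichment test
  against the genome-wide rate with Benjamini–Hochberg adjustment.
* **Synthetic cohorts** — a seeded generator produces segmented profiles
  and matched expression matrices with ground-truth labels for calibration
  and parameter-recovery studies.

## Worked example

Simulate a 539-sample cohort with the endometrial-carcinoma event
structure implanted exactly (52 broad amplifications, 29 focal full-length,
7 truncating, 1 HBD deletion), write it to disk, and run the full pipeline:

```r
library(truncamp)

cfg <- sim_config(
  n_samples = 539,
  counts = c(broad_amp = 52, focal_full_amp = 29,
             truncating_amp = 7, hbd_deletion = 1),
  noise_sd = 0, zero_rate = 0, seed = 42
)
cohort <- simulate_cohort(cfg)
expression <- simulate_expression(cohort$truth, cfg)
paths <- write_fixture(cohort, expression, tempfile("cohort-"))

report <- run_pipeline(list(
  seg = paths[["segments"]],
  gene_model = system.file("extdata", "toy_gene_model.tsv", package = "truncamp"),
  gene = "ESR1",
  arms = system.file("extdata", "toy_cytoband.tsv", package = "truncamp"),
  expr = paths[["expression"]]
))
report
```

```
Cohort truncation report
  samples: 539
  amplified: 88 (16.3%); focal: 36 (6.7%)
  truncating amplifications: 7 (1.3% of cohort, 19.4% of focal)
  3'-block deletions: 1; total truncation rate: 1.5%
  locus enrichment: k = 88 / n = 539, background 0.0220, p = 4.7e-48, q = 4.7e-48
  5':3' fold-of-folds, matched controls: 1.84 (p = 0.000583)
  5':3' fold-of-folds, whole cohort: 1.93 (p = 5.63e-06)
```

Reading the output: 88/539 samples (16.3%) carry an amplification
encompassing or overlapping the gene, 36 (6.7%) of them focal; the 7
truncating amplifications are 19.4% of the focal ones, and together with
the single HBD deletion give a 1.5% overall truncation rate. The gene locus
is amplified far above the genome-wide background rate (2.2% of sample-bins).
The expression section compares the 7 called truncated samples against 7
matched focal-amplified controls and against the rest of the cohort: their
5':3' exon-block expression ratio is elevated (a single noisy cohort;
the implanted generator fold here is 2.1, and the estimate averages to the
implanted value across replicate cohorts — see below). Per-sample ratios,
calls, breakpoints, the recurrence bedGraph and the JSON report are written
when `out_dir` is set.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; see the vignette in `vignettes/` for the model,
decision rules, generator assumptions and limitations.

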