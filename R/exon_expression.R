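# Exon-level expression: RPKM flooring, the 5'-block vs 3'-block log-ratio
# statistic, and group comparisons of the per-sample ratios.

#' Read an exon-by-sample RPKM matrix
#'
#' TSV with one row per sample: first column `sample`, remaining columns the
#' exon values in transcript order (any column names; `exon_1..exon_n` is
#' the dialect this package writes).
#'
#' @param path Path to the TSV.
#' @return An `expr_tbl` tibble: `sample` plus `exon_1..exon_n`.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(raw)[1] != "sample") abort("first column must be `sample`")
  vals <- raw[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("all exon columns must be numeric")
  }
  names(vals) <- paste0("exon_", seq_len(ncol(vals)))
  new_expr_tbl(dplyr::bind_cols(raw[, 1], vals), floored = FALSE)
}

new_expr_tbl <- function(x, floored) {
  structure(as_tibble(x),
            class = unique(c("expr_tbl", class(as_tibble(x)))),
            floored = floored)
}

exon_cols <- function(expr) grep("^exon_", names(expr), value = TRUE)

#' Floor zero RPKM values to 0.1
#'
#' Exact zeros are replaced by 0.1 so that log ratios are defined; all other
#' values are unchanged. Negative values are rejected and flooring twice is
#' an error.
#'
#' @param expr An `expr_tbl` tibble.
#' @return The floored `expr_tbl` (attribute `floored = TRUE`).
#' @export
floor_rpkm <- function(expr) {
  if (isTRUE(attr(expr, "floored"))) abort("matrix is already floored")
  cols <- exon_cols(expr)
  vals <- as.matrix(expr[cols])
  if (any(vals < 0)) abort("RPKM values must be non-negative")
  vals[vals == 0] <- 0.1
  out <- expr
  out[cols] <- as_tibble(vals)
  new_expr_tbl(out, floored = TRUE)
}

#' Per-sample 5':3' exon-block log-ratio
#'
#' For each sample, the ratio is `mean(log2 RPKM over 5' exons) - mean(log2
#' RPKM over 3' exons)` and `fold = 2^r`. A truncating event that lowers 3'-block
#' expression yields `fold > 1`. The ratio cancels any global per-sample
#' scaling (library size), so no normalization beyond the 0.1 floor is
#' applied.
#'
#' @param expr A floored `expr_tbl` tibble.
#' @param blocks An `exon_blocks` partition matching the matrix width.
#' @return Tibble `sample`, `r`, `fold`.
#' @export
block_ratios <- function(expr, blocks) {
  if (!isTRUE(attr(expr, "floored"))) {
    abort("floor the matrix with floor_rpkm() before computing ratios")
  }
  cols <- exon_cols(expr)
  if (length(cols) != blocks$n) {
    abort("matrix width does not match the exon-block partition")
  }
  vals <- as.matrix(expr[cols])
  if (anyNA(vals)) abort("expression matrix must be complete (no NA)")
  lv <- log2(vals)
  r <- rowMeans(lv[, blocks$five_prime, drop = FALSE]) -
    rowMeans(lv[, blocks$three_prime, drop = FALSE])
  tibble(sample = expr$sample, r = unname(r), fold = 2^unname(r))
}

#' Compare 5':3' expression ratios between truncated and control samples
#'
#' Group folds are geometric means (`F_group = 2^mean(r)`), the primary
#' scale-unbiased summary; arithmetic means of the per-sample folds are also
#' reported. The headline statistic is the fold-of-folds
#' `F = F_truncated / F_control`, with a two-tailed Mann-Whitney U test on
#' the per-sample ratios (exact when the smaller group has at most 8
#' samples and the labeling count permits).
#'
#' @param expr A floored `expr_tbl` tibble.
#' @param truncated,control Disjoint character vectors of sample ids.
#' @param blocks An `exon_blocks` partition.
#' @param boot Number of bootstrap resamples for a percentile interval on
#'   the fold-of-folds (0 = no interval).
#' @param boot_seed Seed of the bootstrap resampling.
#' @param conf Confidence level of the interval.
#' @return An object of class `fold_comparison`.
#' @export
group_fold_comparison <- function(expr, truncated, control, blocks,
                                  boot = 0, boot_seed = 1, conf = 0.95) {
  if (length(truncated) == 0 || length(control) == 0) {
    abort("both groups must be non-empty")
  }
  if (length(intersect(truncated, control)) > 0) {
    abort("truncated and control groups overlap")
  }
  missing_ids <- setdiff(c(truncated, control), expr$sample)
  if (length(missing_ids) > 0) {
    abort(paste0("samples absent from the matrix: ",
                 paste(missing_ids, collapse = ", ")))
  }
  ratios <- block_ratios(expr, blocks) %>%
    filter(.data$sample %in% c(truncated, control)) %>%
    mutate(group = if_else(.data$sample %in% truncated, "truncated", "control"))
  rt <- ratios$r[ratios$group == "truncated"]
  rc <- ratios$r[ratios$group == "control"]
  mwu <- mann_whitney_u(rt, rc)
  ci <- NULL
  if (boot > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(boot_seed)
    f_star <- vapply(seq_len(boot), function(b) {
      2^(mean(sample(rt, replace = TRUE)) - mean(sample(rc, replace = TRUE)))
    }, numeric(1))
    ci <- unname(quantile(f_star, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(
    ci_low = if (is.null(ci)) NA_real_ else ci[1],
    ci_high = if (is.null(ci)) NA_real_ else ci[2],
    ratios = ratios,
    f_truncated = 2^mean(rt), f_control = 2^mean(rc),
    fold_of_folds = 2^(mean(rt) - mean(rc)),
    f_truncated_arith = mean(2^rt), f_control_arith = mean(2^rc),
    fold_of_folds_arith = mean(2^rt) / mean(2^rc),
    u = mwu$u, p_value = mwu$p_value, mwu = mwu
  ), class = "fold_comparison")
}

#' @export
print.fold_comparison <- function(x, ...) {
  cat(sprintf(
    "5':3' exon-block fold comparison\n  F_truncated = %.3f, F_control = %.3f, fold-of-folds = %.3f\n  Mann-Whitney U = %g (%s), two-tailed p = %.4g\n",
    x$f_truncated, x$f_control, x$fold_of_folds, x$u, x$mwu$mode, x$p_value))
  invisible(x)
}

#' Tidy per-sample ratios of a fold comparison
#'
#' @param x A `fold_comparison` object.
#' @param ... Unused.
#' @return Tibble `sample`, `group`, `r`, `fold`.
#' @export
tidy.fold_comparison <- function(x, ...) {
  as_tibble(x$ratios[c("sample", "group", "r", "fold")])
}

#' One-row summary of a fold comparison
#'
#' @param x A `fold_comparison` object.
#' @param ... Unused.
#' @return One-row tibble with the group folds, fold-of-folds, U and p.
#' @export
glance.fold_comparison <- function(x, ...) {
  tibble(f_truncated = x$f_truncated, f_control = x$f_control,
         fold_of_folds = x$fold_of_folds,
         fold_of_folds_arith = x$fold_of_folds_arith,
         conf.low = x$ci_low, conf.high = x$ci_high,
         statistic = x$u, p.value = x$p_value, method = x$mwu$mode)
}

#' Within-truncated-group test of 3' vs 5' exon expression
#'
#' Pools log2 RPKM values across the truncated samples and compares the
#' 3'-block values against the 5'-block values with a two-tailed
#' Mann-Whitney U test. `unit = "exon_sample"` uses every sample-exon pair
#' as an observation; `unit = "exon_mean"` first averages each exon across
#' samples.
#'
#' @param expr A floored `expr_tbl` tibble.
#' @param truncated Non-empty character vector of sample ids.
#' @param blocks An `exon_blocks` partition.
#' @param unit Sampling unit, `"exon_sample"` (default) or `"exon_mean"`.
#' @return An `mwu_test` object (3'-block values as the first sample).
#' @export
within_group_block_test <- function(expr, truncated, blocks,
                                    unit = c("exon_sample", "exon_mean")) {
  unit <- match.arg(unit)
  if (length(truncated) == 0) abort("the truncated group is empty")
  if (!isTRUE(attr(expr, "floored"))) {
    abort("floor the matrix with floor_rpkm() before testing")
  }
  rows <- filter(expr, .data$sample %in% truncated)
  if (nrow(rows) < length(unique(truncated))) {
    abort("samples absent from the matrix")
  }
  lv <- log2(as.matrix(rows[exon_cols(rows)]))
  if (unit == "exon_mean") lv <- matrix(colMeans(lv), nrow = 1)
  mann_whitney_u(as.vector(lv[, blocks$three_prime, drop = FALSE]),
                 as.vector(lv[, blocks$five_prime, drop = FALSE]))
}

#' Pick matched amplified controls for a fold comparison
#'
#' Controls emulate the "similarly focal, no intragenic breakpoint" design:
#' samples with a focal full-length amplification of the gene, ranked by the
#' overlap of their attached amplicon with the gene footprint, largest
#' first.
#'
#' @param amp_calls An `amp_call_tbl` tibble.
#' @param trunc_calls A `trunc_call_tbl` tibble.
#' @param gene A `gene_model` tibble.
#' @param m Number of controls wanted.
#' @return Character vector of up to `m` sample ids.
#' @export
pick_controls <- function(amp_calls, trunc_calls, gene, m) {
  fp <- gene_footprint(gene)
  full <- trunc_calls$sample[trunc_calls$event_type == "full_length_amp"]
  cand <- amp_calls %>%
    filter(.data$focal %in% TRUE, .data$sample %in% full) %>%
    mutate(overlap = pmin(.data$amplicon_end, fp["end"]) -
             pmax(.data$amplicon_start, fp["start"])) %>%
    arrange(dplyr::desc(.data$overlap))
  head(cand$sample, m)
}
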