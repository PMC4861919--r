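# Cohort report: end-to-end pipeline driver and the printed-percentage
# arithmetic that cohort headline numbers use.

#' Half-up percentage
#'
#' `100 * k / n` rounded half-up (not banker's rounding) to the requested
#' number of decimals, so that e.g. 8/539 prints as 1.5.
#'
#' @param k,n Counts with `0 <= k <= n`, `n > 0`.
#' @param decimals Decimal places, default 1.
#' @return The rounded percentage.
#' @examples
#' percentage(88, 539, 1)  # 16.3
#' @export
percentage <- function(k, n, decimals = 1) {
  if (any(n <= 0)) abort("n must be positive")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  scale <- 10^decimals
  floor(100 * k / n * scale + 0.5) / scale
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_stage(stage, conditionMessage(e))
  })
}

#' Run the full truncation-analysis pipeline
#'
#' Stages: read inputs, merge amplicons, call gene-level amplification,
#' call truncations on per-exon copy number, localize breakpoints, summarize
#' the cohort, map the binned recurrence profile and minimal common region,
#' test locus enrichment against the genome-wide rate, and (when an
#' expression matrix is supplied) compare 5':3' exon-block expression ratios
#' of truncated samples against matched focal-amplified controls and against
#' the rest of the cohort.
#'
#' @param config A named list, or the path of a YAML file holding one, with
#'   elements: `seg`, `gene_model`, `gene`, `arms` (file paths and gene
#'   symbol); optional `expr` and `labels` paths; optional parameters
#'   `t_amp` (0.3), `t_del` (-0.3), `delta_min` (0.5), `split_after` (4),
#'   `gap_tol` (0), `bin_width` (1e6); optional `out_dir`.
#' @return A `cohort_report` list; when `out_dir` is set, also writes
#'   `report.json`, `calls.tsv`, `truncations.tsv`, `frequency.bedgraph`,
#'   `enrichment.tsv` and `ratios.tsv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- run_stage("config", yaml::read_yaml(config))
  }
  p <- function(name, default) config[[name]] %||% default
  t_amp <- p("t_amp", 0.3); t_del <- p("t_del", -0.3)
  delta_min <- p("delta_min", 0.5); split_after <- p("split_after", 4)
  gap_tol <- p("gap_tol", 0); bin_width <- p("bin_width", 1e6)

  gene <- run_stage("gene_model", load_gene_model(config$gene_model, config$gene))
  arms <- run_stage("arm_table", load_arm_table(config$arms))
  seg <- run_stage("cn_segments", read_seg(config$seg))
  samples <- sort(unique(seg$sample))
  blocks <- exon_blocks(gene, split_after)

  amplicons <- run_stage("amplification_caller",
                         amplicons_from_segments(seg, t_amp = t_amp, gap_tol = gap_tol))
  amp_calls <- run_stage("amplification_caller",
                         call_amplification(amplicons, gene, arms, samples = samples))

  exon_cn <- run_stage("cn_segments", exon_copy_number(seg, gene, samples = samples))
  complete <- exon_cn %>%
    group_by(.data$sample) %>%
    summarise(ok = !anyNA(.data$log2), .groups = "drop")
  callable <- complete$sample[complete$ok]
  trunc_calls <- run_stage("truncation_caller", {
    calls <- call_truncation(filter(exon_cn, .data$sample %in% callable),
                             blocks, t_amp = t_amp, t_del = t_del,
                             delta_min = delta_min)
    skipped <- setdiff(samples, callable)
    if (length(skipped) > 0) {
      calls <- bind_rows(calls, tibble(
        sample = skipped, gene = gene$gene[1], event_type = "none",
        k = NA_integer_, retained_exons = "", lost_exons = "",
        diagnostic = "no_coverage"))
    }
    breakpoint_interval(seg, gene, arrange(calls, .data$sample))
  })
  summary <- run_stage("truncation_caller",
                       cohort_truncation_summary(trunc_calls, amp_calls))

  freq <- run_stage("peak_mapper",
                    amplification_frequency(amplicons, arms, length(samples),
                                            bin_width = bin_width))
  rate <- run_stage("peak_mapper", background_rate(freq))
  fp <- gene_footprint(gene)
  gene_amps <- amp_calls %>% filter(.data$overlap_class != "none")
  mcr <- if (nrow(gene_amps) > 0) {
    run_stage("peak_mapper", minimal_common_region(
      tibble(start = gene_amps$amplicon_start, end = gene_amps$amplicon_end)))
  } else NULL
  enrichment <- if (rate > 0 && rate < 1) {
    run_stage("peak_mapper",
              locus_enrichment(nrow(gene_amps), length(samples), rate))
  } else NULL
  targets <- if (!is.null(mcr)) {
    run_stage("peak_mapper", target_genes(mcr, list(gene)))
  } else NULL

  expression <- NULL
  ratios <- NULL
  if (!is.null(config$expr)) {
    expression <- run_stage("exon_expression", {
      expr <- floor_rpkm(read_expression_matrix(config$expr))
      if (!is.null(config$labels)) {
        labels <- readr::read_tsv(config$labels, show_col_types = FALSE,
                                  progress = FALSE)
        truncated <- labels$sample[labels$group == "truncated"]
        matched_controls <- labels$sample[labels$group == "control"]
      } else {
        truncated <- trunc_calls$sample[trunc_calls$event_type == "truncating_amp"]
        matched_controls <- pick_controls(amp_calls, trunc_calls, gene,
                                          length(truncated))
      }
      if (length(truncated) == 0 || length(matched_controls) == 0) {
        list(available = TRUE, comparable = FALSE)
      } else {
        matched <- group_fold_comparison(expr, truncated, matched_controls, blocks)
        rest <- setdiff(expr$sample, truncated)
        all_mode <- group_fold_comparison(expr, truncated, rest, blocks)
        within <- within_group_block_test(expr, truncated, blocks)
        ratios <- tidy(matched)
        list(available = TRUE, comparable = TRUE,
             truncated = truncated, matched_controls = matched_controls,
             matched = glance(matched), all_cohort = glance(all_mode),
             within_block_p = within$p_value)
      }
    })
  }

  report <- structure(list(
    n = length(samples),
    summary = summary,
    mcr = mcr,
    target_genes = targets,
    enrichment = enrichment,
    background_rate = rate,
    expression = expression,
    parameters = list(t_amp = t_amp, t_del = t_del, delta_min = delta_min,
                      split_after = split_after, gap_tol = gap_tol,
                      bin_width = bin_width, gene = config$gene),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "cohort_report")

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    readr::write_tsv(amp_calls, file.path(out, "calls.tsv"), progress = FALSE)
    readr::write_tsv(trunc_calls, file.path(out, "truncations.tsv"),
                     progress = FALSE)
    write_bedgraph(freq, file.path(out, "frequency.bedgraph"))
    if (!is.null(enrichment)) {
      readr::write_tsv(enrichment, file.path(out, "enrichment.tsv"),
                       progress = FALSE)
    }
    if (!is.null(ratios)) {
      readr::write_tsv(ratios, file.path(out, "ratios.tsv"), progress = FALSE)
    }
    jsonlite::write_json(report_as_list(report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

report_as_list <- function(report) {
  x <- unclass(report)
  x$summary <- as.list(x$summary)
  if (!is.null(x$enrichment)) x$enrichment <- as.list(x$enrichment)
  if (!is.null(x$target_genes)) x$target_genes <- as.list(x$target_genes)
  if (!is.null(x$expression) && isTRUE(x$expression$comparable)) {
    x$expression$matched <- as.list(x$expression$matched)
    x$expression$all_cohort <- as.list(x$expression$all_cohort)
  }
  x
}

#' @export
print.cohort_report <- function(x, ...) {
  s <- x$summary
  cat("Cohort truncation report\n")
  cat(sprintf("  samples: %d\n", x$n))
  cat(sprintf("  amplified: %d (%.1f%%); focal: %d (%.1f%%)\n",
              s$amplified, s$pct_amplified, s$focal, s$pct_focal))
  cat(sprintf("  truncating amplifications: %d (%.1f%% of cohort, %.1f%% of focal)\n",
              s$truncating_amp, s$pct_truncating, s$pct_truncating_of_focal))
  cat(sprintf("  3'-block deletions: %d; total truncation rate: %.1f%%\n",
              s$hbd_deletion, s$truncation_rate))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  locus enrichment: k = %d / n = %d, background %.4f, p = %.3g, q = %.3g\n",
                x$enrichment$k, x$enrichment$n, x$enrichment$background_rate,
                x$enrichment$p, x$enrichment$q))
  }
  if (!is.null(x$expression) && isTRUE(x$expression$comparable)) {
    m <- x$expression$matched; a <- x$expression$all_cohort
    cat(sprintf("  5':3' fold-of-folds, matched controls: %.2f (p = %.3g)\n",
                m$fold_of_folds, m$p.value))
    cat(sprintf("  5':3' fold-of-folds, whole cohort: %.2f (p = %.3g)\n",
                a$fold_of_folds, a$p.value))
  } else if (is.null(x$expression)) {
    cat("  expression: absent\n")
  }
  invisible(x)
}
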