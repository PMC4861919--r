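# Truncation calling on per-exon copy-number vectors.
#
# The phenomenon of interest: an amplification whose 3' boundary falls inside
# the gene, amplifying a 5' exon prefix (e.g. exons 1-4 or 1-3 of ESR1,
# carrying the AF1 and DNA-binding domains) while leaving the 3'
# hormone-binding-domain exons at lower copy number; or, more rarely, a
# heterozygous deletion restricted to the 3' exon block.

#' Classify per-exon copy-number profiles into truncation events
#'
#' Decision rules, applied per sample in this order:
#' \enumerate{
#'   \item \strong{truncating_amp}: there is a split `k` in `1..n-1` with
#'     mean log2 over exons `1..k` at or above `t_amp`, mean over `k+1..n`
#'     below `t_amp`, and a between-block difference of at least
#'     `delta_min`; `k` maximizes the difference (ties broken toward the
#'     smallest `k`).
#'   \item \strong{full_length_amp}: every exon at or above `t_amp`.
#'   \item \strong{hbd_deletion}: no exon at or above `t_amp`, 3'-block mean
#'     at or below `t_del` while the 5'-block mean is above `t_del`.
#'   \item \strong{none} otherwise.
#' }
#' Block means (rather than all-exon exceedance) tolerate single-exon noise.
#' Only 5'-retaining truncations are called; a mirrored 3'-retaining pattern
#' is reported as `none` with diagnostic `"three_prime_retained"`. A profile
#' that is amplified throughout but carries an internal step of at least
#' `delta_min` gets diagnostic `"internal_step"`.
#'
#' @param exon_cn An `exon_cn` tibble from [exon_copy_number()]; no `NA`
#'   values are allowed (impute or drop samples first).
#' @param blocks An `exon_blocks` partition (used for the deletion rule).
#' @param t_amp Amplification threshold (log2), default 0.3.
#' @param t_del Heterozygous-deletion threshold (log2), default -0.3
#'   (single-copy loss attenuated by tumor impurity).
#' @param delta_min Minimum between-block log2 difference for a truncating
#'   call, default 0.5.
#' @return A `trunc_call_tbl` tibble: `sample`, `gene`, `event_type`, `k`,
#'   `retained_exons`, `lost_exons` (compact "1-4"-style strings), and
#'   `diagnostic`.
#' @export
call_truncation <- function(exon_cn, blocks, t_amp = 0.3, t_del = -0.3,
                            delta_min = 0.5) {
  check_number(t_amp, "t_amp")
  check_number(t_del, "t_del")
  check_number(delta_min, "delta_min", lower = 0)
  out <- exon_cn %>%
    arrange(.data$sample, .data$exon) %>%
    group_by(.data$sample, .data$gene) %>%
    dplyr::group_modify(function(df, key) {
      classify_profile(df$log2, blocks, t_amp, t_del, delta_min)
    }) %>%
    ungroup()
  structure(out, class = unique(c("trunc_call_tbl", class(out))))
}

classify_profile <- function(v, blocks, t_amp, t_del, delta_min) {
  n <- length(v)
  if (all(is.na(v))) abort("no coverage: all exon values are missing")
  if (any(is.na(v))) abort("missing exon values; impute or drop the sample first")
  if (n < 2) abort("a truncation call needs at least 2 exons")
  ks <- seq_len(n - 1)
  mean5 <- cumsum(v)[ks] / ks
  mean3 <- (sum(v) - cumsum(v)[ks]) / (n - ks)
  diff <- mean5 - mean3
  ok <- mean5 >= t_amp & mean3 < t_amp & diff >= delta_min
  res <- function(event, k, retained, lost, diagnostic = NA_character_) {
    tibble(event_type = event, k = k,
           retained_exons = compact_exon_set(retained),
           lost_exons = compact_exon_set(lost),
           diagnostic = diagnostic)
  }
  if (any(ok)) {
    k <- ks[ok][which.max(diff[ok])]   # which.max takes the first maximum -> smallest k on ties
    return(res("truncating_amp", k, seq_len(k), seq.int(k + 1, n)))
  }
  if (all(v >= t_amp)) {
    diag <- if (any(diff >= delta_min)) "internal_step" else NA_character_
    return(res("full_length_amp", NA_integer_, seq_len(n), integer(0), diag))
  }
  fp <- blocks$five_prime; tp <- blocks$three_prime
  if (!any(v >= t_amp) && mean(v[tp]) <= t_del && mean(v[fp]) > t_del) {
    return(res("hbd_deletion", blocks$split_after, fp, tp))
  }
  mirrored <- mean3 >= t_amp & mean5 < t_amp & (-diff) >= delta_min
  diag <- if (any(mirrored)) "three_prime_retained" else NA_character_
  res("none", NA_integer_, integer(0), integer(0), diag)
}

compact_exon_set <- function(idx) {
  if (length(idx) == 0) return("")
  idx <- sort(unique(as.integer(idx)))
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = ",")
}

parse_exon_set <- function(x) {
  if (is.na(x) || x == "") return(integer(0))
  unlist(lapply(strsplit(x, ",")[[1]], function(part) {
    ab <- as.integer(strsplit(part, "-")[[1]])
    if (length(ab) == 2) seq.int(ab[1], ab[2]) else ab
  }))
}

#' Localize the intragenic breakpoint of a truncating amplification
#'
#' The breakpoint must lie in the inter-exon gap between the last retained
#' and the first lost exon (in transcript order). When exactly one segment
#' boundary of the sample falls strictly inside that gap, the interval is
#' narrowed to that point; otherwise the full gap is returned. Coordinates
#' are genomic regardless of strand.
#'
#' @param seg A `seg_tbl` tibble.
#' @param gene A `gene_model` tibble.
#' @param calls A `trunc_call_tbl` tibble; only `truncating_amp` rows are
#'   eligible.
#' @return `calls` with added `breakpoint_start` and `breakpoint_end`
#'   columns (`NA` for non-truncating rows).
#' @export
breakpoint_interval <- function(seg, gene, calls) {
  chrom <- gene$chromosome[1]
  on_chrom <- filter(seg, .data$chromosome == chrom)
  interval_for <- function(s, event, k) {
    if (is.na(event) || event != "truncating_amp") return(c(NA_real_, NA_real_))
    last_ret <- filter(gene, .data$exon == k)
    first_lost <- filter(gene, .data$exon == k + 1)
    # transcript-order gap expressed in genomic coordinates
    gap <- sort(c(
      if (gene$strand[1] == "+") last_ret$end else first_lost$end,
      if (gene$strand[1] == "+") first_lost$start else last_ret$start
    ))
    bounds <- filter(on_chrom, .data$sample == s)
    boundary <- unique(c(bounds$start, bounds$end))
    inside <- boundary[boundary > gap[1] & boundary < gap[2]]
    if (length(inside) == 1) c(inside, inside) else gap
  }
  if (any(calls$event_type == "truncating_amp" & is.na(calls$k))) {
    abort("truncating rows must carry a split index k")
  }
  iv <- purrr::pmap(list(calls$sample, calls$event_type, calls$k), interval_for)
  calls$breakpoint_start <- purrr::map_dbl(iv, 1)
  calls$breakpoint_end <- purrr::map_dbl(iv, 2)
  calls
}

#' Cohort-level truncation summary
#'
#' Counts and percentages of amplified, focal, truncating and
#' 3'-block-deleted samples, and the total truncation rate
#' (truncating amplifications plus 3'-block deletions over the cohort).
#' Percentages use half-up rounding to one decimal, matching how such
#' cohort fractions are conventionally printed.
#'
#' @param calls A `trunc_call_tbl` tibble, one row per sample.
#' @param amp_calls An `amp_call_tbl` tibble, one row per sample (defines
#'   the cohort).
#' @return A one-row tibble of counts and percentages.
#' @export
cohort_truncation_summary <- function(calls, amp_calls) {
  if (anyDuplicated(amp_calls$sample) || anyDuplicated(calls$sample)) {
    abort("duplicate sample_id in calls")
  }
  n <- nrow(amp_calls)
  amplified <- sum(amp_calls$overlap_class != "none")
  focal <- sum(amp_calls$focal %in% TRUE)
  truncating <- sum(calls$event_type == "truncating_amp")
  hbd_del <- sum(calls$event_type == "hbd_deletion")
  truncated_total <- truncating + hbd_del
  tibble(
    n = n, amplified = amplified, focal = focal,
    truncating_amp = truncating, hbd_deletion = hbd_del,
    pct_amplified = percentage(amplified, n, 1),
    pct_focal = percentage(focal, n, 1),
    pct_truncating = percentage(truncating, n, 1),
    pct_truncating_of_focal = if (focal > 0) percentage(truncating, focal, 1) else 0,
    truncation_rate = percentage(truncated_total, n, 1)
  )
}
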