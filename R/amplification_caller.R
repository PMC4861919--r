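# Gene-level amplification calling: suprathreshold segment runs ("amplicons"),
# encompassing vs overlapping classification, and the focality rule
# (focal = shorter than half the host chromosome arm).

#' Merge suprathreshold segments into amplicons
#'
#' An amplicon is a maximal run of segments with `log2_ratio >= t_amp`,
#' merging consecutive suprathreshold segments whose positional gap is at
#' most `gap_tol`. With CBS-style input (already maximal-run merged) the
#' default `gap_tol = 0` keeps adjacent amplified segments together and
#' splits runs interrupted by any normal stretch.
#'
#' @param seg A `seg_tbl` tibble.
#' @param t_amp Amplification threshold on the log2 ratio (> 0). The default
#'   0.3 corresponds to roughly 2.5 copies in a pure diploid sample.
#' @param gap_tol Maximum inter-segment gap (bp) bridged when merging.
#' @param chromosome Optional chromosome filter.
#' @return An `amplicon_tbl` tibble: `sample`, `chromosome`, `start`, `end`,
#'   `max_log2`, `n_segments`.
#' @export
amplicons_from_segments <- function(seg, t_amp = 0.3, gap_tol = 0,
                                    chromosome = NULL) {
  check_number(t_amp, "t_amp", lower = .Machine$double.eps)
  check_number(gap_tol, "gap_tol", lower = 0)
  hits <- filter(seg, .data$log2_ratio >= t_amp)
  if (!is.null(chromosome)) {
    chrom <- normalize_chrom(chromosome)
    hits <- filter(hits, .data$chromosome == chrom)
  }
  if (nrow(hits) == 0) {
    out <- tibble(sample = character(0), chromosome = character(0),
                  start = numeric(0), end = numeric(0),
                  max_log2 = numeric(0), n_segments = integer(0))
    return(structure(out, class = unique(c("amplicon_tbl", class(out)))))
  }
  out <- hits %>%
    group_by(.data$sample, .data$chromosome) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(run = cumsum(c(0, pmax(.data$start[-1] -
                                    cummax(.data$end)[-dplyr::n()], 0)) > gap_tol)) %>%
    group_by(.data$sample, .data$chromosome, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              max_log2 = max(.data$log2_ratio), n_segments = dplyr::n(),
              .groups = "drop") %>%
    select(-"run") %>%
    arrange(.data$sample, .data$chromosome, .data$start)
  structure(out, class = unique(c("amplicon_tbl", class(out))))
}

#' Is an amplicon focal?
#'
#' Focal means strictly shorter than half the chromosome arm holding it
#' (strict inequality: an amplicon of exactly half an arm is not focal). Arm
#' membership is by amplicon midpoint; an amplicon spanning the centromere is
#' assigned to the arm holding its larger share.
#'
#' @param amplicons An `amplicon_tbl` tibble (or any tibble with
#'   `chromosome`, `start`, `end`).
#' @param arms An `arm_table` tibble.
#' @return Logical vector, one element per amplicon.
#' @export
is_focal <- function(amplicons, arms) {
  purrr::pmap_lgl(
    list(amplicons$chromosome, amplicons$start, amplicons$end),
    function(chrom, start, end) {
      rows <- arms_of_chromosome(arms, chrom)
      share <- pmax(pmin(rows$end, end) - pmax(rows$start, start), 0)
      host <- if (all(share == 0)) {
        mid <- (start + end) / 2
        which.max(rows$start <= mid & mid < rows$end)
      } else which.max(share)
      (end - start) < 0.5 * (rows$end[host] - rows$start[host])
    }
  )
}

#' Classify gene-level amplification per sample
#'
#' A sample is `encompassing` when some amplicon contains the full gene
#' footprint (first exon start to last exon end), `overlapping` when some
#' amplicon intersects the footprint but none contains it, and `none`
#' otherwise. When several amplicons intersect the footprint, the one with
#' the largest intersection is attached to the call. The focality flag is
#' evaluated on the attached amplicon and is `NA` for class `none`.
#'
#' @param amplicons An `amplicon_tbl` tibble (any chromosome; only the
#'   gene's chromosome is consulted).
#' @param gene A `gene_model` tibble.
#' @param arms An `arm_table` tibble.
#' @param samples Samples to report; defaults to those present in
#'   `amplicons`. Pass the full cohort so that `none` rows are emitted for
#'   samples without amplicons.
#' @return An `amp_call_tbl` tibble: `sample`, `gene`, `overlap_class`,
#'   `focal`, `amplicon_start`, `amplicon_end`, `max_log2`.
#' @export
call_amplification <- function(amplicons, gene, arms, samples = NULL) {
  samples <- samples %||% unique(amplicons$sample)
  fp <- gene_footprint(gene)
  chrom <- gene$chromosome[1]
  on_chrom <- filter(amplicons, .data$chromosome == chrom)
  out <- purrr::map_dfr(samples, function(s) {
    amps <- filter(on_chrom, .data$sample == s)
    inter <- pmin(amps$end, fp["end"]) - pmax(amps$start, fp["start"])
    hit <- which(inter > 0)
    if (length(hit) == 0) {
      return(tibble(sample = s, gene = gene$gene[1], overlap_class = "none",
                    focal = NA, amplicon_start = NA_real_,
                    amplicon_end = NA_real_, max_log2 = NA_real_))
    }
    contains <- amps$start[hit] <= fp["start"] & amps$end[hit] >= fp["end"]
    best <- hit[which.max(inter[hit])]
    cls <- if (any(contains)) "encompassing" else "overlapping"
    tibble(
      sample = s, gene = gene$gene[1], overlap_class = cls,
      focal = is_focal(amps[best, , drop = FALSE], arms),
      amplicon_start = amps$start[best], amplicon_end = amps$end[best],
      max_log2 = amps$max_log2[best]
    )
  })
  structure(out, class = unique(c("amp_call_tbl", class(out))))
}
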