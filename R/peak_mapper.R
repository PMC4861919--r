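# Cross-sample aggregation of amplifications: binned recurrence profile,
# minimal common region, target-gene nomination, and a simplified binomial
# locus-enrichment test against the genome-wide amplification rate.

#' Binned amplification recurrence across samples
#'
#' For each genomic bin, counts the samples with at least one amplicon
#' overlapping the bin. Bins tile each chromosome from 0 to the chromosome
#' end (taken from the arm table).
#'
#' @param amplicons An `amplicon_tbl` tibble for the whole cohort.
#' @param arms An `arm_table` tibble (defines chromosomes and lengths).
#' @param n_samples Cohort size used for the fraction denominator.
#' @param bin_width Bin width in bp, default 1 Mb.
#' @return A `freq_profile` tibble: `chromosome`, `start`, `end`, `count`,
#'   `fraction`.
#' @export
amplification_frequency <- function(amplicons, arms, n_samples,
                                    bin_width = 1e6) {
  check_number(bin_width, "bin_width", lower = 1)
  check_number(n_samples, "n_samples", lower = 1)
  chrom_len <- arms %>%
    group_by(.data$chromosome) %>%
    summarise(len = max(.data$end), .groups = "drop")
  out <- purrr::map_dfr(seq_len(nrow(chrom_len)), function(i) {
    chrom <- chrom_len$chromosome[i]
    starts <- seq(0, chrom_len$len[i] - 1, by = bin_width)
    ends <- pmin(starts + bin_width, chrom_len$len[i])
    amps <- filter(amplicons, .data$chromosome == chrom)
    count <- purrr::map_int(seq_along(starts), function(j) {
      hit <- amps$start < ends[j] & amps$end > starts[j]
      length(unique(amps$sample[hit]))
    })
    tibble(chromosome = chrom, start = starts, end = ends,
           count = count, fraction = count / n_samples)
  })
  structure(out, class = unique(c("freq_profile", class(out))))
}

#' Write a recurrence profile as bedGraph
#'
#' @param freq A `freq_profile` tibble.
#' @param path Output path.
#' @param value Column written as the bedGraph score, `"count"` or
#'   `"fraction"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(freq, path, value = c("count", "fraction")) {
  value <- match.arg(value)
  lines <- sprintf("chr%s\t%d\t%d\t%g", freq$chromosome,
                   as.integer(freq$start), as.integer(freq$end), freq[[value]])
  writeLines(c(sprintf('track type=bedGraph name="amplification_%s"', value),
               lines), path)
  invisible(path)
}

#' Minimal common region of a set of amplifications
#'
#' The intersection of all intervals when it is non-empty; otherwise the
#' leftmost maximal-overlap region (the run of positions covered by the
#' largest number of intervals), flagged with `multiplicity = TRUE`.
#'
#' @param intervals Tibble with `start` and `end` (0-based half-open), all
#'   on one chromosome.
#' @return A list with `start`, `end`, `count` (intervals covering the
#'   region) and `multiplicity` (TRUE when the plain intersection was
#'   empty).
#' @export
minimal_common_region <- function(intervals) {
  if (nrow(intervals) == 0) abort("minimal_common_region needs at least one interval")
  lo <- max(intervals$start); hi <- min(intervals$end)
  if (lo < hi) {
    return(list(start = lo, end = hi, count = nrow(intervals),
                multiplicity = FALSE))
  }
  # sweep line over breakpoints for the maximal-overlap run, leftmost on ties
  ev <- tibble(pos = c(intervals$start, intervals$end),
               delta = rep(c(1L, -1L), each = nrow(intervals))) %>%
    group_by(.data$pos) %>%
    summarise(delta = sum(.data$delta), .groups = "drop") %>%
    arrange(.data$pos) %>%
    mutate(depth = cumsum(.data$delta))
  best <- which.max(ev$depth)
  list(start = ev$pos[best], end = ev$pos[best + 1], count = ev$depth[best],
       multiplicity = TRUE)
}

#' Binomial locus-enrichment test against the genome-wide rate
#'
#' A simplified recurrence test: given `k` amplified samples at a locus out
#' of `n`, the one-sided binomial tail `P(X >= k | n, background_rate)`
#' where the background rate is the genome-wide mean per-bin amplified
#' fraction. q-values are Benjamini-Hochberg across the loci supplied in one
#' call (the test family of the run).
#'
#' @param k Integer vector of amplified-sample counts, one per locus.
#' @param n Cohort size.
#' @param background_rate Genome-wide per-bin amplified fraction, strictly
#'   inside (0, 1).
#' @return Tibble with `k`, `n`, `background_rate`, `p`, `q`.
#' @export
locus_enrichment <- function(k, n, background_rate) {
  check_number(n, "n", lower = 1)
  check_number(background_rate, "background_rate",
               lower = .Machine$double.xmin, upper = 1 - 1e-12)
  if (background_rate <= 0 || background_rate >= 1) {
    abort("background_rate must be strictly between 0 and 1")
  }
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  p <- pbinom(k - 1, n, background_rate, lower.tail = FALSE)
  tibble(k = as.integer(k), n = as.integer(n),
         background_rate = background_rate, p = p, q = bh_fdr(p))
}

#' Genome-wide background amplification rate from a recurrence profile
#'
#' Mean per-bin amplified fraction over the profile; sex chromosomes are
#' excluded by default because their copy-number baseline differs.
#'
#' @param freq A `freq_profile` tibble.
#' @param exclude Chromosomes excluded from the background.
#' @return A single fraction.
#' @export
background_rate <- function(freq, exclude = c("X", "Y")) {
  keep <- filter(freq, !.data$chromosome %in% normalize_chrom(exclude))
  mean(keep$fraction)
}

#' Nominate target genes within a minimal common region
#'
#' Genes whose full footprint lies inside the region, ordered by the share
#' of the region their footprint covers; genes that only partially overlap
#' the region are listed separately.
#'
#' @param mcr A list with `start` and `end` (from
#'   [minimal_common_region()]).
#' @param gene_models List of `gene_model` tibbles on the MCR chromosome.
#' @return Tibble with `gene`, `containment` (`"full"` or `"partial"`) and
#'   `coverage` (fraction of the MCR covered by the gene footprint), fully
#'   contained genes first, coverage-ordered.
#' @export
target_genes <- function(mcr, gene_models) {
  rows <- purrr::map_dfr(gene_models, function(g) {
    fp <- gene_footprint(g)
    inter <- max(0, min(fp["end"], mcr$end) - max(fp["start"], mcr$start))
    tibble(gene = g$gene[1],
           containment = dplyr::case_when(
             inter <= 0 ~ NA_character_,
             fp["start"] >= mcr$start && fp["end"] <= mcr$end ~ "full",
             TRUE ~ "partial"),
           coverage = inter / (mcr$end - mcr$start))
  })
  rows %>%
    filter(!is.na(.data$containment)) %>%
    arrange(dplyr::desc(.data$containment == "full"), dplyr::desc(.data$coverage))
}
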