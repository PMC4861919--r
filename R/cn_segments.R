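# Segmented copy-number profiles: SEG I/O, interval queries, per-exon values.
#
# log2 ratios are copy number relative to the genome-wide average signal, the
# convention of CBS/TCGA level-3 segmented output.

#' Read a SEG file of segmented copy-number profiles
#'
#' Expects the tab-separated CBS/TCGA level-3 dialect with header columns
#' `Sample`, `Chromosome`, `Start`, `End`, `Num_Probes`, `Segment_Mean`
#' (1-based inclusive coordinates on disk). Coordinates are converted to the
#' package-internal 0-based half-open convention and chromosome names are
#' normalized ("chr6" and "6" are the same chromosome). Overlapping segments
#' within one sample and chromosome are rejected.
#'
#' @param path Path to the SEG file.
#' @return A `seg_tbl` tibble with columns `sample`, `chromosome`, `start`,
#'   `end`, `num_markers`, `log2_ratio`, position-sorted within sample and
#'   chromosome.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("SEG file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out) & !is.na(x)) || any(is.na(x))) {
      abort(paste0("non-numeric value in column ", what))
    }
    out
  }
  seg <- tibble(
    sample = raw$Sample,
    chromosome = normalize_chrom(raw$Chromosome),
    start = num(raw$Start, "Start") - 1,   # 1-based inclusive -> 0-based half-open
    end = num(raw$End, "End"),
    num_markers = num(raw$Num_Probes, "Num_Probes"),
    log2_ratio = num(raw$Segment_Mean, "Segment_Mean")
  )
  validate_seg(seg)
}

validate_seg <- function(seg) {
  if (nrow(seg) > 0) {
    if (any(seg$end <= seg$start)) abort("every segment must satisfy end > start")
    if (any(!is.finite(seg$log2_ratio))) abort("log2 ratios must be finite")
    seg <- seg %>%
      arrange(.data$sample, .data$chromosome, .data$start)
    bad <- seg %>%
      group_by(.data$sample, .data$chromosome) %>%
      summarise(overlap = dplyr::n() > 1 &&
                  any(.data$start[-1] < .data$end[-dplyr::n()]),
                .groups = "drop") %>%
      filter(.data$overlap)
    if (nrow(bad) > 0) {
      abort(paste0("overlapping segments within sample ",
                   paste(unique(bad$sample), collapse = ", ")))
    }
  }
  structure(as_tibble(seg), class = unique(c("seg_tbl", class(as_tibble(seg)))))
}

#' Write segments in the SEG dialect
#'
#' @param seg A `seg_tbl` tibble (internal 0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  out <- tibble(
    Sample = seg$sample, Chromosome = seg$chromosome,
    Start = seg$start + 1, End = seg$end,
    Num_Probes = seg$num_markers, Segment_Mean = seg$log2_ratio
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Segments overlapping a genomic interval
#'
#' Strict half-open overlap: a segment touching the query only at its
#' half-open end does not count.
#'
#' @param seg A `seg_tbl` tibble.
#' @param sample_id Sample to query.
#' @param chromosome Chromosome of the query interval.
#' @param start,end Query interval, 0-based half-open.
#' @return The overlapping segments in position order (possibly zero rows).
#' @export
segments_overlapping <- function(seg, sample_id, chromosome, start, end) {
  chrom <- normalize_chrom(chromosome)
  qstart <- start
  qend <- end
  seg %>%
    filter(.data$sample == sample_id, .data$chromosome == chrom,
           .data$start < qend, .data$end > qstart) %>%
    arrange(.data$start)
}

#' Per-exon copy-number values for a gene
#'
#' Assigns each exon the intersection-length-weighted mean of the log2 ratios
#' of the segments overlapping it (weights renormalized over the covered
#' part, so a copy-number breakpoint inside an exon yields the within-exon
#' mixture mean). Exons with no overlapping segment are `NA` — coverage gaps
#' are legal because germline-CNV regions are assumed removed upstream.
#'
#' @param seg A `seg_tbl` tibble.
#' @param gene A `gene_model` tibble.
#' @param samples Samples to evaluate; defaults to every sample in `seg`.
#' @return An `exon_cn` tibble with columns `sample`, `gene`, `exon`, `log2`.
#' @export
exon_copy_number <- function(seg, gene, samples = NULL) {
  samples <- samples %||% unique(seg$sample)
  chrom <- gene$chromosome[1]
  gene_sym <- gene$gene[1]
  exon_idx <- gene$exon
  on_chrom <- filter(seg, .data$chromosome == chrom)
  res <- purrr::map_dfr(samples, function(s) {
    segs <- filter(on_chrom, .data$sample == s)
    log2 <- purrr::map_dbl(seq_len(nrow(gene)), function(i) {
      es <- gene$start[i]; ee <- gene$end[i]
      hit <- filter(segs, .data$start < ee, .data$end > es)
      if (nrow(hit) == 0) return(NA_real_)
      w <- pmin(hit$end, ee) - pmax(hit$start, es)
      sum(w * hit$log2_ratio) / sum(w)
    })
    tibble(sample = s, gene = gene_sym, exon = exon_idx, log2 = log2)
  })
  structure(res, class = unique(c("exon_cn", class(res))))
}
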