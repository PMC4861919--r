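# Gene/exon models and chromosome-arm tables.
#
# All genomic intervals are held internally as 0-based half-open [start, end).
# On-disk dialects are converted on read: the exon-model TSV and SEG files are
# 1-based inclusive, cytoband tables are already 0-based half-open.

#' Load a single-transcript exon model from a TSV file
#'
#' Reads an exon-annotation table (columns `gene`, `chromosome`, `strand`,
#' `exon_number`, `start`, `end`; 1-based inclusive coordinates on disk) and
#' returns the validated exon model of one gene. Exon indices follow
#' transcript order: for a minus-strand gene exon 1 is the genomically last
#' exon. The 5'-to-3' exon numbering is what downstream block statistics
#' (e.g. the AF1/DBD block vs the hormone-binding-domain block of an estrogen
#' receptor gene) are defined on.
#'
#' @param path Path to the exon-model TSV.
#' @param gene_symbol Gene symbol to extract (one canonical transcript per
#'   gene is assumed).
#' @return A `gene_model` tibble with columns `gene`, `chromosome`, `strand`,
#'   `exon`, `start`, `end` (0-based half-open), one row per exon in
#'   transcript order.
#' @examples
#' path <- system.file("extdata", "toy_gene_model.tsv", package = "truncamp")
#' load_gene_model(path, "ESR1")
#' @export
load_gene_model <- function(path, gene_symbol) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene", "chromosome", "strand", "exon_number", "start", "end")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("exon model is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rows <- dplyr::filter(raw, .data$gene == gene_symbol)
  if (nrow(rows) == 0) abort(paste0("gene not found: ", gene_symbol))
  strand <- unique(rows$strand)
  if (length(strand) != 1 || !strand %in% c("+", "-")) {
    abort("strand must be a single value, '+' or '-'")
  }
  chrom <- unique(normalize_chrom(rows$chromosome))
  if (length(chrom) != 1) abort("all exons of a gene must share one chromosome")

  rows <- mutate(rows, start = .data$start - 1)  # 1-based inclusive -> 0-based half-open
  rows <- rows[order(if (strand == "+") rows$start else -rows$start), ]
  rows$assigned <- seq_len(nrow(rows))
  if (any(rows$end <= rows$start)) abort("every exon must satisfy end > start")
  if (any(rows$assigned != rows$exon_number)) {
    abort(paste0("exon numbering of ", gene_symbol,
                 " is not contiguous 1..n in transcript order"))
  }
  by_pos <- arrange(rows, .data$start)
  if (any(by_pos$start[-1] < by_pos$end[-nrow(by_pos)])) {
    abort("exons overlap; the model must contain disjoint exons")
  }
  new_gene_model(tibble(
    gene = gene_symbol, chromosome = chrom, strand = strand,
    exon = rows$assigned, start = rows$start, end = rows$end
  ))
}

new_gene_model <- function(x) {
  structure(as_tibble(x), class = c("gene_model", class(as_tibble(x))))
}

#' Write an exon model back to the TSV dialect
#'
#' Inverse of [load_gene_model()]; coordinates are converted back to 1-based
#' inclusive on disk so that a write/read round trip is exact.
#'
#' @param gene A `gene_model` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(gene, path) {
  g <- as.data.frame(gene)
  out <- tibble(
    gene = g$gene, chromosome = g$chromosome, strand = g$strand,
    exon_number = g$exon, start = g$start + 1, end = g$end
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Genomic footprint of a gene model
#'
#' @param gene A `gene_model` tibble.
#' @return Named numeric vector `c(start, end)`, 0-based half-open, spanning
#'   the first to the last exon in genomic coordinates.
#' @export
gene_footprint <- function(gene) {
  c(start = min(gene$start), end = max(gene$end))
}

#' Partition a gene's exons into 5' and 3' blocks
#'
#' The split is given in transcript order: `split_after = 4` on an 8-exon
#' gene yields the 5' block \{1..4\} (transactivation/DNA-binding domains in
#' the ESR1 convention) and the 3' block \{5..8\} (the hormone-binding
#' domain).
#'
#' @param gene A `gene_model` tibble (or a single integer exon count).
#' @param split_after Last exon index of the 5' block; must leave both
#'   blocks non-empty.
#' @return An `exon_blocks` list with `five_prime`, `three_prime`,
#'   `split_after` and `n`.
#' @export
exon_blocks <- function(gene, split_after) {
  n <- if (is.numeric(gene) && length(gene) == 1) as.integer(gene) else nrow(gene)
  check_number(split_after, "split_after", 1, n - 1)
  structure(
    list(five_prime = seq_len(split_after),
         three_prime = seq.int(split_after + 1, n),
         split_after = as.integer(split_after), n = as.integer(n)),
    class = "exon_blocks"
  )
}

#' Load a chromosome-arm table from a cytoband file
#'
#' Accepts the UCSC `cytoBand.txt` column layout (chrom, chromStart,
#' chromEnd, name, gieStain; 0-based half-open, no header). The p and q arm
#' of each chromosome are the unions of its p- and q-bands.
#'
#' @param path Path to the cytoband TSV.
#' @param acrocentric Allow chromosomes carrying only q-bands (their p arm is
#'   absent rather than an error).
#' @return An `arm_table` tibble with columns `chromosome`, `arm`, `start`,
#'   `end`.
#' @examples
#' path <- system.file("extdata", "toy_cytoband.tsv", package = "truncamp")
#' load_arm_table(path)
#' @export
load_arm_table <- function(path, acrocentric = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  bands <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "name", "stain"),
    show_col_types = FALSE, progress = FALSE
  )
  arm_class <- substr(bands$name, 1, 1)
  if (any(!arm_class %in% c("p", "q"))) {
    abort(paste0("unparseable band name(s): ",
                 paste(unique(bands$name[!arm_class %in% c("p", "q")]),
                       collapse = ", ")))
  }
  arms <- bands %>%
    mutate(chromosome = normalize_chrom(.data$chrom), arm = arm_class) %>%
    group_by(.data$chromosome, .data$arm) %>%
    summarise(start = min(start), end = max(end), .groups = "drop") %>%
    arrange(.data$chromosome, .data$arm)
  bad <- arms %>%
    group_by(.data$chromosome) %>%
    summarise(n_arms = dplyr::n_distinct(.data$arm),
              has_q = any(.data$arm == "q"), .groups = "drop") %>%
    filter(.data$n_arms < 2)
  if (nrow(bad) > 0 && !(acrocentric && all(bad$has_q))) {
    abort(paste0("chromosome(s) with a single arm class: ",
                 paste(bad$chromosome, collapse = ", "),
                 " (set acrocentric = TRUE to allow q-only chromosomes)"))
  }
  overlap <- arms %>%
    group_by(.data$chromosome) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(bad = dplyr::n() > 1 && any(lead(start)[-dplyr::n()] < end[-dplyr::n()]),
              .groups = "drop")
  if (any(overlap$bad)) abort("p and q arms overlap; cytoband table is inconsistent")
  new_arm_table(arms)
}

new_arm_table <- function(x) {
  structure(as_tibble(x), class = c("arm_table", class(as_tibble(x))))
}

# arm rows of one chromosome, or error when absent
arms_of_chromosome <- function(arms, chromosome) {
  target <- normalize_chrom(chromosome)
  rows <- dplyr::filter(arms, .data$chromosome == target)
  if (nrow(rows) == 0) {
    abort(paste0("chromosome ", chromosome, " is missing from the arm table"))
  }
  rows
}
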