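# Shared in-code fixtures: all built programmatically, no data files needed
# beyond the two bundled TSVs under inst/extdata.

toy_gene <- truncamp::toy_gene_model()
toy_blocks <- truncamp::exon_blocks(toy_gene, 4)
toy_arms <- truncamp::arms_from_genome(truncamp::toy_genome())

# seg_tbl from bare vectors (internal coordinates)
make_seg <- function(sample, chromosome, start, end, log2_ratio,
                     num_markers = 100) {
  truncamp:::validate_seg(tibble::tibble(
    sample = sample, chromosome = chromosome, start = start, end = end,
    num_markers = num_markers, log2_ratio = log2_ratio
  ))
}

# exon_cn tibble from one per-exon log2 vector
make_exon_cn <- function(v, sample = "S1", gene = "ESR1") {
  structure(
    tibble::tibble(sample = sample, gene = gene,
                   exon = seq_along(v), log2 = v),
    class = c("exon_cn", class(tibble::tibble()))
  )
}

# floored expression table from a samples-by-exons matrix
make_expr <- function(mat, samples = paste0("S", seq_len(nrow(mat))),
                      floored = TRUE) {
  colnames(mat) <- paste0("exon_", seq_len(ncol(mat)))
  truncamp:::new_expr_tbl(
    dplyr::bind_cols(tibble::tibble(sample = samples),
                     tibble::as_tibble(mat)),
    floored = floored
  )
}

# write a SEG file with on-disk (1-based inclusive) coordinates
write_seg_text <- function(rows, path) {
  header <- "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean"
  writeLines(c(header, rows), path)
  path
}

extdata <- function(name) system.file("extdata", name, package = "truncamp")
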