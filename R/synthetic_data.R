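# Synthetic cohorts of segmented copy-number profiles and matched
# exon-expression matrices with ground-truth labels.
#
# The generator emulates the structure the callers assume: diploid background
# segments with Gaussian log2 noise, broad and focal amplifications of a
# target gene, truncating amplifications whose 3' boundary falls in an
# inter-exon gap (retaining a 5' exon prefix), heterozygous deletions of the
# 3' exon block, and exon-RPKM matrices in which lost exons sit a
# configurable fold below retained exons, with log-normal noise and
# occasional exact zeros.

#' Bundled toy exon model (8-exon surrogate estrogen-receptor gene)
#'
#' A plus-strand 8-exon gene on a 171 Mb chromosome "6" with a 61 Mb p arm,
#' mirroring the exon-count and arm geometry relevant to ESR1-style
#' truncation analysis. Coordinates are fixture values.
#'
#' @return A `gene_model` tibble.
#' @export
toy_gene_model <- function() {
  new_gene_model(tibble(
    gene = "ESR1", chromosome = "6", strand = "+",
    exon = 1:8,
    start = c(152011000, 152101000, 152163000, 152201000,
              152265000, 152311000, 152341000, 152411000),
    end = c(152012000, 152101200, 152163300, 152201350,
            152265140, 152311140, 152341190, 152415000)
  ))
}

#' Bundled toy genome specification
#'
#' Two autosomes with lengths and centromere positions; chromosome "6"
#' hosts the toy gene.
#'
#' @return Tibble with `chromosome`, `length`, `centromere`.
#' @export
toy_genome <- function() {
  tibble(chromosome = c("2", "6"),
         length = c(243e6, 171e6),
         centromere = c(93e6, 61e6))
}

#' Arm table derived from a genome specification
#'
#' @param genome Tibble with `chromosome`, `length`, `centromere`.
#' @return An `arm_table` tibble.
#' @export
arms_from_genome <- function(genome) {
  new_arm_table(bind_rows(
    tibble(chromosome = genome$chromosome, arm = "p",
           start = 0, end = genome$centromere),
    tibble(chromosome = genome$chromosome, arm = "q",
           start = genome$centromere, end = genome$length)
  ) %>% arrange(.data$chromosome, .data$arm))
}

#' Simulation configuration
#'
#' Defaults emulate the cohort structure reported for endometrial
#' carcinoma: out of 539 tumors, 16.3% carry an amplification of the target
#' gene (52/539 broad, 29/539 focal full-length, 7/539 truncating; 6.7%
#' focal in total) and 1/539 carries a 3'-block heterozygous deletion.
#'
#' @param n_samples Cohort size.
#' @param gene A `gene_model` tibble (default [toy_gene_model()]).
#' @param genome Genome specification tibble (default [toy_genome()]).
#' @param prevalence Named fractions for `broad_amp`, `focal_full_amp`,
#'   `truncating_amp`, `hbd_deletion`; must sum to at most 1.
#' @param counts Optional named integer vector with the same names; when
#'   given, exactly these event counts are implanted (deterministic cohort
#'   composition) instead of sampling from `prevalence`.
#' @param amp_log2 Range of implanted amplification levels (log2 ratio).
#' @param del_log2 Implanted deletion level (log2 ratio), default -1
#'   (heterozygous loss in a pure diploid sample).
#' @param noise_sd Gaussian sd of per-segment log2 noise.
#' @param seg_mean_len Mean background segment length (bp; exponential
#'   lengths truncated at arm boundaries).
#' @param split_probs Named probabilities over the truncation split `k`
#'   (exons retained); default mass on k = 3 and k = 4.
#' @param split_after 5'/3' block boundary of the gene (deletion geometry
#'   and expression blocks), default 4.
#' @param focal_len_range Focal amplicon length range (bp).
#' @param broad_frac_range Broad amplicon length as a fraction of the host
#'   arm (both ends above 0.5 so broad events are never focal).
#' @param flank_range Range of the amplicon extension beyond the gene (bp).
#' @param expr_baseline Baseline exon RPKM (equal across exons).
#' @param trunc_expr_fold Realized 5':3' expression fold implanted in
#'   truncated samples.
#' @param hbd_expr_fold Realized 5':3' fold in deletion samples (default 2,
#'   proportional to one lost copy).
#' @param expr_noise_sd Log-normal expression noise sd (log2 scale).
#' @param zero_rate Probability that an expression value is an exact zero
#'   pre-floor.
#' @param seed RNG seed; all generator randomness derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 539,
                       gene = toy_gene_model(),
                       genome = toy_genome(),
                       prevalence = c(broad_amp = 52 / 539,
                                      focal_full_amp = 29 / 539,
                                      truncating_amp = 7 / 539,
                                      hbd_deletion = 1 / 539),
                       counts = NULL,
                       amp_log2 = c(0.8, 2.0),
                       del_log2 = -1,
                       noise_sd = 0.1,
                       seg_mean_len = 2e7,
                       split_probs = c("3" = 0.5, "4" = 0.5),
                       split_after = 4,
                       focal_len_range = c(1e6, 2e7),
                       broad_frac_range = c(0.55, 0.95),
                       flank_range = c(5e5, 8e6),
                       expr_baseline = 20,
                       trunc_expr_fold = 2.1,
                       hbd_expr_fold = 2,
                       expr_noise_sd = 0.25,
                       zero_rate = 0.01,
                       seed = 1) {
  types <- c("broad_amp", "focal_full_amp", "truncating_amp", "hbd_deletion")
  if (!is.null(counts)) {
    if (!all(names(counts) %in% types)) abort("unknown event type in counts")
    if (sum(counts) > n_samples) abort("event counts exceed the cohort size")
  } else {
    if (!all(names(prevalence) %in% types)) abort("unknown event type in prevalence")
    if (any(prevalence < 0) || sum(prevalence) > 1) {
      abort("prevalences must be non-negative and sum to at most 1")
    }
  }
  if (noise_sd < 0 || expr_noise_sd < 0) abort("noise sds must be non-negative")
  if (trunc_expr_fold <= 0 || hbd_expr_fold <= 0) abort("expression folds must be positive")
  if (zero_rate < 0 || zero_rate > 1) abort("zero_rate must lie in [0, 1]")
  if (!gene$chromosome[1] %in% genome$chromosome) {
    abort("the gene's chromosome is missing from the genome specification")
  }
  check_number(split_after, "split_after", 1, nrow(gene) - 1)
  ks <- as.integer(names(split_probs))
  if (any(is.na(ks)) || any(ks < 1 | ks > nrow(gene) - 1)) {
    abort("split_probs names must be valid split indices")
  }
  structure(list(
    n_samples = as.integer(n_samples), gene = gene, genome = genome,
    arms = arms_from_genome(genome),
    prevalence = prevalence, counts = counts,
    amp_log2 = amp_log2, del_log2 = del_log2, noise_sd = noise_sd,
    seg_mean_len = seg_mean_len, split_probs = split_probs,
    split_after = as.integer(split_after),
    focal_len_range = focal_len_range, broad_frac_range = broad_frac_range,
    flank_range = flank_range,
    expr_baseline = expr_baseline, trunc_expr_fold = trunc_expr_fold,
    hbd_expr_fold = hbd_expr_fold, expr_noise_sd = expr_noise_sd,
    zero_rate = zero_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# exponential-length background segment starts for one arm (vectorized)
segment_arm <- function(a, b, mean_len) {
  need <- ceiling(3 * (b - a) / mean_len) + 8
  lens <- pmax(1e5, rexp(need, 1 / mean_len))
  while (sum(lens) < (b - a)) lens <- c(lens, pmax(1e5, rexp(need, 1 / mean_len)))
  starts <- floor(a + c(0, cumsum(lens)))
  starts <- starts[starts < b]
  list(start = starts, end = c(starts[-1], b))
}

# replace the part of a background tiling covered by [s, e) with one segment
carve_event <- function(bg, s, e, level) {
  li <- bg$start < s
  ri <- bg$end > e
  out <- list(
    start = c(bg$start[li], s, pmax(bg$start[ri], e)),
    end = c(pmin(bg$end[li], s), e, bg$end[ri]),
    level = c(bg$level[li], level, bg$level[ri])
  )
  keep <- out$end > out$start
  ord <- order(out$start[keep])
  list(start = out$start[keep][ord], end = out$end[keep][ord],
       level = out$level[keep][ord])
}

# transcript-order inter-exon gap after exon k, in genomic coordinates
inter_exon_gap <- function(gene, k) {
  a <- gene[gene$exon == k, ]
  b <- gene[gene$exon == k + 1, ]
  if (gene$strand[1] == "+") c(a$end, b$start) else c(b$end, a$start)
}

#' Simulate cohort ground truth (event assignment and geometry)
#'
#' Draws each sample's event type (from `prevalence`, or exactly the
#' configured `counts`), the implanted amplification level, the truncation
#' split `k` with its breakpoint placed uniformly inside the inter-exon gap
#' after exon `k`, and the event interval on the gene's host arm. Focal
#' amplicons are shorter than half the host arm, broad ones longer.
#' Deterministic given the config seed.
#'
#' @param config A `sim_config` list.
#' @return A truth tibble: `sample`, `event_type`, `amp_start`, `amp_end`,
#'   `k`, `amp_log2`, `expr_fold`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  types <- c("broad_amp", "focal_full_amp", "truncating_amp", "hbd_deletion")
  events <- if (!is.null(config$counts)) {
    pool <- c(rep(names(config$counts), config$counts),
              rep("none", n - sum(config$counts)))
    sample(pool, n)
  } else {
    prev <- config$prevalence[types]
    prev[is.na(prev)] <- 0
    sample(c(types, "none"), n, replace = TRUE,
           prob = c(prev, 1 - sum(prev)))
  }
  gene <- config$gene
  fp <- gene_footprint(gene)
  host <- arms_of_chromosome(config$arms, gene$chromosome[1])
  mid <- (fp["start"] + fp["end"]) / 2
  host <- host[host$start <= mid & mid < host$end, ]
  arm_len <- host$end - host$start
  plus <- gene$strand[1] == "+"

  place_containing <- function(len) {
    lo <- max(host$start, fp["end"] - len)
    hi <- max(lo, min(fp["start"], host$end - len))
    s <- floor(runif(1, lo, hi))
    c(s, floor(s + len))
  }
  rows <- purrr::map2(ids, events, function(id, ev) {
    s <- e <- NA_real_; k <- NA_integer_; a <- NA_real_; fold <- NA_real_
    if (ev %in% c("broad_amp", "focal_full_amp")) {
      len <- if (ev == "broad_amp") {
        runif(1, config$broad_frac_range[1], config$broad_frac_range[2]) * arm_len
      } else {
        max(runif(1, config$focal_len_range[1], config$focal_len_range[2]),
            (fp["end"] - fp["start"]) + 2e5)
      }
      se <- place_containing(len); s <- se[1]; e <- se[2]
      a <- runif(1, config$amp_log2[1], config$amp_log2[2])
    } else if (ev == "truncating_amp") {
      kk <- names(config$split_probs)
      k <- as.integer(kk[sample.int(length(kk), 1, prob = config$split_probs)])
      gap <- inter_exon_gap(gene, k)
      bp <- floor(runif(1, gap[1] + 1, gap[2] - 1))
      ext <- runif(1, config$flank_range[1], config$flank_range[2])
      if (plus) { s <- floor(max(host$start, fp["start"] - ext)); e <- bp }
      else { s <- bp; e <- floor(min(host$end, fp["end"] + ext)) }
      a <- runif(1, config$amp_log2[1], config$amp_log2[2])
      fold <- config$trunc_expr_fold
    } else if (ev == "hbd_deletion") {
      k <- config$split_after
      gap <- inter_exon_gap(gene, k)
      bp <- floor(runif(1, gap[1] + 1, gap[2] - 1))
      ext <- runif(1, config$flank_range[1], config$flank_range[2])
      if (plus) { s <- bp; e <- floor(min(host$end, fp["end"] + ext)) }
      else { s <- floor(max(host$start, fp["start"] - ext)); e <- bp }
      fold <- config$hbd_expr_fold
    }
    list(sample = id, event_type = ev, amp_start = s, amp_end = e,
         k = k, amp_log2 = a, expr_fold = fold)
  })
  tibble(
    sample = ids,
    event_type = vapply(rows, `[[`, character(1), "event_type"),
    amp_start = vapply(rows, `[[`, numeric(1), "amp_start"),
    amp_end = vapply(rows, `[[`, numeric(1), "amp_end"),
    k = vapply(rows, `[[`, integer(1), "k"),
    amp_log2 = vapply(rows, `[[`, numeric(1), "amp_log2"),
    expr_fold = vapply(rows, `[[`, numeric(1), "expr_fold")
  )
}

#' Simulate a cohort of segmented copy-number profiles with known truth
#'
#' Calls [simulate_truth()] and then renders each sample as segmented
#' copy-number profiles: diploid background segments (log2 ~
#' Normal(0, `noise_sd`), exponential lengths truncated at arm boundaries)
#' on every chromosome of the genome specification, with the sample's
#' event, if any, carved in on the gene's chromosome (amplifications at the
#' implanted level, deletions at `del_log2`, each with the same segment
#' noise). Deterministic given the config seed.
#'
#' @param config A `sim_config` list.
#' @param truth Optional truth tibble from [simulate_truth()]; generated
#'   from the config when omitted.
#' @return A list with `segments` (a `seg_tbl`) and `truth`.
#' @export
simulate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth %||% simulate_truth(config)
  if (nrow(truth) == 0) {
    empty <- tibble(sample = character(0), chromosome = character(0),
                    start = numeric(0), end = numeric(0),
                    num_markers = numeric(0), log2_ratio = numeric(0))
    return(list(segments = validate_seg(empty), truth = truth))
  }
  set.seed(config$seed + 1000003L)
  gene_chrom <- config$gene$chromosome[1]
  n_chrom <- nrow(config$genome)
  arm_list <- lapply(config$genome$chromosome,
                     function(ch) arms_of_chromosome(config$arms, ch))
  acc <- vector("list", nrow(truth) * n_chrom)
  for (i in seq_len(nrow(truth))) {
    ev <- truth$event_type[i]
    for (ci in seq_len(n_chrom)) {
      chrom <- config$genome$chromosome[ci]
      arms <- arm_list[[ci]]
      parts <- lapply(seq_len(nrow(arms)), function(ai) {
        segment_arm(arms$start[ai], arms$end[ai], config$seg_mean_len)
      })
      bg <- list(start = unlist(lapply(parts, `[[`, "start")),
                 end = unlist(lapply(parts, `[[`, "end")))
      bg$level <- rnorm(length(bg$start), 0, config$noise_sd)
      if (ev != "none" && chrom == gene_chrom) {
        level <- if (ev == "hbd_deletion") config$del_log2 else truth$amp_log2[i]
        bg <- carve_event(bg, truth$amp_start[i], truth$amp_end[i],
                          level + rnorm(1, 0, config$noise_sd))
      }
      acc[[(i - 1) * n_chrom + ci]] <- list(
        sample = rep(truth$sample[i], length(bg$start)),
        chromosome = rep(chrom, length(bg$start)),
        start = bg$start, end = bg$end, level = bg$level
      )
    }
  }
  seg <- tibble(
    sample = unlist(lapply(acc, `[[`, "sample")),
    chromosome = unlist(lapply(acc, `[[`, "chromosome")),
    start = unlist(lapply(acc, `[[`, "start")),
    end = unlist(lapply(acc, `[[`, "end"))
  )
  seg$num_markers <- pmax(2, round((seg$end - seg$start) / 5000))
  seg$log2_ratio <- unlist(lapply(acc, `[[`, "level"))
  list(segments = validate_seg(seg), truth = truth)
}

#' Simulate an exon-expression matrix matched to a cohort truth table
#'
#' Each sample starts from the equal per-exon baseline; exons covered by an
#' implanted amplification are scaled by the copy fold `2^amp_log2`
#' (proportional copy-to-expression coupling); in truncating and deletion
#' samples the 3'-lost exons are set so that the realized 5':3' expression
#' ratio equals the implanted `expr_fold`. Exact zeros are injected at
#' `zero_rate`, then multiplicative log-normal noise is applied. Values are
#' pre-floor RPKM; pass the result through [floor_rpkm()] before computing
#' ratios.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param config The same `sim_config`.
#' @return A list with `expr` (an unfloored `expr_tbl`) and `labels`
#'   (tibble `sample`, `group` in truncated/control/other; controls are the
#'   focal full-length-amplified samples).
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 500009L)
  n_ex <- nrow(config$gene)
  vals <- purrr::pmap(
    list(truth$event_type, truth$k, truth$amp_log2, truth$expr_fold),
    function(ev, k, a, fold) {
      v <- rep(config$expr_baseline, n_ex)
      if (ev %in% c("broad_amp", "focal_full_amp")) v <- v * 2^a
      if (ev == "truncating_amp") {
        v[seq_len(k)] <- v[seq_len(k)] * 2^a
        v[seq.int(k + 1, n_ex)] <- config$expr_baseline * 2^a / fold
      }
      if (ev == "hbd_deletion") {
        v[seq.int(k + 1, n_ex)] <- config$expr_baseline / fold
      }
      v[runif(n_ex) < config$zero_rate] <- 0
      v * 2^rnorm(n_ex, 0, config$expr_noise_sd)
    }
  )
  mat <- do.call(rbind, vals)
  colnames(mat) <- paste0("exon_", seq_len(n_ex))
  expr <- new_expr_tbl(dplyr::bind_cols(tibble(sample = truth$sample),
                                        as_tibble(mat)), floored = FALSE)
  labels <- tibble(
    sample = truth$sample,
    group = dplyr::case_when(
      truth$event_type %in% c("truncating_amp", "hbd_deletion") ~ "truncated",
      truth$event_type == "focal_full_amp" ~ "control",
      TRUE ~ "other"
    )
  )
  list(expr = expr, labels = labels)
}

#' Write a simulated cohort to disk in the pipeline's input dialects
#'
#' Emits `segments.seg` (SEG dialect), `expression.tsv`, `labels.tsv` and
#' `truth.tsv`, round-trip readable by [read_seg()] and
#' [read_expression_matrix()].
#'
#' @param cohort List from [simulate_cohort()].
#' @param expression List from [simulate_expression()], or `NULL` to omit
#'   the expression files.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(cohort, expression = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!setequal(unique(cohort$segments$sample), cohort$truth$sample)) {
    abort("segment samples and truth samples disagree")
  }
  paths <- c(
    segments = file.path(dir, "segments.seg"),
    truth = file.path(dir, "truth.tsv")
  )
  write_seg(cohort$segments, paths["segments"])
  readr::write_tsv(cohort$truth, paths["truth"], progress = FALSE)
  if (!is.null(expression)) {
    if (!setequal(expression$expr$sample, cohort$truth$sample)) {
      abort("expression samples and truth samples disagree")
    }
    paths <- c(paths,
               expression = file.path(dir, "expression.tsv"),
               labels = file.path(dir, "labels.tsv"))
    readr::write_tsv(expression$expr, paths["expression"], progress = FALSE)
    readr::write_tsv(expression$labels, paths["labels"], progress = FALSE)
  }
  invisible(paths)
}
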