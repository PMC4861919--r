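# independent oracle for the per-profile decision rules
oracle_classify <- function(v, blocks, t_amp, t_del, delta_min) {
  n <- length(v)
  best_k <- NA_integer_; best_diff <- -Inf
  for (k in 1:(n - 1)) {
    m5 <- mean(v[1:k]); m3 <- mean(v[(k + 1):n])
    if (m5 >= t_amp && m3 < t_amp && (m5 - m3) >= delta_min &&
        (m5 - m3) > best_diff + 1e-12) {
      best_k <- k; best_diff <- m5 - m3
    }
  }
  if (!is.na(best_k)) return(list(event = "truncating_amp", k = best_k))
  if (all(v >= t_amp)) return(list(event = "full_length_amp", k = NA))
  if (!any(v >= t_amp) && mean(v[blocks$three_prime]) <= t_del &&
      mean(v[blocks$five_prime]) > t_del) {
    return(list(event = "hbd_deletion", k = blocks$split_after))
  }
  list(event = "none", k = NA)
}

test_that("decision rules classify the canonical profiles", {
  trunc <- call_truncation(make_exon_cn(c(1.5, 1.5, 1.5, 1.5, 0, 0, 0, 0)),
                           toy_blocks)
  expect_equal(trunc$event_type, "truncating_amp")
  expect_equal(trunc$k, 4L)
  expect_equal(trunc$retained_exons, "1-4")
  expect_equal(trunc$lost_exons, "5-8")

  full <- call_truncation(make_exon_cn(rep(1.5, 8)), toy_blocks)
  expect_equal(full$event_type, "full_length_amp")
  expect_equal(full$lost_exons, "")

  del <- call_truncation(make_exon_cn(c(0, 0, 0, 0, -1, -1, -1, -1)),
                         toy_blocks)
  expect_equal(del$event_type, "hbd_deletion")
  expect_equal(del$lost_exons, "5-8")

  quiet <- call_truncation(make_exon_cn(rep(0, 8)), toy_blocks)
  expect_equal(quiet$event_type, "none")
})

test_that("degenerate exon vectors are rejected", {
  expect_error(call_truncation(make_exon_cn(rep(NA_real_, 8)), toy_blocks),
               "no coverage")
  expect_error(call_truncation(make_exon_cn(c(1, NA, 0, 0, 0, 0, 0, 0)),
                               toy_blocks), "missing")
  expect_error(call_truncation(make_exon_cn(1.5),
                               exon_blocks(2, 1)), "at least 2")
})

test_that("the split maximizes the block difference and matches an oracle", {
  set.seed(31)
  for (rep in 1:50) {
    v <- round(rnorm(8, 0.3, 0.9), 2)   # rounding creates occasional ties
    got <- call_truncation(make_exon_cn(v), toy_blocks)
    want <- oracle_classify(v, toy_blocks, 0.3, -0.3, 0.5)
    expect_equal(got$event_type, want$event)
    if (want$event == "truncating_amp") expect_equal(got$k, want$k)
  }
})

test_that("truncation calls are affine-consistent and delta_min-monotone", {
  set.seed(37)
  for (rep in 1:20) {
    v <- rnorm(8, 0.5, 0.8)
    shift <- runif(1, -1, 1)
    base <- call_truncation(make_exon_cn(v), toy_blocks,
                            t_amp = 0.3, t_del = -0.3, delta_min = 0.5)
    moved <- call_truncation(make_exon_cn(v + shift), toy_blocks,
                             t_amp = 0.3 + shift, t_del = -0.3 + shift,
                             delta_min = 0.5)
    expect_equal(moved$event_type, base$event_type)
    expect_equal(moved$k, base$k)

    strict <- call_truncation(make_exon_cn(v), toy_blocks, delta_min = 1.0)
    if (base$event_type != "truncating_amp") {
      expect_false(strict$event_type == "truncating_amp")
    }
  }
})

test_that("3'-retaining mirror patterns are flagged, not called", {
  got <- call_truncation(make_exon_cn(c(0, 0, 0, 0, 1.5, 1.5, 1.5, 1.5)),
                         toy_blocks)
  expect_equal(got$event_type, "none")
  expect_equal(got$diagnostic, "three_prime_retained")

  stepped <- call_truncation(make_exon_cn(c(2.5, 2.5, 2.5, 2.5, 1, 1, 1, 1)),
                             toy_blocks)
  expect_equal(stepped$event_type, "full_length_amp")
  expect_equal(stepped$diagnostic, "internal_step")
})

test_that("breakpoint intervals localize the truncation boundary", {
  fp <- gene_footprint(toy_gene)
  e4_end <- toy_gene$end[toy_gene$exon == 4]
  e5_start <- toy_gene$start[toy_gene$exon == 5]
  b <- e4_end + 12345   # one segment boundary strictly inside the gap

  seg <- make_seg("S1", "6", c(fp["start"] - 2e6, b), c(b, 170e6), c(1.5, 0))
  calls <- call_truncation(exon_copy_number(seg, toy_gene), toy_blocks)
  located <- breakpoint_interval(seg, toy_gene, calls)
  expect_equal(located$breakpoint_start, b)
  expect_equal(located$breakpoint_end, b)

  # no boundary inside the gap: the full inter-exon interval is returned
  wide <- make_seg("S1", "6", c(0, e5_start + 50),
                   c(e5_start + 50, 170e6), c(1.5, 0))
  calls2 <- call_truncation(exon_copy_number(wide, toy_gene), toy_blocks)
  located2 <- breakpoint_interval(wide, toy_gene, calls2)
  expect_equal(located2$breakpoint_start, e4_end)
  expect_equal(located2$breakpoint_end, e5_start)

  expect_error(
    breakpoint_interval(seg, toy_gene,
                        dplyr::mutate(calls, k = NA_integer_)),
    "split index"
  )
})

test_that("minus-strand breakpoints are bounded by transcript-order exons", {
  # mirror the toy gene onto the minus strand of a 171 Mb chromosome
  minus <- truncamp:::new_gene_model(tibble::tibble(
    gene = "G", chromosome = "6", strand = "-",
    exon = 1:8, start = 171e6 - toy_gene$end, end = 171e6 - toy_gene$start
  ))
  # genomic gap between transcript exons 4 and 5 (exon 5 lies genomically left)
  gap_lo <- minus$end[minus$exon == 5]
  gap_hi <- minus$start[minus$exon == 4]
  b <- floor((gap_lo + gap_hi) / 2)
  # 5'-retaining amplification: high copy from the breakpoint rightwards
  seg <- make_seg("S1", "6", c(0, b), c(b, 171e6), c(0, 1.5))
  calls <- call_truncation(exon_copy_number(seg, minus),
                           exon_blocks(minus, 4))
  expect_equal(calls$event_type, "truncating_amp")
  expect_equal(calls$k, 4L)
  located <- breakpoint_interval(seg, minus, calls)
  # brute-force bounds from the exon coordinate table
  expect_gte(located$breakpoint_start, gap_lo)
  expect_lte(located$breakpoint_end, gap_hi)
  expect_equal(located$breakpoint_start, b)
})

test_that("cohort summaries reproduce printed-style percentages", {
  n <- 539
  ids <- sprintf("S%03d", 1:n)
  event <- rep("none", n)
  event[1:7] <- "truncating_amp"; event[8] <- "hbd_deletion"
  calls <- tibble::tibble(sample = ids, gene = "ESR1", event_type = event)
  cls <- rep("none", n); cls[1:88] <- "encompassing"
  foc <- rep(NA, n); foc[1:88] <- c(rep(TRUE, 36), rep(FALSE, 52))
  amp_calls <- tibble::tibble(sample = ids, overlap_class = cls, focal = foc)

  s <- cohort_truncation_summary(calls, amp_calls)
  expect_equal(s$pct_amplified, 16.3)
  expect_equal(s$pct_focal, 6.7)
  expect_equal(s$pct_truncating_of_focal, 19.4)
  expect_equal(s$truncation_rate, 1.5)

  zero <- cohort_truncation_summary(
    tibble::tibble(sample = ids, gene = "ESR1", event_type = "none"),
    tibble::tibble(sample = ids, overlap_class = "none", focal = NA))
  expect_equal(zero$truncation_rate, 0)

  expect_error(cohort_truncation_summary(calls[c(1, 1, 3:n), ], amp_calls),
               "duplicate")
})
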