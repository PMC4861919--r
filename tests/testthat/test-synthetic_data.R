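test_that("simulation is deterministic given config and seed", {
  cfg <- sim_config(n_samples = 25, seed = 101)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$segments, b$segments)

  # byte-identical SEG output
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_seg(a$segments, p1); write_seg(b$segments, p2)
  expect_identical(readLines(p1), readLines(p2))

  e1 <- simulate_expression(a$truth, cfg)
  e2 <- simulate_expression(b$truth, cfg)
  expect_identical(e1$expr, e2$expr)

  different <- simulate_cohort(sim_config(n_samples = 25, seed = 102))
  expect_false(identical(a$segments, different$segments))
})

test_that("all-zero prevalence yields pure background cohorts", {
  cfg <- sim_config(n_samples = 12,
                    prevalence = c(broad_amp = 0, focal_full_amp = 0,
                                   truncating_amp = 0, hbd_deletion = 0),
                    seed = 5)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$event_type == "none"))
  expect_true(all(is.na(co$truth$amp_start)))
})

test_that("counts mode implants exact event numbers with valid geometry", {
  cfg <- sim_config(n_samples = 60,
                    counts = c(broad_amp = 5, focal_full_amp = 6,
                               truncating_amp = 3, hbd_deletion = 2),
                    noise_sd = 0, seed = 13)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$truth$event_type == "broad_amp"), 5)
  expect_equal(sum(co$truth$event_type == "focal_full_amp"), 6)
  expect_equal(sum(co$truth$event_type == "truncating_amp"), 3)
  expect_equal(sum(co$truth$event_type == "hbd_deletion"), 2)

  fp <- gene_footprint(toy_gene)
  tr <- co$truth[co$truth$event_type == "truncating_amp", ]
  for (i in seq_len(nrow(tr))) {
    gap <- truncamp:::inter_exon_gap(toy_gene, tr$k[i])
    expect_gte(tr$amp_end[i], gap[1])   # 3' boundary inside the inter-exon gap
    expect_lte(tr$amp_end[i], gap[2])
    expect_lte(tr$amp_start[i], fp["start"])
  }
  arm_q <- 171e6 - 61e6
  foc <- co$truth[co$truth$event_type %in% c("focal_full_amp", "truncating_amp"), ]
  expect_true(all(foc$amp_end - foc$amp_start < arm_q / 2))
  br <- co$truth[co$truth$event_type == "broad_amp", ]
  expect_true(all(br$amp_end - br$amp_start > arm_q / 2))

  expect_error(sim_config(n_samples = 4, counts = c(broad_amp = 5)), "exceed")
  expect_error(sim_config(prevalence = c(broad_amp = 0.9, focal_full_amp = 0.3)),
               "sum")
})

test_that("noise-free pipeline output reproduces the truth labels", {
  cfg <- sim_config(n_samples = 60,
                    counts = c(broad_amp = 5, focal_full_amp = 6,
                               truncating_amp = 3, hbd_deletion = 2),
                    noise_sd = 0, split_probs = c("3" = 0.5, "4" = 0.5),
                    seed = 17)
  co <- simulate_cohort(cfg)
  cn <- exon_copy_number(co$segments, toy_gene)
  calls <- call_truncation(cn, toy_blocks)
  merged <- dplyr::left_join(calls, co$truth, by = "sample")
  expected <- dplyr::case_when(
    merged$event_type.y %in% c("broad_amp", "focal_full_amp") ~ "full_length_amp",
    merged$event_type.y == "truncating_amp" ~ "truncating_amp",
    merged$event_type.y == "hbd_deletion" ~ "hbd_deletion",
    TRUE ~ "none"
  )
  expect_equal(merged$event_type.x, expected)
  tr <- merged[merged$event_type.y == "truncating_amp", ]
  expect_equal(tr$k.x, tr$k.y)
})

test_that("prevalence calibration converges at cohort scale", {
  cfg <- sim_config(n_samples = 2000,
                    genome = tibble::tibble(chromosome = "6", length = 171e6,
                                            centromere = 61e6),
                    prevalence = c(broad_amp = 0, focal_full_amp = 0,
                                   truncating_amp = 0.013, hbd_deletion = 0),
                    noise_sd = 0, seed = 19)
  co <- simulate_cohort(cfg)
  cn <- exon_copy_number(co$segments, toy_gene)
  calls <- call_truncation(cn, toy_blocks)
  got <- sum(calls$event_type == "truncating_amp")
  band <- qbinom(c(0.005, 0.995), 2000, 0.013)   # exact 99% interval around 26
  expect_gte(got, band[1])
  expect_lte(got, band[2])
  expect_equal(got, sum(co$truth$event_type == "truncating_amp"))
})

test_that("expression zeros and folds follow the configuration", {
  cfg0 <- sim_config(n_samples = 6, counts = c(truncating_amp = 3),
                     split_probs = c("4" = 1), trunc_expr_fold = 2,
                     expr_noise_sd = 0, zero_rate = 0, seed = 23)
  ex <- simulate_expression(simulate_truth(cfg0), cfg0)
  ratios <- block_ratios(floor_rpkm(ex$expr), toy_blocks)
  truncated <- ex$labels$sample[ex$labels$group == "truncated"]
  expect_equal(ratios$fold[ratios$sample %in% truncated], rep(2, 3))
  expect_equal(ratios$fold[!ratios$sample %in% truncated], rep(1, 3))

  cfg1 <- sim_config(n_samples = 4, zero_rate = 1, seed = 29)
  ex1 <- simulate_expression(simulate_truth(cfg1), cfg1)
  expect_true(all(as.matrix(ex1$expr[, -1]) == 0))
  floored <- floor_rpkm(ex1$expr)
  expect_true(all(as.matrix(floored[, -1]) == 0.1))
  expect_equal(block_ratios(floored, toy_blocks)$fold, rep(1, 4))
})

test_that("fixtures round-trip through the readers", {
  cfg <- sim_config(n_samples = 10, noise_sd = 0.05, seed = 31)
  co <- simulate_cohort(cfg)
  ex <- simulate_expression(co$truth, cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(co, ex, dir)
  expect_true(all(file.exists(paths)))

  seg2 <- read_seg(paths[["segments"]])
  expect_equal(as.data.frame(seg2), as.data.frame(co$segments),
               tolerance = 1e-12)
  expr2 <- read_expression_matrix(paths[["expression"]])
  expect_equal(as.data.frame(expr2), as.data.frame(ex$expr),
               tolerance = 1e-12)

  broken <- co
  broken$truth <- co$truth[-1, ]
  expect_error(write_fixture(broken, ex, dir), "disagree")

  empty <- simulate_cohort(sim_config(n_samples = 0, seed = 1))
  expect_equal(nrow(empty$truth), 0)
})
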