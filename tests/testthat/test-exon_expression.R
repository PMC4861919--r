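test_that("RPKM flooring replaces exact zeros by 0.1 and nothing else", {
  expr <- make_expr(matrix(c(0, 7.3, 2, 1, 0.05, 3, 4, 5), nrow = 1),
                    floored = FALSE)
  out <- floor_rpkm(expr)
  expect_equal(unname(unlist(out[1, -1])), c(0.1, 7.3, 2, 1, 0.05, 3, 4, 5))
  expect_true(attr(out, "floored"))
  expect_error(floor_rpkm(out), "already floored")
  expect_error(floor_rpkm(make_expr(matrix(c(-1, 1), nrow = 1),
                                    floored = FALSE)), "non-negative")
})

test_that("per-sample block ratios follow the closed forms", {
  blocks <- toy_blocks
  flat <- make_expr(matrix(5, nrow = 1, ncol = 8))
  expect_equal(block_ratios(flat, blocks)$r, 0)
  expect_equal(block_ratios(flat, blocks)$fold, 1)

  split <- make_expr(matrix(c(rep(8, 4), rep(2, 4)), nrow = 1))
  expect_equal(block_ratios(split, blocks)$r, 2)
  expect_equal(block_ratios(split, blocks)$fold, 4)

  mixed <- make_expr(matrix(c(4, 4, 4, 4, 4, 4, 1, 1), nrow = 1))
  expect_equal(block_ratios(mixed, blocks)$r, 2 - (2 + 2 + 0 + 0) / 4)
  expect_equal(block_ratios(mixed, blocks)$fold, 2)

  expect_error(block_ratios(make_expr(matrix(1, 1, 8), floored = FALSE),
                            blocks), "floor")

  # global library-size scaling cancels in the ratio
  set.seed(67)
  mat <- matrix(2^rnorm(16, 4), nrow = 2)
  r1 <- block_ratios(make_expr(mat), blocks)$r
  r2 <- block_ratios(make_expr(mat * 7.5), blocks)$r
  expect_equal(r1, r2)
})

test_that("group fold comparison matches the enumeration example", {
  # truncated samples: 5' = 4, 3' = 1 (r = 2); controls flat (r = 0)
  mat <- rbind(
    matrix(c(4, 4, 4, 4, 1, 1, 1, 1), nrow = 3, ncol = 8, byrow = TRUE),
    matrix(1, nrow = 3, ncol = 8)
  )
  expr <- make_expr(mat, samples = c("T1", "T2", "T3", "C1", "C2", "C3"))
  cmp <- group_fold_comparison(expr, c("T1", "T2", "T3"),
                               c("C1", "C2", "C3"), toy_blocks)
  expect_equal(cmp$fold_of_folds, 4.0)
  expect_equal(cmp$p_value, 2 / 20)    # complete separation, C(6,3) labelings
  expect_equal(cmp$mwu$mode, "exact")

  same <- group_fold_comparison(expr, c("T1", "T2"), c("T3"), toy_blocks)
  expect_equal(same$fold_of_folds, 1.0)
  expect_equal(same$p_value, 1.0)

  expect_error(group_fold_comparison(expr, c("T1"), c("T1", "C1"), toy_blocks),
               "overlap")
  expect_error(group_fold_comparison(expr, character(0), "C1", toy_blocks),
               "non-empty")
  expect_error(group_fold_comparison(expr, "NOPE", "C1", toy_blocks), "absent")
})

test_that("scaling the 3' block of truncated samples scales the fold inversely", {
  set.seed(71)
  mat <- matrix(2^rnorm(32, 4), nrow = 4)
  expr <- make_expr(mat, samples = c("T1", "T2", "C1", "C2"))
  base <- group_fold_comparison(expr, c("T1", "T2"), c("C1", "C2"), toy_blocks)
  for (c_scale in c(0.5, 2, 3.7)) {
    mat2 <- mat
    mat2[1:2, 5:8] <- mat2[1:2, 5:8] * c_scale
    expr2 <- make_expr(mat2, samples = c("T1", "T2", "C1", "C2"))
    shifted <- group_fold_comparison(expr2, c("T1", "T2"), c("C1", "C2"),
                                     toy_blocks)
    expect_equal(shifted$fold_of_folds, base$fold_of_folds / c_scale)
  }
})

test_that("within-group block test matches enumeration on one sample", {
  # log2 values 1..4 (5' block) vs 5..8 (3' block): exact p = 2/70
  expr <- make_expr(matrix(2^(1:8), nrow = 1), samples = "T1")
  got <- within_group_block_test(expr, "T1", toy_blocks)
  expect_equal(got$mode, "exact")
  expect_equal(got$p_value, 2 / 70)

  flat <- make_expr(matrix(3, nrow = 1, ncol = 8), samples = "T1")
  expect_equal(within_group_block_test(flat, "T1", toy_blocks)$p_value, 1.0)

  expect_error(within_group_block_test(expr, character(0), toy_blocks), "empty")
})

test_that("pooled within-group test uses the tie-corrected approximation at scale", {
  # 8 samples, complete separation of the pooled 32-vs-32 values
  mat <- matrix(c(rep(8, 4), rep(2, 4)), nrow = 8, ncol = 8, byrow = TRUE)
  expr <- make_expr(mat, samples = paste0("T", 1:8))
  got <- within_group_block_test(expr, paste0("T", 1:8), toy_blocks)
  expect_equal(got$mode, "normal_approx")   # exact mode capped at min group 8
  expect_lt(got$p_value, 1e-6)

  # permutation oracle: no random relabeling is as extreme
  set.seed(73)
  pooled <- c(rep(log2(2), 32), rep(log2(8), 32))
  u_obs <- sum(outer(pooled[1:32], pooled[33:64], ">"))
  extreme <- vapply(1:2000, function(i) {
    lab <- sample(64, 32)
    u <- sum(outer(pooled[lab], pooled[-lab], ">"))
    abs(u - 512) >= abs(u_obs - 512)
  }, logical(1))
  expect_lt(mean(extreme), 0.005)

  # exon-mean mode collapses samples first
  got_mean <- within_group_block_test(expr, paste0("T", 1:8), toy_blocks,
                                      unit = "exon_mean")
  expect_equal(got_mean$n + got_mean$m, 8)
})

test_that("fold-of-folds recovery is unbiased with bootstrap coverage", {
  set.seed(79)
  covered <- logical(60)
  est <- numeric(60)
  for (i in seq_len(60)) {
    cfg <- sim_config(n_samples = 16,
                      counts = c(truncating_amp = 8, focal_full_amp = 8),
                      split_probs = c("4" = 1), trunc_expr_fold = 2.1,
                      expr_noise_sd = 0.25, zero_rate = 0, seed = 1000 + i)
    ex <- simulate_expression(simulate_truth(cfg), cfg)
    expr <- floor_rpkm(ex$expr)
    cmp <- group_fold_comparison(
      expr,
      ex$labels$sample[ex$labels$group == "truncated"],
      ex$labels$sample[ex$labels$group == "control"],
      toy_blocks, boot = 400, boot_seed = i)
    est[i] <- cmp$fold_of_folds
    covered[i] <- cmp$ci_low <= 2.1 && 2.1 <= cmp$ci_high
  }
  expect_lt(abs(mean(est) - 2.1) / 2.1, 0.05)
  expect_gte(mean(covered), 0.90)
})
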