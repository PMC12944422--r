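test_that("intra-participant SD matches hand calculations", {
  tab <- tibble::tibble(
    participant_id = "A", round = "R1", device = "test",
    replicate = 1:3, temperature_c = c(35, 35, 35)
  )
  expect_equal(intra_participant_sd(tab)$per_cell$sd_c, 0)
  tab$temperature_c <- c(1, 2, 3)
  expect_equal(intra_participant_sd(tab)$per_cell$sd_c, 1)
  expect_error(intra_participant_sd(tab[1, ]), "insufficient replicates")
})

test_that("bland_altman: symmetric and degenerate cases, LoA identity", {
  ba <- bland_altman(pairs_from_diffs(c(-1, 0, 1)))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(-1.96, 1.96))
  expect_equal(ba$loa_range, 3.92)

  ba2 <- bland_altman(pairs_from_diffs(rep(-1.42, 5)))
  expect_equal(ba2$bias, -1.42)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(ba2$loa_lower, ba2$loa_upper)

  # identity holds on arbitrary data
  set.seed(1)
  for (i in 1:20) {
    ba3 <- bland_altman(pairs_from_diffs(rnorm(10, -1, 2)))
    expect_equal(ba3$loa_lower, ba3$bias - 1.96 * ba3$sd_diff)
    expect_equal(ba3$loa_upper, ba3$bias + 1.96 * ba3$sd_diff)
    expect_equal(ba3$loa_range, 3.92 * ba3$sd_diff)
  }
  expect_error(bland_altman(pairs_from_diffs(1)), ">= 2")
})

test_that("bland_altman levels: participant means vs replicates", {
  pr <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 2), round = "R1",
    replicate = rep(1:2, 2),
    t_test = c(34, 35, 36, 37), t_ref = c(35, 35, 36, 36)
  ) |> dplyr::mutate(diff = t_test - t_ref)
  bam <- bland_altman(pr, level = "participant_means")
  expect_equal(bam$n_units, 2L)
  expect_equal(bam$bias, mean(c(-0.5, 0.5)))
  bar <- bland_altman(pr, level = "replicates")
  expect_equal(bar$n_units, 4L)
})

test_that("ICC(2,1) absolute agreement: limits, offsets, and mean-squares oracle", {
  set.seed(42)
  subj <- rnorm(12, 35, 1)
  expect_equal(icc_absolute(cbind(subj, subj))$estimate, 1)

  off <- icc_absolute(cbind(subj, subj + 10))$estimate
  expect_lt(off, 0.2)

  # invariant to a constant added to ALL cells; decreases when added to one column
  m <- cbind(subj, subj + rnorm(12, 0, 0.3))
  expect_equal(icc_absolute(m + 5)$estimate, icc_absolute(m)$estimate)
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc_absolute(shifted)$estimate, icc_absolute(m)$estimate)

  # 4 x 2 toy matrix against an independent two-way ANOVA decomposition
  toy <- matrix(c(7, 9, 6, 4, 8, 11, 7, 5), ncol = 2)
  long <- data.frame(y = as.vector(toy),
                     subject = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  av <- anova(stats::lm(y ~ subject + rater, data = long))
  msr <- av["subject", "Mean Sq"]; msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  k <- 2; n <- 4
  expected <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  got <- icc_absolute(toy)
  expect_equal(got$estimate, expected, tolerance = 1e-12)
  expect_equal(c(got$msr, got$msc, got$mse), c(msr, msc, mse))

  expect_error(icc_absolute(matrix(1, 3, 2)), "zero total variance")
})

test_that("paired and one-sample t-tests match hand calculations and error contracts", {
  tt <- paired_t(c(1, 2, 3), c(2, 3, 5))
  expect_equal(tt$statistic, -4.0, tolerance = 1e-12)
  expect_equal(tt$parameter, 2)
  expect_error(paired_t(c(1, 2), c(1, 2)), "degenerate")

  ot <- one_sample_t(c(0, 2), null_mean = 0)
  expect_equal(ot$statistic, 1.0, tolerance = 1e-12)
  expect_error(one_sample_t(c(3, 3, 3), 3), "degenerate")

  # directional: mean shift c drives the sign of t
  set.seed(2)
  b <- rnorm(50, 35, 1)
  expect_lt(paired_t(b - 1.42 + rnorm(50, 0, 0.3), b)$statistic, 0)
  expect_gt(paired_t(b + 0.5 + rnorm(50, 0, 0.1), b)$statistic, 0)
})

test_that("one-sample t on generated per-participant biases detects the offset", {
  cfg <- default_study_config(seed = 31)
  pr <- pair_replicates(generate_study(cfg)) |> dplyr::filter(round == "R1")
  per_part <- dplyr::summarise(dplyr::group_by(pr, participant_id),
                               bias = mean(diff))
  res <- one_sample_t(per_part$bias, 0)
  expect_lt(res$p.value, 0.05)
  expect_lt(res$statistic, 0)
})

test_that("normality gate passes normal data, fails uniform, errors on degenerate input", {
  set.seed(3)
  expect_true(normality_gate(rnorm(200))$pass)
  expect_false(normality_gate(runif(500))$pass)
  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("pearson correlation: exact cases and affine invariance", {
  pr <- pairs_from_diffs(rnorm(10))
  pr$t_ref <- pr$t_ref + 1:10
  pr$t_test <- pr$t_ref
  pr$diff <- pr$t_test - pr$t_ref
  expect_equal(pearson_within_round(pr), 1)
  pr$t_test <- -pr$t_ref + 70
  expect_equal(pearson_within_round(pr, level = "replicates"), -1)
  set.seed(4)
  pr$t_test <- rnorm(10); pr$t_ref <- rnorm(10)
  r0 <- pearson_within_round(pr, level = "replicates")
  pr2 <- pr
  pr2$t_test <- 3 * pr$t_test + 7
  pr2$t_ref <- 0.5 * pr$t_ref - 2
  expect_equal(pearson_within_round(pr2, level = "replicates"), r0)
  pr$t_ref <- rep(35, 10)
  expect_error(pearson_within_round(pr, level = "replicates"), "zero variance")
})

test_that("round-change correlation: identical shifts give r = 1, missing round errors", {
  pr <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:10),
                           round = c("R1", "R2"), replicate = 1:2)
  set.seed(5)
  base <- rnorm(10, 35, 1)
  shift <- rnorm(10, 0, 0.5)
  pr$t_ref <- base[as.integer(factor(pr$participant_id))] +
    ifelse(pr$round == "R2", shift[as.integer(factor(pr$participant_id))], 0)
  pr$t_test <- pr$t_ref - 1
  pr$diff <- pr$t_test - pr$t_ref
  expect_equal(round_change_correlation(pr)$estimate, 1, tolerance = 1e-9)
  expect_error(round_change_correlation(pr[pr$round == "R1", ]), "exactly 2 rounds")
  expect_error(round_change_correlation(pr[-which(pr$participant_id == "P01" &
                                                    pr$round == "R2"), ]),
               "missing a round")
})

test_that("independent device responses give near-zero round-change correlation", {
  # test-device shifts drawn independently of reference shifts
  set.seed(6)
  rs <- replicate(40, {
    n <- 30
    base <- rnorm(n, 35, 1)
    pr <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:n),
                             round = c("R1", "R2"))
    i <- as.integer(factor(pr$participant_id))
    r2 <- pr$round == "R2"
    pr$t_ref <- base[i] + ifelse(r2, rnorm(n, 0, 0.5)[i], 0)
    pr$t_test <- base[i] - 1 + ifelse(r2, rnorm(n, 0, 0.5)[i], 0)
    pr$replicate <- 1L
    pr <- dplyr::bind_rows(pr, dplyr::mutate(pr, replicate = 2L))
    pr$diff <- pr$t_test - pr$t_ref
    round_change_correlation(pr)$estimate
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("one-way bias ANOVA matches a sum-of-squares oracle and error contracts", {
  bias <- c(1.0, 1.2, 0.9, 2.1, 2.0, 2.2, 0.5, 0.4, 0.8)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- bias_anova(bias, grp)
  gm <- mean(bias)
  ssb <- sum(3 * (tapply(bias, grp, mean) - gm)^2)
  ssw <- sum((bias - tapply(bias, grp, mean)[grp])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$p.value, stats::pf(f_oracle, 2, 6, lower.tail = FALSE))

  expect_error(bias_anova(bias, rep(c("a", "b", "c"), c(1, 4, 4))), ">= 2 groups")
  # strongly separated groups are detected
  set.seed(7)
  expect_lt(bias_anova(c(rnorm(10), rnorm(10, 5)), rep(c("a", "b"), each = 10))$p.value,
            1e-6)
})

test_that("agreement_summary assembles a per-round table and tolerates degenerate t", {
  cfg <- study_config(n_participants = 6, n_replicates = 3, seed = 8,
                      pop_sd = 1, participant_bias_sd = 0.2)
  s <- agreement_summary(generate_study(cfg))
  expect_setequal(unique(s$round), c("R1", "R2"))
  expect_equal(sum(s$statistic == "icc_2_1"), 2L)
  wide <- tidyr::pivot_wider(s, names_from = round, values_from = value)
  lo <- wide[wide$statistic == "loa_lower_c", -1]
  bias <- wide[wide$statistic == "bias_c", -1]
  sdd <- wide[wide$statistic == "sd_diff_c", -1]
  expect_equal(unlist(lo), unlist(bias - 1.96 * sdd), ignore_attr = TRUE)

  # zero-noise zero-bias input: bias 0, LoA width 0, t undefined but no error
  cfg0 <- study_config(n_participants = 4, n_replicates = 2, pop_sd = 1,
                       ref_noise_sd = 0, test_noise_sd = 0, bias_intercept = 0,
                       bias_slope = 0, participant_bias_sd = 0,
                       quantize_to = 0, seed = 9)
  s0 <- agreement_summary(generate_study(cfg0))
  expect_true(all(s0$value[s0$statistic == "bias_c"] == 0))
  expect_true(all(s0$value[s0$statistic == "loa_range_c"] == 0))
})
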