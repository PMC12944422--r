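#' Intra-participant precision
#'
#' Sample SD (n-1 denominator) of the repeated readings within each
#' `(participant, device, round)` cell — the study's precision/repeatability
#' metric — plus the mean of those SDs per `(device, round)`.
#'
#' @param table A measurement tibble.
#' @return A list with `per_cell` (tibble: participant_id, device, round, n,
#'   sd_c) and `summary` (tibble: device, round, mean_sd_c).
#' @export
intra_participant_sd <- function(table) {
  counts <- table |>
    dplyr::count(.data$participant_id, .data$round, .data$device)
  short <- dplyr::filter(counts, .data$n < 2L)
  if (nrow(short) > 0) {
    stop("insufficient replicates (< 2) in cell(s): ",
         paste(paste(short$participant_id, short$round, short$device, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  per_cell <- table |>
    dplyr::group_by(.data$participant_id, .data$device, .data$round) |>
    dplyr::summarise(n = dplyr::n(), sd_c = stats::sd(.data$temperature_c),
                     .groups = "drop")
  summary <- per_cell |>
    dplyr::group_by(.data$device, .data$round) |>
    dplyr::summarise(mean_sd_c = mean(.data$sd_c), .groups = "drop")
  list(per_cell = per_cell, summary = summary)
}

# Collapse a paired table to the requested analysis level for one round.
# participant_means: one unit per participant (mean test, mean ref);
# replicates: each paired replicate is a unit.
.paired_units <- function(pairs, round = NULL,
                          level = c("participant_means", "replicates")) {
  level <- match.arg(level)
  if (!is.null(round)) pairs <- dplyr::filter(pairs, .data$round %in% !!round)
  if (nrow(pairs) == 0) stop("no paired rows for the requested round", call. = FALSE)
  if (level == "participant_means") {
    pairs |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(t_test = mean(.data$t_test), t_ref = mean(.data$t_ref),
                       .groups = "drop") |>
      dplyr::mutate(diff = .data$t_test - .data$t_ref)
  } else {
    dplyr::select(pairs, "participant_id", "t_test", "t_ref", "diff")
  }
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean test-minus-reference difference; the 95% limits of
#' agreement are `bias +/- 1.96 * sd(diff)` with the sample SD. At the default
#' `participant_means` level each participant contributes one difference of
#' per-device means; at `replicates` level every paired replicate is a unit.
#'
#' @param pairs A paired tibble from [pair_replicates()], or any data frame
#'   with `t_test` and `t_ref` columns (a `diff` column is recomputed).
#' @param round Optional round label(s) to restrict to.
#' @param level `"participant_means"` (default) or `"replicates"`.
#' @return An object of class `"bland_altman"`: a list with `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `loa_range`, `n_units`, `level`, `round`, and
#'   `points`, a tibble of per-unit `(mean, diff)` coordinates for plotting.
#' @export
bland_altman <- function(pairs, round = NULL,
                         level = c("participant_means", "replicates")) {
  level <- match.arg(level)
  units <- .paired_units(pairs, round, level)
  if (nrow(units) < 2L) {
    stop("Bland-Altman requires >= 2 analysis units", call. = FALSE)
  }
  d <- units$diff
  if (any(!is.finite(d))) stop("non-finite difference(s)", call. = FALSE)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(
      bias = bias, sd_diff = sd_diff,
      loa_lower = bias - 1.96 * sd_diff,
      loa_upper = bias + 1.96 * sd_diff,
      loa_range = 2 * 1.96 * sd_diff,
      n_units = nrow(units), level = level,
      round = if (is.null(round)) "all" else paste(round, collapse = "+"),
      points = tibble::tibble(
        unit = units$participant_id %||% seq_len(nrow(units)),
        mean = (units$t_test + units$t_ref) / 2,
        diff = d
      )
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (%s, level = %s, n = %d)\n  bias %.3f degC, SD of differences %.3f degC\n  95%% LoA [%.3f, %.3f] degC (range %.3f)\n",
    x$round, x$level, x$n_units, x$bias, x$sd_diff,
    x$loa_lower, x$loa_upper, x$loa_range))
  invisible(x)
}

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement form
#' computed from the two-way mean squares of an `n` subjects x `k` raters
#' matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' Unlike consistency forms it penalises a constant offset between raters.
#'
#' @param mat Numeric matrix, subjects in rows, raters/devices in columns,
#'   no missing cells.
#' @return A list of class `"icc"` with `estimate`, `msr`, `msc`, `mse`,
#'   `n`, `k`.
#' @export
icc_absolute <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop("ICC needs >= 2 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(mat)) stop("ICC matrix must be complete", call. = FALSE)
  grand <- mean(mat)
  if (sum((mat - grand)^2) == 0) {
    stop("undefined ICC: zero total variance", call. = FALSE)
  }
  rmeans <- rowMeans(mat); cmeans <- colMeans(mat)
  msr <- k * sum((rmeans - grand)^2) / (n - 1)
  msc <- n * sum((cmeans - grand)^2) / (k - 1)
  resid <- mat - outer(rmeans, rep(1, k)) - outer(rep(1, n), cmeans) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(estimate = est, msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement: %.3f (n = %d subjects, k = %d raters)\n",
              x$estimate, x$n, x$k))
  invisible(x)
}

#' Paired-samples t-test
#'
#' Two-sided t-test on the paired differences `a - b`. Errors on zero-variance
#' differences rather than returning an unusable statistic.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `p.value`, `parameter` (df).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  if (length(d) < 2L) stop("paired t-test needs n >= 2", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("degenerate test: zero-variance differences", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                 p.value = ht$p.value, parameter = unname(ht$parameter))
}

#' One-sample t-test
#'
#' @param values Numeric vector.
#' @param null_mean Null-hypothesis mean (degC), default 0.
#' @return A one-row tibble like [paired_t()].
#' @export
one_sample_t <- function(values, null_mean = 0) {
  if (length(values) < 2L) stop("one-sample t-test needs n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate test: zero variance", call. = FALSE)
  }
  ht <- stats::t.test(values, mu = null_mean)
  tibble::tibble(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                 p.value = ht$p.value, parameter = unname(ht$parameter))
}

#' Shapiro-Wilk normality gate
#'
#' The paired analyses assume approximately normal differences; this gate
#' runs the Shapiro-Wilk test and flags pass/fail at `alpha`.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level, default 0.05.
#' @return One-row tibble: `statistic` (W), `p.value`, `pass`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  if (stats::sd(values) == 0) stop("constant vector: normality undefined", call. = FALSE)
  ht <- stats::shapiro.test(values)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 pass = ht$p.value >= alpha)
}

#' Pearson correlation between devices within a round
#'
#' @inheritParams bland_altman
#' @return Correlation of `(t_test, t_ref)` at the chosen level (numeric).
#' @export
pearson_within_round <- function(pairs, round = NULL,
                                 level = c("participant_means", "replicates")) {
  units <- .paired_units(pairs, round, match.arg(level))
  if (nrow(units) < 3L) stop("Pearson correlation needs >= 3 units", call. = FALSE)
  if (stats::sd(units$t_test) == 0 || stats::sd(units$t_ref) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(units$t_test, units$t_ref)
}

#' Correlation of per-participant round-to-round changes
#'
#' For each participant and device, the change in the per-round mean between
#' the first and second round; returns the Pearson correlation (and p-value)
#' between the two devices' change vectors — near zero when the instruments
#' respond to the environment independently.
#'
#' @param pairs A paired tibble covering exactly two rounds, every
#'   participant present in both.
#' @return One-row tibble: `estimate` (r), `statistic`, `p.value`.
#' @export
round_change_correlation <- function(pairs) {
  rounds <- sort(unique(pairs$round))
  if (length(rounds) != 2L) {
    stop("round_change_correlation needs exactly 2 rounds, got ",
         length(rounds), call. = FALSE)
  }
  means <- pairs |>
    dplyr::group_by(.data$participant_id, .data$round) |>
    dplyr::summarise(t_test = mean(.data$t_test), t_ref = mean(.data$t_ref),
                     .groups = "drop")
  complete <- means |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(complete) > 0) {
    stop("participant(s) missing a round: ",
         paste(complete$participant_id, collapse = ", "), call. = FALSE)
  }
  deltas <- means |>
    tidyr::pivot_wider(names_from = "round", values_from = c("t_test", "t_ref")) |>
    dplyr::mutate(
      d_test = .data[[paste0("t_test_", rounds[2])]] - .data[[paste0("t_test_", rounds[1])]],
      d_ref = .data[[paste0("t_ref_", rounds[2])]] - .data[[paste0("t_ref_", rounds[1])]]
    )
  ht <- stats::cor.test(deltas$d_test, deltas$d_ref)
  tibble::tibble(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                 p.value = ht$p.value)
}

#' One-way ANOVA of per-participant bias across groups
#'
#' Tests whether the mean device bias differs across participant groups
#' (e.g. skin-phototype categories).
#'
#' @param bias Numeric vector of per-participant mean biases (degC).
#' @param group Group label per participant.
#' @return One-row tibble: `statistic` (F), `p.value`, `df1`, `df2`.
#' @export
bias_anova <- function(bias, group) {
  stopifnot(length(bias) == length(group))
  group <- factor(group)
  sizes <- table(group)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("ANOVA needs >= 2 groups with >= 2 members each", call. = FALSE)
  }
  ht <- stats::oneway.test(bias ~ group, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]))
}

#' Per-round agreement summary table
#'
#' Assembles, per round, the descriptive and agreement statistics of a
#' method-comparison study: mean temperature per device, mean
#' intra-participant SD per device, bias, SD of differences, lower/upper LoA
#' and their range, ICC(2,1) on the participants x devices matrix of
#' per-participant means, Pearson correlation, and the paired t-test.
#'
#' @param table A measurement tibble (both devices).
#' @param level Analysis level for bias/LoA/correlation/t-test; default
#'   `participant_means`.
#' @return A tibble with one row per `(round, statistic)` in long form:
#'   columns `round`, `statistic`, `value`.
#' @export
agreement_summary <- function(table, level = c("participant_means", "replicates")) {
  level <- match.arg(level)
  pairs <- pair_replicates(table)
  prec <- intra_participant_sd(table)
  purrr::map_dfr(sort(unique(table$round)), function(r) {
    ba <- bland_altman(pairs, round = r, level = level)
    units <- .paired_units(pairs, r, "participant_means")
    icc <- icc_absolute(cbind(units$t_ref, units$t_test))
    rcor <- pearson_within_round(pairs, round = r, level = level)
    tt_units <- .paired_units(pairs, r, level)
    # degenerate (zero-variance) differences leave the t-test undefined
    tt <- tryCatch(paired_t(tt_units$t_test, tt_units$t_ref),
                   error = function(e) tibble::tibble(
                     estimate = mean(tt_units$diff), statistic = NA_real_,
                     p.value = NA_real_, parameter = NA_real_))
    tab_r <- dplyr::filter(table, .data$round == r)
    mean_temp <- tapply(tab_r$temperature_c, tab_r$device, mean)
    prec_r <- dplyr::filter(prec$summary, .data$round == r)
    msd <- stats::setNames(prec_r$mean_sd_c, prec_r$device)
    tibble::tibble(
      round = r,
      statistic = c("mean_temp_reference_c", "mean_temp_test_c",
                    "mean_intra_sd_reference_c", "mean_intra_sd_test_c",
                    "bias_c", "sd_diff_c", "loa_lower_c", "loa_upper_c",
                    "loa_range_c", "icc_2_1", "pearson_r",
                    "t_statistic", "t_p_value", "n_units"),
      value = c(mean_temp[["reference"]], mean_temp[["test"]],
                msd[["reference"]], msd[["test"]],
                ba$bias, ba$sd_diff, ba$loa_lower, ba$loa_upper,
                ba$loa_range, icc$estimate, rcor,
                tt$statistic, tt$p.value, ba$n_units)
    )
  })
}
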