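#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    statistic = c("bias_c", "sd_diff_c", "loa_lower_c", "loa_upper_c",
                  "loa_range_c"),
    value = c(x$bias, x$sd_diff, x$loa_lower, x$loa_upper, x$loa_range)
  )
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 loa_range = x$loa_range, n_units = x$n_units,
                 level = x$level, round = x$round)
}

#' @export
tidy.icc <- function(x, ...) {
  tibble::tibble(term = c("icc_2_1", "msr", "msc", "mse"),
                 estimate = c(x$estimate, x$msr, x$msc, x$mse))
}

#' @export
glance.icc <- function(x, ...) {
  tibble::tibble(icc = x$estimate, n = x$n, k = x$k)
}
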