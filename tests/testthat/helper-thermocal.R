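# Shared fixtures and independent oracles, all built in code.

# Tiny deterministic measurement table: 2 participants x 1 round x 2 devices
# x n_rep replicates.
tiny_study <- function(n_rep = 3) {
  expand.grid(
    participant_id = c("A", "B"), round = "R1",
    device = c("test", "reference"), replicate = seq_len(n_rep),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  ) |>
    tibble::as_tibble() |>
    dplyr::arrange(participant_id, device, replicate) |>
    dplyr::mutate(temperature_c = 35 + as.integer(factor(participant_id)) +
                    ifelse(device == "test", -1, 0) + 0.1 * replicate)
}

# Paired table built directly from difference values (reference fixed at a
# constant), one participant per row.
pairs_from_diffs <- function(diffs, ref = 35) {
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_along(diffs)),
    round = "R1", replicate = 1L,
    t_test = ref + diffs, t_ref = ref, diff = diffs
  )
}

# Brute-force weighted monotone least squares: enumerate all contiguous
# partitions (2^(n-1)), keep those whose block weighted means are
# non-decreasing, return the fitted vector with minimal weighted SSE.
# The projection onto the monotone cone is unique and is one of these
# candidates, so the minimiser equals it. Independent of pava().
brute_force_isotonic <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    # bit i set => block boundary after position i
    bounds <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, bounds + 1)
    ends <- c(bounds, n)
    means <- mapply(function(s, e) {
      stats::weighted.mean(y[s:e], w[s:e])
    }, starts, ends)
    if (is.unsorted(means)) next
    fitted <- rep(means, ends - starts + 1)
    sse <- sum(w * (y - fitted)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fitted
    }
  }
  best
}

# 1-nearest-neighbour memoriser used as a leakage detector.
knn1_predict <- function(x_train, y_train, x_new) {
  vapply(x_new, function(x0) y_train[which.min(abs(x_train - x0))], numeric(1))
}
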