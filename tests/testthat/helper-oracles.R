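# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles restate the definitions directly and share no code with
# the package internals.

# All strict interior extrema by direct neighbor comparison (assumes no ties).
oracle_extrema <- function(y) {
  n <- length(y)
  idx <- integer(0); kind <- character(0)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) { idx <- c(idx, i); kind <- c(kind, "max") }
    if (y[i] < y[i - 1] && y[i] < y[i + 1]) { idx <- c(idx, i); kind <- c(kind, "min") }
  }
  data.frame(index = idx, kind = kind, value = y[idx], stringsAsFactors = FALSE)
}

# Topographic prominence by exhaustive walk, written independently: collect
# the full stretches left and right of the extremum up to (excluding) the
# first strictly higher sample, take each side's minimum, subtract the higher
# of the two minima.
oracle_prominence <- function(y, index, kind) {
  s <- if (kind == "max") y else -y
  v <- s[index]
  n <- length(s)
  left <- index - 1
  while (left >= 1 && s[left] <= v) left <- left - 1
  right <- index + 1
  while (right <= n && s[right] <= v) right <- right + 1
  lo_l <- min(s[(left + 1):index])
  lo_r <- min(s[index:(right - 1)])
  v - max(lo_l, lo_r)
}

# Same-kind nearest neighbor under the x-double-weighted distance, by full
# enumeration over all same-kind pairs.
oracle_match <- function(cur, tar, cx, tx) {
  t(sapply(seq_len(nrow(cur)), function(j) {
    cand <- which(tar$kind == cur$kind[j])
    d <- sqrt((2 * (cx[cur$index[j]] - tx[tar$index[cand]]))^2 +
                (cur$value[j] - tar$value[cand])^2)
    k <- cand[which.min(d)]
    c(cursor = cur$index[j], target = tar$index[k], dist = min(d))
  }))
}

# Exhaustive per-sample minimization over the inclusive candidate window.
oracle_assign_one <- function(trial, t, win) {
  cand <- win[1]:win[2]
  d <- sqrt((trial$cursor_x[t] - trial$target_x[cand])^2 +
              (trial$cursor_y[t] - trial$target_y[cand])^2)
  k <- which.min(d)  # which.min takes the earliest on ties
  c(intended = cand[k], distance = d[k])
}

# A short synthetic trial from an arbitrary y-curve: x advances at a constant
# horizontal step, cursor is a lagged/noisy copy of the target.
toy_trial <- function(ty, cy = ty, step = 2) {
  n <- length(ty)
  structure(data.frame(sample = seq_len(n),
                       target_x = step * (seq_len(n) - 1), target_y = ty,
                       cursor_x = step * (seq_len(n) - 1), cursor_y = cy,
                       segment = rep("trial", n), stringsAsFactors = FALSE),
            class = c("pursuit_trial", "data.frame"),
            participant = "toy", trial = 1L, velocity = 2L, side = "right")
}

# A small, fast generator config for tests that do not need full-size trials.
small_config <- function(seed = NULL) {
  trajectory_config(samples_per_segment = 120, gap_length = 15,
                    spline_flank = 6, x_span = 450,
                    n_repeats_per_condition = 1, seed = seed)
}

# Deterministic random-coefficient trajectory for one velocity level.
seeded_trajectory <- function(seed, velocity = 2, side = "right",
                              config = trajectory_config()) {
  set.seed(seed)
  build_trajectory(config, velocity = velocity, side = side)
}
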