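#' Evaluate the Wulf-Schmidt waveform
#'
#' Sum of three sine and three cosine harmonics,
#' \deqn{f(x) = \sum_{i=1}^{3} a_i \sin(i x) + b_i \cos(i x),}
#' the building block of every trajectory segment. Amplitudes are in screen
#' pixels, the argument is a phase in radians.
#'
#' @param a Numeric vector of three sine amplitudes (pixels).
#' @param b Numeric vector of three cosine amplitudes (pixels).
#' @param phase Numeric vector of waveform arguments (radians); must be finite.
#' @return Numeric vector of y values (pixels), one per phase. Bounded in
#'   absolute value by \code{sum(abs(a)) + sum(abs(b))}.
#' @examples
#' eval_waveform(c(1, 0, 0), c(0, 0, 0), pi / 2)  # 1
#' @export
eval_waveform <- function(a, b, phase) {
  stopifnot(length(a) == 3L, length(b) == 3L)
  if (!all(is.finite(phase))) stop("'phase' must be finite")
  y <- numeric(length(phase))
  for (i in 1:3) y <- y + a[i] * sin(i * phase) + b[i] * cos(i * phase)
  y
}

#' Draw random segment amplitudes
#'
#' Six independent draws, uniform on \code{[-range, range]} pixels, for the
#' sine and cosine amplitudes of one random trajectory segment.
#'
#' @param range Half-width of the uniform range in pixels (default 40).
#' @return List with numeric fields \code{a} and \code{b} (length 3 each).
#' @export
sample_coefficients <- function(range = 40) {
  stopifnot(range > 0)
  list(a = stats::runif(3, -range, range), b = stats::runif(3, -range, range))
}

#' Trajectory generator configuration
#'
#' Bundles every tunable of the target-trajectory generator. Coordinates use
#' an origin at the screen center with y increasing upward, units in pixels;
#' the target starts at the origin and moves right (or left, mirrored).
#'
#' @param coefficient_range Half-width of the uniform amplitude range for the
#'   random segments, pixels (default 40).
#' @param fixed_middle Amplitudes of the constant middle segment, a list with
#'   fields \code{a} and \code{b}; identical in every trial so the segment can
#'   support implicit sequence learning.
#' @param phase_span Width of the waveform argument interval per segment,
#'   radians (default \code{2 * pi}, one full period of the fundamental).
#' @param samples_per_segment Dense pre-resampling samples per segment
#'   (default 240).
#' @param gap_length Number of dense samples in each inter-segment gap that is
#'   bridged by a cubic spline (default 30).
#' @param spline_flank Dense samples on each side of a gap used to fit the
#'   bridging spline (default 10).
#' @param velocity_levels Three target speeds in pixels per frame, slow to
#'   fast. Defaults give a mean trial duration close to 12 s at 60 Hz.
#' @param frame_rate Sampling/refresh rate in Hz (default 60).
#' @param screen_size Width and height of the screen in pixels
#'   (default \code{c(1920, 1080)}).
#' @param x_span Horizontal extent of a trial in pixels, from the center
#'   toward the screen edge (default 900).
#' @param n_repeats_per_condition Repeats of each of the six conditions
#'   (3 velocities x 2 sides) in a session (default 12, i.e. 72 trials).
#' @param seed Optional integer session seed; per-trial substreams are derived
#'   from it so single trials can be regenerated.
#' @return Object of class \code{trajectory_config} (a list).
#' @export
trajectory_config <- function(coefficient_range = 40,
                              fixed_middle = list(a = c(37, -3, 26),
                                                  b = c(23, -15, -9)),
                              phase_span = 2 * pi,
                              samples_per_segment = 240,
                              gap_length = 30,
                              spline_flank = 10,
                              velocity_levels = c(1.7, 2.4, 3.4),
                              frame_rate = 60,
                              screen_size = c(1920, 1080),
                              x_span = 900,
                              n_repeats_per_condition = 12,
                              seed = NULL) {
  stopifnot(coefficient_range > 0, phase_span > 0,
            samples_per_segment >= 3, gap_length >= 0, spline_flank >= 2,
            length(velocity_levels) == 3, all(velocity_levels > 0),
            !anyDuplicated(velocity_levels),
            frame_rate > 0, length(screen_size) == 2, x_span > 0,
            n_repeats_per_condition >= 1)
  cfg <- list(coefficient_range = coefficient_range,
              fixed_middle = fixed_middle,
              phase_span = phase_span,
              samples_per_segment = samples_per_segment,
              gap_length = gap_length,
              spline_flank = spline_flank,
              velocity_levels = velocity_levels,
              frame_rate = frame_rate,
              screen_size = screen_size,
              x_span = x_span,
              n_repeats_per_condition = n_repeats_per_condition,
              seed = seed)
  class(cfg) <- "trajectory_config"
  cfg
}

# First phase at which the waveform crosses zero in [0, 2*pi); used to anchor
# the opening segment at the screen-center y. A mean-zero-per-period waveform
# always crosses zero.
first_zero_phase <- function(a, b) {
  f <- function(p) eval_waveform(a, b, p)
  grid <- seq(0, 2 * pi, length.out = 721)
  v <- f(grid)
  k <- which(v[-length(v)] * v[-1] <= 0)[1]
  if (is.na(k)) return(0)  # degenerate (all-zero coefficients)
  if (v[k] == 0) return(grid[k])
  stats::uniroot(f, lower = grid[k], upper = grid[k + 1], tol = 1e-10)$root
}

# One equal-chord walk along a polyline: starting at vertex 1, each output
# point is the first crossing of the polyline with the circle of radius
# `step` around the previous point, so consecutive Euclidean spacing is
# exactly `step`. Returns the points, the chord positions, and the leftover
# distance between the last placed point and the polyline end.
chord_walk <- function(x, y, step) {
  n <- length(x)
  px <- numeric(ceiling(1.5 * sum(sqrt(diff(x)^2 + diff(y)^2)) / step) + 8L)
  py <- px
  px[1] <- x[1]; py[1] <- y[1]
  m <- 1L
  j <- 1L          # current polyline segment: between vertex j and j+1
  t0 <- 0          # fraction along that segment already consumed
  cx <- x[1]; cy <- y[1]
  while (TRUE) {
    # advance to the segment containing the first circle crossing
    found <- FALSE
    jj <- j; tt <- t0
    while (jj < n) {
      ax <- x[jj] + tt * (x[jj + 1] - x[jj]) - cx
      ay <- y[jj] + tt * (y[jj + 1] - y[jj]) - cy
      bx <- (1 - tt) * (x[jj + 1] - x[jj])
      by <- (1 - tt) * (y[jj + 1] - y[jj])
      # ||a + u b|| = step for u in (0, 1]
      A <- bx * bx + by * by
      B <- 2 * (ax * bx + ay * by)
      C <- ax * ax + ay * ay - step * step
      disc <- B * B - 4 * A * C
      if (A > 0 && disc >= 0) {
        u <- (-B + sqrt(disc)) / (2 * A)
        if (u > 0 && u <= 1) {
          tt2 <- tt + u * (1 - tt)
          cx <- x[jj] + tt2 * (x[jj + 1] - x[jj])
          cy <- y[jj] + tt2 * (y[jj + 1] - y[jj])
          j <- jj; t0 <- tt2
          found <- TRUE
          break
        }
      }
      jj <- jj + 1L; tt <- 0
    }
    if (!found) break
    m <- m + 1L
    if (m > length(px)) { px <- c(px, numeric(m)); py <- c(py, numeric(m)) }
    px[m] <- cx; py[m] <- cy
  }
  leftover <- sqrt((x[n] - cx)^2 + (y[n] - cy)^2)
  list(x = px[seq_len(m)], y = py[seq_len(m)], leftover = leftover)
}

#' Resample a polyline at constant speed
#'
#' Places points along a polyline so that consecutive points are a constant
#' Euclidean distance apart -- the target's constant-velocity property,
#' implemented by equal-chord stepping (each point is the first intersection
#' of the polyline with a circle of the step radius around the previous
#' point). With \code{snap = TRUE} the step is re-adjusted once so that an
#' integer number of steps ends on the final polyline point, which is then
#' pinned exactly; the adjusted step deviates from the nominal speed by well
#' under 0.5\% for any realistic trial.
#'
#' @param x,y Coordinates of the input polyline (at least 2 points).
#' @param speed Nominal spacing in pixels per frame; must be positive.
#' @param snap Snap the spacing so the walk ends on the last polyline point
#'   (default \code{TRUE}).
#' @return Data frame with columns \code{x}, \code{y} and \code{arc}
#'   (cumulative chord position); points lie on the input polyline. If
#'   \code{speed} is at least the total arc length a two-point degenerate
#'   output is returned with a warning.
#' @export
resample_constant_speed <- function(x, y, speed, snap = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 2, speed > 0)
  L <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (speed >= L) {
    warning("speed exceeds total arc length; returning degenerate two-point output")
    return(data.frame(x = x[c(1, length(x))], y = y[c(1, length(y))],
                      arc = c(0, L)))
  }
  w <- chord_walk(x, y, speed)
  if (snap && w$leftover >= 0.02 * speed) {
    # choose the step so that an integer number of equal chords ends on the
    # polyline end: bisect on the step size (larger steps -> fewer chords,
    # smaller end leftover within a fixed chord count)
    n0 <- length(w$x) - 1L
    N <- if (w$leftover > speed / 2) n0 + 1L else n0
    lo <- speed * 0.8
    hi <- speed * 1.25
    wlo <- chord_walk(x, y, lo)
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      wm <- chord_walk(x, y, mid)
      if (length(wm$x) - 1L <= N - 1L) {
        hi <- mid
      } else {
        lo <- mid
        wlo <- wm
        if (length(wm$x) - 1L == N && wm$leftover < 0.02 * mid) break
      }
    }
    w <- wlo
  }
  if (snap) {
    w$x[length(w$x)] <- x[length(x)]
    w$y[length(w$y)] <- y[length(y)]
  }
  d <- sqrt(diff(w$x)^2 + diff(w$y)^2)
  data.frame(x = w$x, y = w$y, arc = c(0, cumsum(d)))
}

# Build the dense (pre-resampling) trajectory: three waveform segments with
# spline-bridged gaps, on an evenly spaced x grid spanning [0, x_span].
dense_trajectory <- function(config, coefficients) {
  n <- config$samples_per_segment
  g <- config$gap_length
  N <- 3L * n + 2L * g
  x <- seq(0, config$x_span, length.out = N)
  y <- rep(NA_real_, N)
  seg <- rep(NA_character_, N)
  idx <- list(random1  = seq_len(n),
              constant = n + g + seq_len(n),
              random2  = 2L * n + 2L * g + seq_len(n))
  names_seg <- names(idx)
  for (k in seq_along(idx)) {
    cf <- coefficients[[k]]
    ph0 <- if (k == 1L) first_zero_phase(cf$a, cf$b) else 0
    ph <- ph0 + seq(0, config$phase_span, length.out = n)
    y[idx[[k]]] <- eval_waveform(cf$a, cf$b, ph)
    seg[idx[[k]]] <- names_seg[k]
  }
  seg[is.na(seg)] <- "gap"
  if (g > 0) {
    K <- config$spline_flank
    for (gap_start in c(n + 1L, 2L * n + g + 1L)) {
      gi <- gap_start:(gap_start + g - 1L)
      fl <- c((gap_start - K):(gap_start - 1L), (gap_start + g):(gap_start + g + K - 1L))
      y[gi] <- stats::spline(x[fl], y[fl], xout = x[gi], method = "fmm")$y
    }
  }
  data.frame(x = x, y = y, segment = seg)
}

#' Build one target trajectory
#'
#' Assembles a three-segment target trajectory: a random opening segment, the
#' fixed middle segment (identical in every trial), and a random closing
#' segment, with cubic-spline bridges over the inter-segment gaps. The dense
#' curve is then resampled to constant speed, region by region (before,
#' within, after the constant segment) so that the constant segment's sampled
#' coordinates are identical in every trial of the same velocity level. The
#' opening segment's phase is anchored at a zero crossing of its waveform so
#' the trial starts exactly at the screen center.
#'
#' @param config A \code{\link{trajectory_config}}.
#' @param velocity Velocity level, integer 1..3 (index into
#'   \code{config$velocity_levels}).
#' @param side \code{"right"} or \code{"left"}; left trials are mirrored about
#'   the vertical center axis.
#' @param coefficients Optional list of three coefficient sets (as returned by
#'   \code{\link{sample_coefficients}}); the middle entry is ignored and
#'   replaced by \code{config$fixed_middle}. If \code{NULL}, random segments
#'   are drawn from the current RNG stream.
#' @param trial Trial index stored as metadata.
#' @return Object of class \code{pursuit_trajectory}: a data frame with
#'   columns \code{sample}, \code{x}, \code{y}, \code{segment}
#'   (random1/gap/constant/random2), plus attributes \code{velocity},
#'   \code{side}, \code{speed}, \code{trial} and \code{config}.
#' @export
build_trajectory <- function(config = trajectory_config(), velocity = 2,
                             side = c("right", "left"), coefficients = NULL,
                             trial = 1L) {
  side <- match.arg(side)
  stopifnot(velocity %in% 1:3)
  if (is.null(coefficients)) {
    coefficients <- list(sample_coefficients(config$coefficient_range),
                         NULL,
                         sample_coefficients(config$coefficient_range))
  }
  coefficients[[2]] <- config$fixed_middle
  dense <- dense_trajectory(config, coefficients)
  speed <- config$velocity_levels[velocity]

  ci <- which(dense$segment == "constant")
  bounds <- c(1L, ci[1], ci[length(ci)], nrow(dense))
  pieces <- vector("list", 3L)
  for (r in 1:3) {
    rows <- bounds[r]:bounds[r + 1]
    rs <- resample_constant_speed(dense$x[rows], dense$y[rows], speed)
    # carry segment labels by nearest dense arc position
    arc_d <- c(0, cumsum(sqrt(diff(dense$x[rows])^2 + diff(dense$y[rows])^2)))
    lab <- dense$segment[rows][pmax(1L, round(stats::approx(arc_d, seq_along(rows),
                                                            xout = rs$arc,
                                                            rule = 2)$y))]
    if (r == 2L) {
      lab[] <- "constant"
    } else {
      # only the shared boundary point is part of the constant segment;
      # stray nearest-arc hits next to it take the bridging label instead
      near <- if (config$gap_length > 0) "gap" else c("random1", "random2")[(r + 1L) / 2L]
      lab[lab == "constant"] <- near
      if (r == 1L) lab[length(lab)] <- "constant" else lab[1L] <- "constant"
    }
    rs$segment <- lab
    pieces[[r]] <- rs
  }
  # drop duplicated boundary points when concatenating
  out <- rbind(pieces[[1]], pieces[[2]][-1, ], pieces[[3]][-1, ])
  out <- data.frame(sample = seq_len(nrow(out)), x = out$x, y = out$y,
                    segment = out$segment, stringsAsFactors = FALSE)
  if (side == "left") out$x <- -out$x
  structure(out, class = c("pursuit_trajectory", "data.frame"),
            velocity = as.integer(velocity), side = side, speed = speed,
            trial = as.integer(trial), config = config)
}

#' Mirror a trajectory about the vertical center axis
#'
#' Flips the sign of x (origin is the screen center), turning a rightward
#' trial into its leftward twin and vice versa. Applying it twice is the
#' identity. All analysis results are invariant under mirroring.
#'
#' @param traj A \code{pursuit_trajectory}.
#' @return The mirrored trajectory with the \code{side} attribute flipped.
#' @export
mirror_trajectory <- function(traj) {
  traj$x <- -traj$x
  attr(traj, "side") <- if (identical(attr(traj, "side"), "left")) "right" else "left"
  traj
}

#' Generate a full counterbalanced session of target trajectories
#'
#' Crosses the three velocity levels with the two movement sides, repeats each
#' condition \code{n_repeats_per_condition} times and shuffles the trial order
#' under the session seed. Per-trial RNG substreams are derived from the
#' session seed and the trial's position in the condition list, so any single
#' trial can be regenerated without generating the others.
#'
#' @param config A \code{\link{trajectory_config}}; \code{config$seed} (or the
#'   \code{seed} argument) fixes the whole session.
#' @param seed Overrides \code{config$seed} when given.
#' @return List of \code{pursuit_trajectory} objects in presentation order,
#'   with attribute \code{conditions} (data frame of trial, velocity, side).
#' @export
generate_session <- function(config = trajectory_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 0L
  grid <- expand.grid(velocity = 1:3, side = c("right", "left"),
                      stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), config$n_repeats_per_condition), ]
  set.seed(seed)
  ord <- sample.int(nrow(grid))
  grid <- grid[ord, ]
  grid$trial <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  trials <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed((seed + 7919L * ord[i]) %% .Machine$integer.max)
    trials[[i]] <- build_trajectory(config, velocity = grid$velocity[i],
                                    side = grid$side[i], trial = grid$trial[i])
  }
  structure(trials, conditions = grid, seed = seed, config = config,
            class = "pursuit_trajectory_set")
}

#' @export
print.pursuit_trajectory <- function(x, ...) {
  cat(sprintf("Target trajectory: %d samples, velocity level %d (%.2f px/frame), side %s\n",
              nrow(x), attr(x, "velocity"), attr(x, "speed"), attr(x, "side")))
  cat(sprintf("  duration %.2f s at %g Hz; y range [%.1f, %.1f] px\n",
              nrow(x) / attr(x, "config")$frame_rate,
              attr(x, "config")$frame_rate, min(x$y), max(x$y)))
  invisible(x)
}

#' @export
print.pursuit_trajectory_set <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("Session of %d target trajectories (%d conditions x %d repeats), seed %s\n",
              length(x), nrow(unique(cond[c("velocity", "side")])),
              attr(x, "config")$n_repeats_per_condition, attr(x, "seed")))
  invisible(x)
}
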