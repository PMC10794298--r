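#' Synthetic pursuit model
#'
#' Parameters of a simple cursor-control model used to generate synthetic
#' pursuits with known ground truth: the cursor reproduces the target's
#' vertical course with a constant visuomotor lag (negative = lead), optional
#' gain and offset, small superimposed oscillation (joystick jitter below the
#' prominence threshold), Gaussian sample noise, and occasional missed target
#' reversals.
#'
#' @param lag Visuomotor lag in frames; negative values simulate anticipatory
#'   lead.
#' @param lag_jitter_sd Standard deviation of per-sample lag jitter, frames.
#' @param gain Multiplicative gain on the target's y course (default 1).
#' @param offset Constant vertical offset in pixels.
#' @param noise_sd Standard deviation of additive Gaussian noise, pixels.
#' @param jitter_amplitude Amplitude of a superimposed sinusoidal oscillation,
#'   pixels (prominence of the oscillation alone is twice the amplitude).
#' @param jitter_period Period of the oscillation in frames.
#' @param missed_reversal_prob Probability that a target direction change is
#'   missed; around a missed reversal the lag reference is frozen, producing
#'   the "false tracking" pattern of a participant who fails to react.
#' @param freeze_window Half-width in frames of the frozen region around a
#'   missed reversal (default 12).
#' @return Object of class \code{pursuit_model} (a list).
#' @export
pursuit_model <- function(lag = 9, lag_jitter_sd = 0, gain = 1, offset = 0,
                          noise_sd = 3, jitter_amplitude = 0,
                          jitter_period = 60, missed_reversal_prob = 0,
                          freeze_window = 12) {
  stopifnot(noise_sd >= 0, jitter_amplitude >= 0, jitter_period > 0,
            missed_reversal_prob >= 0, missed_reversal_prob <= 1,
            lag_jitter_sd >= 0, freeze_window >= 0)
  structure(list(lag = lag, lag_jitter_sd = lag_jitter_sd, gain = gain,
                 offset = offset, noise_sd = noise_sd,
                 jitter_amplitude = jitter_amplitude,
                 jitter_period = jitter_period,
                 missed_reversal_prob = missed_reversal_prob,
                 freeze_window = freeze_window),
            class = "pursuit_model")
}

#' Clamp a cursor series to the vertical screen bounds
#'
#' Full joystick deflection maps to the screen border, so simulated cursor
#' values are clipped to \code{[-height/2, height/2]} (origin at the screen
#' center). The number of clipped samples is recorded.
#'
#' @param y Numeric cursor y series, pixels.
#' @param screen_height Screen height in pixels (default 1080).
#' @return Clamped series with attribute \code{n_clipped}.
#' @export
clamp_to_screen <- function(y, screen_height = 1080) {
  half <- screen_height / 2
  n_clipped <- sum(y < -half | y > half)
  out <- pmin(pmax(y, -half), half)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Simulate a cursor pursuit of a target trajectory
#'
#' Generates a synchronized cursor series for a target trajectory under a
#' \code{\link{pursuit_model}}:
#' \code{cursor_y(t) = gain * target_y(t - lag + jitter_t) + offset +
#' oscillation + noise}, with the reference index held at the first/last
#' available sample at the trial boundaries (a participant resting at the
#' start position). The cursor's horizontal position is locked to the target
#' (\code{cursor_x = target_x}) as in the task apparatus.
#'
#' @param traj A \code{pursuit_trajectory} (or data frame with \code{x},
#'   \code{y}, \code{segment}).
#' @param model A \code{\link{pursuit_model}}.
#' @param seed Optional integer seed for reproducibility.
#' @param participant Participant id stored as metadata.
#' @return Object of class \code{pursuit_trial}: data frame with columns
#'   \code{sample}, \code{target_x}, \code{target_y}, \code{cursor_x},
#'   \code{cursor_y}, \code{segment}; attributes carry the condition metadata,
#'   the model, and the clip count.
#' @export
simulate_pursuit <- function(traj, model = pursuit_model(), seed = NULL,
                             participant = "sim") {
  n <- nrow(traj)
  stopifnot(abs(model$lag) < n)
  if (!is.null(seed)) set.seed(seed)
  jit <- if (model$lag_jitter_sd > 0) round(stats::rnorm(n, 0, model$lag_jitter_sd)) else 0
  ref <- seq_len(n) - round(model$lag) + jit
  ref <- pmin(pmax(ref, 1L), n)
  if (model$missed_reversal_prob > 0) {
    ext <- find_local_extrema(traj$y)
    if (nrow(ext)) {
      missed <- ext$index[stats::runif(nrow(ext)) < model$missed_reversal_prob]
      for (m in missed) {
        w <- model$freeze_window
        ref[ref >= m - w & ref <= m + w] <- max(1L, m - w)
      }
    }
  }
  osc <- if (model$jitter_amplitude > 0) {
    model$jitter_amplitude * sin(2 * pi * seq_len(n) / model$jitter_period)
  } else 0
  noise <- if (model$noise_sd > 0) stats::rnorm(n, 0, model$noise_sd) else 0
  cy <- model$gain * traj$y[ref] + model$offset + osc + noise
  cfg <- attr(traj, "config")
  height <- if (!is.null(cfg)) cfg$screen_size[2] else 1080
  cy <- clamp_to_screen(cy, height)
  out <- data.frame(sample = seq_len(n),
                    target_x = traj$x, target_y = traj$y,
                    cursor_x = traj$x, cursor_y = as.numeric(cy),
                    segment = traj$segment, stringsAsFactors = FALSE)
  structure(out, class = c("pursuit_trial", "data.frame"),
            velocity = attr(traj, "velocity"), side = attr(traj, "side"),
            speed = attr(traj, "speed"), trial = attr(traj, "trial"),
            participant = participant, model = model,
            n_clipped = attr(cy, "n_clipped"), config = cfg)
}

#' Inject a start offset into a trial
#'
#' Displaces the first cursor sample by \code{offset} pixels from the screen
#' center, decaying smoothly (raised-cosine) to the underlying pursuit over
#' \code{decay_frames} frames. Emulates a trial started with a deflected
#' joystick, the situation targeted by the 100-px start-position QC rule.
#'
#' @param trial A \code{pursuit_trial}.
#' @param offset Displacement of the first sample, pixels.
#' @param decay_frames Frames over which the displacement decays (default 60).
#' @return The modified trial.
#' @export
inject_start_offset <- function(trial, offset, decay_frames = 60) {
  if (offset == 0) return(trial)
  n <- min(decay_frames, nrow(trial))
  w <- (1 + cos(pi * (seq_len(n) - 1) / decay_frames)) / 2
  # anchor: first sample sits exactly at center + offset
  trial$cursor_y[1] <- offset
  if (n > 1) trial$cursor_y[2:n] <- trial$cursor_y[2:n] + offset * w[2:n]
  trial
}

#' Simulate pursuits for a whole session
#'
#' Applies \code{\link{simulate_pursuit}} to every trajectory of a generated
#' session, with per-trial seeds derived from \code{seed}.
#'
#' @param trajectories A \code{pursuit_trajectory_set} from
#'   \code{\link{generate_session}} (or a list of trajectories).
#' @param model A \code{\link{pursuit_model}}.
#' @param seed Integer seed for the session's noise streams.
#' @param participant Participant id stored on every trial.
#' @return A \code{pursuit_session} data frame (long format, one row per
#'   sample) as produced by \code{\link{as_session}}.
#' @export
simulate_session <- function(trajectories, model = pursuit_model(),
                             seed = 0L, participant = "sim") {
  trials <- lapply(seq_along(trajectories), function(i) {
    simulate_pursuit(trajectories[[i]], model,
                     seed = (seed + 104729L * i) %% .Machine$integer.max,
                     participant = participant)
  })
  as_session(trials)
}

#' @export
print.pursuit_trial <- function(x, ...) {
  cat(sprintf("Pursuit trial %s/%s: %d samples, velocity level %s, side %s\n",
              attr(x, "participant"), attr(x, "trial"), nrow(x),
              attr(x, "velocity"), attr(x, "side")))
  if (!is.null(attr(x, "n_clipped")) && attr(x, "n_clipped") > 0)
    cat(sprintf("  %d samples clipped at the screen border\n", attr(x, "n_clipped")))
  invisible(x)
}

#' @export
print.pursuit_model <- function(x, ...) {
  cat(sprintf("Pursuit model: lag %g frames, gain %g, offset %g px, noise sd %g px\n",
              x$lag, x$gain, x$offset, x$noise_sd))
  if (x$jitter_amplitude > 0)
    cat(sprintf("  oscillation: amplitude %g px, period %g frames\n",
                x$jitter_amplitude, x$jitter_period))
  if (x$missed_reversal_prob > 0)
    cat(sprintf("  missed reversal probability %g\n", x$missed_reversal_prob))
  invisible(x)
}
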