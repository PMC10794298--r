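#' Proximity measure between direction changes
#'
#' Euclidean distance between two screen points with the horizontal
#' difference weighted double, \code{sqrt((w * dx)^2 + dy^2)}. Because the
#' target moves at constant speed, horizontal distance is a proxy for time;
#' doubling it favors temporally close direction changes when matching cursor
#' to target extrema.
#'
#' @param px,py Coordinates of the first point (pixels); vectorized.
#' @param qx,qy Coordinates of the second point (pixels); vectorized.
#' @param x_weight Weight on the horizontal difference (default 2).
#' @return Non-negative distances in pixels.
#' @export
weighted_distance <- function(px, py, qx, qy, x_weight = 2) {
  sqrt((x_weight * (px - qx))^2 + (py - qy)^2)
}

#' Match cursor direction changes to target direction changes
#'
#' Implements the similarity and proximity assumptions: every cursor extremum
#' is paired with the target extremum of the same kind (maxima to maxima,
#' minima to minima) that minimizes the x-double-weighted distance
#' (\code{\link{weighted_distance}}). Matching is independent per cursor
#' extremum, so several cursor extrema may share a target extremum. A match is
#' labeled \emph{anticipatory} when the cursor direction change occurs
#' strictly before the matched target direction change, else \emph{adaptive}.
#' Matches whose target order is inconsistent with the cursor order are
#' flagged as crossed.
#'
#' @param cursor_extrema Data frame from \code{\link{detect_extrema}} on the
#'   cursor series.
#' @param target_extrema Data frame from \code{\link{detect_extrema}} on the
#'   target series.
#' @param cursor_x,target_x Full x series of cursor and target (pixels), used
#'   to place the extrema on screen.
#' @param x_weight Weight on the horizontal difference (default 2).
#' @return Data frame, one row per cursor extremum in index order, with
#'   columns \code{cursor_index}, \code{target_index}, \code{kind},
#'   \code{weighted_distance}, \code{label}
#'   ("anticipatory"/"adaptive") and \code{crossed}.
#' @export
match_extrema <- function(cursor_extrema, target_extrema,
                          cursor_x, target_x, x_weight = 2) {
  nc <- nrow(cursor_extrema)
  out <- data.frame(cursor_index = integer(nc), target_index = integer(nc),
                    kind = character(nc), weighted_distance = numeric(nc),
                    label = character(nc), crossed = logical(nc),
                    stringsAsFactors = FALSE)
  if (!nc) return(out)
  for (j in seq_len(nc)) {
    kind <- cursor_extrema$kind[j]
    cand <- target_extrema[target_extrema$kind == kind, , drop = FALSE]
    if (!nrow(cand)) {
      stop(sprintf("no target %s available to match cursor extremum at sample %d",
                   if (kind == "max") "maximum" else "minimum",
                   cursor_extrema$index[j]))
    }
    d <- weighted_distance(cursor_x[cursor_extrema$index[j]],
                           cursor_extrema$value[j],
                           target_x[cand$index], cand$value,
                           x_weight = x_weight)
    best <- which.min(d)  # earliest on ties
    out$cursor_index[j] <- cursor_extrema$index[j]
    out$target_index[j] <- cand$index[best]
    out$kind[j] <- kind
    out$weighted_distance[j] <- d[best]
    out$label[j] <- if (cursor_extrema$index[j] < cand$index[best])
      "anticipatory" else "adaptive"
  }
  if (nc > 1) {
    out$crossed <- c(FALSE, diff(out$target_index) < 0)
  }
  out
}

# Assign the intended trajectory sample to every pursuit sample.
# anchors: data.frame(cursor_index, target_index) including virtual anchors at
# the trial's first and last sample matched to the trajectory's first and last
# sample. Candidates for samples between consecutive cursor anchors are the
# inclusive run of trajectory samples between the two matched target indices
# (span-repaired with [min, max] if crossed); the intended sample minimizes
# plain Euclidean distance, earliest index on ties.
assign_intended <- function(trial, matches) {
  n <- nrow(trial)
  anchors <- data.frame(
    cursor_index = c(1L, matches$cursor_index, n),
    target_index = c(1L, matches$target_index, n))
  # collapse duplicated anchor positions (e.g. an extremum at sample 1)
  anchors <- anchors[!duplicated(anchors$cursor_index), , drop = FALSE]
  nk <- nrow(anchors)
  intended <- integer(n)
  dist <- numeric(n)
  interior <- logical(n)
  win_lo <- integer(n)
  win_hi <- integer(n)
  tx <- trial$target_x
  ty <- trial$target_y
  cx <- trial$cursor_x
  cy <- trial$cursor_y
  for (k in seq_len(nk - 1L)) {
    lo <- anchors$cursor_index[k]
    hi <- anchors$cursor_index[k + 1L]
    span <- if (k < nk - 1L) lo:(hi - 1L) else lo:hi
    w <- range(anchors$target_index[k:(k + 1L)])
    cand <- w[1]:w[2]
    stopifnot(length(cand) >= 1)
    dx <- outer(cx[span], tx[cand], "-")
    dy <- outer(cy[span], ty[cand], "-")
    d2 <- dx * dx + dy * dy
    best <- max.col(-d2, ties.method = "first")
    intended[span] <- cand[best]
    dist[span] <- sqrt(d2[cbind(seq_along(span), best)])
    interior[span] <- k > 1L && k < nk - 1L
    win_lo[span] <- w[1]
    win_hi[span] <- w[2]
  }
  data.frame(sample = seq_len(n), intended = intended,
             intended_x = tx[intended], intended_y = ty[intended],
             distance = dist,
             anticipated = intended > seq_len(n),  # ties are not anticipated
             interior = interior, window_lo = win_lo, window_hi = win_hi)
}

#' Estimate the intended trajectory and tracking errors for one trial
#'
#' The core fitting function. Direction changes of target and cursor are
#' detected (\code{\link{detect_extrema}}; the cursor with a prominence
#' criterion), cursor extrema are matched to same-kind target extrema by the
#' x-double-weighted proximity rule (\code{\link{match_extrema}}), and every
#' pursuit sample is then assigned its intended trajectory sample: the sample,
#' among the trajectory run enclosed by the matched extrema surrounding the
#' pursuit sample, closest in plain Euclidean distance. Samples before the
#' first and after the last cursor extremum are anchored to the trial's first
#' and last sample so that every pursuit sample receives an assignment.
#'
#' Two error series result: the \emph{temporal} error
#' \code{|cursor_y - target_y|} per frame, and the \emph{spatial} error, the
#' Euclidean distance to the intended trajectory sample. A sample is
#' \emph{anticipated} when its intended sample lies strictly later in time.
#'
#' @param trial A \code{pursuit_trial} (or data frame with columns
#'   \code{target_x}, \code{target_y}, \code{cursor_x}, \code{cursor_y} and
#'   optionally \code{segment}).
#' @param min_prominence Minimum prominence for cursor direction changes,
#'   pixels (default 20; see \code{\link{default_prominence}}).
#' @param x_weight Horizontal weight of the proximity measure (default 2).
#' @return Object of class \code{track}, a list with elements \code{trial},
#'   \code{target_extrema}, \code{cursor_extrema}, \code{matches},
#'   \code{assignments}, \code{temporal} and \code{spatial} error series,
#'   and \code{control} (the parameters used). Supports \code{print},
#'   \code{summary}, \code{coef}, \code{plot}, \code{residuals},
#'   \code{fitted}, \code{predict} and \code{simulate}.
#' @examples
#' traj <- build_trajectory(trajectory_config(seed = 1), velocity = 2,
#'                          coefficients = list(
#'                            list(a = c(30, 5, -20), b = c(0, 10, -10)),
#'                            NULL,
#'                            list(a = c(-25, 15, 5), b = c(5, -30, 10))))
#' trial <- simulate_pursuit(traj, pursuit_model(lag = 6, noise_sd = 3), seed = 1)
#' fit <- track(trial)
#' coef(fit)
#' @export
track <- function(trial, min_prominence = 20, x_weight = 2) {
  need <- c("target_x", "target_y", "cursor_x", "cursor_y")
  miss <- setdiff(need, names(trial))
  if (length(miss)) stop("trial is missing column(s): ", paste(miss, collapse = ", "))
  if (!"segment" %in% names(trial)) trial$segment <- "trial"
  if (any(trial$cursor_x != trial$target_x)) {
    warning("cursor_x differs from target_x; analysis assumes x-locked cursor motion")
  }
  target_extrema <- detect_extrema(trial$target_y, min_prominence = 0)
  cursor_extrema <- detect_extrema(trial$cursor_y, min_prominence = min_prominence)
  matches <- match_extrema(cursor_extrema, target_extrema,
                           trial$cursor_x, trial$target_x, x_weight = x_weight)
  assignments <- assign_intended(trial, matches)
  structure(list(trial = trial,
                 target_extrema = target_extrema,
                 cursor_extrema = cursor_extrema,
                 matches = matches,
                 assignments = assignments,
                 temporal = abs(trial$cursor_y - trial$target_y),
                 spatial = assignments$distance,
                 control = list(min_prominence = min_prominence,
                                x_weight = x_weight)),
            class = "track")
}

#' Visuomotor lag implied by a fit
#'
#' Two estimators of the lag between cursor and target, in frames.
#' \code{method = "matches"} (recommended) takes the median index gap between
#' matched cursor and target direction changes: for a pure-delay pursuit it
#' recovers the delay exactly. \code{method = "assignment"} takes the median
#' index gap between pursuit samples and their intended trajectory samples
#' over interior samples; because the intended sample is the spatially nearest
#' trajectory point, this estimate is attenuated on shallow trajectory slopes
#' (see the package vignette) and is mainly useful as a per-sample series.
#'
#' @param fit A \code{track} fit.
#' @param method "matches" or "assignment".
#' @return Lag in frames (positive = cursor behind target).
#' @export
track_lag <- function(fit, method = c("matches", "assignment")) {
  method <- match.arg(method)
  if (method == "matches") {
    if (!nrow(fit$matches)) return(NA_real_)
    stats::median(fit$matches$cursor_index - fit$matches$target_index)
  } else {
    a <- fit$assignments
    a <- a[a$interior, , drop = FALSE]
    if (!nrow(a)) return(NA_real_)
    stats::median(a$sample - a$intended)
  }
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("Intended-trajectory fit: %d samples\n", nrow(x$trial)))
  cat(sprintf("  direction changes: %d target, %d cursor (prominence >= %g px), %d matches (%d crossed)\n",
              nrow(x$target_extrema), nrow(x$cursor_extrema),
              x$control$min_prominence, nrow(x$matches), sum(x$matches$crossed)))
  cat(sprintf("  temporal error %.2f px (mean), spatial error %.2f px (mean), anticipation rate %.3f\n",
              mean(x$temporal), mean(x$spatial), mean(x$assignments$anticipated)))
  invisible(x)
}

#' @export
coef.track <- function(object, ...) {
  c(lag = track_lag(object, "matches"),
    lag_assignment = track_lag(object, "assignment"),
    anticipation_rate = mean(object$assignments$anticipated),
    temporal_mean = mean(object$temporal),
    temporal_rmse = sqrt(mean(object$temporal^2)),
    spatial_mean = mean(object$spatial))
}

#' @export
residuals.track <- function(object, type = c("spatial", "temporal"), ...) {
  type <- match.arg(type)
  if (type == "spatial") object$spatial else object$temporal
}

#' @export
fitted.track <- function(object, ...) {
  object$assignments[c("sample", "intended", "intended_x", "intended_y")]
}

#' @export
predict.track <- function(object, ...) fitted(object)

#' @export
simulate.track <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lag <- round(track_lag(object, "matches"))
  if (is.na(lag)) lag <- 0
  n <- nrow(object$trial)
  ref <- pmin(pmax(seq_len(n) - lag, 1L), n)
  sd_hat <- stats::sd(object$trial$cursor_y - object$trial$target_y[ref])
  traj <- data.frame(x = object$trial$target_x, y = object$trial$target_y,
                     segment = object$trial$segment)
  lapply(seq_len(nsim), function(i) {
    simulate_pursuit(traj, pursuit_model(lag = lag, noise_sd = sd_hat))
  })
}

#' @export
plot.track <- function(x, which = c(1, 2), ...) {
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::plot(x$trial$target_x, x$trial$target_y, type = "l",
                   xlab = "x (px)", ylab = "y (px)",
                   main = "Target, pursuit and matched direction changes", ...)
    graphics::lines(x$trial$cursor_x, x$trial$cursor_y, col = "grey50")
    m <- x$matches
    if (nrow(m)) {
      cols <- ifelse(m$label == "anticipatory", "forestgreen", "firebrick")
      graphics::segments(x$trial$cursor_x[m$cursor_index],
                         x$trial$cursor_y[m$cursor_index],
                         x$trial$target_x[m$target_index],
                         x$trial$target_y[m$target_index], col = cols)
    }
    graphics::legend("topright", lty = 1, bty = "n",
                     col = c("black", "grey50", "forestgreen", "firebrick"),
                     legend = c("target", "cursor", "anticipatory match",
                                "adaptive match"))
  }
  if (2 %in% which) {
    graphics::plot(x$temporal, type = "l", col = "steelblue",
                   xlab = "sample", ylab = "error (px)",
                   main = "Temporal (blue) and spatial (red) tracking error",
                   ylim = range(0, x$temporal, x$spatial))
    graphics::lines(x$spatial, col = "firebrick")
  }
  invisible(x)
}
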