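#' Per-sample temporal tracking error
#'
#' The classical tracking error: absolute vertical deviation of cursor and
#' target compared at the same frame, \code{|cursor_y(t) - target_y(t)|}.
#' Well-defined because the cursor's horizontal position is locked to the
#' target.
#'
#' @param trial A \code{pursuit_trial} or data frame with \code{cursor_y} and
#'   \code{target_y}.
#' @return Non-negative numeric vector, one value per sample.
#' @export
temporal_error <- function(trial) {
  abs(trial$cursor_y - trial$target_y)
}

#' Reduce an error series to a single trial value
#'
#' Arithmetic mean or root-mean-square of a per-sample error series. Both
#' reducers are reported side by side in summaries; the RMS value is never
#' smaller than the mean.
#'
#' @param errors Non-empty numeric series of per-sample errors (pixels).
#' @param reducer "mean" or "rmse".
#' @return Single value in pixels.
#' @export
error_reduce <- function(errors, reducer = c("mean", "rmse")) {
  reducer <- match.arg(reducer)
  if (!length(errors)) stop("empty error series")
  if (reducer == "mean") mean(errors) else sqrt(mean(errors^2))
}

#' Anticipation rate
#'
#' Fraction of pursuit samples whose intended trajectory sample lies strictly
#' later in time (feedforward control); the complement reflects adaptive,
#' feedback-driven tracking.
#'
#' @param fit A \code{track} fit.
#' @param by "trial" for one overall rate, or "segment" for one rate per
#'   trajectory segment (gap samples counted with the adjacent random
#'   segment).
#' @return A fraction in [0, 1], or a named vector of fractions.
#' @export
anticipation_rate <- function(fit, by = c("trial", "segment")) {
  by <- match.arg(by)
  ant <- fit$assignments$anticipated
  if (by == "trial") return(mean(ant))
  seg <- merge_gap_labels(fit$trial$segment)
  tapply(ant, seg, mean)
}

# Gap (spline bridge) samples inherit the label of the adjacent random
# segment, keeping the constant segment uncontaminated: the gap before the
# constant segment counts as random1, the gap after it as random2.
merge_gap_labels <- function(segment) {
  out <- segment
  gap <- which(segment == "gap")
  if (length(gap)) {
    first_const <- which(segment == "constant")[1]
    out[gap] <- ifelse(is.na(first_const) | gap < first_const, "random1", "random2")
  }
  out
}

#' Per-segment error summary of one fit
#'
#' Mean (and RMS) temporal error, mean spatial error and anticipation rate for
#' each trajectory segment, for the two random segments averaged
#' (\code{random_avg}, the mean of the random1 and random2 values) and for the
#' whole trial. Gap samples inherit the adjacent random segment's label.
#'
#' @param fit A \code{track} fit whose trial carries segment labels.
#' @return Data frame with one row per scope (\code{random1},
#'   \code{constant}, \code{random2}, \code{random_avg}, \code{trial}) and
#'   columns \code{n}, \code{temporal_mean}, \code{temporal_rmse},
#'   \code{spatial_mean}, \code{spatial_rmse}, \code{anticipation_rate}.
#' @export
segment_summary <- function(fit) {
  if (is.null(fit$trial$segment))
    stop("trial has no 'segment' column; segment summaries need segment labels")
  seg <- merge_gap_labels(fit$trial$segment)
  scopes <- intersect(c("random1", "constant", "random2"), unique(seg))
  one <- function(idx) {
    data.frame(n = length(idx),
               temporal_mean = mean(fit$temporal[idx]),
               temporal_rmse = sqrt(mean(fit$temporal[idx]^2)),
               spatial_mean = mean(fit$spatial[idx]),
               spatial_rmse = sqrt(mean(fit$spatial[idx]^2)),
               anticipation_rate = mean(fit$assignments$anticipated[idx]))
  }
  rows <- lapply(scopes, function(s) one(which(seg == s)))
  out <- do.call(rbind, rows)
  out <- cbind(segment = scopes, out, stringsAsFactors = FALSE)
  if (all(c("random1", "random2") %in% scopes)) {
    r <- out[out$segment %in% c("random1", "random2"), ]
    avg <- data.frame(segment = "random_avg", n = sum(r$n),
                      temporal_mean = mean(r$temporal_mean),
                      temporal_rmse = mean(r$temporal_rmse),
                      spatial_mean = mean(r$spatial_mean),
                      spatial_rmse = mean(r$spatial_rmse),
                      anticipation_rate = mean(r$anticipation_rate),
                      stringsAsFactors = FALSE)
    out <- rbind(out, avg)
  }
  whole <- cbind(segment = "trial", one(seq_len(nrow(fit$trial))),
                 stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, whole)
}

#' Assign trials to contiguous blocks
#'
#' Retrospectively partitions the trials of a session, in presentation order,
#' into \code{n_blocks} contiguous near-equal groups (sizes differ by at most
#' one, earlier blocks take the remainder) for practice-effect analyses.
#'
#' @param n_trials Number of trials (or a vector whose length is used).
#' @param n_blocks Number of blocks (default 3).
#' @return Integer vector of block ids (1..n_blocks), non-decreasing.
#' @export
assign_blocks <- function(n_trials, n_blocks = 3) {
  if (length(n_trials) > 1) n_trials <- length(n_trials)
  stopifnot(n_blocks >= 1)
  if (n_blocks > n_trials) stop("more blocks than trials")
  base <- n_trials %/% n_blocks
  extra <- n_trials %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, extra), rep(0L, n_blocks - extra))
  rep(seq_len(n_blocks), times = sizes)
}

#' Start-position QC flag
#'
#' A trial is flagged when the cursor starts more than \code{threshold}
#' pixels (strictly) away from the vertical screen center, indicating a
#' deflected joystick at trial onset. The flag is advisory: exclusion
#' additionally requires visual confirmation.
#'
#' @param trial A \code{pursuit_trial}.
#' @param threshold Pixels (default 100).
#' @param center_y Vertical screen-center coordinate (default 0, the package's
#'   centered coordinate convention).
#' @return Logical flag.
#' @export
qc_start_offset <- function(trial, threshold = 100, center_y = 0) {
  abs(trial$cursor_y[1] - center_y) > threshold
}

#' Outlier-trial QC flags
#'
#' Flags trials whose maximum temporal error exceeds the mean plus
#' \code{n_sd} standard deviations of the per-trial maximum temporal errors,
#' pooled across every trial of the dataset (all participants present in the
#' run). Flags are advisory; exclusion requires visual confirmation of each
#' flagged trial.
#'
#' @param max_errors Numeric vector of per-trial maximum temporal errors for
#'   the whole dataset (at least 3 trials).
#' @param n_sd Number of standard deviations (default 3).
#' @return Logical vector of flags, invariant under trial reordering.
#' @export
qc_outlier_trials <- function(max_errors, n_sd = 3) {
  if (length(max_errors) < 3)
    stop("need at least 3 trials to estimate the outlier threshold")
  max_errors > mean(max_errors) + n_sd * stats::sd(max_errors)
}

#' Analyze a whole session
#'
#' Fits \code{\link{track}} to every trial of a session, assigns trial blocks,
#' computes QC flags (start offset per trial; outliers pooled across the whole
#' dataset) and builds a tidy summary table with one row per trial and scope
#' (segments, averaged random, whole trial) ready for any downstream
#' statistics package.
#'
#' @param session A \code{pursuit_session} data frame (see
#'   \code{\link{read_session}} / \code{\link{as_session}}).
#' @param min_prominence Cursor prominence threshold in pixels (default 20).
#' @param x_weight Horizontal weight of the proximity measure (default 2).
#' @param n_blocks Number of trial blocks (default 3).
#' @param start_offset_threshold Start-position QC threshold in pixels
#'   (default 100).
#' @param outlier_sd Outlier QC threshold in standard deviations (default 3).
#' @return Object of class \code{track_session}: list with \code{fits} (one
#'   \code{track} per trial), \code{summary} (the tidy table) and
#'   \code{trials} (per-trial metadata with QC flags and an empty
#'   \code{visually_confirmed_exclusion} column -- exclusion is never
#'   automatic).
#' @export
track_session <- function(session, min_prominence = 20, x_weight = 2,
                          n_blocks = 3, start_offset_threshold = 100,
                          outlier_sd = 3) {
  trials <- split_trials(session)
  fits <- lapply(trials, track, min_prominence = min_prominence,
                 x_weight = x_weight)
  meta <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant = as.character(attr(tr, "participant")),
               trial = as.integer(attr(tr, "trial")),
               velocity = attr(tr, "velocity"),
               side = attr(tr, "side"), stringsAsFactors = FALSE)
  }))
  # blocks per participant, in presentation order
  meta$block <- NA_integer_
  for (p in unique(meta$participant)) {
    i <- which(meta$participant == p)
    meta$block[i[order(meta$trial[i])]] <- assign_blocks(length(i), n_blocks)
  }
  meta$qc_start_offset <- vapply(trials, qc_start_offset, logical(1),
                                 threshold = start_offset_threshold)
  max_err <- vapply(fits, function(f) max(f$temporal), numeric(1))
  meta$max_temporal_error <- max_err
  meta$qc_outlier <- qc_outlier_trials(max_err, n_sd = outlier_sd)
  meta$visually_confirmed_exclusion <- FALSE
  rownames(meta) <- NULL

  summ <- do.call(rbind, lapply(seq_along(fits), function(i) {
    s <- segment_summary(fits[[i]])
    cbind(meta[rep(i, nrow(s)), c("participant", "trial", "velocity", "side",
                                  "block", "qc_start_offset", "qc_outlier")],
          s, row.names = NULL)
  }))
  structure(list(fits = fits, summary = summ, trials = meta),
            class = "track_session")
}

#' @export
print.track_session <- function(x, ...) {
  cat(sprintf("Session analysis: %d trials, %d participant(s)\n",
              nrow(x$trials), length(unique(x$trials$participant))))
  tr <- x$summary[x$summary$segment == "trial", ]
  cat(sprintf("  temporal error %.2f px, spatial error %.2f px (trial means), anticipation rate %.3f\n",
              mean(tr$temporal_mean), mean(tr$spatial_mean),
              mean(tr$anticipation_rate)))
  cat(sprintf("  QC: %d start-offset flag(s), %d outlier flag(s)\n",
              sum(x$trials$qc_start_offset), sum(x$trials$qc_outlier)))
  invisible(x)
}

#' @export
summary.track_session <- function(object, ...) {
  s <- object$summary
  agg <- stats::aggregate(
    s[c("temporal_mean", "temporal_rmse", "spatial_mean", "anticipation_rate")],
    by = list(segment = s$segment, block = s$block), FUN = mean)
  agg[order(agg$segment, agg$block), ]
}
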