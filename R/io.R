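session_columns <- c("participant", "trial", "velocity", "side", "sample",
                     "target_x", "target_y", "cursor_x", "cursor_y", "segment")

#' Combine trials into a session table
#'
#' Stacks \code{pursuit_trial} objects into one long-format data frame, the
#' package's single interchange layout (one row per sample), so simulated and
#' recorded data are handled identically.
#'
#' @param trials List of \code{pursuit_trial} objects.
#' @return A \code{pursuit_session} data frame with columns
#'   \code{participant, trial, velocity, side, sample, target_x, target_y,
#'   cursor_x, cursor_y, segment}.
#' @export
as_session <- function(trials) {
  rows <- lapply(trials, function(tr) {
    data.frame(participant = as.character(attr(tr, "participant") %||% "p1"),
               trial = as.integer(attr(tr, "trial") %||% 1L),
               velocity = as.integer(attr(tr, "velocity") %||% NA_integer_),
               side = as.character(attr(tr, "side") %||% "right"),
               sample = tr$sample,
               target_x = tr$target_x, target_y = tr$target_y,
               cursor_x = tr$cursor_x, cursor_y = tr$cursor_y,
               segment = tr$segment, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pursuit_session", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a session table into trials
#'
#' @param session A \code{pursuit_session} data frame.
#' @return List of \code{pursuit_trial} objects in (participant, trial)
#'   order, metadata restored as attributes.
#' @export
split_trials <- function(session) {
  key <- interaction(session$participant, session$trial, drop = TRUE)
  parts <- split(seq_len(nrow(session)), key)
  # preserve presentation order within participant
  ord <- order(vapply(parts, function(i) session$participant[i[1]], character(1)),
               vapply(parts, function(i) session$trial[i[1]], numeric(1)))
  lapply(parts[ord], function(i) {
    d <- session[i, c("sample", "target_x", "target_y", "cursor_x", "cursor_y",
                      "segment")]
    rownames(d) <- NULL
    structure(d, class = c("pursuit_trial", "data.frame"),
              participant = session$participant[i[1]],
              trial = session$trial[i[1]],
              velocity = session$velocity[i[1]],
              side = session$side[i[1]])
  })
}

#' Read a session CSV
#'
#' Reads and validates the package's interchange format: required columns
#' present, numeric coordinates, samples contiguous and sorted within each
#' trial, cursor x locked to target x (a violation is downgraded to a warning,
#' with the cursor x kept as authoritative for genuinely two-dimensional
#' data).
#'
#' @param path Path to a CSV file.
#' @return A \code{pursuit_session} data frame.
#' @export
read_session <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(session_columns, names(d))
  if (length(miss))
    stop("session file is missing column(s): ", paste(miss, collapse = ", "))
  num <- c("sample", "target_x", "target_y", "cursor_x", "cursor_y")
  for (cn in num) {
    if (!is.numeric(d[[cn]])) stop("non-numeric values in column '", cn, "'")
  }
  key <- interaction(d$participant, d$trial, drop = TRUE)
  for (k in levels(key)) {
    s <- d$sample[key == k]
    if (!length(s)) stop("empty trial ", k)
    if (any(diff(s) != 1))
      stop("samples not contiguous/sorted in trial ", k)
  }
  if (any(d$cursor_x != d$target_x))
    warning("cursor_x differs from target_x; treating cursor_x as authoritative")
  d <- d[session_columns]
  class(d) <- c("pursuit_session", "data.frame")
  d
}

# shared fixed-precision CSV writer: UTF-8, '.' decimal, no row names,
# numeric columns at 6 significant digits -> byte-identical reruns
write_table_fixed <- function(d, path) {
  for (cn in names(d)) {
    if (is.numeric(d[[cn]]) && !is.integer(d[[cn]]))
      d[[cn]] <- signif(d[[cn]], 6)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a session CSV
#'
#' @param session A \code{pursuit_session} data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_session <- function(session, path) {
  write_table_fixed(session[session_columns], path)
}

#' Write the per-sample error table of a session analysis
#'
#' One row per pursuit sample: temporal and spatial error, intended sample
#' index and coordinates, anticipation flag.
#'
#' @param fit A \code{track_session} (or single \code{track}) object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_errors <- function(fit, path) {
  fits <- if (inherits(fit, "track_session")) fit$fits else list(fit)
  meta <- if (inherits(fit, "track_session")) fit$trials else NULL
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    a <- f$assignments
    d <- data.frame(participant = if (is.null(meta)) "p1" else meta$participant[i],
                    trial = if (is.null(meta)) 1L else meta$trial[i],
                    sample = a$sample, segment = f$trial$segment,
                    temporal_error = f$temporal, spatial_error = f$spatial,
                    intended = a$intended, intended_x = a$intended_x,
                    intended_y = a$intended_y, anticipated = a$anticipated,
                    stringsAsFactors = FALSE)
    d
  })
  write_table_fixed(do.call(rbind, rows), path)
}

#' Write the tidy per-trial/per-segment summary table
#'
#' @param fit A \code{track_session} object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary <- function(fit, path) {
  stopifnot(inherits(fit, "track_session"))
  write_table_fixed(fit$summary, path)
}

#' Read a run configuration file
#'
#' Flat key-value YAML or JSON with fields mirroring
#' \code{\link{trajectory_config}}, \code{\link{pursuit_model}} and the
#' analysis thresholds (\code{min_prominence},
#' \code{start_offset_threshold}, \code{outlier_sd}, \code{n_blocks},
#' \code{seed}).
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return Named list of parameters.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config file must be YAML (.yaml/.yml) or JSON (.json)")
  }
}
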