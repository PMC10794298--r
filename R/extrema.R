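#' Find strict local extrema of a series
#'
#' A direction change is a sample strictly greater (local maximum) or strictly
#' smaller (local minimum) than both neighbors. Plateaus (runs of equal
#' values) are collapsed to a single candidate at the plateau midpoint before
#' the strict comparison, so integer-pixel joystick data with flat tops yield
#' one extremum per plateau. Endpoints are never extrema. Returned extrema
#' strictly alternate between maxima and minima.
#'
#' @param y Numeric series of at least 3 samples.
#' @return Data frame with columns \code{index}, \code{kind} ("max"/"min")
#'   and \code{value}, in index order.
#' @export
find_local_extrema <- function(y) {
  if (length(y) < 3) stop("need at least 3 samples to detect direction changes")
  r <- rle(y)
  m <- length(r$values)
  if (m < 3) return(data.frame(index = integer(), kind = character(),
                               value = numeric(), stringsAsFactors = FALSE))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  j <- 2:(m - 1)
  is_max <- v[j] > v[j - 1] & v[j] > v[j + 1]
  is_min <- v[j] < v[j - 1] & v[j] < v[j + 1]
  keep <- j[is_max | is_min]
  if (!length(keep)) return(data.frame(index = integer(), kind = character(),
                                       value = numeric(), stringsAsFactors = FALSE))
  idx <- as.integer(floor((starts[keep] + ends[keep]) / 2))
  data.frame(index = idx,
             kind = ifelse(v[keep] > v[keep - 1], "max", "min"),
             value = v[keep], stringsAsFactors = FALSE)
}

#' Topographic prominence of an extremum
#'
#' How distinct a peak is: for a maximum, its value minus the higher of the
#' two lowest values encountered walking left and right until a strictly
#' higher sample (or the end of the series) is reached. Minima are handled on
#' the negated series. An isolated global extremum therefore gets its
#' height above the higher of the two boundary-side minima.
#'
#' @param y Numeric series.
#' @param index Integer vector of extremum sample indices.
#' @param kind Character vector, "max" or "min", recycled to match
#'   \code{index}.
#' @return Numeric vector of prominences (pixels), all non-negative.
#' @export
peak_prominence <- function(y, index, kind) {
  kind <- rep_len(kind, length(index))
  n <- length(y)
  vapply(seq_along(index), function(k) {
    s <- if (kind[k] == "max") y else -y
    i <- index[k]
    v <- s[i]
    lmin <- v
    p <- i - 1L
    while (p >= 1L && s[p] <= v) { if (s[p] < lmin) lmin <- s[p]; p <- p - 1L }
    rmin <- v
    p <- i + 1L
    while (p <= n && s[p] <= v) { if (s[p] < rmin) rmin <- s[p]; p <- p + 1L }
    v - max(lmin, rmin)
  }, numeric(1))
}

#' Detect direction changes with a prominence criterion
#'
#' Finds all strict local extrema and computes their topographic prominence,
#' keeping those with prominence at or above \code{min_prominence}. For the
#' smooth target trajectory no filtering is needed
#' (\code{min_prominence = 0}); for the cursor, small joystick fluctuations
#' are rejected with the default 20 px threshold (about 2\% of a 1080-px
#' screen height).
#'
#' @param y Numeric series.
#' @param min_prominence Minimum prominence in pixels (default 0, no filter).
#' @return Data frame with columns \code{index}, \code{kind}, \code{value},
#'   \code{prominence}.
#' @export
detect_extrema <- function(y, min_prominence = 0) {
  stopifnot(min_prominence >= 0)
  ext <- find_local_extrema(y)
  if (!nrow(ext)) {
    ext$prominence <- numeric(0)
    return(ext)
  }
  ext$prominence <- peak_prominence(y, ext$index, ext$kind)
  ext[ext$prominence >= min_prominence, , drop = FALSE]
}

#' Suggested prominence threshold for a screen height
#'
#' The cursor prominence criterion scales with the display: about 2\% of the
#' vertical screen extent (cursor control is vertical). For the reference
#' 1080-px screen this suggests 21.6 px; the shipped default threshold is the
#' round 20 px.
#'
#' @param screen_height Screen height in pixels.
#' @param fraction Fraction of the screen height (default 0.02).
#' @return Suggested threshold in pixels.
#' @export
default_prominence <- function(screen_height, fraction = 0.02) {
  stopifnot(screen_height > 0, fraction >= 0)
  fraction * screen_height
}
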