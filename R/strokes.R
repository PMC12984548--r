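#' Segment a trajectory into strokes and in-air movements
#'
#' A stroke is a maximal run of consecutive on-paper samples
#' (`pen_status == 1`); an in-air segment is a maximal run of in-air
#' samples. Each stroke also records the first in-air sample that follows
#' it (the pen-up point), absent when the recording ends on paper.
#'
#' @param trajectory A `pen_trajectory` (may be empty).
#' @return A tibble of class `stroke_set`, one row per segment in temporal
#'   order: `segment` (index), `on_paper` (logical), `samples` (list-column
#'   of sample tibbles), start/end coordinates, centroid coordinates, and
#'   for strokes the following air point (`air_x`, `air_y`, NA when
#'   absent). The stroke count S is `sum(on_paper)`.
#' @export
segment_strokes <- function(trajectory) {
  if (nrow(trajectory) == 0L) {
    out <- tibble::tibble(
      segment = integer(), on_paper = logical(), samples = list(),
      n = integer(), start_x = numeric(), start_y = numeric(),
      end_x = numeric(), end_y = numeric(),
      centroid_x = numeric(), centroid_y = numeric(),
      air_x = numeric(), air_y = numeric()
    )
    class(out) <- c("stroke_set", class(out))
    return(out)
  }
  state <- trajectory$pen_status
  run_id <- cumsum(c(1L, as.integer(diff(state) != 0L)))
  idx <- split(seq_len(nrow(trajectory)), run_id)
  segs <- purrr::imap(idx, function(rows, id) {
    s <- trajectory[rows, , drop = FALSE]
    after <- rows[length(rows)] + 1L
    is_stroke <- state[rows[1]] == 1L
    air <- c(NA_real_, NA_real_)
    if (is_stroke && after <= nrow(trajectory)) {
      # first sample after a stroke is in-air by run maximality
      air <- c(trajectory$x[after], trajectory$y[after])
    }
    tibble::tibble(
      segment = as.integer(id), on_paper = is_stroke, samples = list(s),
      n = nrow(s),
      start_x = s$x[1], start_y = s$y[1],
      end_x = s$x[nrow(s)], end_y = s$y[nrow(s)],
      centroid_x = mean(s$x), centroid_y = mean(s$y),
      air_x = air[1], air_y = air[2]
    )
  })
  out <- dplyr::bind_rows(segs) |> dplyr::arrange(.data$segment)
  class(out) <- c("stroke_set", class(out))
  out
}

#' Stroke count of a stroke set
#' @param stroke_set A [segment_strokes()] result.
#' @return Integer number of on-paper strokes.
#' @export
n_strokes <- function(stroke_set) sum(stroke_set$on_paper)

#' Consecutive-sample difference series
#'
#' First differences of coordinates, pressure and time between
#' consecutive samples of a trajectory, plus the instantaneous Euclidean
#' speed on intervals with positive time step. Time differences are in
#' seconds (timestamps are milliseconds).
#'
#' @param trajectory A `pen_trajectory` with at least one sample.
#' @return A tibble with one row per interval: `dx`, `dy`, `dz`, `dt`
#'   (s), `dist` (planar step length), `speed` (units/s, NA where
#'   `dt <= 0`). Attributes: `m` (count of valid-speed intervals) and
#'   `k_slopes` (count of intervals with `dx != 0`).
#' @export
diff_series <- function(trajectory) {
  n <- nrow(trajectory)
  if (n < 1L) stop("diff_series needs at least one sample", call. = FALSE)
  if (n == 1L) {
    d <- tibble::tibble(dx = numeric(), dy = numeric(), dz = numeric(),
                        dt = numeric(), dist = numeric(), speed = numeric())
    attr(d, "m") <- 0L
    attr(d, "k_slopes") <- 0L
    return(d)
  }
  dx <- diff(trajectory$x)
  dy <- diff(trajectory$y)
  dz <- diff(trajectory$pressure)
  dt <- diff(trajectory$timestamp) / 1000
  dist <- sqrt(dx^2 + dy^2)
  speed <- ifelse(dt > 0, dist / dt, NA_real_)
  d <- tibble::tibble(dx = dx, dy = dy, dz = dz, dt = dt,
                      dist = dist, speed = speed)
  attr(d, "m") <- sum(!is.na(speed))
  attr(d, "k_slopes") <- sum(dx != 0)
  d
}

#' Mean and sample standard deviation of a signal
#'
#' The shared summary used by the variability and signal-to-noise
#' descriptors: arithmetic mean and sample (n - 1) standard deviation.
#' Inputs with fewer than two finite values are flagged undefined rather
#' than raising an error.
#'
#' @param values Numeric vector; non-finite values are dropped.
#' @return A list with `mean`, `sd`, `n` and `defined` (logical).
#' @export
signal_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, n = 0L, defined = FALSE))
  }
  if (n == 1L) {
    return(list(mean = values, sd = NA_real_, n = 1L, defined = FALSE))
  }
  list(mean = mean(values), sd = stats::sd(values), n = n, defined = TRUE)
}
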