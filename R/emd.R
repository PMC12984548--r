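#' First intrinsic mode function by empirical mode decomposition
#'
#' Extracts the highest-frequency oscillatory component (IMF1) of a
#' discrete signal by standard envelope sifting: strict local maxima and
#' minima are bridged by cubic-spline envelopes (boundary behaviour
#' stabilised by mirroring the outermost extrema about the signal ends),
#' the envelope mean is subtracted, and sifting repeats until a
#' Cauchy-type criterion SD = sum((h_prev - h)^2) / sum(h_prev^2) falls
#' below `sd_threshold` or `max_sifts` is reached.
#'
#' Plateaus of tied values (common with integer tablet coordinates) count
#' as a single extremum located at the first sample of the run.
#'
#' @param signal Numeric vector.
#' @param sd_threshold Stopping threshold (default 0.2).
#' @param max_sifts Iteration cap (default 100).
#' @return A list with `imf1` (same length as input, or NULL when the
#'   decomposition is undefined), `n_sifts`, `converged` and `defined`.
#'   Signals shorter than 4 samples or without both an interior maximum
#'   and minimum (monotone/constant signals) are undefined.
#' @export
emd_first_imf <- function(signal, sd_threshold = 0.2, max_sifts = 100L) {
  undefined <- list(imf1 = NULL, n_sifts = 0L, converged = FALSE, defined = FALSE)
  n <- length(signal)
  if (n < 4L || any(!is.finite(signal))) return(undefined)
  h <- as.numeric(signal)
  t_idx <- seq_len(n)
  n_sifts <- 0L
  converged <- FALSE
  while (n_sifts < max_sifts) {
    ext <- local_extrema(h)
    if (length(ext$max) < 1L || length(ext$min) < 1L) {
      if (n_sifts == 0L) return(undefined)
      break
    }
    upper <- mirrored_envelope(t_idx, ext$max, h[ext$max], n)
    lower <- mirrored_envelope(t_idx, ext$min, h[ext$min], n)
    m <- (upper + lower) / 2
    h_new <- h - m
    n_sifts <- n_sifts + 1L
    denom <- sum(h^2)
    sd_crit <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (sd_crit < sd_threshold) {
      converged <- TRUE
      break
    }
  }
  list(imf1 = h, n_sifts = n_sifts, converged = converged, defined = TRUE)
}

# Strict interior extrema with plateau runs collapsed to their first
# sample: a run is a maximum when both flanking values are lower, a
# minimum when both are higher.
local_extrema <- function(s) {
  n <- length(s)
  run_start <- which(c(TRUE, diff(s) != 0))
  run_val <- s[run_start]
  k <- length(run_val)
  maxima <- integer()
  minima <- integer()
  if (k >= 3L) {
    interior <- 2:(k - 1)
    is_max <- run_val[interior] > run_val[interior - 1] & run_val[interior] > run_val[interior + 1]
    is_min <- run_val[interior] < run_val[interior - 1] & run_val[interior] < run_val[interior + 1]
    maxima <- run_start[interior][is_max]
    minima <- run_start[interior][is_min]
  }
  list(max = maxima, min = minima)
}

# Cubic-spline envelope through the extrema, with the outermost extrema
# mirrored about samples 1 and n so the interpolation is anchored past
# both ends.
mirrored_envelope <- function(t_idx, ext_t, ext_v, n) {
  k <- length(ext_t)
  left_t <- 2 * 1 - ext_t[seq_len(min(2L, k))]
  left_v <- ext_v[seq_len(min(2L, k))]
  right_idx <- seq.int(k, by = -1L, length.out = min(2L, k))
  right_t <- 2 * n - ext_t[right_idx]
  right_v <- ext_v[right_idx]
  tt <- c(rev(left_t), ext_t, right_t)
  vv <- c(rev(left_v), ext_v, right_v)
  keep <- !duplicated(tt)
  tt <- tt[keep]
  vv <- vv[keep]
  ord <- order(tt)
  stats::spline(tt[ord], vv[ord], xout = t_idx, method = "natural")$y
}
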