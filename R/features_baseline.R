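#' Feature-extraction configuration
#'
#' Tunable conventions behind the 48-feature extractor. Defaults follow
#' the package's documented choices; every knob is orthogonal.
#'
#' @param di_grid Grid dimension G for the dispersion index (G x G cells
#'   over the on-paper bounding box).
#' @param entropy_bins Histogram bin count for continuous-signal
#'   (first-IMF) entropy symbolization.
#' @param ma_four_quadrant If TRUE, mean azimuth uses four-quadrant
#'   `atan2` angles instead of the two-quadrant slope angle.
#' @param gmrt_convention Tremor convention; only `"turning_angle"` is
#'   implemented (mean absolute turning angle, degrees).
#' @param emd_sd_threshold Cauchy-type stopping threshold for first-IMF
#'   sifting.
#' @param emd_max_sifts Sifting iteration cap.
#' @return A `feature_config` list.
#' @export
feature_config <- function(di_grid = 8L, entropy_bins = 64L,
                           ma_four_quadrant = FALSE,
                           gmrt_convention = "turning_angle",
                           emd_sd_threshold = 0.2, emd_max_sifts = 100L) {
  stopifnot(di_grid >= 1L, entropy_bins >= 2L,
            gmrt_convention == "turning_angle",
            emd_sd_threshold > 0, emd_max_sifts >= 1L)
  structure(
    list(di_grid = as.integer(di_grid),
         entropy_bins = as.integer(entropy_bins),
         ma_four_quadrant = isTRUE(ma_four_quadrant),
         gmrt_convention = gmrt_convention,
         emd_sd_threshold = emd_sd_threshold,
         emd_max_sifts = as.integer(emd_max_sifts)),
    class = "feature_config"
  )
}

# Within-segment rate series. Samples sharing a timestamp with their
# predecessor are dropped (rate-based features skip dt = 0 intervals), so
# every derivative has a positive time step. Acceleration uses the time
# step of the later interval; jerk likewise.
segment_kinematics <- function(samples) {
  if (nrow(samples) >= 2L) {
    keep <- c(TRUE, diff(samples$timestamp) > 0)
    samples <- samples[keep, , drop = FALSE]
  }
  n <- nrow(samples)
  if (n < 2L) return(list(speed = numeric(), accel = numeric(), jerk = numeric()))
  dt <- diff(samples$timestamp) / 1000
  speed <- sqrt(diff(samples$x)^2 + diff(samples$y)^2) / dt
  accel <- if (n >= 3L) diff(speed) / dt[-1] else numeric()
  jerk <- if (n >= 4L) diff(accel) / dt[-(1:2)] else numeric()
  list(speed = speed, accel = accel, jerk = jerk)
}

# Absolute turning angles (degrees) between successive displacement
# vectors within one segment; zero-length displacements are skipped.
segment_turning_angles <- function(samples) {
  if (nrow(samples) < 3L) return(numeric())
  dx <- diff(samples$x)
  dy <- diff(samples$y)
  keep <- dx != 0 | dy != 0
  dx <- dx[keep]
  dy <- dy[keep]
  if (length(dx) < 2L) return(numeric())
  v1x <- dx[-length(dx)]; v1y <- dy[-length(dy)]
  v2x <- dx[-1]; v2y <- dy[-1]
  ang <- atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
  abs(ang) * 180 / pi
}

#' Total, in-air and on-paper durations
#'
#' Total time is the span between first and last timestamp (seconds).
#' The interval between samples i and i+1 is attributed to the pen state
#' of sample i, so air time and paper time partition total time exactly.
#'
#' @param trajectory A `pen_trajectory`.
#' @return Named numeric vector `c(TT, AT, PT)`; all NA when fewer than
#'   two samples.
#' @export
compute_time_features <- function(trajectory) {
  n <- nrow(trajectory)
  if (n < 2L) return(c(TT = NA_real_, AT = NA_real_, PT = NA_real_))
  dt <- diff(trajectory$timestamp) / 1000
  state <- trajectory$pen_status[-n]
  c(TT = sum(dt), AT = sum(dt[state == 0L]), PT = sum(dt[state == 1L]))
}

#' Mean speed, acceleration and jerk magnitudes
#'
#' Rates are computed over consecutive-sample pairs strictly within
#' on-paper strokes (MSP/MAP/MJP) and within in-air segments
#' (MSA/MAA/MJA); a derivative never crosses a pen lift. Acceleration is
#' the first difference of speed over the later interval's time step,
#' jerk the first difference of acceleration; magnitudes are averaged
#' over all qualifying segments. Quantities with no qualifying interval
#' are NA.
#'
#' @param stroke_set A [segment_strokes()] result.
#' @return Named vector `c(MSP, MSA, MAP, MAA, MJP, MJA)`.
#' @export
compute_motion_features <- function(stroke_set) {
  pool <- function(on_paper, field) {
    segs <- stroke_set$samples[stroke_set$on_paper == on_paper]
    vals <- unlist(lapply(segs, function(s) segment_kinematics(s)[[field]]))
    if (length(vals) == 0L) NA_real_ else mean(abs(vals))
  }
  c(MSP = pool(TRUE, "speed"), MSA = pool(FALSE, "speed"),
    MAP = pool(TRUE, "accel"), MAA = pool(FALSE, "accel"),
    MJP = pool(TRUE, "jerk"), MJA = pool(FALSE, "jerk"))
}

#' On-paper pressure mean and variance
#'
#' Mean and sample variance of pen pressure over on-paper samples only
#' (the whole-recording pressure variability PSD deliberately uses all
#' samples instead).
#'
#' @param trajectory A `pen_trajectory`.
#' @return Named vector `c(PM, PV)`; PM needs one on-paper sample, PV two.
#' @export
compute_pressure_summary <- function(trajectory) {
  z <- trajectory$pressure[trajectory$pen_status == 1L]
  PM <- if (length(z) >= 1L) mean(z) else NA_real_
  PV <- if (length(z) >= 2L) stats::var(z) else NA_real_
  c(PM = PM, PV = PV)
}

#' Mean relative tremor descriptors
#'
#' Tremor is summarized as the mean absolute turning angle (degrees)
#' between successive displacement vectors, pooled over all on-paper
#' strokes (GMRTP) and over all in-air segments (GMRTA); segments with
#' fewer than three points (or fewer than two nonzero displacements)
#' contribute nothing. GMRT is the mean of the two components.
#'
#' @param stroke_set A [segment_strokes()] result.
#' @return Named vector `c(GMRTP, GMRTA, GMRT)`.
#' @export
compute_tremor_gmrt <- function(stroke_set) {
  pool <- function(on_paper) {
    segs <- stroke_set$samples[stroke_set$on_paper == on_paper]
    ang <- unlist(lapply(segs, segment_turning_angles))
    if (length(ang) == 0L) NA_real_ else mean(ang)
  }
  GMRTP <- pool(TRUE)
  GMRTA <- pool(FALSE)
  GMRT <- if (is.na(GMRTP) || is.na(GMRTA)) NA_real_ else (GMRTP + GMRTA) / 2
  c(GMRTP = GMRTP, GMRTA = GMRTA, GMRT = GMRT)
}

#' Layout features: pen-downs, extents, dispersion index
#'
#' PWN is the stroke count; XE and YE are the on-paper coordinate
#' extents; DI is the fraction of occupied cells in a G x G grid laid
#' over the on-paper bounding box (NA when fewer than two distinct
#' on-paper positions exist).
#'
#' @param trajectory A `pen_trajectory`.
#' @param stroke_set Matching [segment_strokes()] result.
#' @param grid_g Grid dimension G.
#' @return Named vector `c(PWN, XE, YE, DI)`.
#' @export
compute_layout_features <- function(trajectory, stroke_set, grid_g = 8L) {
  on <- trajectory[trajectory$pen_status == 1L, , drop = FALSE]
  PWN <- n_strokes(stroke_set)
  if (nrow(on) == 0L) {
    return(c(PWN = PWN, XE = NA_real_, YE = NA_real_, DI = NA_real_))
  }
  XE <- max(on$x) - min(on$x)
  YE <- max(on$y) - min(on$y)
  distinct_pos <- nrow(unique(on[, c("x", "y")]))
  if (distinct_pos < 2L) {
    DI <- NA_real_
  } else {
    g <- as.integer(grid_g)
    cell <- function(v) {
      ext <- max(v) - min(v)
      if (ext == 0) rep(0L, length(v)) else pmin(floor((v - min(v)) / ext * g), g - 1L)
    }
    DI <- nrow(unique(data.frame(ix = cell(on$x), iy = cell(on$y)))) / g^2
  }
  c(PWN = PWN, XE = XE, YE = YE, DI = DI)
}

compute_baseline_block <- function(trajectory, stroke_set, config) {
  c(compute_time_features(trajectory)[c("TT", "AT", "PT")],
    compute_motion_features(stroke_set),
    compute_pressure_summary(trajectory),
    compute_tremor_gmrt(stroke_set),
    compute_layout_features(trajectory, stroke_set, config$di_grid))
}
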