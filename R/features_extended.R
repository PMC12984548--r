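#' Canonical names of the 48 per-task features
#'
#' The 18 baseline descriptors followed by the 30 extended descriptors,
#' in the fixed order used by every feature vector and matrix column.
#'
#' @return Character vector of length 48.
#' @export
feature_names <- function() {
  c("TT", "AT", "PT", "MSP", "MSA", "MAP", "MAA", "MJP", "MJA",
    "PM", "PV", "GMRTP", "GMRTA", "GMRT", "PWN", "XE", "YE", "DI",
    "MA", "MS", "TD", "HD", "VD", "MSH", "MSW", "MCD", "MMDS", "MSED",
    "MVA", "MHA", "HSE", "VSE", "HRE_2", "HRE_3", "VRE_2", "VRE_3",
    "CE_X", "CE_Y", "TKE_X", "TKE_Y", "SNRCE_X", "SNRCE_Y",
    "SNRTKE_X", "SNRTKE_Y", "SSD", "PSD", "Altitude", "H_IMF1")
}

#' Directional descriptors: mean azimuth, mean slope, altitude
#'
#' MA is the mean movement direction in degrees over all consecutive-
#' sample intervals; by default the two-quadrant angle atan(dy/dx) in
#' (-90, 90), with vertical steps (dx = 0) contributing sign(dy) * 90.
#' MS is the mean slope dy/dx over intervals with dx != 0 (NA when none).
#' Altitude is the mean elevation angle (degrees) of the 3-vector
#' (dx, dy, dz) towards the pressure axis, over intervals with nonzero
#' 3-vector norm.
#'
#' @param diffs A [diff_series()] result.
#' @param four_quadrant Use atan2 angles in (-180, 180] for MA.
#' @return Named vector `c(MA, MS, Altitude)`.
#' @export
directional_features <- function(diffs, four_quadrant = FALSE) {
  if (nrow(diffs) == 0L) return(c(MA = NA_real_, MS = NA_real_, Altitude = NA_real_))
  dx <- diffs$dx; dy <- diffs$dy; dz <- diffs$dz
  if (four_quadrant) {
    ang <- atan2(dy, dx) * 180 / pi
  } else {
    ang <- ifelse(dx == 0, sign(dy) * 90, atan(dy / dx) * 180 / pi)
  }
  MA <- mean(ang)
  k <- dx != 0
  MS <- if (any(k)) mean(dy[k] / dx[k]) else NA_real_
  norm3 <- sqrt(dx^2 + dy^2 + dz^2)
  valid <- norm3 > 0
  Altitude <- if (any(valid)) mean(asin(dz[valid] / norm3[valid]) * 180 / pi) else NA_real_
  c(MA = MA, MS = MS, Altitude = Altitude)
}

#' Displacement descriptors
#'
#' TD is the total planar path length; HD and VD the total absolute
#' movement along each axis.
#'
#' @param diffs A [diff_series()] result.
#' @return Named vector `c(TD, HD, VD)`.
#' @export
displacement_features <- function(diffs) {
  if (nrow(diffs) == 0L) return(c(TD = NA_real_, HD = NA_real_, VD = NA_real_))
  c(TD = sum(diffs$dist), HD = sum(abs(diffs$dx)), VD = sum(abs(diffs$dy)))
}

#' Stroke-geometry descriptors
#'
#' MSH/MSW average the absolute vertical/horizontal offset between each
#' stroke's start point and the first in-air point after the stroke
#' (strokes without a following air point are excluded; NA when none
#' qualifies). MCD averages consecutive stroke-centroid distances; MMDS
#' the minimum point-pair distance between consecutive strokes; MSED the
#' distance from each stroke's end to the next stroke's start; MVA/MHA
#' the absolute y/x difference of consecutive stroke endpoints. All
#' pairwise descriptors need at least two strokes.
#'
#' @param stroke_set A [segment_strokes()] result.
#' @return Named vector `c(MSH, MSW, MCD, MMDS, MSED, MVA, MHA)`.
#' @export
stroke_geometry_features <- function(stroke_set) {
  st <- stroke_set[stroke_set$on_paper, , drop = FALSE]
  S <- nrow(st)
  out <- c(MSH = NA_real_, MSW = NA_real_, MCD = NA_real_, MMDS = NA_real_,
           MSED = NA_real_, MVA = NA_real_, MHA = NA_real_)
  if (S == 0L) return(out)
  has_air <- !is.na(st$air_x)
  if (any(has_air)) {
    out["MSH"] <- mean(abs(st$air_y[has_air] - st$start_y[has_air]))
    out["MSW"] <- mean(abs(st$air_x[has_air] - st$start_x[has_air]))
  }
  if (S >= 2L) {
    j <- seq_len(S - 1L)
    out["MCD"] <- mean(sqrt((st$centroid_x[j + 1] - st$centroid_x[j])^2 +
                            (st$centroid_y[j + 1] - st$centroid_y[j])^2))
    out["MMDS"] <- mean(vapply(j, function(i) {
      a <- st$samples[[i]]
      b <- st$samples[[i + 1]]
      min(sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2))
    }, numeric(1)))
    out["MSED"] <- mean(sqrt((st$end_x[j] - st$start_x[j + 1])^2 +
                             (st$end_y[j] - st$start_y[j + 1])^2))
    out["MVA"] <- mean(abs(st$end_y[j + 1] - st$end_y[j]))
    out["MHA"] <- mean(abs(st$end_x[j + 1] - st$end_x[j]))
  }
  out
}

#' Shannon entropy of an empirical value distribution
#'
#' Entropy in bits of the empirical distribution p(v) = count(v)/n over
#' exact distinct values. Tablet coordinates are discrete device units,
#' so exact-value counting is the natural symbolization.
#'
#' @param values Numeric vector (at least one value for a defined result).
#' @return Entropy in bits, 0 for constant input, NA for empty input.
#' @export
discrete_shannon_entropy <- function(values) {
  if (length(values) == 0L) return(NA_real_)
  p <- tabulate(match(values, unique(values))) / length(values)
  -sum(p * log2(p))
}

#' Renyi entropy of an empirical value distribution
#'
#' (1 / (1 - alpha)) * log2(sum(p^alpha)) over the exact-value empirical
#' distribution; alpha = 2 is collision entropy. Equals log2(#distinct)
#' for a uniform distribution, any alpha.
#'
#' @param values Numeric vector.
#' @param alpha Renyi order, > 1 (the descriptor set uses 2 and 3).
#' @return Entropy in bits, NA for empty input.
#' @export
discrete_renyi_entropy <- function(values, alpha) {
  stopifnot(alpha > 1)
  if (length(values) == 0L) return(NA_real_)
  p <- tabulate(match(values, unique(values))) / length(values)
  log2(sum(p^alpha)) / (1 - alpha)
}

#' Conventional (squared-signal) energy
#'
#' Total energy sum(s_i^2) plus the per-sample squared series reused by
#' the signal-to-noise descriptors.
#'
#' @param signal Numeric vector.
#' @return List with `total` and `per_sample`.
#' @export
conventional_energy <- function(signal) {
  per <- signal^2
  list(total = sum(per), per_sample = per)
}

#' Teager-Kaiser energy
#'
#' The discrete Teager-Kaiser operator Psi_i = s_i^2 - s_{i-1} s_{i+1}
#' over interior samples, plus its sum. Tracks instantaneous
#' amplitude-frequency energy and is sensitive to tremor-like
#' modulation; zero for constant and linear-in-index signals except the
#' unit contribution of each step of a ramp.
#'
#' @param signal Numeric vector of at least 3 values.
#' @return List with `total` and `per_sample` (length n - 2), or both NA
#'   when fewer than 3 samples.
#' @export
teager_kaiser_energy <- function(signal) {
  n <- length(signal)
  if (n < 3L) return(list(total = NA_real_, per_sample = NULL))
  i <- 2:(n - 1)
  per <- signal[i]^2 - signal[i - 1] * signal[i + 1]
  list(total = sum(per), per_sample = per)
}

#' Signal-to-noise ratio of a per-sample energy series
#'
#' Mean divided by sample standard deviation. Perfectly regular series
#' (sd = 0) and series shorter than two values are NA: the ratio is
#' either infinite or undefined, and downstream imputation handles NA
#' uniformly.
#'
#' @param per_sample_values Numeric per-sample energy series.
#' @return mu/sigma or NA.
#' @export
snr_ratio <- function(per_sample_values) {
  s <- signal_stats(per_sample_values)
  if (!s$defined || s$sd == 0) return(NA_real_)
  s$mean / s$sd
}

#' Shannon entropy of a first intrinsic mode function
#'
#' Continuous IMF values are symbolized by a fixed-bin histogram over the
#' IMF range before Shannon entropy is taken; a constant IMF occupies a
#' single bin and has entropy 0.
#'
#' @param imf An [emd_first_imf()] result.
#' @param bins Histogram bin count.
#' @return Entropy in bits, NA when the decomposition is undefined.
#' @export
imf_entropy <- function(imf, bins = 64L) {
  if (!isTRUE(imf$defined)) return(NA_real_)
  histogram_entropy(imf$imf1, bins)
}

histogram_entropy <- function(values, bins) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  p <- tabulate(idx, nbins = bins)
  p <- p[p > 0] / length(values)
  -sum(p * log2(p))
}

#' Speed and pressure variability
#'
#' SSD is the sample standard deviation of instantaneous speed over all
#' valid (dt > 0) consecutive-sample intervals of the whole trajectory;
#' PSD the sample standard deviation of pressure over all samples,
#' in-air and on-paper alike.
#'
#' @param diffs A [diff_series()] result.
#' @param trajectory The parent `pen_trajectory`.
#' @return Named vector `c(SSD, PSD)`.
#' @export
variability_features <- function(diffs, trajectory) {
  speeds <- diffs$speed[!is.na(diffs$speed)]
  SSD <- if (length(speeds) >= 2L) stats::sd(speeds) else NA_real_
  PSD <- if (nrow(trajectory) >= 2L) stats::sd(trajectory$pressure) else NA_real_
  c(SSD = SSD, PSD = PSD)
}

#' Extract the 48-feature vector of one recording
#'
#' Computes the full per-task descriptor block: the 18 baseline features
#' (durations, speeds/accelerations/jerks, pressure summary, tremor,
#' layout) and the 30 extended features (directional and displacement
#' descriptors, stroke geometry, coordinate entropies, conventional and
#' Teager-Kaiser energies with their signal-to-noise ratios, speed and
#' pressure variability, altitude, and first-IMF entropy). Undefined
#' quantities are NA and never silently 0; an empty trajectory yields an
#' all-NA vector. Deterministic given trajectory and configuration.
#'
#' @param trajectory A `pen_trajectory` (may be empty).
#' @param config A [feature_config()].
#' @return A one-row tibble with the 48 columns of [feature_names()].
#' @export
extract_features <- function(trajectory, config = feature_config()) {
  slots <- stats::setNames(rep(NA_real_, 48L), feature_names())
  n <- nrow(trajectory)
  if (n > 0L) {
    strokes <- segment_strokes(trajectory)
    diffs <- diff_series(trajectory)
    slots[names(slots)[1:18]] <- compute_baseline_block(trajectory, strokes, config)
    slots[c("MA", "MS", "Altitude")] <-
      directional_features(diffs, config$ma_four_quadrant)[c("MA", "MS", "Altitude")]
    slots[c("TD", "HD", "VD")] <- displacement_features(diffs)
    slots[c("MSH", "MSW", "MCD", "MMDS", "MSED", "MVA", "MHA")] <-
      stroke_geometry_features(strokes)
    slots["HSE"] <- discrete_shannon_entropy(trajectory$x)
    slots["VSE"] <- discrete_shannon_entropy(trajectory$y)
    slots["HRE_2"] <- discrete_renyi_entropy(trajectory$x, 2)
    slots["HRE_3"] <- discrete_renyi_entropy(trajectory$x, 3)
    slots["VRE_2"] <- discrete_renyi_entropy(trajectory$y, 2)
    slots["VRE_3"] <- discrete_renyi_entropy(trajectory$y, 3)
    ce_x <- conventional_energy(trajectory$x)
    ce_y <- conventional_energy(trajectory$y)
    slots["CE_X"] <- ce_x$total
    slots["CE_Y"] <- ce_y$total
    tke_x <- teager_kaiser_energy(trajectory$x)
    tke_y <- teager_kaiser_energy(trajectory$y)
    slots["TKE_X"] <- tke_x$total
    slots["TKE_Y"] <- tke_y$total
    slots["SNRCE_X"] <- snr_ratio(ce_x$per_sample)
    slots["SNRCE_Y"] <- snr_ratio(ce_y$per_sample)
    slots["SNRTKE_X"] <- if (is.null(tke_x$per_sample)) NA_real_ else snr_ratio(tke_x$per_sample)
    slots["SNRTKE_Y"] <- if (is.null(tke_y$per_sample)) NA_real_ else snr_ratio(tke_y$per_sample)
    slots[c("SSD", "PSD")] <- variability_features(diffs, trajectory)
    imf <- emd_first_imf(trajectory$x, config$emd_sd_threshold, config$emd_max_sifts)
    slots["H_IMF1"] <- imf_entropy(imf, config$entropy_bins)
  }
  out <- tibble::as_tibble(as.list(slots))
  out$subject_id <- attr(trajectory, "subject_id") %||% NA_character_
  out$task_id <- attr(trajectory, "task_id") %||% NA_integer_
  dplyr::relocate(out, "subject_id", "task_id")
}

#' Extract features for every recording of a cohort
#'
#' @param cohort A [load_cohort()] result (with a `trajectory`
#'   list-column).
#' @param config A [feature_config()].
#' @return A tibble with subject_id, label, task_id and the 48 feature
#'   columns, one row per recording.
#' @export
extract_cohort_features <- function(cohort, config = feature_config()) {
  feats <- purrr::map(cohort$trajectory, extract_features, config = config)
  dplyr::bind_cols(
    cohort |> dplyr::select("subject_id", "label", "task_id"),
    dplyr::bind_rows(feats) |> dplyr::select(dplyr::all_of(feature_names()))
  )
}
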