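#' Class-level effect knobs for the cohort simulator
#'
#' The knobs map onto the motor signatures the feature set targets:
#' positional jitter (tremor), slowing, pressure instability, extra pen
#' lifts, and the per-task probability of an empty recording (a task not
#' completed at all).
#'
#' @param tremor_amplitude High-frequency positional jitter scale
#'   (device units); also scales an 8 Hz sinusoidal tremor component.
#' @param speed_scale Multiplicative slowdown (> 1 = slower traversal).
#' @param pressure_sd Pressure noise scale (device units).
#' @param pen_lift_rate Expected extra pen lifts per task (Poisson mean).
#' @param empty_prob Per-task probability of an empty recording.
#' @return A `class_effects` list.
#' @export
class_effects <- function(tremor_amplitude = 0.5, speed_scale = 1,
                          pressure_sd = 1, pen_lift_rate = 0.3,
                          empty_prob = 0) {
  stopifnot(tremor_amplitude >= 0, speed_scale > 0, pressure_sd >= 0,
            pen_lift_rate >= 0, empty_prob >= 0, empty_prob <= 1)
  structure(list(tremor_amplitude = tremor_amplitude, speed_scale = speed_scale,
                 pressure_sd = pressure_sd, pen_lift_rate = pen_lift_rate,
                 empty_prob = empty_prob),
            class = "class_effects")
}

#' Default patient-class effects
#'
#' A strongly separated patient profile: larger tremor, slower and more
#' variable movement, noisier pressure, more pen lifts, and an empty-
#' recording rate matching the patient share observed in the public
#' cohort (99 empties / 2225 recordings).
#'
#' @return A [class_effects()] list.
#' @export
patient_effects <- function() {
  class_effects(tremor_amplitude = 3, speed_scale = 1.5, pressure_sd = 4,
                pen_lift_rate = 2, empty_prob = 0.045)
}

#' Default healthy-control effects
#'
#' Control empty-recording rate matches the healthy share of the public
#' cohort (54 empties / 2125 recordings).
#'
#' @return A [class_effects()] list.
#' @export
healthy_effects <- function() {
  class_effects(tremor_amplitude = 0.5, speed_scale = 1, pressure_sd = 1,
                pen_lift_rate = 0.3, empty_prob = 0.025)
}

#' Stroke-template polylines for a task
#'
#' Fixed, deterministic polyline targets loosely mirroring the battery's
#' task categories: lines and circles of two radii (graphical tasks),
#' letter-like zigzags (copying), and longer multi-stroke word-like
#' sequences (memory/dictation). Shapes are arbitrary but frozen: the
#' same task id always yields the same template.
#'
#' @param task_id Integer 1-25.
#' @return List of polylines, each a 2-column (x, y) matrix in device
#'   units.
#' @export
task_template <- function(task_id) {
  task_id <- as.integer(task_id)
  stopifnot(task_id >= 1L, task_id <= 25L)
  circle <- function(r, cx = 0, cy = 0, k = 36L) {
    th <- seq(0, 2 * pi, length.out = k + 1L)
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  # letterform-like teeth: forward up-stroke, slightly backward down-stroke,
  # so the x signal carries the small reversals real letters have
  zigzag <- function(n_teeth, w = 60, h = 80, x0 = 0) {
    n_pts <- 2L * n_teeth + 1L
    step <- rep(c(w * 0.6, -w * 0.1), length.out = n_pts - 1L)
    x <- x0 + c(0, cumsum(step))
    y <- rep(c(0, h), length.out = n_pts)
    cbind(x, y)
  }
  mode <- ((task_id - 1L) %% 5L)
  scale <- 1 + 0.1 * task_id
  switch(as.character(mode),
    "0" = list(cbind(c(0, 400) * scale, c(0, 0))),                     # horizontal line
    "1" = list(circle(80 * scale), circle(40 * scale, cx = 250 * scale)), # two circles
    "2" = list(zigzag(4L, w = 60 * scale)),                            # zigzag letterform
    "3" = lapply(0:2, function(i) zigzag(2L, w = 50, h = 70, x0 = i * 180 * scale)), # word-like
    "4" = list(cbind(c(0, 0), c(0, 300) * scale),                      # cross
               cbind(c(-150, 150) * scale, c(150, 150) * scale))
  )
}

#' Simulate one pen recording
#'
#' Traverses each template polyline at a base speed divided by the
#' class's `speed_scale`, samples positions at the given rate, and
#' superimposes white Gaussian jitter plus an 8 Hz sinusoidal tremor
#' (both scaled by `tremor_amplitude`). Pressure is a base level plus
#' Gaussian noise clipped at zero on paper and zero in air. Consecutive
#' strokes are joined by straight in-air transits; extra pen lifts
#' (Poisson count) flip short on-paper spans to in-air. Coordinates are
#' rounded to integer device units so exact-value entropy estimation
#' behaves as on a real tablet. Deterministic given the seed.
#'
#' @param template A [task_template()] polyline list.
#' @param effects A [class_effects()] list.
#' @param seed Integer seed.
#' @param sampling_rate Samples per second (Hz).
#' @param base_speed Traversal speed (device units per second).
#' @param base_pressure On-paper pressure level (device units).
#' @param subject_id,task_id Identifiers to attach.
#' @return A `pen_trajectory`.
#' @export
simulate_trajectory <- function(template, effects, seed = 1L,
                                sampling_rate = 50, base_speed = 300,
                                base_pressure = 512,
                                subject_id = NA_character_,
                                task_id = NA_integer_) {
  stopifnot(length(template) >= 1L)
  lens <- vapply(template, function(p) {
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  if (any(!is.finite(lens)) || all(lens == 0)) {
    stop("degenerate template: zero-length polylines", call. = FALSE)
  }
  set.seed(seed)
  speed <- base_speed / effects$speed_scale
  dt <- 1 / sampling_rate

  resample_path <- function(pts, n_samples) {
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    s_out <- seq(0, cum[length(cum)], length.out = n_samples)
    cbind(stats::approx(cum, pts[, 1], xout = s_out, ties = "ordered")$y,
          stats::approx(cum, pts[, 2], xout = s_out, ties = "ordered")$y)
  }

  xs <- numeric(); ys <- numeric(); on <- integer()
  prev_end <- NULL
  for (p in template) {
    if (!is.null(prev_end)) {
      transit_len <- sqrt(sum((p[1, ] - prev_end)^2))
      n_tr <- max(2L, ceiling(transit_len / speed / dt))
      tr <- resample_path(rbind(prev_end, p[1, ]), n_tr)
      xs <- c(xs, tr[, 1]); ys <- c(ys, tr[, 2]); on <- c(on, rep(0L, n_tr))
    }
    path_len <- sum(sqrt(rowSums(diff(p)^2)))
    n_s <- max(2L, ceiling(path_len / speed / dt))
    sp <- resample_path(p, n_s)
    xs <- c(xs, sp[, 1]); ys <- c(ys, sp[, 2]); on <- c(on, rep(1L, n_s))
    prev_end <- p[nrow(p), ]
  }
  n <- length(xs)
  t_sec <- (seq_len(n) - 1L) * dt

  # extra pen lifts: short in-air windows inside on-paper spans
  n_lifts <- stats::rpois(1, effects$pen_lift_rate)
  if (n_lifts > 0L) {
    candidates <- which(on == 1L)
    candidates <- candidates[candidates > 2L & candidates < n - 2L]
    if (length(candidates) > 0L) {
      starts <- sort(sample(candidates, min(n_lifts, length(candidates))))
      for (s in starts) on[s:min(s + 2L, n)] <- 0L
    }
  }

  amp <- effects$tremor_amplitude
  phase <- stats::runif(2, 0, 2 * pi)
  xs <- xs + stats::rnorm(n, 0, amp) + 0.5 * amp * sin(2 * pi * 8 * t_sec + phase[1])
  ys <- ys + stats::rnorm(n, 0, amp) + 0.5 * amp * sin(2 * pi * 8 * t_sec + phase[2])
  press <- ifelse(on == 1L,
                  pmax(base_pressure + stats::rnorm(n, 0, effects$pressure_sd), 0),
                  0)
  pen_trajectory(round(xs), round(ys), round(press, 1), on,
                 round(t_sec * 1000), subject_id = subject_id, task_id = task_id)
}

#' Synthetic cohort specification
#'
#' Defaults are the study conditions the simulator emulates: 89 patients
#' and 85 controls over the 25-task battery, with the default class
#' effect profiles.
#'
#' @param n_patients,n_healthy Subjects per class.
#' @param tasks Task ids simulated.
#' @param patient,healthy [class_effects()] per class.
#' @param sampling_rate Hz.
#' @param seed Master seed; all randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 89L, n_healthy = 85L, tasks = 1:25,
                        patient = patient_effects(), healthy = healthy_effects(),
                        sampling_rate = 50, seed = 1L) {
  stopifnot(n_patients >= 1L, n_healthy >= 1L, length(tasks) >= 1L,
            sampling_rate > 0)
  structure(list(n_patients = as.integer(n_patients),
                 n_healthy = as.integer(n_healthy),
                 tasks = as.integer(tasks), patient = patient,
                 healthy = healthy, sampling_rate = sampling_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a labelled cohort
#'
#' Generates one recording per (subject, task); each recording is empty
#' with its class's `empty_prob`. With `out_dir` set, recordings are
#' written in the canonical dialect under
#' `out_dir/<subject_id>/T<task>.csv` with a `manifest.csv`; otherwise
#' the cohort stays in memory.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory.
#' @return A cohort tibble (subject_id, label, task_id, n_samples,
#'   empty, trajectory), the same shape [load_cohort()] returns. With
#'   `out_dir`, the manifest path is attached as attribute `manifest`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), out_dir = NULL) {
  subjects <- tibble::tibble(
    subject_id = c(sprintf("P%03d", seq_len(spec$n_patients)),
                   sprintf("H%03d", seq_len(spec$n_healthy))),
    label = rep(c("patient", "healthy"), c(spec$n_patients, spec$n_healthy))
  )
  grid <- tidyr::expand_grid(subjects, task_id = spec$tasks)
  rows <- purrr::pmap(grid, function(subject_id, label, task_id) {
    eff <- if (label == "patient") spec$patient else spec$healthy
    subj_index <- match(subject_id, subjects$subject_id)
    rec_seed <- spec$seed + 997L * subj_index + 31L * task_id
    set.seed(rec_seed)
    is_empty <- stats::runif(1) < eff$empty_prob
    traj <- if (is_empty) {
      pen_trajectory(subject_id = subject_id, task_id = task_id)
    } else {
      simulate_trajectory(task_template(task_id), eff, seed = rec_seed + 1L,
                          sampling_rate = spec$sampling_rate,
                          subject_id = subject_id, task_id = task_id)
    }
    tibble::tibble(subject_id = subject_id, label = label, task_id = task_id,
                   n_samples = nrow(traj), empty = nrow(traj) == 0L,
                   trajectory = list(traj))
  })
  cohort <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rel_paths <- character(nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      sub_dir <- file.path(out_dir, cohort$subject_id[i])
      dir.create(sub_dir, showWarnings = FALSE)
      rel <- file.path(cohort$subject_id[i], sprintf("T%02d.csv", cohort$task_id[i]))
      write_recording(cohort$trajectory[[i]], file.path(out_dir, rel))
      rel_paths[i] <- rel
    }
    manifest <- cohort |>
      dplyr::transmute(.data$subject_id, .data$label, .data$task_id,
                       path = rel_paths)
    manifest_path <- file.path(out_dir, "manifest.csv")
    utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
    attr(cohort, "manifest") <- manifest_path
  }
  cohort
}

#' Check that a feature responds to its generator knob
#'
#' Simulates repeated recordings at a low and a high setting of one
#' effect knob and compares the mean feature value, validating the
#' semantic link between generator knobs and descriptors (tremor drives
#' Teager-Kaiser energy, speed variability drives SSD, pressure noise
#' drives PSD, pen lifts drive PWN).
#'
#' @param feature_name One of [feature_names()].
#' @param knob A [class_effects()] field name.
#' @param low,high Knob settings to contrast.
#' @param n_rep Recordings per setting.
#' @param task_id Template task.
#' @param seed Seed.
#' @return A one-row tibble with mean_low, mean_high, increased.
#' @export
effect_response_check <- function(feature_name, knob, low, high, n_rep = 30L,
                                  task_id = 9L, seed = 1L) {
  stopifnot(feature_name %in% feature_names())
  run <- function(value, offset) {
    eff <- healthy_effects()
    eff[[knob]] <- value
    vals <- vapply(seq_len(n_rep), function(i) {
      traj <- simulate_trajectory(task_template(task_id), eff,
                                  seed = seed + offset + i)
      extract_features(traj)[[feature_name]]
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  mean_low <- run(low, 0L)
  mean_high <- run(high, 100000L)
  tibble::tibble(feature = feature_name, knob = knob,
                 mean_low = mean_low, mean_high = mean_high,
                 increased = mean_high > mean_low)
}
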