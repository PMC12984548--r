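#' Column dialect for raw pen recordings
#'
#' Raw recordings are delimited text with one pen sample per row. The
#' canonical dialect is comma-separated with the header
#' `x,y,pressure,pen_status,timestamp`; other delimited layouts are
#' absorbed by remapping column names or positions here.
#'
#' @param x,y,pressure,pen_status,timestamp Column name (character) or
#'   1-based position (integer) of each signal in the file.
#' @param delim Field delimiter.
#' @param header Whether the file carries a header row.
#' @return A `pen_dialect` list used by [read_recording()] and
#'   [write_recording()].
#' @export
pen_dialect <- function(x = "x", y = "y", pressure = "pressure",
                        pen_status = "pen_status", timestamp = "timestamp",
                        delim = ",", header = TRUE) {
  structure(
    list(x = x, y = y, pressure = pressure, pen_status = pen_status,
         timestamp = timestamp, delim = delim, header = header),
    class = "pen_dialect"
  )
}

canonical_sample_cols <- c("x", "y", "pressure", "pen_status", "timestamp")

#' Construct a pen trajectory tibble
#'
#' A trajectory is an ordered set of pen samples for one subject-task
#' recording: tablet coordinates (device units), pen pressure (device
#' units), pen state (0 = in-air, 1 = on-paper) and a millisecond
#' timestamp. A zero-row trajectory is the empty-recording case and is
#' legal everywhere downstream.
#'
#' @param x,y,pressure,pen_status,timestamp Equal-length numeric vectors.
#' @param subject_id,task_id Optional identifiers attached as attributes.
#' @return A tibble of class `pen_trajectory`.
#' @export
pen_trajectory <- function(x = numeric(), y = numeric(), pressure = numeric(),
                           pen_status = numeric(), timestamp = numeric(),
                           subject_id = NA_character_, task_id = NA_integer_) {
  traj <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y), pressure = as.numeric(pressure),
    pen_status = as.integer(pen_status), timestamp = as.numeric(timestamp)
  )
  validate_trajectory(traj)
  attr(traj, "subject_id") <- subject_id
  attr(traj, "task_id") <- task_id
  class(traj) <- c("pen_trajectory", class(traj))
  traj
}

validate_trajectory <- function(traj, source = "trajectory") {
  if (nrow(traj) == 0L) return(invisible(traj))
  bad_state <- which(!traj$pen_status %in% c(0L, 1L))
  if (length(bad_state) > 0L) {
    stop(sprintf("%s: pen_status outside {0, 1} at row %d", source, bad_state[1]),
         call. = FALSE)
  }
  if (any(!is.finite(traj$timestamp)) || any(traj$timestamp < 0)) {
    stop(sprintf("%s: timestamps must be finite and non-negative", source),
         call. = FALSE)
  }
  dec <- which(diff(traj$timestamp) < 0)
  if (length(dec) > 0L) {
    stop(sprintf("%s: decreasing timestamp between rows %d and %d",
                 source, dec[1], dec[1] + 1L), call. = FALSE)
  }
  invisible(traj)
}

resolve_dialect_columns <- function(raw, dialect, path) {
  cols <- lapply(canonical_sample_cols, function(field) {
    sel <- dialect[[field]]
    if (is.character(sel)) {
      if (!sel %in% names(raw)) {
        stop(sprintf("%s: column '%s' (mapped to %s) not found", path, sel, field),
             call. = FALSE)
      }
      raw[[sel]]
    } else {
      if (sel < 1L || sel > ncol(raw)) {
        stop(sprintf("%s: column position %d (mapped to %s) out of range",
                     path, sel, field), call. = FALSE)
      }
      raw[[sel]]
    }
  })
  names(cols) <- canonical_sample_cols
  cols
}

#' Read one raw pen recording
#'
#' Parses a delimited recording into a [pen_trajectory()]. Rows are kept in
#' file order; timestamps are validated non-decreasing; a zero-row file
#' yields an empty trajectory (the empty-recording case).
#'
#' @param path Path to the recording.
#' @param dialect A [pen_dialect()].
#' @param subject_id,task_id Identifiers to attach.
#' @return A `pen_trajectory` tibble.
#' @export
read_recording <- function(path, dialect = pen_dialect(),
                           subject_id = NA_character_, task_id = NA_integer_) {
  if (!file.exists(path)) stop(sprintf("recording not found: %s", path), call. = FALSE)
  info <- file.info(path)
  if (info$size == 0) {
    return(pen_trajectory(subject_id = subject_id, task_id = task_id))
  }
  raw <- tryCatch(
    utils::read.table(path, sep = dialect$delim, header = dialect$header,
                      colClasses = "character", strip.white = TRUE,
                      blank.lines.skip = TRUE),
    error = function(e) stop(sprintf("%s: parse error (%s)", path, conditionMessage(e)),
                             call. = FALSE)
  )
  if (nrow(raw) == 0L) {
    return(pen_trajectory(subject_id = subject_id, task_id = task_id))
  }
  expected_arity <- max(vapply(canonical_sample_cols, function(f) {
    sel <- dialect[[f]]
    if (is.character(sel)) 0L else as.integer(sel)
  }, integer(1)), 5L)
  if (ncol(raw) < 5L) {
    stop(sprintf("%s: expected at least %d columns, found %d", path,
                 expected_arity, ncol(raw)), call. = FALSE)
  }
  cols <- resolve_dialect_columns(raw, dialect, path)
  header_offset <- if (isTRUE(dialect$header)) 1L else 0L
  num <- lapply(cols, function(v) suppressWarnings(as.numeric(v)))
  for (field in canonical_sample_cols) {
    bad <- which(is.na(num[[field]]) & !is.na(cols[[field]]))
    na_in <- which(is.na(num[[field]]))
    if (length(na_in) > 0L) {
      stop(sprintf("%s: non-numeric %s value at line %d", path, field,
                   na_in[1] + header_offset), call. = FALSE)
    }
  }
  tryCatch(
    pen_trajectory(num$x, num$y, num$pressure, num$pen_status, num$timestamp,
                   subject_id = subject_id, task_id = task_id),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  )
}

#' Write a pen trajectory to disk
#'
#' Inverse of [read_recording()] for the same dialect: reading a written
#' file reproduces the trajectory sample for sample. An empty trajectory
#' writes a header-only file.
#'
#' @param trajectory A `pen_trajectory`.
#' @param path Output path.
#' @param dialect A [pen_dialect()] with character column names.
#' @return `path`, invisibly.
#' @export
write_recording <- function(trajectory, path, dialect = pen_dialect()) {
  validate_trajectory(trajectory, source = path)
  out <- data.frame(
    trajectory$x, trajectory$y, trajectory$pressure,
    trajectory$pen_status, trajectory$timestamp
  )
  names(out) <- vapply(canonical_sample_cols, function(f) {
    sel <- dialect[[f]]
    if (is.character(sel)) sel else canonical_sample_cols[[match(f, canonical_sample_cols)]]
  }, character(1))
  ok <- tryCatch({
    utils::write.table(out, path, sep = dialect$delim, row.names = FALSE,
                       col.names = isTRUE(dialect$header), quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write recording to %s", path), call. = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id,label,task_id,path`,
#' one row per expected recording; `path` may be empty/NA for a recording
#' known to be absent. Labels must be binary (`patient` / `healthy`).
#'
#' @param path Manifest CSV path.
#' @return A tibble with columns subject_id, label, task_id, path.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("subject_id", "label", "task_id", "path")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    stop(sprintf("manifest missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  m$task_id <- as.integer(m$task_id)
  m$path[!nzchar(m$path)] <- NA_character_
  bad <- setdiff(unique(m$label), c("patient", "healthy"))
  if (length(bad) > 0L) {
    stop(sprintf("manifest labels must be 'patient' or 'healthy'; found: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(m[required])
}

#' Load a full cohort of recordings
#'
#' Resolves every manifest row under `root_dir` and parses it. Recordings
#' marked absent (NA path) or parsing to zero samples are recorded as
#' empty; a non-absent path that does not exist on disk is an error.
#'
#' @param root_dir Directory that manifest paths are relative to.
#' @param manifest Manifest tibble (see [read_manifest()]) or path to one.
#' @param dialect A [pen_dialect()].
#' @return A tibble with one row per (subject, task): columns subject_id,
#'   label, task_id, n_samples, empty (logical) and a `trajectory`
#'   list-column.
#' @export
load_cohort <- function(root_dir, manifest, dialect = pen_dialect()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dup <- manifest |>
    dplyr::count(.data$subject_id, .data$task_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop(sprintf("duplicate manifest entries, e.g. subject %s task %s",
                 dup$subject_id[1], dup$task_id[1]), call. = FALSE)
  }
  paths <- ifelse(is.na(manifest$path), NA_character_,
                  file.path(root_dir, manifest$path))
  missing_files <- which(!is.na(paths) & !file.exists(paths))
  if (length(missing_files) > 0L) {
    stop(sprintf("manifest references missing file(s) not marked absent: %s",
                 paste(utils::head(paths[missing_files], 5), collapse = ", ")),
         call. = FALSE)
  }
  trajectories <- purrr::pmap(
    list(paths, manifest$subject_id, manifest$task_id),
    function(p, sid, tid) {
      if (is.na(p)) {
        pen_trajectory(subject_id = sid, task_id = tid)
      } else {
        read_recording(p, dialect, subject_id = sid, task_id = tid)
      }
    }
  )
  manifest |>
    dplyr::mutate(
      trajectory = trajectories,
      n_samples = vapply(trajectories, nrow, integer(1)),
      empty = .data$n_samples == 0L
    ) |>
    dplyr::select("subject_id", "label", "task_id", "n_samples", "empty",
                  "trajectory")
}

#' Census of empty recordings per task and class
#'
#' Counts empty (zero-sample or absent) recordings per task, split by
#' diagnostic class, with grand totals and class shares. An empty
#' recording reflects a task a subject did not (or could not) complete.
#'
#' @param cohort A cohort tibble with columns subject_id, label, task_id
#'   and either `empty` (logical) or `n_samples`.
#' @return A tibble of class `task_census` with one row per task
#'   (columns task_id, total_empty, healthy_empty, patient_empty);
#'   grand totals are stored in attributes `total`, `healthy`, `patient`,
#'   `healthy_share`, `patient_share`.
#' @export
census_empty_files <- function(cohort) {
  if (!"empty" %in% names(cohort)) {
    if (!"n_samples" %in% names(cohort)) {
      stop("cohort needs an 'empty' or 'n_samples' column", call. = FALSE)
    }
    cohort$empty <- cohort$n_samples == 0L
  }
  if (any(is.na(cohort$label)) || !all(cohort$label %in% c("patient", "healthy"))) {
    stop("every recording must carry a 'patient' or 'healthy' label", call. = FALSE)
  }
  census <- cohort |>
    dplyr::group_by(task_id = as.integer(.data$task_id)) |>
    dplyr::summarise(
      total_empty = sum(.data$empty),
      healthy_empty = sum(.data$empty & .data$label == "healthy"),
      patient_empty = sum(.data$empty & .data$label == "patient"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$task_id)
  total <- sum(census$total_empty)
  attr(census, "total") <- total
  attr(census, "healthy") <- sum(census$healthy_empty)
  attr(census, "patient") <- sum(census$patient_empty)
  attr(census, "healthy_share") <- if (total > 0) 100 * sum(census$healthy_empty) / total else NA_real_
  attr(census, "patient_share") <- if (total > 0) 100 * sum(census$patient_empty) / total else NA_real_
  class(census) <- c("task_census", class(census))
  census
}

#' @export
print.task_census <- function(x, ...) {
  cat(sprintf("Empty-recording census: %d total (%d healthy, %d patient)\n",
              attr(x, "total"), attr(x, "healthy"), attr(x, "patient")))
  NextMethod()
}
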