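# Trial-log and landscape/slice readers and writers.
# CSV dialect: UTF-8, comma separated, "." decimal, mandatory header,
# radians stored numerically.

trial_log_columns <- c(
  "participant_id", "group", "z_init_m", "phi_init_rad", "augmented",
  "pi_optimal", "t_optimal_s", "decision", "decision_time_s",
  "v_td_attempt_mps", "v_td_abort_mps", "timing_error_s",
  "timing_category", "safe_outcome", "no_response")

#' Write a trial log to CSV
#'
#' @param logs A trial-log tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(logs, path) {
  readr::write_csv(logs, path, na = "")
  invisible(path)
}

#' Read a trial log from CSV
#'
#' Tolerates logs without the counterfactual/derived columns (as when
#' ingesting external study logs): missing columns are added as NA. When a
#' `last_key` or duplicated-press encoding is present the recorded
#' decision is the last key pressed.
#'
#' @param path CSV path.
#' @return A trial-log tibble.
#' @export
read_trial_log <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("last_key" %in% names(d) && !("decision" %in% names(d)))
    d$decision <- d$last_key
  for (col in trial_log_columns) {
    if (!col %in% names(d)) {
      d[[col]] <- switch(col,
        participant_id = , group = , decision = ,
        timing_category = NA_character_,
        augmented = , safe_outcome = , no_response = NA,
        NA_real_)
    }
  }
  if (all(is.na(d$no_response))) d$no_response <- d$decision == "none"
  tibble::as_tibble(d)
}

#' Export a slice as CSV
#'
#' Columns: `trigger_time_s`, `lift_N`, `contact`, `delta_t_s`,
#' `v_td_mag_mps`, `pi`, `class`. `delta_t_s` and `v_td_mag_mps` are
#' reconstructed from the slice's pi values and lift.
#'
#' @param slice A [pi_timeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_slice_csv <- function(slice, path) {
  stopifnot(inherits(slice, "pi_timeline"))
  v_crt <- attr(slice, "v_crt")
  out <- tibble::tibble(
    trigger_time_s = slice$time,
    lift_N = attr(slice, "lift"),
    contact = slice$contact,
    v_td_mag_mps = ifelse(slice$contact, slice$pi * v_crt, NA_real_),
    pi = ifelse(slice$contact, slice$pi, NA_real_),
    class = ifelse(!slice$contact, "no_contact",
                   ifelse(slice$pi <= 1, "safe", "unsafe")))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Export a landscape as CSV
#'
#' @param landscape A [build_landscape()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "dl_landscape"))
  readr::write_csv(tibble::as_tibble(landscape), path, na = "")
  invisible(path)
}

#' Cache a landscape in a binary columnar file
#'
#' Serialises the landscape (grids, cells and attributes) with `saveRDS`;
#' [read_landscape_cache()] restores it. Intended for large grids that are
#' slow to recompute.
#'
#' @param landscape A [build_landscape()] tibble.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_landscape_cache <- function(landscape, path) {
  stopifnot(inherits(landscape, "dl_landscape"))
  saveRDS(landscape, path)
  invisible(path)
}

#' @rdname write_landscape_cache
#' @export
read_landscape_cache <- function(path) {
  readRDS(path)
}
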