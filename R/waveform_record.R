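#' Phase markers for a hemorrhage experiment
#'
#' The four canonical protocol timepoints: start of baseline, start of
#' hemorrhage, end of hemorrhage, and end of the shock hold, in seconds from
#' the start of the record. Markers must be strictly increasing.
#'
#' @param baseline_start_s,hemorrhage_start_s,hemorrhage_end_s,hold_end_s
#'   timepoints in seconds.
#' @return A `hw_phases` object (named numeric vector of length 4).
#' @examples
#' phase_markers(0, 300, 600, 900)
#' @export
phase_markers <- function(baseline_start_s, hemorrhage_start_s,
                          hemorrhage_end_s, hold_end_s) {
  p <- c(baseline_start_s = baseline_start_s,
         hemorrhage_start_s = hemorrhage_start_s,
         hemorrhage_end_s = hemorrhage_end_s,
         hold_end_s = hold_end_s)
  if (!all(is.finite(p))) hw_stop("phase markers must be finite", class = "hw_marker_error")
  if (any(diff(p) <= 0)) {
    hw_stop("phase markers must be strictly increasing ",
            "(baseline_start < hemorrhage_start < hemorrhage_end < hold_end)",
            class = "hw_marker_error")
  }
  structure(p, class = "hw_phases")
}

#' Construct a uniformly sampled arterial pressure record
#'
#' @param pressure numeric vector of arterial pressure samples (mmHg).
#' @param sample_rate_hz sampling frequency in Hz.
#' @param phases a [phase_markers()] object, or `NULL`.
#' @param subject_id,replicate_id identifiers carried through the pipeline.
#' @param t0 start time in seconds (0-based convention).
#' @return A `hw_record` object.
#' @export
waveform_record <- function(pressure, sample_rate_hz, phases = NULL,
                            subject_id = "S1", replicate_id = "R1", t0 = 0) {
  if (!is.numeric(pressure) || length(pressure) < 1L) {
    hw_stop("pressure must be a non-empty numeric vector", class = "hw_format_error")
  }
  if (anyNA(pressure) || !all(is.finite(pressure))) {
    hw_stop("pressure contains NA or non-finite values; gaps are an error",
            class = "hw_format_error")
  }
  if (!is_num1(sample_rate_hz) || sample_rate_hz <= 0) {
    hw_stop("sample_rate_hz must be a positive number", class = "hw_format_error")
  }
  dur <- length(pressure) / sample_rate_hz
  if (!is.null(phases)) {
    if (!inherits(phases, "hw_phases")) phases <- do.call(phase_markers, as.list(phases))
    if (phases[["hold_end_s"]] > t0 + dur + 1 / sample_rate_hz) {
      hw_stop("phase markers extend beyond record duration", class = "hw_marker_error")
    }
  }
  structure(list(pressure = as.numeric(pressure),
                 sample_rate_hz = sample_rate_hz,
                 t0 = t0,
                 subject_id = as.character(subject_id),
                 replicate_id = as.character(replicate_id),
                 phases = phases),
            class = "hw_record")
}

#' @export
print.hw_record <- function(x, ...) {
  cat(sprintf("<hw_record> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$replicate_id, length(x$pressure),
              x$sample_rate_hz, length(x$pressure) / x$sample_rate_hz))
  if (!is.null(x$phases)) {
    cat(sprintf("  phases: baseline %.1f | hemorrhage %.1f-%.1f | hold end %.1f s\n",
                x$phases[["baseline_start_s"]], x$phases[["hemorrhage_start_s"]],
                x$phases[["hemorrhage_end_s"]], x$phases[["hold_end_s"]]))
  }
  invisible(x)
}

#' Time axis of a record
#' @param record a `hw_record`.
#' @return Numeric vector of sample times in seconds.
#' @export
record_times <- function(record) {
  record$t0 + (seq_along(record$pressure) - 1L) / record$sample_rate_hz
}

#' Hemorrhage ground truth container
#'
#' Cumulative shed blood volume over time together with subject weight and
#' phase markers. The volume series must be non-negative, non-decreasing,
#' zero throughout baseline and constant during the shock hold.
#'
#' @param times_s sample times of the volume series (seconds).
#' @param shed_volume_ml cumulative shed volume (mL) at `times_s`.
#' @param weight_kg subject body weight (kg); estimated blood volume is
#'   80 mL/kg.
#' @param phases a [phase_markers()] object.
#' @param total_shed_ml total shed volume; defaults to `max(shed_volume_ml)`.
#' @return A `hw_truth` object.
#' @export
hemorrhage_truth <- function(times_s, shed_volume_ml, weight_kg, phases,
                             total_shed_ml = max(shed_volume_ml)) {
  if (length(times_s) != length(shed_volume_ml)) {
    hw_stop("times_s and shed_volume_ml lengths differ", class = "hw_format_error")
  }
  if (is.unsorted(times_s, strictly = TRUE)) {
    hw_stop("truth times must be strictly increasing", class = "hw_format_error")
  }
  if (any(shed_volume_ml < 0) || is.unsorted(shed_volume_ml)) {
    hw_stop("shed volume must be non-negative and non-decreasing",
            class = "hw_format_error")
  }
  if (!is_num1(weight_kg) || weight_kg <= 0) {
    hw_stop("weight_kg must be positive", class = "hw_config_error")
  }
  if (!inherits(phases, "hw_phases")) phases <- do.call(phase_markers, as.list(phases))
  structure(list(times_s = as.numeric(times_s),
                 shed_volume_ml = as.numeric(shed_volume_ml),
                 weight_kg = weight_kg,
                 total_shed_ml = total_shed_ml,
                 phases = phases),
            class = "hw_truth")
}

#' Cumulative shed volume at arbitrary query times
#'
#' Previous-value (step) interpolation of the recorded volume series: the
#' reported volume never anticipates blood that has not yet been shed.
#'
#' @param truth a `hw_truth`.
#' @param query_times_s times (seconds) at which to evaluate shed volume.
#' @return Numeric vector of volumes (mL).
#' @export
shed_at <- function(truth, query_times_s) {
  stats::approx(truth$times_s, truth$shed_volume_ml, xout = query_times_s,
                method = "constant", f = 0, rule = 2)$y
}
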