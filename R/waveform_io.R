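#' Read a waveform text file with its phase-marker sidecar
#'
#' The waveform file is delimited text with columns `time_s,pressure_mmhg`
#' (header optional); the marker file lists `name,time_s` rows for the four
#' canonical timepoints (`baseline_start_s`, `hemorrhage_start_s`,
#' `hemorrhage_end_s`, `hold_end_s`). The sample rate is inferred as the
#' reciprocal of the median time step; timestamps must be uniform.
#'
#' @param path waveform file path.
#' @param marker_path marker file path (optional).
#' @param subject_id,replicate_id identifiers to attach.
#' @param tol relative tolerance on timestamp uniformity.
#' @return A `hw_record`.
#' @export
read_waveform <- function(path, marker_path = NULL,
                          subject_id = "S1", replicate_id = "R1",
                          tol = 1e-3) {
  df <- utils::read.csv(path, header = looks_like_header(path))
  if (ncol(df) < 2L) {
    hw_stop("waveform file needs two columns (time_s, pressure_mmhg): ", path,
            class = "hw_format_error")
  }
  tm <- as.numeric(df[[1]]); pr <- as.numeric(df[[2]])
  if (anyNA(tm) || anyNA(pr)) {
    hw_stop("non-numeric or missing values in waveform file: ", path,
            class = "hw_format_error")
  }
  dt <- diff(tm)
  if (length(dt) < 1L || any(dt <= 0)) {
    hw_stop("timestamps must be strictly increasing", class = "hw_format_error")
  }
  step <- stats::median(dt)
  if (max(abs(dt - step)) > tol * step) {
    hw_stop("non-uniform timestamps beyond tolerance", class = "hw_format_error")
  }
  fs <- 1 / step
  phases <- if (!is.null(marker_path)) read_markers(marker_path) else NULL
  waveform_record(pr, fs, phases, subject_id, replicate_id, t0 = tm[1])
}

looks_like_header <- function(path) {
  first <- readLines(path, n = 1L)
  suppressWarnings(is.na(as.numeric(strsplit(first, ",")[[1]][1])))
}

#' Read a phase-marker file
#' @param path marker file (`name,time_s` rows).
#' @return A `hw_phases`.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, header = looks_like_header(path))
  names(df) <- c("name", "time_s")
  need <- c("baseline_start_s", "hemorrhage_start_s", "hemorrhage_end_s",
            "hold_end_s")
  if (!all(need %in% df$name)) {
    hw_stop("marker file must name all of: ", paste(need, collapse = ", "),
            class = "hw_marker_error")
  }
  v <- stats::setNames(as.numeric(df$time_s), df$name)[need]
  do.call(phase_markers, as.list(v))
}

#' Read a ground-truth shed-volume file
#'
#' Expects `time_s,shed_volume_ml` columns with a `# weight_kg:` comment
#' header, as written by [write_experiment()].
#'
#' @param path truth file path.
#' @param phases a `hw_phases` for the same experiment.
#' @return A `hw_truth`.
#' @export
read_ground_truth <- function(path, phases) {
  lines <- readLines(path)
  wline <- grep("^#\\s*weight_kg", lines, value = TRUE)
  if (length(wline) != 1L) {
    hw_stop("truth file must carry a single '# weight_kg:' header field",
            class = "hw_format_error")
  }
  weight <- as.numeric(sub(".*weight_kg\\s*[:=]\\s*", "", wline))
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  hemorrhage_truth(df$time_s, df$shed_volume_ml, weight, phases)
}

#' Design the default windowed-sinc lowpass taps
#' @param cutoff_hz cutoff frequency (Hz).
#' @param n_taps odd number of taps.
#' @param sample_rate_hz sampling rate (Hz).
#' @return Numeric tap vector normalized to unit DC gain.
#' @export
fir_taps <- function(cutoff_hz, n_taps, sample_rate_hz) {
  if (n_taps %% 2L != 1L) {
    hw_stop("n_taps must be odd for zero-phase group-delay compensation",
            class = "hw_param_error")
  }
  nyq <- sample_rate_hz / 2
  if (cutoff_hz >= nyq) {
    hw_stop("cutoff must be below the Nyquist frequency (", nyq, " Hz)",
            class = "hw_param_error")
  }
  taps <- signal::fir1(n_taps - 1L, cutoff_hz / nyq, type = "low")
  as.numeric(taps) / sum(taps)              # DC gain exactly 1
}

fir_apply <- function(x, taps) {
  half <- (length(taps) - 1L) / 2L
  # reflect padding, then linear convolution trimmed to compensate group delay
  pad <- min(half, length(x) - 1L)
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(length(x) - pad):(length(x) - 1L)]))
  if (pad < half) {                          # very short inputs: extend constant
    xp <- c(rep(xp[1], half - pad), xp, rep(xp[length(xp)], half - pad))
  }
  y <- stats::filter(xp, taps, method = "convolution", sides = 2)
  as.numeric(y[(half + 1L):(half + length(x))])
}

#' FIR window lowpass filter with group-delay compensation
#'
#' Applies a Hamming windowed-sinc lowpass (unit DC gain) to the pressure
#' signal, with reflect padding and symmetric (zero-phase) alignment so beat
#' landmarks keep their time positions. The edge region of half the filter
#' length at each end is recorded in the `edge_guard_s` attribute and is
#' excluded from beat detection.
#'
#' @param record a `hw_record`.
#' @param cutoff_hz lowpass cutoff (Hz); default 25 Hz preserves canine beat
#'   morphology while suppressing line noise.
#' @param n_taps odd tap count; if `NULL` (default), 251 at 500 Hz scaled to
#'   the record's sample rate so the impulse-response duration is
#'   rate-independent.
#' @return A filtered `hw_record`.
#' @export
fir_lowpass <- function(record, cutoff_hz = 25, n_taps = NULL) {
  stopifnot(inherits(record, "hw_record"))
  if (is.null(n_taps)) {
    n_taps <- round(251 * record$sample_rate_hz / 500)
    if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
    n_taps <- max(n_taps, 21L)
  }
  taps <- fir_taps(cutoff_hz, n_taps, record$sample_rate_hz)
  out <- record
  out$pressure <- fir_apply(record$pressure, taps)
  attr(out, "edge_guard_s") <- (length(taps) - 1L) / 2L / record$sample_rate_hz
  attr(out, "fir_taps") <- taps
  out
}

#' Downsample a record by an integer factor
#'
#' Anti-alias filters at 40% of the target Nyquist rate and keeps every
#' (source/target)-th sample. Phase markers are in seconds and unchanged.
#'
#' @param record a `hw_record`.
#' @param target_hz target rate; must divide the source rate.
#' @return A `hw_record` at `target_hz`.
#' @export
downsample <- function(record, target_hz) {
  stopifnot(inherits(record, "hw_record"))
  fs <- record$sample_rate_hz
  ratio <- fs / target_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    hw_stop("target rate must divide the source rate (integer factor); ",
            "rational resampling is not supported", class = "hw_param_error")
  }
  ratio <- as.integer(round(ratio))
  out <- record
  if (ratio > 1L) {
    taps <- fir_taps(0.4 * target_hz, 251L, fs)
    filtered <- fir_apply(record$pressure, taps)
    out$pressure <- filtered[seq(1L, length(filtered), by = ratio)]
  }
  out$sample_rate_hz <- target_hz
  out
}
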