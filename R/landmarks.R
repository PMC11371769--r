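#' Detect pulse feet in a filtered pressure record
#'
#' Systolic peaks are located first (prominence-based peak picking with a
#' minimum spacing of `min_rr_s`); each pulse foot is then located in the
#' window between successive peaks as the onset of the upstroke: the last
#' sample (of a lightly smoothed window) at or below 5% of the window's
#' amplitude above its minimum.
#' A flat or noisy diastolic run therefore resolves to the upstroke onset
#' rather than to an arbitrary noise minimum.
#' The window before the first peak is also searched;
#' boundary-adjacent minima and the post-filter edge-guard region are
#' rejected. This two-stage scheme is robust to the baseline drift seen
#' during hemorrhage.
#'
#' @param record a `hw_record` (already lowpass filtered).
#' @param min_rr_s minimum beat spacing in seconds (default 0.25 s, i.e. a
#'   240 bpm ceiling, above the canine tachycardia range).
#' @param min_prominence_mmhg minimum peak prominence (mmHg); should sit
#'   below the smallest expected pulse pressure.
#' @return Integer vector of foot sample indices (possibly empty, with a
#'   warning, for records shorter than two beats).
#' @export
detect_pulse_feet <- function(record, min_rr_s = 0.25,
                              min_prominence_mmhg = 15) {
  stopifnot(inherits(record, "hw_record"))
  x <- record$pressure
  fs <- record$sample_rate_hz
  guard_s <- attr(record, "edge_guard_s")
  guard <- if (is.null(guard_s)) 0L else as.integer(ceiling(guard_s * fs))
  min_dist <- max(2L, as.integer(round(min_rr_s * fs)))
  pk <- pracma::findpeaks(x, minpeakheight = min(x) + min_prominence_mmhg,
                          zero = "+")
  if (is.null(pk) || nrow(pk) < 2L) {
    warning("record shorter than two beats: no pulse feet detected")
    return(integer(0))
  }
  # greedy spacing enforcement, highest first: a systolic/dicrotic cluster
  # resolves to the systolic (higher) peak
  cand <- pk[order(-pk[, 1]), 2]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || min(abs(kept - p)) >= min_dist) kept <- c(kept, p)
  }
  peaks <- sort(kept)
  # prominence screen relative to the surrounding inter-peak minima
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    lo <- if (i == 1L) 1L else peaks[i - 1L]
    hi <- if (i == length(peaks)) length(x) else peaks[i + 1L]
    prom <- x[peaks[i]] - max(min(x[lo:peaks[i]]), min(x[peaks[i]:hi]))
    keep[i] <- prom >= min_prominence_mmhg
  }
  peaks <- peaks[keep]
  if (length(peaks) < 2L) {
    warning("record shorter than two beats: no pulse feet detected")
    return(integer(0))
  }
  windows <- cbind(c(1L, peaks[-length(peaks)]), peaks)
  feet <- integer(0)
  for (i in seq_len(nrow(windows))) {
    w <- x[windows[i, 1]:windows[i, 2]]
    # the diastolic run can be flat to within the noise, so the raw minimum
    # is ill-posed; anchor the foot on the upstroke instead: the last
    # 5%-amplitude crossing of a lightly smoothed window is stable because
    # the upstroke lies well inside the filter passband
    span <- max(5L, as.integer(round(0.03 * fs)) %/% 2L * 2L + 1L)
    s <- if (length(w) >= span) {
      h <- span %/% 2L
      as.numeric(stats::filter(c(w[h:1], w, w[length(w) - 0:(h - 1L)]),
                               rep(1 / span, span), sides = 2))[
                                 (h + 1L):(h + length(w))]
    } else w
    m <- min(s)
    amp <- s[length(s)] - m
    foot_rel <- max(which(s <= m + 0.05 * amp))
    foot <- windows[i, 1] + foot_rel - 1L
    near_edge <- foot <= max(2L, guard) ||
      foot >= length(x) - max(2L, guard) ||
      (i == 1L && foot <= windows[i, 1] + 1L)
    if (!near_edge) feet <- c(feet, foot)
  }
  feet <- feet[diff(c(-min_dist, feet)) >= min_dist]
  feet
}

sg_second_derivative <- function(x) {
  # local quadratic (Savitzky-Golay) second derivative, 5-point window
  k <- c(2, -1, -2, -1, 2) / 7
  n <- length(x)
  if (n < 5L) return(rep(0, n))
  xp <- c(x[3:2], x, x[(n - 1):(n - 2)])
  as.numeric(stats::filter(xp, rev(k), method = "convolution", sides = 2))[3:(n + 2)]
}

find_inflection <- function(seg, peak_rel, refractory = 3L) {
  # first persisted concave-then-convex transition strictly after the peak;
  # returns NA when no persisted concave run exists (notch-free decay). The
  # refractory skips the filter-smeared peak cap so that lowpass smearing of
  # a sharp notch-free peak is not mistaken for a systolic concave region.
  d2 <- sg_second_derivative(seg)
  n <- length(seg)
  lo <- peak_rel + max(3L, refractory)
  # the dicrotic inflection sits in early diastole; the last quarter of the
  # segment is excluded because the next foot's corner rings under the FIR
  hi <- min(n - 1L, peak_rel + floor(0.75 * (n - peak_rel)))
  if (hi - lo < 3L) return(NA_integer_)
  idx <- lo:hi
  # curvature ripple guard: a concave run must be substantial relative to
  # the post-peak curvature scale, not filter ringing
  tol <- max(0.12 * max(abs(d2[idx]), 0), 1e-9 * max(abs(seg)))
  neg <- d2[idx] < -tol
  pos <- d2[idx] > tol
  run_neg <- neg & c(neg[-1], FALSE)         # >= 2 consecutive negatives
  first_neg <- which(run_neg)[1]
  if (is.na(first_neg)) return(NA_integer_)
  run_pos <- pos & c(pos[-1], FALSE)
  cand <- which(run_pos & seq_along(idx) > first_neg + 1L)[1]
  if (is.na(cand)) return(NA_integer_)
  idx[cand]
}

#' Locate the five fiducial landmarks of each beat
#'
#' For every foot-to-foot segment: the systolic peak is the segment maximum;
#' the half-rise is the first upstroke sample at or above half the
#' foot-to-peak amplitude; the first inflection is the first persisted
#' zero-crossing of the smoothed second derivative after the peak; when no
#' such inflection exists the half-drop fallback is used — the first
#' post-peak sample at or below
#' `peak + half_drop_fraction * (next_foot - peak)` — and `used_half_drop`
#' is set. Beats with non-positive pulse amplitude are marked invalid.
#'
#' @param record a `hw_record`.
#' @param feet foot indices from [detect_pulse_feet()].
#' @param half_drop_fraction weight of the half-drop fallback point between
#'   systolic peak and next foot (default 0.5, the midpoint; the dicrotic
#'   position is physiologically ambiguous so this is a tunable).
#' @param post_peak_refractory_s post-systolic refractory (s) excluded from
#'   the inflection search; default 0.024 s skips the concave cap that
#'   lowpass filtering smears over a sharp notch-free peak while staying
#'   inside the systolic wave width at canine heart rates.
#' @return A `hw_landmarks` data frame with columns `beat_time_s`,
#'   `foot_idx`, `half_rise_idx`, `peak_idx`, `inflection_idx`, `end_idx`,
#'   `used_half_drop`, `valid`. Invalid beats are retained in the output with
#'   `valid = FALSE` so callers can report drop counts; downstream feature
#'   extraction uses valid beats only.
#' @export
locate_landmarks <- function(record, feet, half_drop_fraction = 0.5,
                             post_peak_refractory_s = 0.024) {
  stopifnot(inherits(record, "hw_record"))
  if (length(feet) < 2L) {
    hw_stop("need at least two pulse feet to form a beat segment",
            class = "hw_param_error")
  }
  x <- record$pressure
  fs <- record$sample_rate_hz
  refractory <- as.integer(ceiling(post_peak_refractory_s * fs))
  n_beats <- length(feet) - 1L
  out <- data.frame(beat_time_s = numeric(n_beats), foot_idx = integer(n_beats),
                    half_rise_idx = integer(n_beats), peak_idx = integer(n_beats),
                    inflection_idx = integer(n_beats), end_idx = integer(n_beats),
                    used_half_drop = logical(n_beats), valid = logical(n_beats))
  for (b in seq_len(n_beats)) {
    i0 <- feet[b]; i1 <- feet[b + 1L]
    seg <- x[i0:i1]
    peak_rel <- which.max(seg)
    peak <- i0 + peak_rel - 1L
    amp <- seg[peak_rel] - seg[1]
    valid <- peak_rel > 1L && peak_rel < length(seg) && amp > 0
    half_rise <- NA_integer_; infl <- NA_integer_; fallback <- FALSE
    if (valid) {
      thr <- seg[1] + 0.5 * amp
      hr_rel <- which(seg[2:peak_rel] >= thr)[1] + 1L
      half_rise <- i0 + hr_rel - 1L
      infl_rel <- find_inflection(seg, peak_rel, refractory)
      if (is.na(infl_rel)) {
        fallback <- TRUE
        drop_thr <- seg[peak_rel] +
          half_drop_fraction * (seg[length(seg)] - seg[peak_rel])
        cand <- which(seg[(peak_rel + 1L):(length(seg) - 1L)] <= drop_thr)[1]
        infl_rel <- if (is.na(cand)) NA_integer_ else peak_rel + cand
      }
      if (is.na(infl_rel)) valid <- FALSE else infl <- i0 + infl_rel - 1L
    }
    out$beat_time_s[b] <- record$t0 + (i0 - 1L) / fs
    out$foot_idx[b] <- i0
    out$half_rise_idx[b] <- half_rise
    out$peak_idx[b] <- peak
    out$inflection_idx[b] <- infl
    out$end_idx[b] <- i1
    out$used_half_drop[b] <- fallback
    out$valid[b] <- valid
  }
  n_invalid <- sum(!out$valid)
  if (n_invalid > 0L) {
    message(sprintf("locate_landmarks: %d of %d beats marked invalid",
                    n_invalid, n_beats))
  }
  class(out) <- c("hw_landmarks", "data.frame")
  out
}

#' Keep only valid beats of a landmark table
#' @param landmarks a `hw_landmarks`.
#' @return The valid subset (class preserved).
#' @export
valid_beats <- function(landmarks) {
  out <- landmarks[landmarks$valid, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export landmarks as CSV
#' @param landmarks a `hw_landmarks`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(as.data.frame(landmarks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
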