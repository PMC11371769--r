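#' Simulator configuration for a synthetic canine hemorrhage experiment
#'
#' Defines the protocol (baseline, controlled hemorrhage, shock hold), the
#' hemodynamic response model and the noise model for one subject. The
#' hemorrhage terminates at the first of: the time cap, the commanded mean
#' arterial pressure (MAP) entering the target interval, or shed volume
#' reaching `max_loss_fraction` of the estimated blood volume (80 mL/kg).
#'
#' The hemodynamic response to loss fraction `f` (shed volume / estimated
#' blood volume) is linear and monotone:
#' `MAP(f) = map_baseline_mmhg - map_loss_gain * f`,
#' `PP(f)  = pulse_pressure_baseline_mmhg * (1 - pp_loss_frac * f)`,
#' `HR(f)  = heart_rate_baseline_bpm * (1 + heart_rate_gain * f)`.
#' On top of the commanded MAP the simulator superimposes slow physiological
#' baseline variability (a vasomotor-type sinusoid plus an AR(1) drift),
#' i.i.d. Gaussian measurement noise on the pressure samples, and small
#' per-beat RR jitter.
#'
#' @param sample_rate_hz waveform sampling rate (Hz).
#' @param baseline_duration_s baseline phase duration (s).
#' @param hemorrhage_rate_ml_per_min constant hemorrhage rate (mL/min).
#' @param max_hemorrhage_s time cap on the hemorrhage phase (s).
#' @param map_target_mmhg MAP target interval; hemorrhage stops when the
#'   commanded MAP falls to the upper bound.
#' @param max_loss_fraction stop fraction of estimated blood volume.
#' @param hold_duration_s shock-hold duration (s).
#' @param heart_rate_baseline_bpm,heart_rate_gain heart-rate model.
#' @param pulse_pressure_baseline_mmhg,pp_loss_frac pulse-pressure model.
#' @param map_baseline_mmhg,map_loss_gain MAP model.
#' @param noise_sd_mmhg additive Gaussian sample noise SD (mmHg).
#' @param rr_jitter_sd per-beat multiplicative RR jitter SD (log scale).
#' @param map_osc_amp_mmhg,map_osc_period_s slow MAP oscillation.
#' @param map_drift_sd_mmhg,map_drift_tau_s AR(1) MAP drift (stationary SD
#'   and time constant).
#' @param pp_osc_frac,hr_osc_bpm slow relative pulse-pressure and absolute
#'   heart-rate variability amplitudes.
#' @param dicrotic if `FALSE`, beats are generated without a dicrotic wave
#'   (monotone convex decay) so that the half-drop landmark fallback is
#'   exercised.
#' @param weight_kg subject body weight (kg).
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A validated `hw_sim_config` list.
#' @examples
#' cfg <- sim_config(weight_kg = 20)
#' cfg$max_loss_fraction
#' @export
sim_config <- function(sample_rate_hz = 500,
                       baseline_duration_s = 600,
                       hemorrhage_rate_ml_per_min = 15,
                       max_hemorrhage_s = 3600,
                       map_target_mmhg = c(35, 50),
                       max_loss_fraction = 0.40,
                       hold_duration_s = 2700,
                       heart_rate_baseline_bpm = 90,
                       heart_rate_gain = 0.5,
                       pulse_pressure_baseline_mmhg = 40,
                       pp_loss_frac = 0.5,
                       map_baseline_mmhg = 90,
                       map_loss_gain = 110,
                       noise_sd_mmhg = 1,
                       rr_jitter_sd = 0.02,
                       map_osc_amp_mmhg = 4,
                       map_osc_period_s = 70,
                       map_drift_sd_mmhg = 1.5,
                       map_drift_tau_s = 120,
                       pp_osc_frac = 0.02,
                       hr_osc_bpm = 2,
                       dicrotic = TRUE,
                       weight_kg = 20,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "hw_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is_num1(weight_kg) || weight_kg <= 0) {
      hw_stop("weight_kg must be positive", class = "hw_config_error")
    }
    if (!is_num1(hemorrhage_rate_ml_per_min) || hemorrhage_rate_ml_per_min < 0) {
      hw_stop("hemorrhage rate must be non-negative", class = "hw_config_error")
    }
    if (!(max_loss_fraction > 0 && max_loss_fraction <= 1)) {
      hw_stop("max_loss_fraction must be in (0, 1]", class = "hw_config_error")
    }
    if (baseline_duration_s < 0 || hold_duration_s < 0 || max_hemorrhage_s <= 0) {
      hw_stop("durations must be non-negative (time cap positive)",
              class = "hw_config_error")
    }
    if (length(map_target_mmhg) != 2L || diff(map_target_mmhg) < 0) {
      hw_stop("map_target_mmhg must be an interval c(lo, hi)", class = "hw_config_error")
    }
    if (map_target_mmhg[1] >= map_baseline_mmhg) {
      hw_stop("MAP target lower bound must lie below baseline MAP",
              class = "hw_config_error")
    }
    # sampling must resolve the beat morphology (~25 Hz content)
    if (sample_rate_hz <= 2 * 25) {
      hw_stop("sample_rate_hz too low to resolve beat morphology",
              class = "hw_config_error")
    }
    if (noise_sd_mmhg < 0) hw_stop("noise_sd_mmhg must be >= 0", class = "hw_config_error")
  })
  invisible(cfg)
}

#' Compressed desk-scale simulator configuration
#'
#' A shortened protocol (5 min baseline, hemorrhage reaching its stop
#' condition within ~10 min via a higher withdrawal rate, 5 min hold) at
#' 250 Hz, for test suites and examples; the full protocol remains available
#' through [sim_config()].
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `hw_sim_config`.
#' @export
desk_sim_config <- function(...) {
  defaults <- list(sample_rate_hz = 250, baseline_duration_s = 300,
                   hemorrhage_rate_ml_per_min = 60, hold_duration_s = 300)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Analytic beat template
#'
#' Pressure over one cardiac cycle of length `rr_s`, evaluated at times `t`
#' (seconds from the pulse foot). With a dicrotic wave the template is a
#' diastolic baseline plus two Gaussian bumps (systolic wave and a smaller,
#' delayed dicrotic wave), guaranteeing a post-systolic curvature sign
#' change. Without it, the template is a squared-sine upstroke followed by a
#' convex exponential decay, which has no persisted post-systolic concave
#' region, so landmarking must fall back to the half-drop rule.
#'
#' @param t times within the beat, in seconds (0 = pulse foot).
#' @param rr_s beat length (s).
#' @param map_mmhg,pp_mmhg commanded beat mean and pulse pressure.
#' @param dicrotic logical; include the dicrotic wave.
#' @return Numeric pressures (mmHg) at `t`.
#' @export
beat_template <- function(t, rr_s, map_mmhg, pp_mmhg, dicrotic = TRUE) {
  if (dicrotic) {
    mu1 <- 0.18 * rr_s; s1 <- 0.07 * rr_s
    mu2 <- 0.45 * rr_s; s2 <- 0.06 * rr_s
    a1 <- pp_mmhg
    a2 <- 0.25 * pp_mmhg
    # diastolic level so that the beat mean equals the commanded MAP
    bump_area <- (a1 * s1 + a2 * s2) * sqrt(2 * pi)
    dia <- map_mmhg - bump_area / rr_s
    dia + a1 * exp(-(t - mu1)^2 / (2 * s1^2)) +
      a2 * exp(-(t - mu2)^2 / (2 * s2^2))
  } else {
    tp <- 0.18 * rr_s                       # time of systolic peak
    tau <- 0.22 * rr_s                      # decay constant
    # mean of the template over [0, rr): rise integral + decay integral
    rise_int <- tp / 2                      # integral of sin^2 over the rise
    dec_int <- tau * (1 - exp(-(rr_s - tp) / tau))
    dia <- map_mmhg - pp_mmhg * (rise_int + dec_int) / rr_s
    p <- numeric(length(t))
    up <- t < tp
    p[up] <- dia + pp_mmhg * sin(pi * t[up] / (2 * tp))^2
    p[!up] <- dia + pp_mmhg * exp(-(t[!up] - tp) / tau)
    p
  }
}

sim_loss_fraction <- function(t, cfg, hem_start, hem_end) {
  ebv <- 80 * cfg$weight_kg
  shed_t <- pmin(pmax(t - hem_start, 0), hem_end - hem_start)
  (cfg$hemorrhage_rate_ml_per_min / 60) * shed_t / ebv
}

# analytic hemorrhage end time (relative to hemorrhage start)
sim_hem_duration <- function(cfg) {
  ebv <- 80 * cfg$weight_kg
  rate_s <- cfg$hemorrhage_rate_ml_per_min / 60   # mL/s
  t_cap <- cfg$max_hemorrhage_s
  if (rate_s <= 0) return(t_cap)
  t_vol <- cfg$max_loss_fraction * ebv / rate_s
  map_hi <- cfg$map_target_mmhg[2]
  drop_needed <- cfg$map_baseline_mmhg - map_hi
  t_map <- if (drop_needed <= 0) 0 else
    (drop_needed / cfg$map_loss_gain) * ebv / rate_s
  min(t_cap, t_vol, t_map)
}

#' Simulate one synthetic hemorrhage experiment
#'
#' Generates a continuous arterial pressure record covering baseline,
#' hemorrhage and shock hold, together with the ground-truth shed-volume
#' series. Beats are concatenated analytic templates whose commanded MAP,
#' pulse pressure and heart rate are deterministic monotone functions of the
#' current loss fraction; slow baseline variability, per-beat RR jitter and
#' Gaussian sample noise are added from a seeded stream. Identical configs
#' (including seed) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A `hw_experiment`: list with `record` (`hw_record`), `truth`
#'   (`hw_truth`), `commanded` (per-beat data frame of commanded MAP, pulse
#'   pressure, heart rate and loss fraction) and `config_used`.
#' @examples
#' ex <- simulate_subject(desk_sim_config(baseline_duration_s = 10,
#'   hemorrhage_rate_ml_per_min = 300, hold_duration_s = 10, seed = 7))
#' ex$truth$total_shed_ml
#' @export
simulate_subject <- function(config) {
  validate_sim_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, simulate_subject_impl(cfg))
}

simulate_subject_impl <- function(cfg) {
  fs <- cfg$sample_rate_hz
  hem_start <- cfg$baseline_duration_s
  hem_dur <- sim_hem_duration(cfg)
  hem_end <- hem_start + hem_dur
  total_dur <- hem_end + cfg$hold_duration_s
  n <- round(total_dur * fs)
  pressure <- numeric(n)

  # AR(1) drift sampled on a 1 s grid, interpolated to beat times
  drift_n <- ceiling(total_dur) + 2L
  rho <- exp(-1 / cfg$map_drift_tau_s)
  innov_sd <- cfg$map_drift_sd_mmhg * sqrt(1 - rho^2)
  drift <- numeric(drift_n)
  drift[1] <- rnorm(1, 0, cfg$map_drift_sd_mmhg)
  innov <- rnorm(drift_n - 1L, 0, innov_sd)
  for (i in 2:drift_n) drift[i] <- rho * drift[i - 1L] + innov[i - 1L]
  drift_at <- function(t) {
    stats::approx(seq_len(drift_n) - 1, drift, xout = t, rule = 2)$y
  }
  osc_phase <- runif(3, 0, 2 * pi)

  t <- 0
  beat_time <- beat_map <- beat_pp <- beat_hr <- beat_f <- numeric(0)
  while (t < total_dur) {
    f <- sim_loss_fraction(t, cfg, hem_start, hem_end)
    hr <- cfg$heart_rate_baseline_bpm * (1 + cfg$heart_rate_gain * f) +
      cfg$hr_osc_bpm * sin(2 * pi * t / cfg$map_osc_period_s + osc_phase[3])
    rr <- 60 / hr * exp(rnorm(1, 0, cfg$rr_jitter_sd))
    map_cmd <- cfg$map_baseline_mmhg - cfg$map_loss_gain * f
    map_beat <- map_cmd + drift_at(t) +
      cfg$map_osc_amp_mmhg * sin(2 * pi * t / cfg$map_osc_period_s + osc_phase[1])
    pp <- cfg$pulse_pressure_baseline_mmhg * (1 - cfg$pp_loss_frac * f) *
      (1 + cfg$pp_osc_frac * sin(2 * pi * t / (cfg$map_osc_period_s * 0.8) +
                                   osc_phase[2]))
    i0 <- floor(t * fs) + 1L
    i1 <- min(ceiling((t + rr) * fs), n)
    if (i1 >= i0) {
      ts <- (seq(i0, i1) - 1L) / fs
      inb <- ts >= t & ts < t + rr
      if (any(inb)) {
        pressure[seq(i0, i1)[inb]] <-
          beat_template(ts[inb] - t, rr, map_beat, pp, dicrotic = cfg$dicrotic)
      }
    }
    beat_time <- c(beat_time, t)
    beat_map <- c(beat_map, map_beat)
    beat_pp <- c(beat_pp, pp)
    beat_hr <- c(beat_hr, 60 / rr)
    beat_f <- c(beat_f, f)
    t <- t + rr
  }
  if (cfg$noise_sd_mmhg > 0) {
    pressure <- pressure + rnorm(n, 0, cfg$noise_sd_mmhg)
  }

  phases <- phase_markers(0, hem_start, hem_end, total_dur)
  record <- waveform_record(pressure, fs, phases)
  truth_t <- seq(0, total_dur, by = 1)
  rate_s <- cfg$hemorrhage_rate_ml_per_min / 60
  shed <- rate_s * pmin(pmax(truth_t - hem_start, 0), hem_dur)
  # exact stop volume at the hemorrhage end, as a recorded point
  truth_t <- sort(unique(c(truth_t, hem_end)))
  shed <- rate_s * pmin(pmax(truth_t - hem_start, 0), hem_dur)
  truth <- hemorrhage_truth(truth_t, shed, cfg$weight_kg, phases)

  structure(list(record = record,
                 truth = truth,
                 commanded = data.frame(beat_time_s = beat_time,
                                        map_mmhg = beat_map,
                                        map_cmd_mmhg = cfg$map_baseline_mmhg -
                                          cfg$map_loss_gain * beat_f,
                                        pp_mmhg = beat_pp,
                                        hr_bpm = beat_hr,
                                        loss_fraction = beat_f),
                 config_used = cfg),
            class = "hw_experiment")
}

#' @export
print.hw_experiment <- function(x, ...) {
  cat(sprintf("<hw_experiment> %s/%s, total shed %.1f mL of EBV %.0f mL\n",
              x$record$subject_id, x$record$replicate_id,
              x$truth$total_shed_ml, 80 * x$truth$weight_kg))
  print(x$record)
  invisible(x)
}

#' Simulate a cohort of subjects with replicates
#'
#' Subject-level physiology (weight, baseline MAP, heart rate, pulse
#' pressure) is drawn once per subject and shared across that subject's
#' replicates; noise streams and a small hemorrhage-rate jitter differ per
#' replicate. The default cohort structure mirrors a 6-subject, 5-replicate
#' controlled-hemorrhage study (30 experiments).
#'
#' @param base_config a [sim_config()] used as the template.
#' @param n_subjects number of subjects (>= 2: leave-one-subject-out
#'   cross-validation needs at least two groups).
#' @param n_replicates replicates per subject.
#' @param seed master seed; per-stream seeds are derived via [derive_seed()].
#' @return List of `hw_experiment`, length `n_subjects * n_replicates`.
#' @export
simulate_cohort <- function(base_config, n_subjects = 6, n_replicates = 5,
                            seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 2) {
    hw_stop("n_subjects must be >= 2: leave-one-subject-out cross-validation ",
            "requires at least two subject groups", class = "hw_config_error")
  }
  if (!is_count(n_replicates)) {
    hw_stop("n_replicates must be a positive integer", class = "hw_config_error")
  }
  validate_sim_config(base_config)
  out <- vector("list", n_subjects * n_replicates)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    subj <- withr::with_seed(derive_seed(seed, s, 0L), list(
      weight_kg = runif(1, 18, 30),
      map_baseline_mmhg = rnorm(1, base_config$map_baseline_mmhg, 5),
      heart_rate_baseline_bpm = rnorm(1, base_config$heart_rate_baseline_bpm, 8),
      pulse_pressure_baseline_mmhg =
        rnorm(1, base_config$pulse_pressure_baseline_mmhg, 4)
    ))
    for (r in seq_len(n_replicates)) {
      rate_jit <- withr::with_seed(derive_seed(seed, s, r),
                                   runif(1, 0.9, 1.1))
      cfg <- base_config
      cfg[names(subj)] <- subj
      cfg$hemorrhage_rate_ml_per_min <-
        base_config$hemorrhage_rate_ml_per_min * rate_jit
      cfg$seed <- derive_seed(seed, s, r + 1000L)
      ex <- simulate_subject(cfg)
      ex$record$subject_id <- sprintf("S%02d", s)
      ex$record$replicate_id <- sprintf("R%02d", r)
      k <- k + 1L
      out[[k]] <- ex
    }
  }
  out
}

#' Write a synthetic experiment as plain-text files
#'
#' Emits the same text formats consumed by [read_waveform()] and
#' [read_ground_truth()], so synthetic and real data follow one path:
#' `waveform.csv` (`time_s,pressure_mmhg`), `markers.csv` (`name,time_s`)
#' and `truth.csv` (`time_s,shed_volume_ml` with a `# weight_kg:` header).
#'
#' @param experiment a `hw_experiment`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Invisibly, the three file paths.
#' @export
write_experiment <- function(experiment, dir, prefix = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- experiment$record
  if (is.null(prefix)) {
    prefix <- paste0(rec$subject_id, "_", rec$replicate_id)
  }
  wf <- file.path(dir, paste0(prefix, "_waveform.csv"))
  mk <- file.path(dir, paste0(prefix, "_markers.csv"))
  tr <- file.path(dir, paste0(prefix, "_truth.csv"))
  df <- data.frame(time_s = record_times(rec), pressure_mmhg = rec$pressure)
  utils::write.csv(df, wf, row.names = FALSE, quote = FALSE)
  mdf <- data.frame(name = names(rec$phases), time_s = as.numeric(rec$phases))
  utils::write.csv(mdf, mk, row.names = FALSE, quote = FALSE)
  con <- file(tr, "w")
  writeLines(sprintf("# weight_kg: %.6g", experiment$truth$weight_kg), con)
  utils::write.csv(data.frame(time_s = experiment$truth$times_s,
                              shed_volume_ml = experiment$truth$shed_volume_ml),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(waveform = wf, markers = mk, truth = tr))
}
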