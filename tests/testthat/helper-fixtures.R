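# shared fixtures, built in code

# a clean train of identical template beats with flat diastolic padding;
# beats are concatenated exactly as the simulator concatenates them
make_beat_train <- function(n_beats = 10, rr = 0.6, fs = 500,
                            map = 90, pp = 40, dicrotic = TRUE,
                            pad_s = 0.3, noise_sd = 0, seed = 1) {
  t_beat <- seq(0, rr - 1 / fs, by = 1 / fs)
  one <- beat_template(t_beat, rr, map, pp, dicrotic = dicrotic)
  dia_end <- beat_template(rr - 1e-9, rr, map, pp, dicrotic = dicrotic)
  pad <- rep(dia_end, round(pad_s * fs))
  x <- c(pad, rep(one, n_beats), pad)
  if (noise_sd > 0) x <- x + withr::with_seed(seed, rnorm(length(x), 0, noise_sd))
  list(record = waveform_record(x, fs),
       beat_starts = length(pad) + (seq_len(n_beats) - 1L) * length(one) + 1L,
       beat_len = length(one), rr = rr, fs = fs, map = map, pp = pp,
       template = function(t) beat_template(t, rr, map, pp, dicrotic = dicrotic))
}

# small deterministic truth object covering all three phases
make_truth <- function(weight_kg = 20, total = 640, baseline = 60,
                       hem = 120, hold = 60, rate_pts = 241) {
  phases <- phase_markers(0, baseline, baseline + hem, baseline + hem + hold)
  tt <- seq(0, baseline + hem + hold, length.out = rate_pts)
  shed <- pmin(pmax(tt - baseline, 0) / hem, 1) * total
  hemorrhage_truth(tt, shed, weight_kg, phases)
}

# memoised tiny cohort + datasets for model-level tests
tiny_env <- new.env(parent = emptyenv())
tiny_datasets <- function() {
  if (!is.null(tiny_env$ds)) return(tiny_env)
  base <- desk_sim_config(baseline_duration_s = 60,
                          hemorrhage_rate_ml_per_min = 200,
                          hold_duration_s = 60)
  cohort <- simulate_cohort(base, n_subjects = 3, n_replicates = 2, seed = 5)
  registry <- build_registry(feature_config(
    families = c("duration", "amplitude", "slope", "area", "pressure")))
  ds <- lapply(cohort, prepare_dataset, registry = registry, metric = "BLVM")
  tiny_env$cohort <- cohort
  tiny_env$registry <- registry
  tiny_env$ds <- ds
  tiny_env
}

# memoised desk-scale 6x5 cohort shared by the acceptance tests
desk_env <- new.env(parent = emptyenv())
desk_run <- function() {
  if (!is.null(desk_env$cmp)) return(desk_env)
  cohort <- simulate_cohort(desk_sim_config(), n_subjects = 6,
                            n_replicates = 5, seed = 11)
  registry <- build_registry(feature_config(families = c(
    "duration", "amplitude", "slope", "area", "pressure", "rolling")))
  ds <- lapply(cohort, prepare_dataset, registry = registry, metric = "BLVM")
  cfg <- model_config(n_features = 10, min_leaf_size = 8, n_learners = 30)
  preds_blvm <- loso_cv(ds, cfg, smooth_window = 500)
  ds_pebl <- lapply(seq_along(ds), function(i) {
    d <- ds[[i]]
    d$target <- compute_pebl(cohort[[i]]$truth, d$features$beat_times_s)
    d
  })
  cfg$target_metric <- "PEBL"
  preds_pebl <- loso_cv(ds_pebl, cfg, smooth_window = 500)
  pred_sets <- lapply(seq_along(ds), function(i) {
    pb <- preds_blvm[[i]]; pp <- preds_pebl[[i]]
    mk <- function(t, v, nm) structure(data.frame(time_s = t, value = v),
                                       class = c("hw_metric", "data.frame"),
                                       metric_name = nm)
    list(subject_id = pb$subject_id, replicate_id = pb$replicate_id,
         phases = ds[[i]]$record$phases,
         series = list(BLVM = mk(pb$times_s, pb$smoothed, "BLVM"),
                       PEBL = mk(pp$times_s, pp$smoothed, "PEBL"),
                       HemArea = hemarea_from_blvm(mk(pb$times_s, pb$smoothed,
                                                      "BLVM")),
                       MAP = ds[[i]]$map))
  })
  desk_env$cohort <- cohort
  desk_env$ds <- ds
  desk_env$preds_blvm <- preds_blvm
  desk_env$preds_pebl <- preds_pebl
  desk_env$pred_sets <- pred_sets
  desk_env$cmp <- compare_predictors(pred_sets)
  desk_env
}
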