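LANDMARK_NAMES <- c("foot", "half_rise", "peak", "inflection", "end")
LANDMARK_PAIRS <- {
  p <- t(utils::combn(5L, 2L))
  data.frame(from = LANDMARK_NAMES[p[, 1]], to = LANDMARK_NAMES[p[, 2]],
             stringsAsFactors = FALSE)
}
AREA_SPANS <- data.frame(from = c("foot", "peak", "inflection", "foot"),
                         to = c("peak", "inflection", "end", "end"),
                         stringsAsFactors = FALSE)
ROLL_STATS <- c("mean", "sd", "rmssd", "min", "max")
PRESSURE_FEATURES <- c("map", "systolic", "diastolic", "pulse_pressure")

#' Feature extraction configuration
#'
#' Selects the feature families and rolling-window sizes expanded by
#' [build_registry()]. Families: `duration` (time between every ordered
#' landmark pair plus the RR interval), `amplitude` (pressure differences
#' between landmark pairs), `slope` (amplitude over duration), `area`
#' (trapezoidal areas above the foot-value baseline over the spans
#' foot-peak, peak-inflection, inflection-end, foot-end), `pressure`
#' (per-beat MAP, systolic, diastolic, pulse pressure), `ratio` (ordered
#' pairwise ratios of all base features) and `rolling` (trailing-window
#' mean, SD, RMS of successive differences, min and max of each base
#' feature).
#'
#' @param families character subset of the families above (duplicates are
#'   collapsed); the default enables all of them.
#' @param rolling_windows trailing window sizes in beats.
#' @return A `hw_feature_config`.
#' @export
feature_config <- function(families = c("duration", "amplitude", "slope",
                                        "area", "pressure", "ratio",
                                        "rolling"),
                           rolling_windows = c(5L, 15L, 30L)) {
  if (length(families) == 0L) {
    hw_stop("at least one feature family must be enabled", class = "hw_config_error")
  }
  families <- unique(match.arg(families, several.ok = TRUE))
  if ("rolling" %in% families && length(rolling_windows) == 0L) {
    hw_stop("rolling family enabled but no windows given", class = "hw_config_error")
  }
  structure(list(families = families,
                 rolling_windows = sort(unique(as.integer(rolling_windows)))),
            class = "hw_feature_config")
}

base_feature_names <- function(families) {
  nm <- character(0)
  pair_lab <- paste0(LANDMARK_PAIRS$from, "_", LANDMARK_PAIRS$to)
  if ("duration" %in% families) nm <- c(nm, paste0("dur_", pair_lab), "rr_interval")
  if ("amplitude" %in% families) nm <- c(nm, paste0("amp_", pair_lab))
  if ("slope" %in% families) nm <- c(nm, paste0("slope_", pair_lab))
  if ("area" %in% families) {
    nm <- c(nm, paste0("area_", AREA_SPANS$from, "_", AREA_SPANS$to))
  }
  if ("pressure" %in% families) nm <- c(nm, PRESSURE_FEATURES)
  nm
}

#' Build the per-beat feature registry
#'
#' Deterministic Cartesian expansion of the enabled families (see
#' [feature_config()]). With every family enabled the default registry holds
#' 2,106 features: 39 base features (11 durations including the RR interval,
#' 10 amplitudes, 10 slopes, 4 areas, 4 pressure scalars), 39 x 38 = 1,482
#' ordered pairwise ratios, and 39 x 5 statistics x 3 windows = 585 rolling
#' features. The realized length is reported by `print()` and recorded in
#' pipeline manifests.
#'
#' @param config a [feature_config()].
#' @return A `hw_registry` data frame with columns `name`, `family`,
#'   `params`, and attributes `version` and `config`.
#' @export
build_registry <- function(config = feature_config()) {
  stopifnot(inherits(config, "hw_feature_config"))
  fams <- config$families
  base <- base_feature_names(fams)
  base_fam <- c(if ("duration" %in% fams) rep("duration", 11L),
                if ("amplitude" %in% fams) rep("amplitude", 10L),
                if ("slope" %in% fams) rep("slope", 10L),
                if ("area" %in% fams) rep("area", 4L),
                if ("pressure" %in% fams) rep("pressure", 4L))
  entries <- data.frame(name = base, family = base_fam, params = "",
                        stringsAsFactors = FALSE)
  if ("ratio" %in% fams && length(base) > 1L) {
    grid <- expand.grid(den = base, num = base, stringsAsFactors = FALSE)
    grid <- grid[grid$num != grid$den, c("num", "den")]
    ord <- order(match(grid$num, base), match(grid$den, base))
    grid <- grid[ord, ]
    entries <- rbind(entries,
                     data.frame(name = paste0("ratio_", grid$num, "_over_", grid$den),
                                family = "ratio",
                                params = paste0(grid$num, "/", grid$den),
                                stringsAsFactors = FALSE))
  }
  if ("rolling" %in% fams && length(base) > 0L) {
    grid <- expand.grid(base = base, stat = ROLL_STATS,
                        window = config$rolling_windows,
                        stringsAsFactors = FALSE)
    grid <- grid[order(match(grid$base, base), match(grid$stat, ROLL_STATS),
                       grid$window), ]
    entries <- rbind(entries,
                     data.frame(name = paste0("roll_", grid$stat, grid$window,
                                              "_", grid$base),
                                family = "rolling",
                                params = paste0(grid$stat, ",w=", grid$window),
                                stringsAsFactors = FALSE))
  }
  entries <- entries[!duplicated(entries$name), ]
  rownames(entries) <- NULL
  structure(entries, class = c("hw_registry", "data.frame"),
            version = "1", config = config)
}

#' @export
print.hw_registry <- function(x, ...) {
  cat(sprintf("<hw_registry> v%s: %d features\n", attr(x, "version"), nrow(x)))
  print(table(x$family))
  invisible(x)
}

landmark_matrix <- function(landmarks) {
  lm <- valid_beats(landmarks)
  cbind(foot = lm$foot_idx, half_rise = lm$half_rise_idx, peak = lm$peak_idx,
        inflection = lm$inflection_idx, end = lm$end_idx)
}

compute_base_features <- function(record, landmarks, families) {
  x <- record$pressure
  fs <- record$sample_rate_hz
  idx <- landmark_matrix(landmarks)
  n <- nrow(idx)
  cols <- list()
  pair_lab <- paste0(LANDMARK_PAIRS$from, "_", LANDMARK_PAIRS$to)
  durs <- amps <- NULL
  if (any(c("duration", "amplitude", "slope") %in% families)) {
    durs <- sapply(seq_len(nrow(LANDMARK_PAIRS)), function(k) {
      (idx[, LANDMARK_PAIRS$to[k]] - idx[, LANDMARK_PAIRS$from[k]]) / fs
    })
    amps <- sapply(seq_len(nrow(LANDMARK_PAIRS)), function(k) {
      x[idx[, LANDMARK_PAIRS$to[k]]] - x[idx[, LANDMARK_PAIRS$from[k]]]
    })
    durs <- matrix(durs, nrow = n); amps <- matrix(amps, nrow = n)
  }
  if ("duration" %in% families) {
    for (k in seq_along(pair_lab)) cols[[paste0("dur_", pair_lab[k])]] <- durs[, k]
    cols[["rr_interval"]] <- (idx[, "end"] - idx[, "foot"]) / fs
  }
  if ("amplitude" %in% families) {
    for (k in seq_along(pair_lab)) cols[[paste0("amp_", pair_lab[k])]] <- amps[, k]
  }
  if ("slope" %in% families) {
    for (k in seq_along(pair_lab)) {
      cols[[paste0("slope_", pair_lab[k])]] <- amps[, k] / durs[, k]
    }
  }
  if ("area" %in% families) {
    for (k in seq_len(nrow(AREA_SPANS))) {
      a <- numeric(n)
      i_from <- idx[, AREA_SPANS$from[k]]; i_to <- idx[, AREA_SPANS$to[k]]
      foot_val <- x[idx[, "foot"]]
      for (b in seq_len(n)) {
        a[b] <- trapz_above_base(x[i_from[b]:i_to[b]], foot_val[b], 1 / fs)
      }
      cols[[paste0("area_", AREA_SPANS$from[k], "_", AREA_SPANS$to[k])]] <- a
    }
  }
  if ("pressure" %in% families) {
    mapv <- numeric(n)
    for (b in seq_len(n)) {
      mapv[b] <- mean(x[idx[b, "foot"]:(idx[b, "end"] - 1L)])
    }
    cols[["map"]] <- mapv
    cols[["systolic"]] <- x[idx[, "peak"]]
    cols[["diastolic"]] <- x[idx[, "foot"]]
    cols[["pulse_pressure"]] <- x[idx[, "peak"]] - x[idx[, "foot"]]
  }
  do.call(cbind, cols)
}

#' Extract the registry's features for every valid beat
#'
#' One row per valid beat, columns in registry order. Rolling features use
#' trailing (causal) windows with shrinking windows over the first beats, so
#' truncating the record after beat k never changes rows 1..k. Features that
#' reference the inflection landmark are computed identically whether the
#' landmark is a true inflection or the half-drop fallback. Ratio features
#' return 0 when the denominator magnitude is below 1e-9 (documented
#' degenerate convention keeping all features finite).
#'
#' @param record a `hw_record`.
#' @param landmarks a `hw_landmarks` for the record.
#' @param registry a [build_registry()] output.
#' @return A `hw_features` object: list with `values` (beats x features
#'   matrix), `beat_times_s`, `feature_names`, `subject_id`, `replicate_id`.
#' @export
extract_features <- function(record, landmarks, registry = build_registry()) {
  stopifnot(inherits(record, "hw_record"), inherits(registry, "hw_registry"))
  lm <- valid_beats(landmarks)
  if (nrow(lm) == 0L) hw_stop("no valid beats to extract", class = "hw_param_error")
  cfg <- attr(registry, "config")
  fams <- cfg$families
  base <- compute_base_features(record, landmarks, fams)
  blocks <- list(base)
  if ("ratio" %in% fams && ncol(base) > 1L) {
    bn <- colnames(base)
    ratio_entries <- registry[registry$family == "ratio", ]
    nm <- sub("^ratio_", "", ratio_entries$name)
    num <- sub("_over_.*$", "", nm)
    den <- sub("^.*_over_", "", nm)
    denm <- base[, den, drop = FALSE]
    r <- base[, num, drop = FALSE] / denm
    r[abs(denm) < 1e-9] <- 0
    colnames(r) <- ratio_entries$name
    blocks <- c(blocks, list(r))
  }
  if ("rolling" %in% fams && ncol(base) > 0L) {
    roll_entries <- registry[registry$family == "rolling", ]
    rcols <- matrix(0, nrow(base), nrow(roll_entries),
                    dimnames = list(NULL, roll_entries$name))
    fun_map <- list(mean = roll_mean, sd = roll_sd, rmssd = roll_rmssd,
                    min = roll_min, max = roll_max)
    stat <- sub(",.*$", "", roll_entries$params)
    win <- as.integer(sub("^.*w=", "", roll_entries$params))
    colb <- sub("^roll_[a-z]+[0-9]+_", "", roll_entries$name)
    for (j in seq_len(nrow(roll_entries))) {
      rcols[, j] <- fun_map[[stat[j]]](base[, colb[j]], win[j])
    }
    blocks <- c(blocks, list(rcols))
  }
  values <- do.call(cbind, blocks)
  values <- values[, registry$name, drop = FALSE]
  structure(list(values = values,
                 beat_times_s = lm$beat_time_s,
                 feature_names = registry$name,
                 subject_id = record$subject_id,
                 replicate_id = record$replicate_id,
                 registry_version = attr(registry, "version")),
            class = "hw_features")
}

#' @export
print.hw_features <- function(x, ...) {
  cat(sprintf("<hw_features> %s/%s: %d beats x %d features\n",
              x$subject_id, x$replicate_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Persist a feature matrix as CSV with a JSON sidecar
#' @param features a `hw_features`.
#' @param path CSV output path; the sidecar is written as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  df <- data.frame(beat_time_s = features$beat_times_s,
                   features$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(registry_version = features$registry_version,
                            subject_id = features$subject_id,
                            replicate_id = features$replicate_id,
                            n_features = ncol(features$values)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
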