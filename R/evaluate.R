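#' Regression scores of predictions against ground truth
#'
#' The headline R-squared is from the linear regression of predictions on
#' ground truth (the square of their correlation); the coefficient of
#' determination `1 - SSE/SST` is also returned for reference. RMSE is the
#' root mean squared prediction error, and NRMSE divides it by the range of
#' the ground-truth data so models on different scales can be compared.
#'
#' @param pred,truth equal-length numeric series (>= 2 points).
#' @return List with `r_squared` (regression), `rmse`, and additionally
#'   `nrmse` and `cod` from [regression_report()].
#' @export
regression_scores <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2L) {
    hw_stop("pred and truth must be equal-length series of >= 2 points",
            class = "hw_param_error")
  }
  if (stats::sd(truth) == 0) {
    hw_stop("constant ground truth: R-squared is undefined",
            class = "hw_degenerate_error")
  }
  r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, truth)^2
  rmse <- sqrt(mean((pred - truth)^2))
  list(r_squared = r2, rmse = rmse)
}

#' @rdname regression_scores
#' @export
regression_report <- function(pred, truth) {
  sc <- regression_scores(pred, truth)
  rng <- max(truth) - min(truth)
  sc$nrmse <- sc$rmse / rng
  sc$cod <- 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  sc
}

#' Robust linear fit of predictions against ground truth
#'
#' Ordinary least squares is always computed; when more than `trigger_frac`
#' of the studentized residuals exceed `trigger_abs` in magnitude, an
#' iteratively reweighted least-squares fit with bisquare weights is run to
#' reduce sensitivity to the outliers. Both fits and the final robust
#' weights are returned for audit.
#'
#' @param pred,truth equal-length numeric series.
#' @param trigger_frac,trigger_abs outlier criterion on studentized
#'   residuals (defaults: > 1% beyond |3|).
#' @param force_robust always run the robust fit.
#' @return List with `slope`, `intercept`, `weights`, `robust_used`, `ols`
#'   (slope/intercept of the plain fit).
#' @export
robust_fit <- function(pred, truth, trigger_frac = 0.01, trigger_abs = 3,
                       force_robust = FALSE) {
  if (length(pred) != length(truth) || length(pred) < 2L) {
    hw_stop("pred and truth must be equal-length series of >= 2 points",
            class = "hw_param_error")
  }
  ols <- stats::lm(pred ~ truth)
  res <- stats::rstudent(ols)
  res[!is.finite(res)] <- 0
  outlier_frac <- mean(abs(res) > trigger_abs)
  use_robust <- force_robust || outlier_frac > trigger_frac
  if (use_robust && length(pred) > 2L) {
    rfit <- MASS::rlm(pred ~ truth, psi = MASS::psi.bisquare, maxit = 50)
    if (!rfit$converged) {
      warning("robust fit did not converge; returning last iterate")
    }
    list(slope = unname(coef(rfit)[2]), intercept = unname(coef(rfit)[1]),
         weights = rfit$w, robust_used = TRUE,
         ols = list(slope = unname(coef(ols)[2]),
                    intercept = unname(coef(ols)[1])))
  } else {
    list(slope = unname(coef(ols)[2]), intercept = unname(coef(ols)[1]),
         weights = rep(1, length(pred)), robust_used = FALSE,
         ols = list(slope = unname(coef(ols)[2]),
                    intercept = unname(coef(ols)[1])))
  }
}

#' Per-beat mean arterial pressure
#'
#' MAP for each beat is the mean pressure over the foot-to-foot segment
#' (half-open: the next foot belongs to the next beat), reported at the
#' beat time.
#'
#' @param record a `hw_record`.
#' @param landmarks a `hw_landmarks`.
#' @return A `hw_metric` series named "MAP".
#' @export
compute_map <- function(record, landmarks) {
  lm <- valid_beats(landmarks)
  if (nrow(lm) < 1L) hw_stop("need at least one beat", class = "hw_param_error")
  x <- record$pressure
  mapv <- vapply(seq_len(nrow(lm)), function(b) {
    mean(x[lm$foot_idx[b]:(lm$end_idx[b] - 1L)])
  }, numeric(1))
  new_metric_series(lm$beat_time_s, mapv, "MAP")
}

#' Normalize a metric series to fixed-length study regions
#'
#' Linearly interpolates the series onto `points_per_region` equally spaced
#' query times within each of the baseline, hemorrhage and shock-hold
#' regions (half-open spacing `start + (0:(p-1))/p * duration`), so
#' datasets of different durations become comparable point-by-point.
#'
#' @param metric a `hw_metric` (beat-aligned times and values).
#' @param phases a `hw_phases`.
#' @param points_per_region points per region (default 100).
#' @return List with `times_s`, `values` (length `3 * points_per_region`),
#'   `region` (factor: baseline/hemorrhage/hold) and `phases`.
#' @export
region_normalize <- function(metric, phases, points_per_region = 100L) {
  stopifnot(inherits(phases, "hw_phases"))
  p <- points_per_region
  bounds <- list(baseline = c(phases[["baseline_start_s"]],
                              phases[["hemorrhage_start_s"]]),
                 hemorrhage = c(phases[["hemorrhage_start_s"]],
                                phases[["hemorrhage_end_s"]]),
                 hold = c(phases[["hemorrhage_end_s"]], phases[["hold_end_s"]]))
  for (r in names(bounds)) {
    n_in <- sum(metric$time_s >= bounds[[r]][1] & metric$time_s < bounds[[r]][2])
    if (n_in < 2L) {
      hw_stop("region '", r, "' contains fewer than 2 samples",
              class = "hw_param_error")
    }
  }
  times <- unlist(lapply(bounds, function(b) {
    b[1] + (seq_len(p) - 1L) / p * (b[2] - b[1])
  }), use.names = FALSE)
  vals <- stats::approx(metric$time_s, metric$value, xout = times, rule = 2)$y
  list(times_s = times, values = vals,
       region = factor(rep(c("baseline", "hemorrhage", "hold"), each = p),
                       levels = c("baseline", "hemorrhage", "hold")),
       phases = phases)
}

#' ROC curve and AUROC for baseline-vs-hemorrhage discrimination
#'
#' Thresholds sweep the unique score values; AUROC is the probability that
#' a hemorrhage point outranks a baseline point, with ties counting one
#' half. The orientation is set automatically so an informative predictor
#' scores above 0.5, and the chosen direction is recorded.
#'
#' @param scores numeric predictor values.
#' @param labels logical or 0/1 vector (TRUE/1 = hemorrhage).
#' @return List with `auroc`, `direction` (1 if higher score means
#'   hemorrhage, -1 if flipped) and `roc` (data frame of fpr/tpr).
#' @export
roc_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    hw_stop("both classes must be present for ROC analysis",
            class = "hw_param_error")
  }
  auc_for <- function(s) {
    r <- rank(s)                            # midranks handle ties as 1/2
    n1 <- sum(labels); n0 <- sum(!labels)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  a <- auc_for(scores)
  direction <- if (a >= 0.5) 1 else -1
  s <- scores * direction
  a <- max(a, 1 - a)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  roc <- t(vapply(thr, function(th) {
    pos <- s >= th
    c(fpr = mean(pos[!labels]), tpr = mean(pos[labels]))
  }, numeric(2)))
  list(auroc = a, direction = direction,
       roc = data.frame(threshold = thr, fpr = roc[, 1], tpr = roc[, 2]))
}

#' Detection configuration
#'
#' @param direction "falling" for metrics that drop during hemorrhage
#'   (BLVM, MAP) or "rising" for metrics that increase (PEBL, HemArea); the
#'   baseline threshold percentile follows the direction (25th for falling,
#'   75th for rising).
#' @param consecutive_required consecutive positive points required.
#' @param points_per_region normalized points per study region.
#' @return A `hw_detection_config`.
#' @export
detection_config <- function(direction = c("falling", "rising"),
                             consecutive_required = 5L,
                             points_per_region = 100L) {
  direction <- match.arg(direction)
  structure(list(direction = direction,
                 percentile = if (direction == "falling") 25 else 75,
                 consecutive_required = as.integer(consecutive_required),
                 points_per_region = as.integer(points_per_region)),
            class = "hw_detection_config")
}

#' Hemorrhage detection latency on a region-normalized series
#'
#' The threshold is the stated percentile of the `points_per_region`
#' baseline points (25th for falling metrics, 75th for rising). Each
#' post-baseline point is positive when strictly beyond the threshold
#' (strict comparison: a flat baseline equal to its own percentile must not
#' self-trigger). Detection is the first run of `consecutive_required`
#' positive points; the reported time is the onset (first index) of the
#' run, with the completion index also returned, converted to minutes after
#' hemorrhage onset via the region's real duration.
#'
#' @param normalized output of [region_normalize()].
#' @param config a [detection_config()].
#' @return List with `detected`, `detection_min` (Inf when never detected),
#'   `onset_index`, `completion_index`, `completion_min`, `threshold`.
#' @export
detection_time <- function(normalized, config = detection_config()) {
  p <- config$points_per_region
  vals <- normalized$values
  if (length(vals) != 3L * p) {
    hw_stop("normalized series must hold 3 x points_per_region values",
            class = "hw_param_error")
  }
  baseline <- vals[seq_len(p)]
  thr <- stats::quantile(baseline, config$percentile / 100, names = FALSE,
                         type = 7)
  post <- vals[(p + 1L):(3L * p)]
  positive <- if (config$direction == "falling") post < thr else post > thr
  m <- config$consecutive_required
  runs <- stats::filter(as.numeric(positive), rep(1, m), sides = 1)
  onset_rel <- which(runs == m)[1] - m + 1L
  if (is.na(onset_rel)) {
    return(list(detected = FALSE, detection_min = Inf,
                onset_index = NA_integer_, completion_index = NA_integer_,
                completion_min = Inf, threshold = thr))
  }
  onset <- p + onset_rel                    # 1-based index into the 3p series
  completion <- onset + m - 1L
  hem_start <- normalized$phases[["hemorrhage_start_s"]]
  to_min <- function(i) (normalized$times_s[i] - hem_start) / 60
  list(detected = TRUE,
       detection_min = to_min(onset),
       onset_index = onset,
       completion_index = completion,
       completion_min = to_min(completion),
       threshold = thr)
}

PREDICTOR_DIRECTIONS <- c(BLVM = "falling", PEBL = "rising",
                          HemArea = "rising", MAP = "falling")

#' Compare predictors by AUROC and detection latency
#'
#' For each dataset and each predictor series, region-normalizes the
#' series, computes the baseline-vs-hemorrhage AUROC (first two regions)
#' and the detection latency, then averages over replicates within subject
#' and across subjects. No-detection results are censored at the end of the
#' hold when averaging, and the number detected is reported.
#'
#' @param pred_sets list of datasets; each a list with `subject_id`,
#'   `replicate_id`, `phases`, and `series` (named list of `hw_metric`,
#'   e.g. BLVM, PEBL, HemArea, MAP).
#' @param directions named character vector mapping predictor names to
#'   "falling"/"rising"; defaults cover BLVM, PEBL, HemArea, MAP.
#' @param points_per_region normalized points per region.
#' @return List with `per_dataset` (long data frame), `summary` (one row
#'   per predictor: mean AUROC, mean detection minutes, n detected) and
#'   `ranking` (predictors ordered by mean detection time).
#' @export
compare_predictors <- function(pred_sets, directions = PREDICTOR_DIRECTIONS,
                               points_per_region = 100L) {
  rows <- list()
  for (ds in pred_sets) {
    cens_min <- (ds$phases[["hold_end_s"]] -
                   ds$phases[["hemorrhage_start_s"]]) / 60
    for (nm in names(ds$series)) {
      dir <- directions[[nm]]
      if (is.null(dir)) hw_stop("no direction known for predictor ", nm,
                                class = "hw_param_error")
      norm <- region_normalize(ds$series[[nm]], ds$phases, points_per_region)
      p <- points_per_region
      roc <- roc_auroc(norm$values[seq_len(2L * p)],
                       rep(c(FALSE, TRUE), each = p))
      det <- detection_time(norm, detection_config(dir, points_per_region =
                                                     points_per_region))
      rows[[length(rows) + 1L]] <-
        data.frame(subject = ds$subject_id, replicate = ds$replicate_id,
                   predictor = nm, auroc = roc$auroc,
                   detected = det$detected,
                   detection_min = min(det$detection_min, cens_min),
                   stringsAsFactors = FALSE)
    }
  }
  per_ds <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_ds, per_ds$predictor), function(d) {
    by_subj <- stats::aggregate(cbind(auroc, detection_min) ~ subject,
                                data = d, mean)
    data.frame(predictor = d$predictor[1],
               mean_auroc = mean(by_subj$auroc),
               mean_detection_min = mean(by_subj$detection_min),
               n_detected = sum(d$detected), n_datasets = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  ranking <- summ$predictor[order(summ$mean_detection_min)]
  list(per_dataset = per_ds, summary = summ, ranking = ranking)
}
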