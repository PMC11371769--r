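test_that("regression scores match a closed-form normal-equations oracle", {
  expect_equal(regression_scores(1:10 + 0.0, 1:10 + 0.0),
               list(r_squared = 1, rmse = 0))
  # uniform offset: RMSE equals the offset
  tr <- seq(0, 1, length.out = 50)
  sc <- regression_scores(tr + 0.1, tr)
  expect_equal(sc$rmse, 0.1)
  expect_equal(sc$r_squared, 1)
  withr::with_seed(12, {
    truth <- rnorm(50); pred <- 0.8 * truth + rnorm(50, 0, 0.3)
    sc <- regression_scores(pred, truth)
    # oracle from raw sums (textbook normal equations)
    n <- 50
    sxy <- sum(pred * truth) - sum(pred) * sum(truth) / n
    sxx <- sum(truth^2) - sum(truth)^2 / n
    syy <- sum(pred^2) - sum(pred)^2 / n
    expect_equal(sc$r_squared, sxy^2 / (sxx * syy), tolerance = 1e-12)
    expect_equal(sc$rmse, sqrt(mean((pred - truth)^2)), tolerance = 1e-12)
  })
  expect_error(regression_scores(1:5 + 0.0, rep(1, 5)),
               class = "hw_degenerate_error")
})

test_that("normalized RMSE honours its defining identity and affine invariance", {
  withr::with_seed(13, {
    truth <- runif(100); pred <- truth + rnorm(100, 0, 0.05)
    rep1 <- regression_report(pred, truth)
    expect_equal(rep1$nrmse * (max(truth) - min(truth)), rep1$rmse,
                 tolerance = 1e-14)
    # scaling both series by a > 0 leaves NRMSE unchanged
    rep2 <- regression_report(7.3 * pred, 7.3 * truth)
    expect_equal(rep2$nrmse, rep1$nrmse, tolerance = 1e-12)
    expect_equal(rep2$r_squared, rep1$r_squared, tolerance = 1e-12)
  })
})

test_that("robust regression downweights gross outliers", {
  withr::with_seed(14, {
    truth <- seq(0, 10, length.out = 60)
    pred <- 2 * truth + 1 + rnorm(60, 0, 0.05)
    clean <- robust_fit(pred, truth)
    expect_false(clean$robust_used)
    expect_equal(clean$slope, 2, tolerance = 0.01)
    expect_true(all(clean$weights == 1))
    # one gross outlier
    pred_c <- pred; pred_c[30] <- 60
    fit <- robust_fit(pred_c, truth)
    expect_true(fit$robust_used)
    expect_lt(fit$weights[30], 0.1)
    expect_lt(abs(fit$slope - 2), abs(fit$ols$slope - 2))
    # two points: exact line
    two <- robust_fit(c(1, 3), c(0, 1))
    expect_equal(two$slope, 2)
    expect_equal(two$intercept, 1)
  })
})

test_that("per-beat MAP equals segment means", {
  rec <- waveform_record(rep(80, 3000), 500)
  lmk <- structure(data.frame(beat_time_s = c(0, 1, 2),
                              foot_idx = c(1L, 501L, 1001L),
                              half_rise_idx = c(10L, 510L, 1010L),
                              peak_idx = c(100L, 600L, 1100L),
                              inflection_idx = c(200L, 700L, 1200L),
                              end_idx = c(501L, 1001L, 1501L),
                              used_half_drop = FALSE, valid = TRUE),
                   class = c("hw_landmarks", "data.frame"))
  expect_equal(compute_map(rec, lmk)$value, rep(80, 3))
  # symmetric triangular beat 60 -> 120 -> 60: mean 90
  tri <- c(seq(60, 120, length.out = 251), seq(120, 60, length.out = 251)[-1])
  rec2 <- waveform_record(rep(tri[-501], 3), 500)
  lmk2 <- structure(data.frame(beat_time_s = c(0, 1),
                               foot_idx = c(1L, 501L),
                               half_rise_idx = c(100L, 600L),
                               peak_idx = c(251L, 751L),
                               inflection_idx = c(400L, 900L),
                               end_idx = c(501L, 1001L),
                               used_half_drop = FALSE, valid = TRUE),
                    class = c("hw_landmarks", "data.frame"))
  expect_equal(compute_map(rec2, lmk2)$value, rep(90, 2), tolerance = 1e-3)
  # simulator beats against a dense-mean oracle (noiseless)
  tr <- make_beat_train(n_beats = 5, rr = 0.5, fs = 500, map = 85, pp = 35)
  lmk3 <- locate_landmarks(tr$record, detect_pulse_feet(tr$record))
  m <- compute_map(tr$record, lmk3)
  lv <- valid_beats(lmk3)
  for (b in seq_len(nrow(lv))) {
    dense <- approx(seq_along(tr$record$pressure), tr$record$pressure,
                    xout = seq(lv$foot_idx[b], lv$end_idx[b] - 1, by = 0.1))$y
    expect_equal(m$value[b], mean(dense), tolerance = 0.01)
  }
})

test_that("region normalization equals direct piecewise-linear interpolation", {
  phases <- phase_markers(0, 100, 200, 300)
  tt <- seq(0, 300, by = 0.5)
  mk <- function(v) structure(data.frame(time_s = tt, value = v),
                              class = c("hw_metric", "data.frame"),
                              metric_name = "X")
  # constant series -> constant 300-point output
  rn <- region_normalize(mk(rep(2, length(tt))), phases, 100)
  expect_length(rn$values, 300)
  expect_equal(rn$values, rep(2, 300))
  # sawtooth versus the direct interpolation formula
  saw <- ((tt / 7) %% 1) * 3
  rn2 <- region_normalize(mk(saw), phases, 100)
  oracle <- approx(tt, saw, xout = rn2$times_s, rule = 2)$y
  expect_equal(rn2$values, oracle)
  # nodes already on the query grid reproduce exactly (linear values)
  lin <- structure(data.frame(time_s = rn2$times_s, value = rn2$times_s * 2),
                   class = c("hw_metric", "data.frame"), metric_name = "X")
  rn3 <- region_normalize(lin, phases, 100)
  expect_equal(rn3$values, rn3$times_s * 2, tolerance = 1e-10)
  # per-region monotone min/max preservation
  mono <- mk(sort(runif(length(tt))))
  rn4 <- region_normalize(mono, phases, 100)
  expect_gte(min(rn4$values), min(mono$value))
  expect_lte(max(rn4$values), max(mono$value))
  # a region with < 2 samples errors, naming the region
  sparse <- structure(data.frame(time_s = c(0, 50, 150, 160, 250),
                                 value = 1:5),
                      class = c("hw_metric", "data.frame"), metric_name = "X")
  expect_error(region_normalize(structure(
    data.frame(time_s = c(0, 150, 160, 250), value = 1:4),
    class = c("hw_metric", "data.frame"), metric_name = "X"), phases, 100),
    regexp = "baseline", class = "hw_param_error")
})

test_that("AUROC equals exhaustive pairwise concordance, with tie and transform invariance", {
  conc_oracle <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  # perfectly separated
  expect_equal(roc_auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auroc, 1)
  # all identical scores
  expect_equal(roc_auroc(rep(1, 10), rep(c(FALSE, TRUE), 5))$auroc, 0.5)
  # worked concordance example: 2 of 4 pairs concordant
  r <- roc_auroc(c(0.9, 0.3, 0.8, 0.4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auroc,
               conc_oracle(c(0.9, 0.3, 0.8, 0.4), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(r$auroc, 0.5)
  withr::with_seed(15, {
    for (rep in 1:5) {
      n <- sample(20:200, 1)
      labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
      scores <- round(rnorm(n) + labels, 1)     # rounding induces ties
      got <- roc_auroc(scores, labels)$auroc
      want <- conc_oracle(scores, labels)
      want <- max(want, 1 - want)               # orientation auto-set
      expect_equal(got, want, tolerance = 1e-12)
      # invariance under a strictly monotone transform
      expect_equal(roc_auroc(exp(scores), labels)$auroc, got,
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auroc(1:5, rep(TRUE, 5)), class = "hw_param_error")
})

test_that("cross-check: AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(16, {
    labels <- runif(120) > 0.5
    scores <- rnorm(120) + 0.8 * labels
    ours <- roc_auroc(scores, labels)$auroc
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, direction = "<"))))
    expect_equal(ours, max(ref, 1 - ref), tolerance = 1e-12)
  })
})

test_that("detection time equals a direct 5-consecutive-run scan", {
  phases <- phase_markers(0, 100, 200, 300)
  norm <- function(v) list(times_s = c(seq(0, 99), seq(100, 199),
                                       seq(200, 299)),
                           values = v,
                           region = factor(rep(c("baseline", "hemorrhage",
                                                 "hold"), each = 100)),
                           phases = phases)
  # flat baseline at 1.0 then permanent drop to 0.5 at normalized index 100
  v <- c(rep(1, 100), rep(0.5, 200))
  det <- detection_time(norm(v), detection_config("falling"))
  expect_true(det$detected)
  expect_equal(det$onset_index, 101)       # 1-based: first hemorrhage point
  expect_equal(det$completion_index, 105)  # the run completes 4 points later
  expect_equal(det$detection_min, 0)       # onset at hemorrhage start
  expect_equal(det$completion_min, 4 / 60)
  # never crossing: no detection
  det2 <- detection_time(norm(rep(1, 300)), detection_config("falling"))
  expect_false(det2$detected)
  expect_identical(det2$detection_min, Inf)
  # a 4-point transient dip does not qualify
  v3 <- rep(1, 300); v3[150:153] <- 0
  det3 <- detection_time(norm(v3), detection_config("falling"))
  expect_false(det3$detected)
  # direct scan oracle on randomized series
  withr::with_seed(17, {
    for (rep in 1:10) {
      v <- c(runif(100, 0.9, 1.1), runif(200, 0.5, 1.1))
      cfgd <- detection_config("falling")
      det <- detection_time(norm(v), cfgd)
      thr <- quantile(v[1:100], 0.25, names = FALSE)
      pos <- v[101:300] < thr
      onset <- NA
      for (i in seq_len(196)) {
        if (all(pos[i:(i + 4)])) { onset <- i; break }
      }
      if (is.na(onset)) {
        expect_false(det$detected)
      } else {
        expect_equal(det$onset_index, onset + 100)
      }
    }
  })
})

test_that("making post-baseline values more extreme never delays detection", {
  phases <- phase_markers(0, 100, 200, 300)
  withr::with_seed(18, {
    v <- c(runif(100, 0.95, 1.05), runif(200, 0.7, 1.05))
    norm <- list(times_s = seq(0, 299), values = v,
                 region = factor(rep(c("baseline", "hemorrhage", "hold"),
                                     each = 100)), phases = phases)
    det1 <- detection_time(norm, detection_config("falling"))
    v2 <- v; v2[101:300] <- v2[101:300] - 0.2
    norm2 <- norm; norm2$values <- v2
    det2 <- detection_time(norm2, detection_config("falling"))
    expect_lte(det2$detection_min, det1$detection_min)
  })
})

test_that("compare_predictors aggregates and ranks; identical series tie", {
  phases <- phase_markers(0, 100, 200, 300)
  tt <- seq(0, 300, by = 0.5)
  base <- 1 - pmin(pmax(tt - 100, 0) / 100, 1) * 0.8
  mk <- function(v, nm) structure(data.frame(time_s = tt, value = v),
                                  class = c("hw_metric", "data.frame"),
                                  metric_name = nm)
  ds <- list(subject_id = "S1", replicate_id = "R1", phases = phases,
             series = list(BLVM = mk(base, "BLVM"), MAP = mk(base, "MAP")))
  cmp <- compare_predictors(list(ds))
  expect_equal(nrow(cmp$per_dataset), 2)
  d <- cmp$per_dataset
  expect_equal(d$detection_min[d$predictor == "BLVM"],
               d$detection_min[d$predictor == "MAP"])
  expect_equal(d$auroc[1], d$auroc[2])
})
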