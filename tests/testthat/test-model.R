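# independent brute-force MRMR oracle: explicit MI tables + greedy MID scheme
oracle_mi <- function(bx, by) {
  tab <- table(bx, by) / length(bx)
  px <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  }
  s
}
oracle_bin <- function(x, nb = 10) {
  br <- unique(quantile(x, seq(0, 1, length.out = nb + 1), names = FALSE,
                        type = 1))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}
oracle_mrmr <- function(X, y, k, nb = 10) {
  BX <- apply(X, 2, oracle_bin, nb = nb)
  by <- oracle_bin(y, nb)
  rel <- sapply(seq_len(ncol(X)), function(j) oracle_mi(BX[, j], by))
  sel <- integer(0)
  for (step in seq_len(k)) {
    score <- sapply(seq_len(ncol(X)), function(j) {
      if (j %in% sel) return(-Inf)
      if (!length(sel)) rel[j] else
        rel[j] - mean(sapply(sel, function(s) oracle_mi(BX[, j], BX[, s])))
    })
    sel <- c(sel, which.max(score))
  }
  colnames(X)[sel]
}

test_that("MRMR ranking matches an exhaustive brute-force oracle", {
  withr::with_seed(21, {
    n <- 400
    target <- runif(n)
    X <- cbind(A = target + rnorm(n, 0, 0.05),
               C = rnorm(n))
    X <- cbind(X, B = X[, "A"])            # exact copy of A
    X <- X[, c("A", "B", "C")]
    got <- mrmr_rank(X, target, k = 3)
    want <- oracle_mrmr(X, target, k = 3)
    expect_identical(got, want)
    # the informative feature ranks first; its exact copy is fully redundant,
    # so independent noise outranks it once the redundancy penalty applies
    expect_identical(got[1], "A")
    expect_identical(got[2], "C")
  })
  # randomized instances against the oracle
  withr::with_seed(33, {
    for (rep in 1:3) {
      n <- 200; p <- 6
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("f", 1:p)))
      y <- X[, 1] * 2 + X[, 3] + rnorm(n)
      expect_identical(mrmr_rank(X, y, k = 4), oracle_mrmr(X, y, k = 4))
    }
  })
})

test_that("MRMR handles degenerate selections deterministically", {
  X <- matrix(c(1:20), ncol = 1, dimnames = list(NULL, "only"))
  y <- rnorm(20)
  expect_identical(mrmr_rank(X, y, 1), "only")
  # two identical features: both selected, copy ranked second
  X2 <- cbind(a = 1:50 + rnorm(50, 0, 0.1), b = 0)
  X2[, "b"] <- X2[, "a"]
  expect_identical(mrmr_rank(X2, seq_len(50) + rnorm(50), 2), c("a", "b"))
  expect_error(mrmr_rank(X2, rep(1, 50), 2), class = "hw_param_error")
  expect_error(mrmr_rank(X2, rnorm(50), 3), class = "hw_param_error")
})

test_that("bagged trees recover a step function and are deterministic", {
  withr::with_seed(10, {
    x <- runif(200, -1, 1)
    y <- as.numeric(x >= 0)
    X <- data.frame(x = x)
    cfg <- model_config(n_features = 1, min_leaf_size = 4, n_learners = 20)
    model <- train_bagged_trees(X, y, cfg)
    pred <- predict(model, X)
    # a depth-1 tree oracle splitting at 0 achieves R^2 = 1; the ensemble
    # must be nearly as good on the training data
    expect_gte(cor(pred, y)^2, 0.95)
    # constant target: perfect fit
    m0 <- train_bagged_trees(X, rep(2.5, 200), cfg)
    expect_equal(predict(m0, X), rep(2.5, 200))
    # same data + seed: identical predictions
    m2 <- train_bagged_trees(X, y, cfg)
    expect_identical(predict(m2, X), pred)
    expect_error(train_bagged_trees(X, y, model_config(min_leaf_size = 300)),
                 class = "hw_degenerate_error")
  })
})

test_that("single-learner mode degenerates to one tree on the full data", {
  withr::with_seed(11, {
    X <- data.frame(x = runif(100))
    y <- X$x * 3
    m <- train_bagged_trees(X, y, model_config(n_learners = 1,
                                               min_leaf_size = 4))
    expect_length(m$trees, 1)
    expect_equal(predict(m, X), as.numeric(predict(m$trees[[1]],
                                                   newdata = X)))
  })
})

test_that("LOSO folds exclude the held-out subject and cover all replicates", {
  env <- tiny_datasets()
  preds <- loso_cv(env$ds, model_config(n_features = 5, n_learners = 5),
                   smooth_window = 50)
  expect_length(preds, length(env$ds))
  folds <- attr(preds, "folds")
  expect_length(folds, 3)           # one fold per subject
  for (s in names(folds)) {
    expect_false(s %in% folds[[s]]$model$training_subjects)
  }
  # two subjects, one replicate: each trained on the other
  ds2 <- env$ds[c(1, 3)]
  p2 <- loso_cv(ds2, model_config(n_features = 5, n_learners = 5),
                smooth_window = 50)
  f2 <- attr(p2, "folds")
  expect_identical(f2[["S01"]]$model$training_subjects, "S02")
  expect_identical(f2[["S02"]]$model$training_subjects, "S01")
  expect_error(loso_cv(env$ds[1:2], model_config()), class = "hw_param_error")
})

test_that("training a fold is blind to the held-out subject's data", {
  env <- tiny_datasets()
  cfg <- model_config(n_features = 5, n_learners = 5, seed = 3)
  full <- loso_cv(env$ds, cfg, smooth_window = 50)
  f_full <- attr(full, "folds")
  # the fold that holds out S03 must equal a model trained directly on the
  # pooled S01+S02 data with the same configuration (hash comparison of
  # predictions on a fixed probe)
  train_idx <- 1:4                  # S01 and S02 datasets
  Xtr <- do.call(rbind, lapply(env$ds[train_idx],
                               function(d) d$features$values))
  ytr <- unlist(lapply(env$ds[train_idx], function(d) d$target$value))
  sel <- mrmr_rank(Xtr, ytr, k = cfg$n_features)
  direct <- train_bagged_trees(Xtr[, sel, drop = FALSE], ytr, cfg)
  expect_identical(f_full[["S03"]]$selected_features, sel)
  probe <- env$ds[[1]]$features$values[1:50, ]
  expect_identical(
    rlang::hash(predict(f_full[["S03"]]$model,
                        probe[, f_full[["S03"]]$selected_features])),
    rlang::hash(predict(direct, probe[, sel])))
})

test_that("feature rankings are recomputed per fold and can differ across folds", {
  withr::with_seed(19, {
    # subject A carries the signal in column "sig"; subject B carries it in
    # column "nse": each fold must rank the other subject's informative
    # column first
    mk <- function(subject, swap) {
      n <- 300
      y <- seq(0, 1, length.out = n)
      clean <- y + rnorm(n, 0, 0.01)
      noise <- rnorm(n)
      X <- if (swap) cbind(sig = noise, nse = clean) else
        cbind(sig = clean, nse = noise)
      list(features = structure(list(values = X, beat_times_s = seq_len(n),
                                     feature_names = colnames(X),
                                     subject_id = subject,
                                     replicate_id = "R01"),
                                class = "hw_features"),
           target = structure(data.frame(time_s = seq_len(n), value = y),
                              class = c("hw_metric", "data.frame"),
                              metric_name = "BLVM"))
    }
    ds <- list(mk("A", FALSE), mk("B", TRUE))
    preds <- loso_cv(ds, model_config(n_features = 1, n_learners = 3),
                     smooth_window = 10)
    folds <- attr(preds, "folds")
    expect_identical(folds[["A"]]$selected_features, "nse")  # trained on B
    expect_identical(folds[["B"]]$selected_features, "sig")  # trained on A
  })
})

test_that("prediction smoothing equals an explicit windowed-mean oracle", {
  expect_equal(smooth_predictions(rep(3, 20), 5), rep(3, 20))
  # series shorter than the window: global mean everywhere
  expect_equal(smooth_predictions(c(1, 2, 3), 500), rep(2, 3))
  # unit step, window 5, versus a direct loop with symmetric shrinking
  # clipped centered windows (MATLAB movmean convention)
  win_oracle <- function(x, w) {
    before <- floor((w - 1) / 2); after <- w - 1 - before
    sapply(seq_along(x), function(i) {
      mean(x[max(i - before, 1):min(i + after, length(x))])
    })
  }
  x <- c(rep(0, 10), rep(1, 10))
  expect_equal(smooth_predictions(x, 5), win_oracle(x, 5))
  withr::with_seed(4, {
    x <- rnorm(101)
    for (w in c(1, 2, 7, 100, 101)) {
      expect_equal(smooth_predictions(x, w), win_oracle(x, w),
                   tolerance = 1e-12)
    }
  })
  expect_error(smooth_predictions(1:10, 0), class = "hw_param_error")
})

test_that("grid search scores all 12 configurations and applies the tie-breaks", {
  env <- tiny_datasets()
  gs <- grid_search(env$ds, n_learners = 3, smooth_window = 50)
  expect_equal(nrow(gs$table), 12)
  expect_setequal(unique(gs$table$n_features), c(5, 10, 20))
  expect_setequal(unique(gs$table$min_leaf_size), c(4, 8, 12, 16))
  best_row <- which(gs$table$n_features == gs$best$n_features &
                      gs$table$min_leaf_size == gs$best$min_leaf_size)
  expect_equal(gs$table$mean_r_squared[best_row],
               max(gs$table$mean_r_squared))
  # single-config grid: best is that config
  g1 <- grid_search(env$ds, grid = data.frame(n_features = 5,
                                              min_leaf_size = 8),
                    n_learners = 3, smooth_window = 50)
  expect_equal(g1$best$n_features, 5)
  expect_equal(g1$best$min_leaf_size, 8)
})
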