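#' Model configuration
#'
#' The tuning grid used for the decision-tree ensembles: number of MRMR-
#' selected features in {5, 10, 20} and minimum leaf size in {4, 8, 12, 16},
#' i.e. 12 configurations per prediction metric. `n_learners` defaults to 30
#' bootstrap trees; a documented single-tree mode (`n_learners = 1`) is
#' available since bagging with one learner degenerates to a single CART fit
#' on a bootstrap resample.
#'
#' @param n_features number of features selected by MRMR.
#' @param min_leaf_size minimum observations per terminal leaf.
#' @param n_learners trees in the bagged ensemble.
#' @param target_metric one of "BLVM", "PEBL", "HemArea".
#' @param seed integer seed for the bootstrap streams.
#' @return A `hw_model_config`.
#' @export
model_config <- function(n_features = 10L, min_leaf_size = 8L,
                         n_learners = 30L,
                         target_metric = c("BLVM", "PEBL", "HemArea"),
                         seed = 1L) {
  target_metric <- match.arg(target_metric)
  stopifnot(is_count(n_features), is_count(min_leaf_size), is_count(n_learners))
  structure(list(n_features = as.integer(n_features),
                 min_leaf_size = as.integer(min_leaf_size),
                 n_learners = as.integer(n_learners),
                 target_metric = target_metric,
                 seed = as.integer(seed)),
            class = "hw_model_config")
}

#' The default hyperparameter grid
#' @return Data frame of 12 rows: `n_features` in {5,10,20} crossed with
#'   `min_leaf_size` in {4,8,12,16}.
#' @export
default_grid <- function() {
  expand.grid(n_features = c(5L, 10L, 20L), min_leaf_size = c(4L, 8L, 12L, 16L),
              KEEP.OUT.ATTRS = FALSE)
}

# equal-frequency discretization into at most n_bins bins
ef_bin <- function(x, n_bins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               na.rm = TRUE, names = FALSE, type = 1))
  if (length(br) < 2L) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

mi_binned <- function(bx, by, nx, ny) {
  n <- length(bx)
  joint <- tabulate(bx + nx * (by - 1L), nbins = nx * ny) / n
  px <- tabulate(bx, nbins = nx) / n
  py <- tabulate(by, nbins = ny) / n
  pij <- joint[joint > 0]
  outer_p <- as.numeric(outer(px, py))[joint > 0]
  sum(pij * log(pij / outer_p))
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' MID (mutual-information difference) scheme: the first feature maximizes
#' mutual information (MI) with the target; each subsequent feature
#' maximizes `relevance - mean(MI with already-selected features)`. MI is
#' estimated by equal-frequency binning (default 10 bins) of both feature
#' and target. Deterministic: ties are broken by registry (column) order.
#'
#' @param features a `hw_features`, or a numeric matrix with column names.
#' @param target a `hw_metric` aligned 1:1 with the feature rows, or a
#'   numeric vector.
#' @param k number of features to select.
#' @param n_bins bins for the MI estimate.
#' @return Character vector of `k` selected feature names, in rank order.
#' @export
mrmr_rank <- function(features, target, k, n_bins = 10L) {
  X <- if (inherits(features, "hw_features")) features$values else features
  y <- if (inherits(target, "hw_metric")) target$value else target
  if (nrow(X) != length(y)) {
    hw_stop("feature rows and target values are not aligned", class = "hw_param_error")
  }
  p <- ncol(X)
  if (!is_count(k) || k > p) {
    hw_stop("k must be a positive count <= number of features (", p, ")",
            class = "hw_param_error")
  }
  if (length(unique(y)) < 2L) {
    hw_stop("constant target: relevance is undefined", class = "hw_param_error")
  }
  by <- ef_bin(y, n_bins)
  BX <- apply(X, 2L, ef_bin, n_bins = n_bins)
  relevance <- vapply(seq_len(p), function(j) {
    mi_binned(BX[, j], by, n_bins, n_bins)
  }, numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    score <- if (step == 1L) relevance else
      relevance - red_sum / length(selected)
    score[selected] <- -Inf
    pick <- which.max(score)               # which.max takes the first tie
    selected <- c(selected, pick)
    if (step < k) {
      cand <- setdiff(seq_len(p), selected)
      for (j in cand) {
        red_sum[j] <- red_sum[j] + mi_binned(BX[, j], BX[, pick], n_bins, n_bins)
      }
    }
  }
  colnames(X)[selected]
}

#' Train a bagged ensemble of CART regression trees
#'
#' Each tree is grown on a bootstrap resample (sampling n of n with
#' replacement, seeded) with the configured minimum leaf size and no
#' complexity pruning; the ensemble prediction is the mean over trees.
#'
#' @param X numeric matrix or data frame of predictors (no NA).
#' @param y numeric target vector.
#' @param config a [model_config()].
#' @return A `hw_model`: list with `trees`, `selected_features` (the
#'   training column names), `config_used`, `training_subjects`.
#' @export
train_bagged_trees <- function(X, y, config = model_config()) {
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) hw_stop("NA in training data", class = "hw_param_error")
  n <- nrow(X)
  if (config$min_leaf_size >= n) {
    hw_stop("min_leaf_size >= number of training samples: degenerate model",
            class = "hw_degenerate_error")
  }
  dat <- cbind(.y = y, X)
  ctrl <- rpart::rpart.control(minbucket = config$min_leaf_size,
                               minsplit = 2L * config$min_leaf_size,
                               cp = 1e-6, xval = 0L,
                               maxsurrogate = 0L, usesurrogate = 0L)
  trees <- withr::with_seed(config$seed, lapply(seq_len(config$n_learners),
    function(i) {
      rows <- if (config$n_learners == 1L) seq_len(n) else
        sample.int(n, n, replace = TRUE)
      rpart::rpart(.y ~ ., data = dat[rows, , drop = FALSE], control = ctrl)
    }))
  structure(list(trees = trees,
                 selected_features = colnames(X),
                 config_used = config,
                 training_subjects = character(0)),
            class = "hw_model")
}

#' @export
predict.hw_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$selected_features, drop = FALSE]
  preds <- vapply(object$trees, function(tr) {
    as.numeric(predict(tr, newdata = newdata))
  }, numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Centered moving-mean smoothing with shrinking edge windows
#'
#' The window shrinks symmetrically at both edges so the output has the
#' same length as the input; a series shorter than the window smooths to
#' its global mean at every point. Used to generalize prediction trends
#' (default 500 prediction points).
#'
#' @param raw numeric series.
#' @param window window size in points (>= 1).
#' @return Smoothed numeric series, same length.
#' @export
smooth_predictions <- function(raw, window = 500L) {
  if (!is_count(window)) {
    hw_stop("window must be a positive integer", class = "hw_param_error")
  }
  n <- length(raw)
  if (n == 0L) return(raw)
  before <- floor((window - 1) / 2)
  after <- window - 1L - before
  cs <- cumsum(c(0, raw))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

dataset_ids <- function(datasets) {
  data.frame(subject = vapply(datasets, function(d) d$features$subject_id, ""),
             replicate = vapply(datasets, function(d) d$features$replicate_id, ""))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: MRMR ranking and ensemble training use only the
#' remaining subjects' pooled beats, and every replicate of the held-out
#' subject is predicted blind. With 6 subjects x 5 replicates this yields 30
#' blind prediction datasets.
#'
#' @param datasets list of datasets, each a list with elements `features`
#'   (a `hw_features`) and `target` (a `hw_metric` aligned to its beats).
#' @param config a [model_config()].
#' @param smooth_window moving-mean window for the smoothed predictions.
#' @return A `hw_predictions`: list with one element per dataset carrying
#'   `subject_id`, `replicate_id`, `times_s`, `raw`, `smoothed`, `truth`,
#'   plus attributes `folds` (selected features per fold) and `config`.
#' @export
loso_cv <- function(datasets, config = model_config(), smooth_window = 500L) {
  ids <- dataset_ids(datasets)
  subjects <- unique(ids$subject)
  if (length(subjects) < 2L) {
    hw_stop("leave-one-subject-out needs >= 2 subjects", class = "hw_param_error")
  }
  out <- vector("list", length(datasets))
  folds <- list()
  for (s in subjects) {
    train_idx <- which(ids$subject != s)
    test_idx <- which(ids$subject == s)
    stopifnot(length(intersect(train_idx, test_idx)) == 0L)
    Xtr <- do.call(rbind, lapply(datasets[train_idx],
                                 function(d) d$features$values))
    ytr <- unlist(lapply(datasets[train_idx], function(d) d$target$value))
    sel <- mrmr_rank(Xtr, ytr, k = config$n_features)
    model <- train_bagged_trees(Xtr[, sel, drop = FALSE], ytr, config)
    model$training_subjects <- setdiff(subjects, s)
    folds[[s]] <- list(selected_features = sel, model = model)
    for (i in test_idx) {
      d <- datasets[[i]]
      raw <- predict(model, d$features$values)
      out[[i]] <- list(subject_id = d$features$subject_id,
                       replicate_id = d$features$replicate_id,
                       times_s = d$features$beat_times_s,
                       raw = raw,
                       smoothed = smooth_predictions(raw, smooth_window),
                       truth = d$target$value)
    }
  }
  structure(out, class = "hw_predictions", folds = folds, config = config)
}

#' Grid search over the hyperparameter grid with LOSO scoring
#'
#' Runs [loso_cv()] for every grid row, scoring each configuration by the
#' regression R-squared and RMSE of the smoothed predictions, averaged over
#' replicates within subject and then across subjects. The best
#' configuration maximizes mean R-squared, with ties broken by lower RMSE
#' and then by fewer features.
#'
#' @param datasets as in [loso_cv()].
#' @param grid data frame with columns `n_features`, `min_leaf_size`
#'   (default [default_grid()], 12 configurations).
#' @param n_learners,seed,smooth_window passed through to the models.
#' @param target_metric label recorded in the result.
#' @return List with `table` (one row per configuration: n_features,
#'   min_leaf_size, mean_r_squared, mean_rmse) and `best` (a
#'   [model_config()]).
#' @export
grid_search <- function(datasets, grid = default_grid(),
                        target_metric = "BLVM", n_learners = 30L, seed = 1L,
                        smooth_window = 500L) {
  if (nrow(grid) == 0L) hw_stop("empty grid", class = "hw_param_error")
  ids <- dataset_ids(datasets)
  res <- grid
  res$mean_r_squared <- NA_real_
  res$mean_rmse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg <- model_config(n_features = grid$n_features[g],
                        min_leaf_size = grid$min_leaf_size[g],
                        n_learners = n_learners,
                        target_metric = target_metric, seed = seed)
    preds <- loso_cv(datasets, cfg, smooth_window = smooth_window)
    per_ds <- t(vapply(preds, function(p) {
      unlist(regression_scores(p$smoothed, p$truth))
    }, numeric(2)))
    by_subj <- rowsum(per_ds, ids$subject) / as.vector(table(ids$subject)[
      sort(unique(ids$subject))])
    res$mean_r_squared[g] <- mean(by_subj[, 1])
    res$mean_rmse[g] <- mean(by_subj[, 2])
  }
  ord <- order(-res$mean_r_squared, res$mean_rmse, res$n_features)
  best <- res[ord[1], ]
  list(table = res,
       best = model_config(n_features = best$n_features,
                           min_leaf_size = best$min_leaf_size,
                           n_learners = n_learners,
                           target_metric = target_metric, seed = seed))
}
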