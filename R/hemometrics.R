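new_metric_series <- function(times_s, values, metric_name) {
  structure(data.frame(time_s = times_s, value = values),
            class = c("hw_metric", "data.frame"), metric_name = metric_name)
}

#' @export
print.hw_metric <- function(x, ...) {
  cat(sprintf("<hw_metric> %s: %d points, range [%.4g, %.4g]\n",
              attr(x, "metric_name"), nrow(x), min(x$value), max(x$value)))
  invisible(x)
}

#' Blood loss volume metric (BLVM)
#'
#' `BLVM(t) = 1 - shed(t) / total_shed` over baseline and hemorrhage, on a
#' 0-1 scale (1 = no blood loss, 0 = maximal loss). During the shock hold
#' the metric is 0 by definition: maximal hemorrhage volume is maintained
#' with no active hemorrhage. Volumes at query times use previous-value
#' (step) interpolation.
#'
#' @param truth a [hemorrhage_truth()].
#' @param query_times times (s) at which to evaluate, typically beat times.
#' @return A `hw_metric` series named "BLVM".
#' @examples
#' tr <- hemorrhage_truth(c(0, 10, 20, 30), c(0, 0, 250, 500), 20,
#'                        phase_markers(0, 10, 30, 40))
#' compute_blvm(tr, c(5, 25, 35))$value
#' @export
compute_blvm <- function(truth, query_times) {
  stopifnot(inherits(truth, "hw_truth"))
  if (!is_num1(truth$total_shed_ml) || truth$total_shed_ml <= 0) {
    hw_stop("total shed volume must be positive; a study with no hemorrhage ",
            "has no defined BLVM", class = "hw_degenerate_error")
  }
  v <- 1 - shed_at(truth, query_times) / truth$total_shed_ml
  v[query_times >= truth$phases[["hemorrhage_end_s"]]] <- 0
  new_metric_series(query_times, v, "BLVM")
}

#' Percent estimated blood loss (PEBL)
#'
#' `PEBL(t) = shed(t) / (80 mL/kg x weight_kg)`: shed volume as a fraction
#' of the estimated total blood volume. Constant during the hold at its
#' hemorrhage-end value (the shed series is frozen there).
#'
#' @inheritParams compute_blvm
#' @return A `hw_metric` series named "PEBL".
#' @export
compute_pebl <- function(truth, query_times) {
  stopifnot(inherits(truth, "hw_truth"))
  ebv <- 80 * truth$weight_kg
  new_metric_series(query_times, shed_at(truth, query_times) / ebv, "PEBL")
}

#' Cumulative hemorrhage area from a BLVM series
#'
#' `HemArea(k) = sum_{i<=k} |BLVM(t_i) - 1| * dt_i` with
#' `dt_i = t_i - t_{i-1}` (left-rectangle slices; the first slice uses the
#' first available step). Non-decreasing by construction, and keeps growing
#' during the hold where BLVM is defined as 0 (integrand 1).
#'
#' @param blvm a `hw_metric` series on the 0-1 BLVM scale with strictly
#'   increasing times.
#' @return A `hw_metric` series named "HemArea" (unit: seconds times the
#'   0-1 metric, i.e. fraction-seconds).
#' @export
hemarea_from_blvm <- function(blvm) {
  t <- blvm$time_s
  if (is.unsorted(t, strictly = TRUE)) {
    hw_stop("BLVM times must be strictly increasing", class = "hw_param_error")
  }
  dt <- diff(t)
  dt <- c(if (length(dt)) dt[1] else 0, dt)
  new_metric_series(t, cumsum(abs(blvm$value - 1) * dt), "HemArea")
}

#' Cumulative hemorrhage area from the ground-truth volume series
#'
#' Rectangle-rule cumulative integral of shed volume over time (mL*s),
#' evaluated at the query times. It keeps increasing through the shock hold:
#' the shed volume is constant there but the volume-duration burden grows.
#'
#' @inheritParams compute_blvm
#' @return A `hw_metric` series named "HemAreaTruth".
#' @export
hemarea_ground_truth <- function(truth, query_times) {
  stopifnot(inherits(truth, "hw_truth"))
  t <- as.numeric(query_times)
  if (is.unsorted(t, strictly = TRUE)) {
    hw_stop("query times must be strictly increasing", class = "hw_param_error")
  }
  v <- shed_at(truth, t)
  dt <- diff(t)
  dt <- c(if (length(dt)) dt[1] else 0, dt)
  new_metric_series(t, cumsum(v * dt), "HemAreaTruth")
}

#' Export a metric series as CSV
#' @param metric a `hw_metric`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_metric <- function(metric, path) {
  df <- data.frame(time_s = metric$time_s, value = metric$value,
                   metric_name = attr(metric, "metric_name"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
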