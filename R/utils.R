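#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx quantile rnorm runif sd predict lm median coef
#'   residuals
#' @importFrom utils read.csv write.csv head tail
NULL

hw_stop <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "hw_error"))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a per-stream RNG seed from a master seed
#'
#' Deterministic key scheme mapping (master seed, subject, replicate) to a
#' 32-bit seed so each subject-replicate gets an independent, reproducible
#' random stream.
#'
#' @param master integer master seed.
#' @param subject subject index (0 for subject-level draws).
#' @param replicate replicate index (0 for subject-level draws).
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(master, subject = 0L, replicate = 0L) {
  m <- as.double(master) %% 1048576          # keep products in double-exact range
  s <- (m * 1009 + as.double(subject) * 7919 + as.double(replicate) * 104729) %%
    2147483647
  as.integer(s)
}

# trailing (causal) rolling statistics with shrinking windows at the start ----

roll_embed <- function(x, n, fun_row) {
  # full windows via embed(), shrinking head windows computed directly
  len <- length(x)
  if (len == 0L) return(numeric(0))
  n <- min(n, len)
  out <- numeric(len)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) out[i] <- fun_row(x[seq_len(i)])
  }
  if (len >= n) {
    m <- stats::embed(x, n)                  # rows: windows ending at n..len
    out[n:len] <- fun_row(m)
  }
  out
}

roll_mean <- function(x, n) {
  len <- length(x)
  if (len == 0L) return(numeric(0))
  n <- min(n, len)
  cs <- cumsum(x)
  out <- numeric(len)
  head_idx <- seq_len(n - 1L)
  if (n > 1L) out[head_idx] <- cs[head_idx] / head_idx
  idx <- n:len
  out[idx] <- (cs[idx] - c(0, cs)[idx - n + 1L]) / n
  out
}

roll_sd <- function(x, n) {
  len <- length(x)
  if (len == 0L) return(numeric(0))
  n <- min(n, len)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  out <- numeric(len)
  k <- pmin(seq_len(len), n)
  s <- cs - c(rep(0, n), cs[seq_len(len - n)])
  s2 <- cs2 - c(rep(0, n), cs2[seq_len(len - n)])
  v <- (s2 - s^2 / k) / pmax(k - 1L, 1L)
  v[k < 2L] <- 0
  out[] <- sqrt(pmax(v, 0))
  out
}

roll_min <- function(x, n) {
  len <- length(x)
  if (len == 0L) return(numeric(0))
  n <- min(n, len)
  out <- numeric(len)
  if (n > 1L) out[seq_len(n - 1L)] <- cummin(x[seq_len(n - 1L)])
  if (len >= n) {
    m <- stats::embed(x, n)
    out[n:len] <- do.call(pmin, as.data.frame(m))
  }
  out
}

roll_max <- function(x, n) {
  len <- length(x)
  if (len == 0L) return(numeric(0))
  n <- min(n, len)
  out <- numeric(len)
  if (n > 1L) out[seq_len(n - 1L)] <- cummax(x[seq_len(n - 1L)])
  if (len >= n) {
    m <- stats::embed(x, n)
    out[n:len] <- do.call(pmax, as.data.frame(m))
  }
  out
}

# RMS of successive differences over a trailing window of n values (n-1 diffs);
# windows with fewer than 2 values yield 0.
roll_rmssd <- function(x, n) {
  len <- length(x)
  if (len == 0L) return(numeric(0))
  if (len == 1L) return(0)
  d2 <- diff(x)^2
  dm <- roll_mean(d2, max(n - 1L, 1L))
  c(0, sqrt(dm))
}

# trapezoidal area of y - y[1] over uniformly sampled span, dx = 1/fs
trapz_above_base <- function(y, base, dx) {
  if (length(y) < 2L) return(0)
  z <- y - base
  sum((z[-1] + z[-length(z)]) / 2) * dx
}
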