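# Internal helpers shared across modules.

#' Signal a classed error
#' @noRd
eod_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "eod_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so that seeded generator calls do
#' not perturb unrelated randomness.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a parent seed and a string label
#'
#' Deterministic, order-independent sub-stream seeding for per-recording
#' randomness. Stays below 2^31 - 1.
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  (as.integer(seed) %% 2147480000L) %/% 7L + 13L * h + 1L
}

#' Mean-reverting Gaussian random walk (AR(1)) on a regular grid
#'
#' Discrete Ornstein-Uhlenbeck process with stationary standard deviation
#' `sd_stat` and e-folding time `tau_s`, sampled every `dt_s` seconds.
#' The first value is drawn from the stationary distribution.
#' @noRd
ou_path <- function(n, sd_stat, tau_s, dt_s = 1) {
  if (n <= 0) return(numeric(0))
  if (sd_stat <= 0) return(numeric(n))
  phi <- exp(-dt_s / tau_s)
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_stat)
  if (n > 1) {
    eps <- rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
  }
  x
}

#' Linear interpolation of a path defined on a regular grid starting at 0
#' @noRd
interp_path <- function(path, dt_s, t) {
  if (length(path) == 0) return(numeric(length(t)))
  if (length(path) == 1) return(rep(path, length(t)))
  grid <- (seq_along(path) - 1) * dt_s
  approx(grid, path, xout = t, rule = 2)$y
}

#' Smooth 0 -> 1 cosine ramp on [0, 1], clamped outside
#' @noRd
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  0.5 - 0.5 * cos(pi * u)
}

#' Contiguous runs of TRUE in a logical vector
#'
#' Returns a data.frame with 1-based start/end indices (empty if none).
#' @noRd
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
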