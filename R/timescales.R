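#' Characteristic timescale of a piecewise-constant signal
#'
#' For a signal made of runs of constant value, the characteristic
#' timescale (CT) is the mean duration of its maximal constant runs. The
#' first and last runs are excluded because they may be truncated by the
#' recording edges. Only run lengths matter, not the values themselves.
#'
#' @param signal Numeric vector sampled at `f` Hz.
#' @param f Sampling rate, Hz.
#' @return Mean interior run duration in seconds.
#' @export
piecewise_ct <- function(signal, f = 200) {
  r <- rle(signal)
  if (length(r$lengths) < 3) {
    stop("fewer than 3 constant runs: no interior run to measure")
  }
  interior <- r$lengths[-c(1L, length(r$lengths))]
  mean(interior) / f
}

#' Normalized autocorrelation of a rate series
#'
#' Biased (1/n) autocovariance of the mean-subtracted series, normalized
#' to 1 at lag zero, evaluated at every lag up to `max_lag`.
#'
#' @param rate Numeric series sampled at `f` Hz.
#' @param max_lag Maximum lag in seconds (default 2).
#' @param f Sampling rate, Hz.
#' @return Tibble with columns `lag_s` and `ac`.
#' @export
autocorrelation <- function(rate, max_lag = 2, f = 200) {
  n_lag <- round(max_lag * f)
  if (length(rate) <= 2 * n_lag) {
    stop("series must be longer than twice the maximum lag")
  }
  if (stats::var(rate) == 0) stop("zero-variance series has no autocorrelation")
  a <- stats::acf(rate, lag.max = n_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  tibble::tibble(lag_s = (0:n_lag) / f, ac = a)
}

# Continuous two-phase decay of the log-autocorrelation: a fast exponent
# t1 up to the transition lag c, a slow exponent t2 beyond it.
two_phase_model <- function(x, a, c, t1, t2) {
  ifelse(x < c, -a - x / t1, -a - c / t1 - (x - c) / t2)
}

#' Fit the two-exponent timescale model to an autocorrelation
#'
#' Fits the logarithm of the autocorrelation with a continuous two-phase
#' linear decay: slope `-1/t1` (fast timescale) up to transition lag `c`,
#' then slope `-1/t2` (slow timescale). Parameters are box-constrained
#' (`0 < t1 <= 1.5` s, `0.5 <= t2 <= 20` s, `0.03 <= c <= 0.2` s,
#' `a >= 0`) and estimated by bounded least squares with weights
#' proportional to the squared autocorrelation value (the approximate
#' inverse variance of the log of an estimated autocorrelation), from five
#' deterministic multi-starts. Non-positive autocorrelation values are
#' masked before taking logs. The fast timescale `t1` is the downstream
#' characteristic timescale.
#'
#' @param ac Tibble from [autocorrelation()] (columns `lag_s`, `ac`), or a
#'   numeric vector of autocorrelations at lags `0:k` with `lag_step_s`.
#' @param lag_step_s Lag step in seconds when `ac` is a bare vector.
#' @return An object of class `act_fit`: list with `a`, `c`, `t1`, `t2`,
#'   `residual` (weighted SSE), `at_boundary` (TRUE when any parameter sits
#'   at a box constraint), and `n_lags` used.
#' @export
fit_characteristic_timescale <- function(ac, lag_step_s = 1 / 200) {
  if (is.data.frame(ac)) {
    x <- ac$lag_s
    y <- ac$ac
  } else {
    x <- (seq_along(ac) - 1) * lag_step_s
    y <- as.numeric(ac)
  }
  keep <- x > 0 & y > 0  # lag 0 is 1 by construction; mask nonpositive ac
  x <- x[keep]
  ly <- log(y[keep])
  w <- y[keep]^2  # inverse variance of log(ac) for an estimated ac
  if (length(x) < 5) stop("fewer than 5 usable lags for the timescale fit")
  lower <- c(a = 0, c = 0.03, t1 = 1e-4, t2 = 0.5)
  upper <- c(a = 10, c = 0.2, t1 = 1.5, t2 = 20)
  obj <- function(p) {
    sum(w * (ly - two_phase_model(x, p[1], p[2], p[3], p[4]))^2)
  }
  starts <- list(
    c(0, 0.1, 0.05, 1), c(0, 0.1, 0.1, 5), c(0, 0.15, 0.3, 2),
    c(0.1, 0.05, 0.7, 10), c(0, 0.2, 1.2, 5)
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("timescale fit failed from every start")
  p <- best$par
  tol <- 1e-6
  at_boundary <- any(p - lower < tol * pmax(1, abs(lower))) ||
    any(upper - p < tol * pmax(1, abs(upper)))
  structure(
    list(a = unname(p[1]), c = unname(p[2]), t1 = unname(p[3]),
         t2 = unname(p[4]), residual = best$value,
         at_boundary = at_boundary, n_lags = length(x)),
    class = "act_fit"
  )
}

#' @export
print.act_fit <- function(x, ...) {
  cat(sprintf(
    "<act_fit> t1 = %.4f s, t2 = %.3f s, c = %.3f s, a = %.4f (residual %.4g%s)\n",
    x$t1, x$t2, x$c, x$a, x$residual,
    if (x$at_boundary) ", at constraint boundary" else ""
  ))
  invisible(x)
}

#' Log-spaced state-length grid snapped to the sampling grid
#'
#' @param n Number of grid points (default 20).
#' @param S_min,S_max Range in seconds (defaults 0.010 and 3).
#' @param f Sampling rate, Hz.
#' @return Increasing vector of state lengths (seconds), each an integer
#'   number of samples, duplicates removed.
#' @export
state_length_grid <- function(n = 20, S_min = 0.010, S_max = 3, f = 200) {
  s <- exp(seq(log(S_min), log(S_max), length.out = n))
  unique(pmax(1, round(s * f))) / f
}

#' Survey differentiation as a function of state length
#'
#' Computes normalized spectral differentiation averaged across all
#' analysis windows for each state length in the grid, keeping `W` fixed.
#'
#' @param rates A [rate_matrix()].
#' @param cfg An [nd_config()]; its `S` is ignored in favor of the grid.
#' @param S_grid Increasing vector of state lengths in seconds (default
#'   [state_length_grid()] over 10 ms to 3 s, capped at `W/2`).
#' @param epochs Optional epochs passed through to [nd_timeseries()].
#' @return An object of class `nd_curve`: tibble with columns `S_s`, `nd`.
#' @export
nd_vs_state_length <- function(rates, cfg = nd_config(), S_grid = NULL,
                               epochs = NULL) {
  f <- attr(rates, "sampling_rate")
  if (is.null(S_grid)) {
    S_grid <- state_length_grid(f = f, S_max = min(3, cfg$W / 2))
  }
  S_grid <- S_grid[S_grid <= cfg$W / 2 + 1e-9]
  emr <- mean(rates)
  vals <- vapply(S_grid, function(S) {
    c2 <- nd_config(W = cfg$W, S = S, f = f, taper = cfg$taper,
                    min_units = cfg$min_units)
    mean(nd_timeseries(rates, epochs = epochs, cfg = c2,
                       ensemble_mean_rate = emr)$nd)
  }, numeric(1))
  structure(
    tibble::tibble(S_s = S_grid, nd = vals),
    class = c("nd_curve", class(tibble::tibble()))
  )
}

#' Detect the optimal timescale of a differentiation curve
#'
#' Classifies an `nd_curve`: an interior maximum reports that state length;
#' a maximum at the longest probed state length is "optimum-beyond-range";
#' a maximum at the shortest probed state length (the ensemble "loss of
#' optimality" signature, differentiation still rising at the shortest
#' timescale) reports that length flagged `at_boundary`; an all-zero curve
#' (e.g. a unit with too few spikes) is "zero".
#'
#' @param curve An `nd_curve` (columns `S_s`, `nd`).
#' @return List with `classification` (one of `"interior-optimum"`,
#'   `"optimum-beyond-range"`, `"zero"`), `S_opt` (seconds or `NA`), and
#'   `at_boundary` (TRUE when the optimum sits at the short end).
#' @export
detect_optimal_timescale <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  if (all(curve$nd == 0)) {
    return(list(classification = "zero", S_opt = NA_real_, at_boundary = FALSE))
  }
  i <- which.max(curve$nd)
  if (i == nrow(curve) && nrow(curve) > 1) {
    return(list(classification = "optimum-beyond-range",
                S_opt = curve$S_s[i], at_boundary = FALSE))
  }
  list(classification = "interior-optimum", S_opt = curve$S_s[i],
       at_boundary = i == 1L)
}

#' Power-law fit of the decaying tail of a differentiation curve
#'
#' Least-squares regression of `log(nd)` on `log(S)` restricted to state
#' lengths above `S_min` with positive differentiation.
#'
#' @param curve An `nd_curve`.
#' @param S_min Lower edge of the fitted range, seconds.
#' @return List with `exponent` (slope) and `intercept` (log scale).
#' @export
power_law_fit <- function(curve, S_min) {
  keep <- curve$S_s > S_min & curve$nd > 0
  if (sum(keep) < 3) stop("need at least 3 positive points above S_min")
  fit <- stats::lm(log(nd) ~ log(S_s), data = curve[keep, ])
  list(exponent = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
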