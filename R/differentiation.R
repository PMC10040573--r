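#' Configuration for spectral differentiation
#'
#' Holds the analysis-window length `W`, the state length `S`, the sampling
#' rate `f`, the taper choice, and the minimum ensemble size. Differentiation
#' of a window is the median pairwise Euclidean distance between the
#' `floor(W/S)` concatenated per-unit power spectra ("states") tiling it.
#'
#' @param W Analysis window length, seconds (default 3).
#' @param S State length, seconds (default 0.3). `f * S` must be within half
#'   a sample of an integer; it is snapped to the nearest integer count.
#' @param f Sampling rate, Hz (default 200).
#' @param taper `"none"` (default) or `"tukey"`: a Tukey taper with shape
#'   parameter 1 applied to each state segment before the Fourier transform.
#' @param min_units Minimum ensemble size for which differentiation is
#'   reported (default 10), guarding against singular extreme units.
#'
#' @return An object of class `nd_config`.
#' @export
nd_config <- function(W = 3, S = 0.3, f = 200,
                      taper = c("none", "tukey"), min_units = 10) {
  taper <- match.arg(taper)
  stopifnot(S > 0, W >= S, f > 0, min_units >= 1)
  n_state <- round(f * S)
  if (abs(f * S - n_state) > 0.5 + 1e-9 || n_state < 1) {
    stop(sprintf("state length %g s does not align with the %g Hz sampling grid", S, f))
  }
  if (abs(f * S - n_state) > 1e-9) {
    S <- n_state / f  # snap to the sampling grid
  }
  if (floor(W / S + 1e-9) < 2) {
    stop("W/S must allow at least 2 states per window")
  }
  structure(
    list(W = W, S = S, f = f, taper = taper, min_units = min_units,
         n_state = n_state),
    class = "nd_config"
  )
}

#' @export
print.nd_config <- function(x, ...) {
  cat(sprintf(
    "<nd_config> W = %g s, S = %g s (%d samples), f = %g Hz, taper = %s, min_units = %d\n",
    x$W, x$S, x$n_state, x$f, x$taper, x$min_units
  ))
  invisible(x)
}

#' Tukey (cosine-tapered) window
#'
#' With shape parameter `alpha = 1` this is the Hann window.
#'
#' @param n Number of samples.
#' @param alpha Shape parameter in \[0, 1\]: fraction of the window inside
#'   the cosine taper.
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 1) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (alpha > 0) {
    lo <- x < alpha / 2
    hi <- x >= 1 - alpha / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  }
  w
}

#' Split a window of a rate matrix into state blocks
#'
#' Tiles the analysis window with `floor(window_length / S)` contiguous,
#' non-overlapping state blocks in temporal order; a trailing remainder
#' shorter than `S` is dropped.
#'
#' @param rates A [rate_matrix()].
#' @param window Numeric length-2 vector `c(start, end)` in seconds
#'   (half-open), inside the support of `rates`.
#' @param S State length in seconds.
#'
#' @return List of units-by-samples matrices, each with `round(f * S)`
#'   columns.
#' @export
segment_states <- function(rates, window, S) {
  f <- attr(rates, "sampling_rate")
  t0 <- attr(rates, "t0")
  n_state <- round(f * S)
  stopifnot(n_state >= 1)
  i0 <- round((window[1] - t0) * f)   # 0-based sample offset
  i1 <- round((window[2] - t0) * f)
  if (i0 < 0 || i1 > ncol(rates)) stop("window outside rate matrix support")
  n_states <- (i1 - i0) %/% n_state
  if (n_states < 2) {
    stop("fewer than 2 states in window: median pairwise distance undefined")
  }
  lapply(seq_len(n_states), function(s) {
    cols <- (i0 + (s - 1L) * n_state + 1L):(i0 + s * n_state)
    rates[, cols, drop = FALSE]
  })
}

#' Spectral state vector of one state block
#'
#' For each unit, computes the unnormalized forward discrete Fourier
#' transform of its rate within the state, squares the magnitude, keeps the
#' non-negative frequencies (DC through Nyquist), and concatenates the
#' per-unit spectra in unit order into one state vector. Frequency
#' resolution is `1/S` Hz.
#'
#' @param block Units-by-samples numeric matrix (one state).
#' @param taper `"none"` or `"tukey"` (shape parameter 1).
#' @return Numeric vector of length `n_units * (floor(n_samples/2) + 1)`.
#' @export
state_psd <- function(block, taper = "none") {
  block <- rbind(block)  # promote a bare vector to a 1-unit matrix
  n <- ncol(block)
  keep <- seq_len(n %/% 2 + 1L)
  if (identical(taper, "tukey")) {
    block <- sweep(block, 2, tukey_window(n, 1), `*`)
  }
  # mvfft transforms columns, so transpose: units end up in columns
  sp <- stats::mvfft(t(block))
  as.vector(Mod(sp[keep, , drop = FALSE])^2)
}

#' Raw spectral differentiation of a set of states
#'
#' The median over all unordered pairs of Euclidean distances between state
#' vectors. With an even number of pairs the median is the mean of the two
#' middle values.
#'
#' @param states A list of equal-length numeric state vectors, or a matrix
#'   with one state per row.
#' @return A single non-negative number (units s^-2 when states are PSDs of
#'   rates in spikes/s).
#' @export
spectral_differentiation_raw <- function(states) {
  if (is.list(states)) {
    len <- lengths(states)
    if (length(unique(len)) != 1) stop("state vectors differ in length")
    states <- do.call(rbind, states)
  }
  if (nrow(states) < 2) stop("need at least 2 states")
  stats::median(stats::dist(states))
}

#' Normalize raw spectral differentiation
#'
#' Divides the raw value (computed on mean-normalized rates) by `sqrt(N)`
#' to remove the dimensionality growth with ensemble size and by `S^2` to
#' remove the quadratic growth of total Fourier power with state length.
#'
#' @param nd_raw Raw differentiation computed on rates already divided by
#'   the scalar ensemble-session mean rate.
#' @param N Number of units in the ensemble.
#' @param S State length, seconds.
#' @return Normalized differentiation, `nd_raw * N^-0.5 * S^-2`.
#' @export
normalize_nd <- function(nd_raw, N, S) {
  stopifnot(N >= 1, S > 0)
  nd_raw / (sqrt(N) * S^2)
}

#' Analytic upper bounds on spectral differentiation
#'
#' Each Fourier coefficient of a signal with maximum amplitude `A` over
#' `f*S` samples is at most `A*f*S`, so each PSD entry is at most
#' `A^2 f^2 S^2`; with `N` units the raw median distance is bounded by
#' `N A^2 f^2 S^2`, and after dividing by `sqrt(N)` and `S^2` the
#' normalized metric is bounded by `A^2 f^2`, independent of `N` and `S`.
#'
#' @param A Maximum signal amplitude. For normalized differentiation this
#'   is the maximum mean-normalized firing rate (dimensionless).
#' @param f Sampling rate, Hz.
#' @param S State length, seconds.
#' @param N Number of units.
#' @return Upper bound in s^-2.
#' @export
bound_raw <- function(A, f, S, N) {
  stopifnot(A > 0, f > 0, S > 0, N > 0)
  N * A^2 * f^2 * S^2
}

#' @rdname bound_raw
#' @export
bound_normalized <- function(A, f) {
  stopifnot(A > 0, f > 0)
  A^2 * f^2
}

# Tile [start, end) with non-overlapping W windows, dropping the remainder.
window_starts <- function(start, end, W) {
  n <- floor((end - start) / W + 1e-9)
  if (n < 1) return(numeric(0))
  start + W * (seq_len(n) - 1)
}

#' Spectral differentiation time series
#'
#' Tiles each epoch with non-overlapping analysis windows of length `W`
#' (incomplete trailing windows are dropped; windows never straddle epoch
#' boundaries) and computes raw and normalized spectral differentiation per
#' window. Rates are first divided by the scalar ensemble mean rate (mean
#' over all units and the whole matrix, or `ensemble_mean_rate` if the
#' matrix is a session subset), so the normalized metric is invariant
#' under uniform rescaling of all rates.
#'
#' @param rates A [rate_matrix()] with at least `cfg$min_units` rows.
#' @param epochs Optional data frame with columns `start_s`, `end_s` and
#'   optionally `epoch_id`, `category`; defaults to one epoch covering the
#'   whole matrix.
#' @param cfg An [nd_config()].
#' @param ensemble_mean_rate Scalar ensemble-session mean rate used for
#'   amplitude normalization; defaults to the grand mean of `rates`.
#'
#' @return A tibble of class `nd_series` with columns `epoch_id`,
#'   `category`, `window_center_s`, `nd_raw`, `nd`, `n_units`,
#'   `amplitude_max` (max mean-normalized rate in the window), plus
#'   attributes `config` and `ensemble_mean_rate`.
#' @export
nd_timeseries <- function(rates, epochs = NULL, cfg = nd_config(),
                          ensemble_mean_rate = NULL) {
  f <- attr(rates, "sampling_rate")
  t0 <- attr(rates, "t0")
  N <- nrow(rates)
  if (N < cfg$min_units) {
    stop(sprintf(
      "ensemble has %d units; differentiation requires at least %d (the 10-neuron rule guards against singular extreme units)",
      N, cfg$min_units
    ))
  }
  if (is.null(ensemble_mean_rate)) ensemble_mean_rate <- mean(rates)
  if (ensemble_mean_rate <= 0) stop("ensemble mean rate is zero: no spikes")
  if (is.null(epochs)) {
    epochs <- data.frame(start_s = t0, end_s = t0 + ncol(rates) / f)
  }
  if (is.null(epochs$epoch_id)) epochs$epoch_id <- seq_len(nrow(epochs))
  if (is.null(epochs$category)) epochs$category <- NA_character_
  norm <- unclass(rates) / ensemble_mean_rate

  rows <- lapply(seq_len(nrow(epochs)), function(e) {
    starts <- window_starts(epochs$start_s[e], epochs$end_s[e], cfg$W)
    if (!length(starts)) return(NULL)
    vals <- vapply(starts, function(ws) {
      blocks <- segment_states(rates, c(ws, ws + cfg$W), cfg$S)
      sv <- lapply(blocks, function(b) {
        state_psd(unclass(b) / ensemble_mean_rate, taper = cfg$taper)
      })
      raw <- spectral_differentiation_raw(sv)
      i0 <- round((ws - t0) * f) + 1L
      amax <- max(norm[, i0:(i0 + round(cfg$W * f) - 1L)])
      c(raw, amax)
    }, numeric(2))
    tibble::tibble(
      epoch_id = epochs$epoch_id[e],
      category = epochs$category[e],
      window_center_s = starts + cfg$W / 2,
      nd_raw = vals[1, ],
      nd = normalize_nd(vals[1, ], N, cfg$S),
      n_units = N,
      amplitude_max = vals[2, ]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- cfg
  attr(out, "ensemble_mean_rate") <- ensemble_mean_rate
  class(out) <- c("nd_series", class(out))
  out
}

#' Mean-firing-rate differentiation (control metric)
#'
#' A simpler variation-across-states metric: each unit's rate is divided by
#' that unit's own session-mean rate; within each state the mean of the
#' normalized rates over units and samples is taken; the metric for a
#' window is the population variance (divide by the number of states) of
#' those per-state means.
#'
#' @inheritParams nd_timeseries
#' @return Tibble with columns `epoch_id`, `category`, `window_center_s`,
#'   `mfrd`, `n_units`.
#' @export
mfr_differentiation <- function(rates, epochs = NULL, cfg = nd_config()) {
  f <- attr(rates, "sampling_rate")
  t0 <- attr(rates, "t0")
  unit_means <- rowMeans(rates)
  drop <- unit_means <= 0
  if (any(drop)) {
    warning(sprintf("%d unit(s) with zero session-mean rate dropped", sum(drop)))
  }
  m <- unclass(rates)[!drop, , drop = FALSE] / unit_means[!drop]
  mr <- rate_matrix(m, sampling_rate = f, t0 = t0,
                    unit_ids = attr(rates, "unit_ids")[!drop])
  if (is.null(epochs)) {
    epochs <- data.frame(start_s = t0, end_s = t0 + ncol(rates) / f)
  }
  if (is.null(epochs$epoch_id)) epochs$epoch_id <- seq_len(nrow(epochs))
  if (is.null(epochs$category)) epochs$category <- NA_character_

  rows <- lapply(seq_len(nrow(epochs)), function(e) {
    starts <- window_starts(epochs$start_s[e], epochs$end_s[e], cfg$W)
    if (!length(starts)) return(NULL)
    v <- vapply(starts, function(ws) {
      blocks <- segment_states(mr, c(ws, ws + cfg$W), cfg$S)
      state_means <- vapply(blocks, mean, numeric(1))
      mean((state_means - mean(state_means))^2)  # population variance
    }, numeric(1))
    tibble::tibble(
      epoch_id = epochs$epoch_id[e],
      category = epochs$category[e],
      window_center_s = starts + cfg$W / 2,
      mfrd = v,
      n_units = nrow(mr)
    )
  })
  dplyr::bind_rows(rows)
}

#' Stimulus differentiation of a pixel movie
#'
#' Treats every pixel as a "unit" and applies exactly the spectral
#' differentiation computation (including the ensemble-mean amplitude
#' normalization and the `sqrt(N)`, `S^2` factors) to the pixels-by-frames
#' intensity matrix, which must be sampled at the configured rate.
#'
#' @param movie Pixels-by-frames numeric matrix, or a [rate_matrix()].
#' @inheritParams nd_timeseries
#' @return An `nd_series` tibble as from [nd_timeseries()].
#' @export
stimulus_differentiation <- function(movie, epochs = NULL, cfg = nd_config()) {
  if (!inherits(movie, "rate_matrix")) {
    movie <- rate_matrix(movie, sampling_rate = cfg$f, t0 = 0)
  }
  cfg$min_units <- min(cfg$min_units, nrow(movie))  # pixels, not neurons
  nd_timeseries(movie, epochs = epochs, cfg = cfg)
}

#' Evoked (trial-locked) spectral differentiation
#'
#' Computes one normalized differentiation value per event over the short
#' window `[t, t + window)` split into `floor(window/S)` states — by
#' default 300 ms of activity split into five 60 ms states. Events whose
#' window overlaps the end of the recording are skipped with a warning.
#'
#' @param rates A [rate_matrix()].
#' @param event_times Event onset times in seconds.
#' @param window Post-event window length, seconds (default 0.3).
#' @param S State length, seconds (default 0.06).
#' @param min_units Minimum ensemble size (default 10).
#' @param ensemble_mean_rate Optional scalar session mean rate override.
#'
#' @return Tibble with columns `event_time_s`, `nd_raw`, `nd`, `n_units`,
#'   `mean_rate` (raw ensemble mean rate within the window, spikes/s).
#' @export
evoked_nd <- function(rates, event_times, window = 0.3, S = 0.06,
                      min_units = 10, ensemble_mean_rate = NULL) {
  f <- attr(rates, "sampling_rate")
  t0 <- attr(rates, "t0")
  end <- t0 + ncol(rates) / f
  keep <- event_times + window <= end + 1e-9 & event_times >= t0
  if (any(!keep)) {
    warning(sprintf("%d event(s) overlapping the recording end skipped", sum(!keep)))
  }
  event_times <- event_times[keep]
  cfg <- nd_config(W = window, S = S, f = f, min_units = min_units)
  if (nrow(rates) < min_units) {
    stop(sprintf(
      "ensemble has %d units; differentiation requires at least %d",
      nrow(rates), min_units
    ))
  }
  if (is.null(ensemble_mean_rate)) ensemble_mean_rate <- mean(rates)
  if (ensemble_mean_rate <= 0) stop("ensemble mean rate is zero: no spikes")
  N <- nrow(rates)
  res <- vapply(event_times, function(tc) {
    blocks <- segment_states(rates, c(tc, tc + window), S)
    sv <- lapply(blocks, function(b) {
      state_psd(unclass(b) / ensemble_mean_rate, taper = cfg$taper)
    })
    raw <- spectral_differentiation_raw(sv)
    c(raw, mean(unlist(lapply(blocks, mean))))
  }, numeric(2))
  tibble::tibble(
    event_time_s = event_times,
    nd_raw = if (length(event_times)) res[1, ] else numeric(0),
    nd = normalize_nd(if (length(event_times)) res[1, ] else numeric(0), N, S),
    n_units = N,
    mean_rate = if (length(event_times)) res[2, ] else numeric(0)
  )
}
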