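#' Piecewise-constant random signal
#'
#' Generates a signal that is resampled every `ct` seconds to a uniform
#' random integer in `value_range`, with consecutive values forced to be
#' distinct so every segment is a maximal constant run. The sparse variant
#' holds a baseline value outside a random `active_fraction` of segments,
#' mimicking sparse activity such as neural firing.
#'
#' @param ct Characteristic timescale, seconds (>= 2 samples).
#' @param duration Signal duration, seconds.
#' @param f Sampling rate, Hz (default 200).
#' @param value_range Integer range of values (default `c(0, 255)`).
#' @param sparse If TRUE, only a fraction of segments are active.
#' @param active_fraction Fraction of active segments when `sparse`.
#' @param baseline Baseline value of inactive segments (default 0).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return Numeric vector of length `round(duration * f)`.
#' @export
gen_piecewise_constant <- function(ct, duration, f = 200,
                                   value_range = c(0, 255), sparse = FALSE,
                                   active_fraction = 0.25, baseline = 0,
                                   seed = 1) {
  stopifnot(ct >= 2 / f, duration > 0)
  seg_len <- round(ct * f)
  n_total <- round(duration * f)
  n_seg <- ceiling(n_total / seg_len)
  vals <- withr::with_seed(seed, {
    v <- numeric(n_seg)
    lo <- value_range[1]
    hi <- value_range[2]
    active <- if (sparse) stats::runif(n_seg) < active_fraction else rep(TRUE, n_seg)
    prev <- NA_real_
    for (i in seq_len(n_seg)) {
      if (!active[i]) {
        v[i] <- baseline
      } else {
        repeat {
          x <- sample(lo:hi, 1)
          # resample on collision so consecutive values always differ
          if (is.na(prev) || x != prev) break
        }
        v[i] <- x
      }
      prev <- v[i]
    }
    v
  })
  rep(vals, each = seg_len)[seq_len(n_total)]
}

#' Synthetic visual stimulus movies
#'
#' Generates pixels-by-frames intensity movies sampled at `f` Hz:
#' * `gray` — constant mean-luminance screen (zero differentiation);
#' * `flashes` — full-field 1.75 s gray epochs alternating with 0.25 s
#'   black-or-white flashes (mean constant-run duration 1 s);
#' * `gabor` / `static_gratings` — every pixel an independent
#'   piecewise-constant signal with a 250 ms characteristic timescale;
#' * `shuffled_movie` — the same with a 1/30 s timescale (frame-shuffled
#'   movie statistics);
#' * `natural_like` — temporally correlated surrogate for natural movies:
#'   shared low-rank spatial factors with AR(1) temporal dynamics of
#'   correlation time `natural_tau`, plus weak per-pixel AR(1) noise.
#'
#' @param category One of `"gray"`, `"flashes"`, `"gabor"`,
#'   `"static_gratings"`, `"shuffled_movie"`, `"natural_like"`.
#' @param duration Movie duration, seconds.
#' @param resolution Pixel grid `c(rows, cols)` (default `c(4, 4)`).
#' @param f Sampling (frame) rate, Hz (default 200).
#' @param natural_tau AR(1) correlation time of the naturalistic surrogate,
#'   seconds (default 0.5).
#' @param seed Integer seed.
#' @return A [rate_matrix()] of pixel intensities (0-255), pixels in rows.
#' @export
gen_stimulus <- function(category, duration, resolution = c(4, 4), f = 200,
                         natural_tau = 0.5, seed = 1) {
  n_pix <- prod(resolution)
  n_fr <- round(duration * f)
  gray <- 127
  m <- switch(
    category,
    gray = matrix(gray, n_pix, n_fr),
    flashes = {
      cyc_gray <- round(1.75 * f)
      cyc_flash <- round(0.25 * f)
      n_cyc <- ceiling(n_fr / (cyc_gray + cyc_flash))
      cols <- withr::with_seed(seed, {
        flash_vals <- sample(c(0, 255), n_cyc, replace = TRUE)
        unlist(lapply(seq_len(n_cyc), function(i) {
          c(rep(gray, cyc_gray), rep(flash_vals[i], cyc_flash))
        }))
      })[seq_len(n_fr)]
      matrix(rep(cols, each = n_pix), n_pix, n_fr)
    },
    gabor = ,
    static_gratings = t(vapply(seq_len(n_pix), function(p) {
      gen_piecewise_constant(0.25, duration, f, seed = seed + p)
    }, numeric(n_fr))),
    shuffled_movie = t(vapply(seq_len(n_pix), function(p) {
      gen_piecewise_constant(round(f / 30) / f, duration, f, seed = seed + p)
    }, numeric(n_fr))),
    natural_like = withr::with_seed(seed, {
      K <- 3
      phi <- exp(-1 / (f * natural_tau))
      innov_sd <- sqrt(1 - phi^2)  # unit stationary variance
      fac <- vapply(seq_len(K), function(k) {
        as.numeric(stats::arima.sim(list(ar = phi), n_fr, sd = innov_sd))
      }, numeric(n_fr))
      load <- matrix(stats::rnorm(n_pix * K, sd = 1 / sqrt(K)), n_pix, K)
      noise <- t(vapply(seq_len(n_pix), function(p) {
        as.numeric(stats::arima.sim(list(ar = phi), n_fr, sd = 0.2 * innov_sd))
      }, numeric(n_fr)))
      m <- gray + 45 * (load %*% t(fac) + noise)
      m[m < 0] <- 0
      m[m > 255] <- 255
      m
    }),
    stop("unknown stimulus category: ", category)
  )
  rate_matrix(m, sampling_rate = f, t0 = 0,
              unit_ids = paste0("px", seq_len(n_pix)))
}

#' Inhomogeneous Poisson spike trains by thinning
#'
#' Simulates spike times from a nonnegative rate signal sampled at `f` Hz:
#' candidate events are drawn from a homogeneous Poisson process at the
#' rate maximum and accepted with probability `rate(t) / rate_max`
#' (piecewise-constant interpolation). The expected spike count equals the
#' time integral of the rate.
#'
#' @param rate_signal Nonnegative rate series in spikes/s, sampled at `f`.
#' @param duration Duration in seconds (defaults to the signal length).
#' @param f Sampling rate of `rate_signal`, Hz (default 200).
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
gen_poisson_spikes <- function(rate_signal, duration = NULL, f = 200, seed = 1) {
  if (any(rate_signal < 0)) stop("rate_signal must be nonnegative")
  if (is.null(duration)) duration <- length(rate_signal) / f
  rmax <- max(rate_signal)
  if (rmax == 0) return(numeric(0))
  withr::with_seed(seed, {
    n_cand <- stats::rpois(1, rmax * duration)
    if (n_cand == 0) return(numeric(0))
    t_cand <- sort(stats::runif(n_cand, 0, duration))
    idx <- pmin(length(rate_signal), floor(t_cand * f) + 1L)
    t_cand[stats::runif(n_cand) < rate_signal[idx] / rmax]
  })
}

#' Virtual-neuron ensembles from a single spike train
#'
#' Builds `n_copies` virtual neurons from one seed spike train by adding
#' either i.i.d. Gaussian jitter to every spike or a constant per-copy
#' offset. Spike times are clipped to the session bounds (not wrapped), so
#' each copy keeps the original spike count.
#'
#' @param spikes Sorted spike times, seconds.
#' @param n_copies Number of virtual neurons (>= 1).
#' @param jitter_sd SD of per-spike Gaussian jitter, seconds (default 0).
#' @param offsets Optional numeric vector of per-copy constant offsets in
#'   seconds; when given it overrides `jitter_sd`.
#' @param session_duration Session length for clipping, seconds.
#' @param seed Integer seed.
#' @return List of `n_copies` sorted spike-time vectors.
#' @export
gen_virtual_ensemble <- function(spikes, n_copies, jitter_sd = 0,
                                 offsets = NULL, session_duration,
                                 seed = 1) {
  stopifnot(n_copies >= 1)
  if (!is.null(offsets)) stopifnot(length(offsets) == n_copies)
  hi <- session_duration - 1e-9  # keep spikes strictly inside [0, duration)
  withr::with_seed(seed, {
    lapply(seq_len(n_copies), function(i) {
      s <- if (!is.null(offsets)) {
        spikes + offsets[i]
      } else if (jitter_sd > 0) {
        spikes + stats::rnorm(length(spikes), sd = jitter_sd)
      } else {
        spikes
      }
      sort(pmin(hi, pmax(0, s)))
    })
  })
}

#' Specification of a synthetic change-detection session
#'
#' Parameter bundle for [gen_change_detection_session()]. Defaults emulate
#' an image change-detection experiment: images flashed every 750 ms
#' (250 ms on, 500 ms gray), a subset of flashes changing image identity,
#' outcomes drawn as hit/miss, and on hit trials a multiplicative firing
#' transient in the 300 ms post-change window.
#'
#' @param n_units Number of units (default 40).
#' @param rate_range Range of per-unit baseline rates, spikes/s
#'   (default `c(2, 15)`).
#' @param n_changes Number of image-change trials (default 30).
#' @param flash_period Flash-to-flash period, seconds (default 0.75).
#' @param image_duration Image-on duration per flash, seconds (default 0.25).
#' @param change_every Change events occur every this many flashes
#'   (default 4).
#' @param coupling Modulation depth of the shared flash-evoked drive
#'   (default 0.3).
#' @param p_hit Probability that a change is detected (default 0.5).
#' @param hit_effect Amplitude of the multiplicative rate transient on hit
#'   trials (default 1: rates double at change onset; 0 disables the
#'   effect).
#' @param hit_tau Decay time of the hit transient, seconds (default 0.15).
#' @param seed Integer seed.
#' @return A list of class `synthetic_session_spec`.
#' @export
synthetic_session_spec <- function(n_units = 40, rate_range = c(2, 15),
                                   n_changes = 30, flash_period = 0.75,
                                   image_duration = 0.25, change_every = 4,
                                   coupling = 0.3, p_hit = 0.5,
                                   hit_effect = 1, hit_tau = 0.15, seed = 1) {
  stopifnot(n_units >= 1, all(rate_range >= 0), n_changes >= 1,
            hit_effect >= 0, p_hit >= 0, p_hit <= 1)
  structure(
    list(n_units = n_units, rate_range = rate_range, n_changes = n_changes,
         flash_period = flash_period, image_duration = image_duration,
         change_every = change_every, coupling = coupling, p_hit = p_hit,
         hit_effect = hit_effect, hit_tau = hit_tau, seed = seed),
    class = "synthetic_session_spec"
  )
}

#' Generate a synthetic change-detection session
#'
#' Builds a full session from a [synthetic_session_spec()]: a flash
#' schedule with periodic image changes, hit/miss outcomes from a
#' Bernoulli draw, per-unit inhomogeneous Poisson spike trains driven by a
#' shared flash-locked drive, a multiplicative rate transient in the
#' 300 ms post-change window on hit trials, unit metadata, and a smoothed
#' nonnegative running-speed trace. Identical seeds give identical
#' sessions.
#'
#' @param spec A [synthetic_session_spec()].
#' @param f Sampling rate for the internal rate signals, Hz (default 200).
#' @return List with elements `spike_table` (a [spike_table()]), `trials`
#'   (tibble: `change_time_s`, `outcome`), `speed` (tibble: `time_s`,
#'   `speed_cm_s`), and `duration` (seconds).
#' @export
gen_change_detection_session <- function(spec = synthetic_session_spec(),
                                         f = 200) {
  n_flashes <- spec$n_changes * spec$change_every + 2 * spec$change_every
  t_start <- 1
  flash_times <- t_start + spec$flash_period * (seq_len(n_flashes) - 1)
  change_idx <- seq(spec$change_every, by = spec$change_every,
                    length.out = spec$n_changes)
  change_times <- flash_times[change_idx]
  duration <- ceiling(max(flash_times) + spec$flash_period + 1)
  n_bins <- round(duration * f)
  tgrid <- (seq_len(n_bins) - 0.5) / f

  withr::with_seed(spec$seed, {
    outcomes <- ifelse(stats::runif(spec$n_changes) < spec$p_hit, "hit", "miss")

    # shared flash-locked drive: 1 while an image is on, 0 during gray
    drive <- numeric(n_bins)
    for (ft in flash_times) {
      on <- tgrid >= ft & tgrid < ft + spec$image_duration
      drive[on] <- 1
    }
    # multiplicative hit transient over the 300 ms post-change window
    gain <- rep(1, n_bins)
    for (i in seq_len(spec$n_changes)) {
      if (outcomes[i] == "hit" && spec$hit_effect > 0) {
        sel <- tgrid >= change_times[i] & tgrid < change_times[i] + 0.3
        gain[sel] <- gain[sel] *
          (1 + spec$hit_effect * exp(-(tgrid[sel] - change_times[i]) / spec$hit_tau))
      }
    }

    base <- stats::runif(spec$n_units, spec$rate_range[1], spec$rate_range[2])
    unit_ids <- sprintf("u%03d", seq_len(spec$n_units))
    spk <- lapply(seq_len(spec$n_units), function(i) {
      rate <- base[i] * (1 + spec$coupling * drive) * gain
      gen_poisson_spikes(rate, duration, f,
                         seed = stats::runif(1, 1, 2^30))
    })
    names(spk) <- unit_ids

    is_fs <- stats::runif(spec$n_units) < 0.2
    units <- tibble::tibble(
      unit_id = unit_ids,
      area = sample(c("VISp", "VISl", "VISal"), spec$n_units, replace = TRUE),
      layer = sample(c("2/3", "4", "5", "6"), spec$n_units, replace = TRUE),
      waveform_width_ms = round(ifelse(is_fs, stats::runif(spec$n_units, 0.2, 0.38),
                                       stats::runif(spec$n_units, 0.42, 0.7)), 3),
      snr = round(stats::runif(spec$n_units, 2.6, 6), 2),
      mouse_id = "mouse01"
    )
    spikes <- tibble::tibble(
      unit_id = rep(unit_ids, lengths(spk)),
      spike_time_s = unlist(spk, use.names = FALSE)
    )

    speed_t <- seq(0, duration, by = 0.1)
    raw <- stats::rnorm(length(speed_t))
    sm <- stats::filter(c(numeric(10), raw, numeric(10)), rep(1 / 21, 21))
    sm <- as.numeric(sm[11:(10 + length(speed_t))])
    speed <- tibble::tibble(
      time_s = speed_t,
      speed_cm_s = pmax(0, 8 + 25 * sm)
    )

    list(
      spike_table = spike_table(spikes, units, session_duration = duration),
      trials = tibble::tibble(change_time_s = change_times, outcome = outcomes),
      speed = speed,
      duration = duration
    )
  })
}
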