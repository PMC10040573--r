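#' Assemble a spike table from spikes and unit metadata
#'
#' Bundles per-unit spike times with unit metadata into a validated list
#' structure, the common input of the firing-rate pipeline. Spike times are
#' in seconds from session start; each unit's times must be sorted,
#' non-negative and lie within the session.
#'
#' @param spikes Data frame with columns `unit_id` and `spike_time_s`.
#' @param units Data frame with columns `unit_id`, `area`, `layer`,
#'   `waveform_width_ms`, `snr`, `mouse_id`. Extra columns are kept.
#' @param session_duration Session length in seconds. Defaults to the
#'   latest spike time rounded up to the next second.
#'
#' @return An object of class `spike_table`: a list with elements `spikes`
#'   (tibble), `units` (tibble) and `session_duration` (seconds).
#' @export
spike_table <- function(spikes, units, session_duration = NULL) {
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(spikes)))
  stopifnot("unit_id" %in% names(units))
  spikes <- tibble::as_tibble(spikes)
  units <- tibble::as_tibble(units)
  if (anyDuplicated(units$unit_id)) {
    stop("duplicated unit_id in unit metadata")
  }
  if (any(spikes$spike_time_s < 0)) stop("negative spike times")
  if (is.null(session_duration)) {
    session_duration <- if (nrow(spikes)) ceiling(max(spikes$spike_time_s)) else 0
  }
  if (any(spikes$spike_time_s > session_duration)) {
    stop("spike times exceed session_duration")
  }
  # enforce per-unit sorted order once so downstream binning can rely on it
  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$spike_time_s)
  structure(
    list(spikes = spikes, units = units, session_duration = session_duration),
    class = "spike_table"
  )
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf(
    "<spike_table> %d units, %d spikes, %.1f s session\n",
    nrow(x$units), nrow(x$spikes), x$session_duration
  ))
  invisible(x)
}

#' Classify units as regular- or fast-spiking
#'
#' Units with sufficient signal-to-noise ratio are split by mean waveform
#' width into regular-spiking (RS, putatively excitatory; broad waveform)
#' and fast-spiking (FS, putatively inhibitory; narrow waveform). Units at
#' exactly the width threshold are RS. Units failing the SNR filter, or
#' with missing width or SNR, are excluded.
#'
#' @param units Data frame with columns `waveform_width_ms` and `snr`.
#' @param width_threshold Waveform width cut in milliseconds (default 0.4).
#' @param snr_threshold Minimum SNR, exclusive (default 2.5).
#'
#' @return Character vector (one of `"RS"`, `"FS"`, `"excluded"`) aligned
#'   with the rows of `units`.
#' @export
classify_units <- function(units, width_threshold = 0.4, snr_threshold = 2.5) {
  stopifnot(width_threshold > 0, snr_threshold > 0)
  width <- units$waveform_width_ms
  snr <- units$snr
  n_missing <- sum(is.na(width) | is.na(snr))
  if (n_missing > 0) {
    warning(sprintf("%d unit(s) with missing waveform width or SNR excluded", n_missing))
  }
  cls <- rep("excluded", nrow(units))
  ok <- !is.na(width) & !is.na(snr) & snr > snr_threshold
  cls[ok & width >= width_threshold] <- "RS"
  cls[ok & width < width_threshold] <- "FS"
  cls
}

#' Bin spike times into a binary series
#'
#' Divides `[0, duration)` into half-open bins `[b*dt, (b+1)*dt)` and marks
#' a bin 1 if at least one spike falls inside it. Multiple spikes in a bin
#' collapse to a single 1.
#'
#' @param spikes Numeric vector of spike times (seconds), sorted ascending.
#' @param duration Series duration in seconds.
#' @param bin_width Bin width in seconds (default 0.005, i.e. 200 Hz).
#'
#' @return Integer vector of 0/1 of length `round(duration / bin_width)`.
#' @export
bin_spikes <- function(spikes, duration, bin_width = 0.005) {
  stopifnot(bin_width > 0, duration > 0)
  if (is.unsorted(spikes)) stop("spike times must be sorted ascending")
  if (length(spikes) && any(spikes < 0)) stop("negative spike times")
  n_bins <- round(duration / bin_width)
  if (length(spikes) && max(spikes) >= duration) {
    stop(sprintf(
      "spike at %.6f s lies at or beyond duration %.6f s",
      max(spikes), duration
    ))
  }
  out <- integer(n_bins)
  if (length(spikes)) {
    idx <- floor(spikes / bin_width) + 1L
    idx[idx > n_bins] <- n_bins  # guards float round-up at the last edge
    out[unique(idx)] <- 1L
  }
  out
}

#' Truncated, renormalized Gaussian smoothing kernel
#'
#' @param kernel_sd Kernel standard deviation in seconds.
#' @param kernel_cutoff Truncation half-width in seconds.
#' @param f Sampling rate in Hz.
#' @return Numeric vector of kernel taps summing to 1.
#' @keywords internal
gaussian_kernel <- function(kernel_sd = 0.010, kernel_cutoff = 0.025, f = 200) {
  stopifnot(kernel_cutoff >= kernel_sd, kernel_sd > 0)
  half <- round(kernel_cutoff * f)
  x <- (-half:half) / f
  k <- exp(-x^2 / (2 * kernel_sd^2))
  k / sum(k)  # renormalize after truncation: constant in -> constant out
}

#' Smooth a binary spike series into a firing rate
#'
#' Convolves the binary series with a truncated Gaussian kernel
#' (renormalized to unit mass after truncation) and scales by the sampling
#' rate so the output is in spikes/second. Edges are zero-padded and the
#' output has the same length as the input.
#'
#' @param binary Numeric/integer vector, typically from [bin_spikes()].
#' @param kernel_sd Gaussian SD in seconds (default 0.010).
#' @param kernel_cutoff Truncation half-width in seconds (default 0.025).
#' @param f Sampling rate in Hz (default 200).
#'
#' @return Numeric vector of firing rates (spikes/s), same length as input.
#' @export
smooth_rates <- function(binary, kernel_sd = 0.010, kernel_cutoff = 0.025, f = 200) {
  k <- gaussian_kernel(kernel_sd, kernel_cutoff, f)
  half <- (length(k) - 1L) / 2L
  padded <- c(numeric(half), as.numeric(binary), numeric(half))
  # filter() computes a running weighted sum; sides = 2 centers the kernel
  sm <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(sm[(half + 1L):(half + length(binary))]) * f
}

#' Construct a rate matrix
#'
#' A rate matrix is a units-by-bins numeric matrix with a fixed sampling
#' rate; all differentiation metrics consume it.
#'
#' @param values Numeric matrix, units in rows, time bins in columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0 Time of the first bin's left edge, seconds.
#' @param unit_ids Identifiers for the rows.
#' @return A `rate_matrix` object (numeric matrix with attributes).
#' @export
rate_matrix <- function(values, sampling_rate = 200, t0 = 0,
                        unit_ids = rownames(values)) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("rate values must be non-negative")
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(nrow(values)))
  structure(
    values,
    sampling_rate = sampling_rate,
    t0 = t0,
    unit_ids = as.character(unit_ids),
    class = c("rate_matrix", "matrix", "array")
  )
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf(
    "<rate_matrix> %d units x %d bins @ %g Hz (t0 = %g s)\n",
    nrow(x), ncol(x), attr(x, "sampling_rate"), attr(x, "t0")
  ))
  invisible(x)
}

#' Build a smoothed firing-rate matrix from a spike table
#'
#' Bins each unit's spikes at the sampling rate and smooths with the
#' truncated Gaussian kernel, producing the units-by-bins firing-rate
#' matrix at `f` Hz.
#'
#' @param st A [spike_table()], or a named list of spike-time vectors.
#' @param duration Duration in seconds (defaults to the spike table's
#'   session duration).
#' @param f Sampling rate, Hz (default 200).
#' @param kernel_sd,kernel_cutoff Smoothing kernel parameters in seconds.
#' @param unit_ids Restrict to these units (default: all).
#'
#' @return A [rate_matrix()] in spikes/second.
#' @export
build_rate_matrix <- function(st, duration = NULL, f = 200,
                              kernel_sd = 0.010, kernel_cutoff = 0.025,
                              unit_ids = NULL) {
  if (inherits(st, "spike_table")) {
    if (is.null(duration)) duration <- st$session_duration
    ids <- if (is.null(unit_ids)) st$units$unit_id else unit_ids
    spk <- split(st$spikes$spike_time_s, factor(st$spikes$unit_id, levels = ids))
  } else {
    stopifnot(is.list(st), !is.null(duration))
    ids <- if (is.null(unit_ids)) names(st) else unit_ids
    if (is.null(ids)) ids <- as.character(seq_along(st))
    spk <- st
    names(spk) <- ids
  }
  bw <- 1 / f
  rows <- lapply(spk, function(s) {
    s <- s[s < duration]  # clip spikes beyond the requested duration
    smooth_rates(bin_spikes(s, duration, bw), kernel_sd, kernel_cutoff, f)
  })
  rate_matrix(do.call(rbind, rows), sampling_rate = f, t0 = 0, unit_ids = ids)
}
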