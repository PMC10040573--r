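#' Read pipeline input tables
#'
#' Thin readers for the delimited-text interchange formats: spikes
#' (`unit_id`, `spike_time_s`), unit metadata (`unit_id`, `area`, `layer`,
#' `waveform_width_ms`, `snr`, `mouse_id`), stimulus epochs (`start_s`,
#' `end_s`, `stimulus` or `category`) and running speed (`time_s`,
#' `speed_cm_s`).
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_spikes_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(x)))
  x
}

#' @rdname read_spikes_csv
#' @export
read_units_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  stopifnot("unit_id" %in% names(x))
  x
}

#' @rdname read_spikes_csv
#' @export
read_epochs_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("start_s", "end_s") %in% names(x)))
  x
}

#' @rdname read_spikes_csv
#' @export
read_speed_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("time_s", "speed_cm_s") %in% names(x)))
  x
}

#' Write a table as CSV with stable float formatting
#'
#' Numeric columns are written with 10 significant digits so repeated runs
#' under the same seed produce byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_csv_stable <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- formatC(x[[j]], digits = 10, format = "g")
  }
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
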