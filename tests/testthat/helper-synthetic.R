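# Shared builders for synthetic ensembles and sessions used across tests.

# n_units i.i.d. constant-rate Poisson units as a rate matrix
make_iid_ensemble <- function(n_units = 60, rate = 10, dur = 60, f = 200,
                              seed = 100) {
  spk <- lapply(seq_len(n_units), function(i) {
    gen_poisson_spikes(rep(rate, dur * f), dur, f, seed = seed + i)
  })
  names(spk) <- sprintf("u%02d", seq_len(n_units))
  build_rate_matrix(spk, duration = dur, f = f)
}

# A session whose windows have real dynamic range: epochs of very different
# drive strength, as a stimulus-block session would have.
make_heterogeneous_session <- function(n_units = 20, dur = 90, f = 200,
                                       seed = 200) {
  env <- rep_len(rep(c(0.2, 1, 3, 0.5, 2, 0.1), each = 15 * f), dur * f)
  drive <- gen_piecewise_constant(0.25, dur, f, value_range = c(0, 3),
                                  seed = seed)
  spk <- lapply(seq_len(n_units), function(i) {
    gen_poisson_spikes(2 + 3 * env * drive, dur, f, seed = seed + i)
  })
  names(spk) <- sprintf("u%02d", seq_len(n_units))
  build_rate_matrix(spk, duration = dur, f = f)
}

# One change-detection session -> c(welch p, hit-miss nd difference)
run_hitmiss_session <- function(seed, hit_effect = 1) {
  spec <- synthetic_session_spec(seed = seed, hit_effect = hit_effect)
  ses <- gen_change_detection_session(spec)
  rm_ <- build_rate_matrix(ses$spike_table)
  ev <- evoked_nd(rm_, ses$trials$change_time_s)
  out <- ses$trials$outcome[match(ev$event_time_s, ses$trials$change_time_s)]
  hit <- ev$nd[out == "hit"]
  miss <- ev$nd[out == "miss"]
  if (length(hit) < 3 || length(miss) < 3) return(c(NA_real_, NA_real_))
  c(stats::t.test(hit, miss)$p.value, mean(hit) - mean(miss))
}

# Brute-force median pairwise Euclidean distance (independent oracle)
median_pairwise_oracle <- function(states) {
  if (is.list(states)) states <- do.call(rbind, states)
  n <- nrow(states)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, sqrt(sum((states[i, ] - states[j, ])^2)))
    }
  }
  stats::median(d)
}
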