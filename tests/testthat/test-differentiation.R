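test_that("configuration enforces window/state arithmetic", {
  cfg <- nd_config(W = 3, S = 0.3)
  expect_equal(cfg$n_state, 60)
  expect_error(nd_config(W = 0.3, S = 0.2), "at least 2 states")
  expect_equal(nd_config(W = 3, S = 0.0126)$S, 0.015)  # snapped to 3 samples
  expect_error(nd_config(W = 3, S = 0.002), "sampling grid")
})

test_that("state segmentation tiles windows without overlap", {
  rm_ <- rate_matrix(matrix(runif(2 * 700), 2), 200)
  expect_length(segment_states(rm_, c(0, 3), 0.3), 10)
  expect_length(segment_states(rm_, c(0, 0.3), 0.06), 5)
  expect_length(segment_states(rm_, c(0, 0.6), 0.3), 2)
  blocks <- segment_states(rm_, c(0, 3), 0.3)
  expect_equal(do.call(cbind, blocks), unclass(rm_)[, 1:600],
               ignore_attr = TRUE)
  expect_error(segment_states(rm_, c(0, 0.3), 0.3), "fewer than 2")
})

test_that("state PSD is the squared-magnitude unnormalized DFT over non-negative frequencies", {
  expect_equal(state_psd(matrix(1, 1, 4)), c(16, 0, 0))
  expect_equal(state_psd(matrix(0, 3, 8)), rep(0, 3 * 5))
  # per-unit block length floor(fS/2)+1, concatenated in unit order
  blk <- matrix(runif(3 * 60), 3)
  v <- state_psd(blk)
  expect_length(v, 3 * 31)
  expect_equal(v[1:31], as.numeric(Mod(fft(blk[1, ]))[1:31]^2))
  # scaling the block by Q scales every PSD entry by Q^2
  expect_equal(state_psd(blk * 3), 9 * v)
})

test_that("raw differentiation is the median pairwise distance (oracle equivalence)", {
  expect_equal(spectral_differentiation_raw(list(c(16, 0, 0), c(0, 0, 0))), 16)
  same <- replicate(5, runif(12), simplify = FALSE)
  expect_equal(spectral_differentiation_raw(rep(same[1], 5)), 0)
  expect_error(spectral_differentiation_raw(list(1:3, 1:4)), "length")
  for (seed in 1:50) {
    set.seed(seed)
    states <- matrix(rexp(sample(2:9, 1) * 20), ncol = 20)
    expect_equal(spectral_differentiation_raw(states),
                 median_pairwise_oracle(states))
  }
})

test_that("normalization removes the sqrt(N) and S^2 factors", {
  expect_equal(normalize_nd(5, 4, 0.5), 10)
  expect_equal(normalize_nd(5, 1, 1), 5)
})

test_that("pairwise distances of disjoint ensembles combine orthogonally", {
  set.seed(9)
  A <- matrix(rexp(4 * 10), 4)
  B <- matrix(rexp(4 * 15), 4)
  dA <- as.matrix(dist(A))
  dB <- as.matrix(dist(B))
  dU <- as.matrix(dist(cbind(A, B)))
  expect_equal(dU, sqrt(dA^2 + dB^2))
})

test_that("analytic bounds follow N A^2 f^2 S^2 and A^2 f^2", {
  expect_equal(bound_normalized(50, 200), 1e8)
  expect_equal(bound_normalized(1, 200), 4e4)
  expect_equal(bound_raw(1, 200, 1, 2), 8e4)
  expect_equal(bound_raw(2, 100, 0.5, 3), 3 * 4 * 1e4 * 0.25)
})

test_that("nd time series gates small ensembles, tiles epochs, and is scale invariant", {
  cfg <- nd_config(W = 3, S = 0.3)
  small <- rate_matrix(matrix(1, 9, 600), 200)
  expect_error(nd_timeseries(small, cfg = cfg), "at least 10")

  const <- rate_matrix(matrix(2, 12, 30 * 200), 200)
  nd_c <- nd_timeseries(const, cfg = cfg)
  expect_equal(nrow(nd_c), 10)              # 30 s epoch, W = 3 -> 10 windows
  expect_equal(nd_c$nd, rep(0, 10))         # constant rates

  # windows never straddle epoch boundaries; incomplete tails dropped
  ep <- data.frame(start_s = c(0, 7), end_s = c(7, 14))
  nd_e <- nd_timeseries(const, epochs = ep, cfg = cfg)
  expect_equal(nd_e$window_center_s, c(1.5, 4.5, 8.5, 11.5))

  rmh <- make_heterogeneous_session(n_units = 12, dur = 24, seed = 50)
  nd_a <- nd_timeseries(rmh, cfg = cfg)
  rms <- rate_matrix(unclass(rmh) * 2.5, 200)
  nd_b <- nd_timeseries(rms, cfg = cfg)
  expect_equal(nd_b$nd, nd_a$nd, tolerance = 1e-12)   # uniform rescaling
  expect_true(all(nd_a$nd <= bound_normalized(nd_a$amplitude_max, 200)))
})

test_that("raw differentiation scales quadratically with amplitude", {
  rmh <- make_heterogeneous_session(n_units = 12, dur = 12, seed = 60)
  blocks <- segment_states(rmh, c(0, 3), 0.3)
  sv <- lapply(blocks, state_psd)
  for (Q in c(0.5, 3.7)) {
    svQ <- lapply(blocks, function(b) state_psd(unclass(b) * Q))
    expect_equal(spectral_differentiation_raw(svQ),
                 Q^2 * spectral_differentiation_raw(sv),
                 tolerance = 1e-12)
  }
})

test_that("mean-firing-rate differentiation is the population variance of state means", {
  f <- 200
  # one window of 2 states with normalized per-state means 1 and 3
  vals <- c(rep(1, 60), rep(3, 60), rep(0, 120))
  rm_ <- rate_matrix(matrix(rep(vals, each = 12), 12, byrow = FALSE), f)
  ep <- data.frame(start_s = 0, end_s = 0.6)
  mf <- mfr_differentiation(rm_, epochs = ep, cfg = nd_config(W = 0.6, S = 0.3))
  expect_equal(mf$mfrd, 1.0)

  const <- rate_matrix(matrix(5, 12, 600), f)
  expect_equal(mfr_differentiation(const, cfg = nd_config(W = 3, S = 0.3))$mfrd, 0)

  # invariant under uniform rescaling of any single unit's rate
  rmh <- make_heterogeneous_session(n_units = 12, dur = 12, seed = 70)
  m2 <- unclass(rmh)
  m2[3, ] <- m2[3, ] * 10
  mf1 <- mfr_differentiation(rmh, cfg = nd_config(W = 3, S = 0.3))
  mf2 <- mfr_differentiation(rate_matrix(m2, f), cfg = nd_config(W = 3, S = 0.3))
  expect_equal(mf2$mfrd, mf1$mfrd, tolerance = 1e-12)
})

test_that("stimulus differentiation is the same computation with pixels as units", {
  m <- gen_stimulus("static_gratings", duration = 6, resolution = c(4, 4), seed = 2)
  cfg <- nd_config(W = 3, S = 0.3)
  sd_ <- stimulus_differentiation(m, cfg = cfg)
  nd_ <- nd_timeseries(m, cfg = cfg)
  expect_equal(sd_$nd, nd_$nd)
  expect_equal(stimulus_differentiation(gen_stimulus("gray", 6, seed = 1),
                                        cfg = cfg)$nd, rep(0, 2))
})

test_that("evoked differentiation matches a one-window epoch and skips late events", {
  rmh <- make_heterogeneous_session(n_units = 12, dur = 12, seed = 80)
  ev <- evoked_nd(rmh, event_times = c(2, 5.5), window = 0.3, S = 0.06)
  expect_equal(nrow(ev), 2)
  # agrees with nd_timeseries on the same single window and mean rate
  cfg <- nd_config(W = 0.3, S = 0.06)
  ref <- nd_timeseries(rmh, epochs = data.frame(start_s = 2, end_s = 2.3),
                       cfg = cfg, ensemble_mean_rate = mean(rmh))
  expect_equal(ev$nd[1], ref$nd)
  expect_length(segment_states(rmh, c(2, 2.3), 0.06), 5)

  const <- rate_matrix(matrix(2, 12, 600), 200)
  expect_equal(evoked_nd(const, 1)$nd, 0)
  expect_warning(ev2 <- evoked_nd(rmh, c(2, 11.9)), "skipped")
  expect_equal(nrow(ev2), 1)
})
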