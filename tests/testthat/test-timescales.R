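test_that("piecewise characteristic timescale is the mean interior run duration", {
  f <- 200
  flashes <- gen_stimulus("flashes", duration = 50, seed = 3)  # 25 full cycles
  expect_equal(piecewise_ct(flashes[1, ], f), 1.0)
  toy <- gen_piecewise_constant(0.6, 12, f, seed = 5)
  expect_equal(piecewise_ct(toy, f), 0.6)
  runs <- rep(c(1, 2, 9, 4, 7), each = 40)  # 0.2 s runs
  expect_equal(piecewise_ct(runs, f), 0.2)
  # only run lengths matter, not values
  expect_equal(piecewise_ct(runs * 31 + 5, f), 0.2)
  expect_error(piecewise_ct(c(1, 1, 2, 2), f), "interior")
})

test_that("autocorrelation is the biased normalized autocovariance", {
  set.seed(2)
  w <- rnorm(5000)
  a <- autocorrelation(w, max_lag = 0.1, f = 200)
  expect_equal(a$ac[1], 1)
  expect_true(all(abs(a$ac[-1]) < 3 / sqrt(5000)))
  set.seed(3)
  z <- as.numeric(arima.sim(list(ar = 0.9), 20000))
  az <- autocorrelation(z, max_lag = 0.05, f = 200)
  expect_equal(az$ac[-1], 0.9^(1:10), tolerance = 0.05)
  expect_error(autocorrelation(rep(1, 1000), 0.1), "variance")
  expect_error(autocorrelation(rnorm(100), max_lag = 2, f = 200), "longer")
})

test_that("two-exponent fit recovers generating parameters and stays in its box", {
  x <- seq(0.005, 2, by = 0.005)
  model <- function(x, a, c, t1, t2) {
    ifelse(x < c, -a - x / t1, -a - c / t1 - (x - c) / t2)
  }
  ac <- tibble::tibble(lag_s = c(0, x),
                       ac = c(1, exp(model(x, 0.05, 0.1, 0.1, 5))))
  fit <- fit_characteristic_timescale(ac)
  expect_equal(fit$t1, 0.1, tolerance = 0.05)
  expect_equal(fit$t2, 5, tolerance = 0.05)
  expect_equal(fit$c, 0.1, tolerance = 0.05)

  # single-exponential limit: t2's lower box edge biases t1 slightly
  ac2 <- tibble::tibble(lag_s = c(0, x), ac = c(1, exp(-x / 0.2)))
  fit2 <- fit_characteristic_timescale(ac2)
  expect_equal(fit2$t1, 0.2, tolerance = 0.15)
  expect_true(fit2$at_boundary)

  # constraints hold for arbitrary model-generated inputs; recovery error
  # shrinks as multiplicative noise shrinks
  errs <- numeric(0)
  for (noise in c(0.1, 0.01, 0.001)) {
    set.seed(round(1000 * noise))
    acn <- tibble::tibble(
      lag_s = c(0, x),
      ac = c(1, exp(model(x, 0.02, 0.08, 0.25, 3)) *
               exp(rnorm(length(x), sd = noise)))
    )
    fn <- fit_characteristic_timescale(acn)
    expect_gt(fn$t1, 0); expect_lte(fn$t1, 1.5)
    expect_gte(fn$t2, 0.5); expect_lte(fn$t2, 20)
    expect_gte(fn$c, 0.03); expect_lte(fn$c, 0.2)
    expect_gte(fn$a, 0)
    errs <- c(errs, abs(fn$t1 - 0.25))
  }
  expect_lt(errs[3], errs[1] + 1e-9)
  expect_lt(errs[3] / 0.25, 0.05)
  expect_error(fit_characteristic_timescale(tibble::tibble(
    lag_s = c(0, 0.01, 0.02), ac = c(1, 0.5, 0.2))), "5 usable")
})

test_that("the state-length grid is increasing and sample-aligned", {
  g <- state_length_grid(f = 200)
  expect_true(all(diff(g) > 0))
  expect_equal(round(g * 200), g * 200)
  expect_equal(min(g), 0.010)
  expect_equal(max(g), 3)
})

test_that("dense signals give flat-then-decreasing curves; sparse give interior optima", {
  f <- 200
  cfg <- nd_config(W = 3, S = 0.3, f = f, min_units = 1)
  dense <- gen_piecewise_constant(0.6, 120, f, seed = 11)
  cur_d <- nd_vs_state_length(rate_matrix(matrix(dense, 1), f), cfg)
  below <- cur_d$nd[cur_d$S_s <= 0.31]
  above <- cur_d$nd[cur_d$S_s > 0.6]
  expect_lt(max(below) / min(below), 1.25)              # flat below CT
  expect_lt(mean(utils::tail(above, 2)) / mean(utils::head(above, 2)), 0.92)
  expect_lt(power_law_fit(cur_d, 0.6)$exponent, -0.15)  # power-law decay

  sparse <- gen_piecewise_constant(0.6, 120, f, sparse = TRUE, seed = 12)
  cur_s <- nd_vs_state_length(rate_matrix(matrix(sparse, 1), f), cfg)
  opt <- detect_optimal_timescale(cur_s)
  expect_equal(opt$classification, "interior-optimum")
  expect_false(opt$at_boundary)
  expect_gt(opt$S_opt, 0.2)      # optimum near the 0.6 s timescale
  expect_lt(opt$S_opt, 1.8)

  flat0 <- nd_vs_state_length(rate_matrix(matrix(7, 1, 120 * f), f), cfg)
  expect_equal(flat0$nd, rep(0, nrow(flat0)))
})

test_that("optimal-timescale detection classifies curves", {
  unimodal <- tibble::tibble(S_s = c(0.05, 0.1, 0.2, 0.4), nd = c(1, 5, 2, 1))
  o <- detect_optimal_timescale(unimodal)
  expect_equal(o$classification, "interior-optimum")
  expect_equal(o$S_opt, 0.1)
  expect_false(o$at_boundary)

  falling <- tibble::tibble(S_s = c(0.05, 0.1, 0.2, 0.4), nd = c(9, 5, 2, 1))
  o2 <- detect_optimal_timescale(falling)
  expect_true(o2$at_boundary)          # loss of optimality at the short end
  expect_equal(o2$S_opt, 0.05)

  rising <- tibble::tibble(S_s = c(0.05, 0.1, 0.2, 0.4), nd = c(1, 2, 5, 9))
  expect_equal(detect_optimal_timescale(rising)$classification,
               "optimum-beyond-range")
  zeros <- tibble::tibble(S_s = c(0.05, 0.1), nd = c(0, 0))
  expect_equal(detect_optimal_timescale(zeros)$classification, "zero")
})

test_that("power-law fits recover exponents and ignore curve scale", {
  S <- exp(seq(log(0.05), log(3), length.out = 12))
  for (p in c(-2, -1)) {
    cur <- tibble::tibble(S_s = S, nd = S^p)
    expect_equal(power_law_fit(cur, 0.04)$exponent, p, tolerance = 1e-9)
    cur10 <- tibble::tibble(S_s = S, nd = 10 * S^p)
    expect_equal(power_law_fit(cur10, 0.04)$exponent, p, tolerance = 1e-9)
  }
  set.seed(8)
  noisy <- tibble::tibble(S_s = S, nd = S^(-1.5) * exp(rnorm(12, sd = 0.05)))
  expect_equal(power_law_fit(noisy, 0.04)$exponent, -1.5, tolerance = 0.1)
  expect_error(power_law_fit(tibble::tibble(S_s = S[1:2], nd = c(1, 2)), 0.01),
               "at least 3")
})
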