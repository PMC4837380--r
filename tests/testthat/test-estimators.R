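test_that("stationary_summary computes time-weighted pooled moments", {
  N <- 50
  tr <- synthetic_traj(0:200, rep(N, 201), rho = rep(0, 201), N = N)
  st <- stationary_summary(tr, transient = 10)
  expect_equal(st$mean_n, N)
  expect_equal(st$var_n, 0)
  expect_equal(st$mean_rho, 0)
  expect_equal(sum(st$hist_n), 1)
  expect_equal(st$hist_n[N + 1], 1)

  # i.i.d. Bernoulli(1/2) * N samples: variance -> N/4 per-node, i.e. N/4
  set.seed(1)
  ns <- rbinom(20000, N, 0.5)
  st2 <- stationary_summary(synthetic_traj(seq_along(ns), ns, N = N),
                            transient = 0)
  expect_lt(abs(st2$var_n - N / 4) / (N / 4), 0.05)

  expect_error(stationary_summary(tr, transient = 1000), "transient")
})

test_that("stationary_summary is invariant under relabeling and splitting", {
  set.seed(2)
  x <- cumsum(sample(c(-1, 1), 4000, TRUE)) + 100
  x <- pmin(pmax(x, 0), 200)
  one <- synthetic_traj(1:4000, x, N = 200)
  st1 <- stationary_summary(one, transient = 0)

  # split into 4 segments presented as different realizations
  seg <- rep(1:4, each = 1000)
  split_tr <- dplyr::bind_rows(lapply(1:4, function(k) {
    tibble::tibble(t = 1:1000, n = x[seg == k], graph_id = 1L, real_id = k)
  }))
  attr(split_tr, "params") <- attr(one, "params")
  class(split_tr) <- class(one)
  st2 <- stationary_summary(split_tr, transient = 0)
  expect_equal(st2$mean_n, st1$mean_n)
  expect_equal(st2$var_n, st1$var_n)
  expect_equal(st2$hist_n, st1$hist_n)

  # relabeling realizations changes nothing
  split_tr$real_id <- 5 - split_tr$real_id
  st3 <- stationary_summary(split_tr, transient = 0)
  expect_equal(st3$var_n, st2$var_n)
})

test_that("distributions are classified against the uniform variance level", {
  N <- 20
  point <- c(rep(0, 10), 1, rep(0, 10))
  expect_identical(classify_distribution(point), "unimodal")
  extremes <- c(0.5, rep(0, 19), 0.5)
  expect_identical(classify_distribution(extremes), "bimodal")
  expect_identical(classify_distribution(rep(1 / 21, 21)), "uniform")
  expect_error(classify_distribution(rep(1, 21)), "normalized")
})

test_that("empirical critical point interpolates the uniform crossing", {
  N <- 100
  u <- N * (N + 2) / 12
  a <- c(0.001, 0.004, 0.016, 0.064)
  a0 <- 0.008
  # synthetic variance curve crossing exactly at a0, linear in log a
  v <- u + 400 * (log(a0) - log(a))
  est <- interp_critical_a(a, v, N)
  expect_equal(est$a_c, a0, tolerance = 1e-12)
  expect_equal(est$bracket, c(0.004, 0.016))
  expect_error(interp_critical_a(a, v + 1e5, N), "does not cross")
})

test_that("empirical ACF recovers known correlation structures", {
  # white noise: zero beyond lag 0
  set.seed(3)
  wn <- synthetic_traj(1:20000, rnorm(20000, 100, 5), N = 200)
  ac <- empirical_acf(wn, max_lag = 10, transient = 0)
  expect_equal(ac$nacf[1], 1)
  expect_lt(max(abs(ac$nacf[-1])), 0.03)
  # K(0) equals the sample variance
  st <- stationary_summary(wn, transient = 0)
  expect_equal(ac$acf[1], st$var_n, tolerance = 1e-8)

  # OU-like series with known rate r: fitted exponential rate ~ r
  r <- 0.05
  x <- ou_series(40000, dt = 1, rate = r, sd_st = 3, seed = 4)
  tr <- synthetic_traj(1:40000, x + 50, N = 100)
  ac2 <- empirical_acf(tr, max_lag = 40, transient = 0)
  fit <- stats::lm(log(nacf) ~ lag, data = ac2[ac2$nacf > 0.1, ])
  expect_lt(abs(-stats::coef(fit)[[2]] - r) / r, 0.1)

  expect_error(empirical_acf(wn, max_lag = 1e6, transient = 0), "span")
})

test_that("2D lattice autocorrelation decays as a single exponential at 2a", {
  g <- make_network("lattice2d", N = 900)
  tr <- simulate_ensemble(g, a = 0.02, h = 1, t_max = 6000,
                          sample_interval = 0.5, n_real = 2, seed = 31)
  ac <- empirical_acf(tr, max_lag = 60, lag_step = 0.5, transient = 900)
  win <- ac$lag >= 5 & ac$lag <= 50 & ac$nacf > 0
  fit <- stats::lm(log(nacf) ~ lag, data = ac[win, ])
  expect_lt(abs(-stats::coef(fit)[[2]] - 0.04) / 0.04, 0.35)
})

test_that("scan_variance brackets the transition and carries theory", {
  graphs <- lapply(1:3, function(s)
    make_network("er", N = 100, mean_degree = 8, seed = s))
  sc <- scan_variance(graphs, h = 1, a_grid = c(0.001, 0.01, 0.05, 0.3),
                      t_max = 2000, n_real = 3, seed = 41)
  expect_true(all(c("var_n", "var_theory", "classification") %in% names(sc)))
  expect_true(all(diff(sc$var_n) < 0))
  u <- 100 * 102 / 12
  expect_gt(sc$var_n[1], u)   # far below a_c: bimodal
  expect_lt(sc$var_n[4], u)   # far above: unimodal
  expect_true(sc$classification[1] != "unimodal")
  expect_identical(sc$classification[4], "unimodal")
  ac_emp <- attr(sc, "a_c_empirical")
  ac_th <- critical_a(100, 1, degree_stats(graphs[[1]]))$a_c
  expect_lt(abs(log(ac_emp / ac_th)), log(2.5))
})
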