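d_hom <- degree_stats_nominal(8, 0, 2500)
d_dich <- degree_stats_nominal(8, 16, 2500)
d_ba <- degree_stats_nominal(8, 64 * 1.16, 2500)  # BA-like heterogeneity

test_that("stationary variance interpolates between N^2/4 and N/4", {
  N <- 2500
  for (d in list(d_hom, d_dich, d_ba)) {
    expect_lt(abs(variance_st(N, 1e4, 1, d)$variance - N / 4) / (N / 4), 1e-3)
    expect_lt(abs(variance_st(N, 1e-7, 1, d)$variance - N^2 / 4) / (N^2 / 4),
              1e-2)
  }
  v0 <- variance_st(N, 0, 1, d_dich)
  expect_equal(v0$variance, N^2 / 4)
  expect_false(v0$validity_ok)
  expect_true(variance_st(N, 0.01, 1, d_dich)$validity_ok)
})

test_that("variance is monotone in noise and in heterogeneity", {
  N <- 2500
  as <- 10^seq(-4, 3, length.out = 40)
  vs <- vapply(as, function(a) variance_st(N, a, 1, d_dich)$variance, 0)
  expect_true(all(diff(vs) < 0))
  expect_true(all(vs <= N^2 / 4 * 1.01 & vs >= N / 4 * 0.99))

  hets <- c(0, 0.25, 0.5, 1, 2)
  for (a in c(0.005, 0.05, 0.5)) {
    vh <- vapply(hets, function(ht)
      variance_st(N, a, 1, degree_stats_nominal(8, 64 * ht, N))$variance, 0)
    expect_true(all(diff(vh) > 0))
    rh <- vapply(hets, function(ht)
      rho_st(N, a, 1, degree_stats_nominal(8, 64 * ht, N)), 0)
    expect_true(all(diff(rh) < 0))
  }
})

test_that("theory agrees with the exact birth-death chain as O(1/N)", {
  # frozen constant: |var_th - var_exact| / var_exact <= 4 / N
  for (N in c(8, 16, 32, 64)) {
    d <- degree_stats_nominal(N - 1, 0, N)
    for (a in c(0.5 / N, 2 / N, 0.5, 5)) {
      ve <- birth_death_stationary(N, a, 1, spectrum = FALSE)$var_n
      vt <- variance_st(N, a, 1, d)$variance
      expect_lt(abs(vt - ve) / ve, 4 / N)
    }
  }
})

test_that("asymptotic branches match the full curve inside their regimes", {
  N <- 2500
  ast <- crossover_a(N, 1, d_ba)$a_star
  for (a in c(ast / 20, ast / 5)) {
    expect_lt(abs(variance_asymptotic(N, a, 1, d_ba, "small_a") /
                  variance_st(N, a, 1, d_ba)$variance - 1), 0.05)
  }
  for (a in c(5 * ast, 20 * ast)) {
    expect_lt(abs(variance_asymptotic(N, a, 1, d_ba, "large_a") /
                  variance_st(N, a, 1, d_ba)$variance - 1), 0.05)
  }
  # and diverge outside
  expect_gt(abs(variance_asymptotic(N, 20 * ast, 1, d_ba, "small_a") /
                variance_st(N, 20 * ast, 1, d_ba)$variance - 1), 0.05)
  expect_gt(abs(variance_asymptotic(N, ast / 20, 1, d_ba, "large_a") /
                variance_st(N, ast / 20, 1, d_ba)$variance - 1), 0.05)
})

test_that("crossover scales as h N^{-1/2} and rescales with h", {
  expect_equal(crossover_a(2500, 2, d_dich)$a_star,
               2 * crossover_a(2500, 1, d_dich)$a_star, tolerance = 1e-5)
  Ns <- c(1e3, 1e4, 1e5)
  as <- vapply(Ns, function(N) crossover_a(N, 1, d_ba)$a_star, 0)
  slope <- stats::coef(stats::lm(log(as) ~ log(Ns)))[[2]]
  expect_lt(abs(slope + 0.5), 0.05)
  # vanishing heterogeneity: the branches no longer cross in range
  expect_warning(crossover_a(2500, 1, d_hom), "boundary")
})

test_that("critical point grows linearly with degree heterogeneity", {
  N <- 2500
  cr <- critical_a(N, 1, d_hom)
  expect_equal(cr$a_c_meanfield, 1 / N)
  expect_lt(abs(cr$a_c / cr$a_c_meanfield - 1), 5 / N)  # h/N (1 + O(1/N))
  vars <- 64 * c(0, 0.5, 1, 1.5, 2)
  acs <- vapply(vars, function(v)
    critical_a(N, 1, degree_stats_nominal(8, v, N))$a_c, 0)
  fit <- stats::lm(acs ~ vars)
  expect_gt(stats::coef(fit)[[2]], 0)
  expect_lt(max(abs(stats::residuals(fit))), 1e-12 * max(acs))  # exactly linear
  # dichotomous vs ER ordering at matched mean degree
  ac_er <- critical_a(N, 1, degree_stats_nominal(8, 7.97, N))$a_c
  ac_di <- critical_a(N, 1, d_dich)$a_c
  expect_gt(ac_di / ac_er, 1)
  expect_lt(ac_di / ac_er, 3)
})

test_that("interface density has the right limits and expression", {
  N <- 2500
  expect_lt(abs(rho_st(N, 1e5, 1, d_dich) - 0.5), 1e-3)
  expect_lt(rho_st(N, 1e-7, 1, d_dich), 1e-3)
  expect_equal(rho_st(N, 0, 1, d_dich), 0)
  r <- rho_st(N, 0.05, 1, d_dich)
  expect_gt(r, 0); expect_lte(r, 0.5)
})

test_that("autocorrelation components reduce to a single mode when homogeneous", {
  N <- 2500
  cmp <- acf_components(N, 0.02, 1, d_hom)
  expect_equal(cmp$rate_slow, 0.04)
  expect_equal(cmp$rate_fast, 1.04)
  expect_lt(abs(cmp$amp_fast) / cmp$variance, 5e-3)  # 0 up to O(1/N)
  expect_equal(acf_theory(0, N, 0.02, 1, d_hom),
               variance_st(N, 0.02, 1, d_hom)$variance)
})

test_that("heterogeneity lifts the slow-mode tail of the autocorrelation", {
  N <- 2500
  taus <- seq(60, 150, by = 10)
  offs <- vapply(c(0.25, 1, 2), function(ht) {
    d <- degree_stats_nominal(8, 64 * ht, N)
    cmp <- acf_components(N, 0.01, 1, d)
    # long lags: log K ~ log(S1/var) - 2 a tau; positive, growing offset
    k <- acf_theory(taus, N, 0.01, 1, d) / cmp$variance
    resid <- log(k) + 2 * 0.01 * taus
    expect_lt(stats::sd(resid), 1e-3)      # parallel to e^{-2 a tau}
    mean(resid)
  }, 0)
  expect_true(all(offs > 0))
  expect_true(all(diff(offs) > 0))
})

test_that("annealed class dynamics reproduces the two-exponential ACF", {
  # independent check of S1: simulate the annealed model and compare the
  # measured normalized ACF with the predicted mixture at moderate lags
  N <- 1200
  d <- degree_stats_nominal(12, 64, N)
  tr <- simulate_nvm_annealed(c(600, 600), c(4, 20), a = 0.1, h = 1,
                              t_max = 30000, sample_interval = 0.2, seed = 21)
  ac <- empirical_acf(tr, max_lag = 30, lag_step = 0.2, transient = 100)
  cmp <- acf_components(N, 0.1, 1, d)
  pred <- (cmp$amp_slow * exp(-cmp$rate_slow * ac$lag) +
           cmp$amp_fast * exp(-cmp$rate_fast * ac$lag)) / cmp$variance
  expect_lt(max(abs(ac$nacf - pred)), 0.05)
  # the early fast-mode dip distinguishes the mixture from a single mode
  single <- exp(-cmp$rate_slow * ac$lag)
  expect_gt(max(abs(single - pred)), 0.01)
})

test_that("dimensionless outputs depend only on a/h and the moments", {
  N <- 2500
  v1 <- variance_st(N, 0.02, 1, d_dich)$variance
  v2 <- variance_st(N, 0.06, 3, d_dich)$variance
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(rho_st(N, 0.02, 1, d_dich), rho_st(N, 0.1, 5, d_dich),
               tolerance = 1e-12)
})

test_that("the bundled prediction object is coherent and tidies", {
  th <- nvm_theory(2500, 0.01, 1, d_dich)
  expect_s3_class(th, "nvm_theory")
  expect_equal(th$acf$variance, th$var_n_st)
  expect_equal(th$var_uniform, 2500 * 2502 / 12)
  td <- tidy(th)
  expect_true(all(c("quantity", "value") %in% names(td)))
  expect_identical(glance(th)$phase,
                   if (th$var_n_st > th$var_uniform) "bimodal" else "unimodal")
})
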