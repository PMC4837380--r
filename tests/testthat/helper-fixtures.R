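# shared fixtures built in code

# wrap plain columns as an nvm_trajectory so estimators can be tested on
# synthetic series with known moments
synthetic_traj <- function(t, n, rho = NULL, N, a = 0.1, h = 1, dt = NULL) {
  out <- tibble::tibble(t = t, n = n)
  if (!is.null(rho)) out$rho <- rho
  if (is.null(dt)) dt <- if (length(t) > 1) t[2] - t[1] else 1
  attr(out, "params") <- list(a = a, h = h, N = N, seed = NA,
                              kind = "synthetic", sample_interval = dt,
                              t_max = max(t), events = NA)
  class(out) <- c("nvm_trajectory", class(out))
  out
}

# discrete Ornstein-Uhlenbeck-like AR(1) series with relaxation rate r
ou_series <- function(n_steps, dt, rate, sd_st = 1, seed = 1) {
  set.seed(seed)
  phi <- exp(-rate * dt)
  x <- numeric(n_steps)
  x[1] <- rnorm(1, 0, sd_st)
  eps <- rnorm(n_steps - 1, 0, sd_st * sqrt(1 - phi^2))
  for (i in 2:n_steps) x[i] <- phi * x[i - 1] + eps[i - 1]
  x
}

small_er <- function(N = 60, seed = 1) {
  make_network("er", N = N, mean_degree = 8, seed = seed)
}
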