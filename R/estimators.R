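#' Stationary summary of simulated trajectories
#'
#' Pools one or more trajectories (a single [simulate_nvm()] result or a
#' [simulate_ensemble()] tibble) into steady-state estimates of the mean
#' and variance of n, the occupancy histogram over `0..N`, and the mean
#' interface density, after discarding an initial transient.  Samples on
#' the uniform grid are equally weighted, which is the time-weighted
#' average of the piecewise-constant process.
#'
#' @param trajs An `nvm_trajectory` tibble (single run or ensemble).
#' @param transient Time units to discard from the start of every
#'   realization; defaults to `N` (the conventional transient).
#' @return An object of class `nvm_stationary`: a list with `mean_n`,
#'   `var_n`, `se_var_n` (a between-realization standard error when
#'   possible), `hist_n`, `mean_rho`, `n_samples`, `n_realizations`,
#'   `transient`, `N`.
#' @export
stationary_summary <- function(trajs, transient = NULL) {
  p <- attr(trajs, "params")
  N <- p$N
  if (is.null(transient)) transient <- N
  df <- tibble::as_tibble(trajs)
  if (!"graph_id" %in% names(df)) df$graph_id <- 1L
  if (!"real_id" %in% names(df)) df$real_id <- 1L
  df <- dplyr::filter(df, .data$t >= transient)
  if (nrow(df) == 0) stop("no samples left after discarding the transient")

  per <- dplyr::summarise(dplyr::group_by(df, .data$graph_id, .data$real_id),
                          v = mean(.data$n^2) - mean(.data$n)^2,
                          .groups = "drop")
  var_pooled <- mean(df$n^2) - mean(df$n)^2
  se <- if (nrow(per) > 1) stats::sd(per$v) / sqrt(nrow(per)) else NA_real_

  hist_n <- tabulate(as.integer(round(df$n)) + 1L, nbins = N + 1L)
  structure(list(
    mean_n = mean(df$n),
    var_n = var_pooled,
    se_var_n = se,
    hist_n = hist_n / sum(hist_n),
    mean_rho = if ("rho" %in% names(df)) mean(df$rho) else NA_real_,
    n_samples = nrow(df),
    n_realizations = nrow(per),
    transient = transient,
    N = N
  ), class = "nvm_stationary")
}

#' @export
print.nvm_stationary <- function(x, ...) {
  cat(sprintf(
    "<stationary estimate: N=%d, %d realization(s), %d samples>\n",
    x$N, x$n_realizations, x$n_samples))
  cat(sprintf("  mean_n = %.3f  var_n = %.4g (se %.3g)  mean_rho = %.4g\n",
              x$mean_n, x$var_n, x$se_var_n, x$mean_rho))
  cat(sprintf("  classification vs uniform N(N+2)/12 = %.4g: %s\n",
              x$N * (x$N + 2) / 12, classify_distribution(x)))
  invisible(x)
}

#' Classify the stationary distribution of n
#'
#' Bimodal / uniform / unimodal classification by comparing the variance of
#' n with the discrete-uniform value \eqn{N(N+2)/12}: above means bimodal
#' (order-dominated, peaks at 0 and N), below means unimodal (peak at N/2).
#' Values within `n_se` standard errors of the level (or exactly equal,
#' when no standard error is available) are called uniform.
#'
#' @param x An `nvm_stationary` object, or a normalized histogram over
#'   `0..N` (numeric vector of length N+1).
#' @param se Optional standard error of the variance estimate (taken from
#'   `x` when available).
#' @param n_se Width of the uniform band in standard errors.
#' @return `"bimodal"`, `"uniform"` or `"unimodal"`.
#' @export
classify_distribution <- function(x, se = NULL, n_se = 3) {
  if (inherits(x, "nvm_stationary")) {
    v <- x$var_n
    N <- x$N
    if (is.null(se)) se <- x$se_var_n
  } else {
    h <- as.numeric(x)
    if (abs(sum(h) - 1) > 1e-8) stop("histogram must be normalized")
    N <- length(h) - 1L
    n <- 0:N
    v <- sum(h * n^2) - sum(h * n)^2
  }
  u <- N * (N + 2) / 12
  band <- if (!is.null(se) && is.finite(se)) n_se * se else 0
  band <- max(band, 1e-9 * u)  # exact ties up to rounding count as uniform
  if (abs(v - u) <= band) "uniform" else if (v > u) "bimodal" else "unimodal"
}

#' Locate the empirical critical point on a variance-vs-noise curve
#'
#' Linear interpolation of `var_n` against `log(a)` across the
#' discrete-uniform level `N(N+2)/12`.  Exposed separately from the
#' simulation driver so synthetic curves can be inverted directly.
#'
#' @param a Increasing noise grid.
#' @param var_n Stationary variance estimates at `a`.
#' @param N System size.
#' @return A list with `a_c`, `bracket` (the two grid points) and
#'   `bracket_var`.
#' @export
interp_critical_a <- function(a, var_n, N) {
  stopifnot(length(a) == length(var_n), length(a) >= 2, !is.unsorted(a))
  u <- N * (N + 2) / 12
  s <- sign(var_n - u)
  ix <- which(s[-1] * s[-length(s)] <= 0)
  if (length(ix) == 0) {
    stop(sprintf(paste0("variance curve does not cross the uniform level ",
                        "%.4g (endpoints %.4g, %.4g)"),
                 u, var_n[1], var_n[length(var_n)]))
  }
  i <- ix[1]
  la <- log(a)
  w <- (u - var_n[i]) / (var_n[i + 1] - var_n[i])
  list(a_c = exp(la[i] + w * (la[i + 1] - la[i])),
       bracket = a[c(i, i + 1)],
       bracket_var = var_n[c(i, i + 1)])
}

#' Empirical critical point from simulations on a graph ensemble
#'
#' Simulates the model on every graph for each noise value in `a_grid`,
#' estimates the stationary variance of n (pooled over graphs and
#' realizations) and locates the crossing of the uniform level by
#' [interp_critical_a()].
#'
#' @param graphs List of igraph graphs (or one graph).
#' @param h Interaction rate.
#' @param a_grid Increasing noise grid bracketing the transition.
#' @param t_max,n_real,transient,sample_interval Simulation protocol per
#'   (graph, a) pair.
#' @param seed Base seed.
#' @return A list with `a_c`, `bracket`, `bracket_var` and `scan` (tibble
#'   of `a`, `var_n`, `mean_rho`, `classification`).
#' @export
critical_a_empirical <- function(graphs, h, a_grid, t_max, n_real = 1L,
                                 transient = NULL, sample_interval = 1,
                                 seed = 1L) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  scan <- scan_ensemble(graphs, h, a_grid, t_max, n_real, transient,
                        sample_interval, seed)
  N <- igraph::vcount(graphs[[1]])
  est <- interp_critical_a(scan$a, scan$var_n, N)
  c(est, list(scan = scan))
}

# shared simulation sweep over a noise grid
scan_ensemble <- function(graphs, h, a_grid, t_max, n_real, transient,
                          sample_interval, seed) {
  purrr::map_dfr(seq_along(a_grid), function(j) {
    tr <- simulate_ensemble(graphs, a = a_grid[j], h = h, t_max = t_max,
                            sample_interval = sample_interval,
                            n_real = n_real, seed = seed + 10000L * j)
    st <- stationary_summary(tr, transient = transient)
    tibble::tibble(a = a_grid[j], var_n = st$var_n, se_var_n = st$se_var_n,
                   mean_rho = st$mean_rho,
                   classification = classify_distribution(st))
  })
}

#' Empirical stationary autocorrelation of n
#'
#' \eqn{K(\tau) = \langle n(t) n(t+\tau)\rangle - \langle n\rangle^2},
#' averaged over time (after the transient) and over realizations; the lag
#' grid is a multiple of the trajectory sampling interval.  `K(0)` equals
#' the pooled sample variance.
#'
#' @param trajs An `nvm_trajectory` tibble (single run or ensemble).
#' @param max_lag Largest lag, in model time units; must be smaller than
#'   the post-transient span.
#' @param lag_step Lag grid step (defaults to the sampling interval).
#' @param transient Time discarded from each realization (default `N`).
#' @return A tibble with columns `lag`, `acf` (autocovariance) and `nacf`
#'   (normalized by `K(0)`), with attribute `params`.
#' @export
empirical_acf <- function(trajs, max_lag, lag_step = NULL, transient = NULL) {
  p <- attr(trajs, "params")
  dt <- p$sample_interval
  if (is.null(lag_step)) lag_step <- dt
  step <- as.integer(round(lag_step / dt))
  if (abs(step * dt - lag_step) > 1e-9) {
    stop("lag_step must be a multiple of the sampling interval")
  }
  if (is.null(transient)) transient <- p$N
  df <- tibble::as_tibble(trajs)
  if (!"graph_id" %in% names(df)) df$graph_id <- 1L
  if (!"real_id" %in% names(df)) df$real_id <- 1L
  df <- dplyr::filter(df, .data$t >= transient)
  span <- max(df$t) - min(df$t)
  if (max_lag >= span) stop("max_lag must be below the post-transient span")

  lags <- seq(0L, as.integer(floor(max_lag / dt)), by = step)
  nbar <- mean(df$n)
  pieces <- split(df$n, interaction(df$graph_id, df$real_id, drop = TRUE))
  sums <- numeric(length(lags)); cnts <- numeric(length(lags))
  for (x in pieces) {
    Tn <- length(x)
    for (j in seq_along(lags)) {
      L <- lags[j]
      if (Tn - L < 2) next
      sums[j] <- sums[j] + sum(x[1:(Tn - L)] * x[(1 + L):Tn])
      cnts[j] <- cnts[j] + (Tn - L)
    }
  }
  K <- sums / cnts - nbar^2
  out <- tibble::tibble(lag = lags * dt, acf = K, nacf = K / K[1])
  attr(out, "params") <- p
  attr(out, "n_realizations") <- length(pieces)
  class(out) <- c("nvm_acf", class(out))
  out
}

#' Plot an empirical autocorrelation
#'
#' Normalized autocorrelation on a log-linear scale (the layout in which
#' the two-exponential structure is visible as an initial deviation from a
#' straight line followed by a parallel shifted tail).
#'
#' @param object Result of [empirical_acf()].
#' @param theory Optional `nvm_theory` object to overlay.
#' @param ... Unused.
#' @export
autoplot.nvm_acf <- function(object, theory = NULL, ...) {
  pl <- ggplot2::ggplot(dplyr::filter(object, .data$nacf > 0),
                        ggplot2::aes(.data$lag, .data$nacf)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (model time units)",
                  y = "K(tau) / K(0)") +
    ggplot2::theme_minimal()
  if (!is.null(theory) && !is.null(theory$acf)) {
    cmp <- theory$acf
    lg <- seq(0, max(object$lag), length.out = 200)
    th <- (cmp$amp_slow * exp(-cmp$rate_slow * lg) +
           cmp$amp_fast * exp(-cmp$rate_fast * lg)) / cmp$variance
    pl <- pl + ggplot2::geom_line(
      data = tibble::tibble(lag = lg, nacf = th),
      colour = "red3")
  }
  pl
}

#' Variance scan over a noise grid
#'
#' Sweeps the noise parameter over `a_grid` for an ensemble, returning the
#' per-a stationary estimates together with the annealed-theory curve
#' evaluated at the ensemble-averaged empirical moments (the protocol used
#' to reproduce the variance-transition figures).
#'
#' @inheritParams critical_a_empirical
#' @return A tibble `a`, `var_n`, `se_var_n`, `mean_rho`, `classification`,
#'   `var_theory`, `rho_theory`.
#' @export
scan_variance <- function(graphs, h, a_grid, t_max, n_real = 1L,
                          transient = NULL, sample_interval = 1, seed = 1L) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  stats <- dplyr::bind_rows(lapply(graphs, degree_stats))
  d <- degree_stats_nominal(mean(stats$mu_k), mean(stats$var_k),
                            igraph::vcount(graphs[[1]]))
  N <- d$N[1]
  scan <- scan_ensemble(graphs, h, a_grid, t_max, n_real, transient,
                        sample_interval, seed)
  scan$var_theory <- vapply(scan$a,
                            function(a) variance_st(N, a, h, d)$variance, 0)
  scan$rho_theory <- vapply(scan$a, function(a) rho_st(N, a, h, d), 0)
  attr(scan, "a_c_empirical") <- tryCatch(
    interp_critical_a(scan$a, scan$var_n, N)$a_c,
    error = function(e) NA_real_)
  scan
}
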