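## Annealed-approximation closed forms.
##
## All quantities are expressed through the degree moments mu_k, sigma_k^2
## via the second-moment ratio g = <k^2>/<k>^2 = 1 + sigma_k^2/mu_k^2, and
## through the rate combination lambda = h / (2(2a+h)).  The central object
## is the degree-weighted covariance sum
##   Vt/mu_k^2 = (N g/4) (2a+h)(4a+h) / (2a(4a+h) + h^2 g / N),
## from which follow the slow-mode weight S1, the stationary variance of n,
## the stationary interface density and the autocorrelation components.

# resolve a DegreeStats-like argument into (mu_k, var_k, g)
as_degstats <- function(d) {
  if (igraph::is_igraph(d)) d <- degree_stats(d)
  if (is.data.frame(d)) d <- as.list(d[1, ])
  if (is.null(d$mu_k)) stop("degree stats need at least `mu_k` (and `var_k`)")
  if (is.null(d$var_k)) d$var_k <- 0
  d$g2 <- 1 + d$var_k / d$mu_k^2
  d
}

theory_core <- function(N, a, h, g2) {
  lam <- h / (2 * (2 * a + h))
  denom <- 2 * a * (4 * a + h) + h^2 * g2 / N
  Vt <- (N * g2 / 4) * (2 * a + h) * (4 * a + h) / denom # = Vtilde / mu_k^2
  S1 <- (N / 4 + lam * Vt) / (1 - lam)
  varn <- N / 4 + (h / (2 * a + h)) * S1
  list(lam = lam, denom = denom, Vt = Vt, S1 = S1, var = varn)
}

#' Stationary variance of the aggregate state n (annealed approximation)
#'
#' Closed-form steady-state variance of the number of nodes in state 1
#' under the annealed approximation for uncorrelated networks.  It depends
#' on the network only through \eqn{g = \langle k^2\rangle/\langle
#' k\rangle^2 = 1 + \sigma_k^2/\mu_k^2}: heterogeneity increases the
#' variance at every finite noise level.  The formula interpolates between
#' the voter limit \eqn{N^2/4} as \eqn{a \to 0} and the independent-spin
#' limit \eqn{N/4} as \eqn{a \to \infty}.
#'
#' The accompanying side condition (positivity of the denominator
#' \eqn{2a(4a+h) + h^2 g/N}) is necessary and sufficient for a stationary
#' fluctuation balance; it always holds for `h > 0`.
#'
#' At exactly `a = 0` there is no stationary balance (the voter model is
#' absorbing) and the voter limit `N^2/4` is returned with
#' `validity_ok = FALSE`.
#'
#' @param N System size.
#' @param a,h Model rates.
#' @param d Degree statistics: an igraph graph, a [degree_stats()] /
#'   [degree_stats_nominal()] tibble, or a list with `mu_k`, `var_k`.
#' @return A list with `variance` and `validity_ok`.
#' @examples
#' d <- degree_stats_nominal(mu_k = 8, var_k = 16, N = 2500)
#' variance_st(2500, a = 0.01, h = 1, d = d)
#' @export
variance_st <- function(N, a, h, d) {
  stopifnot(N >= 2, a >= 0, h >= 0, a + h > 0)
  d <- as_degstats(d)
  if (a == 0) {
    return(list(variance = N^2 / 4, validity_ok = FALSE))
  }
  co <- theory_core(N, a, h, d$g2)
  list(variance = co$var, validity_ok = co$denom > 0)
}

#' Asymptotic branches of the stationary variance
#'
#' First-order-in-N approximations of [variance_st()] in the two scaling
#' regimes of the noise parameter.  For \eqn{a} of order \eqn{N^{-1/2}} or
#' smaller (`branch = "small_a"`),
#' \deqn{\sigma^2_{st}[n] \approx N/4 + h N^2 g / (4 (2 a N + h g)),}
#' and for \eqn{a} of order \eqn{N^{-1/2}} or larger (`branch = "large_a"`),
#' \deqn{\sigma^2_{st}[n] \approx N/4 + N h / (2(4a+h)) + h^2 N g /
#'   (8 a (4a+h)),}
#' with \eqn{g = 1 + \sigma_k^2/\mu_k^2}.  Both are explicit functions of
#' the normalized degree heterogeneity.
#'
#' @inheritParams variance_st
#' @param branch `"small_a"` or `"large_a"`.
#' @return Variance value(s); vectorized over `a`.
#' @export
variance_asymptotic <- function(N, a, h, d, branch = c("small_a", "large_a")) {
  branch <- match.arg(branch)
  d <- as_degstats(d)
  g2 <- d$g2
  if (branch == "small_a") {
    N / 4 + h * N^2 * g2 / (4 * (2 * a * N + h * g2))
  } else {
    N / 4 + N * h / (2 * (4 * a + h)) + h^2 * N * g2 / (8 * a * (4 * a + h))
  }
}

#' Crossover noise level between the asymptotic branches
#'
#' The noise value \eqn{a^*} that minimizes the distance between the
#' logarithms of the two asymptotic variance expressions, located by a
#' coarse logarithmic grid scan followed by bracketed refinement to
#' relative tolerance `tol`.  Below \eqn{a^*} the small-a branch describes
#' the variance; above it the large-a branch does.  \eqn{a^*} scales as
#' \eqn{h N^{-1/2}}, so it is invariant under joint rescaling of `(a, h)`
#' in units of `h`.
#'
#' @inheritParams variance_st
#' @param lower,upper Search range for `a` (defaults `1e-4 h` to `10 h`).
#' @param tol Relative tolerance of the minimizer.
#' @return A list with `a_star` and `log_distance` at the minimum.
#' @export
crossover_a <- function(N, h, d, lower = 1e-4 * h, upper = 10 * h,
                        tol = 1e-6) {
  stopifnot(h > 0)
  d <- as_degstats(d)
  f <- function(la) {
    a <- exp(la)
    abs(log(variance_asymptotic(N, a, h, d, "small_a")) -
        log(variance_asymptotic(N, a, h, d, "large_a")))
  }
  grid <- seq(log(lower), log(upper), length.out = 400)
  fv <- vapply(grid, f, 0)
  i0 <- which.min(fv)
  ## warn on non-unique minima (several separated near-minimal points)
  near <- which(fv <= fv[i0] + 1e-12)
  if (any(diff(near) > 1)) {
    warning("non-unique crossover minimum; returning the smallest")
    i0 <- near[1]
  }
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  o <- optimize(f, c(lo, hi), tol = tol * 1e-2)
  a_star <- exp(o$minimum)
  if (a_star < lower * 1.05 || a_star > upper * 0.95) {
    warning("crossover minimum lies at the search boundary; the branches ",
            "do not approach each other inside the range (this happens for ",
            "vanishing degree heterogeneity)")
  }
  list(a_star = a_star, log_distance = o$objective)
}

#' Critical point of the bimodal-unimodal finite-size transition
#'
#' The noise level at which the stationary distribution of n becomes
#' uniform, defined by the stationary variance reaching the
#' discrete-uniform value \eqn{N(N+2)/12}.  Solving the small-a asymptotic
#' branch for this level gives, to first order in N,
#' \deqn{a_c = h\, g\, (2N+1) / (2N(N-1)), \quad g = 1 +
#'   \sigma_k^2/\mu_k^2,}
#' i.e. \eqn{a_c \approx (h/N)(1 + \sigma_k^2/\mu_k^2)}: the critical point
#' grows linearly with the degree heterogeneity, while the mean-field
#' prediction \eqn{a_c = h/N} carries no network dependence beyond the
#' size.  The transition is a finite-size effect in both cases
#' (\eqn{a_c \to 0} as \eqn{N \to \infty}).
#'
#' @inheritParams variance_st
#' @return A list with `a_c` (annealed) and `a_c_meanfield` (`h/N`).
#' @export
critical_a <- function(N, h, d) {
  stopifnot(h > 0, N >= 2)
  d <- as_degstats(d)
  list(a_c = h * d$g2 * (2 * N + 1) / (2 * N * (N - 1)),
       a_c_meanfield = h / N)
}

#' Stationary mean interface density (annealed approximation)
#'
#' Steady-state fraction of active links, expressed through the stationary
#' variance of n:
#' \deqn{\langle\rho\rangle_{st} = \tfrac12 - \frac{g}{2N} -
#'   \frac{2(4a+h)}{hN^2}\Big(\sigma^2_{st}[n] - \frac N4 -
#'   \frac{Nh}{2(4a+h)}\Big).}
#' It tends to 0 for \eqn{a \to 0} (order) and to 1/2 for \eqn{a \to
#' \infty} (full disorder), and decreases with degree heterogeneity at
#' fixed noise.  For intermediate noise the annealed value is known to
#' overestimate the order (underestimate local effects) on real networks;
#' it should not be compared quantitatively against simulation there.
#'
#' @inheritParams variance_st
#' @return Mean interface density, clamped to `[0, 1/2]`.
#' @export
rho_st <- function(N, a, h, d) {
  stopifnot(N >= 2, a >= 0, h >= 0, a + h > 0)
  d <- as_degstats(d)
  if (a == 0) return(0)
  co <- theory_core(N, a, h, d$g2)
  T3 <- co$var - N / 4 - N * h / (2 * (4 * a + h))
  val <- 0.5 - d$g2 / (2 * N) - 2 * (4 * a + h) * T3 / (h * N^2)
  min(max(val, 0), 0.5)
}

#' Components of the stationary autocorrelation of n
#'
#' Under the annealed approximation the steady-state autocorrelation
#' \eqn{K_{st}[n](\tau)} is a sum of two exponentials,
#' \deqn{K(\tau) = S_1 e^{-2a\tau} + (\sigma^2_{st}[n] - S_1)
#'   e^{-(2a+h)\tau},}
#' where the slow mode (rate `2a`) is the relaxation of the degree-weighted
#' magnetization and the fast mode (rate `2a+h`) the relaxation of
#' individual nodes towards it.  The slow weight \eqn{S_1} is the
#' stationary covariance between n and the degree-weighted magnetization;
#' for homogeneous degrees \eqn{S_1 = \sigma^2_{st}[n]} and the fast
#' component vanishes (fully-connected/mean-field single exponential).
#' For heterogeneous networks \eqn{S_1 > \sigma^2_{st}[n]}: the fast weight
#' is negative, which is what lifts the long-lag tail of the normalized
#' autocorrelation *above* \eqn{e^{-2a\tau}} by a vertical offset growing
#' with heterogeneity.
#'
#' @inheritParams variance_st
#' @return A list with `amp_slow` (\eqn{S_1}), `amp_fast`, `rate_slow`
#'   (`2a`), `rate_fast` (`2a+h`), `s1`, `variance`.
#' @export
acf_components <- function(N, a, h, d) {
  stopifnot(N >= 2, a > 0, h >= 0)
  d <- as_degstats(d)
  co <- theory_core(N, a, h, d$g2)
  list(amp_slow = co$S1, amp_fast = co$var - co$S1,
       rate_slow = 2 * a, rate_fast = 2 * a + h,
       s1 = co$S1, variance = co$var)
}

#' Theoretical stationary autocorrelation of n
#'
#' Evaluates the two-exponential autocorrelation of [acf_components()] at
#' the given lags; `acf_theory(0, ...)` equals the stationary variance.
#'
#' @param tau Lag(s), `>= 0`, in model time units.
#' @inheritParams variance_st
#' @return Numeric vector of autocovariance values.
#' @export
acf_theory <- function(tau, N, a, h, d) {
  stopifnot(all(tau >= 0))
  cmp <- acf_components(N, a, h, d)
  cmp$amp_slow * exp(-cmp$rate_slow * tau) +
    cmp$amp_fast * exp(-cmp$rate_fast * tau)
}

#' All annealed-theory predictions for one parameter set
#'
#' Bundles the stationary variance (with validity flag), both asymptotic
#' branches at the working noise level, the crossover `a*`, the critical
#' point (annealed and mean-field), the stationary interface density and
#' the autocorrelation components into one object.
#'
#' @inheritParams variance_st
#' @return An object of class `nvm_theory` (a list).
#' @examples
#' th <- nvm_theory(2500, a = 0.01, h = 1,
#'                  d = degree_stats_nominal(8, 16, 2500))
#' tidy(th)
#' @export
nvm_theory <- function(N, a, h, d) {
  d <- as_degstats(d)
  vs <- variance_st(N, a, h, d)
  cr <- critical_a(N, h, d)
  cmp <- if (a > 0) acf_components(N, a, h, d) else NULL
  structure(list(
    N = N, a = a, h = h,
    mu_k = d$mu_k, var_k = d$var_k, heterogeneity = d$var_k / d$mu_k^2,
    var_n_st = vs$variance, validity_ok = vs$validity_ok,
    var_small_a = variance_asymptotic(N, a, h, d, "small_a"),
    var_large_a = variance_asymptotic(N, a, h, d, "large_a"),
    a_star = crossover_a(N, h, d)$a_star,
    a_c = cr$a_c, a_c_meanfield = cr$a_c_meanfield,
    rho_st = rho_st(N, a, h, d),
    var_uniform = N * (N + 2) / 12,
    acf = cmp
  ), class = "nvm_theory")
}

#' @export
print.nvm_theory <- function(x, ...) {
  cat(sprintf("<annealed noisy voter theory: N=%d a=%g h=%g het=%.4g>\n",
              x$N, x$a, x$h, x$heterogeneity))
  cat(sprintf("  var_st[n] = %.6g  (uniform level %.6g, %s phase)\n",
              x$var_n_st, x$var_uniform,
              if (x$var_n_st > x$var_uniform) "bimodal" else "unimodal"))
  cat(sprintf("  a_c = %.6g (mean-field %.6g), a* = %.6g\n",
              x$a_c, x$a_c_meanfield, x$a_star))
  cat(sprintf("  rho_st = %.6g\n", x$rho_st))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname nvm_theory
#' @param x An `nvm_theory` object.
#' @param ... Unused.
#' @export
tidy.nvm_theory <- function(x, ...) {
  tibble::tibble(
    quantity = c("var_n_st", "var_small_a", "var_large_a", "a_star", "a_c",
                 "a_c_meanfield", "rho_st", "var_uniform"),
    value = c(x$var_n_st, x$var_small_a, x$var_large_a, x$a_star, x$a_c,
              x$a_c_meanfield, x$rho_st, x$var_uniform)
  )
}

#' @rdname nvm_theory
#' @export
glance.nvm_theory <- function(x, ...) {
  tibble::tibble(N = x$N, a = x$a, h = x$h,
                 heterogeneity = x$heterogeneity,
                 validity_ok = x$validity_ok,
                 phase = if (x$var_n_st > x$var_uniform) "bimodal"
                         else "unimodal")
}

#' Plot the variance-vs-noise theory curves
#'
#' Stationary variance of n against the noise parameter: full annealed
#' curve, both asymptotic branches, the uniform-distribution level and the
#' critical point, on log-log axes (the layout of the standard
#' variance-transition figure).
#'
#' @param object An `nvm_theory` object.
#' @param a_range Range of `a` to display.
#' @param ... Unused.
#' @export
autoplot.nvm_theory <- function(object, a_range = c(1e-4, 10) * object$h,
                                ...) {
  d <- list(mu_k = object$mu_k, var_k = object$var_k)
  as <- exp(seq(log(a_range[1]), log(a_range[2]), length.out = 200))
  df <- tibble::tibble(
    a = rep(as, 3),
    curve = rep(c("annealed", "small-a branch", "large-a branch"),
                each = length(as)),
    variance = c(
      vapply(as, function(a) variance_st(object$N, a, object$h, d)$variance, 0),
      variance_asymptotic(object$N, as, object$h, d, "small_a"),
      variance_asymptotic(object$N, as, object$h, d, "large_a")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$variance,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$var_uniform, colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$a_c, colour = "grey50",
                        linetype = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "noise parameter a", y = "stationary variance of n") +
    ggplot2::theme_minimal()
}
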