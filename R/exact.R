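#' Exact stationary distribution of n on the complete graph
#'
#' On the complete graph the total number of up-nodes is itself a Markov
#' birth-death chain with birth rate \eqn{q_n = (N-n)(a + h n/(N-1))} and
#' death rate \eqn{p_n = n(a + h (N-n)/(N-1))}; detailed balance gives the
#' stationary distribution in product form (a symmetric beta-binomial).
#' At \eqn{a = h/(N-1)} the distribution is exactly uniform on `0..N`
#' (variance `N(N+2)/12`); for \eqn{a \gg h} it approaches binomial(N,1/2)
#' (variance `N/4`); for \eqn{a \ll h/N} it concentrates at the extremes
#' (variance approaching `N^2/4`).
#'
#' For `a = 0` the chain is absorbing at 0 and N; the absorbing structure
#' is returned with a flag instead of a stationary distribution.
#'
#' @param N Number of nodes (`>= 2`).
#' @param a,h Model rates.
#' @param spectrum Also compute the slowest relaxation rates of the chain
#'   generator (dense eigendecomposition).
#' @return An object of class `nvm_exact`: list with `dist` (length N+1),
#'   `var_n`, `mean_n`, `relaxation_rates` (slowest nonzero decay rates of
#'   the chain generator, when `N <= 200`), `absorbing` flag.
#' @export
birth_death_stationary <- function(N, a, h, spectrum = N <= 200) {
  stopifnot(N >= 2, a >= 0, h >= 0, a + h > 0)
  n <- 0:N
  q <- (N - n) * (a + h * n / (N - 1))       # n -> n+1
  p <- n * (a + h * (N - n) / (N - 1))       # n -> n-1
  if (a == 0) {
    dist <- rep(0, N + 1); dist[c(1, N + 1)] <- 0.5
    return(structure(list(dist = dist, mean_n = N / 2, var_n = N^2 / 4,
                          relaxation_rates = NULL, absorbing = TRUE, N = N),
                     class = "nvm_exact"))
  }
  logw <- cumsum(c(0, log(q[1:N]) - log(p[2:(N + 1)])))
  w <- exp(logw - max(logw))
  dist <- w / sum(w)
  mean_n <- sum(dist * n)
  var_n <- sum(dist * n^2) - mean_n^2
  rates <- NULL
  if (spectrum) {
    Q <- matrix(0, N + 1, N + 1)
    Q[cbind(1:N, 2:(N + 1))] <- q[1:N]
    Q[cbind(2:(N + 1), 1:N)] <- p[2:(N + 1)]
    diag(Q) <- -rowSums(Q)
    ev <- sort(abs(Re(eigen(Q, only.values = TRUE)$values)))
    rates <- ev[ev > 1e-9][1:min(3, sum(ev > 1e-9))]
  }
  structure(list(dist = dist, mean_n = mean_n, var_n = var_n,
                 relaxation_rates = rates, absorbing = FALSE, N = N),
            class = "nvm_exact")
}

#' @export
print.nvm_exact <- function(x, ...) {
  cat(sprintf("<exact solution: N=%d%s mean_n=%.3f var_n=%.5g>\n", x$N,
              if (x$absorbing) " (absorbing)" else "", x$mean_n, x$var_n))
  invisible(x)
}

#' Exact master-equation solution for a small system
#'
#' Enumerates all `2^N` configurations of a graph (node 1 of the R graph is
#' the least significant bit), builds the full master-equation generator
#' from the single-node rates, and solves for the stationary distribution,
#' the variance of n, the pairwise covariance matrix \eqn{\sigma_{ij}}
#' (whose total sum equals the variance of n), and the leading relaxation
#' rates of the generator.  This is the brute-force ground truth against
#' which the annealed closed forms and the simulator are validated.
#'
#' For `a = 0` the two homogeneous configurations are absorbing; they are
#' reported with a flag instead of a unique stationary state.
#'
#' @param g igraph graph with at most `max_nodes` nodes.
#' @param a,h Model rates.
#' @param spectrum Also compute the leading relaxation rates (dense eigen
#'   decomposition; default for `N <= 10`).
#' @param max_nodes Safety bound on the enumeration.
#' @return An object of class `nvm_exact_ctmc`: list with `stationary`
#'   (length `2^N`), `p_n` (marginal of n), `mean_s` (per-node means),
#'   `var_n`, `cov` (`N x N`), `relaxation_rates`, `absorbing`.
#' @export
ctmc_solve <- function(g, a, h, spectrum = igraph::vcount(g) <= 10,
                       max_nodes = 12L) {
  N <- igraph::vcount(g)
  if (N > max_nodes) stop("ctmc_solve is limited to ", max_nodes, " nodes")
  stopifnot(a >= 0, h >= 0, a + h > 0)
  ks <- igraph::degree(g)
  if (min(ks) < 1) stop("graph has isolated nodes; model undefined")
  nbr <- lapply(igraph::as_adj_list(g), as.integer)

  ns <- 2^N
  states <- 0:(ns - 1)
  smat <- matrix(0L, ns, N)
  for (i in 1:N) smat[, i] <- bitwAnd(states %/% 2^(i - 1), 1L)

  ## sparse generator: ns * N single-flip transitions
  from <- integer(ns * N); to <- integer(ns * N); rate <- numeric(ns * N)
  idx <- 1L
  for (i in 1:N) {
    dis <- integer(ns)
    for (j in nbr[[i]]) dis <- dis + (smat[, j] != smat[, i])
    r <- a + h * dis / ks[i]
    tgt <- bitwXor(states, 2^(i - 1))
    rng <- idx:(idx + ns - 1L)
    from[rng] <- states + 1L; to[rng] <- tgt + 1L; rate[rng] <- r
    idx <- idx + ns
  }
  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate, dims = c(ns, ns))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)

  nvec <- rowSums(smat)
  if (a == 0) {
    pi_st <- NULL
    absorbing <- which(nvec %in% c(0, N))
    res <- list(stationary = NULL, absorbing_states = absorbing - 1L,
                absorbing = TRUE)
  } else {
    ## null vector of Q^T with a normalization row appended
    M <- Matrix::t(Q)
    M[ns, ] <- 1
    b <- c(rep(0, ns - 1), 1)
    pi_st <- as.numeric(Matrix::solve(M, b))
    pi_st[pi_st < 0 & pi_st > -1e-12] <- 0
    pi_st <- pi_st / sum(pi_st)
    res <- list(stationary = pi_st, absorbing = FALSE)
  }

  if (!is.null(pi_st)) {
    mean_s <- as.numeric(crossprod(smat, pi_st))
    es2 <- crossprod(smat, smat * pi_st)       # <s_i s_j>
    covm <- as.matrix(es2) - outer(mean_s, mean_s)
    p_n <- vapply(0:N, function(v) sum(pi_st[nvec == v]), 0)
    mean_n <- sum(p_n * (0:N))
    var_n <- sum(p_n * (0:N)^2) - mean_n^2
    res <- c(res, list(mean_s = mean_s, cov = covm, p_n = p_n,
                       mean_n = mean_n, var_n = var_n))
  }
  if (spectrum) {
    ev <- eigen(as.matrix(Q), only.values = TRUE)$values
    rr <- sort(abs(Re(ev)))
    res$relaxation_rates <- rr[rr > 1e-9][1:min(5, sum(rr > 1e-9))]
    res$n_zero_modes <- sum(rr <= 1e-9)
  }
  res$N <- N
  structure(res, class = "nvm_exact_ctmc")
}

#' @export
print.nvm_exact_ctmc <- function(x, ...) {
  if (x$absorbing) {
    cat(sprintf("<exact CTMC: N=%d, absorbing (a=0), %d absorbing states>\n",
                x$N, length(x$absorbing_states)))
  } else {
    cat(sprintf("<exact CTMC: N=%d, var_n=%.5g, mean_s in [%.4f, %.4f]>\n",
                x$N, x$var_n, min(x$mean_s), max(x$mean_s)))
  }
  invisible(x)
}
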