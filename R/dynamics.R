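#' Single-node transition rate of the noisy voter model
#'
#' The rate at which node `i` flips its binary state: a noise term `a`
#' independent of the neighbourhood plus an interaction (herding) term
#' `h * d_i / k_i`, where `d_i` is the number of neighbours currently in the
#' opposite state and `k_i` the degree.  With `a = 0` and time measured in
#' units of `1/h` these are the rates of the original voter model; with
#' `h = 0` every node is an independent random telegraph with rate `a`.
#'
#' @param state 0/1 vector of node states.
#' @param i Node id (1-based).
#' @param g igraph graph.
#' @param a,h Noise and interaction rate parameters (per unit time).
#' @return Nonnegative flip rate for node `i`.
#' @export
flip_rate <- function(state, i, g, a, h) {
  stopifnot(a >= 0, h >= 0, a + h > 0)
  ki <- igraph::degree(g, i)
  if (ki == 0) stop("flip rate undefined for isolated node (k_i = 0)")
  nb <- as.integer(igraph::neighbors(g, i))
  a + h * sum(state[nb] != state[i]) / ki
}

#' Simulate the noisy voter model on a graph
#'
#' Statistically exact, event-driven (Gillespie) simulation of the
#' continuous-time Markov process whose per-node rates are [flip_rate()].
#' The total state is sampled on a fixed grid of `sample_interval` time
#' units by carrying the last value forward, which is unbiased for time
#' averages of a piecewise-constant process.
#'
#' With `a = 0` the homogeneous configurations are absorbing; a trajectory
#' that reaches (or starts in) one stays there, which is valid output, not
#' an error.
#'
#' @param g igraph graph (minimum degree 1).
#' @param a,h Model rates, both `>= 0`, not both 0.
#' @param t_max Simulated time horizon (model time units; one unit is about
#'   `N` update events).
#' @param sample_interval Observable sampling grid step.
#' @param initial `"random"` (i.i.d. Bernoulli(1/2)), `"all_zero"`,
#'   `"all_one"`, or a 0/1 vector of length N.
#' @param seed Integer seed (reproducible trajectories).
#' @param record_rho Also record the interface density.
#' @return A tibble of class `nvm_trajectory` with columns `t`, `n` and
#'   (optionally) `rho`, and attributes `params` (list with `a`, `h`, `N`,
#'   `seed`, `kind`) and `s_final`.
#' @examples
#' g <- make_network("er", N = 50, mean_degree = 8, seed = 1)
#' tr <- simulate_nvm(g, a = 0.1, h = 1, t_max = 50, seed = 1)
#' head(tr)
#' @export
simulate_nvm <- function(g, a, h, t_max, sample_interval = 1,
                         initial = "random", seed = NULL, record_rho = TRUE) {
  stopifnot(a >= 0, h >= 0, a + h > 0, t_max > 0, sample_interval > 0)
  N <- igraph::vcount(g)
  if (min(igraph::degree(g)) < 1) stop("graph has isolated nodes; model undefined")
  if (!is.null(seed)) set.seed(seed)

  s0 <- if (is.numeric(initial)) {
    stopifnot(length(initial) == N, all(initial %in% c(0, 1)))
    as.integer(initial)
  } else {
    switch(match.arg(initial, c("random", "all_zero", "all_one")),
      random = rbinom(N, 1L, 0.5),
      all_zero = integer(N),
      all_one = rep.int(1L, N)
    )
  }

  al <- igraph::as_adj_list(g)
  adj <- as.integer(unlist(lapply(al, as.integer))) - 1L
  ptr <- c(0L, cumsum(vapply(al, length, 1L)))

  res <- nvm_gillespie_cpp(adj, ptr, s0, a, h, t_max, sample_interval,
                           record_rho)
  out <- tibble::tibble(t = res$t, n = res$n)
  if (record_rho) out$rho <- res$rho
  attr(out, "params") <- list(
    a = a, h = h, N = N, seed = seed,
    kind = if (!is.null(igraph::graph_attr(g, "kind")))
      igraph::graph_attr(g, "kind") else "user",
    sample_interval = sample_interval, t_max = t_max,
    events = res$events
  )
  attr(out, "s_final") <- res$s_final
  class(out) <- c("nvm_trajectory", class(out))
  out
}

#' Interface density of a configuration
#'
#' Fraction of links whose endpoints are in different states, computed on
#' the real adjacency.  0 for a homogeneous configuration; 1/2 on average
#' for i.i.d. random states.
#'
#' @param state 0/1 vector of node states.
#' @param g igraph graph.
#' @return Value in `[0, 1]`.
#' @export
interface_density <- function(state, g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  mean(state[el[, 1]] != state[el[, 2]])
}

#' Simulate an ensemble of realizations
#'
#' Runs [simulate_nvm()] over a list of graphs with `n_real` realizations
#' per graph, using seeds derived from `seed` so the ensemble is
#' reproducible, and returns the trajectories in one long tibble with
#' `graph_id` / `real_id` columns.
#'
#' @param graphs List of igraph graphs (or a single graph).
#' @param n_real Realizations per graph.
#' @inheritParams simulate_nvm
#' @return A tibble with columns `graph_id`, `real_id`, `t`, `n`, `rho`;
#'   attribute `params` as in [simulate_nvm()].
#' @export
simulate_ensemble <- function(graphs, a, h, t_max, sample_interval = 1,
                              n_real = 1L, initial = "random", seed = 1L,
                              record_rho = TRUE) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  combos <- expand.grid(real_id = seq_len(n_real),
                        graph_id = seq_along(graphs))
  res <- purrr::pmap(combos, function(real_id, graph_id) {
    tr <- simulate_nvm(graphs[[graph_id]], a, h, t_max, sample_interval,
                       initial,
                       seed = seed + 1000L * (graph_id - 1L) + real_id - 1L,
                       record_rho = record_rho)
    tr$graph_id <- graph_id
    tr$real_id <- real_id
    tr
  })
  out <- dplyr::bind_rows(res)
  attr(out, "params") <- utils::modifyList(attr(res[[1]], "params"),
                                           list(seed = seed))
  class(out) <- c("nvm_trajectory", class(out))
  out
}

#' Write / read a trajectory as CSV
#'
#' CSV with header `t,n,rho` (plus `graph_id,real_id` for ensembles) and a
#' JSON metadata sidecar `<path>.json` holding the model parameters.
#'
#' @param traj An `nvm_trajectory` tibble.
#' @param path Output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- attr(traj, "params")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  mpath <- paste0(path, ".json")
  if (file.exists(mpath)) {
    attr(df, "params") <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  }
  class(df) <- c("nvm_trajectory", class(df))
  df
}

#' @export
print.nvm_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  if (!is.null(p)) {
    cat(sprintf("<noisy voter trajectory: N=%d a=%g h=%g kind=%s>\n",
                p$N, p$a, p$h, p$kind))
  }
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Fraction of nodes in state 1 (and interface density, if recorded)
#' against model time.
#'
#' @param object An `nvm_trajectory`.
#' @param ... Unused.
#' @export
autoplot.nvm_trajectory <- function(object, ...) {
  p <- attr(object, "params")
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object), n = .data$n / p$N),
    dplyr::any_of(c("n", "rho")),
    names_to = "observable", values_to = "value"
  )
  df$observable <- factor(df$observable, c("n", "rho"),
                          c("n/N", "interface density"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~observable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (model units)", y = NULL,
                  title = sprintf("noisy voter model, N=%d, a=%g, h=%g",
                                  p$N, p$a, p$h)) +
    ggplot2::theme_minimal()
}

#' Simulate the annealed dynamics of a degree-class network
#'
#' Exact event-driven simulation of the noisy voter model on the *annealed*
#' (weighted fully-connected) counterpart of a network whose nodes fall
#' into a small number of degree classes (e.g. dichotomous networks).
#' Under the annealed weights the flip rates depend on the configuration
#' only through the degree-weighted magnetization, so the class occupation
#' counts form an exact low-dimensional Markov chain and the simulation
#' costs O(1) per event.  This is the reference dynamics for which the
#' closed-form variance and autocorrelation are exact up to O(1/N) terms,
#' used to validate them independently of any real-graph effects.
#'
#' @param sizes Integer vector of class sizes.
#' @param degrees Degrees of the classes (same length).
#' @param a,h Model rates.
#' @inheritParams simulate_nvm
#' @return An `nvm_trajectory` tibble with columns `t`, `n`.
#' @examples
#' tr <- simulate_nvm_annealed(c(50, 50), c(4, 12), a = 0.1, h = 1,
#'                             t_max = 100, seed = 1)
#' @export
simulate_nvm_annealed <- function(sizes, degrees, a, h, t_max,
                                  sample_interval = 1, initial = "random",
                                  seed = NULL) {
  stopifnot(length(sizes) == length(degrees), all(sizes >= 1),
            all(degrees >= 1), a >= 0, h >= 0, a + h > 0, t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- sum(sizes)
  n0 <- if (is.numeric(initial) && length(initial) == length(sizes)) {
    as.integer(initial)
  } else {
    switch(match.arg(initial, c("random", "all_zero", "all_one")),
      random = rbinom(length(sizes), sizes, 0.5),
      all_zero = integer(length(sizes)),
      all_one = as.integer(sizes)
    )
  }
  res <- nvm_annealed_cpp(as.integer(sizes), as.numeric(degrees),
                          n0, a, h, t_max, sample_interval)
  out <- tibble::tibble(t = res$t, n = res$n)
  mu <- sum(sizes * degrees) / N
  v <- sum(sizes * (degrees - mu)^2) / N
  attr(out, "params") <- list(a = a, h = h, N = N, seed = seed,
                              kind = "annealed", mu_k = mu, var_k = v,
                              sample_interval = sample_interval,
                              t_max = t_max, events = res$events)
  class(out) <- c("nvm_trajectory", class(out))
  out
}
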