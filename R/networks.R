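#' Generate a network from one of the standard ensembles
#'
#' Builds the undirected simple graphs on which the noisy voter model is
#' studied: Erdős–Rényi random graphs, Barabási–Albert scale-free graphs,
#' dichotomous graphs (half the nodes with degree `k1`, half with `k2`,
#' wired as an uncorrelated configuration-ensemble graph), complete graphs,
#' random-regular graphs and periodic 2D lattices.  The ensembles are
#' conventionally matched on mean degree so that they differ only in degree
#' heterogeneity \eqn{\sigma_k^2/\mu_k^2}.
#'
#' Every generated graph is simple (no self-loops or multi-edges) and has
#' minimum degree at least 1; generators that can produce isolated nodes
#' (`er`) are retried until this holds, because the interaction term of the
#' model divides by the degree.
#'
#' @param kind One of `"er"`, `"ba"`, `"dichotomous"`, `"complete"`,
#'   `"random_regular"`, `"lattice2d"`.
#' @param N Number of nodes (for `lattice2d`, must be a perfect square or
#'   `side` must be given).
#' @param mean_degree Target mean degree (used by `er`; for `ba` the
#'   attachment count defaults to `round(mean_degree/2)`).
#' @param m Attachment count for `ba` (overrides `mean_degree`).
#' @param k1,k2 The two degrees of a dichotomous graph (`ceiling(N/2)` nodes
#'   of degree `k1`, `floor(N/2)` of degree `k2`).
#' @param k Degree of a random-regular graph.
#' @param side Side length of the periodic square lattice.
#' @param seed Integer seed; the generator is reproducible given `(kind, N,
#'   params, seed)`.
#' @param max_tries Bounded number of regeneration attempts for constraints
#'   (minimum degree, simple-graph rejection).
#'
#' @return An [igraph][igraph::igraph-package] graph with graph attribute
#'   `kind` recording provenance.
#' @examples
#' g <- make_network("dichotomous", N = 100, k1 = 4, k2 = 12, seed = 1)
#' degree_stats(g)
#' @export
make_network <- function(kind = c("er", "ba", "dichotomous", "complete",
                                  "random_regular", "lattice2d"),
                         N, mean_degree = NULL, m = NULL, k1 = NULL, k2 = NULL,
                         k = NULL, side = NULL, seed = NULL, max_tries = 100L) {
  kind <- match.arg(kind)
  if (N < 2) stop("N must be at least 2")
  if (!is.null(seed)) set.seed(seed)

  g <- switch(kind,
    complete = igraph::make_full_graph(N),
    er = {
      if (is.null(mean_degree)) stop("er networks need `mean_degree`")
      if (mean_degree >= N) stop("infeasible: mean_degree must be < N")
      p <- mean_degree / (N - 1)
      gg <- NULL
      for (try in seq_len(max_tries)) {
        cand <- igraph::sample_gnp(N, p)
        if (min(igraph::degree(cand)) >= 1) { gg <- cand; break }
      }
      if (is.null(gg)) {
        stop("er generation failed: could not avoid isolated nodes in ",
             max_tries, " tries (mean_degree too small for N?)")
      }
      gg
    },
    ba = {
      if (is.null(m)) {
        if (is.null(mean_degree)) stop("ba networks need `m` or `mean_degree`")
        m <- max(1L, as.integer(round(mean_degree / 2)))
      }
      if (m >= N) stop("infeasible: attachment count m must be < N")
      igraph::sample_pa(N, m = m, directed = FALSE,
                        start.graph = igraph::make_full_graph(m + 1))
    },
    dichotomous = {
      if (is.null(k1) || is.null(k2)) stop("dichotomous networks need `k1` and `k2`")
      if (max(k1, k2) >= N) stop("infeasible degree: k >= N")
      if (min(k1, k2) < 1) stop("infeasible degree: k < 1")
      degs <- c(rep.int(k1, ceiling(N / 2)), rep.int(k2, floor(N / 2)))
      if (sum(degs) %% 2 != 0) {
        stop("infeasible degree sequence: odd total stub count (",
             sum(degs), "); adjust k1/k2 or N")
      }
      sample_simple_degseq(degs, max_tries)
    },
    random_regular = {
      if (is.null(k)) stop("random_regular networks need `k`")
      if (k >= N) stop("infeasible degree: k >= N")
      if ((N * k) %% 2 != 0) stop("infeasible degree sequence: N*k is odd")
      igraph::sample_k_regular(N, k)
    },
    lattice2d = {
      if (is.null(side)) {
        side <- as.integer(round(sqrt(N)))
        if (side^2 != N) stop("lattice2d needs a square N or an explicit `side`")
      }
      igraph::make_lattice(c(side, side), periodic = TRUE)
    }
  )
  g <- igraph::simplify(g)
  if (min(igraph::degree(g)) < 1) stop("generation failed: isolated node in ", kind)
  igraph::graph_attr(g, "kind") <- kind
  g
}

# Uniform simple graph with the given degree sequence.  Viger-Latapy is used
# because plain stub matching has vanishing acceptance probability for the
# dense tails used here; fall back to the simple heuristic method.
sample_simple_degseq <- function(degs, max_tries) {
  g <- tryCatch(igraph::sample_degseq(degs, method = "vl"),
                error = function(e) NULL)
  if (is.null(g)) {
    for (try in seq_len(max_tries)) {
      g <- tryCatch(igraph::sample_degseq(degs, method = "fast.heur.simple"),
                    error = function(e) NULL)
      if (!is.null(g) && igraph::is_simple(g)) break
      g <- NULL
    }
  }
  if (is.null(g)) {
    stop("configuration-model generation failed after bounded retries ",
         "(degree sequence may be infeasible as a simple graph)")
  }
  g
}

#' Moments of the realized degree sequence
#'
#' Computes the degree-distribution averages the annealed theory is
#' expressed in: the mean degree \eqn{\mu_k}, the degree variance
#' \eqn{\sigma_k^2}, the normalized heterogeneity \eqn{\sigma_k^2/\mu_k^2},
#' the second moment \eqn{\langle k^2\rangle}, and whether the maximum
#' degree respects the structural cutoff \eqn{\sqrt{\mu_k N}} below which
#' an uncorrelated simple graph with this degree sequence exists.
#'
#' Moments are those of the *realized* sequence (population denominators),
#' not of the nominal ensemble.
#'
#' @param g An igraph graph, or a numeric degree sequence.
#' @return A one-row tibble with columns `N`, `mu_k`, `var_k`,
#'   `heterogeneity`, `second_moment`, `k_max`, `cutoff_ok`.
#' @examples
#' degree_stats(make_network("complete", N = 5))
#' @export
degree_stats <- function(g) {
  ks <- if (igraph::is_igraph(g)) igraph::degree(g) else as.numeric(g)
  N <- length(ks)
  mu <- mean(ks)
  v <- mean((ks - mu)^2)
  tibble::tibble(
    N = N,
    mu_k = mu,
    var_k = v,
    heterogeneity = v / mu^2,
    second_moment = v + mu^2,
    k_max = max(ks),
    cutoff_ok = max(ks) <= sqrt(mu * N)
  )
}

#' Nominal degree moments
#'
#' Builds the same structure as [degree_stats()] from nominal ensemble
#' moments instead of a realized graph, for design studies.
#'
#' @param mu_k Mean degree.
#' @param var_k Degree variance.
#' @param N System size.
#' @export
degree_stats_nominal <- function(mu_k, var_k, N) {
  tibble::tibble(
    N = N, mu_k = mu_k, var_k = var_k,
    heterogeneity = var_k / mu_k^2,
    second_moment = var_k + mu_k^2,
    k_max = NA_real_, cutoff_ok = NA
  )
}

#' Annealed (weighted fully-connected) view of a graph
#'
#' Replaces the adjacency matrix by the connection probabilities of the
#' uncorrelated configuration ensemble, \eqn{w_{ij} = k_i k_j / (N \mu_k)}
#' with zero diagonal.  Row sums reproduce the degree sequence up to the
#' excluded self-term \eqn{k_i^2/(N\mu_k)}, so the approximation preserves
#' the degree sequence (and hence the number of links) to O(1/N).
#'
#' A warning is emitted when the structural cutoff is violated, in which
#' case some weights exceed 1 and the annealed view is unreliable.
#'
#' @param g An igraph graph.
#' @return A symmetric `N x N` numeric matrix with zero diagonal.
#' @examples
#' w <- annealed_weights(make_network("complete", N = 4))
#' rowSums(w)
#' @export
annealed_weights <- function(g) {
  ks <- igraph::degree(g)
  N <- length(ks)
  mu <- mean(ks)
  if (max(ks) > sqrt(mu * N)) {
    warning("structural cutoff violated (k_max > sqrt(mu_k * N)); ",
            "annealed weights may exceed 1")
  }
  w <- outer(ks, ks) / (N * mu)
  diag(w) <- 0
  w
}

#' Diagnostic check for degree correlations and structural cutoff
#'
#' The annealed approximation assumes an uncorrelated network.  This check
#' reports the degree assortativity and the structural-cutoff status with a
#' pass/warn verdict; it never blocks.
#'
#' @param g An igraph graph.
#' @param assort_warn Absolute assortativity above which to warn.
#' @return A one-row tibble with `assortativity`, `cutoff_ok`, `verdict`.
#' @export
check_uncorrelated <- function(g, assort_warn = 0.1) {
  r <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(r)) r <- 0 # regular graphs: undefined, 0 by convention
  st <- degree_stats(g)
  verdict <- if (abs(r) > assort_warn || !st$cutoff_ok) "warn" else "pass"
  tibble::tibble(assortativity = r, cutoff_ok = st$cutoff_ok, verdict = verdict)
}

#' Read / write an edge list
#'
#' Whitespace-delimited `"u v"` pairs, 0-based node ids, one undirected edge
#' per line, `#` comments allowed.
#'
#' @param path File path.
#' @return `read_edgelist()` returns an igraph graph; `write_edgelist()`
#'   returns `path` invisibly.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no edges in ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed edge line(s): ", paste(which(bad), collapse = ", "))
  el <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(el) || any(el < 0)) stop("node ids must be nonnegative integers")
  g <- igraph::graph_from_edgelist(el + 1L, directed = FALSE)
  igraph::simplify(g)
}

#' @rdname read_edgelist
#' @param g An igraph graph to write (0-based ids in the file).
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  writeLines(c("# noisyvoter edge list (0-based, undirected)",
               paste(el[, 1], el[, 2])), path)
  invisible(path)
}

#' Generate an ensemble of networks
#'
#' Convenience wrapper producing `n_graphs` independent graphs with seeds
#' derived from `seed`, plus the ensemble-averaged degree moments used when
#' evaluating the annealed theory against simulations.
#'
#' @inheritParams make_network
#' @param n_graphs Number of graphs.
#' @param ... Passed to [make_network()].
#' @return A list with elements `graphs` (list) and `stats` (tibble of
#'   per-graph degree moments) and `mean_stats` (ensemble means).
#' @export
make_ensemble <- function(kind, N, n_graphs = 20L, seed = 1L, ...) {
  graphs <- lapply(seq_len(n_graphs), function(i) {
    make_network(kind, N = N, seed = seed + i - 1L, ...)
  })
  stats <- dplyr::bind_rows(lapply(graphs, degree_stats))
  ms <- dplyr::summarise(stats, dplyr::across(c("mu_k", "var_k",
                                                "heterogeneity", "second_moment"), mean))
  list(graphs = graphs, stats = stats,
       mean_stats = degree_stats_nominal(ms$mu_k, ms$var_k, N))
}
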