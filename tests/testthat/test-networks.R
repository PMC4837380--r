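test_that("complete and dichotomous generators have the advertised degrees", {
  g <- make_network("complete", N = 5)
  expect_true(all(igraph::degree(g) == 4))
  expect_equal(igraph::ecount(g), 10)

  gd <- make_network("dichotomous", N = 1000, k1 = 4, k2 = 12, seed = 1)
  ks <- igraph::degree(gd)
  expect_equal(sum(ks == 4), 500)
  expect_equal(sum(ks == 12), 500)
  st <- degree_stats(gd)
  expect_equal(st$mu_k, 8)
  expect_equal(st$var_k, 16)
  expect_equal(st$heterogeneity, 0.25)

  gr <- make_network("random_regular", N = 100, k = 8, seed = 1)
  expect_true(all(igraph::degree(gr) == 8))
  expect_equal(degree_stats(gr)$heterogeneity, 0)

  gl <- make_network("lattice2d", N = 49)
  expect_true(all(igraph::degree(gl) == 4))
})

test_that("infeasible degree sequences are rejected with an explanation", {
  expect_error(make_network("dichotomous", N = 5, k1 = 1, k2 = 2),
               "odd total stub")
  expect_error(make_network("dichotomous", N = 10, k1 = 4, k2 = 12),
               "k >= N")
  expect_error(make_network("random_regular", N = 9, k = 3), "odd")
  expect_error(make_network("er", N = 1), "at least 2")
  expect_error(make_network("er", N = 100), "mean_degree")
})

test_that("generators leave no isolated nodes and are reproducible", {
  for (kind in c("er", "ba", "dichotomous")) {
    args <- switch(kind,
      er = list(mean_degree = 4), ba = list(m = 2),
      dichotomous = list(k1 = 2, k2 = 6))
    g1 <- do.call(make_network, c(list(kind, N = 200, seed = 7), args))
    g2 <- do.call(make_network, c(list(kind, N = 200, seed = 7), args))
    expect_gte(min(igraph::degree(g1)), 1)
    expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
    expect_identical(igraph::graph_attr(g1, "kind"), kind)
  }
})

test_that("degree_stats flags the structural cutoff", {
  star <- igraph::make_star(10, mode = "undirected")
  st <- degree_stats(star)
  expect_false(st$cutoff_ok)  # hub degree 9 > sqrt(1.8 * 10)
  expect_true(degree_stats(make_network("complete", N = 5))$cutoff_ok)
  expect_equal(st$second_moment, st$var_k + st$mu_k^2)
})

test_that("ensembles at matched mean degree are ordered by heterogeneity", {
  N <- 600
  er <- make_ensemble("er", N, n_graphs = 8, mean_degree = 8, seed = 1)
  ba <- make_ensemble("ba", N, n_graphs = 8, m = 4, seed = 1)
  di <- make_ensemble("dichotomous", N, n_graphs = 8, k1 = 4, k2 = 12,
                      seed = 1)
  mu <- c(er$mean_stats$mu_k, ba$mean_stats$mu_k, di$mean_stats$mu_k)
  expect_true(all(abs(mu - 8) / 8 < 0.02))
  expect_gt(ba$mean_stats$heterogeneity, er$mean_stats$heterogeneity)
  expect_gt(di$mean_stats$heterogeneity, er$mean_stats$heterogeneity)
})

test_that("annealed weights preserve the degree sequence", {
  gr <- make_network("random_regular", N = 50, k = 6, seed = 2)
  w <- annealed_weights(gr)
  expect_true(all(abs(w[upper.tri(w)] - 6 / 50) < 1e-12))
  expect_true(all(diag(w) == 0))

  gd <- make_network("dichotomous", N = 100, k1 = 4, k2 = 12, seed = 3)
  w <- annealed_weights(gd)
  ks <- igraph::degree(gd)
  # row sums reproduce k_i up to the excluded self-term k_i^2/(N mu_k)
  expect_true(all(abs(rowSums(w) - ks) <= ks^2 / (100 * 8) + 1e-12))
  vals <- sort(unique(round(w[upper.tri(w)], 12)))
  expect_equal(vals, sort(c(16, 48, 144) / (100 * 8)))
})

test_that("annealed weights warn when the structural cutoff is violated", {
  star <- igraph::make_star(10, mode = "undirected")
  expect_warning(annealed_weights(star), "cutoff")
})

test_that("uncorrelatedness diagnostics behave on regular, ER and star graphs", {
  gr <- make_network("random_regular", N = 60, k = 4, seed = 1)
  rep1 <- check_uncorrelated(gr)
  expect_equal(rep1$assortativity, 0)
  expect_identical(rep1$verdict, "pass")

  rs <- vapply(1:10, function(s) {
    check_uncorrelated(make_network("er", N = 800, mean_degree = 8,
                                    seed = s))$assortativity
  }, 0)
  expect_lt(max(abs(rs)), 0.1)

  star <- igraph::make_star(10, mode = "undirected")
  expect_identical(check_uncorrelated(star)$verdict, "warn")
})

test_that("edge lists round-trip through the text format", {
  g <- make_network("er", N = 40, mean_degree = 5, seed = 4)
  path <- tempfile(fileext = ".txt")
  write_edgelist(g, path)
  g2 <- read_edgelist(path)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_identical(igraph::as_edgelist(igraph::simplify(g)),
                   igraph::as_edgelist(g2))
  expect_error(suppressWarnings(read_edgelist(tempfile())),
               "cannot open|no edges")
})
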