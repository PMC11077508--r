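test_that("degree-preserving rewiring keeps the exact degree sequence", {
  set.seed(11)
  for (i in 1:20) {
    m <- rand_multiplex(sample(8:15, 1), p = stats::runif(1, 0.2, 0.6))
    g <- m$layers[[1]]
    r <- rewire_degree_preserving(g, swaps_per_edge = 5, seed = i)
    expect_equal(igraph::degree(r), igraph::degree(g))
    expect_equal(igraph::gsize(r), igraph::gsize(g))
    expect_false(igraph::any_loop(r))
    expect_false(igraph::any_multiple(r))
  }
})

test_that("rewiring is deterministic under a seed and randomizes without one", {
  g <- ring_lattice(30, 0.2)
  r1 <- rewire_degree_preserving(g, seed = 99)
  r2 <- rewire_degree_preserving(g, seed = 99)
  expect_identical(igraph::as_edgelist(r1), igraph::as_edgelist(r2))
  r3 <- rewire_degree_preserving(g, seed = 100)
  expect_false(identical(igraph::as_edgelist(r1), igraph::as_edgelist(r3)))
})

test_that("4-cycle swaps land on the only degree-preserving alternative", {
  # the simple graphs with degree sequence (2,2,2,2) on 4 nodes are the
  # 4-cycles: {12,23,34,41}, {12,24,43,31}, {13,32,24,41} (enumeration)
  cyc <- tibble::tibble(from = c("1", "2", "3", "4"), to = c("2", "3", "4", "1"))
  is_two_regular <- function(g) all(igraph::degree(g) == 2)
  for (s in 1:20) {
    r <- rewire_degree_preserving(cyc, swaps_per_edge = 3, seed = s)
    expect_true(is_two_regular(r))
    expect_equal(igraph::gsize(r), 4)
    expect_false(igraph::any_multiple(r))
  }
})

test_that("degenerate graphs return partially rewired output with a warning", {
  star <- tibble::tibble(from = c("1", "1", "1"), to = c("2", "3", "4"))
  expect_warning(r <- rewire_degree_preserving(star, swaps_per_edge = 2),
                 "attempt cap")
  expect_equal(unname(sort(igraph::degree(r))), c(1, 1, 1, 3))
})

test_that("rewiring agrees with igraph's degree-preserving rewire on degree sequences", {
  set.seed(12)
  g <- igraph::sample_gnm(25, 60)
  igraph::V(g)$name <- as.character(1:25)
  ours <- rewire_degree_preserving(g, swaps_per_edge = 10, seed = 5)
  theirs <- igraph::rewire(g, igraph::keeping_degseq(niter = 600))
  expect_equal(igraph::degree(ours)[order(names(igraph::degree(ours)))],
               igraph::degree(theirs)[order(names(igraph::degree(theirs)))])
})

test_that("geometry-preserving rewiring preserves degrees and the binned length histogram", {
  set.seed(13)
  n <- 40
  coords <- tibble::tibble(node = as.character(1:n),
                           x = stats::runif(n), y = stats::runif(n), z = 0)
  g <- igraph::sample_gnm(n, 150)
  igraph::V(g)$name <- as.character(1:n)

  # same binning rule as the generator: equal-width bins spanning the range
  # of all pairwise node distances
  edge_bins <- function(gg, n_bins) {
    nd <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
    el <- igraph::as_edgelist(gg, names = FALSE)
    d <- nd[el]
    brk <- seq(min(nd[nd > 0]) - 1e-9, max(nd) + 1e-9,
               length.out = n_bins + 1)
    tabulate(findInterval(d, brk, rightmost.closed = TRUE, all.inside = TRUE),
             nbins = n_bins)
  }
  for (nb in c(5, 10)) {
    r <- rewire_geometry_preserving(g, coords, n_bins = nb,
                                    swaps_per_edge = 3, seed = 7)
    expect_equal(igraph::degree(r), igraph::degree(g))
    expect_equal(edge_bins(r, nb), edge_bins(g, nb))
  }
  expect_error(rewire_geometry_preserving(g, coords[-1, ], n_bins = 5),
               "missing coordinates")
})

test_that("geometry constraint keeps edge lengths closer than free rewiring", {
  set.seed(14)
  n <- 60
  coords <- tibble::tibble(node = as.character(1:n),
                           x = stats::runif(n), y = stats::runif(n))
  # spatially embedded network: connect preferentially at short distance
  nd <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  pairs <- which(upper.tri(nd), arr.ind = TRUE)
  prob <- exp(-6 * nd[pairs])
  keep <- pairs[stats::runif(nrow(pairs)) < prob, , drop = FALSE]
  g <- tibble::tibble(from = as.character(keep[, 1]), to = as.character(keep[, 2]))

  lengths_of <- function(gg) nd[igraph::as_edgelist(gg, names = FALSE)]
  d_orig <- lengths_of(as_network_graph(g, nodes = coords$node))
  ks_geo <- ks_free <- numeric(20)
  for (s in 1:20) {
    geo <- rewire_geometry_preserving(g, coords, n_bins = 10,
                                      swaps_per_edge = 3, seed = s,
                                      nodes = coords$node)
    fre <- rewire_degree_preserving(g, swaps_per_edge = 3, seed = s,
                                    nodes = coords$node)
    ks_geo[s] <- suppressWarnings(
      stats::ks.test(d_orig, lengths_of(geo))$statistic)
    ks_free[s] <- suppressWarnings(
      stats::ks.test(d_orig, lengths_of(fre))$statistic)
  }
  expect_lt(mean(ks_geo), mean(ks_free))
})

test_that("single-bin geometry rewiring behaves like unconstrained rewiring", {
  set.seed(15)
  n <- 30
  coords <- tibble::tibble(node = as.character(1:n),
                           x = stats::runif(n), y = stats::runif(n))
  g <- igraph::sample_gnm(n, 90)
  igraph::V(g)$name <- as.character(1:n)
  r_geo <- rewire_geometry_preserving(g, coords, n_bins = 1,
                                      swaps_per_edge = 5, seed = 8)
  r_free <- rewire_degree_preserving(g, swaps_per_edge = 5, seed = 8)
  # same seed, same proposal stream, no bin rejections: identical output
  expect_identical(igraph::as_edgelist(r_geo), igraph::as_edgelist(r_free))
})

test_that("density-matched random graphs preserve edge count but not degrees", {
  g <- ring_lattice(40, 0.2)
  r <- sample_density_matched(g, seed = 3)
  expect_equal(igraph::gsize(r), igraph::gsize(g))
  expect_equal(igraph::vcount(r), igraph::vcount(g))
  degs_differ <- vapply(1:10, function(s) {
    !identical(sort(igraph::degree(sample_density_matched(g, seed = s))),
               sort(igraph::degree(g)))
  }, TRUE)
  expect_true(any(degs_differ))
})

test_that("null ensembles are reproducible and break identical-layer redundancy", {
  a <- igraph::as_data_frame(ring_lattice(25, 0.2))
  m <- as_multiplex(list(A = a, B = a))
  ens1 <- null_ensemble(m, "degree_preserving", n_surrogates = 15, seed = 21)
  ens2 <- null_ensemble(m, "degree_preserving", n_surrogates = 15, seed = 21)
  expect_equal(ens1$nulls, ens2$nulls)
  # observed identical layers: R = F, S = 0; rewired layers diverge, S > 0
  expect_equal(ens1$observed$S, 0)
  expect_gt(mean(ens1$nulls$S), 0)
  # every surrogate conserves the decomposition identity
  expect_true(all(abs(ens1$nulls$R + ens1$nulls$U_A + ens1$nulls$U_B +
                        ens1$nulls$S - ens1$nulls$F_joint) < 1e-12))
})

test_that("ensemble term tests report add-one p-values against the nulls", {
  a <- igraph::as_data_frame(ring_lattice(25, 0.2))
  m <- as_multiplex(list(A = a, B = a))
  ens <- null_ensemble(m, "degree_preserving", n_surrogates = 19, seed = 22)
  tt <- test_against_null(ens, direction = "less")
  expect_setequal(tt$term, c("R", "U_A", "U_B", "S"))
  # observed S = 0 sits below every null S
  expect_equal(tt$p[tt$term == "S"], 1 / 20)
  expect_true(all(tt$p > 0 & tt$p <= 1))
})

test_that("ensemble summaries are stable across master seeds", {
  set.seed(30)
  m <- er_multiplex(40, 0.15, 0.15, seed = 77)
  meanS <- vapply(1:5, function(s) {
    mean(null_ensemble(m, "degree_preserving", n_surrogates = 40,
                       swaps_per_edge = 3, seed = s)$nulls$S)
  }, 0)
  expect_lt(stats::sd(meanS) / mean(meanS), 0.05)
})
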