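test_that("worked four-node example decomposes exactly", {
  res <- decompose_efficiency(worked_example())
  g <- glance(res)
  expect_equal(g$R, 1 / 6)
  expect_equal(g$U_A, 5 / 9)
  expect_equal(g$U_B, 1 / 6)
  expect_equal(g$S, 1 / 36)
  expect_equal(g$F_joint, 11 / 12)

  cc <- res$class_counts
  expect_equal(cc$n[cc$class == "synergistic"], 1L)
  expect_equal(cc$n[cc$class == "unique:A"], 3L)
  expect_equal(cc$n[cc$class == "unique:B"], 2L)
  expect_equal(cc$n[cc$class == "redundant"], 0L)
  expect_equal(sum(cc$n), 6L)

  pp <- tidy(res)
  syn <- pp[pp$class == "synergistic", ]
  expect_equal(nrow(syn), 1)
  expect_setequal(c(syn$node_u, syn$node_v), c("1", "4"))
  expect_equal(syn$r, 0)
  expect_equal(syn$u_A, 1 / 3)
  expect_equal(syn$u_B, 0)
  expect_equal(syn$s, 1 / 6)
})

test_that("pair classification follows the three length conditions", {
  expect_equal(classify_pair(3, 2, 2), "unique_B")
  expect_equal(classify_pair(2, 2, 2), "redundant")
  expect_equal(classify_pair(3, Inf, 2), "synergistic")
  expect_equal(classify_pair(1, 1, 1), "redundant")
  expect_equal(classify_pair(Inf, Inf, Inf), "unreachable")
  expect_equal(classify_pair(2, Inf, 2), "unique_A")
  # vectorized
  expect_equal(classify_pair(c(3, 2), c(2, 2), c(2, 2)),
               c("unique_B", "redundant"))
  # union monotonicity violations are contract errors
  expect_error(classify_pair(2, 3, 4), "cannot lengthen")
  expect_error(classify_pair(2, 3, Inf), "cannot lengthen")
})

test_that("pair atoms follow the min/max formulas and reject bad input", {
  a <- pair_atoms(1 / 3, 0, 1 / 2)
  expect_equal(a$r, 0)
  expect_equal(a$u_A, 1 / 3)
  expect_equal(a$u_B, 0)
  expect_equal(a$s, 1 / 6)

  b <- pair_atoms(0.4, 0.4, 0.4)
  expect_equal(unlist(b), c(r = 0.4, u_A = 0, u_B = 0, s = 0))

  d <- pair_atoms(1, 1 / 2, 1)
  expect_equal(unlist(d), c(r = 1 / 2, u_A = 1 / 2, u_B = 0, s = 0))

  expect_error(pair_atoms(0.9, 0.2, 0.5), "joint efficiency")
})

test_that("decomposition agrees with the brute-force oracle on random multiplexes", {
  set.seed(101)
  for (i in 1:300) {
    m <- rand_multiplex(sample(3:6, 1), p = stats::runif(1, 0.1, 0.8))
    res <- decompose_efficiency(m)
    oracle <- brute_decompose(m)
    g <- glance(res)
    expect_equal(g$R, oracle$R, tolerance = 1e-12)
    expect_equal(g$U_A, oracle$U_A, tolerance = 1e-12)
    expect_equal(g$U_B, oracle$U_B, tolerance = 1e-12)
    expect_equal(g$S, oracle$S, tolerance = 1e-12)
    expect_equal(g$F_joint, oracle$F_joint, tolerance = 1e-12)
  }
})

test_that("atoms conserve joint efficiency and satisfy structural invariants", {
  set.seed(202)
  for (i in 1:200) {
    m <- rand_multiplex(sample(4:10, 1), p = stats::runif(1, 0.05, 0.7))
    res <- decompose_efficiency(m)
    pp <- tidy(res)
    # per-pair conservation and non-negativity
    expect_true(all(abs(pp$r + pp$u_A + pp$u_B + pp$s - pp$f_joint) < 1e-12))
    expect_true(all(pp$r >= 0 & pp$u_A >= 0 & pp$u_B >= 0 & pp$s >= -1e-15))
    # at most one strictly positive unique atom per pair
    expect_true(all(pmin(pp$u_A, pp$u_B) == 0))
    # global conservation
    expect_lt(abs(sum(res$atoms) - res$F_joint), 1e-12)
    # class counts sum to number of pairs
    expect_equal(sum(res$class_counts$n), res$n_pairs)
  }
})

test_that("length-route and atom-route classification agree", {
  set.seed(303)
  for (i in 1:100) {
    m <- rand_multiplex(sample(4:8, 1), p = stats::runif(1, 0.1, 0.6))
    pp <- tidy(decompose_efficiency(m))
    atom_class <- ifelse(pp$f_joint == 0, "unreachable",
                  ifelse(pp$s > 0, "synergistic",
                  ifelse(pp$u_A > 0, "unique_A",
                  ifelse(pp$u_B > 0, "unique_B", "redundant"))))
    length_class <- classify_pair(pp$l_A, pp$l_B, pp$l_joint)
    expect_equal(length_class, atom_class)
  }
})

test_that("swapping layer order swaps unique atoms and leaves R, S invariant", {
  set.seed(404)
  for (i in 1:50) {
    m <- rand_multiplex(sample(4:8, 1), p = 0.3)
    swapped <- as_multiplex(list(A = igraph::as_data_frame(m$layers[[2]]),
                                 B = igraph::as_data_frame(m$layers[[1]])))
    g1 <- glance(decompose_efficiency(m))
    g2 <- glance(decompose_efficiency(swapped))
    expect_equal(g1$R, g2$R)
    expect_equal(g1$S, g2$S)
    expect_equal(g1$U_A, g2$U_B)
    expect_equal(g1$U_B, g2$U_A)
  }
})

test_that("identical and nested layers collapse to the degenerate atoms", {
  a <- tibble::tibble(from = c("1", "2", "3"), to = c("2", "3", "4"))
  ident <- glance(decompose_efficiency(list(A = a, B = a)))
  expect_equal(ident$S, 0)
  expect_equal(ident$U_A, 0)
  expect_equal(ident$U_B, 0)
  expect_equal(ident$R, ident$F_joint)

  # layer A subset of layer B: no unique A, no synergy
  b <- dplyr::bind_rows(a, tibble::tibble(from = "1", to = "4"))
  nested <- glance(decompose_efficiency(list(A = a, B = b)))
  expect_equal(nested$U_A, 0)
  expect_equal(nested$S, 0)
})

test_that("length profile rows sum to one and length-1 pairs are never synergistic", {
  set.seed(505)
  for (i in 1:30) {
    m <- rand_multiplex(sample(5:9, 1), p = stats::runif(1, 0.15, 0.6))
    prof <- by_length_profile(decompose_efficiency(m))
    sums <- tapply(prof$proportion, prof$l_joint, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    l1 <- prof[prof$l_joint == 1 & prof$class == "synergistic", ]
    if (nrow(l1)) expect_equal(l1$proportion, 0)
  }
  # worked example: joint has 5 direct edges, one length-2 pair
  prof <- by_length_profile(decompose_efficiency(worked_example()), wide = TRUE)
  expect_equal(prof$l_joint, c(1, 2))
  expect_equal(prof$synergistic, c(0, 1))
  expect_equal(prof$`unique:A`[1], 3 / 5)
  expect_equal(prof$`unique:B`[1], 2 / 5)
})

test_that("pair gain measures steps saved against the next-best alternative", {
  res <- decompose_efficiency(worked_example())
  expect_equal(pair_gain(res, "1", "4"), 1)   # synergistic: 3 - 2
  expect_equal(pair_gain(res, "4", "1"), 1)   # order-insensitive lookup
  # unique pair with the other layer disconnected: infinite gain
  expect_equal(pair_gain(res, "1", "2"), Inf)
  # unique:B pair (1,3): l_A = 2, l_B = 1
  expect_equal(pair_gain(res, "1", "3"), 1)
  expect_error(pair_gain(res, "1", "99"), "not found")
})

test_that("edgewise networks partition reachable pairs by mode", {
  res <- decompose_efficiency(worked_example())
  nets <- edgewise_networks(res)
  expect_named(nets, c("redundant", "unique:A", "unique:B", "synergistic"))
  expect_equal(nrow(nets$synergistic), 1)
  expect_setequal(c(nets$synergistic$from, nets$synergistic$to), c("1", "4"))
  total <- sum(vapply(nets, nrow, 0L))
  expect_equal(total, res$n_pairs - res$n_unreachable)

  # identical layers: only the redundant network is populated, with weight 0
  a <- tibble::tibble(from = c("1", "2"), to = c("2", "3"))
  nets2 <- edgewise_networks(decompose_efficiency(list(A = a, B = a)))
  expect_equal(nrow(nets2$synergistic), 0)
  expect_equal(nrow(nets2$`unique:A`), 0)
  expect_equal(nrow(nets2$redundant), 3)
  expect_true(all(nets2$redundant$weight == 0))
})

test_that("unreachable pairs keep zero atoms and are excluded from proportions", {
  # two disjoint components in every layer
  a <- tibble::tibble(from = c("1", "3"), to = c("2", "4"))
  b <- tibble::tibble(from = c("1", "3"), to = c("2", "4"))
  res <- decompose_efficiency(list(A = a, B = b))
  expect_gt(res$n_unreachable, 0)
  pp <- tidy(res)
  unr <- pp[pp$class == "unreachable", ]
  expect_true(all(unr$r == 0 & unr$s == 0 & unr$u_A == 0 & unr$u_B == 0))
  cp <- class_proportions(res)
  expect_false("unreachable" %in% cp$class)
  expect_equal(sum(cp$proportion), 1)
  cp_all <- class_proportions(res, include_unreachable = TRUE)
  expect_equal(sum(cp_all$proportion), 1)
  expect_true("unreachable" %in% cp_all$class)
})
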