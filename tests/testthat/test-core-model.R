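test_that("module_stats reproduces hand-counted quantities", {
  g <- two_triangles()
  s <- module_stats(g, c("a", "b", "c"), gamma = 1)
  expect_equal(s$n_m, 3L)
  expect_equal(s$l_m, 3L)
  expect_equal(s$theta_m, 7)
  expect_equal(s$theta_in, 6)
  expect_equal(s$theta_out, 1)
  expect_equal(s$a, 1 / 3)
  expect_equal(s$Q_m, 3 / 7 - (7 / 14)^2)

  # whole network: Q_m = 1 - gamma
  s_all <- module_stats(g, igraph::V(g)$name, gamma = 1)
  expect_equal(s_all$Q_m, 0)
  expect_equal(s_all$l_m, igraph::gsize(g))

  # singleton of degree d: l_m = 0, Q_m = -gamma (d/2L)^2 < 0
  s1 <- module_stats(g, "c", gamma = 2)
  expect_equal(s1$l_m, 0L)
  expect_equal(s1$theta_out, 3)
  expect_true(is.na(s1$a))
  expect_equal(s1$Q_m, -2 * (3 / 14)^2)
})

test_that("module_stats rejects bad input", {
  g <- two_triangles()
  expect_error(module_stats(g, character(0)), "non-empty")
  expect_error(module_stats(g, c("a", "zzz")), "zzz")
  edgeless <- mr_network(matrix(character(0), ncol = 2),
                         nodes = c("x", "y"))
  expect_error(module_stats(edgeless, "x"), "no edges")
  expect_error(module_stats(g, "a", gamma = 0), "positive")
})

test_that("modularity matches hand arithmetic and trivial identities", {
  g <- two_triangles()
  expect_equal(network_modularity(g, triangle_partition()),
               2 * (3 / 7 - 1 / 4))
  # one-module partition -> 0 for any simple graph at gamma = 1
  whole <- stats::setNames(rep("m", 6), igraph::V(g)$name)
  expect_equal(network_modularity(g, whole), 0)
  # all singletons: -gamma * sum (d_i / 2L)^2
  singles <- stats::setNames(igraph::V(g)$name, igraph::V(g)$name)
  d <- igraph::degree(g)
  expect_equal(network_modularity(g, singles, gamma = 1.7),
               -1.7 * sum((d / 14)^2))
})

test_that("modularity errors name the offending node", {
  g <- two_triangles()
  p <- triangle_partition()
  expect_error(network_modularity(g, p[-1]), "a")
  p2 <- c(p, ghost = "t9")
  expect_error(network_modularity(g, p2), "ghost")
})

test_that("modularity agrees with a brute-force double-loop oracle", {
  for (seed in 1:8) {
    g <- random_network(n = sample(8:30, 1), p = 0.25, seed = seed)
    p <- random_partition(g, k = sample(2:5, 1), seed = seed + 100)
    for (gam in c(0.5, 1, 2)) {
      expect_equal(network_modularity(g, p, gam),
                   brute_force_modularity(g, p, gam),
                   tolerance = 1e-12)
    }
  }
})

test_that("whole-network modularity is 0 at gamma 1 on random graphs", {
  for (seed in 1:5) {
    g <- random_network(25, 0.2, seed)
    whole <- stats::setNames(rep("all", igraph::vcount(g)),
                             igraph::V(g)$name)
    expect_equal(network_modularity(g, whole), 0, tolerance = 1e-14)
  }
})

test_that("per-module counts conserve edges and degrees", {
  for (seed in 1:6) {
    g <- random_network(30, 0.15, seed)
    p <- random_partition(g, 4, seed + 50)
    L <- igraph::gsize(g)
    mods <- partition_modules(p)
    st <- lapply(mods, function(m) module_stats(g, m))
    theta_sum <- sum(vapply(st, `[[`, 0, "theta_m"))
    l_sum <- sum(vapply(st, `[[`, 0, "l_m"))
    el <- igraph::as_edgelist(g)
    inter <- sum(p[el[, 1]] != p[el[, 2]])
    expect_equal(theta_sum, 2 * L)
    expect_equal(l_sum + inter, L)
    for (s in st) {
      expect_equal(s$theta_m, s$theta_in + s$theta_out)
      expect_lte(s$l_m, s$n_m * (s$n_m - 1) / 2)
    }
  }
})

test_that("qualification test applies both strict inequalities", {
  # K5 with one external edge in a 40-edge network
  pairs <- t(utils::combn(5, 2))
  k5 <- cbind(paste0("k", pairs[, 1]), paste0("k", pairs[, 2]))
  fill <- cbind(paste0("f", 1:29), paste0("f", 2:30))
  g <- mr_network(rbind(k5, c("k1", "f1"), fill))
  expect_equal(igraph::gsize(g), 40L)
  q <- qualifies_as_module(g, paste0("k", 1:5))
  expect_true(q$qualifies)
  expect_equal(q$stats$theta_in, 20)
  expect_equal(q$stats$theta_out, 1)

  # a = 2 boundary: triangle (l_m = 3) with exactly 6 external edges
  tri <- cbind(c("a", "b", "c"), c("b", "c", "a"))
  ext <- cbind(rep(c("a", "b", "c"), each = 2), paste0("x", 1:6))
  g2 <- mr_network(rbind(tri, ext, cbind(paste0("y", 1:20), paste0("y", 2:21))))
  q2 <- qualifies_as_module(g2, c("a", "b", "c"))
  expect_equal(q2$stats$theta_in, q2$stats$theta_out)
  expect_false(q2$qualifies)
  expect_false(q2$internal_exceeds_external)
  expect_true(q2$q_positive)

  # whole network: Q_m = 0 is not positive
  g3 <- two_triangles()
  q3 <- qualifies_as_module(g3, igraph::V(g3)$name)
  expect_false(q3$qualifies)
  expect_false(q3$q_positive)
})

test_that("qualification is invariant under node relabeling", {
  g <- two_triangles()
  perm <- c(a = "P", b = "Q", c = "R", d = "S", e = "T", f = "U")
  el <- igraph::as_edgelist(g)
  g2 <- mr_network(cbind(perm[el[, 1]], perm[el[, 2]]))
  for (m in list(c("a", "b", "c"), c("a", "d"), "e")) {
    expect_equal(qualifies_as_module(g, m)$qualifies,
                 qualifies_as_module(g2, unname(perm[m]))$qualifies)
  }
})

test_that("resolution limits are exact and monotone", {
  rl <- resolution_limits(800)
  expect_equal(rl$l_min, 20)
  expect_equal(rl$l_max, 200)
  expect_equal(rl$refinable_threshold, 40)
  rl2 <- resolution_limits(2)
  expect_equal(rl2$l_min, 1)
  expect_equal(rl2$l_max, 0.5)
  expect_equal(rl2$refinable_threshold, 2)
  expect_error(resolution_limits(0), "integer")
  Ls <- c(1, 2, 8, 32, 100, 801, 5000)
  for (f in c("l_min", "l_max", "refinable_threshold")) {
    vals <- vapply(Ls, function(L) resolution_limits(L)[[f]], 0)
    expect_true(all(diff(vals) >= 0))
  }
  # ordering l_min < refinable <= l_max holds from L = 32 on
  for (L in c(32, 33, 100, 1000)) {
    rl <- resolution_limits(L)
    expect_lt(rl$l_min, rl$refinable_threshold)
    expect_lte(rl$refinable_threshold, rl$l_max)
  }
})

test_that("partition density matches hand fixtures and bounds", {
  # two K4 joined by one bridge: PD = 12/13
  g <- two_cliques(4)
  expect_equal(partition_density(g, two_cliques_partition(4)), 12 / 13)

  # disjoint cliques partitioned into themselves -> exactly 1
  pairs <- t(utils::combn(4, 2))
  cl <- rbind(cbind(paste0("a", pairs[, 1]), paste0("a", pairs[, 2])),
              cbind(paste0("b", pairs[, 1]), paste0("b", pairs[, 2])))
  gd <- mr_network(cl)
  pd <- partition_density(gd, as_partition(list(A = paste0("a", 1:4),
                                                B = paste0("b", 1:4))))
  expect_equal(pd, 1)

  # a tree module contributes 0
  tree <- mr_network(cbind(c("t1", "t2", "t3"), c("t2", "t3", "t4")))
  expect_equal(partition_density(tree, stats::setNames(rep("m", 4),
                                                       paste0("t", 1:4))), 0)

  # PD <= 1 on random graphs/partitions
  for (seed in 1:6) {
    g <- random_network(20, 0.25, seed)
    p <- random_partition(g, 4, seed + 10)
    expect_lte(partition_density(g, p), 1)
  }
})

test_that("composite score adds its two bounded components", {
  expect_equal(composite_score(0, 0), 0)
  expect_equal(composite_score(0.5, 0.5), 1.0)
  g <- two_triangles()
  p <- triangle_partition()
  q <- network_modularity(g, p)
  pd <- partition_density(g, p)
  expect_equal(pd, 6 / 7)
  expect_equal(composite_score(q, pd), 2 * (3 / 7 - 1 / 4) + 6 / 7)
  expect_gt(composite_score(0.4, 0.3), composite_score(0.3, 0.3))
  expect_gt(composite_score(0.4, 0.4), composite_score(0.4, 0.3))
})
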