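test_that("sensor adjacency follows the triangulation and 1-Hz rules", {
  m <- fx_montage32()
  adj <- build_sensor_adjacency(m, c(9, 10, 12))
  expect_equal(adj$n_nodes, 32 * 3)
  # 9-10 spectrally adjacent, 10-12 not
  node <- function(chn, fi) chn + (fi - 1) * 32
  has_edge <- function(a, b) any((adj$edges[, 1] == a & adj$edges[, 2] == b) |
                                   (adj$edges[, 1] == b & adj$edges[, 2] == a))
  expect_true(has_edge(node(1, 1), node(1, 2)))
  expect_false(has_edge(node(1, 2), node(1, 3)))
  # spatial links replicate per frequency; symmetric, no self-links
  expect_false(any(adj$edges[, 1] == adj$edges[, 2]))
  full <- fx_adj64()
  deg <- tabulate(as.vector(full$spatial_edges), 64)
  expect_true(all(deg >= 2))
})

test_that("element t map matches hand-computed arithmetic and handles
           degenerate variance", {
  a <- c(1.1, 2.3, 0.7); b <- c(2.0, 2.8, 3.1)
  tm <- element_t_map(matrix(c(a, b), ncol = 1),
                      factor(rep(c("g1", "g2"), each = 3),
                             levels = c("g1", "g2")))
  sp <- sqrt((var(a) * 2 + var(b) * 2) / 4)
  expect_equal(tm$t, (mean(a) - mean(b)) / (sp * sqrt(2 / 3)),
               tolerance = 1e-12)
  expect_equal(tm$df[1], 4)
  expect_equal(tm$p, 2 * pt(-abs(tm$t), 4), tolerance = 1e-12)
  # identical groups give t = 0; constant elements are flagged, t = 0
  x <- matrix(rnorm(8), 4)
  tm0 <- element_t_map(rbind(x, x), rep(c("a", "b"), each = 4))
  expect_equal(tm0$t, c(0, 0))
  xc <- matrix(5, 6, 1)
  tmc <- element_t_map(xc, rep(c("a", "b"), each = 3))
  expect_true(tmc$zero_variance)
  expect_equal(tmc$t, 0)
  # t expectation scales like delta * sqrt(n/2) under unit noise
  set.seed(71)
  tt <- replicate(200, {
    v <- matrix(rnorm(40), 40)
    v[1:20, ] <- v[1:20, ] + 1
    element_t_map(v, rep(c("a", "b"), each = 20))$t
  })
  expect_equal(mean(tt), sqrt(20 / 2), tolerance = 0.12)
})

test_that("cluster test reduces to the suprathreshold t-sum under a complete
           graph and respects the two-channel/two-bin rule", {
  set.seed(72)
  # complete-graph oracle
  adjc <- structure(list(edges = t(combn(100, 2)), n_nodes = 100,
                         node_channel = rep(1:10, 10),
                         node_freq = rep(1:10, each = 10),
                         type = "sensor_freq"),
                    class = "adjacency_graph")
  v <- matrix(rnorm(12 * 100), 12)
  g <- rep(c("a", "b"), each = 6)
  cr <- cluster_permutation_test(v, g, adjc, element_alpha = 0.3,
                                 n_perm = 100, seed = 1)
  tm <- element_t_map(v, g)
  tc <- qt(1 - 0.15, 10)
  for (sgn in c(1, -1)) {
    expected <- sum(tm$t[sgn * tm$t > tc])
    got <- Filter(function(cl) cl$sign == sgn, cr$clusters)
    if (abs(expected) > 0) {
      expect_equal(got[[1]]$mass, expected, tolerance = 1e-10)
    }
  }
  # min-channel / min-freq rule: a single-channel band of suprathreshold
  # elements is discarded
  m <- fx_montage32()
  adj <- build_sensor_adjacency(m, 1:10)
  set.seed(73)
  v2 <- matrix(rnorm(20 * adj$n_nodes, 0, 0.2), 20)
  onechan <- which(adj$node_channel == 5)
  v2[1:10, onechan] <- v2[1:10, onechan] + 5
  cr2 <- cluster_permutation_test(v2, rep(c("a", "b"), each = 10), adj,
                                  n_perm = 100, seed = 2)
  for (cl in cr2$clusters)
    expect_gte(length(unique(adj$node_channel[cl$members])), 2)
  # identical data in both groups: no significant cluster
  v3 <- rbind(v2[1:10, ], v2[1:10, ])
  cr3 <- cluster_permutation_test(v3, rep(c("a", "b"), each = 10), adj,
                                  n_perm = 100, seed = 3)
  expect_false(any(vapply(cr3$clusters, `[[`, logical(1), "significant")))
  expect_error(cluster_permutation_test(v2, rep(c("a", "b"), each = 10),
                                        adj, n_perm = 50), "refused")
})

test_that("cluster and NBS tests are seed-reproducible and two-sided
           symmetric", {
  m <- fx_montage32()
  adj <- build_sensor_adjacency(m, 1:10)
  set.seed(74)
  v <- matrix(rnorm(16 * adj$n_nodes), 16)
  inj <- which(adj$node_channel %in% 1:6 & adj$node_freq %in% 3:6)
  v[1:8, inj] <- v[1:8, inj] + 1.6
  g <- rep(c("MBSR", "control"), each = 8)
  r1 <- cluster_permutation_test(v, factor(g, levels = c("MBSR", "control")),
                                 adj, n_perm = 200, seed = 9)
  r2 <- cluster_permutation_test(v, factor(g, levels = c("MBSR", "control")),
                                 adj, n_perm = 200, seed = 9)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p_value"),
                   vapply(r2$clusters, `[[`, numeric(1), "p_value"))
  # relabelling the groups flips signs but keeps p-values
  r3 <- cluster_permutation_test(v, factor(g, levels = c("control", "MBSR")),
                                 adj, n_perm = 200, seed = 9)
  expect_equal(sort(vapply(r1$clusters, `[[`, numeric(1), "p_value")),
               sort(vapply(r3$clusters, `[[`, numeric(1), "p_value")))
  expect_equal(r1$clusters[[1]]$sign, -r3$clusters[[1]]$sign)
})

test_that("NBS matches an exhaustive all-relabelings oracle on a toy graph
           and scores singleton edges", {
  # 5 ROIs, 4 + 4 subjects: enumerate all C(8,4) = 70 label assignments
  set.seed(75)
  nroi <- 5
  diff <- array(0, c(8, nroi, nroi))
  for (i in 1:8) {
    m <- matrix(rnorm(nroi^2, 0, 0.5), nroi)
    m <- (m + t(m)) / 2; diag(m) <- 0
    diff[i, , ] <- m
  }
  diff[1:4, 1, 2] <- diff[1:4, 1, 2] + 3
  diff[1:4, 2, 1] <- diff[1:4, 1, 2]
  g <- rep(c("a", "b"), each = 4)
  res <- nbs_test(diff, g, edge_alpha = 0.05, n_perm = 500, seed = 4)
  expect_gte(length(res$components), 1)
  top <- res$components[[1]]
  expect_equal(top$size, 1)
  expect_equal(sort(as.vector(top$edges)), c(1, 2))
  # oracle: exact permutation distribution of the max component size
  ut <- which(upper.tri(matrix(0, nroi, nroi)))
  prs <- arrayInd(ut, c(nroi, nroi))
  vals <- t(apply(diff, 1, function(mm) mm[ut]))
  tcrit <- qt(1 - 0.025, 6)
  combos <- combn(8, 4)
  exact <- apply(combos, 2, function(idx) {
    gg <- rep("b", 8); gg[idx] <- "a"
    tv <- element_t_map(vals, factor(gg, levels = c("a", "b")))$t
    best <- 0
    for (sgn in c(1, -1)) {
      eidx <- which(sgn * tv > tcrit)
      if (!length(eidx)) next
      gr <- igraph::graph_from_edgelist(prs[eidx, , drop = FALSE],
                                        directed = FALSE)
      mb <- igraph::components(gr)$membership
      best <- max(best, max(table(mb[prs[eidx, 1]])))
    }
    best
  })
  p_exact <- mean(exact >= top$size)
  expect_lt(abs(top$p_value - p_exact), 0.08)
  expect_error(nbs_test(diff, g, n_perm = 50), "refused")
})
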