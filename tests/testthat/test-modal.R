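test_that("noise floor demands sigma^2 events in the spot-size window", {
  set.seed(31)
  # a dense single blob: threshold no higher than the bulk and one cluster
  g <- generate(fixture_library("one_blob", n = 1e5))
  x <- g$events$values[, 1]; y <- g$events$values[, 2]
  w <- compute_weights(x, y, 257L)
  d <- kde_dct(w, 0.01)
  fl <- noise_floor(d, w, 0.01, sigma = 3)
  expect_equal(fl, direct_noise_floor(d, w, 0.01, 3))
  lab <- modal_cluster(d, fl)
  expect_identical(lab$n_clusters, 1L)
  # 5 events cannot clear sigma = 3 (more than 9 events required)
  w5 <- compute_weights(runif(5), runif(5), 65L)
  d5 <- kde_dct(w5, 0.05)
  expect_identical(noise_floor(d5, w5, 0.05, 3), Inf)
  # 9 events of mass is exactly not enough: strict inequality
  w9 <- matrix(0, 65, 65); w9[30, 30] <- 9
  expect_identical(noise_floor(kde_dct(w9, 0.05), w9, 0.05, 3), Inf)
  w10 <- matrix(0, 65, 65); w10[30, 30] <- 9.5
  expect_true(is.finite(noise_floor(kde_dct(w10, 0.05), w10, 0.05, 3)))
})

test_that("modal clustering recovers the modal structure of simple fields", {
  G <- 129L
  gx <- seq(0, 1, length.out = G)
  # one bump: single cluster, no boundary
  d1 <- outer(gx, gx, function(x, y) dnorm(x, 0.5, 0.1) * dnorm(y, 0.5, 0.1))
  l1 <- modal_cluster(d1, 1e-6)
  expect_identical(l1$n_clusters, 1L)
  expect_false(any(l1$labels == -1L))
  expect_false(any(l1$labels == 0L))
  # monotone planar ramp: one cluster (single global maximum)
  dr <- outer(gx, gx, function(x, y) 1 + x + 0.5 * y)
  lr <- modal_cluster(dr, 0)
  expect_identical(lr$n_clusters, 1L)
  # two equal bumps: two clusters, boundary near the mid valley
  d2 <- outer(gx, gx, function(x, y)
    dnorm(x, 0.3, 0.05) * dnorm(y, 0.5, 0.05) +
    dnorm(x, 0.7, 0.05) * dnorm(y, 0.5, 0.05))
  l2 <- modal_cluster(d2, 1e-4)
  expect_identical(l2$n_clusters, 2L)
  brows <- ((which(l2$labels == -1L) - 1) %% G) + 1
  expect_true(all(abs(gx[brows] - 0.5) < 0.08))
})

test_that("labels form a partition with one mode per cluster", {
  set.seed(32)
  for (k in 1:4) {
    b <- random_blob_events(k, n = 6000 * k, sd = 0.03)
    w <- compute_weights(b$x, b$y, 257L)
    d <- kde_dct(w, 0.01)
    fl <- noise_floor(d, w, 0.01)
    lab <- modal_cluster(d, fl)
    expect_identical(lab$n_clusters, k)   # 8-SD separated components
    expect_false(any(lab$labels == 0L))
    expect_identical(length(lab$modes), lab$n_clusters)
    expect_true(all(d[lab$modes] >= fl))
  }
})

test_that("cluster graph topology matches constructed adjacency", {
  G <- 129L
  gx <- seq(0, 1, length.out = G)
  bump <- function(cx, cy) outer(gx, gx, function(x, y)
    dnorm(x, cx, 0.06) * dnorm(y, cy, 0.06))
  # two faces -> one edge, no interior vertices
  d2 <- bump(0.3, 0.5) + bump(0.7, 0.5)
  g2 <- build_cluster_graph(modal_cluster(d2, 1e-4), d2)
  expect_identical(length(g2$edges), 1L)
  expect_identical(length(g2$vertices), 0L)
  # three mutually adjacent faces -> three edges, a central meeting point
  d3 <- bump(0.32, 0.32) + bump(0.68, 0.32) + bump(0.5, 0.68)
  g3 <- build_cluster_graph(modal_cluster(d3, 1e-4), d3)
  expect_identical(length(g3$edges), 3L)
  expect_gte(length(g3$vertices), 1L)
  pairs3 <- t(vapply(g3$edges, function(e) c(e$a, e$b), numeric(2)))
  expect_identical(nrow(unique(pairs3)), 3L)
  # chain of three: ends not adjacent -> two edges
  dc <- bump(0.2, 0.5) + bump(0.5, 0.5) + bump(0.8, 0.5)
  gc <- build_cluster_graph(modal_cluster(dc, 1e-4), dc)
  expect_identical(length(gc$edges), 2L)
})

test_that("event assignment is a deterministic partition", {
  set.seed(33)
  g <- generate(fixture_library("two_blobs", n = 10000))
  x <- g$events$values[, 1]; y <- g$events$values[, 2]
  w <- compute_weights(x, y, 257L)
  d <- kde_dct(w, 0.01)
  lab <- modal_cluster(d, noise_floor(d, w, 0.01))
  a <- assign_events(x, y, lab$labels)
  expect_identical(length(a), length(x))
  expect_true(all(a >= 1))
  expect_identical(sum(tabulate(a)), length(x))  # counts sum to n
  # against generator truth: valley misassignment under 1%
  expect_gt(leaf_purity(a, g$labels), 0.99)
  expect_identical(a, assign_events(x, y, lab$labels))
  # an event at a mode location gets that cluster
  mode1 <- lab$modes[1]
  mx <- ((mode1 - 1) %% 257) / 256; my <- ((mode1 - 1) %/% 257) / 256
  expect_identical(assign_events(mx, my, lab$labels), lab$labels[mode1])
})

test_that("too many modes raise the widen signal", {
  g <- generate(fixture_library("many_spikes"))
  x <- g$events$values[, 1]; y <- g$events$values[, 2]
  w <- compute_weights(x, y, 257L)
  d <- kde_dct(w, 0.01)
  lab <- modal_cluster(d, noise_floor(d, w, 0.01), max_clusters = 12L)
  expect_true(lab$widen)
  # at doubled width the structure is tractable
  d2 <- kde_dct(w, 0.02)
  lab2 <- modal_cluster(d2, noise_floor(d2, w, 0.02), max_clusters = 12L)
  expect_false(lab2$widen)
  expect_lte(lab2$n_clusters, 12L)
})

test_that("identical inputs give identical labelings", {
  set.seed(34)
  b <- random_blob_events(3, 8000)
  w <- compute_weights(b$x, b$y, 257L)
  d <- kde_dct(w, 0.01)
  fl <- noise_floor(d, w, 0.01)
  l1 <- modal_cluster(d, fl)
  l2 <- modal_cluster(d, fl)
  expect_identical(l1$labels, l2$labels)
  expect_identical(l1$modes, l2$modes)
})
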