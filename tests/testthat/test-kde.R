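test_that("bilinear binning distributes mass by proximity", {
  # exactly on a node
  w <- compute_weights(64 / 256, 64 / 256, 257L)
  expect_equal(w[65, 65], 1)
  expect_equal(sum(w), 1)
  # centre of a cell: 0.25 at each corner
  w <- compute_weights(10.5 / 256, 20.5 / 256, 257L)
  expect_equal(w[11:12, 21:22], matrix(0.25, 2, 2))
  # mass conservation on random input
  set.seed(21)
  w <- compute_weights(runif(1000), runif(1000), 257L)
  expect_equal(sum(w), 1000, tolerance = 1e-12)
  # empty input
  expect_equal(sum(compute_weights(numeric(0), numeric(0), 65L)), 0)
})

test_that("spectral KDE equals direct reflected-Gaussian convolution", {
  G <- 65L
  for (W in c(0.02, 0.05, 0.1)) {
    spike <- matrix(0, G, G); spike[33, 33] <- 1
    expect_lt(max(abs(kde_dct(spike, W) - direct_kde(spike, W))), 1e-6)
    set.seed(22)
    rnd <- matrix(rexp(G * G), G, G)
    expect_lt(max(abs(kde_dct(rnd, W) - direct_kde(rnd, W))), 1e-6)
    corner <- matrix(0, G, G); corner[1, 1] <- 2; corner[G, 20] <- 1
    expect_lt(max(abs(kde_dct(corner, W) - direct_kde(corner, W))), 1e-6)
  }
})

test_that("uniform weights are an eigen-input of the reflective smoother", {
  G <- 33L
  u <- matrix(1, G, G)
  d <- kde_dct(u, 0.07)
  expect_lt(diff(range(d)), 1e-9 * mean(d))
})

test_that("KDE is linear and transpose-symmetric", {
  G <- 65L
  w1 <- matrix(0, G, G); w1[10, 12] <- 1
  w2 <- matrix(0, G, G); w2[55, 50] <- 1
  both <- w1 + w2
  # linearity (densities are normalised by mass: scale back)
  d <- kde_dct(both, 0.04) * 2
  expect_lt(max(abs(d - kde_dct(w1, 0.04) - kde_dct(w2, 0.04))), 1e-9)
  set.seed(23)
  w <- matrix(runif(G * G), G, G)
  expect_lt(max(abs(t(kde_dct(t(w), 0.05)) - kde_dct(w, 0.05))), 1e-10)
})

test_that("density grids integrate to one and stay nonnegative", {
  set.seed(24)
  for (W in c(0.01, 0.05)) {
    w <- compute_weights(rbeta(20000, 2, 2), rbeta(20000, 3, 2), 257L)
    d <- kde_dct(w, W)
    expect_true(all(d >= 0))
    h <- 1 / 256
    tw <- matrix(1, 257, 257); tw[c(1, 257), ] <- tw[, c(1, 257)] / 2
    tw[c(1, 257), c(1, 257)] <- 0.25
    expect_equal(sum(d * tw) * h^2, 1, tolerance = 1e-3)
  }
})

test_that("squared-kernel pass obeys the width-doubling identity", {
  # the squared-kernel pass at width 2W is the plain pass at W*sqrt(2) up
  # to normalisation, which is what lets the widened iteration reuse a DCT
  G <- 65L; W <- 0.05
  set.seed(25)
  w <- matrix(rexp(G * G), G, G)
  vsq <- kde_variance(w, 2 * W)
  dpl <- kde_dct(w, W * sqrt(2))
  expect_lt(max(abs(vsq / sum(vsq) - dpl / sum(dpl))), 1e-8)
})

test_that("variance grid is a narrower, taller companion of the density", {
  G <- 65L; W <- 0.06
  spike <- matrix(0, G, G); spike[33, 33] <- 1
  d <- kde_dct(spike, W)
  v <- kde_variance(spike, W)
  # normalised profiles along the centre row: variance bump is narrower
  pd <- d[, 33] / max(d); pv <- v[, 33] / max(v)
  expect_lt(sum(pv > 0.5), sum(pd > 0.5))
  expect_equal(which.max(pv), 33L)
  expect_equal(kde_variance(matrix(0, G, G), W), matrix(0, G, G))
})

test_that("pointwise variance estimate scales as 1/n", {
  set.seed(26)
  vs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    w <- compute_weights(runif(n), runif(n), 65L)
    v <- kde_variance(w, 0.05)
    d <- kde_dct(w, 0.05)
    v[33, 33]
  }, numeric(1))
  slopes <- diff(log10(vs))
  expect_true(all(abs(slopes + 1) < 0.15))  # slope -1 on log-log
})

test_that("KDE error against the true density decreases with n", {
  set.seed(27)
  truth <- function(x, y) dnorm(x, 0.5, 0.1) * dnorm(y, 0.5, 0.1)
  G <- 257L
  gx <- seq(0, 1, length.out = G)
  td <- outer(gx, gx, truth)
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    x <- pmin(pmax(rnorm(n, 0.5, 0.1), 0), 1)
    y <- pmin(pmax(rnorm(n, 0.5, 0.1), 0), 1)
    d <- kde_dct(compute_weights(x, y, G), 0.02)
    max(abs(d - td))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
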