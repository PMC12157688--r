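test_that("KLD of exact reference quantiles is near zero", {
  n <- 1000
  v <- qnorm((1:n - 0.5) / n, 0.5, 0.05)
  expect_lt(estimate_kld(v, function(q) pnorm(q, 0.5, 0.05)), 0.005)
})

test_that("KLD from a matching normal is small, decreasing in n", {
  set.seed(101)
  meds <- vapply(c(1e3, 1e4, 1e5), function(n) {
    median(vapply(1:8, function(i) {
      x <- rnorm(n, 0.5, 0.05)
      estimate_kld(x, function(q) pnorm(q, mean(x), sd(x)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
  expect_lt(meds[3], 0.04)
})

test_that("KLD of a bimodal sample tracks the numerically integrated truth", {
  mix <- function(x) 0.5 * dnorm(x, 0.3, 0.03) + 0.5 * dnorm(x, 0.7, 0.03)
  m2 <- integrate(function(x) x^2 * mix(x), 0, 1)$value
  mu <- 0.5; sg <- sqrt(m2 - mu^2)
  true_kl <- integrate(function(x) {
    fx <- mix(x)
    ifelse(fx > 0, fx * log(fx / dnorm(x, mu, sg)), 0)
  }, 0.05, 0.95)$value
  set.seed(7)
  x <- c(rnorm(5e4, 0.3, 0.03), rnorm(5e4, 0.7, 0.03))
  est <- estimate_kld(x, function(q) pnorm(q, mean(x), sd(x)))
  expect_gt(est, true_kl * 0.8)
})

test_that("dimension qualification follows the divergence thresholds", {
  expect_false(qualify_dimension(rep(0.4, 1000))$qualified)  # zero variance
  set.seed(3)
  bimodal <- c(rnorm(5e4, 0.3, 0.03), rnorm(5e4, 0.7, 0.03))
  expect_true(qualify_dimension(bimodal)$qualified)
  unimodal <- rnorm(1e5, 0.5, 0.05)
  expect_false(qualify_dimension(unimodal)$qualified)
  expect_warning(q <- qualify_dimension(runif(10)), "too few")
  expect_false(q$qualified)
})

test_that("qualification is invariant to event order", {
  set.seed(4)
  x <- c(rnorm(2e4, 0.3, 0.03), rnorm(2e4, 0.7, 0.03))
  a <- qualify_dimension(x)
  b <- qualify_dimension(sample(x))
  expect_equal(a$kld_normal, b$kld_normal)
  expect_identical(a$qualified, b$qualified)
})

test_that("mass mode adds the exponential reference on non-zero values", {
  set.seed(5)
  x <- ifelse(runif(5e4) < 0.4, 0, rexp(5e4, 20))  # exponential-like stain
  q <- qualify_dimension(x, mode = "mass")
  expect_false(is.na(q$kld_exponential))
  expect_lt(q$kld_exponential, 0.2)   # looks exponential: not qualified
  expect_false(q$qualified)
  # fluorescence mode leaves the exponential test off by default
  qf <- qualify_dimension(x, mode = "fluorescence")
  expect_true(is.na(qf$kld_exponential))
})

test_that("pair enumeration covers qualified, single and empty cases", {
  res <- function(dim, kld, q)
    list(dimension = dim, kld_normal = kld, qualified = q)
  # three qualified -> all C(3,2) pairs
  r <- list(res(1L, 0.5, TRUE), res(2L, 0.01, FALSE), res(3L, 0.3, TRUE),
            res(4L, 0.02, FALSE), res(5L, 0.2, TRUE))
  expect_equal(enumerate_pairs(r),
               matrix(c(1L, 1L, 3L, 3L, 5L, 5L), 3, 2,
                      dimnames = list(NULL, c("i", "j"))))
  # one qualified pairs with best unqualified by kld_normal
  r <- list(res(1L, 0.01, FALSE), res(2L, 0.5, TRUE), res(3L, 0.02, FALSE),
            res(4L, 0.03, FALSE))
  expect_equal(unname(enumerate_pairs(r)), matrix(c(2L, 4L), 1))
  # none qualified: two largest divergences
  r <- list(res(1L, 0.01, FALSE), res(2L, 0.03, FALSE), res(3L, 0.02, FALSE))
  expect_equal(unname(enumerate_pairs(r)), matrix(c(2L, 3L), 1))
  expect_error(enumerate_pairs(r[1]), "at least two")
})

test_that("at least one pair is returned for any qualification outcome", {
  res <- function(dim, kld, q)
    list(dimension = dim, kld_normal = kld, qualified = q)
  set.seed(6)
  for (i in 1:25) {
    D <- sample(2:8, 1)
    r <- lapply(seq_len(D), function(d)
      res(d, runif(1, 0, 0.1), runif(1) < 0.3))
    p <- enumerate_pairs(r)
    expect_gte(nrow(p), 1)
    expect_true(all(p[, 1] < p[, 2]))
  }
})
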