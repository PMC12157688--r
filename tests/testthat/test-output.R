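test_that("RDP keeps endpoints and respects the tolerance", {
  # collinear points collapse to the endpoints
  line <- cbind(seq(0, 1, length.out = 100), seq(0, 0.5, length.out = 100))
  expect_equal(rdp_simplify(line, 0.01), line[c(1, 100), ])
  # a right angle with legs longer than the tolerance keeps its corner
  ang <- rbind(c(0, 0), c(0.5, 0), c(0.5, 0.5))
  dense <- rbind(cbind(seq(0, 0.5, by = 0.01), 0),
                 cbind(0.5, seq(0.01, 0.5, by = 0.01)))
  simp <- rdp_simplify(dense, 0.01)
  expect_true(any(simp[, 1] == 0.5 & simp[, 2] == 0))
  # a sub-tolerance sine wiggle flattens to a segment
  t <- seq(0, 1, length.out = 200)
  wig <- cbind(t, 0.002 * sin(20 * pi * t))
  expect_identical(nrow(rdp_simplify(wig, 0.01)), 2L)
  # never grows, idempotent at fixed tolerance
  set.seed(61)
  poly <- cbind(cumsum(runif(50)), cumsum(rnorm(50, 0, 0.1)))
  s1 <- rdp_simplify(poly, 0.05)
  expect_lte(nrow(s1), nrow(poly))
  expect_equal(rdp_simplify(s1, 0.05), s1)
})

test_that("mahalanobis distance matches its analytic cases", {
  mu <- c(0.3, 0.6)
  x <- rbind(mu, mu + c(1, 0), mu + c(2, 0))
  # the small stabilising ridge shifts distances by O(1e-6)
  expect_equal(unname(mahalanobis_distance(x, mu, diag(2))), c(0, 1, 2),
               tolerance = 1e-5)
  expect_equal(unname(mahalanobis_distance(rbind(mu + c(2, 0)), mu,
                                           diag(c(4, 1)))), 1,
               tolerance = 1e-5)
  # rank-deficient covariance is ridge-regularised to something usable
  d <- mahalanobis_distance(matrix(rnorm(20), 10, 2), c(0, 0),
                            matrix(1, 2, 2))
  expect_true(all(is.finite(d) & d >= 0))
  # a fully degenerate leaf (NA covariance) reports zero distances
  expect_equal(mahalanobis_distance(rbind(c(1, 2)), c(0, 0),
                                    matrix(NA_real_, 2, 2)), 0)
})

test_that("gating tree JSON round-trips the topology", {
  g <- generate(fixture_library("four_grid", n = 20000))
  fit <- epp(g$events)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(fit, path)
  back <- read_tree_json(path)
  shape <- function(nd) {
    if (nd$type == "leaf")
      return(list(nd$leaf_id, nd$label, nd$n))
    list(nd$dim_names, nrow(nd$polygon), round(nd$score, 9),
         round(nd$P, 12), shape(nd$in_node), shape(nd$out_node))
  }
  expect_identical(shape(back), shape(fit$tree))
  parsed <- jsonlite::read_json(path)
  expect_identical(parsed$version, "epp_tree_v1")
  expect_true(is.null(parsed$tree$polygon) == (fit$tree$type == "leaf"))
  # a 1-leaf tree has no polygon keys anywhere
  g1 <- generate(fixture_library("one_blob", n = 2000))
  f1 <- epp(g1$events)
  write_tree_json(f1, path)
  expect_false(grepl("polygon", paste(readLines(path), collapse = "")))
})

test_that("simplified polygons gate nearly all events like the grid split", {
  g <- generate(fixture_library("two_blobs"))
  fit <- epp(g$events)
  nd <- fit$tree
  # gate events by the RDP polygon (extended to the border) instead of the
  # grid ownership mask: agreement must be at least 99%
  poly <- nd$polygon
  v <- fit$events$values[, nd$dims]
  # boundary here is x ~ 0.5 chains: classify by side of the polyline via
  # nearest-vertex normal test (the polygon is y-monotone in this fixture)
  xb <- approx(poly[, 2], poly[, 1], xout = pmin(pmax(v[, 2],
               min(poly[, 2])), max(poly[, 2])), rule = 2)$y
  by_poly <- v[, 1] < xb
  G <- nrow(nd$in_mask)
  gx <- pmin(pmax(round(v[, 1] * (G - 1)), 0), G - 1) + 1
  gy <- pmin(pmax(round(v[, 2] * (G - 1)), 0), G - 1) + 1
  by_grid <- nd$in_mask[cbind(gx, gy)]
  agree <- max(mean(by_poly == by_grid), mean(by_poly != by_grid))
  expect_gte(agree, 0.99)
})

test_that("assignment CSV round-trips the partition", {
  g <- generate(fixture_library("triangle_blobs", n = 9000))
  fit <- epp(g$events)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assignments_csv(fit, path)
  back <- read_assignments_csv(path)
  expect_identical(names(back), c("event_id", "leaf_id", "mahalanobis"))
  expect_identical(nrow(back), nrow(fit$events$values))
  expect_identical(back$leaf_id, fit$assignments$leaf_id)
  expect_identical(back$event_id, fit$assignments$event_id)
  expect_equal(back$mahalanobis, fit$assignments$mahalanobis)
})
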