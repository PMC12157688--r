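# leaves of a fitted tree, in leaf_id order
tree_leaves_pub <- function(fit) epp:::tree_leaves(fit$tree)

test_that("well-separated mixtures are recovered exactly and purely", {
  for (nm in c("two_blobs", "triangle_blobs", "four_grid")) {
    g <- generate(fixture_library(nm))
    fit <- epp(g$events)
    k <- length(unique(g$labels))
    expect_identical(length(tree_leaves_pub(fit)), k)
    expect_gte(leaf_purity(predict(fit), g$labels), 0.99)
  }
})

test_that("a single Gaussian is one leaf at any n", {
  for (n in c(1e3, 1e4)) {
    g <- generate(fixture_library("one_blob", n = n))
    fit <- epp(g$events)
    expect_identical(length(tree_leaves_pub(fit)), 1L)
  }
})

test_that("the root split uses the only informative dimension pair", {
  g <- generate(fixture_library("pair13_only"))
  fit <- epp(g$events)
  expect_identical(fit$tree$dims, c(1L, 3L))
  expect_gte(leaf_purity(predict(fit), g$labels), 0.99)
})

test_that("leaves partition the censored events", {
  g <- generate(fixture_library("chain_blobs"))
  fit <- epp(g$events)
  rows <- sort(unlist(lapply(tree_leaves_pub(fit), `[[`, "rows")))
  expect_identical(rows, seq_len(nrow(fit$events$values)))
  a <- fit$assignments
  expect_identical(nrow(a), nrow(fit$events$values))
  expect_true(all(a$leaf_id >= 1))
  expect_true(all(a$mahalanobis >= 0))
})

test_that("identical input and config give identical trees", {
  g <- generate(fixture_library("four_grid", n = 20000))
  f1 <- epp(g$events)
  f2 <- epp(g$events)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_tree_json(f1, p1); write_tree_json(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(predict(f1), predict(f2))
})

test_that("balance mode favours even first splits over satellite clipping", {
  g <- generate(fixture_library("tiny_plus_overlap"))
  fb <- epp(g$events, mode = "best_balance")
  fs <- epp(g$events, mode = "best_separation")
  evenness <- function(P) min(P, 1 - P)
  expect_gte(evenness(fb$tree$P), evenness(fs$tree$P))
  # separation mode's first split isolates the 2% satellite
  side_rows <- lapply(c("in_node", "out_node"), function(s)
    unlist(lapply(epp:::tree_leaves(fs$tree[[s]]), `[[`, "rows")))
  small <- side_rows[[which.min(lengths(side_rows))]]
  expect_lt(length(small) / nrow(fs$events$values), 0.1)
  expect_gt(mean(g$labels[small] == 3), 0.5)
  expect_gt(sum(g$labels[small] == 3) / sum(g$labels == 3), 0.8)
})

test_that("recursion depth respects the binary-tree bound", {
  g <- generate(fixture_library("four_grid", n = 20000))
  fit <- epp(g$events)
  depth <- function(node) if (node$type == "leaf") 0L else
    1L + max(depth(node$in_node), depth(node$out_node))
  nl <- length(tree_leaves_pub(fit))
  expect_lte(depth(fit$tree), nl - 1L)
})

test_that("population size stopping suppresses recursion into small children", {
  g <- generate(fixture_library("four_grid", n = 20000))
  cfg <- epp_config(min_events_abs = 30000L)
  fit <- epp(g$events, config = cfg)
  expect_identical(length(epp:::tree_leaves(fit$tree)), 1L)
  # a relative floor lets the root split but makes both children leaves
  cfg2 <- epp_config(min_events_rel = 0.6)
  fit2 <- epp(g$events, config = cfg2)
  expect_identical(length(epp:::tree_leaves(fit2$tree)), 2L)
})

test_that("fit methods expose the expected summaries", {
  g <- generate(fixture_library("two_blobs", n = 5000))
  fit <- epp(g$events)
  expect_s3_class(fit, "epp")
  expect_output(print(fit), "2 leaves")
  s <- summary(fit)
  expect_identical(nrow(s$leaves), 2L)
  expect_equal(sum(s$leaves$n), 5000L)
  # predict on new data routes through the stored tree
  g2 <- generate(fixture_library("two_blobs", n = 1000, seed = 9))
  p <- predict(fit, g2$events)
  expect_gte(leaf_purity(p, g2$labels), 0.99)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
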