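# Independent oracles and small constructors shared across the suite.

# Direct reflected-Gaussian convolution: 1-D smoothing matrix whose source
# columns are image-summed over mirror reflections at both grid ends,
# normalised the same way as the production kernel (unit mass per source).
reflected_smoother <- function(W, G, n_images = 4) {
  h <- 1 / (G - 1)
  L <- 2 * (G - 1)
  A <- matrix(0, G, G)
  targets <- 0:(G - 1)
  for (j in 1:G) {
    pos <- unique(c(outer(2 * (-n_images:n_images) * (G - 1),
                          c(j - 1, -(j - 1)), "+")))
    for (p in pos) A[, j] <- A[, j] + stats::dnorm(abs(targets - p) * h,
                                                   sd = W)
  }
  # normalise by the full-line kernel mass, the same convention as the
  # production kernel (unit sum over one period of the wrapped kernel);
  # sources on the reflection axis have a single image family and hence
  # half the raw column mass, as in the even extension
  A / sum(stats::dnorm((-n_images * L):(n_images * L) * h, sd = W))
}

# density by direct convolution (the brute-force oracle for kde_dct)
direct_kde <- function(weights, W) {
  G <- nrow(weights)
  h <- 1 / (G - 1)
  A <- reflected_smoother(W, G)
  (A %*% weights %*% t(A)) / (sum(weights) * h^2)
}

# sliding-window noise floor computed naively (oracle for noise_floor)
direct_noise_floor <- function(density, weights, W, sigma = 3) {
  G <- nrow(density)
  L <- max(1L, min(as.integer(round((4 * W * (G - 1))^2)), length(density)))
  ord <- order(as.vector(density))
  wv <- as.vector(weights)[ord]
  for (i in seq_len(length(ord) - L + 1)) {
    if (sum(wv[i:(i + L - 1)]) > sigma^2) return(density[ord[i]])
  }
  Inf
}

# abstract cluster graph from a face-pair edge list (saddles optional)
make_graph <- function(k, pairs, saddles = rep(0, nrow(pairs))) {
  edges <- lapply(seq_len(nrow(pairs)), function(i)
    list(a = min(pairs[i, 1], pairs[i, 2]),
         b = max(pairs[i, 1], pairs[i, 2]),
         points = integer(0), saddle = saddles[i], saddle_point = 1L))
  structure(list(faces = seq_len(k), edges = edges, modes = NULL,
                 vertices = integer(0), labels = NULL, grid_size = NA,
                 widen = FALSE),
            class = "epp_cluster_graph")
}

# brute-force enumeration of contiguous 2-partitions with their crossing
# edge sets (oracle for enumerate_separations); returns sorted keys
# "boundary_bits in_bits" matching the implementation's encoding
partition_oracle <- function(k, pairs) {
  conn <- function(set) {
    if (length(set) <= 1) return(TRUE)
    seen <- set[1]
    repeat {
      nb <- unique(c(pairs[pairs[, 1] %in% seen & pairs[, 2] %in% set, 2],
                     pairs[pairs[, 2] %in% seen & pairs[, 1] %in% set, 1]))
      grown <- union(seen, nb[nb %in% set])
      if (length(grown) == length(seen)) break
      seen <- grown
    }
    length(seen) == length(set)
  }
  res <- character(0)
  for (m in 1:(2^(k - 1) - 1)) {
    A <- which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0)
    B <- setdiff(seq_len(k), A)
    if (!conn(A) || !conn(B)) next
    cross <- which(xor(pairs[, 1] %in% A, pairs[, 2] %in% A))
    inside <- if (1 %in% A) A else B
    res <- c(res, paste(sum(2^(cross - 1)), sum(2^(inside - 1))))
  }
  sort(res)
}

candidate_keys <- function(cands)
  sort(vapply(cands, function(cd) paste(cd$boundary_bits, cd$in_bits), ""))

# random connected multigraph on k faces: spanning tree plus extras
random_multigraph <- function(k, max_extra = 4) {
  perm <- sample(k)
  tree <- cbind(perm[-1],
                perm[vapply(2:k, function(i) sample(i - 1, 1), integer(1))])
  ap <- t(utils::combn(k, 2))
  nextra <- sample(0:max_extra, 1)
  extra <- ap[sample(nrow(ap), min(nextra, nrow(ap)), replace = TRUE), ,
              drop = FALSE]
  pairs <- rbind(tree, extra)
  cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
}

# majority-mapping purity of predicted leaves against generator labels
leaf_purity <- function(pred, truth) {
  tab <- table(pred, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}

# events drawn uniformly from k well-separated Gaussian bumps laid out on a
# circle (used for random cluster-graph generation)
random_blob_events <- function(k, n = 4000, sd = 0.04) {
  ang <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)] +
    stats::runif(1, 0, 2 * pi)
  cx <- 0.5 + 0.28 * cos(ang); cy <- 0.5 + 0.28 * sin(ang)
  comp <- sample.int(k, n, replace = TRUE)
  x <- pmin(pmax(stats::rnorm(n, cx[comp], sd), 0), 1)
  y <- pmin(pmax(stats::rnorm(n, cy[comp], sd), 0), 1)
  list(x = x, y = y, comp = comp)
}
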