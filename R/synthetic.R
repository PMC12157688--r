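#' Synthetic mixture specification
#'
#' Describes a D-dimensional mixture of near-normal populations on the unit
#' hypercube with known component labels, emulating transformed cytometry
#' data: positive populations are truncated multivariate normals;
#' `mass_like` style additionally replaces designated negative dimensions
#' by a point mass at zero plus an exponential tail mapped into the bottom
#' of the scale.
#'
#' @param components list of `list(weight, mean, cov)`; weights must sum to
#'   1, means lie in (0, 1), covariances be positive definite. `cov` may be
#'   a single number (isotropic standard deviation, squared internally), a
#'   vector of per-dimension standard deviations, or a full matrix.
#' @param n number of events.
#' @param style `"gaussian"` or `"mass_like"`.
#' @param seed integer seed; generation is reproducible.
#' @param negative_dims (mass_like) dimensions drawn as zero-inflated
#'   exponential instead of normal.
#' @param zero_fraction,tail_scale (mass_like) fraction of exact zeros and
#'   the exponential tail scale on the transformed axis.
#' @return a `mixture_spec`.
#' @export
mixture_spec <- function(components, n, style = c("gaussian", "mass_like"),
                         seed = 1L, negative_dims = integer(0),
                         zero_fraction = 0.3, tail_scale = 0.05) {
  style <- match.arg(style)
  D <- length(components[[1]]$mean)
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  comps <- lapply(components, function(cp) {
    stopifnot(length(cp$mean) == D)
    if (any(cp$mean <= 0 | cp$mean >= 1))
      stop("component means must lie strictly inside (0, 1)")
    cv <- cp$cov
    if (is.null(dim(cv))) {
      if (length(cv) == 1) cv <- rep(cv, D)
      cv <- diag(cv^2, D)
    }
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("component covariance must be positive definite")
    list(weight = cp$weight, mean = cp$mean, cov = cv)
  })
  structure(list(D = D, components = comps, n = as.integer(n),
                 style = style, seed = as.integer(seed),
                 negative_dims = as.integer(negative_dims),
                 zero_fraction = zero_fraction, tail_scale = tail_scale),
            class = "mixture_spec")
}

# multivariate normal draws truncated to [0,1]^D by rejection (resampling,
# not clipping, so components stay near-normal on the cube)
rmvnorm_trunc <- function(n, mean, cov) {
  D <- length(mean)
  R <- chol(cov)
  out <- matrix(NA_real_, 0, D)
  tries <- 0L
  while (nrow(out) < n) {
    m <- max(n - nrow(out), 16L)
    z <- matrix(stats::rnorm(m * D), m, D) %*% R
    z <- sweep(z, 2, mean, "+")
    ok <- rowSums(z < 0 | z > 1) == 0
    out <- rbind(out, z[ok, , drop = FALSE])
    tries <- tries + 1L
    if (tries > 1000L)
      stop("infeasible truncation: component mean too far outside [0,1]")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic event matrix with known labels
#'
#' @param spec a [mixture_spec()].
#' @return list with `events` (an [epp_events]) and `labels` (true
#'   component index per event).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  w <- vapply(spec$components, `[[`, numeric(1), "weight")
  counts <- as.vector(stats::rmultinom(1, spec$n, w))
  vals <- matrix(NA_real_, spec$n, spec$D)
  labels <- integer(spec$n)
  at <- 0L
  for (k in seq_along(spec$components)) {
    if (counts[k] == 0L) next
    cp <- spec$components[[k]]
    rows <- at + seq_len(counts[k])
    vals[rows, ] <- rmvnorm_trunc(counts[k], cp$mean, cp$cov)
    labels[rows] <- k
    at <- at + counts[k]
  }
  if (spec$style == "mass_like" && length(spec$negative_dims)) {
    for (d in spec$negative_dims) {
      z <- stats::runif(spec$n) < spec$zero_fraction
      tail <- stats::rexp(spec$n, rate = 1 / spec$tail_scale)
      vals[, d] <- ifelse(z, 0, pmin(tail, 1))
    }
  }
  perm <- sample.int(spec$n)
  list(events = epp_events(vals[perm, , drop = FALSE],
                           paste0("M", seq_len(spec$D))),
       labels = labels[perm])
}

#' Canonical synthetic fixtures
#'
#' Named mixture specifications used across the test-suite and the
#' worked examples. Constants are versioned here; changing them is a
#' breaking test change.
#'
#' * `one_blob` - a single Gaussian component (no split expected).
#' * `two_blobs` - two components 0.4 apart at SD 0.03 (> 8 SD).
#' * `triangle_blobs` - three mutually adjacent components.
#' * `chain_blobs` - three collinear components (ends not adjacent).
#' * `four_grid` - four components at (0.3, 0.3), (0.3, 0.7), (0.7, 0.3),
#'   (0.7, 0.7), SD 0.03.
#' * `tiny_plus_overlap` - a 2% well-separated satellite plus two broadly
#'   overlapping major components.
#' * `pair13_only` - D = 3; dimensions 1 and 3 bimodal, dimension 2 an
#'   uninformative N(0.5, 0.05^2) marginal.
#' * `many_spikes` - thirteen narrow spikes in three groups: too many
#'   modes at the default kernel width, three after widening.
#'
#' @param name fixture name.
#' @param n events (defaults per fixture).
#' @param seed integer seed.
#' @return a [mixture_spec()].
#' @export
fixture_library <- function(name = c("one_blob", "two_blobs",
                                     "triangle_blobs", "chain_blobs",
                                     "four_grid", "tiny_plus_overlap",
                                     "pair13_only", "many_spikes"),
                            n = NULL, seed = 1L) {
  name <- match.arg(name)
  comp <- function(w, m, s) list(weight = w, mean = m, cov = s)
  specs <- switch(name,
    one_blob = list(comp(1, c(0.5, 0.5), 0.05)),
    two_blobs = list(comp(0.5, c(0.3, 0.5), 0.03),
                     comp(0.5, c(0.7, 0.5), 0.03)),
    triangle_blobs = list(comp(1 / 3, c(0.3, 0.3), 0.03),
                          comp(1 / 3, c(0.7, 0.3), 0.03),
                          comp(1 / 3, c(0.5, 0.7), 0.03)),
    chain_blobs = list(comp(1 / 3, c(0.2, 0.5), 0.03),
                       comp(1 / 3, c(0.5, 0.5), 0.03),
                       comp(1 / 3, c(0.8, 0.5), 0.03)),
    four_grid = list(comp(0.25, c(0.3, 0.3), 0.03),
                     comp(0.25, c(0.3, 0.7), 0.03),
                     comp(0.25, c(0.7, 0.3), 0.03),
                     comp(0.25, c(0.7, 0.7), 0.03)),
    tiny_plus_overlap = list(comp(0.49, c(0.33, 0.5), 0.08),
                             comp(0.49, c(0.57, 0.5), 0.08),
                             comp(0.02, c(0.78, 0.5), 0.02)),
    pair13_only = list(
      list(weight = 0.5, mean = c(0.3, 0.5, 0.3), cov = c(0.03, 0.05, 0.03)),
      list(weight = 0.5, mean = c(0.7, 0.5, 0.7), cov = c(0.03, 0.05, 0.03))),
    many_spikes = {
      centers <- c(0.25, 0.5, 0.75)
      offs <- list(c(-0.06, -0.03, 0, 0.03, 0.06),
                   c(-0.045, -0.015, 0.015, 0.045),
                   c(-0.045, -0.015, 0.015, 0.045))
      out <- list()
      for (g in 1:3) for (o in offs[[g]])
        out[[length(out) + 1L]] <- comp(1 / 13, c(centers[g] + o, 0.5), 0.006)
      out
    })
  defaults <- c(one_blob = 10000, two_blobs = 20000, triangle_blobs = 30000,
                chain_blobs = 30000, four_grid = 40000,
                tiny_plus_overlap = 30000, pair13_only = 20000,
                many_spikes = 26000)
  mixture_spec(specs, n = if (is.null(n)) defaults[[name]] else n,
               seed = seed)
}
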