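#' Bilinear weight array for one dimension pair
#'
#' Each event distributes unit mass to the four grid nodes surrounding it,
#' proportionally to proximity (area binning), on a `grid_size` x
#' `grid_size` grid spanning the closed unit square (spacing
#' `1/(grid_size-1)`). Rows index the first (x) dimension.
#'
#' @param x,y event values in \[0, 1\], equal length.
#' @param grid_size nodes per axis (default 257 = 2^8 + 1).
#' @return numeric `grid_size` x `grid_size` matrix; total mass equals the
#'   number of events.
#' @export
compute_weights <- function(x, y, grid_size = 257L) {
  stopifnot(length(x) == length(y))
  G <- as.integer(grid_size)
  w <- numeric(G * G)
  n <- length(x)
  if (n == 0L) return(matrix(w, G, G))
  stopifnot(all(x >= 0 & x <= 1), all(y >= 0 & y <= 1))
  gx <- x * (G - 1); gy <- y * (G - 1)
  i0 <- pmin(floor(gx), G - 2); j0 <- pmin(floor(gy), G - 2)
  fx <- gx - i0; fy <- gy - j0
  acc <- function(w, idx, val) {
    s <- rowsum(val, idx)
    ui <- as.integer(rownames(s))
    w[ui] <- w[ui] + s[, 1]
    w
  }
  base <- i0 + 1 + j0 * G
  w <- acc(w, base,         (1 - fx) * (1 - fy))
  w <- acc(w, base + 1,     fx * (1 - fy))
  w <- acc(w, base + G,     (1 - fx) * fy)
  w <- acc(w, base + G + 1, fx * fy)
  matrix(w, G, G)
}

# Discrete 1-D Gaussian kernel on the circular even extension of the grid
# (length 2(G-1)), image-summed over enough periods that the wrap-around
# tail is negligible, and normalised to unit sum so smoothing conserves
# mass. `normalize = FALSE` keeps raw pdf samples scaled by the grid
# spacing (used for the squared-kernel variance pass).
gauss_kernel1d <- function(W, grid_size, normalize = TRUE) {
  G <- as.integer(grid_size)
  L <- 2L * (G - 1L)
  h <- 1 / (G - 1)
  t <- 0:(L - 1)
  k <- numeric(L)
  for (m in -4:4) k <- k + stats::dnorm((t + m * L) * h, sd = W)
  if (normalize) k / sum(k) else k * h
}

# separable smoothing of a G x G grid with per-axis circular kernels via FFT
# on the even (reflective) extension; exact up to FFT round-off
smooth_grid <- function(grid, kx, ky = kx) {
  G <- nrow(grid)
  L <- 2L * (G - 1L)
  pass <- function(M, k) {
    E <- rbind(M, M[(G - 1L):2L, , drop = FALSE])
    S <- Re(stats::mvfft(stats::mvfft(E) * stats::fft(k), inverse = TRUE)) / L
    S[1:G, , drop = FALSE]
  }
  t(pass(t(pass(grid, kx)), ky))
}

#' Gaussian kernel density estimate of a weight grid
#'
#' Smooths the bilinear weight array with a bivariate Gaussian of standard
#' deviation `W` (as a fraction of full scale) under reflective boundary
#' conditions, computed spectrally on the even extension of the grid (the
#' cosine-transform trick), and normalises to a probability density on the
#' unit square.
#'
#' @param weights weight matrix from [compute_weights()].
#' @param W kernel standard deviation, fraction of full scale (> 0).
#' @return density matrix (>= 0), same size as `weights`.
#' @export
kde_dct <- function(weights, W) {
  stopifnot(W > 0)
  G <- nrow(weights)
  n <- sum(weights)
  if (n == 0) return(weights)
  h <- 1 / (G - 1)
  k <- gauss_kernel1d(W, G)
  pmax(smooth_grid(weights, k) / (n * h^2), 0)
}

#' Squared-kernel companion grid for the merging test
#'
#' Smooths the weight array with the pointwise square of the same discrete
#' Gaussian kernel (a Gaussian of standard deviation `W/sqrt(2)`, rescaled),
#' giving the plug-in estimate of the pointwise sampling variance of the
#' density estimator, `Var f_hat(g) ~ (K^2 * w)(g) / n^2`, used to
#' standardise density dips in [dbm_merge()]. The squared-kernel pass at
#' width `2W` is, up to normalisation, the plain density pass at width
#' `W*sqrt(2)`, which is what makes kernel doubling cheap.
#'
#' @param weights weight matrix from [compute_weights()].
#' @param W kernel standard deviation of the *density* pass.
#' @return variance grid (density-squared units), same size as `weights`.
#' @export
kde_variance <- function(weights, W) {
  stopifnot(W > 0)
  G <- nrow(weights)
  n <- sum(weights)
  if (n == 0) return(weights)
  h <- 1 / (G - 1)
  ksq <- gauss_kernel1d(W, G, normalize = FALSE)^2
  pmax(smooth_grid(weights, ksq) / (n^2 * h^4), 0)
}

#' Density grid for one dimension pair
#'
#' Convenience wrapper binding the weight array, density, variance grid and
#' kernel width together.
#'
#' @param x,y event values in \[0, 1\].
#' @param W kernel standard deviation (fraction of full scale).
#' @param grid_size nodes per axis.
#' @return an object of class `epp_density`.
#' @export
density_grid <- function(x, y, W, grid_size = 257L) {
  weights <- compute_weights(x, y, grid_size)
  structure(list(grid_size = as.integer(grid_size), weights = weights,
                 density = kde_dct(weights, W),
                 variance_density = kde_variance(weights, W),
                 W = W, n_events = length(x)),
            class = "epp_density")
}
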