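#' Kullback-Leibler divergence of a sample from a parametric reference
#'
#' m-spacing estimator built from the order statistics and the reference
#' cumulative distribution function: with sorted values x_(1..n),
#' m = ceiling(sqrt(n)) and clamped indices j_lo = max(i-m, 1),
#' j_hi = min(i+m, n),
#' \deqn{\hat D = \frac{1}{n}\sum_i \log\frac{(j_{hi}-j_{lo})/n}
#'   {F(x_{(j_{hi})}) - F(x_{(j_{lo})})}}
#' which is a consistent estimator of KL(sample || reference) and tends to 0
#' when the sample is drawn from the reference. Degenerate spacings are
#' floored at machine epsilon.
#'
#' @param values numeric sample (sorted internally).
#' @param reference_cdf vectorised CDF, strictly increasing on the data
#'   range.
#' @return nonnegative divergence estimate (small negative estimator noise is
#'   clamped to 0); `NA` if `n < 20`.
#' @export
estimate_kld <- function(values, reference_cdf) {
  values <- sort(values[is.finite(values)])
  n <- length(values)
  if (n < 20) return(NA_real_)
  m <- ceiling(sqrt(n))
  i <- seq_len(n)
  j_lo <- pmax(i - m, 1L); j_hi <- pmin(i + m, n)
  dF <- pmax(reference_cdf(values[j_hi]) - reference_cdf(values[j_lo]),
             .Machine$double.eps)
  d <- mean(log(((j_hi - j_lo) / n) / dF))
  max(d, 0)
}

#' Qualify one dimension for gating
#'
#' A dimension is informative when its sample distribution diverges from the
#' uninformative references: a moment-matched normal (always) and, in mass
#' mode, an exponential fitted by the mean of the non-zero values (low mass
#' cytometry signals pile up at zero with a roughly exponential non-zero
#' tail). Uniform single-positive or single-negative stains look normal (or
#' exponential) and are skipped.
#'
#' @param values one dimension of transformed event data.
#' @param thresholds list with `normal` (default 0.04) and `exponential`
#'   (default 0.2) divergence thresholds.
#' @param mode `"fluorescence"` (normal test only) or `"mass"` (both tests).
#' @param exponential_test override the mode default (`NULL` = mass only).
#' @return list with `kld_normal`, `kld_exponential` (or `NA` when the test
#'   is disabled) and `qualified`.
#' @export
qualify_dimension <- function(values,
                              thresholds = list(normal = 0.04, exponential = 0.2),
                              mode = c("fluorescence", "mass"),
                              exponential_test = NULL) {
  mode <- match.arg(mode)
  stopifnot(thresholds$normal > 0, thresholds$exponential > 0)
  if (is.null(exponential_test)) exponential_test <- (mode == "mass")
  values <- values[is.finite(values)]
  n <- length(values)
  out <- list(kld_normal = NA_real_, kld_exponential = NA_real_,
              qualified = FALSE)
  if (n < 20) {
    warning("too few events (", n, ") to judge dimension; left unqualified")
    return(out)
  }
  mu <- mean(values); sdev <- stats::sd(values)
  if (!is.finite(sdev) || sdev == 0) return(out)  # constant: degenerate normal
  out$kld_normal <- estimate_kld(values, function(q) stats::pnorm(q, mu, sdev))
  q_norm <- is.finite(out$kld_normal) && out$kld_normal >= thresholds$normal
  q_exp <- TRUE
  if (exponential_test) {
    nz <- values[values > 0]
    if (length(nz) >= 20) {
      rate <- 1 / mean(nz)
      out$kld_exponential <- estimate_kld(nz, function(q) stats::pexp(q, rate))
      q_exp <- is.finite(out$kld_exponential) &&
        out$kld_exponential >= thresholds$exponential
    }
  }
  out$qualified <- q_norm && q_exp
  out
}

# qualify all phenotyping dimensions of an event matrix
qualify_all <- function(events, cfg) {
  dims <- which(events$phenotyping_mask)
  res <- lapply(dims, function(d)
    c(list(dimension = d),
      suppressWarnings(qualify_dimension(
        events$values[, d],
        thresholds = list(normal = cfg$kld_threshold_normal,
                          exponential = cfg$kld_threshold_exponential),
        mode = cfg$cytometry, exponential_test = cfg$exponential_test))))
  res
}

#' Enumerate the dimension pairs to examine
#'
#' All pairs of qualified dimensions; if exactly one qualifies it is paired
#' with the unqualified dimension of highest divergence from normal; if none
#' qualify, the two dimensions with the highest divergence from normal are
#' paired — so at least the most promising pair is always tried. Ties on
#' divergence break toward the lower dimension index; output is ordered
#' ascending-index pairs.
#'
#' @param results list of per-dimension qualification results, each with
#'   `dimension`, `kld_normal`, `qualified`.
#' @return a two-column integer matrix of dimension index pairs.
#' @export
enumerate_pairs <- function(results) {
  if (length(results) < 2) stop("need at least two phenotyping dimensions")
  dims <- vapply(results, `[[`, integer(1), "dimension")
  qual <- vapply(results, function(r) isTRUE(r$qualified), logical(1))
  kldn <- vapply(results, function(r) {
    k <- r$kld_normal
    if (is.null(k) || !is.finite(k)) -Inf else k
  }, numeric(1))
  ord <- order(dims)
  dims <- dims[ord]; qual <- qual[ord]; kldn <- kldn[ord]
  q <- dims[qual]
  if (length(q) >= 2) {
    pairs <- t(utils::combn(q, 2))
  } else if (length(q) == 1) {
    uq <- which(!qual)
    best <- uq[order(-kldn[uq], dims[uq])][1]
    pairs <- matrix(sort(c(q, dims[best])), 1)
  } else {
    top2 <- order(-kldn, dims)[1:2]
    pairs <- matrix(sort(dims[top2]), 1)
  }
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j")
  pairs
}
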