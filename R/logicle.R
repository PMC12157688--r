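#' Logicle display transform
#'
#' The logicle (biexponential) scale is linear around data zero and
#' logarithmic at high signal. It is parameterised by the top-of-scale value
#' `T`, the total number of display decades `M`, the linearisation width `W`
#' in decades (`W = 0` gives an arcsinh-like scale, as used for mass
#' cytometry), and `A` additional negative display decades. The transform
#' maps raw intensity onto the unit display interval, with `x = T`
#' mapping to exactly 1 and data zero sitting at `(A + W) / (M + A)`.
#'
#' @param T top-of-scale raw value (> 0).
#' @param M total display decades (> 0), e.g. 4.5 for fluorescence or 4.3
#'   for mass cytometry.
#' @param W linearisation width in decades (>= 0).
#' @param A additional negative decades (default 0).
#' @return an object of class `logicle_spec` holding the solved biexponential
#'   coefficients.
#' @export
logicle_spec <- function(T = 262144, M = 4.5, W = 0.5, A = 0) {
  stopifnot(T > 0, M > 0, W >= 0, A >= 0)
  w  <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b  <- (M + A) * log(10)
  # d solves 2 ln(d/b) + w (b + d) = 0 on (0, b]; d = b when w = 0
  d <- if (w == 0) b else
    stats::uniroot(function(d) 2 * log(d / b) + w * (b + d),
                   lower = b * 1e-12, upper = b, tol = 1e-14)$root
  c_a  <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a * exp(-d * x1)
  a <- T / (exp(b) - mf_a - c_a * exp(-d))
  structure(list(T = T, M = M, W = W, A = A,
                 a = a, b = b, c = c_a * a, d = d, f = -mf_a * a,
                 w = w, x1 = x1),
            class = "logicle_spec")
}

# biexponential S(y): raw value at display position y (inverse transform),
# reflected below x1 so the scale is smooth and odd around data zero
logicle_inverse <- function(y, spec) {
  stopifnot(inherits(spec, "logicle_spec"))
  biexp <- function(u)
    spec$a * exp(spec$b * u) - spec$c * exp(-spec$d * u) + spec$f
  neg <- y < spec$x1
  out <- numeric(length(y))
  out[!neg] <- biexp(y[!neg])
  out[neg]  <- -biexp(2 * spec$x1 - y[neg])
  out
}

#' Apply (or invert) the logicle transform
#'
#' Maps raw intensities onto the unit display scale by numerically inverting
#' the biexponential. Strictly increasing; non-finite inputs propagate as
#' `NA` (to be censored downstream). Values beyond the display range map
#' outside \[0, 1\] and are likewise left for [censor()].
#'
#' @param x numeric vector of raw intensities.
#' @param spec a [logicle_spec].
#' @return display values, nominally on \[0, 1\].
#' @export
logicle_transform <- function(x, spec) {
  stopifnot(inherits(spec, "logicle_spec"))
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  if (!any(ok)) return(out)
  xv <- x[ok]
  # vectorised bisection: S is strictly increasing, so bracket then bisect
  lo <- rep(-0.5, length(xv)); hi <- rep(1.5, length(xv))
  while (any(bad <- logicle_inverse(lo, spec) > xv)) lo[bad] <- lo[bad] - 0.5
  while (any(bad <- logicle_inverse(hi, spec) < xv)) hi[bad] <- hi[bad] + 0.5
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    below <- logicle_inverse(mid, spec) < xv
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out[ok] <- (lo + hi) / 2
  out
}

#' Transform an event matrix onto the unit interval
#'
#' Applies per-dimension logicle transforms from a transform configuration.
#' Dimensions without a configured transform are left unchanged (assumed
#' already on \[0, 1\]).
#'
#' @param events raw [epp_events].
#' @param config a transform configuration as returned by
#'   [read_transform_config()], or a named list of [logicle_spec] objects.
#' @return transformed `epp_events` (not yet censored).
#' @export
transform_events <- function(events, config) {
  stopifnot(inherits(events, "epp_events"))
  specs <- if (inherits(config, "epp_transform_config")) config$specs else config
  v <- events$values
  for (nm in intersect(names(specs), events$marker_names))
    v[, nm] <- logicle_transform(v[, nm], specs[[nm]])
  epp_events(v, events$marker_names, events$phenotyping_mask, events$source_ids)
}

#' Read a transform/phenotyping configuration
#'
#' JSON schema: `{"dimensions": [{"name", "T", "M", "W", "A", "phenotyping"},
#' ...]}`. Dimensions omitted from the file keep their values untransformed
#' and default to non-phenotyping.
#'
#' @param path JSON file path.
#' @return an `epp_transform_config`: a list with `specs` (named
#'   [logicle_spec] list) and `phenotyping` (named logical).
#' @export
read_transform_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$dimensions)) stop("config has no 'dimensions' key")
  specs <- list(); phen <- logical(0)
  for (d in cfg$dimensions) {
    if (is.null(d$name)) stop("config dimension without a name")
    if (!is.null(d$T))
      specs[[d$name]] <- logicle_spec(T = d$T, M = d$M %||% 4.5,
                                      W = d$W %||% 0.5, A = d$A %||% 0)
    phen[d$name] <- isTRUE(d$phenotyping)
  }
  structure(list(specs = specs, phenotyping = phen),
            class = "epp_transform_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
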