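#' Ramer-Douglas-Peucker polyline simplification
#'
#' Keeps the endpoints and recursively retains the point of maximum
#' perpendicular deviation while it exceeds the tolerance; every dropped
#' point lies within `tolerance` (in scale units) of the simplified line.
#' Idempotent and never increases the point count.
#'
#' @param polyline numeric matrix with columns x, y (>= 2 points).
#' @param tolerance maximum allowed deviation, fraction of full scale.
#' @return the simplified polyline matrix.
#' @export
rdp_simplify <- function(polyline, tolerance = 0.01) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2, nrow(polyline) >= 2, tolerance >= 0)
  n <- nrow(polyline)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  recurse <- function(i, j) {
    if (j - i < 2) return()
    p <- polyline[i, ]; q <- polyline[j, ]
    seg <- q - p
    len <- sqrt(sum(seg^2))
    mid <- (i + 1):(j - 1)
    dx <- polyline[mid, 1] - p[1]; dy <- polyline[mid, 2] - p[2]
    dev <- if (len == 0) sqrt(dx^2 + dy^2)
           else abs(dx * seg[2] - dy * seg[1]) / len
    m <- which.max(dev)
    if (dev[m] > tolerance) {
      k <- mid[m]
      keep[k] <<- TRUE
      recurse(i, k); recurse(k, j)
    }
  }
  recurse(1, n)
  polyline[keep, , drop = FALSE]
}

# ridge-regularised covariance; falls back to the diagonal when still
# singular
regularize_cov <- function(sigma) {
  D <- nrow(sigma)
  ridge <- 1e-6 * sum(diag(sigma)) / D
  s <- sigma + diag(max(ridge, .Machine$double.eps), D)
  ok <- tryCatch({ solve(s); TRUE }, error = function(e) FALSE)
  if (!ok) {
    warning("singular covariance; falling back to diagonal")
    s <- diag(pmax(diag(sigma), .Machine$double.eps), D)
  }
  s
}

#' Mahalanobis distance from a population centre
#'
#' `sqrt((x - mu)' Sigma^{-1} (x - mu))` with a ridge-regularised
#' covariance (`1e-6 * trace/D` on the diagonal), falling back to the
#' diagonal covariance when still singular.
#'
#' @param x numeric matrix of events (rows) over the phenotyping
#'   dimensions.
#' @param mu centre vector.
#' @param sigma covariance matrix.
#' @return nonnegative distances, one per row.
#' @export
mahalanobis_distance <- function(x, mu, sigma) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(numeric(0))
  if (any(!is.finite(sigma)))
    return(rep(0, nrow(x)))  # degenerate population: distance is moot
  sqrt(pmax(stats::mahalanobis(x, mu, regularize_cov(sigma)), 0))
}

# recursive tree -> plain list following the JSON schema
tree_to_schema <- function(node) {
  if (node$type == "leaf")
    return(list(leaf_id = node$leaf_id, label = node$label,
                n = node$n))
  list(dims = as.list(node$dim_names),
       polygon = lapply(seq_len(nrow(node$polygon)),
                        function(i) as.list(unname(node$polygon[i, ]))),
       score = node$score, P = node$P,
       "in" = tree_to_schema(node$in_node),
       out = tree_to_schema(node$out_node))
}

#' Serialize a gating tree as JSON
#'
#' Schema (`epp_tree_v1`): an internal node is
#' `{"dims": [nameX, nameY], "polygon": [[x, y], ...], "score": s,
#' "P": p, "in": node, "out": node}` with the polygon in transformed
#' \[0, 1\] coordinates, simplified by [rdp_simplify()] at the configured
#' tolerance; a leaf is `{"leaf_id": id, "label": str, "n": count}`.
#' Scores are the approximate events-near-boundary estimates.
#'
#' @param fit a fitted [epp] object (or a bare tree node list).
#' @param path output file.
#' @export
write_tree_json <- function(fit, path) {
  tree <- if (inherits(fit, "epp")) fit$tree else fit
  obj <- list(version = "epp_tree_v1", tree = tree_to_schema(tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a gating tree JSON back into node lists
#'
#' Inverse of [write_tree_json()] for the topology, dimensions, polygons,
#' scores and leaf descriptions (grid-level side masks are not serialized).
#'
#' @param path JSON file.
#' @return the tree as nested node lists.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$version, "epp_tree_v1"))
    stop("not an epp_tree_v1 file: ", path)
  conv <- function(nd) {
    if (!is.null(nd$leaf_id))
      return(list(type = "leaf", leaf_id = as.integer(nd$leaf_id),
                  label = nd$label, n = as.integer(nd$n)))
    poly <- do.call(rbind, lapply(nd$polygon, function(p)
      c(x = as.numeric(p[[1]]), y = as.numeric(p[[2]]))))
    list(type = "split", dim_names = unlist(nd$dims), polygon = poly,
         score = as.numeric(nd$score), P = as.numeric(nd$P),
         in_node = conv(nd[["in"]]), out_node = conv(nd$out))
  }
  conv(obj$tree)
}

#' Write per-event assignments as CSV
#'
#' Header `event_id,leaf_id,mahalanobis`; one row per non-censored event in
#' input order. `event_id` is the original row index (stable through
#' censoring), `leaf_id` the algorithmic phenotype, and `mahalanobis` the
#' covariance-scaled distance of the event from its leaf centre over the
#' phenotyping dimensions.
#'
#' @param fit a fitted [epp] object.
#' @param path output file.
#' @export
write_assignments_csv <- function(fit, path) {
  stopifnot(inherits(fit, "epp"))
  df <- fit$assignments
  df$mahalanobis <- format(df$mahalanobis, digits = 17, trim = TRUE,
                           scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an assignments CSV
#'
#' @param path CSV written by [write_assignments_csv()].
#' @return data frame with `event_id`, `leaf_id`, `mahalanobis`.
#' @export
read_assignments_csv <- function(path) {
  utils::read.csv(path, colClasses = c(event_id = "integer",
                                       leaf_id = "integer",
                                       mahalanobis = "numeric"))
}
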