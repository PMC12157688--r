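#' Score a separation boundary
#'
#' Integrates the density along the boundary polyline and scales it to the
#' approximate number of events within a strip of half-width `W` along the
#' border: `score = n * 2W * sum(density * segment length)`. Lower is
#' better; a boundary through empty space scores 0.
#'
#' @param boundary_points grid-point indices of the boundary, chained end to
#'   end.
#' @param density density grid.
#' @param n events in the population.
#' @param W kernel standard deviation used for the grid.
#' @return approximate events-near-boundary score (>= 0).
#' @export
score_boundary <- function(boundary_points, density, n, W) {
  stopifnot(length(boundary_points) >= 1)
  G <- nrow(density)
  h <- 1 / (G - 1)
  d <- density[boundary_points]
  if (length(boundary_points) == 1L)
    return(n * 2 * W * d * h)
  r <- ((boundary_points - 1) %% G)
  cc <- ((boundary_points - 1) %/% G)
  seg <- sqrt(diff(r)^2 + diff(cc)^2) * h
  n * 2 * W * sum((d[-1] + d[-length(d)]) / 2 * seg)
}

#' Balance-weighted score
#'
#' Divides a boundary score by the balance factor `4P(1-P)`, which is 1 at
#' an even split and penalises lopsided ones; used in best-balance mode.
#'
#' @param score events-near-boundary score.
#' @param P fraction of population events on the "in" side, in (0, 1).
#' @return the balanced score.
#' @export
apply_balance <- function(score, P) {
  if (!is.finite(P) || P <= 0 || P >= 1)
    stop("degenerate split: P must lie strictly between 0 and 1")
  score / (4 * P * (1 - P))
}

# boundary grid points of a candidate: boundary cells touching (8-adjacency)
# at least one face on each side, chained into a polyline
candidate_boundary_points <- function(labels, in_faces, out_faces) {
  G <- nrow(labels)
  bp <- which(labels == -1L)
  keep <- vapply(bp, function(p) {
    nb <- labels[neighbors8(p, G)]
    any(nb %in% in_faces) && any(nb %in% out_faces)
  }, logical(1))
  pts <- bp[keep]
  if (length(pts) == 0L) return(integer(0))
  unlist(lapply(connected_components(pts, G),
                function(cmp) chain_points(cmp, G)), use.names = FALSE)
}

#' Analyze one dimension pair
#'
#' Runs the full per-pair pipeline at the current kernel width: weight
#' array, density and variance grids, noise floor, modal clustering,
#' cluster graph, density-based merging, dual-graph enumeration and
#' scoring. Whenever a stage signals that the structure is too complex
#' (more than `max_clusters` clusters or `max_edges` edges, or a
#' non-chainable boundary), the kernel width doubles and the pass restarts
#' from the weights, up to `W_max`.
#'
#' @param events censored, transformed [epp_events].
#' @param dims integer pair of (phenotyping) dimension indices.
#' @param cfg an [epp_config()].
#' @return the best candidate separation for this pair as a list (score,
#'   balanced score, `P`, boundary points and polyline, side masks, kernel
#'   width used, number of widenings), or `NULL` when the pair supports no
#'   separation.
#' @export
analyze_pair <- function(events, dims, cfg = epp_config()) {
  x <- events$values[, dims[1]]
  y <- events$values[, dims[2]]
  n <- length(x)
  G <- cfg$grid_size
  W <- cfg$W_init
  widenings <- 0L
  if (n <= cfg$sigma^2) return(NULL)  # can never clear the noise floor
  weights <- compute_weights(x, y, G)
  repeat {
    dens <- kde_dct(weights, W)
    vgrid <- kde_variance(weights, W)
    floor_ <- noise_floor(dens, weights, W, cfg$sigma)
    widen <- FALSE
    if (!is.finite(floor_)) {
      widen <- TRUE  # window too small to collect sigma^2 events yet
    } else {
      labeling <- modal_cluster(dens, floor_, cfg$max_clusters)
      if (labeling$widen) widen <- TRUE
      else if (labeling$n_clusters <= 1L) return(NULL)
      else {
        graph <- build_cluster_graph(labeling, dens, cfg$max_edges)
        if (graph$widen || length(graph$edges) == 0L) widen <- TRUE
        else {
          merged <- dbm_merge(graph, dens, vgrid, cfg$dbm_z,
                              cfg$dbm_both_modes)
          if (length(merged$faces) <= 1L) return(NULL)
          cand <- best_candidate(merged, dens, x, y, n, W, cfg)
          if (!is.null(cand)) {
            cand$dims <- dims
            cand$W <- W
            cand$widenings <- widenings
            return(cand)
          }
          return(NULL)
        }
      }
    }
    if (!widen) return(NULL)
    W <- W * 2
    widenings <- widenings + 1L
    if (W > cfg$W_max) return(NULL)
  }
}

# score every enumerated separation of a merged graph and keep the best
best_candidate <- function(merged, dens, x, y, n, W, cfg) {
  cands <- enumerate_separations(dualize(merged))
  if (length(cands) == 0L) return(NULL)
  labels <- merged$labels
  assigned <- assign_events(x, y, labels)
  counts <- tabulate(assigned, nbins = length(merged$faces))
  best <- NULL
  for (cd in cands) {
    in_faces <- bits_of(cd$in_bits) + 1L
    out_faces <- bits_of(cd$out_bits) + 1L
    P <- sum(counts[in_faces]) / n
    if (!is.finite(P) || P <= 0 || P >= 1) next
    bpts <- candidate_boundary_points(labels, in_faces, out_faces)
    if (length(bpts) == 0L) next
    sc <- score_boundary(bpts, dens, n, W)
    bal <- if (cfg$mode == "best_balance") apply_balance(sc, P) else sc
    if (is.null(best) || bal < best$balanced_score ||
        (bal == best$balanced_score &&
         cd$boundary_bits < best$boundary_bits)) {
      best <- list(score = sc, balanced_score = bal, P = P,
                   boundary_bits = cd$boundary_bits,
                   in_faces = in_faces, out_faces = out_faces,
                   boundary_points = bpts, labels = labels,
                   in_mask = matrix(resolve_boundary_labels(labels) %in%
                                      in_faces, nrow(labels)))
    }
  }
  best
}
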