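#' Noise floor for founding clusters
#'
#' Limits the effect of counting noise in sparse regions: no mode may be
#' founded below a density at which the local event support is too thin.
#' A window of `round((4W * (grid_size - 1))^2)` grid points (the number of
#' grid squares with area close to the +/-2W spot size of the kernel) is
#' slid along the grid points sorted ascending by density, from the lowest
#' density upward; the threshold is the density at the start of the first
#' window whose summed weights exceed `sigma^2` (with the default
#' `sigma = 3`, more than 9 events of mass are required).
#'
#' @param density density grid from [kde_dct()].
#' @param weights matching weight grid.
#' @param W kernel standard deviation (fraction of full scale).
#' @param sigma significance parameter (default 3).
#' @return the density threshold, or `Inf` when no window holds enough mass
#'   (no cluster can be founded; the caller widens the kernel or stops).
#' @export
noise_floor <- function(density, weights, W, sigma = 3) {
  stopifnot(sigma > 0)
  G <- nrow(density)
  NP <- length(density)
  L <- round((4 * W * (G - 1))^2)
  L <- max(1L, min(as.integer(L), NP))
  ord <- order(as.vector(density))
  cw <- cumsum(as.vector(weights)[ord])
  if (cw[NP] <= sigma^2) return(Inf)
  s <- cw[L:NP] - c(0, cw)[1:(NP - L + 1)]
  hit <- which(s > sigma^2)
  if (length(hit) == 0) return(Inf)
  density[ord[hit[1]]]
}

#' Modal clustering of a density grid
#'
#' Partitions the grid into basins of local density maxima by a
#' descending-density sweep (ties broken by (row, col) ascending), marking
#' points where two basins meet as boundary points, then classifies
#' below-floor points outward in contiguity layers to their nearest
#' significant cluster.
#'
#' @param density density grid.
#' @param noise_floor density threshold from [noise_floor()].
#' @param max_clusters raise the `widen` flag when more clusters than this
#'   are founded (default 12); the caller then doubles the kernel width and
#'   restarts from the weights.
#' @return an `epp_labeling`: list with `labels` (matrix: cluster id >= 1 or
#'   -1 for boundary), `modes` (per-cluster founding grid index),
#'   `n_clusters`, `noise_floor` and `widen`.
#' @export
modal_cluster <- function(density, noise_floor, max_clusters = 12L) {
  G <- nrow(density)
  dv <- as.vector(density)
  rr <- rep.int(seq_len(G), G); cc <- rep(seq_len(G), each = G)
  ord <- order(-dv, rr, cc)
  res <- .modal_sweep(dv, G, noise_floor, ord, as.integer(max_clusters))
  structure(list(labels = matrix(res$labels, G, G), modes = res$modes,
                 n_clusters = res$n_clusters, noise_floor = noise_floor,
                 widen = res$widen),
            class = "epp_labeling")
}

# 8-neighbourhood (1-based vector indices) of grid point p on a G x G grid
neighbors8 <- function(p, G) {
  r <- ((p - 1L) %% G) + 1L
  c <- ((p - 1L) %/% G) + 1L
  dr <- c(-1L, 1L, 0L, 0L, -1L, 1L, 1L, -1L)
  dc <- c(0L, 0L, -1L, 1L, 1L, 1L, -1L, -1L)
  rr <- r + dr; cc <- c + dc
  ok <- rr >= 1L & rr <= G & cc >= 1L & cc <= G
  rr[ok] + (cc[ok] - 1L) * G
}

# adjacent cluster ids (sorted) of each boundary point, as a list
boundary_adjacency <- function(labels) {
  G <- nrow(labels)
  bp <- which(labels == -1L)
  lapply(bp, function(p) {
    nb <- neighbors8(p, G)
    sort(unique(labels[nb][labels[nb] > 0L]))
  })
}

#' Build the plane cluster graph from a labelling
#'
#' Boundary points adjacent to exactly two clusters are grouped by their
#' cluster pair and chained (8-connected components) into edges; points
#' where three or more clusters meet are the graph vertices. Each edge
#' carries its maximum-density (saddle) point. The grid border closes the
#' regions; the outside is not a face.
#'
#' @param labeling an `epp_labeling` from [modal_cluster()].
#' @param density the density grid the labelling came from.
#' @param max_edges raise `widen` when more edges than this are found
#'   (default 32, the bit-vector capacity of the dual enumeration).
#' @return an `epp_cluster_graph`: list with `faces`, `modes` (data frame of
#'   cluster, grid point, density), `edges` (each with `a`, `b`, `points`
#'   chained in walk order, `saddle`, `saddle_point`), `vertices`, `labels`,
#'   and a `widen` flag.
#' @export
build_cluster_graph <- function(labeling, density, max_edges = 32L) {
  labels <- labeling$labels
  G <- nrow(labels)
  K <- labeling$n_clusters
  md <- data.frame(cluster = seq_len(K), point = labeling$modes,
                   density = density[labeling$modes])
  bp <- which(labels == -1L)
  adj <- boundary_adjacency(labels)
  nadj <- lengths(adj)
  vertices <- bp[nadj >= 3L]
  out <- list(faces = seq_len(K), modes = md, edges = list(),
              vertices = vertices, labels = labels, grid_size = G,
              widen = FALSE)
  class(out) <- "epp_cluster_graph"
  if (K < 2L || length(bp) == 0L) return(out)
  two <- nadj == 2L
  if (!any(two)) return(out)
  keys <- vapply(adj[two], paste, character(1), collapse = "-")
  pts <- bp[two]
  edges <- list()
  for (key in unique(keys)) {
    members <- pts[keys == key]
    pair <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    for (comp in connected_components(members, G)) {
      chain <- chain_points(comp, G)
      si <- which.max(density[chain])
      edges[[length(edges) + 1L]] <-
        list(a = pair[1], b = pair[2], points = chain,
             saddle = density[chain][si], saddle_point = chain[si])
    }
  }
  # deterministic edge order: by face pair, then first point
  o <- order(vapply(edges, `[[`, numeric(1), "a"),
             vapply(edges, `[[`, numeric(1), "b"),
             vapply(edges, function(e) min(e$points), numeric(1)))
  out$edges <- edges[o]
  if (length(out$edges) > max_edges) out$widen <- TRUE
  out
}

# 8-connected components of a set of grid points (indices); BFS on a hash
connected_components <- function(points, G) {
  if (length(points) == 0L) return(list())
  inset <- new.env(parent = emptyenv())
  for (p in points) assign(as.character(p), TRUE, inset)
  seen <- new.env(parent = emptyenv())
  comps <- list()
  for (p in sort(points)) {
    if (!is.null(seen[[as.character(p)]])) next
    comp <- integer(0); queue <- p
    seen[[as.character(p)]] <- TRUE
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      comp <- c(comp, q)
      for (nb in neighbors8(q, G)) {
        k <- as.character(nb)
        if (!is.null(inset[[k]]) && is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# order the points of one 8-connected chain end to end; branches (rare)
# are appended by nearest remaining point, which is adequate for scoring
# and polygon output
chain_points <- function(points, G) {
  n <- length(points)
  if (n <= 2L) return(points)
  rs <- ((points - 1L) %% G) + 1L
  cs <- ((points - 1L) %/% G) + 1L
  adjmat <- abs(outer(rs, rs, "-")) <= 1L & abs(outer(cs, cs, "-")) <= 1L
  diag(adjmat) <- FALSE
  deg <- rowSums(adjmat)
  start <- if (any(deg == 1L)) which(deg == 1L)[1] else 1L
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    path[i] <- cur
    visited[cur] <- TRUE
    nxt <- which(adjmat[cur, ] & !visited)
    if (length(nxt) == 0L) {
      rest <- which(!visited)
      if (length(rest) == 0L) break
      d <- (rs[rest] - rs[cur])^2 + (cs[rest] - cs[cur])^2
      nxt <- rest[which.min(d)]
    } else if (length(nxt) > 1L) {
      # prefer 4-neighbours to keep the walk tight
      man <- abs(rs[nxt] - rs[cur]) + abs(cs[nxt] - cs[cur])
      nxt <- nxt[order(man, nxt)][1]
    }
    cur <- nxt
  }
  points[path]
}

#' Assign events to clusters by grid-cell ownership
#'
#' Each event takes the label of its nearest grid node; events landing on a
#' boundary cell are assigned to the adjacent cluster with the lowest id
#' (deterministic; the boundary is one grid line wide).
#'
#' @param x,y event values in \[0, 1\].
#' @param labels label matrix (cluster ids and -1 boundary cells).
#' @return integer vector of cluster ids, one per event.
#' @export
assign_events <- function(x, y, labels) {
  resolved <- resolve_boundary_labels(labels)
  G <- nrow(labels)
  i <- pmin(pmax(round(x * (G - 1)), 0), G - 1) + 1
  j <- pmin(pmax(round(y * (G - 1)), 0), G - 1) + 1
  resolved[cbind(i, j)]
}

# replace boundary cells by the lowest adjacent cluster id; isolated
# leftovers (no cluster in the 8-neighbourhood) inherit iteratively
resolve_boundary_labels <- function(labels) {
  G <- nrow(labels)
  res <- labels
  repeat {
    bp <- which(res <= 0L)
    if (length(bp) == 0L) break
    changed <- FALSE
    for (p in bp) {
      nb <- res[neighbors8(p, G)]
      nb <- nb[nb > 0L]
      if (length(nb)) { res[p] <- min(nb); changed <- TRUE }
    }
    if (!changed) { res[res <= 0L] <- 1L; break }
  }
  res
}
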