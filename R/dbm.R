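#' Density-based merging of a cluster graph
#'
#' Removes edges whose density dip is not statistically significant and
#' merges the faces they separate. Edges (parallel edges between the same
#' face pair are spliced, their saddle recomputed as the maximum over the
#' combined chains) are processed in descending order of saddle density.
#' An edge is retained only when *both* modal densities exceed the saddle
#' density by `z` standard errors,
#' \deqn{t_i = (\hat f(m_i) - \hat f(s)) / \sqrt{\hat V(m_i) + \hat V(s)} > z,}
#' with the pointwise variance taken from the squared-kernel grid of
#' [kde_variance()]. On a removal the two faces merge (the merged face
#' keeps the higher-density mode) and processing restarts, until a fixed
#' point is reached.
#'
#' @param graph an `epp_cluster_graph` from [build_cluster_graph()].
#' @param density density grid.
#' @param variance_density matching variance grid.
#' @param z significance multiplier (default 3).
#' @param both_modes require the dip to be significant against both modes
#'   (default, conservative) or either one.
#' @return the merged `epp_cluster_graph`; `face_map` gives the original
#'   cluster id to merged face id mapping, and `labels` is relabelled
#'   accordingly. A single remaining face with no edges is a valid result
#'   meaning no separation in this pair.
#' @export
dbm_merge <- function(graph, density, variance_density, z = 3,
                      both_modes = TRUE) {
  stopifnot(inherits(graph, "epp_cluster_graph"), z > 0)
  K <- length(graph$faces)
  if (K == 0L || length(graph$edges) == 0L) return(graph)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # per-face representative mode (grid point); merged face keeps the
  # higher-density mode
  mode_pt <- graph$modes$point
  repeat {
    roots <- vapply(seq_len(K), find, integer(1))
    groups <- list()
    for (e in graph$edges) {
      ra <- roots[e$a]; rb <- roots[e$b]
      if (ra == rb) next
      key <- paste(min(ra, rb), max(ra, rb))
      g <- groups[[key]]
      if (is.null(g))
        groups[[key]] <- list(a = min(ra, rb), b = max(ra, rb),
                              points = e$points, saddle = e$saddle,
                              saddle_point = e$saddle_point)
      else {
        g$points <- c(g$points, e$points)
        if (e$saddle > g$saddle) { g$saddle <- e$saddle
                                   g$saddle_point <- e$saddle_point }
        groups[[key]] <- g
      }
    }
    if (length(groups) == 0L) break
    ord <- order(-vapply(groups, `[[`, numeric(1), "saddle"),
                 vapply(groups, `[[`, numeric(1), "a"),
                 vapply(groups, `[[`, numeric(1), "b"))
    removed <- FALSE
    for (g in groups[ord]) {
      fs <- density[g$saddle_point]
      vs <- variance_density[g$saddle_point]
      t_ab <- vapply(c(g$a, g$b), function(f) {
        mp <- mode_pt[f]
        (density[mp] - fs) / sqrt(variance_density[mp] + vs)
      }, numeric(1))
      ok <- if (both_modes) all(t_ab > z) else any(t_ab > z)
      if (!ok) {
        # merge: lower root wins the name, higher-density mode survives
        keep <- if (density[mode_pt[g$a]] >= density[mode_pt[g$b]])
          mode_pt[g$a] else mode_pt[g$b]
        parent[g$b] <- g$a
        mode_pt[g$a] <- keep
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  roots <- vapply(seq_len(K), find, integer(1))
  new_ids <- match(roots, sort(unique(roots)))
  faces <- sort(unique(new_ids))
  # rebuild the merged graph with relabelled faces and spliced edges
  merged_edges <- list()
  bykey <- list()
  for (e in graph$edges) {
    a <- new_ids[e$a]; b <- new_ids[e$b]
    if (a == b) next
    key <- paste(min(a, b), max(a, b))
    g <- bykey[[key]]
    if (is.null(g))
      bykey[[key]] <- list(a = min(a, b), b = max(a, b), points = e$points,
                           saddle = e$saddle, saddle_point = e$saddle_point)
    else {
      g$points <- c(g$points, e$points)
      if (e$saddle > g$saddle) { g$saddle <- e$saddle
                                 g$saddle_point <- e$saddle_point }
      bykey[[key]] <- g
    }
  }
  if (length(bykey)) {
    o <- order(vapply(bykey, `[[`, numeric(1), "a"),
               vapply(bykey, `[[`, numeric(1), "b"))
    merged_edges <- unname(bykey[o])
  }
  modes <- data.frame(cluster = faces,
                      point = mode_pt[sort(unique(roots))])
  modes$density <- density[modes$point]
  labels <- graph$labels
  pos <- labels > 0L
  labels[pos] <- new_ids[labels[pos]]
  out <- list(faces = faces, modes = modes, edges = merged_edges,
              vertices = graph$vertices, labels = labels,
              grid_size = graph$grid_size, widen = FALSE,
              face_map = new_ids)
  class(out) <- "epp_cluster_graph"
  out
}
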