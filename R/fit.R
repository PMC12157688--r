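#' Fit an EPP gating tree
#'
#' The main entry point: recursively gates an event matrix by exhaustive
#' projection pursuit. Per population, each phenotyping dimension is
#' qualified by its Kullback-Leibler divergence from an uninformative
#' reference, all qualified dimension pairs are examined with
#' [analyze_pair()], the best-scoring candidate separation divides the
#' population in two, and the procedure recurses into both sides until no
#' statistically supported split remains. The final populations (leaves)
#' are the algorithmic phenotypes.
#'
#' Input values must already be compensated/unmixed and display-transformed
#' onto the unit interval (see [transform_events()]); events with any
#' phenotyping value outside \[0, 1\] are censored before gating.
#'
#' @param x an [epp_events], or a numeric matrix / data frame of
#'   transformed intensities (events in rows).
#' @param markers optional character vector restricting the phenotyping
#'   dimensions to these markers.
#' @param config an [epp_config()]; the `mode` and `cytometry` arguments
#'   are convenience overrides of the corresponding config fields.
#' @param mode `"best_balance"` or `"best_separation"`.
#' @param cytometry `"fluorescence"` or `"mass"`.
#' @param verbose log per-population progress to stderr.
#' @return an object of class `epp`: the gating tree, the censored events,
#'   per-event leaf assignments with Mahalanobis distances, and the
#'   configuration.
#' @seealso [write_tree_json()], [write_assignments_csv()],
#'   [predict.epp()], [plot.epp()]
#' @export
epp <- function(x, markers = NULL, config = epp_config(), mode = NULL,
                cytometry = NULL, verbose = FALSE) {
  if (!inherits(x, "epp_events")) x <- epp_events(x)
  if (!is.null(mode) || !is.null(cytometry)) {
    if (!is.null(mode)) config$mode <- match.arg(mode, c("best_balance",
                                                         "best_separation"))
    if (!is.null(cytometry)) {
      config$cytometry <- match.arg(cytometry, c("fluorescence", "mass"))
    }
  }
  if (!is.null(markers)) {
    if (!all(markers %in% x$marker_names))
      stop("unknown marker(s): ",
           paste(setdiff(markers, x$marker_names), collapse = ", "))
    x$phenotyping_mask <- x$marker_names %in% markers
  }
  if (sum(x$phenotyping_mask) < 2)
    stop("need at least two phenotyping dimensions")
  ev <- censor(x)
  n_censored <- attr(ev, "n_censored")
  N <- nrow(ev$values)
  leaf_id <- 0L
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }

  recurse <- function(rows, depth, path_tokens) {
    n <- length(rows)
    make_leaf <- function() {
      leaf_id <<- leaf_id + 1L
      label <- if (length(path_tokens)) {
        # one token per marker, the most recent (deepest) split wins
        mk <- sub("[+-]$", "", path_tokens)
        paste(path_tokens[!duplicated(mk, fromLast = TRUE)], collapse = "")
      } else "all"
      list(type = "leaf", leaf_id = leaf_id, label = label, n = n,
           rows = rows)
    }
    if (n < max(cfg_min_abs, ceiling(cfg_min_rel * N)) || n < 2L)
      return(make_leaf())
    sub <- events_subset(ev, rows)
    qual <- qualify_all(sub, config)
    pairs <- enumerate_pairs(qual)
    say("population n=%d depth=%d: %d/%d dims qualified, %d pair(s)",
        n, depth, sum(vapply(qual, function(r) isTRUE(r$qualified),
                             logical(1))), length(qual), nrow(pairs))
    best <- NULL
    for (pi in seq_len(nrow(pairs))) {
      dims <- pairs[pi, ]
      cand <- analyze_pair(sub, dims, config)
      if (is.null(cand)) next
      if (cand$widenings > 0)
        say("  pair (%s, %s): widened kernel %d time(s) to W=%g",
            ev$marker_names[dims[1]], ev$marker_names[dims[2]],
            cand$widenings, cand$W)
      if (is.null(best) || cand$balanced_score < best$balanced_score ||
          (cand$balanced_score == best$balanced_score &&
           (dims[1] < best$dims[1] ||
            (dims[1] == best$dims[1] && dims[2] < best$dims[2])))) {
        best <- cand
      }
    }
    if (is.null(best)) {
      say("  no supported split: leaf")
      return(make_leaf())
    }
    G <- nrow(best$in_mask)
    gx <- pmin(pmax(round(sub$values[, best$dims[1]] * (G - 1)), 0),
               G - 1) + 1
    gy <- pmin(pmax(round(sub$values[, best$dims[2]] * (G - 1)), 0),
               G - 1) + 1
    inside <- best$in_mask[cbind(gx, gy)]
    if (!any(inside) || all(inside)) return(make_leaf())
    say("  split on (%s, %s): score=%.2f P=%.3f",
        ev$marker_names[best$dims[1]], ev$marker_names[best$dims[2]],
        best$score, best$P)
    tok <- split_tokens(sub, rows[inside], rows[!inside], best$dims, ev)
    node <- list(type = "split", n = n, dims = unname(best$dims),
                 dim_names = ev$marker_names[best$dims],
                 score = best$score, balanced_score = best$balanced_score,
                 P = best$P, W = best$W,
                 polyline = grid_polyline(best$boundary_points, G),
                 in_mask = best$in_mask)
    node$polygon <- rdp_simplify(node$polyline, config$rdp_tolerance)
    node$in_node <- recurse(rows[inside], depth + 1L,
                            c(path_tokens, tok$in_tok))
    node$out_node <- recurse(rows[!inside], depth + 1L,
                             c(path_tokens, tok$out_tok))
    node
  }

  cfg_min_abs <- max(config$min_events_abs, 1L)
  cfg_min_rel <- config$min_events_rel
  tree <- if (N == 0L) list(type = "leaf", leaf_id = 1L, label = "all",
                            n = 0L, rows = integer(0))
          else recurse(seq_len(N), 0L, character(0))
  fit <- structure(list(tree = tree, events = ev, config = config,
                        n_censored = n_censored, log = log_lines,
                        call = match.call()),
                   class = "epp")
  fit$assignments <- tree_assignments(fit)
  fit
}

# +/- tokens for the child labels: the split's own dimensions, signed by
# which side has the higher mean; markers whose sibling means barely
# differ are not annotated (at least the strongest one always is)
split_tokens <- function(sub, in_rows, out_rows, dims, ev) {
  vin <- ev$values[in_rows, dims, drop = FALSE]
  vout <- ev$values[out_rows, dims, drop = FALSE]
  dmean <- colMeans(vin) - colMeans(vout)
  keep <- order(-abs(dmean))[seq_len(min(2L, length(dims)))]
  keep <- keep[abs(dmean[keep]) >= 0.05 | keep == keep[1]]
  nm <- ev$marker_names[dims]
  list(in_tok = paste0(nm[keep], ifelse(dmean[keep] >= 0, "+", "-")),
       out_tok = paste0(nm[keep], ifelse(dmean[keep] >= 0, "-", "+")))
}

# grid point indices -> coordinates on the unit square (x = row axis)
grid_polyline <- function(points, G) {
  cbind(x = ((points - 1) %% G) / (G - 1),
        y = ((points - 1) %/% G) / (G - 1))
}

# collect leaves of a tree (in leaf_id order)
tree_leaves <- function(node) {
  if (node$type == "leaf") return(list(node))
  c(tree_leaves(node$in_node), tree_leaves(node$out_node))
}

# per-event leaf ids and Mahalanobis distances from the leaf centre
tree_assignments <- function(fit) {
  leaves <- tree_leaves(fit$tree)
  N <- nrow(fit$events$values)
  leaf <- integer(N)
  maha <- numeric(N)
  pd <- which(fit$events$phenotyping_mask)
  for (lf in leaves) {
    leaf[lf$rows] <- lf$leaf_id
    v <- fit$events$values[lf$rows, pd, drop = FALSE]
    maha[lf$rows] <- mahalanobis_distance(v, colMeans(v), stats::cov(v))
  }
  data.frame(event_id = fit$events$source_ids, leaf_id = leaf,
             mahalanobis = maha)
}

#' @export
print.epp <- function(x, ...) {
  leaves <- tree_leaves(x$tree)
  cat(sprintf(paste0("EPP gating tree: %d events (%d censored), ",
                     "%d leaves, mode=%s\n"),
              nrow(x$events$values), x$n_censored, length(leaves),
              x$config$mode))
  invisible(x)
}

#' @export
summary.epp <- function(object, ...) {
  leaves <- tree_leaves(object$tree)
  N <- nrow(object$events$values)
  df <- data.frame(
    leaf_id = vapply(leaves, `[[`, integer(1), "leaf_id"),
    label = vapply(leaves, `[[`, character(1), "label"),
    n = vapply(leaves, function(l) as.integer(l$n), integer(1)))
  df$fraction <- if (N > 0) df$n / N else NA_real_
  df <- df[order(df$leaf_id), ]
  rownames(df) <- NULL
  structure(list(leaves = df, n_events = N, n_censored = object$n_censored,
                 mode = object$config$mode),
            class = "summary.epp")
}

#' @export
print.summary.epp <- function(x, ...) {
  cat(sprintf("EPP gating result (%s): %d events, %d censored, %d leaves\n",
              x$mode, x$n_events, x$n_censored, nrow(x$leaves)))
  print(x$leaves, digits = 3)
  invisible(x)
}

#' Route new events down a fitted gating tree
#'
#' @param object a fitted `epp` object.
#' @param newdata matrix/data frame (or [epp_events]) of *transformed*
#'   values with the same columns as the training data; defaults to the
#'   training events.
#' @param ... unused.
#' @return integer vector of leaf ids (`NA` for events censored on input).
#' @export
predict.epp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$assignments$leaf_id)
  nd <- if (inherits(newdata, "epp_events")) newdata
        else epp_events(as.matrix(newdata),
                        phenotyping_mask = object$events$phenotyping_mask)
  out <- rep(NA_integer_, nrow(nd$values))
  v <- nd$values[, nd$phenotyping_mask, drop = FALSE]
  ok <- rowSums(!is.finite(v) | v < 0 | v > 1) == 0
  route <- function(node, rows) {
    if (length(rows) == 0L) return()
    if (node$type == "leaf") { out[rows] <<- node$leaf_id; return() }
    G <- nrow(node$in_mask)
    gx <- pmin(pmax(round(nd$values[rows, node$dims[1]] * (G - 1)), 0),
               G - 1) + 1
    gy <- pmin(pmax(round(nd$values[rows, node$dims[2]] * (G - 1)), 0),
               G - 1) + 1
    inside <- node$in_mask[cbind(gx, gy)]
    route(node$in_node, rows[inside])
    route(node$out_node, rows[!inside])
  }
  route(object$tree, which(ok))
  out
}

#' Plot one split of a fitted gating tree
#'
#' Draws the two-dimensional projection of an internal node with its events
#' (coloured by side) and the separating boundary.
#'
#' @param x a fitted `epp` object.
#' @param node which internal node to draw, as a vector of `"in"`/`"out"`
#'   steps from the root (default: the root split).
#' @param max_points subsample cap for drawing.
#' @param ... passed to [graphics::plot()].
#' @export
plot.epp <- function(x, node = character(0), max_points = 20000, ...) {
  nd <- x$tree
  rows <- seq_len(nrow(x$events$values))
  for (step in node) {
    stopifnot(nd$type == "split", step %in% c("in", "out"))
    leaves_in <- unlist(lapply(tree_leaves(nd$in_node), `[[`, "rows"))
    rows <- if (step == "in") intersect(rows, leaves_in)
            else setdiff(rows, leaves_in)
    nd <- if (step == "in") nd$in_node else nd$out_node
  }
  if (nd$type != "split") stop("selected node is a leaf; nothing to draw")
  v <- x$events$values[rows, nd$dims, drop = FALSE]
  if (length(rows) > max_points) {
    keep <- seq(1, length(rows), length.out = max_points)
    v <- v[keep, , drop = FALSE]
  }
  G <- nrow(nd$in_mask)
  gi <- pmin(pmax(round(v[, 1] * (G - 1)), 0), G - 1) + 1
  gj <- pmin(pmax(round(v[, 2] * (G - 1)), 0), G - 1) + 1
  side <- nd$in_mask[cbind(gi, gj)]
  graphics::plot(v[, 1], v[, 2], pch = ".", cex = 2,
                 col = ifelse(side, "#1f77b4", "#d62728"),
                 xlab = nd$dim_names[1], ylab = nd$dim_names[2],
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::lines(nd$polygon[, 1], nd$polygon[, 2], lwd = 2)
  graphics::title(sprintf("split %s x %s  (score %.1f, P %.2f)",
                          nd$dim_names[1], nd$dim_names[2], nd$score, nd$P))
  invisible(x)
}
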