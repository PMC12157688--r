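#' Match table between two labelings
#'
#' Counts shared events between every population of labeling A (rows) and
#' labeling B (columns) over the same event universe.
#'
#' @param labels_a,labels_b per-event population ids (equal length);
#'   `NA` marks events unlabeled in that scheme.
#' @return an `epp_match_table`: list with `counts` (matrix), `row_totals`,
#'   `col_totals`, and per-row `dominant` column index (argmax counts).
#' @export
match_table <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must cover the same events")
  ra <- sort(unique(labels_a[!is.na(labels_a)]))
  rb <- sort(unique(labels_b[!is.na(labels_b)]))
  counts <- matrix(0L, length(ra), length(rb),
                   dimnames = list(as.character(ra), as.character(rb)))
  both <- !is.na(labels_a) & !is.na(labels_b)
  if (any(both)) {
    tab <- table(factor(labels_a[both], levels = ra),
                 factor(labels_b[both], levels = rb))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts,
                 row_totals = as.integer(table(factor(labels_a, levels = ra))),
                 col_totals = as.integer(table(factor(labels_b, levels = rb))),
                 dominant = if (ncol(counts)) apply(counts, 1, which.max)
                            else integer(0)),
            class = "epp_match_table")
}

#' @export
print.epp_match_table <- function(x, ...) {
  cat("match table:", nrow(x$counts), "x", ncol(x$counts), "populations\n")
  print(x$counts)
  invisible(x)
}

#' Jaccard similarity of two event sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty (by
#' convention).
#'
#' @param set_a,set_b vectors of event ids.
#' @return coefficient in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Central similarity of two event sets
#'
#' Restricts the Jaccard comparison to the central cores of the two
#' populations: within each set independently, the `trim` fraction (default
#' 80%) of its events with the smallest Mahalanobis distance from that
#' set's own mean (per-set covariance over the phenotyping dimensions) is
#' kept, and the Jaccard coefficient is computed between the two sets
#' intersected with the union of the kept cores. Discrepancies confined to
#' the outer tails therefore do not count against the match.
#'
#' @param set_a,set_b vectors of event ids (values of
#'   `events$source_ids`).
#' @param events the shared [epp_events] universe.
#' @param trim central fraction kept per set (default 0.8).
#' @return coefficient in \[0, 1\].
#' @export
central_similarity <- function(set_a, set_b, events, trim = 0.8) {
  stopifnot(inherits(events, "epp_events"), trim > 0, trim <= 1)
  pd <- which(events$phenotyping_mask)
  core <- function(ids) {
    rows <- match(unique(ids), events$source_ids)
    rows <- rows[!is.na(rows)]
    if (length(rows) < length(pd) + 2) return(events$source_ids[rows])
    v <- events$values[rows, pd, drop = FALSE]
    d <- mahalanobis_distance(v, colMeans(v), stats::cov(v))
    keep <- rank(d, ties.method = "first") <= ceiling(trim * length(rows))
    events$source_ids[rows[keep]]
  }
  kept <- union(core(set_a), core(set_b))
  jaccard(intersect(set_a, kept), intersect(set_b, kept))
}
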