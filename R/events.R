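#' Event matrix container
#'
#' An `epp_events` object holds event-level cytometry data: an N x D numeric
#' matrix of intensities (raw or transformed onto the unit interval), the
#' marker names, a logical mask of the dimensions that take part in
#' phenotyping, and the original row indices, which stay stable through
#' censoring.
#'
#' @param values numeric matrix (events in rows, markers in columns) or a
#'   data frame of numeric columns.
#' @param marker_names character vector of unique column labels; defaults to
#'   the column names of `values`.
#' @param phenotyping_mask logical vector marking the dimensions eligible for
#'   gating; defaults to all `TRUE`.
#' @param source_ids integer vector of original row indices.
#' @return an object of class `epp_events`.
#' @export
epp_events <- function(values, marker_names = colnames(values),
                       phenotyping_mask = NULL, source_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(marker_names))
    marker_names <- paste0("M", seq_len(ncol(values)))
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(values))
    stop("marker_names length must equal the number of columns")
  if (anyDuplicated(marker_names))
    stop("duplicate marker names: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  if (is.null(phenotyping_mask)) phenotyping_mask <- rep(TRUE, ncol(values))
  phenotyping_mask <- as.logical(phenotyping_mask)
  if (length(phenotyping_mask) != ncol(values))
    stop("phenotyping_mask length must equal the number of columns")
  if (is.null(source_ids)) source_ids <- seq_len(nrow(values))
  colnames(values) <- marker_names
  structure(list(values = values, marker_names = marker_names,
                 phenotyping_mask = phenotyping_mask,
                 source_ids = as.integer(source_ids)),
            class = "epp_events")
}

#' @export
print.epp_events <- function(x, ...) {
  cat(sprintf("epp_events: %d events x %d markers (%d phenotyping)\n",
              nrow(x$values), ncol(x$values), sum(x$phenotyping_mask)))
  cat("markers:", paste(x$marker_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epp_events <- function(x) dim(x$values)

# subset rows, keeping source ids aligned
events_subset <- function(events, idx) {
  epp_events(events$values[idx, , drop = FALSE], events$marker_names,
             events$phenotyping_mask, events$source_ids[idx])
}

#' Censor out-of-range events
#'
#' Removes every event having any phenotyping-dimension value outside the
#' closed interval \[0, 1\] (or a non-finite value there). Non-phenotyping
#' columns are carried through untouched. Original row indices of the
#' survivors are preserved in `source_ids`. Idempotent.
#'
#' @param events an [epp_events] object with transformed values.
#' @param verbose emit a message with the censored count.
#' @return the censored `epp_events`; the number removed is in
#'   `attr(, "n_censored")`.
#' @export
censor <- function(events, verbose = FALSE) {
  stopifnot(inherits(events, "epp_events"))
  v <- events$values[, events$phenotyping_mask, drop = FALSE]
  if (nrow(v) == 0L || ncol(v) == 0L) {
    out <- events
    attr(out, "n_censored") <- 0L
    return(out)
  }
  ok <- rowSums(!is.finite(v) | v < 0 | v > 1) == 0L
  out <- events_subset(events, which(ok))
  attr(out, "n_censored") <- sum(!ok)
  if (verbose && any(!ok))
    message(sum(!ok), " event(s) censored (outside [0, 1])")
  out
}
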