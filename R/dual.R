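# Bit-vector helpers. Faces and cluster-graph edges are bit positions
# (0-based); sets of them are exact integer-valued doubles (bits 0..52, of
# which 32 are used), so graph surgery is pure arithmetic. Every union
# formed here is of disjoint sets, so bitwise OR is plain addition.
bit <- function(i) 2^i
bits_of <- function(x) {
  b <- integer(0); i <- 0L
  while (x > 0) {
    if (x %% 2 >= 1) b <- c(b, i)
    x <- x %/% 2; i <- i + 1L
  }
  b
}
min_bit <- function(x) bits_of(x)[1]
max_bit <- function(x) { b <- bits_of(x); b[length(b)] }

#' Dual graph of a cluster graph
#'
#' One dual node per face (a bitset with that face's bit), one dual edge
#' per shared boundary between a pair of faces. Parallel cluster-graph
#' edges between the same face pair are represented as one dual edge whose
#' edge bitset is the OR of their bits: a separation boundary between two
#' face sets always consists of *all* crossing edges, never a proper subset.
#'
#' @param graph an `epp_cluster_graph` (typically after [dbm_merge()]).
#' @return an `epp_dual`: list with `nodes` (integer face bitsets) and
#'   `edges` (data frame of node indices `a`, `b` and edge bitset `bits`).
#' @export
dualize <- function(graph) {
  stopifnot(inherits(graph, "epp_cluster_graph"))
  k <- length(graph$faces)
  if (length(graph$edges) > 32L)
    stop("more than 32 cluster-graph edges; widen the kernel")
  nodes <- vapply(seq_len(k), function(i) bit(i - 1L), numeric(1))
  a <- integer(0); b <- integer(0); bits <- numeric(0)
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    key <- which(a == min(e$a, e$b) & b == max(e$a, e$b))
    if (length(key)) {
      bits[key] <- bits[key] + bit(i - 1L)
    } else {
      a <- c(a, min(e$a, e$b)); b <- c(b, max(e$a, e$b))
      bits <- c(bits, bit(i - 1L))
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(a = a, b = b, bits = bits),
                 n_cluster_edges = length(graph$edges)),
            class = "epp_dual")
}

#' Enumerate all two-part separations of a cluster graph
#'
#' Stack-driven search over simplified dual graphs: pop a graph; if exactly
#' one dual edge remains, its edge bitset is the boundary of a candidate
#' separation and its two endpoint node bitsets are the two sides;
#' otherwise each dual edge extending the removal order is removed in turn
#' (its endpoints merged, dual edges that become parallel merged by bitwise
#' OR) and the simplified graph pushed. Every emitted candidate is a
#' continuous boundary separating two contiguous face sets, and each
#' distinct separation is emitted once.
#'
#' @param dual an `epp_dual` from [dualize()].
#' @return list of candidates, each with `boundary_bits` (cluster-edge
#'   bitset), `in_bits`/`out_bits` (face bitsets; the "in" side contains the
#'   lowest-numbered face), ordered lexicographically by boundary bitset.
#' @export
enumerate_separations <- function(dual) {
  stopifnot(inherits(dual, "epp_dual"))
  if (nrow(dual$edges) == 0L) return(list())
  seen_state <- new.env(parent = emptyenv())
  seen_cand <- new.env(parent = emptyenv())
  out <- list()
  emit <- function(boundary, side_a, side_b) {
    if (side_a %% 2 == 1) { inb <- side_a; outb <- side_b }
    else { inb <- side_b; outb <- side_a }
    key <- paste(boundary, inb)
    if (!is.null(seen_cand[[key]])) return()
    seen_cand[[key]] <- TRUE
    out[[length(out) + 1L]] <<- list(boundary_bits = boundary,
                                     in_bits = inb, out_bits = outb)
  }
  stack <- list(list(nodes = dual$nodes, edges = dual$edges,
                     removed_max = -1L, removed_bits = 0))
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ne <- nrow(st$edges)
    if (ne == 1L) {
      emit(st$edges$bits[1], st$nodes[st$edges$a[1]], st$nodes[st$edges$b[1]])
      next
    }
    for (ei in seq_len(ne)) {
      ebits <- st$edges$bits[ei]
      if (max_bit(ebits) <= st$removed_max) next
      ea <- st$edges$a[ei]; eb <- st$edges$b[ei]
      nodes <- st$nodes
      nodes[ea] <- nodes[ea] + nodes[eb]  # disjoint face sets
      nodes <- nodes[-eb]
      ed <- st$edges[-ei, , drop = FALSE]
      # re-point endpoints at the merged node, then splice parallels
      ed$a[ed$a == eb] <- ea
      ed$b[ed$b == eb] <- ea
      ed$a[ed$a > eb] <- ed$a[ed$a > eb] - 1L
      ed$b[ed$b > eb] <- ed$b[ed$b > eb] - 1L
      lo <- pmin(ed$a, ed$b); hi <- pmax(ed$a, ed$b)
      ed$a <- lo; ed$b <- hi
      if (nrow(ed)) {
        key <- paste(ed$a, ed$b)
        if (anyDuplicated(key)) {
          bits <- vapply(split(ed$bits, key), sum, numeric(1))
          first <- !duplicated(key)
          ed <- ed[first, , drop = FALSE]
          ed$bits <- unname(bits[paste(ed$a, ed$b)])
        }
      }
      rb <- st$removed_bits + ebits
      skey <- as.character(rb)
      if (!is.null(seen_state[[skey]])) next
      seen_state[[skey]] <- TRUE
      stack[[length(stack) + 1L]] <-
        list(nodes = nodes, edges = ed,
             removed_max = max(st$removed_max, max_bit(ebits)),
             removed_bits = rb)
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "boundary_bits"))]
}
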