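# Gap filling and connected peak-subgraph extraction over region masks.

# Per-base shortest distance (in steps) to the nearest region base,
# looking backward (`forward = TRUE`: distance from the nearest region
# base at or before each base) or forward.  Distances are capped at
# cap + 1 ("infinity").  Vectorized within nodes via the last-mark trick;
# cross-node propagation follows the topological order.
.mask_distance <- function(mask, graph, cap, forward = TRUE) {
  n <- length(graph$ids)
  INF <- cap + 1L
  bnd <- rep(INF, n)        # distance at the node's outgoing boundary
  out <- mask; out$data <- numeric(length(mask$data))
  ord <- if (forward) graph$topo else rev(graph$topo)
  nbr <- if (forward) graph$pred else graph$succ
  for (i in ord) {
    len <- graph$lengths[i]
    sl <- mask$starts[i]:(mask$starts[i] + len - 1L)
    m <- mask$data[sl]
    if (!forward) m <- rev(m)
    din <- INF
    for (p in nbr[[i]]) din <- min(din, bnd[p])
    pos <- seq_len(len)
    # position of last region base at or before each base; the incoming
    # boundary acts as a virtual mark at position -din
    lastmark <- cummax(ifelse(m, pos, -Inf))
    d <- pmin(pos - pmax(lastmark, -din), INF)
    bnd[i] <- min(d[len], INF)
    if (!forward) d <- rev(d)
    out$data[sl] <- d
  }
  out
}

#' Fill short gaps between significant regions
#'
#' Joins candidate regions connected by a directed path shorter than the
#' read length: every base lying on \emph{some} directed path between two
#' region bases with fewer than \code{r} intervening bases is added (if a
#' gap is spanned by several short paths, all of them are filled; longer
#' parallel paths are left untouched).  A gap of exactly \code{r} bases is
#' not joined.
#'
#' @param regions a \code{region_set}.
#' @param r read length in bases.
#' @param graph the \code{graph_genome}.
#' @return a \code{region_set} containing the input (monotone) and
#'   idempotent under reapplication.
#' @export
fill_gaps <- function(regions, r, graph) {
  stopifnot(r >= 1)
  if (!any(regions$data)) return(regions)
  A <- .mask_distance(regions, graph, cap = r, forward = TRUE)
  B <- .mask_distance(regions, graph, cap = r, forward = FALSE)
  out <- regions
  # a base with backward distance a and forward distance b sits on a path
  # with a + b - 1 intervening bases between two region bases
  out$data <- regions$data | (A$data + B$data <= r)
  out
}

#' Group region bases into connected peak subgraphs
#'
#' Partition of the included bases into maximal components under graph
#' adjacency: consecutive bases within a node, or node-end to
#' successor-node-start across an edge.  Component ids are assigned
#' deterministically by the smallest contained (node id, offset).
#'
#' @param regions a \code{region_set}. @param graph the
#'   \code{graph_genome}.
#' @return list of \code{peak_subgraph} objects, each holding its
#'   \code{id} and its member base runs (data.frame \code{node},
#'   \code{start}, \code{end}).
#' @export
connected_subgraphs <- function(regions, graph) {
  runs <- region_intervals(regions)
  if (!nrow(runs)) return(list())
  runs$idx <- node_index(graph, runs$node)
  nr <- nrow(runs)
  # run adjacency: run u ending at its node's end connects to run v
  # starting at 0 on a successor node
  first_run_at0 <- rep(NA_integer_, length(graph$ids))
  at0 <- which(runs$start == 0L)
  first_run_at0[runs$idx[at0]] <- at0
  efrom <- integer(0); eto <- integer(0)
  for (u in seq_len(nr)) {
    if (runs$end[u] != graph$lengths[runs$idx[u]]) next
    for (s in graph$succ[[runs$idx[u]]]) {
      v <- first_run_at0[s]
      if (!is.na(v)) { efrom <- c(efrom, u); eto <- c(eto, v) }
    }
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = efrom, to = eto), directed = FALSE,
    vertices = data.frame(name = seq_len(nr)))
  comp <- igraph::components(ig)$membership[as.character(seq_len(nr))]
  groups <- split(seq_len(nr), comp)
  # deterministic ids by smallest contained (node id, offset)
  keys <- vapply(groups, function(g)
    min(runs$node[g] * 2^32 + runs$start[g]), numeric(1))
  groups <- groups[order(keys)]
  lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    rr <- runs[g, c("node", "start", "end", "idx")]
    rr <- rr[order(rr$node, rr$start), , drop = FALSE]
    rownames(rr) <- NULL
    structure(list(id = k, runs = rr), class = "peak_subgraph")
  })
}

#' @export
print.peak_subgraph <- function(x, ...) {
  cat(sprintf("peak_subgraph %d: %d runs over %d nodes, %d bases\n",
              x$id, nrow(x$runs), length(unique(x$runs$node)),
              sum(x$runs$end - x$runs$start)))
  invisible(x)
}
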