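#' Project a graph onto its linear reference path
#'
#' Builds the graph-to-linear coordinate system used for the background
#' track and for reporting peaks on the linear reference.  Reference-path
#' nodes get cumulative offsets along the reference.  Every off-reference
#' node is assigned the coordinate obtained by walking the shortest
#' backward distance from its first base to the end of the nearest
#' upstream reference node, and then walking that same distance forward
#' along the reference; parallel alleles therefore collapse to the same
#' linear position.  Ties among equally short backward routes are broken
#' by the smallest predecessor node id.
#'
#' @param graph a \code{graph_genome}.
#' @return an object of class \code{linear_projection} with fields
#'   \code{node_offsets} (integer vector, linear coordinate of each node's
#'   first base, aligned with \code{graph$ids}) and \code{path_length}
#'   (total reference length in bases).
#' @export
build_linear_projection <- function(graph) {
  stopifnot(inherits(graph, "graph_genome"))
  n <- length(graph$ids)
  off <- rep(NA_real_, n)
  rp <- graph$ref_path
  off[rp] <- cumsum(c(0, graph$lengths[rp[-length(rp)]]))
  path_length <- sum(graph$lengths[rp])

  # D[v]: shortest backward distance from the first base of off-reference
  # node v to the end boundary of a reference node; B[v]: the linear
  # coordinate of that boundary.  DAG dynamic program in topological order.
  D <- rep(Inf, n); B <- rep(NA_real_, n)
  for (i in graph$topo) {
    if (graph$on_ref[i]) next
    best_d <- Inf; best_b <- NA_real_
    for (p in graph$pred[[i]]) {        # preds visited earlier in topo order
      if (graph$on_ref[p]) {
        d <- 0; b <- off[p] + graph$lengths[p]
      } else {
        if (!is.finite(D[p])) next
        d <- D[p] + graph$lengths[p]; b <- B[p]
      }
      # preds are sorted ascending by id, so strict '<' keeps the smallest
      # predecessor id on ties
      if (d < best_d) { best_d <- d; best_b <- b }
    }
    D[i] <- best_d; B[i] <- best_b
    if (is.finite(best_d)) off[i] <- min(best_b + best_d, path_length)
  }
  if (anyNA(off)) {
    bad <- graph$ids[which(is.na(off))[1L]]
    stop("node ", bad, " has no backward route to the reference path: ",
         "cannot project it to linear coordinates")
  }
  structure(list(node_offsets = as.numeric(off), path_length = path_length),
            class = "linear_projection")
}

#' Project a single graph position to a linear coordinate
#'
#' Positions on reference nodes map exactly to their cumulative reference
#' coordinate.  Off-reference positions map to the coordinate of the
#' nearest upstream reference boundary plus the shortest backward distance
#' (the node-level part is precomputed in \code{proj}), clamped to the
#' reference length.
#'
#' @param node node id. @param offset 0-based offset within the node.
#' @param graph a \code{graph_genome}.
#' @param proj a \code{\link{build_linear_projection}} result.
#' @return integer linear coordinate (0-based).
#' @export
project_position_to_linear <- function(node, offset, graph, proj) {
  i <- node_index(graph, node)
  if (is.na(i)) stop("unknown node id: ", node)
  if (offset < 0 || offset >= graph$lengths[i])
    stop("offset ", offset, " out of bounds for node ", node)
  min(proj$node_offsets[i] + offset, proj$path_length)
}

# Linear coordinate of every base of every node, as a flat track-shaped
# integer vector (see new_track()); clamped so it can index a linear
# vector of length path_length.
base_coords <- function(graph, proj) {
  segs <- lapply(seq_along(graph$ids), function(i)
    pmin(proj$node_offsets[i] + seq_len(graph$lengths[i]) - 1,
         proj$path_length - 1))
  as.numeric(unlist(segs, use.names = FALSE))
}

#' @export
print.linear_projection <- function(x, ...) {
  cat(sprintf("linear_projection: %d nodes over a %d bp reference path\n",
              length(x$node_offsets), x$path_length))
  invisible(x)
}
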