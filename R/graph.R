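#' Construct a sequence graph with a designated linear reference path
#'
#' A \code{graph_genome} is a directed acyclic graph of sequence nodes with a
#' designated walk (\code{ref_path}) representing the linear reference
#' genome.  Parallel nodes off the reference path represent alternative
#' alleles (SNP branches, insertions); deletion alleles are edges skipping
#' reference nodes.  All coordinates in the package are 0-based, half-open.
#'
#' @param nodes named character vector (or list) of node sequences over
#'   \code{ACGTN}; names are the (integer) node ids.
#' @param edges two-column matrix or data.frame of node ids, one directed
#'   edge \code{from -> to} per row.  Duplicated edges are dropped.
#' @param ref_path integer vector of node ids forming the reference walk;
#'   consecutive entries must be edges.
#' @param name label for the graph (used as the chromosome name when peaks
#'   are projected to linear coordinates).
#' @return an object of class \code{graph_genome}.  Nodes are stored sorted
#'   by id; a topological order (ties broken by ascending node id) is
#'   computed at construction, so cyclic graphs are rejected here.
#' @examples
#' g <- graph_genome(c(`1` = "ACGT", `2` = "A", `3` = "G", `4` = "TT"),
#'                   edges = rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)),
#'                   ref_path = c(1, 2, 4))
#' topological_order(g)
#' @export
graph_genome <- function(nodes, edges, ref_path, name = "graph") {
  if (is.list(nodes)) nodes <- unlist(nodes)
  if (is.null(names(nodes)) || anyNA(suppressWarnings(as.integer(names(nodes)))))
    stop("nodes must be named by integer node ids")
  ids <- as.integer(names(nodes))
  if (anyDuplicated(ids)) stop("node ids must be unique")
  seqs <- toupper(as.character(nodes))
  if (any(!nzchar(seqs))) stop("node sequences must be non-empty")
  if (any(grepl("[^ACGTN]", seqs)))
    stop("node sequences must be over the alphabet ACGTN")

  ord <- order(ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  n <- length(ids)
  lengths <- nchar(seqs)

  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    if (ncol(edges) != 2L) stop("edges must have two columns (from, to)")
    storage.mode(edges) <- "integer"
    em <- unique(edges)
  }
  efrom <- match(em[, 1L], ids); eto <- match(em[, 2L], ids)
  if (anyNA(efrom) || anyNA(eto)) {
    bad <- c(em[, 1L][is.na(efrom)], em[, 2L][is.na(eto)])
    stop("edge refers to unknown node id: ", bad[1L])
  }

  succ <- rep(list(integer(0)), n)
  pred <- rep(list(integer(0)), n)
  if (length(efrom)) {
    o <- order(efrom, eto)
    sp <- split(eto[o], factor(efrom[o], levels = seq_len(n)))
    succ <- unname(lapply(sp, as.integer))
    o <- order(eto, efrom)
    sp <- split(efrom[o], factor(eto[o], levels = seq_len(n)))
    pred <- unname(lapply(sp, as.integer))
  }

  ref_path <- as.integer(ref_path)
  if (length(ref_path) == 0L) stop("a reference path is required")
  rp <- match(ref_path, ids)
  if (anyNA(rp)) stop("ref_path refers to unknown node id: ",
                      ref_path[which(is.na(rp))[1L]])
  if (length(rp) > 1L) {
    for (k in seq_len(length(rp) - 1L))
      if (!(rp[k + 1L] %in% succ[[rp[k]]]))
        stop("ref_path is not a walk: no edge ", ids[rp[k]], " -> ",
             ids[rp[k + 1L]])
  }
  if (anyDuplicated(rp)) stop("ref_path revisits a node (cycle)")
  on_ref <- logical(n); on_ref[rp] <- TRUE

  g <- structure(list(
    ids = ids, seqs = seqs, lengths = lengths,
    succ = succ, pred = pred,
    ref_path = rp, ref_path_ids = ids[rp], on_ref = on_ref,
    name = name, topo = integer(0)
  ), class = "graph_genome")
  g$topo <- .kahn_order(g)   # errors on cycles
  g
}

# Kahn's algorithm; ties broken by ascending node id (storage order is
# id-ascending so min index == min id).
.kahn_order <- function(g) {
  n <- length(g$ids)
  indeg <- lengths(g$pred)
  frontier <- which(indeg == 0L)
  out <- integer(n)
  for (k in seq_len(n)) {
    if (!length(frontier))
      stop("graph contains a cycle: only directed acyclic graphs are supported")
    i <- frontier[which.min(frontier)]
    frontier <- frontier[frontier != i]
    out[k] <- i
    for (j in g$succ[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) frontier <- c(frontier, j)
    }
  }
  out
}

#' Topological order of a sequence graph
#'
#' @param graph a \code{graph_genome}.
#' @return integer vector of node ids such that every edge goes from an
#'   earlier to a later id in the vector; ties are broken deterministically
#'   by ascending node id.
#' @export
topological_order <- function(graph) {
  stopifnot(inherits(graph, "graph_genome"))
  graph$ids[graph$topo]
}

node_index <- function(graph, ids) match(as.integer(ids), graph$ids)

#' Total number of bases in a graph
#' @param graph a \code{graph_genome}.
#' @return integer: the sum of node lengths.
#' @export
graph_n_bases <- function(graph) sum(graph$lengths)

#' @export
print.graph_genome <- function(x, ...) {
  cat(sprintf("graph_genome '%s': %d nodes (%d bp), %d edges, ref path %d nodes (%d bp)\n",
              x$name, length(x$ids), sum(x$lengths), sum(lengths(x$succ)),
              length(x$ref_path), sum(x$lengths[x$ref_path])))
  invisible(x)
}

#' Edge list of a graph
#' @param graph a \code{graph_genome}.
#' @return two-column integer matrix of node ids (from, to), sorted.
#' @export
graph_edges <- function(graph) {
  from <- rep(seq_along(graph$ids), lengths(graph$succ))
  to <- unlist(graph$succ, use.names = FALSE)
  cbind(from = graph$ids[from], to = graph$ids[to])
}
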