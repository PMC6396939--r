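#' Construct an oriented interval through the graph
#'
#' An interval is an ordered node path with a 0-based start offset on the
#' first node and an exclusive end offset on the last node.  The node path
#' is always stored in graph (forward) order; \code{direction} records the
#' strand of the originating read and drives fragment extension only.
#'
#' @param node_path integer vector of node ids; consecutive entries must be
#'   edges of the graph when one is supplied for validation.
#' @param start 0-based offset on the first node.
#' @param end exclusive offset on the last node.
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @param graph optional \code{graph_genome} used to validate the interval.
#' @return an object of class \code{graph_interval}.
#' @export
graph_interval <- function(node_path, start, end,
                           direction = c("forward", "reverse"),
                           graph = NULL) {
  direction <- match.arg(direction)
  node_path <- as.integer(node_path)
  start <- as.integer(start); end <- as.integer(end)
  iv <- structure(list(node_path = node_path, start = start, end = end,
                       direction = direction), class = "graph_interval")
  if (!is.null(graph)) validate_interval(iv, graph)
  iv
}

validate_interval <- function(iv, graph) {
  idx <- node_index(graph, iv$node_path)
  if (anyNA(idx)) stop("interval visits unknown node id: ",
                       iv$node_path[which(is.na(idx))[1L]])
  if (length(idx) > 1L) {
    for (k in seq_len(length(idx) - 1L))
      if (!(idx[k + 1L] %in% graph$succ[[idx[k]]]))
        stop("interval is not a path: no edge ", iv$node_path[k], " -> ",
             iv$node_path[k + 1L])
  }
  if (iv$start < 0L || iv$start >= graph$lengths[idx[1L]])
    stop("interval start offset out of bounds")
  if (iv$end < 1L || iv$end > graph$lengths[idx[length(idx)]])
    stop("interval end offset out of bounds")
  if (length(idx) == 1L && iv$start >= iv$end)
    stop("single-node interval must have start < end")
  invisible(iv)
}

#' Number of graph bases covered by an interval
#' @param iv a \code{graph_interval}. @param graph the \code{graph_genome}.
#' @return integer base count.
#' @export
interval_length <- function(iv, graph) {
  idx <- node_index(graph, iv$node_path)
  if (length(idx) == 1L) return(iv$end - iv$start)
  (graph$lengths[idx[1L]] - iv$start) +
    sum(graph$lengths[idx[-c(1L, length(idx))]]) + iv$end
}

# Covered bases as a matrix of per-node segments: columns idx, start, end
# (0-based half-open within each node).
interval_segments <- function(iv, graph) {
  idx <- node_index(graph, iv$node_path)
  k <- length(idx)
  s <- integer(k); e <- graph$lengths[idx]
  s[1L] <- iv$start; e[k] <- iv$end
  cbind(idx = idx, start = s, end = e)
}

#' Construct an alignment (a mapped read)
#'
#' @param iv a \code{graph_interval} covering the graph bases the read
#'   traverses.
#' @param mapq integer mapping quality.
#' @param read_id read name.
#' @param graph optional graph for validation; the read length is defined
#'   as the interval length.
#' @return an object of class \code{graph_alignment}.
#' @export
alignment <- function(iv, mapq = 60L, read_id = "", graph = NULL) {
  if (!is.null(graph)) validate_interval(iv, graph)
  structure(list(interval = iv, mapq = as.integer(mapq),
                 read_id = as.character(read_id),
                 read_length = if (!is.null(graph))
                   interval_length(iv, graph) else NA_integer_),
            class = "graph_alignment")
}

#' Read alignments from GAM JSON-lines
#'
#' Consumes the JSON rendering of vg's Graph Alignment/Map format
#' (\code{vg view -a}): one JSON object per line with \code{name},
#' \code{mapping_quality} and \code{path.mapping[]} entries carrying
#' \code{position.node_id}, \code{position.offset},
#' \code{position.is_reverse} and edit lengths.  Reverse-strand records
#' (mappings listed along the read, offsets measured from the node end)
#' are converted to forward node order with \code{direction = "reverse"}.
#' Unmapped records (no path) are skipped and counted.
#'
#' @param path file of JSON lines.
#' @param graph the \code{graph_genome} the reads were aligned to (needed
#'   to convert reverse-strand offsets).
#' @return list of \code{graph_alignment}; the number of skipped unmapped
#'   records is attached as attribute \code{"n_unmapped"}.
#' @export
load_alignments <- function(path, graph) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  n_unmapped <- 0L
  for (k in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[k], simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed GAM JSON at '", path, "' line ", k,
                           ": ", conditionMessage(e), call. = FALSE))
    maps <- rec$path$mapping
    if (is.null(maps) || !length(maps)) { n_unmapped <- n_unmapped + 1L; next }
    nid <- vapply(maps, function(m) as.integer(m$position$node_id), integer(1))
    off <- vapply(maps, function(m) as.integer(m$position$offset %||% 0L),
                  integer(1))
    rev <- vapply(maps, function(m) isTRUE(m$position$is_reverse), logical(1))
    cov <- vapply(maps, function(m) {
      if (is.null(m$edit)) return(0L)
      sum(vapply(m$edit, function(e) as.integer(e$from_length %||% 0L),
                 integer(1)))
    }, integer(1))
    if (any(cov <= 0L))
      stop("GAM record at '", path, "' line ", k,
           ": mapping covers no graph bases")
    idx <- node_index(graph, nid)
    if (anyNA(idx))
      stop("GAM record at '", path, "' line ", k,
           ": unknown node id ", nid[which(is.na(idx))[1L]])
    if (rev[1L]) {
      # mappings run along the read, i.e. backwards through the graph;
      # offsets count from the (forward) node end
      lens <- graph$lengths[idx]
      fwd_start <- lens - off - cov       # forward-coords segment starts
      m <- length(nid)
      iv <- graph_interval(rev(nid),
                           start = fwd_start[m],
                           end = lens[1L] - off[1L],
                           direction = "reverse")
    } else {
      m <- length(nid)
      iv <- graph_interval(nid, start = off[1L], end = off[m] + cov[m],
                           direction = "forward")
    }
    validate_interval(iv, graph)
    out[[k]] <- alignment(iv, mapq = rec$mapping_quality %||% 0L,
                          read_id = rec$name %||% "", graph = graph)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write alignments as GAM JSON-lines
#'
#' Inverse of \code{\link{load_alignments}} (used by the simulator):
#' forward reads are written with mappings in graph order; reverse reads
#' are written in read order with offsets measured from the node end, the
#' convention vg uses for reverse-strand mappings.
#'
#' @param alignments list of \code{graph_alignment}.
#' @param path output file. @param graph the \code{graph_genome}.
#' @return \code{path}, invisibly.
#' @export
write_alignments <- function(alignments, path, graph) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (a in alignments) {
    segs <- interval_segments(a$interval, graph)
    fwd <- a$interval$direction == "forward"
    ord <- if (fwd) seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
    maps <- lapply(ord, function(i) {
      len <- graph$lengths[segs[i, "idx"]]
      cov <- segs[i, "end"] - segs[i, "start"]
      o <- if (fwd) segs[i, "start"] else len - segs[i, "end"]
      list(position = c(list(node_id = graph$ids[segs[i, "idx"]],
                             offset = o),
                        if (!fwd) list(is_reverse = TRUE)),
           edit = list(list(from_length = cov, to_length = cov)))
    })
    rec <- list(name = a$read_id, mapping_quality = a$mapq,
                path = list(mapping = maps))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Filter alignments on mapping quality
#'
#' Retains exactly the alignments with \code{mapq >= min_mapq} (boundary
#' inclusive), preserving order.  The default threshold of 37 matches the
#' quality cutoff commonly applied to vg graph alignments
#' (\code{vg filter -q 37}).
#'
#' @param alignments list of \code{graph_alignment}.
#' @param min_mapq minimum mapping quality to keep.
#' @return filtered list.
#' @export
filter_alignments <- function(alignments, min_mapq = 37L) {
  keep <- vapply(alignments, function(a) a$mapq >= min_mapq, logical(1))
  alignments[keep]
}
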