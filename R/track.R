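# Per-base tracks over every node of a graph, stored as one flat vector
# with per-node start indices.  Fragment pileups, background rates, p/q
# score tracks and region masks all share this shape.

#' Create an empty per-base track over a graph
#'
#' @param graph a \code{graph_genome}.
#' @param init initial value for every base (numeric or logical).
#' @return object of class \code{pileup_track}: flat \code{data} vector
#'   plus per-node \code{starts}/\code{lengths} aligned with
#'   \code{graph$ids}.
#' @export
new_track <- function(graph, init = 0) {
  n_bases <- sum(graph$lengths)
  starts <- cumsum(c(1L, graph$lengths[-length(graph$lengths)]))
  structure(list(data = rep(init, n_bases), starts = starts,
                 lengths = graph$lengths, ids = graph$ids),
            class = "pileup_track")
}

#' Extract the per-base values of one node from a track
#' @param track a \code{pileup_track}. @param node node id.
#' @return vector of the node's per-base values.
#' @export
track_node <- function(track, node) {
  i <- match(as.integer(node), track$ids)
  if (is.na(i)) stop("unknown node id: ", node)
  track$data[track$starts[i]:(track$starts[i] + track$lengths[i] - 1L)]
}

track_same_shape <- function(a, b) {
  identical(a$ids, b$ids) && identical(a$lengths, b$lengths)
}

#' @export
print.pileup_track <- function(x, ...) {
  cat(sprintf("pileup_track: %d nodes, %d bases; values in [%g, %g]\n",
              length(x$ids), length(x$data),
              suppressWarnings(min(x$data)), suppressWarnings(max(x$data))))
  invisible(x)
}

#' Write / read a track as node-indexed JSON (lossless)
#'
#' @param track a \code{pileup_track}. @param path output file.
#' @return \code{path} invisibly (writer); a \code{pileup_track} (reader,
#'   which needs the \code{graph} to restore the shape).
#' @export
write_track_json <- function(track, path) {
  vals <- lapply(seq_along(track$ids), function(i)
    track$data[track$starts[i]:(track$starts[i] + track$lengths[i] - 1L)])
  names(vals) <- track$ids
  writeLines(jsonlite::toJSON(vals, digits = NA), path)
  invisible(path)
}

#' @param graph the \code{graph_genome} the track was computed on.
#' @rdname write_track_json
#' @export
read_track_json <- function(path, graph) {
  vals <- jsonlite::fromJSON(path)
  tr <- new_track(graph, 0)
  idx <- match(as.integer(names(vals)), graph$ids)
  if (anyNA(idx)) stop("track refers to unknown node ids")
  for (k in seq_along(vals)) {
    i <- idx[k]
    if (length(vals[[k]]) != graph$lengths[i])
      stop("track length mismatch on node ", graph$ids[i])
    tr$data[tr$starts[i]:(tr$starts[i] + tr$lengths[i] - 1L)] <- vals[[k]]
  }
  tr
}

#' Export a track to bedGraph over projected linear coordinates
#'
#' Diagnostic only: parallel alleles collapse to the same linear position,
#' so the export takes the maximum value among bases projecting to each
#' coordinate.
#'
#' @param track a \code{pileup_track}. @param graph the graph.
#' @param proj a \code{\link{build_linear_projection}} result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_track_bedgraph <- function(track, graph, proj, path) {
  coords <- base_coords(graph, proj)
  lin <- rep(0, proj$path_length)
  o <- order(track$data)           # max wins after ordered assignment
  lin[coords[o] + 1] <- track$data[o]
  r <- rle(lin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = graph$name, start = starts, end = ends,
                   value = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
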