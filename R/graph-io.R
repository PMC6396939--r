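#' Read a sequence graph from vg-style JSON or GFA1
#'
#' Two interchange dialects are supported: the JSON rendering of vg graphs
#' (\code{vg view -j}: objects with \code{node}, \code{edge} and \code{path}
#' arrays) and GFA1 (\code{S}/\code{L}/\code{P} lines, forward orientations
#' only).  The linear reference path must be present as a vg \code{path}
#' record or GFA \code{P} line, or be supplied via \code{ref_path}.
#' Graphs with cycles are rejected.
#'
#' @param path file path of the graph.
#' @param format \code{"vg-json"} or \code{"gfa1"}.
#' @param ref_path optional integer vector of node ids overriding the
#'   reference path declared in the file.
#' @param name optional graph name; defaults to the declared path name.
#' @return a validated \code{\link{graph_genome}}.
#' @export
load_graph <- function(path, format = c("vg-json", "gfa1"), ref_path = NULL,
                       name = NULL) {
  format <- match.arg(format)
  if (format == "vg-json") .load_graph_vg_json(path, ref_path, name)
  else .load_graph_gfa1(path, ref_path, name)
}

.load_graph_vg_json <- function(path, ref_path = NULL, name = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed vg JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$node) || !length(doc$node))
    stop("vg JSON '", path, "' declares no nodes")
  ids <- vapply(doc$node, function(n) {
    if (is.null(n$id) || is.null(n$sequence))
      stop("malformed node record in '", path,
           "': need both 'id' and 'sequence'")
    as.integer(n$id)
  }, integer(1))
  seqs <- vapply(doc$node, function(n) as.character(n$sequence), character(1))
  names(seqs) <- ids
  edges <- if (length(doc$edge)) {
    t(vapply(doc$edge, function(e) {
      if (is.null(e$from) || is.null(e$to))
        stop("malformed edge record in '", path, "': need 'from' and 'to'")
      if (isTRUE(e$from_start) || isTRUE(e$to_end))
        stop("reversing edge in '", path, "': only forward DAG edges supported")
      c(as.integer(e$from), as.integer(e$to))
    }, integer(2)))
  } else matrix(integer(0), ncol = 2L)
  pname <- NULL
  if (is.null(ref_path)) {
    if (is.null(doc$path) || !length(doc$path))
      stop("no reference path in '", path,
           "': supply one via ref_path= or add a vg path record")
    p <- doc$path[[1L]]
    pname <- p$name
    ref_path <- vapply(p$mapping, function(m) {
      nid <- m$position$node_id
      if (is.null(nid)) stop("malformed path mapping in '", path, "'")
      as.integer(nid)
    }, integer(1))
  }
  graph_genome(seqs, edges, ref_path,
               name = name %||% pname %||% "graph")
}

.load_graph_gfa1 <- function(path, ref_path = NULL, name = NULL) {
  lines <- readLines(path)
  seqs <- character(0); sids <- integer(0)
  efrom <- integer(0); eto <- integer(0)
  pname <- NULL; ppath <- NULL
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    switch(substr(ln, 1L, 1L),
      "H" = NULL,
      "S" = {
        if (length(f) < 3L)
          stop("malformed S line at '", path, "' line ", k)
        sids <- c(sids, as.integer(f[2L])); seqs <- c(seqs, f[3L])
      },
      "L" = {
        if (length(f) < 5L)
          stop("malformed L line at '", path, "' line ", k)
        if (f[3L] != "+" || f[5L] != "+")
          stop("non-forward orientation in L line at '", path, "' line ", k,
               ": only forward DAG edges supported")
        efrom <- c(efrom, as.integer(f[2L])); eto <- c(eto, as.integer(f[4L]))
      },
      "P" = {
        if (length(f) < 3L)
          stop("malformed P line at '", path, "' line ", k)
        if (is.null(ppath)) {
          pname <- f[2L]
          segs <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
          if (any(!grepl("\\+$", segs)))
            stop("P line at '", path, "' line ", k,
                 " uses reverse orientation: unsupported")
          ppath <- as.integer(sub("\\+$", "", segs))
        }
      },
      stop("unrecognized GFA record '", substr(ln, 1L, 1L), "' at '", path,
           "' line ", k)
    )
  }
  if (!length(sids)) stop("GFA '", path, "' declares no segments")
  names(seqs) <- sids
  if (is.null(ref_path)) {
    if (is.null(ppath))
      stop("no reference path in '", path,
           "': supply one via ref_path= or add a P line")
    ref_path <- ppath
  }
  graph_genome(seqs, cbind(efrom, eto), ref_path,
               name = name %||% pname %||% "graph")
}

#' Write a sequence graph to vg-style JSON or GFA1
#'
#' Inverse of \code{\link{load_graph}}: a written graph loads back
#' content-identical in either dialect.
#'
#' @param graph a \code{graph_genome}.
#' @param path output file path.
#' @param format \code{"vg-json"} or \code{"gfa1"}.
#' @return \code{path}, invisibly.
#' @export
write_graph <- function(graph, path, format = c("vg-json", "gfa1")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "graph_genome"))
  if (format == "vg-json") {
    em <- graph_edges(graph)
    doc <- list(
      node = lapply(seq_along(graph$ids), function(i)
        list(id = graph$ids[i], sequence = graph$seqs[i])),
      edge = lapply(seq_len(nrow(em)), function(i)
        list(from = em[i, 1L], to = em[i, 2L])),
      path = list(list(
        name = graph$name,
        mapping = lapply(seq_along(graph$ref_path), function(k)
          list(position = list(node_id = graph$ref_path_ids[k]),
               rank = k))))
    )
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  } else {
    em <- graph_edges(graph)
    lines <- c(
      "H\tVN:Z:1.0",
      sprintf("S\t%d\t%s", graph$ids, graph$seqs),
      if (nrow(em)) sprintf("L\t%d\t+\t%d\t+\t0M", em[, 1L], em[, 2L]),
      sprintf("P\t%s\t%s\t*", graph$name,
              paste0(graph$ref_path_ids, "+", collapse = ","))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
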