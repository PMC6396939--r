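# Maximum-read-support path selection within peak subgraphs, summit
# calling, trimming and linear projection of final peaks.

# Directed adjacency between the runs of one subgraph: run u -> run v iff
# u reaches its node's end, v starts at 0 and the nodes are an edge.
.run_adjacency <- function(runs, graph) {
  nr <- nrow(runs)
  run_at0 <- rep(NA_integer_, length(graph$ids))
  at0 <- which(runs$start == 0L)
  run_at0[runs$idx[at0]] <- at0
  succ <- rep(list(integer(0)), nr)
  pred <- rep(list(integer(0)), nr)
  for (u in seq_len(nr)) {
    if (runs$end[u] != graph$lengths[runs$idx[u]]) next
    for (s in graph$succ[[runs$idx[u]]]) {
      v <- run_at0[s]
      if (!is.na(v)) {
        succ[[u]] <- c(succ[[u]], v)
        pred[[v]] <- c(pred[[v]], u)
      }
    }
  }
  list(succ = succ, pred = pred)
}

# Map an alignment to the sequence of run indices containing it, or NULL
# if some covered base falls outside the subgraph's runs.
.aln_run_seq <- function(aln, runs, runs_by_idx, graph) {
  segs <- interval_segments(aln$interval, graph)
  out <- integer(nrow(segs))
  for (k in seq_len(nrow(segs))) {
    cand <- runs_by_idx[[as.character(segs[k, "idx"])]]
    if (is.null(cand)) return(NULL)
    hit <- cand[runs$start[cand] <= segs[k, "start"] &
                  runs$end[cand] >= segs[k, "end"]]
    if (!length(hit)) return(NULL)
    out[k] <- hit[1L]
  }
  out
}

# Assemble a graph_interval from an ordered sequence of run indices.
.runs_to_interval <- function(rseq, runs, graph) {
  graph_interval(runs$node[rseq],
                 start = runs$start[rseq[1L]],
                 end = runs$end[rseq[length(rseq)]])
}

#' Maximum-read-support path through a peak subgraph
#'
#' Selects, over all maximal directed paths through the subgraph, the one
#' containing the largest number of input alignments (an alignment counts
#' iff its interval is entirely contained in the path).  Computed by
#' dynamic programming over the subgraph's run adjacency in topological
#' order; because an alignment can span several nodes, the DP state
#' carries the short suffix of runs needed to decide containment exactly.
#' Ties are broken by preferring reference-path nodes, then smaller node
#' ids.
#'
#' @param subgraph a \code{peak_subgraph}.
#' @param alignments the filtered input alignments.
#' @param graph the \code{graph_genome}.
#' @return an object of class \code{graph_peak} with the selected
#'   \code{path} (a \code{graph_interval}), its \code{support} and
#'   \code{length} in bases; the summit is filled in by
#'   \code{\link{peak_summit}}.  \code{NULL} for an empty subgraph.
#' @export
find_max_path <- function(subgraph, alignments, graph) {
  runs <- subgraph$runs
  if (!nrow(runs)) return(NULL)
  adj <- .run_adjacency(runs, graph)
  runs_by_idx <- split(seq_len(nrow(runs)), as.character(runs$idx))

  aln_seqs <- list()
  for (a in alignments) {
    rs <- .aln_run_seq(a, runs, runs_by_idx, graph)
    if (!is.null(rs)) aln_seqs[[length(aln_seqs) + 1L]] <- rs
  }
  by_final <- split(aln_seqs,
                    vapply(aln_seqs, function(x) x[length(x)], integer(1)))
  m <- if (length(aln_seqs))
    max(lengths(aln_seqs)) else 1L          # suffix length the DP must carry

  gain <- function(state) {                 # state ends at the current run
    v <- state[length(state)]
    cand <- by_final[[as.character(v)]]
    if (is.null(cand)) return(0L)
    g <- 0L
    for (q in cand) {
      k <- length(q)
      if (k <= length(state) &&
          identical(q, state[(length(state) - k + 1L):length(state)]))
        g <- g + 1L
    }
    g
  }

  memo <- new.env(parent = emptyenv())
  # value(state): best gain collectable strictly after the current run
  value <- function(state) {
    key <- paste(state, collapse = ",")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- state[length(state)]
    nxt <- adj$succ[[v]]
    best <- 0L
    for (w in nxt) {
      ns <- c(state, w)
      if (length(ns) > m) ns <- ns[-1L]
      cand <- gain(ns) + value(ns)
      if (cand > best) best <- cand
    }
    assign(key, best, envir = memo)
    best
  }

  # deterministic successor preference on ties: higher value, then
  # reference node, then smaller node id, then smaller offset
  pick <- function(cands, scores) {
    o <- order(-scores, !graph$on_ref[runs$idx[cands]],
               runs$node[cands], runs$start[cands])
    cands[o[1L]]
  }

  sources <- which(lengths(adj$pred) == 0L)
  src_scores <- vapply(sources, function(v)
    gain(v) + value(v), numeric(1))
  start <- pick(sources, src_scores)
  total <- src_scores[match(start, sources)]

  path <- start
  state <- start
  repeat {
    v <- state[length(state)]
    nxt <- adj$succ[[v]]
    if (!length(nxt)) break
    scores <- vapply(nxt, function(w) {
      ns <- c(state, w)
      if (length(ns) > m) ns <- ns[-1L]
      gain(ns) + value(ns)
    }, numeric(1))
    w <- pick(nxt, scores)
    path <- c(path, w)
    state <- c(state, w)
    if (length(state) > m) state <- state[-1L]
  }

  iv <- .runs_to_interval(path, runs, graph)
  structure(list(path = iv, support = as.integer(total),
                 summit = NULL, summit_qscore = NA_real_,
                 subgraph_id = subgraph$id,
                 length = interval_length(iv, graph)),
            class = "graph_peak")
}

#' @export
print.graph_peak <- function(x, ...) {
  cat(sprintf(
    "graph_peak (subgraph %d): %d nodes, %d bp, support %d%s\n",
    x$subgraph_id, length(x$path$node_path), x$length, x$support,
    if (!is.null(x$summit))
      sprintf(", summit %d:%d (q-score %.2f)", x$summit$node,
              x$summit$offset, x$summit_qscore) else ""))
  invisible(x)
}

#' Drop peaks shorter than the fragment length
#'
#' Retains peaks whose path covers at least \code{f} bases (a peak of
#' length exactly \code{f} is kept).
#'
#' @param peaks list of \code{graph_peak}. @param f fragment length.
#' @return filtered list.
#' @export
remove_short_peaks <- function(peaks, f) {
  peaks[vapply(peaks, function(p) p$length >= f, logical(1))]
}

# Flat track indices of a path's bases, in path order.
.path_base_index <- function(iv, graph, track) {
  segs <- interval_segments(iv, graph)
  unlist(lapply(seq_len(nrow(segs)), function(k) {
    i <- segs[k, "idx"]
    (track$starts[i] + segs[k, "start"]):(track$starts[i] + segs[k, "end"] - 1L)
  }), use.names = FALSE)
}

#' Locate the summit of a peak
#'
#' The summit is the path base with the lowest q-value (highest q-score);
#' ties go to the leftmost base along the path.
#'
#' @param peak a \code{graph_peak}. @param qtrack the q-score track.
#' @param graph the \code{graph_genome}.
#' @return the peak with \code{summit} (node, offset) and
#'   \code{summit_qscore} filled in.
#' @export
peak_summit <- function(peak, qtrack, graph) {
  idxs <- .path_base_index(peak$path, graph, qtrack)
  best <- which.max(qtrack$data[idxs])       # first maximum = leftmost
  segs <- interval_segments(peak$path, graph)
  seglen <- segs[, "end"] - segs[, "start"]
  cum <- cumsum(seglen)
  k <- which(best <= cum)[1L]
  within <- best - c(0L, cum)[k] - 1L
  peak$summit <- list(node = graph$ids[segs[k, "idx"]],
                      offset = as.integer(segs[k, "start"] + within))
  peak$summit_qscore <- qtrack$data[idxs[best]]
  peak
}

#' Trim a peak to a fixed width around its summit
#'
#' Returns the sub-interval of the peak path of length
#' \code{min(width, path length)} centered on the summit (width/2 on each
#' side, shifted inward at path ends).  The untrimmed path is kept in
#' \code{full_path}.
#'
#' @param peak a \code{graph_peak} with a summit. @param width target
#'   width in bases (120 by default, a common convention for comparing
#'   peak sets). @param graph the \code{graph_genome}.
#' @return the trimmed \code{graph_peak}.
#' @export
trim_peak <- function(peak, width = 120L, graph) {
  stopifnot(width >= 1L)
  if (is.null(peak$summit)) stop("trim_peak needs a summit; call peak_summit first")
  L <- peak$length
  w <- min(width, L)
  segs <- interval_segments(peak$path, graph)
  seglen <- segs[, "end"] - segs[, "start"]
  cum <- cumsum(seglen)
  # 0-based index of the summit along the path
  k <- match(node_index(graph, peak$summit$node), segs[, "idx"])
  sidx <- c(0L, cum)[k] + (peak$summit$offset - segs[k, "start"])
  from <- max(0L, min(sidx - w %/% 2L, L - w))   # 0-based, half-open window
  to <- from + w
  locate <- function(pos, exclusive = FALSE) {   # path index -> (seg, offset)
    p <- if (exclusive) pos - 1L else pos
    k <- which(p < cum)[1L]
    off <- segs[k, "start"] + (p - c(0L, cum)[k])
    list(k = k, off = as.integer(off + if (exclusive) 1L else 0L))
  }
  a <- locate(from); b <- locate(to, exclusive = TRUE)
  iv <- graph_interval(graph$ids[segs[a$k:b$k, "idx"]],
                       start = a$off, end = b$off,
                       direction = peak$path$direction)
  peak$full_path <- peak$path
  peak$path <- iv
  peak$length <- interval_length(iv, graph)
  peak
}

#' Project final peaks to linear reference coordinates
#'
#' Each peak's start and end are projected through the graph-to-linear
#' rule (parallel alleles collapse, so a peak through an alternative
#' allele spans the same linear interval as its reference counterpart);
#' the end is coerced to exceed the start.  Output is sorted by
#' (chrom, start).
#'
#' @param peaks list of \code{graph_peak} (with summits).
#' @param proj a \code{\link{build_linear_projection}}.
#' @param graph the \code{graph_genome}.
#' @return data.frame of linear peaks: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{name}, \code{score} (summit
#'   q-score x 10, rounded, capped at 1000), \code{support},
#'   \code{summit_qscore} and narrowPeak-style \code{summit_offset}
#'   relative to the peak start.
#' @export
peaks_to_linear <- function(peaks, proj, graph) {
  rows <- lapply(peaks, function(p) {
    iv <- p$path
    s <- project_position_to_linear(iv$node_path[1L], iv$start, graph, proj)
    e <- project_position_to_linear(iv$node_path[length(iv$node_path)],
                                    iv$end - 1L, graph, proj) + 1
    e <- max(e, s + 1)
    so <- if (!is.null(p$summit))
      max(0, project_position_to_linear(p$summit$node, p$summit$offset,
                                        graph, proj) - s) else NA_real_
    data.frame(chrom = graph$name, start = s, end = e,
               name = sprintf("peak_%d", p$subgraph_id),
               score = min(1000, round(10 * (p$summit_qscore %|NA|% 0))),
               support = p$support,
               summit_qscore = p$summit_qscore,
               summit_offset = so)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), support = integer(0),
                      summit_qscore = numeric(0), summit_offset = numeric(0)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Write linear peaks in narrowPeak (BED6+4) format
#'
#' @param linear_peaks data.frame from \code{\link{peaks_to_linear}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_narrowpeak <- function(linear_peaks, path) {
  df <- data.frame(linear_peaks$chrom, linear_peaks$start, linear_peaks$end,
                   linear_peaks$name, linear_peaks$score, ".",
                   linear_peaks$support, -1,
                   round(linear_peaks$summit_qscore, 5),
                   linear_peaks$summit_offset)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read graph peaks as JSON-lines
#'
#' One JSON object per peak: subgraph id, node path with offsets, support,
#' summit and its q-score.  Bit-stable given identical inputs.
#'
#' @param peaks list of \code{graph_peak}. @param path file path.
#' @return \code{path} invisibly (writer); list of \code{graph_peak}
#'   (reader).
#' @export
write_peaks_json <- function(peaks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in peaks) {
    rec <- list(subgraph_id = p$subgraph_id,
                node_path = p$path$node_path,
                start = p$path$start, end = p$path$end,
                length = p$length, support = p$support,
                summit_node = p$summit$node, summit_offset = p$summit$offset,
                summit_qscore = p$summit_qscore)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_peaks_json
#' @export
read_peaks_json <- function(path) {
  lapply(readLines(path), function(ln) {
    rec <- jsonlite::fromJSON(ln)
    structure(list(
      path = graph_interval(rec$node_path, rec$start, rec$end),
      support = rec$support,
      summit = list(node = rec$summit_node, offset = rec$summit_offset),
      summit_qscore = rec$summit_qscore,
      subgraph_id = rec$subgraph_id, length = rec$length),
      class = "graph_peak")
  })
}

#' Alternative allele peak through a motif-matched sub-region
#'
#' After the maximum path of a subgraph is reported, scans its sequence
#' for the binding motif and, if a match exists, looks for a path through
#' the matched sub-region that differs from the maximum path in at least
#' one node and is covered by at least one input read.  Such alternative
#' peaks are candidates for allele-specific (differential) binding.
#'
#' @param subgraph a \code{peak_subgraph}.
#' @param pwm a \code{\link{pwm_model}}.
#' @param alignments the filtered input alignments.
#' @param graph the \code{graph_genome}.
#' @param peak the subgraph's maximum-path peak; recomputed when NULL.
#' @param max_paths cap on the number of alternative run paths enumerated.
#' @return a \code{graph_peak} for the best-supported alternative path, or
#'   \code{NULL} when there is no motif match or no read-covered
#'   alternative.
#' @export
alternative_peak <- function(subgraph, pwm, alignments, graph, peak = NULL,
                             max_paths = 1000L) {
  if (is.null(peak)) peak <- find_max_path(subgraph, alignments, graph)
  if (is.null(peak)) return(NULL)
  seqs <- path_sequence(peak$path, graph)
  hits <- pwm_matches(seqs, pwm)
  if (!nrow(hits)) return(NULL)

  runs <- subgraph$runs
  adj <- .run_adjacency(runs, graph)
  runs_by_idx <- split(seq_len(nrow(runs)), as.character(runs$idx))
  # run sequence of the maximum path
  max_rseq <- integer(0)
  for (k in seq_along(peak$path$node_path)) {
    cand <- runs_by_idx[[as.character(node_index(graph,
                                                 peak$path$node_path[k]))]]
    segs <- interval_segments(peak$path, graph)
    hit <- cand[runs$start[cand] <= segs[k, "start"] &
                  runs$end[cand] >= segs[k, "end"]]
    max_rseq <- c(max_rseq, hit[1L])
  }

  # enumerate maximal run paths (bounded) and keep read-covered paths that
  # differ from the maximum path in at least one node
  paths <- list()
  walk <- function(p) {
    if (length(paths) >= max_paths) return()
    v <- p[length(p)]
    nxt <- adj$succ[[v]]
    if (!length(nxt)) { paths[[length(paths) + 1L]] <<- p; return() }
    for (w in nxt) walk(c(p, w))
  }
  for (s in which(lengths(adj$pred) == 0L)) walk(s)

  aln_seqs <- list()
  for (a in alignments) {
    rs <- .aln_run_seq(a, runs, runs_by_idx, graph)
    if (!is.null(rs)) aln_seqs[[length(aln_seqs) + 1L]] <- rs
  }
  contained <- function(q, p) {
    pos <- match(q[1L], p)
    !is.na(pos) && pos + length(q) - 1L <= length(p) &&
      identical(p[pos:(pos + length(q) - 1L)], q)
  }

  best <- NULL; best_support <- 0L
  for (p in paths) {
    diff_runs <- setdiff(p, max_rseq)
    if (!length(diff_runs)) next
    sup <- 0L; touches <- FALSE
    for (q in aln_seqs) {
      if (contained(q, p)) {
        sup <- sup + 1L
        if (any(q %in% diff_runs)) touches <- TRUE
      }
    }
    if (touches && sup > best_support) { best <- p; best_support <- sup }
  }
  if (is.null(best)) return(NULL)
  iv <- .runs_to_interval(best, runs, graph)
  structure(list(path = iv, support = best_support, summit = NULL,
                 summit_qscore = NA_real_, subgraph_id = subgraph$id,
                 length = interval_length(iv, graph)),
            class = "graph_peak")
}

#' Concatenated base sequence of a graph interval
#' @param iv a \code{graph_interval}. @param graph the graph.
#' @return character scalar.
#' @export
path_sequence <- function(iv, graph) {
  segs <- interval_segments(iv, graph)
  paste(vapply(seq_len(nrow(segs)), function(k)
    substr(graph$seqs[segs[k, "idx"]], segs[k, "start"] + 1L,
           segs[k, "end"]), character(1)), collapse = "")
}
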