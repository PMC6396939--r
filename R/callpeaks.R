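#' Call ChIP-seq peaks on a variation graph
#'
#' Runs the whole graph peak-calling pipeline: mapping-quality filtering,
#' fragment-length estimation (unless supplied), breadth-first fragment
#' pileup, projected local-lambda background track, per-base Poisson
#' p-values and Benjamini-Hochberg q-values, thresholding, gap filling,
#' connected peak-subgraph extraction, maximum-read-support path selection
#' with summits, removal of peaks shorter than the fragment length,
#' trimming around summits, and projection to linear coordinates.  The
#' run is fully deterministic given its inputs.
#'
#' Without control alignments the input reads serve as their own
#' background; the smallest local window is then dropped (default windows
#' 5 kb and 10 kb instead of 1 kb and 10 kb) to avoid the signal
#' inflating its own background.
#'
#' @param graph a \code{\link{graph_genome}}.
#' @param alignments input (ChIP) alignments, a list of
#'   \code{graph_alignment}.
#' @param control optional control alignments; NULL for no-control mode.
#' @param fragment_length optional known fragment length; estimated by
#'   strand cross-correlation when NULL.
#' @param read_length optional read length; modal alignment length when
#'   NULL.
#' @param qvalue FDR threshold on q-values (default 0.05).
#' @param min_mapq mapping-quality filter (default 37).
#' @param trim_width width to trim peaks to around their summit (default
#'   120); NULL to disable trimming.
#' @param windows local background window sizes in bases.
#' @return an object of class \code{dag_peaks}: \code{peaks} (list of
#'   \code{graph_peak} with summits; untrimmed paths kept in
#'   \code{full_path}), \code{linear} (projected peak table),
#'   \code{qtrack}, \code{subgraphs}, \code{report} (read counts,
#'   fragment length, peak count) and the parameters used.
#' @examples
#' sim <- simulate_experiment(sim_config(backbone_length = 20000L,
#'                                       n_sites = 2L, n_alt_sites = 0L,
#'                                       seed = 7L))
#' res <- call_peaks(sim$graph, sim$input, sim$control,
#'                   fragment_length = 200L)
#' res
#' @export
call_peaks <- function(graph, alignments, control = NULL,
                       fragment_length = NULL, read_length = NULL,
                       qvalue = 0.05, min_mapq = 37L, trim_width = 120L,
                       windows = NULL) {
  stopifnot(inherits(graph, "graph_genome"))
  n_raw <- length(alignments)
  alignments <- filter_alignments(alignments, min_mapq)
  if (!length(alignments)) stop("no alignments pass the mapq filter")
  no_control <- is.null(control)
  control <- if (no_control) alignments
             else filter_alignments(control, min_mapq)
  if (is.null(windows))
    windows <- if (no_control) c(5000L, 10000L) else c(1000L, 10000L)

  flm <- NULL
  if (is.null(fragment_length) || is.null(read_length)) {
    flm <- estimate_fragment_length(alignments, graph)
    if (is.null(fragment_length)) fragment_length <- flm$fragment_length
    if (is.null(read_length)) read_length <- flm$read_length
  }
  f <- as.integer(fragment_length); r <- as.integer(read_length)

  proj <- build_linear_projection(graph)
  pileup <- fragment_pileup(alignments, f, graph)
  bg <- background_track(control, graph, proj, f, window_sizes = windows,
                         n_input = length(alignments),
                         n_control = length(control))
  ptrack <- pvalue_track(pileup, bg)
  qtrack <- qvalue_track(ptrack)
  regions <- threshold_track(qtrack, alpha = qvalue)
  filled <- fill_gaps(regions, r, graph)
  subgraphs <- connected_subgraphs(filled, graph)

  peaks <- list()
  for (sg in subgraphs) {
    p <- find_max_path(sg, alignments, graph)
    if (is.null(p)) next
    peaks[[length(peaks) + 1L]] <- peak_summit(p, qtrack, graph)
  }
  peaks <- remove_short_peaks(peaks, f)
  if (!is.null(trim_width))
    peaks <- lapply(peaks, trim_peak, width = trim_width, graph = graph)
  linear <- peaks_to_linear(peaks, proj, graph)

  structure(list(
    peaks = peaks, linear = linear, subgraphs = subgraphs,
    qtrack = qtrack, pileup = pileup, background = bg, proj = proj,
    fragment_model = flm, graph_name = graph$name,
    params = list(fragment_length = f, read_length = r, qvalue = qvalue,
                  min_mapq = min_mapq, trim_width = trim_width,
                  windows = windows, no_control = no_control),
    report = list(
      n_alignments = n_raw, n_after_filter = length(alignments),
      n_control = if (no_control) NA_integer_ else length(control),
      fragment_length = f, read_length = r,
      n_subgraphs = length(subgraphs), n_peaks = length(peaks))),
    class = "dag_peaks")
}

#' @export
print.dag_peaks <- function(x, ...) {
  r <- x$report
  cat(sprintf("dag_peaks on '%s': %d peaks (q < %g)\n", x$graph_name,
              r$n_peaks, x$params$qvalue))
  cat(sprintf("  alignments: %d (%d after mapq >= %d filter)%s\n",
              r$n_alignments, r$n_after_filter, x$params$min_mapq,
              if (x$params$no_control) ", no control (self-background)"
              else sprintf(", %d control reads", r$n_control)))
  cat(sprintf("  fragment length %d, read length %d, %d candidate subgraphs\n",
              r$fragment_length, r$read_length, r$n_subgraphs))
  invisible(x)
}

#' @export
summary.dag_peaks <- function(object, ...) {
  print(object)
  if (nrow(object$linear)) {
    lin <- object$linear
    cat(sprintf("  summit q-scores: median %.2f, max %.2f\n",
                stats::median(lin$summit_qscore), max(lin$summit_qscore)))
    cat(sprintf("  linear spans: %s\n",
                paste(sprintf("%s:%d-%d", lin$chrom, lin$start, lin$end),
                      collapse = ", ")))
  }
  invisible(object)
}

#' @export
as.data.frame.dag_peaks <- function(x, ...) x$linear

#' Run the peak caller on files and write all outputs
#'
#' File-level orchestration of \code{\link{call_peaks}}: loads graph and
#' GAM JSON alignments, runs the pipeline, and writes
#' \code{<prefix>_peaks.jsonl} (graph peaks), \code{<prefix>.narrowPeak}
#' (linear projection) and \code{<prefix>_report.json}.
#'
#' @param graph_file vg-JSON (or GFA1, by extension \code{.gfa}) graph.
#' @param alignment_file GAM JSON-lines input reads.
#' @param control_file optional GAM JSON-lines control reads.
#' @param out_prefix path prefix for outputs.
#' @param ... passed to \code{\link{call_peaks}}.
#' @return the \code{dag_peaks} object, invisibly.
#' @export
run_callpeaks <- function(graph_file, alignment_file, control_file = NULL,
                          out_prefix = "dagpeaks", ...) {
  fmt <- if (grepl("\\.gfa$", graph_file)) "gfa1" else "vg-json"
  graph <- load_graph(graph_file, fmt)
  alns <- load_alignments(alignment_file, graph)
  ctrl <- if (!is.null(control_file)) load_alignments(control_file, graph)
  res <- call_peaks(graph, alns, ctrl, ...)
  write_peaks_json(res$peaks, paste0(out_prefix, "_peaks.jsonl"))
  write_narrowpeak(res$linear, paste0(out_prefix, ".narrowPeak"))
  writeLines(jsonlite::toJSON(res$report, auto_unbox = TRUE, digits = NA),
             paste0(out_prefix, "_report.json"))
  invisible(res)
}
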