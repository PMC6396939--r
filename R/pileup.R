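#' Estimate the fragment length by strand cross-correlation
#'
#' Implements the linear fragment-length estimation step on the graph's
#' reference path: the 5' start of every alignment is projected to linear
#' coordinates by strand (the exclusive fragment end for reverse reads, so
#' that the optimal shift equals the fragment length directly), and the
#' shift maximizing the cross-correlation between the forward and reverse
#' start-density vectors is returned.  The read length is taken as the
#' modal alignment length.  Two ideal point clusters separated by exactly
#' \code{d} therefore yield an estimate of exactly \code{d}.
#'
#' @param alignments list of (already filtered) \code{graph_alignment}.
#' @param graph the \code{graph_genome}.
#' @param shift_min,shift_max inclusive range of shifts (bp) scanned.
#' @param min_alignments floor below which estimation refuses to run.
#' @param smooth moving-average window (shifts) applied to the
#'   correlation profile before the argmax; 1 disables smoothing.
#' @return object of class \code{fragment_length_model} with fields
#'   \code{fragment_length}, \code{read_length}, \code{method} and
#'   \code{correlation_profile} (data.frame of shift and score).
#' @export
estimate_fragment_length <- function(alignments, graph,
                                     shift_min = 0L, shift_max = 600L,
                                     min_alignments = 100L, smooth = 21L) {
  stopifnot(shift_min < shift_max)
  if (length(alignments) < min_alignments)
    stop("only ", length(alignments), " alignments (< ", min_alignments,
         "): too few to estimate the fragment length; pass fragment_length ",
         "explicitly")
  proj <- build_linear_projection(graph)
  L <- proj$path_length
  is_rev <- vapply(alignments, function(a)
    a$interval$direction == "reverse", logical(1))
  five_prime <- vapply(alignments, function(a) {
    iv <- a$interval
    if (iv$direction == "forward")
      project_position_to_linear(iv$node_path[1L], iv$start, graph, proj)
    else
      project_position_to_linear(iv$node_path[length(iv$node_path)],
                                 iv$end - 1L, graph, proj) + 1
  }, numeric(1))
  # forward starts indexed at coord+1; reverse (exclusive) ends indexed at
  # coord, so that matching indices correspond to a separation of exactly
  # the scanned shift
  fwd <- tabulate(pmin(five_prime[!is_rev], L - 1) + 1, nbins = L)
  rev <- tabulate(pmax(1, pmin(five_prime[is_rev], L)), nbins = L)
  fp <- which(fwd > 0L); fv <- fwd[fp]
  shifts <- shift_min:shift_max
  score <- vapply(shifts, function(d) {
    tgt <- fp - 1L + d
    ok <- tgt >= 1L & tgt <= L
    sum(fv[ok] * rev[tgt[ok]])
  }, numeric(1))
  # moving-average smoothing before the argmax suppresses per-shift
  # sampling noise; the profile itself is returned unsmoothed
  sm <- if (smooth > 1L) {
    k <- min(smooth, length(score))
    cs <- cumsum(c(0, score))
    h <- k %/% 2L
    lo <- pmax(seq_along(score) - h, 1L)
    hi <- pmin(seq_along(score) + h, length(score))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else score
  f <- shifts[which.max(sm)]             # smallest shift wins ties
  lens <- vapply(alignments, function(a) a$read_length, integer(1))
  tab <- tabulate(lens)
  r <- which.max(tab)
  if (f < r) {
    warning("cross-correlation estimate (", f, ") below the read length (",
            r, "); using the read length")
    f <- r
  }
  structure(list(fragment_length = as.integer(f), read_length = as.integer(r),
                 method = "strand cross-correlation",
                 correlation_profile = data.frame(shift = shifts,
                                                  score = score)),
            class = "fragment_length_model")
}

#' @export
print.fragment_length_model <- function(x, ...) {
  cat(sprintf("fragment_length_model (%s): f = %d, r = %d\n",
              x$method, x$fragment_length, x$read_length))
  invisible(x)
}

# Covered-base segments of one alignment extended to fragment length f:
# the read's own bases plus every path of length f - r continuing from the
# read's 3' end in the read's direction (breadth-first, union over paths).
# Returns a matrix with columns idx, start, end (0-based half-open).
.extend_segments <- function(aln, f, graph) {
  segs <- interval_segments(aln$interval, graph)
  r <- interval_length(aln$interval, graph)
  rem <- f - r
  if (rem <= 0L) return(segs)
  k <- nrow(segs)
  if (aln$interval$direction == "forward") {
    i <- segs[k, "idx"]
    avail <- graph$lengths[i] - segs[k, "end"]
    take <- min(rem, avail)
    segs[k, "end"] <- segs[k, "end"] + take
    budget <- rem - avail                 # what crosses the node end
    if (budget > 0L)
      segs <- rbind(segs, .bfs_cover(graph, i, budget, forward = TRUE))
  } else {
    i <- segs[1L, "idx"]
    avail <- segs[1L, "start"]
    take <- min(rem, avail)
    segs[1L, "start"] <- segs[1L, "start"] - take
    budget <- rem - avail
    if (budget > 0L)
      segs <- rbind(segs, .bfs_cover(graph, i, budget, forward = FALSE))
  }
  segs
}

# Union of bases reachable within `budget` steps from the boundary of
# node `from` following successor (forward) or predecessor edges.  A node
# entered with budget b contributes its first (forward) or last (reverse)
# min(b, length) bases; the per-node maximum entering budget over all
# paths realizes the union.  Paths hitting sinks/sources just truncate.
.bfs_cover <- function(graph, from, budget, forward = TRUE) {
  nbr <- if (forward) graph$succ else graph$pred
  best <- new.env(parent = emptyenv())
  queue <- nbr[[from]]
  qb <- rep.int(budget, length(queue))
  while (length(queue)) {
    v <- queue[[1L]]; b <- qb[[1L]]
    queue <- queue[-1L]; qb <- qb[-1L]
    key <- as.character(v)
    prev <- best[[key]]
    if (!is.null(prev) && prev >= b) next
    assign(key, b, envir = best)
    left <- b - graph$lengths[v]
    if (left > 0L) {
      nx <- nbr[[v]]
      queue <- c(queue, nx)
      qb <- c(qb, rep.int(left, length(nx)))
    }
  }
  nodes <- as.integer(ls(best))
  if (!length(nodes)) return(matrix(integer(0), ncol = 3L,
                                    dimnames = list(NULL,
                                      c("idx", "start", "end"))))
  bud <- vapply(as.character(nodes), function(k) best[[k]], numeric(1))
  cov <- pmin(bud, graph$lengths[nodes])
  if (forward)
    cbind(idx = nodes, start = 0L, end = as.integer(cov))
  else
    cbind(idx = nodes, start = as.integer(graph$lengths[nodes] - cov),
          end = graph$lengths[nodes])
}

#' Bases covered by an alignment extended to fragment length f
#'
#' Fragment extension on a graph: the read is extended by \code{f - r}
#' bases from its 3' end along \emph{all} possible paths (breadth-first),
#' forward alignments along successor edges, reverse alignments along
#' predecessor edges.  The result is the union of bases covered by the
#' read and any extension path; each base is covered at most once per
#' read.  Extension paths reaching a sink (or source) contribute the bases
#' they can.
#'
#' @param aln a \code{graph_alignment}.
#' @param f fragment length; must be at least the read length.
#' @param graph the \code{graph_genome}.
#' @return data.frame with columns \code{node}, \code{start}, \code{end}:
#'   the covered bases as per-node half-open runs.
#' @export
extend_alignment <- function(aln, f, graph) {
  if (f < interval_length(aln$interval, graph))
    stop("fragment length ", f, " is shorter than the alignment")
  segs <- .extend_segments(aln, f, graph)
  df <- data.frame(node = graph$ids[segs[, "idx"]],
                   start = as.integer(segs[, "start"]),
                   end = as.integer(segs[, "end"]))
  df[order(df$node, df$start), , drop = FALSE]
}

#' Fragment pileup: per-base count of extended reads
#'
#' The value at each base is the number of alignments whose extended
#' coverage set (see \code{\link{extend_alignment}}) contains that base.
#'
#' @param alignments list of \code{graph_alignment} (mapq-filtered).
#' @param f fragment length (estimated or user-supplied).
#' @param graph the \code{graph_genome}.
#' @return a \code{pileup_track} of nonnegative counts.
#' @export
fragment_pileup <- function(alignments, f, graph) {
  tr <- new_track(graph, 0)
  for (a in alignments) {
    segs <- .extend_segments(a, f, graph)
    for (row in seq_len(nrow(segs))) {
      i <- segs[row, "idx"]
      lo <- tr$starts[i] + segs[row, "start"]
      hi <- tr$starts[i] + segs[row, "end"] - 1L
      tr$data[lo:hi] <- tr$data[lo:hi] + 1
    }
  }
  tr
}

#' Local-lambda Poisson background track
#'
#' Estimates the expected read rate at every graph base the way MACS2
#' estimates its local lambda on a linear genome: control read 5' starts
#' are projected to linear coordinates, per-base densities are computed
#' globally and in centered windows of each requested size, the rate is
#' \code{f * max(global, window densities)}, and the linear rate vector is
#' assigned back to every graph base through its projected coordinate
#' (parallel alleles therefore share rates).  Finally all rates are
#' multiplied by \code{n_input / n_control}, scaling the control track to
#' the input sequencing depth.
#'
#' @param control_alignments list of \code{graph_alignment}; may be the
#'   input alignments themselves (no-control mode, in which case the
#'   caller should drop the smallest window, see \code{\link{call_peaks}}).
#' @param graph the \code{graph_genome}.
#' @param proj a \code{\link{build_linear_projection}} result.
#' @param f fragment length in bases.
#' @param window_sizes window sizes (bp) for the local averages.
#' @param n_input,n_control read counts used for depth scaling.
#' @return object of class \code{background_track}: \code{rates} (a
#'   \code{pileup_track} of strictly positive Poisson rates),
#'   \code{global_rate} and \code{scale}.
#' @export
background_track <- function(control_alignments, graph, proj, f,
                             window_sizes = c(1000L, 10000L),
                             n_input = length(control_alignments),
                             n_control = length(control_alignments)) {
  if (!length(control_alignments)) stop("empty control alignment set")
  L <- proj$path_length
  if (any(window_sizes %% 2L != 0L) || any(window_sizes >= L))
    stop("window sizes must be even and smaller than the reference length")
  starts <- vapply(control_alignments, function(a) {
    iv <- a$interval
    if (iv$direction == "forward")
      project_position_to_linear(iv$node_path[1L], iv$start, graph, proj)
    else
      project_position_to_linear(iv$node_path[length(iv$node_path)],
                                 iv$end - 1L, graph, proj)
  }, numeric(1))
  cnt <- tabulate(pmin(starts, L - 1) + 1, nbins = L)
  cs <- c(0, cumsum(cnt))
  g <- length(control_alignments) / L
  dens <- rep(g, L)
  pos <- seq_len(L) - 1L
  for (w in window_sizes) {
    lo <- pmax(0L, pos - w %/% 2L)
    hi <- pmin(L, pos + w %/% 2L)
    dens <- pmax(dens, (cs[hi + 1L] - cs[lo + 1L]) / w)
  }
  scale <- n_input / n_control
  lin_rate <- pmax(f * dens * scale, .Machine$double.eps)
  tr <- new_track(graph, 0)
  tr$data <- lin_rate[base_coords(graph, proj) + 1]
  structure(list(rates = tr, global_rate = f * g * scale, scale = scale,
                 window_sizes = window_sizes),
            class = "background_track")
}

#' @export
print.background_track <- function(x, ...) {
  cat(sprintf("background_track: global rate %.4g, scale %.3g, windows %s\n",
              x$global_rate, x$scale,
              paste(x$window_sizes, collapse = "/")))
  invisible(x)
}
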