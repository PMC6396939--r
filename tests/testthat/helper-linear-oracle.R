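# A scalar (purely linear-coordinate) implementation of the five
# peak-calling steps, written independently of the graph code: reads are
# plain (start, end, strand) rows on a sequence of length L.  Used to
# check that the graph pipeline reduces exactly to classic linear peak
# calling on chain graphs.

linear_estimate_f <- function(reads, L, shift_min = 0L, shift_max = 600L,
                              smooth = 21L) {
  fwd <- tabulate(reads$start[reads$strand == "+"] + 1L, nbins = L)
  rev <- tabulate(reads$end[reads$strand == "-"], nbins = L)
  shifts <- shift_min:shift_max
  # fwd index = coord+1, rev index = coord: fwd[i] pairs with rev[i-1+d]
  sc <- vapply(shifts, function(d) {
    i <- which(fwd > 0L)
    j <- i - 1L + d
    ok <- j >= 1L & j <= L
    sum(fwd[i[ok]] * rev[j[ok]])
  }, numeric(1))
  smoothed <- stats::filter(sc, rep(1 / smooth, smooth), sides = 2)
  # partial windows at the edges
  for (k in which(is.na(smoothed))) {
    lo <- max(1L, k - smooth %/% 2L); hi <- min(length(sc), k + smooth %/% 2L)
    smoothed[k] <- mean(sc[lo:hi])
  }
  shifts[which.max(smoothed)]
}

linear_pileup <- function(reads, f, L) {
  delta <- numeric(L + 1L)
  for (i in seq_len(nrow(reads))) {
    if (reads$strand[i] == "+") {
      a <- reads$start[i]; b <- min(L, reads$start[i] + f)
    } else {
      a <- max(0L, reads$end[i] - f); b <- reads$end[i]
    }
    delta[a + 1L] <- delta[a + 1L] + 1
    delta[b + 1L] <- delta[b + 1L] - 1
  }
  cumsum(delta)[seq_len(L)]
}

linear_background <- function(control, L, f, windows, n_input, n_control) {
  starts <- ifelse(control$strand == "+", control$start, control$end - 1L)
  cnt <- tabulate(pmin(starts, L - 1L) + 1L, nbins = L)
  cs <- c(0, cumsum(cnt))
  dens <- rep(nrow(control) / L, L)
  for (w in windows) {
    i <- seq_len(L) - 1L
    lo <- pmax(0L, i - w %/% 2L); hi <- pmin(L, i + w %/% 2L)
    dens <- pmax(dens, (cs[hi + 1L] - cs[lo + 1L]) / w)
  }
  pmax(f * dens * (n_input / n_control), .Machine$double.eps)
}

linear_fill_gaps <- function(mask, r) {
  rl <- rle(mask)
  ends <- cumsum(rl$lengths)
  for (k in seq_along(rl$values)) {
    if (rl$values[k] || k == 1L || k == length(rl$values)) next
    if (rl$lengths[k] < r)
      mask[(ends[k] - rl$lengths[k] + 1L):ends[k]] <- TRUE
  }
  mask
}

# the full scalar pipeline; returns the sorted set of peak base
# coordinates (0-based) plus the per-run peak table
linear_pipeline <- function(reads, control, L, f = NULL, r = NULL,
                            alpha = 0.05, windows = c(1000L, 10000L)) {
  if (is.null(f)) f <- linear_estimate_f(reads, L)
  if (is.null(r)) {
    lens <- reads$end - reads$start
    r <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  }
  pile <- linear_pileup(reads, f, L)
  lambda <- linear_background(control, L, f, windows,
                              n_input = nrow(reads),
                              n_control = nrow(control))
  p <- stats::ppois(pile - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  mask <- q < alpha
  mask <- linear_fill_gaps(mask, r)
  rl <- rle(mask)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths
  keep <- rl$values & rl$lengths >= f
  peaks <- data.frame(start = starts[keep], end = ends[keep])
  bases <- unlist(lapply(seq_len(nrow(peaks)), function(k)
    seq.int(peaks$start[k], peaks$end[k] - 1L)), use.names = FALSE)
  list(f = f, r = r, peaks = peaks, bases = sort(bases), mask = mask,
       q = q)
}

# project a list of graph alignments on a chain graph to linear rows
alignments_to_linear <- function(alignments, graph, proj) {
  do.call(rbind, lapply(alignments, function(a) {
    iv <- a$interval
    s <- project_position_to_linear(iv$node_path[1L], iv$start, graph, proj)
    e <- project_position_to_linear(iv$node_path[length(iv$node_path)],
                                    iv$end - 1L, graph, proj) + 1L
    data.frame(start = s, end = e,
               strand = if (iv$direction == "forward") "+" else "-")
  }))
}

# the union of untrimmed peak-path bases of a dag_peaks result, projected
# to linear coordinates
dag_peak_bases <- function(res, graph) {
  out <- integer(0)
  for (p in res$peaks) {
    iv <- if (!is.null(p$full_path)) p$full_path else p$path
    s <- project_position_to_linear(iv$node_path[1L], iv$start, graph,
                                    res$proj)
    e <- project_position_to_linear(iv$node_path[length(iv$node_path)],
                                    iv$end - 1L, graph, res$proj) + 1L
    out <- c(out, seq.int(s, e - 1L))
  }
  sort(unique(out))
}
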