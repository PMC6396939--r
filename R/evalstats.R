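#' One-sided two-proportion z-test (pooled variance)
#'
#' Tests whether the proportion in group 1 exceeds that in group 2 using
#' the pooled estimate \eqn{\hat p = (x_1+x_2)/(n_1+n_2)},
#' \eqn{z = (x_1/n_1 - x_2/n_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},
#' with the one-sided upper-tail normal p-value.  This is the standard
#' test for comparing e.g. motif-match rates between two peak sets.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return an object of class \code{htest} with the z statistic, the
#'   one-sided p-value and both sample proportions.
#' @examples
#' two_proportion_z_test(927, 14637, 750, 13073)
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("need 0 <= x <= n in both groups")
  p_hat <- (x1 + x2) / (n1 + n2)
  if (p_hat == 0 || p_hat == 1)
    stop("degenerate test: pooled proportion is ", p_hat)
  p1 <- x1 / n1; p2 <- x2 / n2
  z <- (p1 - p2) / sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  structure(list(
    statistic = c(z = z),
    p.value = stats::pnorm(z, lower.tail = FALSE),
    estimate = c(`prop 1` = p1, `prop 2` = p2),
    alternative = "greater",
    method = "One-sided two-proportion z-test (pooled variance)",
    data.name = sprintf("%d/%d vs %d/%d", x1, n1, x2, n2)),
    class = "htest")
}

#' Percentage of peaks with a motif match
#'
#' @param matches number of peaks with at least one motif match.
#' @param total number of peaks.
#' @return percentage, rounded to two decimals.
#' @examples
#' motif_match_ratio(927, 14637)   # 6.33
#' @export
motif_match_ratio <- function(matches, total) {
  if (total <= 0) stop("undefined ratio: total must be positive")
  if (matches < 0 || matches > total) stop("need 0 <= matches <= total")
  round(100 * matches / total, 2)
}

#' Build a log-odds position weight matrix from base counts
#'
#' Converts a JASPAR-style count matrix to per-position log2-odds scores
#' against a background base composition, with a pseudocount distributed
#' by the background.  The default score threshold is the smallest score
#' whose upper-tail probability under the background model is at most
#' \code{score_p}, computed exactly by discretized convolution of the
#' per-position score distributions.
#'
#' @param counts 4 x width numeric matrix with rownames A, C, G, T.
#' @param background length-4 base frequency vector summing to 1.
#' @param pseudocount total pseudocount added per column (split by
#'   background frequency).
#' @param score_p upper-tail probability defining the default match
#'   threshold.
#' @return object of class \code{pwm_model}: \code{log_odds} (4 x width),
#'   \code{width}, \code{background}, \code{score_threshold} and the
#'   consensus sequence.
#' @export
pwm_model <- function(counts, background = rep(0.25, 4), pseudocount = 0.8,
                      score_p = 1e-4) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (any(background <= 0)) stop("background frequencies must be positive")
  w <- ncol(counts)
  probs <- sweep(counts + pseudocount * background, 2L,
                 colSums(counts) + pseudocount, `/`)
  lo <- log2(probs / background)
  thr <- .pwm_threshold(lo, background, score_p)
  structure(list(log_odds = lo, width = w, background = background,
                 score_threshold = thr,
                 consensus = paste(rownames(lo)[apply(lo, 2L, which.max)],
                                   collapse = "")),
            class = "pwm_model")
}

# Exact upper-tail score threshold under the background model: convolve
# the per-position score distributions on a 1e-3 grid and take the
# smallest score whose tail probability is <= p.
.pwm_threshold <- function(lo, background, p) {
  grid <- 1000
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(lo))) {
    keys <- as.numeric(names(dist))
    sc <- round(lo[, j] * grid)
    nk <- as.vector(outer(keys, sc, `+`))
    np <- as.vector(outer(unname(dist), background, `*`))
    agg <- tapply(np, nk, sum)
    dist <- agg
    names(dist) <- names(agg)
  }
  keys <- as.numeric(names(dist))
  o <- order(keys, decreasing = TRUE)
  tailp <- cumsum(dist[o])
  ok <- which(tailp <= p)
  if (!length(ok)) return(max(keys) / grid + 1 / grid)  # nothing passes
  # back off by the maximum rounding error so unrounded window scores at
  # the selected level still pass
  keys[o][max(ok)] / grid - (ncol(lo) + 1) * 0.5 / grid
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the common JASPAR text layout: a \code{>} header line followed
#' by four rows \code{A [ ... ]} etc. (brackets optional).
#'
#' @param path file path.
#' @return 4 x width count matrix with rownames A, C, G, T; the motif
#'   name is attached as attribute \code{"name"}.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  name <- sub("^>\\s*", "", lines[grepl("^>", lines)][1] %||% "motif")
  rows <- lines[grepl("^[ACGT]", lines)]
  if (length(rows) != 4L) stop("JASPAR file '", path,
                               "' must have rows for A, C, G and T")
  bases <- substr(rows, 1L, 1L)
  vals <- lapply(rows, function(r) {
    r <- gsub("[][]", " ", substr(r, 2L, nchar(r)))
    as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
  })
  if (length(unique(lengths(vals))) != 1L)
    stop("JASPAR rows in '", path, "' have unequal widths")
  m <- do.call(rbind, vals)
  rownames(m) <- bases
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  attr(m, "name") <- name
  m
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model: width %d, consensus %s, score threshold %.3f\n",
              x$width, x$consensus, x$score_threshold))
  invisible(x)
}

revcomp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

.seq_codes <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1L]], c("A", "C", "G", "T"))
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of \code{pwm$width} bases on the forward strand
#' and on the reverse complement; scores are sums of per-position
#' log2-odds (\code{N} contributes 0).  Offsets are 0-based positions of
#' the window on the forward sequence for both strands.
#'
#' @param sequence character scalar over ACGTN.
#' @param pwm a \code{\link{pwm_model}}.
#' @return data.frame with columns \code{offset}, \code{strand}
#'   (\code{"+"}/\code{"-"}) and \code{score}; zero rows when the
#'   sequence is shorter than the motif.
#' @export
pwm_scan <- function(sequence, pwm) {
  w <- pwm$width
  scan1 <- function(s) {
    codes <- .seq_codes(s)
    L <- length(codes)
    if (L < w) return(numeric(0))
    vapply(0:(L - w), function(o) {
      cc <- codes[(o + 1L):(o + w)]
      ok <- !is.na(cc)
      sum(pwm$log_odds[cbind(cc[ok], which(ok))])
    }, numeric(1))
  }
  fs <- scan1(sequence)
  rs <- scan1(revcomp(sequence))
  L <- nchar(sequence)
  out <- rbind(
    if (length(fs)) data.frame(offset = 0:(L - w), strand = "+", score = fs),
    if (length(rs)) data.frame(offset = L - w - (0:(L - w)), strand = "-",
                               score = rs))
  if (is.null(out))
    out <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  out
}

#' Motif matches above the PWM threshold
#'
#' @param sequence character scalar. @param pwm a \code{pwm_model}.
#' @param threshold score cutoff; defaults to the PWM's exact-tail
#'   threshold.
#' @return the \code{\link{pwm_scan}} rows with \code{score >= threshold},
#'   sorted by decreasing score.  A peak "has a motif match" iff this has
#'   at least one row for its path sequence.
#' @export
pwm_matches <- function(sequence, pwm, threshold = pwm$score_threshold) {
  sc <- pwm_scan(sequence, pwm)
  sc <- sc[sc$score >= threshold, , drop = FALSE]
  sc[order(-sc$score, sc$offset), , drop = FALSE]
}
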