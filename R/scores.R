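#' Upper-tail Poisson p-value
#'
#' \code{P(X >= count)} for \code{X ~ Poisson(rate)} — the upper tail
#' including the observed count, the convention MACS2 uses, so a count of
#' 0 always gives p = 1.  Vectorized over \code{count} and \code{rate}.
#'
#' @param count nonnegative integer observed count(s).
#' @param rate positive Poisson rate(s).
#' @return p-value(s) in (0, 1].
#' @export
poisson_pvalue <- function(count, rate) {
  if (any(rate <= 0)) stop("Poisson rate must be positive")
  if (any(count < 0)) stop("count must be nonnegative")
  stats::ppois(count - 1, rate, lower.tail = FALSE)
}

# score cap: -log10 p and -log10 q are truncated here to avoid infinities
# when p underflows
SCORE_CAP <- 1000

#' Per-base -log10 Poisson p-value track
#'
#' Treats the fragment pileup as counts and the background track as rates
#' in Poisson distributions and scores every base.  Computed in log space
#' (so p-values far below double precision still get finite scores) and
#' capped at 1000.
#'
#' @param pileup a \code{pileup_track} of counts.
#' @param background a \code{\link{background_track}}.
#' @return a \code{score_track} with \code{kind = "p"}.
#' @export
pvalue_track <- function(pileup, background) {
  rates <- background$rates
  if (!track_same_shape(pileup, rates))
    stop("pileup and background tracks have different shapes")
  logp <- stats::ppois(pileup$data - 1, rates$data, lower.tail = FALSE,
                       log.p = TRUE)
  tr <- pileup
  tr$data <- pmin(-logp / log(10), SCORE_CAP)
  class(tr) <- c("score_track", "pileup_track")
  attr(tr, "kind") <- "p"
  tr
}

#' Benjamini-Hochberg q-value track over all graph bases
#'
#' Every base of the graph (reference and alternative alleles alike) is
#' one test.  Bases are pooled by distinct p-value, the BH adjustment is
#' applied with the multiplicity of each distinct value over the total
#' base count, and monotonicity is enforced, all on the -log10 scale so
#' underflowing p-values keep finite q-scores.  Scores are capped at 1000.
#'
#' @param ptrack a \code{score_track} with \code{kind = "p"} (values are
#'   -log10 p).
#' @return a \code{score_track} with \code{kind = "q"} (values -log10 q).
#' @export
qvalue_track <- function(ptrack) {
  if (!identical(attr(ptrack, "kind"), "p"))
    stop("qvalue_track needs a p-value score track")
  s <- ptrack$data
  N <- length(s)
  sv <- sort(unique(s), decreasing = TRUE)      # ascending p
  cnt <- tabulate(match(s, sv), nbins = length(sv))
  ranks <- cumsum(cnt)                          # bases with p' <= p
  qs_raw <- sv + log10(ranks) - log10(N)        # -log10( p * N / rank )
  qs <- rev(cummax(rev(qs_raw)))                # q_i = min_{j>=i} raw_j
  qs <- pmax(pmin(qs, sv), 0)                   # q >= p and q <= 1
  tr <- ptrack
  tr$data <- pmin(qs[match(s, sv)], SCORE_CAP)
  attr(tr, "kind") <- "q"
  tr
}

#' Threshold a q-score track into candidate regions
#'
#' A base is included iff its q-value is strictly below \code{alpha}
#' (q-score strictly above \code{-log10(alpha)}).
#'
#' @param qtrack a \code{score_track} with \code{kind = "q"}.
#' @param alpha FDR threshold in (0, 1); default 0.05.
#' @return a \code{region_set}: a logical mask in track shape.
#' @export
threshold_track <- function(qtrack, alpha = 0.05) {
  if (!identical(attr(qtrack, "kind"), "q"))
    stop("threshold_track needs a q-value score track")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  mask <- qtrack
  mask$data <- qtrack$data > -log10(alpha)
  attr(mask, "kind") <- NULL
  class(mask) <- c("region_set", "pileup_track")
  mask
}

#' Maximal per-node intervals of a region set
#'
#' @param regions a \code{region_set} (logical mask track).
#' @return data.frame with columns \code{node}, \code{start}, \code{end}:
#'   the maximal runs of included bases within each node.
#' @export
region_intervals <- function(regions) {
  out <- vector("list", length(regions$ids))
  for (i in seq_along(regions$ids)) {
    v <- regions$data[regions$starts[i]:(regions$starts[i] +
                                           regions$lengths[i] - 1L)]
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out[[i]] <- data.frame(node = regions$ids[i], start = starts[keep],
                           end = ends[keep])
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(node = integer(0), start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}
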