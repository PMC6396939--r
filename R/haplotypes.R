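#' Construct a variant-by-haplotype allele panel
#'
#' @param variants data.frame with columns \code{pos} (0-based linear
#'   position, strictly increasing), \code{ref}, \code{alt} and
#'   \code{type} (\code{"snp"}, \code{"ins"} or \code{"del"}).
#' @param genotypes haplotype-by-variant 0/1 matrix (rows = haplotypes,
#'   columns = variants); rownames are haplotype ids.
#' @param nodes optional per-variant graph annotation, a list parallel to
#'   \code{variants} with entries \code{alt_node} (NA for deletions),
#'   \code{ref_nodes} (reference nodes replaced/skipped by the alt
#'   allele) and, for deletions, \code{from}/\code{to} (the flanking
#'   nodes of the deletion edge).  Needed to extract alleles from
#'   alignments.
#' @return object of class \code{haplotype_panel}.
#' @export
haplotype_panel <- function(variants, genotypes, nodes = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("pos", "ref", "alt", "type") %in% names(variants)))
  genotypes <- as.matrix(genotypes)
  if (nrow(variants) != ncol(genotypes))
    stop("genotypes must have one column per variant")
  if (is.unsorted(variants$pos, strictly = TRUE))
    stop("variant positions must be strictly increasing")
  if (!all(genotypes %in% c(0L, 1L)))
    stop("genotype indicators must be 0 or 1")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("hap", seq_len(nrow(genotypes)))
  if (!is.null(nodes) && length(nodes) != nrow(variants))
    stop("nodes annotation must be parallel to variants")
  structure(list(variants = variants, genotypes = genotypes, nodes = nodes),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d variants x %d haplotypes (%s)\n",
              nrow(x$variants), nrow(x$genotypes),
              paste(names(table(x$variants$type)),
                    table(x$variants$type), sep = ":", collapse = ", ")))
  invisible(x)
}

#' Alleles an alignment carries at the panel's variant sites
#'
#' Inspects the alignment's node path: traversing a variant's alternative
#' node (or, for deletions, the edge that skips the deleted reference
#' nodes) means the alignment carries the alt allele; traversing a
#' reference node of the variant means it carries the ref allele.
#'
#' @param aln a \code{graph_alignment}.
#' @param panel a \code{haplotype_panel} with node annotations.
#' @param graph the \code{graph_genome}.
#' @return integer vector, one entry per panel variant: 1 (alt), 0 (ref)
#'   or NA (site not covered by the alignment).
#' @export
alignment_variant_alleles <- function(aln, panel, graph) {
  if (is.null(panel$nodes))
    stop("panel lacks graph node annotations; cannot extract alleles")
  path <- aln$interval$node_path
  nv <- nrow(panel$variants)
  out <- rep(NA_integer_, nv)
  adjacent <- function(a, b) {     # does the path use edge a -> b?
    m <- length(path)
    m >= 2L && any(path[-m] == a & path[-1L] == b)
  }
  for (k in seq_len(nv)) {
    an <- panel$nodes[[k]]
    out[k] <- switch(panel$variants$type[k],
      del = if (adjacent(an$from, an$to)) 1L           # the deletion edge
            else if (any(an$ref_nodes %in% path)) 0L else NA_integer_,
      ins = if (an$alt_node %in% path) 1L              # the inserted node
            else if (adjacent(an$from, an$to)) 0L else NA_integer_,
      snp = if (an$alt_node %in% path) 1L
            else if (any(an$ref_nodes %in% path)) 0L else NA_integer_)
  }
  out
}

#' Haplotypes compatible with an alignment
#'
#' A haplotype is compatible when it carries every alternative allele the
#' alignment uses and, in the default strict mode, also matches the
#' reference allele at covered reference sites.
#'
#' @param alleles per-variant allele vector from
#'   \code{\link{alignment_variant_alleles}} (1/0/NA).
#' @param panel a \code{haplotype_panel}.
#' @param require_ref_match if \code{FALSE}, only alt alleles constrain
#'   compatibility (a haplotype may carry extra variants the alignment
#'   covers as reference).
#' @return character vector of compatible haplotype ids.
#' @export
alignment_haplotype_compatibility <- function(alleles, panel,
                                              require_ref_match = TRUE) {
  if (length(alleles) != nrow(panel$variants))
    stop("allele vector does not match the panel")
  cov <- which(!is.na(alleles))
  haps <- rownames(panel$genotypes)
  if (!length(cov)) return(haps)
  G <- panel$genotypes[, cov, drop = FALSE]
  tgt <- alleles[cov]
  ok <- if (require_ref_match)
    apply(G, 1L, function(g) all(g == tgt))
  else
    apply(G, 1L, function(g) all(g[tgt == 1L] == 1L))
  haps[ok]
}

#' Can all reads in a peak be explained by at most two haplotypes?
#'
#' TRUE iff there exist two haplotypes (possibly the same one, allowing
#' for diploidy) such that every alignment's compatibility set contains at
#' least one of them.  Removing an alignment can never flip TRUE to FALSE.
#'
#' @param compat_sets list of per-alignment compatible haplotype id
#'   vectors (from \code{\link{alignment_haplotype_compatibility}}).
#' @param panel a \code{haplotype_panel}.
#' @return logical.
#' @export
peak_two_haplotype_test <- function(compat_sets, panel) {
  if (!length(compat_sets)) return(TRUE)
  if (any(lengths(compat_sets) == 0L)) return(FALSE)
  haps <- rownames(panel$genotypes)
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      h1 <- haps[i]; h2 <- haps[j]
      if (all(vapply(compat_sets, function(s) h1 %in% s || h2 %in% s,
                     logical(1))))
        return(TRUE)
    }
  }
  FALSE
}

#' Read a haplotype panel from a VCF with per-haplotype genotype columns
#'
#' Expects haploid GT columns (one column per haplotype, values 0/1), the
#' layout the simulator writes.  Indel records use the usual anchored-base
#' VCF convention and are converted back to 0-based positions and bare
#' alleles.  Graph node annotations are not present in a VCF, so the
#' returned panel supports genotype operations only.
#'
#' @param path VCF file path.
#' @return a \code{haplotype_panel} without node annotations.
#' @export
read_haplotype_panel <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_haplotype_panel requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  pos1 <- as.integer(fix[, "POS"])
  type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp",
                 ifelse(nchar(alt) > nchar(ref), "ins", "del"))
  # undo VCF anchoring: SNPs and insertion anchors are the (1-based)
  # reported base; deletions report the anchor base before the first
  # deleted base
  pos0 <- ifelse(type == "del", pos1, pos1 - 1L)
  vref <- ifelse(type == "snp", ref,
                 ifelse(type == "del", substr(ref, 2L, nchar(ref)), ""))
  valt <- ifelse(type == "snp", alt,
                 ifelse(type == "ins", substr(alt, 2L, nchar(alt)), ""))
  variants <- data.frame(pos = pos0, ref = vref, alt = valt, type = type,
                         stringsAsFactors = FALSE)
  geno <- t(apply(gt, 2L, function(col) as.integer(col)))
  rownames(geno) <- colnames(gt)
  colnames(geno) <- NULL
  haplotype_panel(variants, geno)
}
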