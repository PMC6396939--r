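# Synthetic fixture generator: variant graphs (chain backbone + SNP/indel
# bubbles), haplotype panels, planted binding sites and simulated
# ChIP/control alignments in the formats the pipeline consumes.

#' Simulation configuration
#'
#' Defaults emulate a pruned plant-scale pangenome neighbourhood: a 100 kb
#' backbone, roughly one variant per 18 bp (SNPs at 5\% per base plus
#' indels at 0.5\%, both thinned to non-overlapping bubbles), 10
#' haplotypes, 200 bp fragments sequenced as 36 bp single-end reads, and
#' 10 planted binding sites of which 3 carry their motif only on a
#' non-reference allele.
#'
#' @param backbone_length reference length in bases.
#' @param node_size maximum node length the backbone is chopped into.
#' @param snp_rate,indel_rate per-base variant probabilities.
#' @param n_haplotypes haplotypes in the panel.
#' @param n_sites planted binding sites; \code{n_alt_sites} of them have
#'   the motif only on an alternative allele.
#' @param fragment_length,read_length fragment and read lengths (bases).
#' @param reads_per_site ChIP reads per planted site.
#' @param background_reads uniformly placed reads added to the ChIP set.
#' @param control_reads uniformly placed control reads.
#' @param alt_fraction fraction of an alt-site's reads drawn from
#'   haplotypes carrying the site's alternative allele.
#' @param center_sd Gaussian jitter (bp) of fragment centers around the
#'   site for the tightly positioned fragment fraction.
#' @param dispersed_fraction fraction of site fragments placed uniformly
#'   across the protected region instead of tightly centered; their
#'   end-reads are the ones that physically cover the site sequence, as
#'   loosely positioned sonication fragments do in real ChIP libraries.
#' @param low_mapq_fraction fraction of extra noise reads emitted with
#'   mapping quality below 37 (for filter testing).
#' @param seed integer fixing all randomness.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(backbone_length = 100000L, node_size = 32L,
                       snp_rate = 0.05, indel_rate = 0.005,
                       n_haplotypes = 10L, n_sites = 10L, n_alt_sites = 3L,
                       fragment_length = 200L, read_length = 36L,
                       reads_per_site = 100L, background_reads = 1000L,
                       control_reads = 2000L, alt_fraction = 0.8,
                       center_sd = 20, dispersed_fraction = 0.3,
                       low_mapq_fraction = 0, seed = 1L) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            fragment_length >= read_length, read_length >= 1,
            n_alt_sites <= n_sites, alt_fraction >= 0, alt_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Synthetic transcription-factor motif used to mark planted sites: a
# sharply peaked 8 bp profile whose single-mismatch score falls below the
# default match threshold.
SYNTHETIC_MOTIF_CONSENSUS <- "TGACGTCA"

#' Count matrix of the synthetic test motif
#' @param peak_count counts on the consensus base per position.
#' @return 4 x 8 count matrix suitable for \code{\link{pwm_model}}.
#' @export
synthetic_motif_counts <- function(peak_count = 97) {
  bases <- strsplit(SYNTHETIC_MOTIF_CONSENSUS, "")[[1L]]
  m <- matrix(1, nrow = 4L, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- peak_count
  m
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Sample and thin variant positions.  `forced` is a data.frame of SNPs
# that must survive (alt-site motif variants); `blocked` is a two-column
# matrix of [start, end) intervals no sampled variant may touch.
.sample_variants <- function(config, L, forced, blocked) {
  margin <- 50L
  snp_pos <- which(stats::runif(L) < config$snp_rate) - 1L
  ind_pos <- which(stats::runif(L) < config$indel_rate) - 1L
  vars <- rbind(
    if (length(snp_pos))
      data.frame(pos = snp_pos, type = "snp", size = 1L,
                 alt = NA_character_),
    if (length(ind_pos))
      data.frame(pos = ind_pos,
                 type = sample(c("ins", "del"), length(ind_pos),
                               replace = TRUE),
                 size = sample.int(8L, length(ind_pos), replace = TRUE),
                 alt = NA_character_))
  if (is.null(vars))
    vars <- data.frame(pos = integer(0), type = character(0),
                       size = integer(0), alt = character(0))
  vars$forced <- logical(nrow(vars))
  if (nrow(forced)) {
    forced$forced <- TRUE
    vars <- rbind(forced[, names(vars)], vars)
  }
  # span reserved on the reference: [pos, pos+size) for SNPs/deletions;
  # insertions reserve their anchor base and the next one, which also
  # keeps variant positions unique after thinning
  span_start <- vars$pos
  span_end <- ifelse(vars$type == "ins", vars$pos + 2L,
                     vars$pos + vars$size)
  ok <- span_start >= margin & span_end <= L - margin
  if (nrow(blocked)) {
    for (b in seq_len(nrow(blocked)))
      ok <- ok & (vars$forced |
                    span_end <= blocked[b, 1L] | span_start >= blocked[b, 2L])
  }
  vars <- vars[ok, , drop = FALSE]
  span_start <- span_start[ok]; span_end <- span_end[ok]
  # thin to non-overlapping bubbles; forced variants always survive
  fi <- which(vars$forced)
  fs <- span_start[fi]; fe <- span_end[fi]
  o <- order(span_start)
  keep <- logical(nrow(vars))
  keep[fi] <- TRUE
  last_end <- -1L
  n_dropped <- 0L
  # a full reference base must separate bubbles, so adjacent alleles
  # always connect through a shared reference segment
  for (k in o) {
    if (vars$forced[k]) { last_end <- max(last_end, span_end[k]); next }
    clash <- span_start[k] <= last_end ||
      (length(fi) && any(fs <= span_end[k] & fe >= span_start[k]))
    if (clash) { n_dropped <- n_dropped + 1L; next }
    keep[k] <- TRUE
    last_end <- span_end[k]
  }
  if (n_dropped) message(n_dropped, " overlapping variants thinned")
  vars <- vars[keep, , drop = FALSE]
  vars[order(vars$pos), , drop = FALSE]
}

#' Simulate a variant graph with a haplotype panel
#'
#' Splits a chain backbone into nodes of at most \code{node_size} bases
#' and plants SNP bubbles (1 bp alternative branch), insertion nodes and
#' deletion edges at the configured per-base rates (overlapping variants
#' are thinned with a message).  Every variant is carried by at least one
#' haplotype.  Node ids increase left to right, so ascending id is a
#' topological order.
#'
#' @param config a \code{\link{sim_config}} (its \code{seed} is set here
#'   unless \code{seed = FALSE}).
#' @param backbone optional backbone sequence (generated when NULL).
#' @param forced optional data.frame of SNPs that must be present:
#'   columns \code{pos}, \code{type = "snp"}, \code{size = 1}, plus
#'   \code{alt} giving the forced alternative base.
#' @param blocked optional matrix of [start, end) linear intervals to
#'   keep free of sampled variants.
#' @param seed set \code{FALSE} to reuse the caller's RNG state.
#' @return list with \code{graph} (a \code{graph_genome}), \code{panel}
#'   (a \code{\link{haplotype_panel}} with node annotations) and
#'   \code{backbone}.
#' @export
simulate_graph <- function(config, backbone = NULL, forced = NULL,
                           blocked = NULL, seed = TRUE) {
  if (isTRUE(seed)) set.seed(config$seed)
  L <- config$backbone_length
  if (is.null(backbone)) backbone <- random_dna(L)
  stopifnot(nchar(backbone) == L)
  if (is.null(forced))
    forced <- data.frame(pos = integer(0), type = character(0),
                         size = integer(0), alt = character(0))
  if (is.null(blocked)) blocked <- matrix(numeric(0), ncol = 2L)
  vars <- .sample_variants(config, L, forced, blocked)
  nv <- nrow(vars)

  # node boundaries: regular chops plus variant span edges
  span_start <- ifelse(vars$type == "ins", vars$pos + 1L, vars$pos)
  span_end <- ifelse(vars$type == "ins", vars$pos + 1L,
                     vars$pos + vars$size)
  cuts <- sort(unique(c(seq(0L, L, by = config$node_size), L,
                        span_start, span_end)))
  seg_start <- cuts[-length(cuts)]
  seg_end <- cuts[-1L]
  keep <- seg_end > seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  K <- length(seg_start)

  # per-segment variant roles
  seg_of <- function(p) findInterval(p, seg_start)
  snp_at <- integer(K)        # variant index whose (1 bp) ref segment this is
  ins_after <- integer(K)     # variant index anchored at this segment's end
  del_first <- integer(K)     # variant index whose deleted span starts here
  del_nsegs <- integer(K)
  for (v in seq_len(nv)) {
    if (vars$type[v] == "snp") snp_at[seg_of(vars$pos[v])] <- v
    else if (vars$type[v] == "ins") ins_after[seg_of(vars$pos[v])] <- v
    else {
      s1 <- seg_of(vars$pos[v])
      s2 <- seg_of(vars$pos[v] + vars$size[v] - 1L)
      del_first[s1] <- v
      del_nsegs[s1] <- s2 - s1 + 1L
    }
  }

  # assign ids left to right, alternative nodes right after the reference
  # node(s) they parallel
  next_id <- 0L
  ref_id <- integer(K)
  alt_id <- rep(NA_integer_, nv)
  alt_seq <- rep(NA_character_, nv)
  for (k in seq_len(K)) {
    next_id <- next_id + 1L
    ref_id[k] <- next_id
    v <- snp_at[k]
    if (v) {
      ref_base <- substr(backbone, vars$pos[v] + 1L, vars$pos[v] + 1L)
      alt <- if (vars$forced[v]) vars$alt[v]
             else sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L)
      next_id <- next_id + 1L
      alt_id[v] <- next_id
      alt_seq[v] <- alt
    }
    v <- ins_after[k]
    if (v) {
      next_id <- next_id + 1L
      alt_id[v] <- next_id
      alt_seq[v] <- random_dna(vars$size[v])
    }
  }

  seqs <- character(next_id)
  seqs[ref_id] <- substring(backbone, seg_start + 1L, seg_end)
  has_alt <- !is.na(alt_id)
  seqs[alt_id[has_alt]] <- alt_seq[has_alt]
  names(seqs) <- seq_len(next_id)

  # edges: reference chain, bubble branches, deletion skips
  ef <- ref_id[-K]; et <- ref_id[-1L]
  nodes_ann <- vector("list", nv)
  var_rows <- vector("list", nv)
  for (v in seq_len(nv)) {
    p <- vars$pos[v]
    if (vars$type[v] == "snp") {
      k <- seg_of(p)
      if (k > 1L) { ef <- c(ef, ref_id[k - 1L]); et <- c(et, alt_id[v]) }
      if (k < K) { ef <- c(ef, alt_id[v]); et <- c(et, ref_id[k + 1L]) }
      nodes_ann[[v]] <- list(alt_node = alt_id[v], ref_nodes = ref_id[k])
      var_rows[[v]] <- data.frame(
        pos = p, ref = substr(backbone, p + 1L, p + 1L),
        alt = alt_seq[v], type = "snp")
    } else if (vars$type[v] == "ins") {
      k <- seg_of(p)                  # insertion between segment k and k+1
      ef <- c(ef, ref_id[k], alt_id[v])
      et <- c(et, alt_id[v], ref_id[k + 1L])
      nodes_ann[[v]] <- list(alt_node = alt_id[v], ref_nodes = integer(0),
                             from = ref_id[k], to = ref_id[k + 1L])
      var_rows[[v]] <- data.frame(pos = p, ref = "", alt = alt_seq[v],
                                  type = "ins")
    } else {
      s1 <- seg_of(p); s2 <- s1 + del_nsegs[s1] - 1L
      ef <- c(ef, ref_id[s1 - 1L]); et <- c(et, ref_id[s2 + 1L])
      nodes_ann[[v]] <- list(alt_node = NA_integer_,
                             ref_nodes = ref_id[s1:s2],
                             from = ref_id[s1 - 1L], to = ref_id[s2 + 1L])
      var_rows[[v]] <- data.frame(
        pos = p, ref = substr(backbone, p + 1L, p + vars$size[v]),
        alt = "", type = "del")
    }
  }

  graph <- graph_genome(seqs, cbind(ef, et), ref_path = ref_id,
                        name = "sim")

  if (nv) {
    variants <- do.call(rbind, var_rows)
    geno <- matrix(0L, nrow = config$n_haplotypes, ncol = nv,
                   dimnames = list(paste0("hap", seq_len(config$n_haplotypes)),
                                   NULL))
    for (v in seq_len(nv)) {
      maf <- if (vars$forced[v]) 0.5 else stats::runif(1L, 0.1, 0.9)
      carriers <- which(stats::rbinom(config$n_haplotypes, 1L, maf) == 1L)
      if (!length(carriers))
        carriers <- sample.int(config$n_haplotypes, 1L)
      if (vars$forced[v]) {          # both allele groups must be populated
        if (length(carriers) == config$n_haplotypes)
          carriers <- carriers[-1L]
        if (length(carriers) < 2L)
          carriers <- sample.int(config$n_haplotypes, 2L)
      }
      geno[carriers, v] <- 1L
    }
    panel <- haplotype_panel(variants, geno, nodes = nodes_ann)
  } else {
    panel <- haplotype_panel(
      data.frame(pos = integer(0), ref = character(0), alt = character(0),
                 type = character(0)),
      matrix(integer(0), nrow = config$n_haplotypes, ncol = 0L,
             dimnames = list(paste0("hap", seq_len(config$n_haplotypes)),
                             NULL)),
      nodes = list())
  }
  attr(panel, "forced") <- which(vars$forced)
  list(graph = graph, panel = panel, backbone = backbone)
}

#' Write a haplotype panel as a VCF with haploid genotype columns
#'
#' @param panel a \code{haplotype_panel}. @param path output file.
#' @param backbone the backbone sequence (for indel anchor bases).
#' @param chrom chromosome name.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(panel, path, backbone, chrom = "sim") {
  v <- panel$variants
  haps <- rownames(panel$genotypes)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(backbone)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", haps), collapse = "\t"))
  recs <- character(nrow(v))
  for (k in seq_len(nrow(v))) {
    if (v$type[k] == "snp") {
      pos1 <- v$pos[k] + 1L; ref <- v$ref[k]; alt <- v$alt[k]
    } else if (v$type[k] == "ins") {
      pos1 <- v$pos[k] + 1L
      anchor <- substr(backbone, pos1, pos1)
      ref <- anchor; alt <- paste0(anchor, v$alt[k])
    } else {
      pos1 <- v$pos[k]                       # anchor base before deletion
      anchor <- substr(backbone, pos1, pos1)
      ref <- paste0(anchor, v$ref[k]); alt <- anchor
    }
    recs[k] <- paste(c(chrom, pos1, sprintf("var%d", k), ref, alt, ".",
                       "PASS", ".", "GT", panel$genotypes[, k]),
                     collapse = "\t")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Write a FASTA file with one sequence
#' @param seq sequence string. @param path file. @param name record name.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seq, path, name = "backbone") {
  starts <- seq(1L, nchar(seq), by = 70L)
  writeLines(c(paste0(">", name),
               substring(seq, starts, pmin(starts + 69L, nchar(seq)))),
             path)
  invisible(path)
}

# Per-haplotype walk through the graph: node id vector plus cumulative
# start coordinate of each step.
.hap_paths <- function(graph, panel) {
  nv <- nrow(panel$variants)
  rp_ids <- graph$ref_path_ids
  K <- length(rp_ids)
  # role lookups on reference path positions
  snp_at <- integer(K); ins_after <- integer(K)
  del_first <- integer(K); del_nsegs <- integer(K)
  pos_of <- match(rp_ids, graph$ids)
  for (v in seq_len(nv)) {
    an <- panel$nodes[[v]]
    tp <- panel$variants$type[v]
    if (tp == "snp") snp_at[match(an$ref_nodes[1L], rp_ids)] <- v
    else if (tp == "ins") ins_after[match(an$from, rp_ids)] <- v
    else {
      s1 <- match(an$ref_nodes[1L], rp_ids)
      del_first[s1] <- v
      del_nsegs[s1] <- length(an$ref_nodes)
    }
  }
  lapply(seq_len(nrow(panel$genotypes)), function(h) {
    g <- panel$genotypes[h, ]
    out <- integer(K + nv)
    n_out <- 0L
    k <- 1L
    while (k <= K) {
      v <- del_first[k]
      if (v && g[v] == 1L) { k <- k + del_nsegs[k]; next }
      v <- snp_at[k]
      n_out <- n_out + 1L
      out[n_out] <- if (v && g[v] == 1L) panel$nodes[[v]]$alt_node
                    else rp_ids[k]
      v <- ins_after[k]
      if (v && g[v] == 1L) {
        n_out <- n_out + 1L
        out[n_out] <- panel$nodes[[v]]$alt_node
      }
      k <- k + 1L
    }
    out <- out[seq_len(n_out)]
    lens <- graph$lengths[match(out, graph$ids)]
    list(nodes = out, starts = cumsum(c(0L, lens[-length(lens)])),
         lengths = lens, total = sum(lens))
  })
}

# Carve a haplotype-coordinate interval [a, b) out of a haplotype path.
.hap_interval <- function(hp, a, b, direction) {
  j1 <- findInterval(a, hp$starts)
  j2 <- findInterval(b - 1L, hp$starts)
  graph_interval(hp$nodes[j1:j2],
                 start = a - hp$starts[j1],
                 end = b - hp$starts[j2],
                 direction = direction)
}

#' Simulate ChIP and control reads around planted binding sites
#'
#' Per site, fragments of the configured length are centered on the site
#' (Gaussian jitter, sd 20 bp) on a haplotype-consistent path through the
#' graph; a uniformly chosen fragment end yields one read with the
#' matching strand (forward reads start upstream of the site, reverse
#' reads end downstream — the geometry both the cross-correlation
#' estimator and fragment extension assume).  Background and control
#' reads are uniform over a random haplotype.  All reads are emitted as
#' already-aligned records with mapping quality 60 (plus optional
#' low-quality noise reads).
#'
#' @param graph,panel a \code{\link{simulate_graph}} result.
#' @param sites data.frame with columns \code{pos} (linear position),
#'   \code{variant} (panel variant index whose alt allele carries the
#'   motif, or NA for reference-allele sites).
#' @param config the \code{\link{sim_config}}.
#' @param seed set \code{FALSE} to reuse the caller's RNG state.
#' @return list with \code{input} and \code{control} alignment lists and
#'   \code{truth} (one row per read: id, role, site, haplotype, strand,
#'   haplotype-coordinates start, carries_alt).
#' @export
simulate_reads <- function(graph, panel, sites, config, seed = TRUE) {
  if (isTRUE(seed)) set.seed(config$seed + 1L)
  f <- config$fragment_length; r <- config$read_length
  hps <- .hap_paths(graph, panel)
  n_hap <- length(hps)
  input <- list(); control <- list(); truth <- list()
  emit <- function(set, hap, a, b, dir, id, role, site, carries_alt) {
    iv <- .hap_interval(hps[[hap]], a, b, dir)
    aln <- alignment(iv, mapq = 60L, read_id = id, graph = graph)
    truth[[length(truth) + 1L]] <<- list(
      read_id = id, role = role, site = site, haplotype = hap,
      strand = if (dir == "forward") "+" else "-", hap_start = a,
      carries_alt = carries_alt)
    if (set == "input") input[[length(input) + 1L]] <<- aln
    else control[[length(control) + 1L]] <<- aln
  }

  # anchor each site inside every haplotype: haplotype coordinate of the
  # node covering the site's linear position
  proj <- build_linear_projection(graph)
  site_center <- function(hap, pos, variant) {
    hp <- hps[[hap]]
    if (!is.na(variant)) {
      an <- panel$nodes[[variant]]
      j <- match(an$alt_node, hp$nodes)
      if (is.na(j)) j <- match(an$ref_nodes[1L], hp$nodes)
      if (!is.na(j)) return(hp$starts[j])
    }
    lin <- proj$node_offsets[match(hp$nodes, graph$ids)]
    j <- findInterval(pos, lin)
    hp$starts[j] + min(pos - lin[j], hp$lengths[j] - 1L)
  }

  for (s in seq_len(nrow(sites))) {
    v <- sites$variant[s]
    carriers <- if (!is.na(v)) which(panel$genotypes[, v] == 1L) else integer(0)
    noncarr <- setdiff(seq_len(n_hap), carriers)
    for (i in seq_len(config$reads_per_site)) {
      hap <- if (!is.na(v)) {
        if (stats::runif(1L) < config$alt_fraction || !length(noncarr))
          sample(rep(carriers, 2L), 1L)
        else sample(rep(noncarr, 2L), 1L)
      } else sample.int(n_hap, 1L)
      center <- site_center(hap, sites$pos[s], v)
      jitter <- if (stats::runif(1L) < config$dispersed_fraction)
        stats::runif(1L, -f / 2, f / 2)
      else stats::rnorm(1L, 0, config$center_sd)
      a <- round(center - f / 2 + jitter)
      a <- max(0L, min(a, hps[[hap]]$total - f))
      carries <- !is.na(v) && hap %in% carriers
      id <- sprintf("site%d_read%d", s, i)
      if (stats::runif(1L) < 0.5)
        emit("input", hap, a, a + r, "forward", id, "site", s, carries)
      else
        emit("input", hap, a + f - r, a + f, "reverse", id, "site", s,
             carries)
    }
  }
  uniform_read <- function(set, id, role) {
    hap <- sample.int(n_hap, 1L)
    a <- sample.int(hps[[hap]]$total - r, 1L) - 1L
    dir <- if (stats::runif(1L) < 0.5) "forward" else "reverse"
    emit(set, hap, a, a + r, dir, id, role, NA_integer_, NA)
  }
  for (i in seq_len(config$background_reads))
    uniform_read("input", sprintf("bg_read%d", i), "background")
  for (i in seq_len(config$control_reads))
    uniform_read("control", sprintf("ctrl_read%d", i), "control")
  if (config$low_mapq_fraction > 0) {
    n_noise <- ceiling(config$low_mapq_fraction * length(input))
    for (i in seq_len(n_noise)) {
      uniform_read("input", sprintf("noise_read%d", i), "noise")
      input[[length(input)]]$mapq <- sample(0:36, 1L)
    }
  }
  truth <- data.frame(
    read_id = vapply(truth, `[[`, character(1), "read_id"),
    role = vapply(truth, `[[`, character(1), "role"),
    site = vapply(truth, function(x) as.integer(x$site), integer(1)),
    haplotype = vapply(truth, `[[`, integer(1), "haplotype"),
    strand = vapply(truth, `[[`, character(1), "strand"),
    hap_start = vapply(truth, function(x) as.numeric(x$hap_start),
                       numeric(1)),
    carries_alt = vapply(truth, function(x) as.logical(x$carries_alt),
                         logical(1)))
  list(input = input, control = control, truth = truth)
}

#' Simulate a complete ChIP-seq experiment on a variant graph
#'
#' Orchestrates the generator: draws a backbone, places binding sites,
#' embeds the synthetic motif consensus at each site (alt-allele sites
#' get a mismatch base on the reference and a forced SNP whose
#' alternative allele restores the consensus, so the motif exists only on
#' the alternative branch), samples the remaining variants away from the
#' motif windows, builds graph and haplotype panel, and simulates reads.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir optional directory: when given, writes graph.json,
#'   graph.gfa, backbone.fa, variants.vcf, input.gamjson, control.gamjson
#'   and truth.tsv there.
#' @return list with \code{graph}, \code{panel}, \code{backbone},
#'   \code{sites} (pos, variant, alt_node), \code{input}, \code{control},
#'   \code{truth}, \code{motif} (the count matrix) and \code{config}.
#' @export
simulate_experiment <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  L <- config$backbone_length
  backbone_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  motif <- strsplit(SYNTHETIC_MOTIF_CONSENSUS, "")[[1L]]
  w <- length(motif)
  margin <- 2L * config$fragment_length
  pos <- round(seq(margin, L - margin, length.out = config$n_sites))
  is_alt <- seq_len(config$n_sites) <= config$n_alt_sites

  forced <- list()
  for (s in seq_len(config$n_sites)) {
    backbone_chars[(pos[s] + 1L):(pos[s] + w)] <- motif
    if (is_alt[s]) {
      off <- 4L                       # mismatch in the motif core
      consensus_base <- motif[off + 1L]
      backbone_chars[pos[s] + off + 1L] <-
        sample(setdiff(c("A", "C", "G", "T"), consensus_base), 1L)
      forced[[length(forced) + 1L]] <- data.frame(
        pos = pos[s] + off, type = "snp", size = 1L, alt = consensus_base)
    }
  }
  backbone <- paste(backbone_chars, collapse = "")
  forced <- if (length(forced)) do.call(rbind, forced)
            else data.frame(pos = integer(0), type = character(0),
                            size = integer(0), alt = character(0))
  blocked <- cbind(pos, pos + w)      # keep sampled variants out of motifs

  sim <- simulate_graph(config, backbone = backbone, forced = forced,
                        blocked = blocked, seed = FALSE)
  forced_idx <- attr(sim$panel, "forced")
  site_variant <- rep(NA_integer_, config$n_sites)
  if (length(forced_idx)) {
    fpos <- sim$panel$variants$pos[forced_idx]
    for (s in which(is_alt))
      site_variant[s] <- forced_idx[match(pos[s] + 4L, fpos)]
  }
  sites <- data.frame(pos = pos, variant = site_variant,
                      alt_node = vapply(site_variant, function(v)
                        if (is.na(v)) NA_integer_
                        else sim$panel$nodes[[v]]$alt_node, integer(1)))

  reads <- simulate_reads(sim$graph, sim$panel, sites, config, seed = FALSE)

  out <- c(sim, reads,
           list(sites = sites, motif = synthetic_motif_counts(),
                config = config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_graph(out$graph, file.path(dir, "graph.json"), "vg-json")
    write_graph(out$graph, file.path(dir, "graph.gfa"), "gfa1")
    write_fasta(backbone, file.path(dir, "backbone.fa"))
    write_vcf(out$panel, file.path(dir, "variants.vcf"), backbone)
    write_alignments(out$input, file.path(dir, "input.gamjson"), out$graph)
    write_alignments(out$control, file.path(dir, "control.gamjson"),
                     out$graph)
    utils::write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
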