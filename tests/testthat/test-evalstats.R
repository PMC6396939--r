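# Two-proportion z-test, motif-match ratios, the PWM scanner, and
# haplotype-compatibility analysis.

test_that("the pooled z-test reproduces published-scale comparisons", {
  # 927/14637 vs 750/13073: z close to 2.08, one-sided p close to 1.9%
  t1 <- two_proportion_z_test(927, 14637, 750, 13073)
  expect_s3_class(t1, "htest")
  expect_equal(unname(t1$statistic), 2.08, tolerance = 0.005 / 2.08)
  expect_equal(round(t1$p.value, 3), 0.019)
  # 8340/75132 vs 8314/75132: not significant, p about 0.42
  t2 <- two_proportion_z_test(8340, 75132, 8314, 75132)
  expect_lt(abs(t2$p.value - 0.42), 0.005)

  t0 <- two_proportion_z_test(30, 300, 10, 100)
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 0.5)
})

test_that("z-test is antisymmetric under group swap and guards input", {
  set.seed(6)
  for (rep in 1:10) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    x1 <- sample.int(n1 - 1L, 1); x2 <- sample.int(n2 - 1L, 1)
    a <- two_proportion_z_test(x1, n1, x2, n2)
    b <- two_proportion_z_test(x2, n2, x1, n1)
    expect_equal(unname(a$statistic), -unname(b$statistic))
    expect_equal(a$p.value, 1 - b$p.value)
  }
  expect_error(two_proportion_z_test(0, 10, 0, 20), "degenerate")
  expect_error(two_proportion_z_test(10, 10, 20, 20), "degenerate")
  expect_error(two_proportion_z_test(5, 0, 1, 2), "positive")
  expect_error(two_proportion_z_test(11, 10, 1, 2), "0 <= x <= n")
})

test_that("motif match ratios report two decimals", {
  expect_equal(motif_match_ratio(8340, 75132), 11.10)
  expect_equal(motif_match_ratio(8314, 75132), 11.07)
  expect_equal(motif_match_ratio(927, 14637), 6.33)
  expect_equal(motif_match_ratio(750, 13073), 5.74)
  expect_equal(motif_match_ratio(0, 10), 0)
  expect_error(motif_match_ratio(1, 0), "positive")
  expect_error(motif_match_ratio(5, 3), "matches <= total")
})

test_that("PWM scoring is maximal on the consensus and strand-symmetric", {
  pwm <- pwm_model(synthetic_motif_counts())
  expect_equal(pwm$consensus, "TGACGTCA")
  sc <- pwm_scan(pwm$consensus, pwm)
  fwd <- sc[sc$strand == "+", ]
  expect_equal(fwd$offset, 0L)
  expect_equal(fwd$score, sum(apply(pwm$log_odds, 2, max)))
  rc <- pwm_scan(chartr("ACGT", "TGCA",
                        paste(rev(strsplit(pwm$consensus, "")[[1]]),
                              collapse = "")), pwm)
  expect_equal(rc$score[rc$strand == "-"], fwd$score)
  # shorter than the motif: empty scan
  expect_equal(nrow(pwm_scan("ACG", pwm)), 0L)
})

test_that("window scores equal exhaustive per-position sums", {
  set.seed(12)
  counts <- matrix(sample(1:50, 24, replace = TRUE), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_model(counts)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 20, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    sc <- pwm_scan(s, pwm)
    fwd <- sc[sc$strand == "+", ]
    for (k in seq_len(nrow(fwd))) {
      win <- strsplit(substr(s, fwd$offset[k] + 1,
                             fwd$offset[k] + pwm$width), "")[[1]]
      want <- sum(vapply(seq_along(win), function(j) {
        i <- match(win[j], c("A", "C", "G", "T"))
        if (is.na(i)) 0 else pwm$log_odds[i, j]
      }, numeric(1)))
      expect_equal(fwd$score[k], want)
    }
  }
})

test_that("the threshold bounds the exact background tail", {
  counts <- matrix(c(40, 2, 2, 2,  2, 40, 2, 2,  2, 2, 40, 2,
                     2, 2, 2, 40,  40, 2, 2, 2), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  # width 5: all 4^5 windows enumerable; a 1e-4 tail is unreachable (the
  # consensus alone has mass 4^-5), so use 2e-3
  pwm <- pwm_model(counts, score_p = 2e-3)
  kmers <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 5))
  scores <- apply(kmers, 1, function(w)
    sum(pwm$log_odds[cbind(match(w, c("A", "C", "G", "T")), 1:5)]))
  expect_lte(mean(scores >= pwm$score_threshold), 2e-3)
  # the threshold sits at the lowest admissible score level: one level
  # further down, the exact tail exceeds score_p
  lv <- sort(unique(round(scores, 6)), decreasing = TRUE)
  tails <- vapply(lv, function(t) mean(scores >= t - 1e-6), numeric(1))
  kstar <- max(which(tails <= 2e-3))
  expect_gt(tails[kstar + 1], 2e-3)
  expect_lte(pwm$score_threshold, lv[kstar] + 0.004)   # 1e-3 grid slack
  expect_gt(pwm$score_threshold, lv[kstar + 1])
  expect_gte(nrow(pwm_matches(pwm$consensus, pwm)), 1L)

  # the unreachable 1e-4 tail on a width-5 motif admits no match at all
  strict <- pwm_model(counts, score_p = 1e-4)
  expect_equal(nrow(pwm_matches(strict$consensus, strict)), 0L)
})

test_that("JASPAR matrices parse from bracketed text", {
  f <- withr::local_tempfile()
  writeLines(c(">MA0000.1 synthTF",
               "A  [ 1  2 30 ]",
               "C  [ 5  6  1 ]",
               "G  [90  2  1 ]",
               "T  [ 4 90  1 ]"), f)
  m <- read_jaspar(f)
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(unname(m["G", 1]), 90)
  expect_equal(unname(m["T", 2]), 90)
  expect_equal(attr(m, "name"), "MA0000.1 synthTF")
  expect_equal(pwm_model(m)$consensus, "GTA")
  mp <- read_jaspar(system.file("extdata", "synthetic_tf.jaspar",
                                package = "dagpeaks"))
  expect_equal(pwm_model(mp)$consensus, "TGACGTCA")
})

test_that("haplotype compatibility follows the allele content of reads", {
  cfg <- sim_config(backbone_length = 4000L, n_sites = 1L, n_alt_sites = 1L,
                    reads_per_site = 150L, background_reads = 50L,
                    control_reads = 50L, seed = 21L)
  sim <- simulate_experiment(cfg)
  panel <- sim$panel
  haps <- rownames(panel$genotypes)

  # reads carrying no alternative allele are compatible with all
  # haplotypes under the relaxed rule, and constrain under the strict one
  for (a in sim$input[1:30]) {
    al <- alignment_variant_alleles(a, panel, sim$graph)
    strict <- alignment_haplotype_compatibility(al, panel)
    relaxed <- alignment_haplotype_compatibility(al, panel,
                                                 require_ref_match = FALSE)
    expect_true(all(strict %in% relaxed))
    if (!any(al == 1L, na.rm = TRUE) && !any(al == 0L, na.rm = TRUE))
      expect_setequal(strict, haps)
    # brute force over haplotypes
    cov <- which(!is.na(al))
    want <- haps[vapply(seq_along(haps), function(h)
      all(panel$genotypes[h, cov] == al[cov]), logical(1))]
    expect_setequal(strict, want)
  }

  # a read through an alt node is compatible exactly with the carriers
  v <- sim$sites$variant[1]
  an <- panel$nodes[[v]]$alt_node
  alt_read <- NULL
  for (a in sim$input)
    if (an %in% a$interval$node_path) { alt_read <- a; break }
  expect_false(is.null(alt_read))   # dispersed fragments do cover the site
  al <- alignment_variant_alleles(alt_read, panel, sim$graph)
  expect_equal(al[v], 1L)
  compat <- alignment_haplotype_compatibility(al, panel,
                                              require_ref_match = FALSE)
  expect_true(all(compat %in% haps[panel$genotypes[, v] == 1L]))
})

test_that("simulated reads are compatible with their source haplotype", {
  cfg <- sim_config(backbone_length = 6000L, n_sites = 2L, n_alt_sites = 1L,
                    reads_per_site = 50L, background_reads = 100L,
                    control_reads = 50L, seed = 31L)
  sim <- simulate_experiment(cfg)
  for (i in seq_along(sim$input)) {
    a <- sim$input[[i]]
    al <- alignment_variant_alleles(a, sim$panel, sim$graph)
    compat <- alignment_haplotype_compatibility(al, sim$panel)
    expect_true(paste0("hap", sim$truth$haplotype[i]) %in% compat,
                label = sim$truth$read_id[i])
  }
})

test_that("two-haplotype coverage is found by exhaustive pair search", {
  geno <- matrix(c(1, 0, 0,
                   0, 1, 0,
                   0, 0, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("hap", 1:3), NULL))
  panel <- haplotype_panel(
    data.frame(pos = c(10, 20, 30), ref = "A", alt = "C", type = "snp"),
    geno)
  # all reference-only reads: trivially coverable
  expect_true(peak_two_haplotype_test(list(paste0("hap", 1:3),
                                           paste0("hap", 1:3)), panel))
  # a single alignment is always coverable
  expect_true(peak_two_haplotype_test(list("hap2"), panel))
  # three alignments pinned to three distinct haplotypes are not
  expect_false(peak_two_haplotype_test(list("hap1", "hap2", "hap3"), panel))
  expect_true(peak_two_haplotype_test(list("hap1", "hap2", "hap1"), panel))
  expect_false(peak_two_haplotype_test(list(character(0), "hap1"), panel))
  # monotone: removing an alignment never flips TRUE to FALSE
  sets <- list(c("hap1", "hap2"), "hap2", c("hap2", "hap3"), "hap3")
  full <- peak_two_haplotype_test(sets, panel)
  expect_true(full)
  for (k in seq_along(sets))
    expect_true(peak_two_haplotype_test(sets[-k], panel))
})
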