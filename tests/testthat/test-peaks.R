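# Gap filling, connected subgraphs, maximum-support paths, summits,
# trimming, linear projection and alternative peaks.

mask_track <- function(g, idx) {
  tr <- new_track(g, FALSE)
  tr$data[idx] <- TRUE
  class(tr) <- c("region_set", "pileup_track")
  tr
}

test_that("gap filling joins regions separated by short chain gaps", {
  g <- chain_graph(100L, node_size = 20L)
  rs <- mask_track(g, c(1:50, 56:100))       # 5 intervening bases
  out <- fill_gaps(rs, 36L, g)
  expect_true(all(out$data))
  # a gap of exactly r bases is not joined
  rs2 <- mask_track(g, c(1:30, 67:100))      # 36 intervening bases
  expect_equal(fill_gaps(rs2, 36L, g)$data, rs2$data)
  # one fewer makes it join
  rs3 <- mask_track(g, c(1:30, 66:100))      # 35 intervening bases
  expect_true(all(fill_gaps(rs3, 36L, g)$data))
})

test_that("parallel branches fill only along the short path", {
  # gap spanned by a 10 bp branch and a 40 bp branch, r = 36
  g <- graph_genome(c(`1` = strrep("A", 50), `2` = strrep("C", 10),
                      `3` = strrep("G", 40), `4` = strrep("T", 50)),
                    rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)),
                    ref_path = c(1, 3, 4))
  rs <- new_track(g, FALSE)
  rs$data[1:50] <- TRUE                               # all of node 1
  rs$data[(sum(g$lengths[1:3]) + 1):sum(g$lengths)] <- TRUE  # all of node 4
  class(rs) <- c("region_set", "pileup_track")
  out <- fill_gaps(rs, 36L, g)
  expect_true(all(track_node(out, 2L)))
  expect_false(any(track_node(out, 3L)))
  expect_equal(sum(out$data), 50L + 10L + 50L)
})

test_that("gap filling matches the bounded path-enumeration oracle", {
  set.seed(31)
  for (rep in 1:30) {
    g <- random_dag(sample(4:12, 1L))
    rs <- random_mask(g, 0.35)
    r <- sample(2:6, 1L)
    got <- fill_gaps(rs, r, g)
    want <- oracle_fill_gaps(rs, r, g)
    expect_equal(got$data, want$data, label = sprintf("rep %d r=%d", rep, r))
    # monotone: the input regions are always contained in the output
    expect_true(all(got$data | !rs$data))
  }
})

test_that("gap filling is idempotent on chain and bubble topologies", {
  # on chains and clean bubbles (parallel branches that only meet at
  # their flanks) one filling pass is transitively closed
  g <- chain_graph(200L, node_size = 40L)
  set.seed(91)
  for (rep in 1:10) {
    rs <- random_mask(g, 0.25)
    out <- fill_gaps(rs, 15L, g)
    expect_equal(fill_gaps(out, 15L, g)$data, out$data)
  }
  sim <- simulate_graph(sim_config(backbone_length = 3000L, seed = 37L))
  rs <- random_mask(sim$graph, 0.2)
  out <- fill_gaps(rs, 36L, sim$graph)
  expect_equal(fill_gaps(out, 36L, sim$graph)$data, out$data)
})

test_that("connected subgraphs partition the mask deterministically", {
  g <- chain_graph(60L, node_size = 20L)
  sg <- connected_subgraphs(mask_track(g, 10:40), g)
  expect_length(sg, 1L)
  expect_equal(sum(sg[[1]]$runs$end - sg[[1]]$runs$start), 31L)

  # two runs on disjoint bubble arms stay separate components
  gb <- toy_bubble()
  rs <- new_track(gb, FALSE)
  rs$data[5] <- TRUE   # node 2 (the 1 bp ref allele)
  rs$data[6] <- TRUE   # node 3 (the alt allele)
  class(rs) <- c("region_set", "pileup_track")
  sg <- connected_subgraphs(rs, gb)
  expect_length(sg, 2L)
  expect_equal(sg[[1]]$runs$node, 2L)   # ids ordered by smallest (node, off)
  expect_equal(sg[[2]]$runs$node, 3L)

  expect_length(connected_subgraphs(mask_track(g, integer(0)), g), 0L)
})

test_that("components equal the union-find oracle on random masks", {
  set.seed(13)
  for (rep in 1:20) {
    g <- random_dag(sample(4:10, 1L))
    rs <- random_mask(g, 0.4)
    sg <- connected_subgraphs(rs, g)
    want <- oracle_components(rs, g)
    expect_length(sg, length(want))
    got_sets <- lapply(sg, function(s)
      sort(unlist(Map(function(i, a, b) paste0(i, ":", seq.int(a, b - 1L)),
                      s$runs$idx, s$runs$start, s$runs$end))))
    want_sets <- lapply(want, sort)
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(want_sets, paste, character(1), collapse = ","))
  }
})

test_that("max path selection counts contained reads and breaks ties", {
  g <- toy_bubble()
  rs <- new_track(g, TRUE)
  class(rs) <- c("region_set", "pileup_track")
  sg <- connected_subgraphs(rs, g)[[1]]
  via <- function(mid, n) lapply(seq_len(n), function(i)
    alignment(graph_interval(c(1L, mid, 4L), 2L, 1L), graph = g))
  pk <- find_max_path(sg, c(via(2L, 3L), via(3L, 7L)), g)
  expect_identical(pk$path$node_path, c(1L, 3L, 4L))
  expect_equal(pk$support, 7L)
  expect_equal(pk$length, 7L)
  # reversed weights choose the reference branch
  pk2 <- find_max_path(sg, c(via(2L, 7L), via(3L, 3L)), g)
  expect_identical(pk2$path$node_path, c(1L, 2L, 4L))
  expect_equal(pk2$support, 7L)
  # exact tie prefers the reference branch
  pk3 <- find_max_path(sg, c(via(2L, 5L), via(3L, 5L)), g)
  expect_identical(pk3$path$node_path, c(1L, 2L, 4L))

  # chain subgraph: the full run with every contained read
  gc <- chain_graph(50L, node_size = 10L)
  rsc <- mask_track(gc, 11:40)
  sgc <- connected_subgraphs(rsc, gc)[[1]]
  inside <- alignment(graph_interval(c(2L, 3L), 2L, 5L), graph = gc)
  outside <- alignment(graph_interval(c(1L, 2L), 5L, 5L), graph = gc)
  pkc <- find_max_path(sgc, list(inside, inside, outside), gc)
  expect_equal(pkc$support, 2L)
  expect_equal(pkc$length, 30L)
})

test_that("max-path support matches brute-force enumeration on random DAGs", {
  set.seed(59)
  for (rep in 1:40) {
    g <- random_dag(sample(4:12, 1L))
    rs <- random_mask(g, 0.6)
    sgs <- connected_subgraphs(rs, g)
    if (!length(sgs)) next
    alns <- lapply(1:15, function(i) random_alignment(g, max_len = 6L))
    for (sg in sgs) {
      pk <- find_max_path(sg, alns, g)
      expect_equal(pk$support, oracle_max_path_support(sg, alns, g),
                   label = sprintf("rep %d subgraph %d", rep, sg$id))
    }
  }
})

test_that("short peaks are removed with an inclusive boundary", {
  g <- chain_graph(600L, node_size = 600L)
  mk <- function(len) {
    iv <- graph_interval(1L, 0L, len)
    structure(list(path = iv, support = 1L, subgraph_id = 1L, length = len),
              class = "graph_peak")
  }
  kept <- remove_short_peaks(lapply(c(199L, 200L, 201L), mk), 200L)
  expect_length(kept, 2L)
  expect_equal(vapply(kept, `[[`, integer(1), "length"), c(200L, 201L))
  expect_length(remove_short_peaks(lapply(c(5L, 80L), mk), 1L), 2L)
})

test_that("summits take the first base of the maximal q-score plateau", {
  g <- chain_graph(30L, node_size = 7L)
  qt <- new_track(g, 0)
  class(qt) <- c("score_track", "pileup_track")
  attr(qt, "kind") <- "q"
  iv <- graph_interval(g$ids, 0L, g$lengths[length(g$ids)])
  pk <- structure(list(path = iv, support = 0L, subgraph_id = 1L,
                       length = 30L), class = "graph_peak")
  qt$data <- seq_len(30)                       # monotone: summit at the end
  ps <- peak_summit(pk, qt, g)
  expect_equal(ps$summit$node, g$ids[length(g$ids)])
  expect_equal(ps$summit$offset, g$lengths[length(g$ids)] - 1L)
  qt$data <- rep(0, 30); qt$data[12:18] <- 7   # plateau: leftmost wins
  ps <- peak_summit(pk, qt, g)
  expect_equal(ps$summit$node, 2L)
  expect_equal(ps$summit$offset, 4L)
  expect_equal(ps$summit_qscore, 7)
  # random scores: argmax oracle
  set.seed(21)
  for (rep in 1:5) {
    qt$data <- sample(100, 30, replace = TRUE)
    ps <- peak_summit(pk, qt, g)
    best <- which.max(qt$data)
    expect_equal(ps$summit$node, g$ids[findInterval(best - 1L,
                                                    cumsum(c(0, g$lengths)))])
  }
})

test_that("trimming centers a fixed window on the summit", {
  g <- chain_graph(500L, node_size = 50L)
  qt <- new_track(g, 0)
  class(qt) <- c("score_track", "pileup_track")
  attr(qt, "kind") <- "q"
  iv <- graph_interval(g$ids, 0L, 50L)
  pk <- structure(list(path = iv, support = 0L, subgraph_id = 1L,
                       length = 500L), class = "graph_peak")
  proj <- build_linear_projection(g)
  lin_span <- function(p) {
    s <- project_position_to_linear(p$path$node_path[1L], p$path$start, g,
                                    proj)
    n <- length(p$path$node_path)
    c(s, project_position_to_linear(p$path$node_path[n], p$path$end - 1L,
                                    g, proj) + 1L)
  }
  qt$data[251] <- 5                            # summit at base 250
  tp <- trim_peak(peak_summit(pk, qt, g), 120L, g)
  expect_equal(tp$length, 120L)
  expect_equal(lin_span(tp), c(190L, 310L))
  expect_equal(tp$full_path$node_path, g$ids)
  # summit 10 bases from the start: window shifts inward to [0, 120)
  qt$data <- rep(0, 500); qt$data[11] <- 5
  tp <- trim_peak(peak_summit(pk, qt, g), 120L, g)
  expect_equal(lin_span(tp), c(0L, 120L))
  # path shorter than the window is returned whole
  short <- structure(list(path = graph_interval(c(1L, 2L), 10L, 20L),
                          support = 0L, subgraph_id = 1L, length = 60L),
                     class = "graph_peak")
  tp <- trim_peak(peak_summit(short, qt, g), 120L, g)
  expect_equal(tp$length, 60L)
  expect_equal(lin_span(tp), c(10L, 70L))
})

test_that("linear projection of peaks collapses alleles and sorts output", {
  g <- toy_bubble()
  proj <- build_linear_projection(g)
  mk <- function(nodes, s, e, id) {
    iv <- graph_interval(nodes, s, e)
    structure(list(path = iv, support = 3L, subgraph_id = id,
                   summit = list(node = nodes[1], offset = s),
                   summit_qscore = 12.3,
                   length = interval_length(iv, g)), class = "graph_peak")
  }
  ref_peak <- mk(c(1L, 2L, 4L), 0L, 2L, 2L)
  alt_peak <- mk(c(1L, 3L, 4L), 0L, 2L, 1L)
  lin <- peaks_to_linear(list(ref_peak, alt_peak), proj, g)
  expect_equal(lin$start, c(0, 0))
  expect_equal(lin$end, c(7, 7))      # same span through either allele
  expect_equal(lin$score, c(123, 123))
  expect_true(!is.unsorted(lin$start))

  f <- withr::local_tempfile()
  write_narrowpeak(lin, f)
  fields <- strsplit(readLines(f), "\t")
  expect_true(all(lengths(fields) == 10L))
})

test_that("graph peaks round-trip through JSON lines", {
  g <- toy_bubble()
  iv <- graph_interval(c(1L, 3L, 4L), 1L, 2L)
  pk <- structure(list(path = iv, support = 4L,
                       summit = list(node = 3L, offset = 0L),
                       summit_qscore = 8.25, subgraph_id = 2L,
                       length = interval_length(iv, g)),
                  class = "graph_peak")
  f <- withr::local_tempfile()
  write_peaks_json(list(pk), f)
  back <- read_peaks_json(f)[[1]]
  expect_identical(back$path$node_path, pk$path$node_path)
  expect_equal(back$summit, pk$summit)
  expect_equal(back$summit_qscore, pk$summit_qscore)
  expect_equal(back$support, pk$support)
})

test_that("alternative peaks require a motif match and read coverage", {
  # bubble carrying the synthetic motif; alt branch differs mid-motif
  pwm <- pwm_model(synthetic_motif_counts())
  left <- "CCCCCTGAC"                  # motif TGACGTCA split across nodes
  g <- graph_genome(c(`1` = left, `2` = "G", `3` = "T", `4` = "TCACCCCC"),
                    rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)),
                    ref_path = c(1, 2, 4))
  rs <- new_track(g, TRUE)
  class(rs) <- c("region_set", "pileup_track")
  sg <- connected_subgraphs(rs, g)[[1]]
  ref_read <- function() alignment(graph_interval(c(1L, 2L, 4L), 3L, 3L),
                                   graph = g)
  alt_read <- function() alignment(graph_interval(c(1L, 3L, 4L), 3L, 3L),
                                   graph = g)
  # consensus path (via node 2: ...TGACGTCA...) wins; alt allele covered
  alns <- c(lapply(1:5, function(i) ref_read()),
            lapply(1:2, function(i) alt_read()))
  pk <- find_max_path(sg, alns, g)
  expect_identical(pk$path$node_path, c(1L, 2L, 4L))
  alt <- alternative_peak(sg, pwm, alns, g, peak = pk)
  expect_false(is.null(alt))
  expect_true(3L %in% alt$path$node_path)
  expect_equal(alt$support, 2L)
  # alternative allele with zero reads yields nothing
  alns_ref_only <- lapply(1:5, function(i) ref_read())
  pk <- find_max_path(sg, alns_ref_only, g)
  expect_null(alternative_peak(sg, pwm, alns_ref_only, g, peak = pk))
  # no motif anywhere: nothing
  g2 <- graph_genome(c(`1` = "CCCCCCCCC", `2` = "G", `3` = "T",
                       `4` = "CCCCCCCC"),
                     rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)),
                     ref_path = c(1, 2, 4))
  rs2 <- new_track(g2, TRUE)
  class(rs2) <- c("region_set", "pileup_track")
  sg2 <- connected_subgraphs(rs2, g2)[[1]]
  alns2 <- lapply(1:3, function(i)
    alignment(graph_interval(c(1L, 2L, 4L), 3L, 3L), graph = g2))
  pk2 <- find_max_path(sg2, alns2, g2)
  expect_null(alternative_peak(sg2, pwm, alns2, g2, peak = pk2))
})
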