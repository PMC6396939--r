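# Toy graphs and random-structure generators used across the tests.

# 1(ACGT) -> {2(A), 3(G)} -> 4(TT); reference through 2.
toy_bubble <- function() {
  graph_genome(c(`1` = "ACGT", `2` = "A", `3` = "G", `4` = "TT"),
               edges = rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)),
               ref_path = c(1, 2, 4))
}

# a pure chain of total length L chopped into nodes of at most node_size
chain_graph <- function(L, node_size = 32L, seqs = NULL) {
  starts <- seq(0L, L - 1L, by = node_size)
  ends <- pmin(starts + node_size, L)
  if (is.null(seqs)) {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  } else s <- seqs
  nodes <- substring(s, starts + 1L, ends)
  names(nodes) <- seq_along(nodes)
  n <- length(nodes)
  edges <- if (n > 1L) cbind(1:(n - 1L), 2:n) else matrix(integer(0), ncol = 2)
  graph_genome(nodes, edges, ref_path = seq_len(n), name = "chain")
}

# random connected DAG: node 1 is the only source, edges go small -> large
# id, every node has an incoming edge from a smaller one, and the
# reference path walks from node 1 to a sink.
random_dag <- function(n_nodes = 8L, max_node_len = 4L, extra_edges = 0.3) {
  lens <- sample.int(max_node_len, n_nodes, replace = TRUE)
  nodes <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  names(nodes) <- seq_len(n_nodes)
  ef <- integer(0); et <- integer(0)
  for (v in 2:n_nodes) {
    u <- sample.int(v - 1L, 1L)
    ef <- c(ef, u); et <- c(et, v)
  }
  for (u in 1:(n_nodes - 1L)) {
    for (v in (u + 1L):n_nodes) {
      if (stats::runif(1) < extra_edges / n_nodes) {
        ef <- c(ef, u); et <- c(et, v)
      }
    }
  }
  em <- unique(cbind(ef, et))
  succ <- split(em[, 2L], factor(em[, 1L], levels = seq_len(n_nodes)))
  rp <- 1L
  repeat {
    nx <- succ[[rp[length(rp)]]]
    if (!length(nx)) break
    rp <- c(rp, min(nx))
  }
  graph_genome(nodes, em, ref_path = rp, name = "rand")
}

# random alignment following a random walk through the graph
random_alignment <- function(graph, max_len = 10L, id = "r",
                             mapq = 60L) {
  i <- sample.int(length(graph$ids), 1L)
  start <- sample.int(graph$lengths[i], 1L) - 1L
  path <- i
  remaining <- sample.int(max_len, 1L) - (graph$lengths[i] - start)
  while (remaining > 0L && length(graph$succ[[path[length(path)]]])) {
    nx <- graph$succ[[path[length(path)]]]
    j <- nx[sample.int(length(nx), 1L)]
    path <- c(path, j)
    remaining <- remaining - graph$lengths[j]
  }
  last <- path[length(path)]
  end <- if (length(path) == 1L) {
    cand <- seq.int(start + 1L, graph$lengths[last])
    cand[sample.int(length(cand), 1L)]
  } else graph$lengths[last] + min(remaining, 0L)
  dir <- if (stats::runif(1) < 0.5) "forward" else "reverse"
  alignment(graph_interval(graph$ids[path], start, end, dir),
            mapq = mapq, read_id = id, graph = graph)
}

# random region mask over a graph with given per-base inclusion rate,
# returned as a region_set-shaped logical track
random_mask <- function(graph, rate = 0.3) {
  tr <- new_track(graph, FALSE)
  tr$data <- stats::runif(length(tr$data)) < rate
  class(tr) <- c("region_set", "pileup_track")
  tr
}

# base-level directed adjacency of a graph: list mapping "node:offset"
# keys to successor keys (used by several brute-force oracles)
base_graph <- function(graph) {
  out <- list()
  for (i in seq_along(graph$ids)) {
    len <- graph$lengths[i]
    for (k in seq_len(len) - 1L) {
      key <- paste0(i, ":", k)
      nxt <- if (k < len - 1L) paste0(i, ":", k + 1L)
             else if (length(graph$succ[[i]]))
               paste0(graph$succ[[i]], ":", 0L)
             else character(0)
      out[[key]] <- nxt
    }
  }
  out
}

base_key_index <- function(graph) {
  keys <- unlist(lapply(seq_along(graph$ids), function(i)
    paste0(i, ":", seq_len(graph$lengths[i]) - 1L)), use.names = FALSE)
  stats::setNames(seq_along(keys), keys)
}
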