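# Brute-force oracles, coded independently of the package's algorithms:
# exhaustive path enumeration and base-level searches on tiny graphs.

# --- fragment extension oracle: enumerate every directed path of length
# f - r from the read's 3' end and union the covered bases ----------------
oracle_extend <- function(aln, f, graph) {
  segs <- interval_segments(aln$interval, graph)
  covered <- new.env(parent = emptyenv())
  mark <- function(i, off) assign(paste0(i, ":", off), TRUE, envir = covered)
  for (k in seq_len(nrow(segs)))
    for (o in seq.int(segs[k, "start"], segs[k, "end"] - 1L))
      mark(segs[k, "idx"], o)
  rem <- f - interval_length(aln$interval, graph)
  fwd <- aln$interval$direction == "forward"
  # start base just beyond the 3' end
  step <- function(i, off, budget) {
    if (budget <= 0L) return()
    if (fwd) {
      if (off >= graph$lengths[i]) {
        for (s in graph$succ[[i]]) step(s, 0L, budget)
        return()
      }
      mark(i, off)
      step(i, off + 1L, budget - 1L)
    } else {
      if (off < 0L) {
        for (p in graph$pred[[i]]) step(p, graph$lengths[p] - 1L, budget)
        return()
      }
      mark(i, off)
      step(i, off - 1L, budget - 1L)
    }
  }
  if (rem > 0L) {
    if (fwd) {
      k <- nrow(segs)
      step(segs[k, "idx"], segs[k, "end"], rem)
    } else {
      step(segs[1L, "idx"], segs[1L, "start"] - 1L, rem)
    }
  }
  sort(ls(covered))
}

# package extension result in the same "idx:offset" key space
extend_keys <- function(aln, f, graph) {
  segs <- dagpeaks:::.extend_segments(aln, f, graph)
  sort(unlist(lapply(seq_len(nrow(segs)), function(k)
    paste0(segs[k, "idx"], ":",
           seq.int(segs[k, "start"], segs[k, "end"] - 1L))),
    use.names = FALSE))
}

# --- gap-filling oracle: bounded DFS over bases, marking every base on a
# directed path between two region bases with < r intervening bases ------
oracle_fill_gaps <- function(regions, r, graph) {
  bg <- base_graph(graph)
  keyidx <- base_key_index(graph)
  in_region <- regions$data[keyidx]
  names(in_region) <- names(keyidx)
  filled <- in_region
  # DFS from every region base through non-region bases, depth < r;
  # when another region base is reached, mark the whole path
  dfs <- function(key, path) {
    for (nxt in bg[[key]]) {
      if (in_region[[nxt]]) {
        if (length(path)) filled[path] <<- TRUE
      } else if (length(path) < r - 1L) {
        dfs(nxt, c(path, nxt))
      }
    }
  }
  for (key in names(in_region)[in_region]) dfs(key, character(0))
  out <- regions
  out$data <- unname(filled[names(keyidx)])
  out
}

# --- union-find connected components over region bases ------------------
oracle_components <- function(regions, graph) {
  keyidx <- base_key_index(graph)
  keys <- names(keyidx)[regions$data[keyidx]]
  parent <- stats::setNames(keys, keys)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[max(ra, rb)]] <<- min(ra, rb)
  }
  bg <- base_graph(graph)
  for (k in keys)
    for (nxt in bg[[k]])
      if (nxt %in% keys) union(k, nxt)
  split(keys, vapply(keys, find, character(1)))
}

# --- maximum-path oracle: enumerate every maximal path through the
# subgraph's base set and count contained alignments ---------------------
oracle_max_path_support <- function(subgraph, alignments, graph) {
  runs <- subgraph$runs
  nr <- nrow(runs)
  succ <- lapply(seq_len(nr), function(u) {
    if (runs$end[u] != graph$lengths[runs$idx[u]]) return(integer(0))
    which(runs$start == 0L & runs$idx %in% graph$succ[[runs$idx[u]]])
  })
  has_pred <- logical(nr)
  for (u in seq_len(nr)) has_pred[succ[[u]]] <- TRUE
  paths <- list()
  walk <- function(p) {
    nxt <- succ[[p[length(p)]]]
    if (!length(nxt)) { paths[[length(paths) + 1L]] <<- p; return() }
    for (w in nxt) walk(c(p, w))
  }
  for (s in which(!has_pred)) walk(s)
  # direct containment test on base keys, independent of the DP
  path_keys <- function(rseq) {
    unlist(lapply(rseq, function(j)
      paste0(runs$idx[j], ":", seq.int(runs$start[j], runs$end[j] - 1L))),
      use.names = FALSE)
  }
  aln_keys <- lapply(alignments, function(a) {
    segs <- interval_segments(a$interval, graph)
    unlist(lapply(seq_len(nrow(segs)), function(k)
      paste0(segs[k, "idx"], ":",
             seq.int(segs[k, "start"], segs[k, "end"] - 1L))),
      use.names = FALSE)
  })
  aln_nodes <- lapply(alignments, function(a)
    node_index(graph, a$interval$node_path))
  best <- 0L
  for (p in paths) {
    pk <- path_keys(p)
    pn <- runs$idx[p]
    sup <- 0L
    for (ai in seq_along(aln_keys)) {
      if (!all(aln_keys[[ai]] %in% pk)) next
      # node sequence must appear consecutively in the path
      an <- aln_nodes[[ai]]
      pos <- match(an[1L], pn)
      if (!is.na(pos) && pos + length(an) - 1L <= length(pn) &&
          identical(pn[pos:(pos + length(an) - 1L)], an))
        sup <- sup + 1L
    }
    if (sup > best) best <- sup
  }
  best
}

# --- backward-shortest-distance projection oracle (Dijkstra over the
# reversed base graph) ---------------------------------------------------
oracle_project <- function(node, offset, graph, proj) {
  i <- node_index(graph, node)
  if (graph$on_ref[i])
    return(proj$node_offsets[i] + offset)
  # breadth-first backward search (unit weights) until reference bases
  ref_coord <- function(j, o) {
    stopifnot(graph$on_ref[j])
    proj$node_offsets[j] + o
  }
  frontier <- list(c(i, offset))
  dist <- 0L
  seen <- character(0)
  repeat {
    dist <- dist + 1L
    nxt <- list()
    hits <- numeric(0)
    for (st in frontier) {
      j <- st[1L]; o <- st[2L]
      preds <- if (o > 0L) list(c(j, o - 1L))
               else lapply(graph$pred[[j]], function(p)
                 c(p, graph$lengths[p] - 1L))
      for (pp in preds) {
        if (graph$on_ref[pp[1L]]) {
          hits <- c(hits, ref_coord(pp[1L], pp[2L]) + dist)
        } else {
          key <- paste0(pp[1L], ":", pp[2L])
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            nxt[[length(nxt) + 1L]] <- pp
          }
        }
      }
    }
    if (length(hits))                    # all coordinates at minimal distance
      return(sort(unique(pmin(proj$path_length, hits))))
    if (!length(nxt)) return(NA_real_)   # no backward route
    frontier <- nxt
  }
}

# --- Benjamini-Hochberg oracle on raw p-values --------------------------
oracle_bh <- function(p) stats::p.adjust(p, method = "BH")
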