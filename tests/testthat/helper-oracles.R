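# Independent brute-force oracles used to validate the package's
# betweenness, path-length and community-quality computations.

# adjacency list (by node name) from an igraph graph
adj_list <- function(g) {
  nm <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  adj <- stats::setNames(vector("list", length(nm)), nm)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS distances from src over an adjacency list
bf_dist <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  q <- src
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.infinite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
  }
  d
}

# enumerate every shortest path between s and t explicitly
bf_all_shortest_paths <- function(adj, d_from_s, s, t) {
  if (is.infinite(d_from_s[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][d_from_s[adj[[v]]] == d_from_s[v] - 1]
    out <- list()
    for (p in preds) for (path in walk(p)) out <- c(out, list(c(path, v)))
    out
  }
  walk(t)
}

# node and link betweenness by full path enumeration (unordered pairs,
# endpoints excluded, multiple shortest paths share unit weight)
bf_betweenness <- function(g) {
  adj <- adj_list(g)
  nm <- names(adj)
  nb <- stats::setNames(rep(0, length(nm)), nm)
  lb <- new.env()
  for (si in seq_along(nm)) {
    d <- bf_dist(adj, nm[si])
    for (ti in seq_along(nm)) {
      if (ti <= si) next
      paths <- bf_all_shortest_paths(adj, d, nm[si], nm[ti])
      if (!length(paths)) next
      w <- 1 / length(paths)
      for (p in paths) {
        if (length(p) > 2) {
          inner <- p[-c(1, length(p))]
          nb[inner] <- nb[inner] + w
        }
        for (k in seq_len(length(p) - 1)) {
          key <- paste(sort(c(p[k], p[k + 1])), collapse = "|")
          lb[[key]] <- (if (is.null(lb[[key]])) 0 else lb[[key]]) + w
        }
      }
    }
  }
  lbv <- unlist(as.list(lb))
  list(node = nb, link = lbv)
}

# mean finite pairwise distance via BFS
bf_cpl <- function(g) {
  adj <- adj_list(g)
  nm <- names(adj)
  ds <- c()
  for (si in seq_along(nm)) {
    d <- bf_dist(adj, nm[si])
    if (si < length(nm)) ds <- c(ds, d[nm[(si + 1):length(nm)]])
  }
  ds <- ds[is.finite(ds)]
  if (!length(ds)) return(NaN)
  mean(ds)
}

# random named G(n, p) graph
random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# all set partitions of a vector of items (Bell-number enumeration)
all_partitions <- function(items) {
  if (!length(items)) return(list(list()))
  out <- list()
  rec <- function(i, blocks) {
    if (i > length(items)) { out[[length(out) + 1]] <<- blocks; return(invisible()) }
    for (b in seq_along(blocks)) {
      nb <- blocks; nb[[b]] <- c(nb[[b]], items[i])
      rec(i + 1, nb)
    }
    rec(i + 1, c(blocks, list(items[i])))
  }
  rec(2, list(items[1]))
  out
}

# exhaustive optimum of the Potts quality over all partitions (n <= 8)
bf_best_partition <- function(g, gamma) {
  nm <- igraph::V(g)$name
  best <- -Inf
  for (blocks in all_partitions(nm)) {
    lab <- stats::setNames(rep(seq_along(blocks), lengths(blocks)),
                           unlist(blocks))
    q <- potts_quality(g, lab, gamma)
    if (q > best) best <- q
  }
  best
}
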