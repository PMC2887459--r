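#' Node betweenness centrality
#'
#' Betweenness of a node v is the weighted number of shortest paths between
#' unordered pairs of other nodes that pass through v: each pair {s, t}
#' contributes \eqn{\sigma_{st}(v)/\sigma_{st}}, where \eqn{\sigma_{st}} is
#' the number of shortest s-t paths, so multiple shortest paths share unit
#' weight.  Endpoints are excluded and the values are unnormalised.
#'
#' @param net An undirected named `igraph` graph.
#' @return Named numeric vector of betweenness values.
#' @export
node_betweenness <- function(net) {
  b <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(net)$name)
}

#' Link (edge) betweenness centrality
#'
#' Per-edge analogue of [node_betweenness()]: the weighted number of
#' pairwise shortest paths running along each edge.  In a connected graph of
#' N nodes the single edge of a degree-1 node lies on exactly the N-1
#' shortest paths from that node to every other node and on no others, so
#' pendant edges carry a betweenness of exactly N-1 -- the characteristic
#' spike in link-betweenness distributions of sparse interactomes.
#'
#' @param net An undirected named `igraph` graph.
#' @return Data frame with columns `from`, `to` and `betweenness`, one row
#'   per edge.
#' @export
link_betweenness <- function(net) {
  eb <- igraph::edge_betweenness(net, directed = FALSE)
  el <- igraph::as_edgelist(net, names = TRUE)
  data.frame(from = pmin(el[, 1L], el[, 2L]),
             to = pmax(el[, 1L], el[, 2L]),
             betweenness = as.numeric(eb),
             stringsAsFactors = FALSE)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs at finite
#' distance.  If no pair is connected (e.g. an empty or edgeless graph) the
#' result is `NaN`.
#'
#' @param net An undirected `igraph` graph.
#' @return Mean finite shortest-path length (`NaN` if there is none).
#' @export
characteristic_path_length <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) return(NaN)
  d <- igraph::distances(net)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NaN)
  mean(d)
}

#' Targeted hub-deletion experiment
#'
#' Starting from the complete network, removes the target nodes one at a
#' time in order of decreasing *original* degree (ties broken by node name)
#' and records, after every removal, the characteristic path length of the
#' surviving graph, its number of connected components and the size of its
#' largest component.  Rising CPL under deletion signals loss of global
#' connectivity; `NaN` CPL means no connected pair survives.
#'
#' @param net An undirected named `igraph` graph.
#' @param targets Character vector of nodes to delete.
#' @return A `data.frame` with columns `rank`, `node`, `cpl`,
#'   `n_components`, `largest_component`.
#' @export
deletion_experiment <- function(net, targets) {
  nm <- igraph::V(net)$name
  missing <- setdiff(targets, nm)
  if (length(missing)) {
    stop(sprintf("deletion target '%s' not in network", missing[1L]))
  }
  deg <- igraph::degree(net)
  targets <- unique(targets)
  ord <- targets[order(-deg[targets], targets)]
  g <- net
  out <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    g <- igraph::delete_vertices(g, ord[i])
    comp <- igraph::components(g)
    out[[i]] <- data.frame(rank = i, node = ord[i],
                           cpl = characteristic_path_length(g),
                           n_components = comp$no,
                           largest_component = if (comp$no > 0L) max(comp$csize) else 0L,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Remove the most central members from a deletion target set
#'
#' Either removes the `k` members with the highest betweenness (ties broken
#' by node name), or removes every member whose betweenness exceeds a
#' threshold -- typically the maximum betweenness over a reference set such
#' as the party hubs, which isolates the few extreme connectors among the
#' date hubs.
#'
#' @param targets Character vector of node names.
#' @param bc Named numeric vector of node betweenness values (e.g. from
#'   [node_betweenness()]).
#' @param k Number of top-betweenness members to drop.
#' @param threshold Drop members with `bc > threshold` (used when `k` is
#'   missing).
#' @return The reduced target set (sorted).
#' @export
exclude_top_bc <- function(targets, bc, k = NULL, threshold = NULL) {
  targets <- sort(unique(targets))
  if (!is.null(k)) {
    stopifnot(k >= 0)
    if (k > length(targets)) stop("k exceeds the number of targets")
    if (k == 0L) return(targets)
    ord <- targets[order(-bc[targets], targets)]
    return(sort(setdiff(targets, ord[seq_len(k)])))
  }
  if (is.null(threshold)) stop("supply k or threshold")
  sort(targets[bc[targets] <= threshold])
}
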