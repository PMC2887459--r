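#' Generate a planted modular network with optional pendant nodes
#'
#' Draws a stochastic block model ("planted partition") graph: every pair of
#' nodes inside a block is linked independently with probability `p_in`,
#' every cross-block pair with probability `p_out`.  Optionally, `n_pendants`
#' degree-1 nodes are then attached, each to a uniformly chosen block node;
#' a pendant inherits the community of its attachment point.  Pendants
#' emulate the spike of degree-1 proteins seen in interaction data sets,
#' whose single link necessarily carries a link betweenness of N-1.
#'
#' @param sizes Integer vector of block sizes (each >= 1).
#' @param p_in Within-block edge probability.
#' @param p_out Between-block edge probability.
#' @param n_pendants Number of degree-1 nodes to attach.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list with `network` (an undirected named `igraph` graph) and
#'   `partition` (named integer vector of planted community labels).
#' @export
planted_modular_graph <- function(sizes, p_in, p_out, n_pendants = 0L, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("all block sizes must be >= 1")
  if (sum(sizes) < 2L) stop("planted graph needs at least 2 nodes")
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  set.seed(seed)
  nb <- sum(sizes)
  pref <- matrix(p_out, length(sizes), length(sizes))
  diag(pref) <- p_in
  g <- igraph::sample_sbm(nb, pref.matrix = pref, block.sizes = sizes,
                          directed = FALSE, loops = FALSE)
  nm <- sprintf("v%04d", seq_len(nb))
  igraph::V(g)$name <- nm
  part <- stats::setNames(rep(seq_along(sizes), sizes), nm)
  if (n_pendants > 0L) {
    pn <- sprintf("p%04d", seq_len(n_pendants))
    anchors <- sample(nm, n_pendants, replace = TRUE)
    g <- g + igraph::vertices(pn)
    g <- igraph::add_edges(g, rbind(pn, anchors))
    part <- c(part, stats::setNames(part[anchors], pn))
  }
  list(network = g, partition = part)
}

#' Simulate expression profiles with tunable hub-partner correlation
#'
#' Produces a genes-by-conditions matrix emulating the co-expression
#' structure behind the date/party hub analysis.  Each designated hub gets an
#' i.i.d. standard normal profile.  Every other node is assigned to its
#' nearest designated hub by graph distance (ties broken by the hub's sorted
#' position) and receives the profile
#' \deqn{x_j = \rho x_h + \sqrt{1-\rho^2}\,\varepsilon_j,}
#' with independent standard normal noise, so its expected Pearson
#' correlation with the hub is \eqn{\rho}.  Nodes unreachable from any hub
#' get pure noise.  A hub planted at high \eqn{\rho} therefore behaves like a
#' "party" hub (high avPCC) and one at \eqn{\rho \approx 0} like a "date"
#' hub.
#'
#' @param net An undirected named `igraph` graph.
#' @param hubs Character vector of designated hub node names.
#' @param rho Target hub-partner correlation(s) in `[-1, 1]`: a single value
#'   or a vector named by hub.
#' @param n_conditions Number of conditions (columns); must be >= 4.
#' @param seed Integer seed.
#' @return Numeric matrix with one row per network node.
#' @export
simulate_expression <- function(net, hubs, rho, n_conditions, seed = 1L) {
  if (n_conditions < 4L) stop("n_conditions must be >= 4")
  nm <- igraph::V(net)$name
  if (!all(hubs %in% nm)) stop("hubs must be a subset of network nodes")
  hubs <- sort(unique(hubs))
  if (is.null(names(rho))) {
    rho <- stats::setNames(rep_len(rho, length(hubs)), hubs)
  }
  if (!all(hubs %in% names(rho))) stop("rho must be named by hub (or a single value)")
  if (any(abs(rho) > 1)) stop("rho must lie in [-1, 1]")
  set.seed(seed)
  expr <- matrix(NA_real_, length(nm), n_conditions,
                 dimnames = list(nm, sprintf("c%03d", seq_len(n_conditions))))
  for (h in hubs) expr[h, ] <- stats::rnorm(n_conditions)
  d <- igraph::distances(net, v = hubs, to = nm)
  others <- setdiff(nm, hubs)
  for (v in others) {
    dv <- d[, v]
    if (all(is.infinite(dv))) {
      expr[v, ] <- stats::rnorm(n_conditions)
    } else {
      h <- hubs[which.min(dv)]  # hubs sorted, so ties go to first by id
      r <- rho[[h]]
      expr[v, ] <- r * expr[h, ] + sqrt(1 - r^2) * stats::rnorm(n_conditions)
    }
  }
  expr
}

#' Simulate a toy ontology and community-biased annotations
#'
#' Builds a random tree-shaped ontology of the requested depth with
#' `n_leaf_terms` leaves, then annotates every protein with one leaf term.
#' When a community partition is supplied, each community is associated with
#' a preferred leaf and a protein picks its community's leaf with probability
#' `p_bias` (otherwise a uniformly random leaf), so proteins in the same
#' community tend to share annotations -- the structure that makes
#' cross-community (high-betweenness) links functionally dissimilar.
#'
#' @param n_leaf_terms Number of leaf terms (>= 1).
#' @param depth Tree depth (>= 1); leaves sit at this depth below the root.
#' @param proteins Character vector of protein identifiers to annotate.
#' @param partition Optional named community labels used for the biased
#'   annotation rule.
#' @param p_bias Probability that a protein draws its community's preferred
#'   leaf rather than a uniform one (only with `partition`).
#' @param seed Integer seed.
#' @return An `annotation_data` object with ancestor-closed annotations.
#' @export
simulate_ontology <- function(n_leaf_terms, depth, proteins, partition = NULL,
                              p_bias = 0.8, seed = 1L) {
  if (!length(proteins)) stop("no proteins to annotate")
  if (depth < 1L) stop("depth must be >= 1")
  if (n_leaf_terms < 1L) stop("need at least one leaf term")
  set.seed(seed)
  root <- "T:root"
  levels <- list(root)
  # internal layers narrow towards the root
  if (depth > 1L) {
    for (lev in seq_len(depth - 1L)) {
      n_at <- max(1L, ceiling(n_leaf_terms / 2^(depth - lev)))
      levels[[lev + 1L]] <- sprintf("T:L%d.%02d", lev, seq_len(n_at))
    }
  }
  leaves <- sprintf("T:leaf%02d", seq_len(n_leaf_terms))
  levels[[depth + 1L]] <- leaves
  parents <- list()
  for (lev in 2:(depth + 1L)) {
    for (t in levels[[lev]]) {
      parents[[t]] <- sample(levels[[lev - 1L]], 1L)
    }
  }
  # drop internal terms that ended up on no leaf's ancestor path
  keep <- root
  for (lf in leaves) {
    t <- lf
    while (!is.null(parents[[t]])) { keep <- c(keep, t, parents[[t]]); t <- parents[[t]] }
  }
  keep <- unique(c(keep, leaves))
  parents <- parents[intersect(names(parents), keep)]
  leaf_of <- NULL
  if (!is.null(partition)) {
    comm <- sort(unique(partition))
    leaf_of <- stats::setNames(leaves[(seq_along(comm) - 1L) %% n_leaf_terms + 1L],
                               comm)
  }
  pick <- function(p) {
    if (!is.null(leaf_of) && p %in% names(partition)) {
      if (stats::runif(1) < p_bias) return(leaf_of[[as.character(partition[[p]])]])
    }
    sample(leaves, 1L)
  }
  ann <- stats::setNames(lapply(proteins, pick), proteins)
  annotation_data(parents, ann)
}
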