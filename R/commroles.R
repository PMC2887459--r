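#' Canonicalise a community partition
#'
#' Relabels communities as consecutive integers ordered by decreasing
#' community size, breaking size ties by the lexicographically smallest
#' member name, so that partitions differing only by label permutation
#' become identical.
#'
#' @param part Named vector of community labels.
#' @return Named integer vector with canonical labels 1, 2, ...
#' @export
canonicalise_partition <- function(part) {
  nm <- names(part)
  if (is.null(nm)) stop("partition must be named by node")
  groups <- split(nm, as.character(part))
  size <- lengths(groups)
  smallest <- vapply(groups, min, "")
  ord <- order(-size, smallest)
  new_lab <- stats::setNames(seq_along(ord), names(groups)[ord])
  stats::setNames(as.integer(new_lab[as.character(part)]), nm)
}

#' Potts/modularity quality of a partition
#'
#' The resolution-tunable modularity
#' \deqn{Q_\gamma = \sum_{ij} \left[\frac{A_{ij}}{2m} -
#'   \gamma\frac{k_i k_j}{(2m)^2}\right]\delta(c_i, c_j),}
#' summed over ordered pairs including \eqn{i = j} in the null term, with
#' the configuration-model null of the Reichardt-Bornholdt Potts
#' formulation.  At \eqn{\gamma = 1} this is Newman-Girvan modularity;
#' larger \eqn{\gamma} favours more, smaller communities.
#'
#' @param net An undirected named `igraph` graph with at least one edge.
#' @param part Named community labels covering all nodes.
#' @param gamma Resolution parameter, > 0.
#' @return The quality value.
#' @export
potts_quality <- function(net, part, gamma = 1) {
  m <- igraph::ecount(net)
  if (m == 0L) stop("potts_quality undefined for an empty edge set")
  stopifnot(gamma > 0)
  nm <- igraph::V(net)$name
  if (!all(nm %in% names(part))) stop("partition must cover all nodes")
  lab <- as.character(part[nm])
  deg <- igraph::degree(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  within <- lab[match(el[, 1L], nm)] == lab[match(el[, 2L], nm)]
  a_term <- sum(within) / m  # = sum_ij A_ij delta / (2m), ordered pairs
  k_by_comm <- tapply(deg, lab, sum)
  null_term <- sum((k_by_comm / (2 * m))^2)
  a_term - gamma * null_term
}

#' Detect communities by Potts/modularity optimisation
#'
#' Greedy local-move and aggregation (Louvain) optimisation of the
#' resolution-tunable modularity [potts_quality()], restarted `n_restarts`
#' times with different random node orders; the best partition found is
#' returned, and is additionally guaranteed to score at least as well as
#' the all-singletons and one-community partitions.  Deterministic given
#' `seed`.
#'
#' @param net An undirected named `igraph` graph.
#' @param gamma Resolution parameter (> 0); larger values yield more
#'   communities.
#' @param n_restarts Number of random restarts (>= 1).
#' @param seed Integer seed.
#' @return Named integer vector of canonical community labels.
#' @export
detect_communities <- function(net, gamma = 1, n_restarts = 20L, seed = 1L) {
  nm <- igraph::V(net)$name
  if (igraph::ecount(net) == 0L) {
    return(canonicalise_partition(stats::setNames(seq_along(nm), nm)))
  }
  best <- NULL
  best_q <- -Inf
  consider <- function(p) {
    q <- potts_quality(net, p, gamma)
    if (q > best_q + 1e-12 ||
        (q > best_q - 1e-12 && !is.null(best) &&
         length(unique(p)) < length(unique(best)))) {
      best <<- p
      best_q <<- q
    }
  }
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    ord <- sample(nm)
    cl <- igraph::cluster_louvain(net, resolution = gamma)
    consider(refine_partition(net, stats::setNames(igraph::membership(cl), nm),
                              gamma, order = ord))
    consider(refine_partition(net, stats::setNames(seq_along(nm), nm),
                              gamma, order = ord))
  }
  for (cand in list(stats::setNames(seq_along(nm), nm),
                    stats::setNames(rep(1L, length(nm)), nm))) {
    q <- potts_quality(net, cand, gamma)
    if (q > best_q) { best <- cand; best_q <- q }
  }
  canonicalise_partition(best)
}

# greedy single-node local moves: repeatedly move a node to the neighbouring
# (or a fresh singleton) community that most increases the Potts quality,
# until no improving move exists; deterministic given the input
refine_partition <- function(net, part, gamma, order = NULL) {
  nm <- if (is.null(order)) sort(igraph::V(net)$name) else order
  m <- igraph::ecount(net)
  lab <- part
  adj <- lapply(stats::setNames(nm, nm), function(v) {
    igraph::V(net)$name[igraph::neighbors(net, v)]
  })
  deg <- igraph::degree(net)
  ktot <- tapply(deg[names(lab)], lab, sum)  # total degree per community
  repeat {
    improved <- FALSE
    for (v in nm) {
      cv <- as.character(lab[[v]])
      nbl <- lab[adj[[v]]]
      if (!length(nbl)) next
      k_in <- tapply(rep(1, length(nbl)), as.character(nbl), sum)
      cand <- setdiff(unique(as.character(nbl)), cv)
      free_lab <- as.character(max(as.integer(lab)) + 1L)
      cand <- c(cand, free_lab)
      kv <- deg[[v]]
      kin_cv <- if (cv %in% names(k_in)) k_in[[cv]] else 0
      best_dq <- 0
      best_c <- cv
      for (cc in cand) {
        kin_cc <- if (cc %in% names(k_in)) k_in[[cc]] else 0
        kt_cc <- if (cc %in% names(ktot)) ktot[[cc]] else 0
        dq <- (kin_cc - kin_cv) / m -
          gamma / (4 * m^2) * ((kt_cc + kv)^2 - kt_cc^2 -
                                 ktot[[cv]]^2 + (ktot[[cv]] - kv)^2)
        if (dq > best_dq + 1e-12) { best_dq <- dq; best_c <- cc }
      }
      if (best_c != cv) {
        ktot[[cv]] <- ktot[[cv]] - kv
        if (!best_c %in% names(ktot)) ktot[[best_c]] <- 0
        ktot[[best_c]] <- ktot[[best_c]] + kv
        lab[[v]] <- if (is.character(part)) best_c else as.integer(best_c)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  lab
}

# kappa_is: links of each node into each community; rows nodes, cols communities
kappa_matrix <- function(net, part) {
  nm <- igraph::V(net)$name
  lab <- as.character(part[nm])
  labs <- sort(unique(lab))
  el <- igraph::as_edgelist(net, names = TRUE)
  k <- matrix(0L, length(nm), length(labs), dimnames = list(nm, labs))
  if (nrow(el)) {
    for (i in seq_len(nrow(el))) {
      a <- el[i, 1L]; b <- el[i, 2L]
      k[a, lab[match(b, nm)]] <- k[a, lab[match(b, nm)]] + 1L
      k[b, lab[match(a, nm)]] <- k[b, lab[match(a, nm)]] + 1L
    }
  }
  k
}

#' Within-community degree z-score
#'
#' For node i in community c, \eqn{z_i = (\kappa_i - \bar\kappa_c) /
#' \sigma_c}, where \eqn{\kappa_i} is the number of links of i to other
#' members of c and the mean and population standard deviation are taken
#' over the members of c.  Communities in which every member has the same
#' within-community degree (\eqn{\sigma_c = 0}) give z = 0.
#'
#' @param net An undirected named `igraph` graph.
#' @param part Named community labels covering all nodes.
#' @return Named numeric vector of z-scores.
#' @export
within_community_z <- function(net, part) {
  nm <- igraph::V(net)$name
  lab <- as.character(part[nm])
  km <- kappa_matrix(net, part)
  kappa <- km[cbind(seq_along(nm), match(lab, colnames(km)))]
  z <- numeric(length(nm))
  for (cc in unique(lab)) {
    idx <- lab == cc
    kc <- kappa[idx]
    s <- sqrt(mean((kc - mean(kc))^2))  # population sd
    z[idx] <- if (s > 0) (kc - mean(kc)) / s else 0
  }
  stats::setNames(z, nm)
}

#' Participation coefficient
#'
#' \eqn{P_i = 1 - \sum_s (\kappa_{is}/k_i)^2}, where \eqn{\kappa_{is}} is
#' the number of links of node i into community s and \eqn{k_i} its total
#' degree.  P is 0 when all links stay inside the node's own community and
#' approaches 1 when links spread evenly over many communities.  Isolated
#' nodes get P = 0.
#'
#' @inheritParams within_community_z
#' @return Named numeric vector of participation coefficients in `[0, 1)`.
#' @export
participation_coefficient <- function(net, part) {
  nm <- igraph::V(net)$name
  km <- kappa_matrix(net, part)
  k <- rowSums(km)
  p <- ifelse(k > 0, 1 - rowSums((km / pmax(k, 1))^2), 0)
  stats::setNames(as.numeric(p), nm)
}

#' Assign Guimera-Amaral topological roles
#'
#' Divides the (z, P) plane into the seven classical cartographic roles.
#' Community hubs are nodes with within-community degree z >= 2.5; they are
#' split by participation coefficient into R5 "provincial hub" (P <= 0.30),
#' R6 "connector hub" (0.30 < P <= 0.75) and R7 "kinless hub" (P > 0.75).
#' Non-hubs are split into R1 "ultra-peripheral" (P <= 0.05), R2
#' "peripheral" (0.05 < P <= 0.625), R3 "non-hub connector" (0.625 < P <=
#' 0.80) and R4 "non-hub kinless" (P > 0.80).  Boundaries are closed on the
#' lower-numbered side, except that z = 2.5 is a hub.
#'
#' @param z Named numeric vector of within-community degree z-scores.
#' @param p Named numeric vector of participation coefficients.
#' @return Named factor with levels `R1`..`R7`.
#' @export
assign_roles <- function(z, p) {
  stopifnot(length(z) == length(p))
  role <- ifelse(z >= 2.5,
                 ifelse(p <= 0.30, "R5", ifelse(p <= 0.75, "R6", "R7")),
                 ifelse(p <= 0.05, "R1",
                        ifelse(p <= 0.625, "R2", ifelse(p <= 0.80, "R3", "R4"))))
  stats::setNames(factor(role, levels = paste0("R", 1:7)), names(z))
}

#' Full per-node role table
#'
#' Convenience wrapper computing within-community degree, z-score,
#' participation coefficient and role for every node.
#'
#' @inheritParams within_community_z
#' @return Data frame with columns `node`, `degree`, `community`, `kappa`,
#'   `z`, `p`, `role`.
#' @export
node_roles <- function(net, part) {
  nm <- igraph::V(net)$name
  lab <- part[nm]
  km <- kappa_matrix(net, part)
  kappa <- km[cbind(seq_along(nm), match(as.character(lab), colnames(km)))]
  z <- within_community_z(net, part)
  p <- participation_coefficient(net, part)
  data.frame(node = nm, degree = as.integer(igraph::degree(net)),
             community = as.integer(lab), kappa = as.integer(kappa),
             z = as.numeric(z), p = as.numeric(p),
             role = as.character(assign_roles(z, p)),
             stringsAsFactors = FALSE)
}

#' Per-node Jaccard distance between two community assignments
#'
#' For a node belonging to community set `g1` in one partition and `g2` in
#' the other, the distance is \eqn{1 - |g_1 \cap g_2| / |g_1 \cup g_2|}: 0
#' for identical communities, approaching 1 for communities sharing only
#' the focal node.
#'
#' @param g1,g2 Character vectors: the node's community in each partition
#'   (both must be non-empty).
#' @return The Jaccard distance in `[0, 1)`.
#' @export
jaccard_node <- function(g1, g2) {
  if (!length(g1) || !length(g2)) stop("community sets must be non-empty")
  1 - length(intersect(g1, g2)) / length(union(g1, g2))
}

#' Compare two community partitions on their common nodes
#'
#' Communities are first pruned to the common node set; the per-node
#' Jaccard distance [jaccard_node()] is then averaged over all common
#' nodes.  If role labels are supplied, the number and percentage of common
#' nodes with identical role assignments is also reported.
#'
#' @param p1,p2 Named community labels.
#' @param common Node names to compare on; defaults to the intersection of
#'   the two partitions' name sets.
#' @param roles1,roles2 Optional named role labels (e.g. the `role` column
#'   of [node_roles()], named by node).
#' @return A list with `n_common`, `mean_jaccard`, `per_node` (named
#'   distances) and, when roles are given, `role_overlap` and
#'   `role_overlap_pct`.
#' @export
compare_partitions <- function(p1, p2, common = NULL,
                               roles1 = NULL, roles2 = NULL) {
  if (is.null(common)) common <- intersect(names(p1), names(p2))
  common <- sort(common)
  if (!length(common)) stop("no common nodes to compare")
  if (!all(common %in% names(p1)) || !all(common %in% names(p2))) {
    stop("common nodes must be present in both partitions")
  }
  g1 <- split(intersect(names(p1), common), as.character(p1[intersect(names(p1), common)]))
  g2 <- split(intersect(names(p2), common), as.character(p2[intersect(names(p2), common)]))
  j <- vapply(common, function(v) {
    jaccard_node(g1[[as.character(p1[[v]])]], g2[[as.character(p2[[v]])]])
  }, 0)
  out <- list(n_common = length(common), mean_jaccard = mean(j), per_node = j)
  if (!is.null(roles1) && !is.null(roles2)) {
    same <- sum(as.character(roles1[common]) == as.character(roles2[common]),
                na.rm = TRUE)
    out$role_overlap <- same
    out$role_overlap_pct <- 100 * same / length(common)
  }
  out
}
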