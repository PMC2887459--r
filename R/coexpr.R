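#' Pearson correlation of two expression profiles
#'
#' Positions missing in either profile are dropped pairwise.  If fewer than
#' two shared positions remain, or either surviving profile is constant, the
#' correlation is undefined and `NA` is returned (propagated, not raised).
#'
#' @param x,y Numeric vectors of equal length.
#' @return The Pearson product-moment correlation, or `NA_real_`.
#' @export
pairwise_pcc <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Identify hubs by degree threshold or top-percent rank
#'
#' In `"degree"` mode, all nodes with degree at least `value` are hubs (the
#' classic "degree >= 5" definition).  In `"top_percent"` mode the smallest
#' degree cutoff \eqn{d^*} is found such that at least `value` percent of
#' nodes (rounded down, at least one) have degree \eqn{\ge d^*}, and all
#' such nodes are returned: whole degree classes are kept, so the hub set
#' may exceed `value` percent of nodes.
#'
#' @param net An undirected named `igraph` graph.
#' @param mode `"degree"` or `"top_percent"`.
#' @param value Degree threshold, or percentage in `(0, 100]`.
#' @return Character vector of hub node names (sorted).
#' @export
hub_set <- function(net, mode = c("degree", "top_percent"), value) {
  mode <- match.arg(mode)
  stopifnot(value > 0)
  if (igraph::vcount(net) == 0L) return(character(0))
  deg <- igraph::degree(net)
  if (mode == "degree") {
    return(sort(names(deg)[deg >= value]))
  }
  n_target <- max(1, floor(value * length(deg) / 100))
  cuts <- sort(unique(deg), decreasing = TRUE)
  for (d in cuts) {
    if (sum(deg >= d) >= n_target) return(sort(names(deg)[deg >= d]))
  }
  sort(names(deg))
}

#' Average partner co-expression (avPCC) of a node
#'
#' Computes the mean Pearson correlation between a node's expression profile
#' and each interaction partner's profile, averaging only over partners with
#' a defined correlation (partners missing from the expression matrix or
#' with constant/insufficient shared data are excluded and counted).
#'
#' @param net An undirected named `igraph` graph.
#' @param expr Numeric expression matrix with node identifiers as row names.
#' @param node Node name.
#' @return One-row data frame with columns `node`, `degree`,
#'   `n_partners_used` and `avpcc` (`NA` if no partner qualifies or the node
#'   itself has no expression data).
#' @export
avpcc <- function(net, expr, node) {
  if (!node %in% igraph::V(net)$name) stop(sprintf("node '%s' not in network", node))
  partners <- igraph::V(net)$name[igraph::neighbors(net, node)]
  deg <- length(partners)
  if (!node %in% rownames(expr)) {
    return(data.frame(node = node, degree = deg, n_partners_used = 0L,
                      avpcc = NA_real_, stringsAsFactors = FALSE))
  }
  pcc <- vapply(partners, function(p) {
    if (!p %in% rownames(expr)) return(NA_real_)
    pairwise_pcc(expr[node, ], expr[p, ])
  }, 0)
  used <- sum(!is.na(pcc))
  data.frame(node = node, degree = deg, n_partners_used = used,
             avpcc = if (used > 0L) mean(pcc, na.rm = TRUE) else NA_real_,
             stringsAsFactors = FALSE)
}

#' avPCC table for a set of hubs
#'
#' @param net An undirected named `igraph` graph.
#' @param expr Expression matrix (rows named by node).
#' @param hubs Character vector of hub names; defaults to `hub_set(net,
#'   "degree", 5)`.
#' @return Data frame with one row per hub; see [avpcc()].
#' @export
hub_table <- function(net, expr, hubs = hub_set(net, "degree", 5)) {
  out <- do.call(rbind, lapply(sort(hubs), avpcc, net = net, expr = expr))
  if (is.null(out)) {
    out <- data.frame(node = character(0), degree = integer(0),
                      n_partners_used = integer(0), avpcc = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Classify hubs as date or party by an avPCC threshold
#'
#' Hubs with avPCC at or above the threshold are "party" hubs (local
#' coordinators, co-expressed with their partners); hubs below it are "date"
#' hubs.  A hub whose avPCC is undefined keeps an undefined class.  The
#' boundary is closed on the party side: an avPCC exactly equal to the
#' threshold is classified as party.
#'
#' @param records Data frame with an `avpcc` column (e.g. from
#'   [hub_table()]).
#' @param threshold avPCC threshold in `(-1, 1)`; the conventional value is
#'   0.5.
#' @return `records` with an added `class` column (`"date"`, `"party"` or
#'   `NA`).
#' @export
classify_date_party <- function(records, threshold = 0.5) {
  stopifnot(threshold > -1, threshold < 1)
  records$class <- ifelse(is.na(records$avpcc), NA_character_,
                          ifelse(records$avpcc >= threshold, "party", "date"))
  records
}
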