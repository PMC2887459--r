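#' Set information content (SIC) of ontology terms
#'
#' For a protein universe P (all annotated proteins) and the subset P_t
#' annotated (after ancestor closure) with term t,
#' \deqn{SIC(t) = -\log(|P_t|/|P|) / \log |P|,}
#' a normalised information content: a term annotating every protein is
#' uninformative (SIC = 0) and rarer terms carry more weight.  The natural
#' logarithm is used; the base cancels in the functional-similarity ratio.
#' Terms annotating no protein are excluded with a warning.
#'
#' @param annot An `annotation_data` object (annotations ancestor-closed).
#' @return Named numeric vector of SIC values (>= 0).
#' @export
term_sic <- function(annot) {
  stopifnot(inherits(annot, "annotation_data"))
  n_p <- length(annot$annotations)
  if (n_p < 1L) stop("no annotated proteins")
  counts <- table(unlist(annot$annotations, use.names = FALSE))
  absent <- setdiff(annot$terms, names(counts))
  if (length(absent)) {
    warning(sprintf("%d term(s) annotate no protein and are excluded", length(absent)))
  }
  if (n_p == 1L) {
    return(stats::setNames(rep(0, length(counts)), names(counts)))
  }
  sic <- -log(as.numeric(counts) / n_p) / log(n_p)
  stats::setNames(sic, names(counts))
}

#' SIC-weighted functional similarity of two proteins
#'
#' With G_A and G_B the ancestor-closed annotation sets of the two
#' proteins,
#' \deqn{FS(A, B) = \sum_{t \in G_A \cap G_B} SIC(t) \Big/
#'   \sum_{t \in G_A \cup G_B} SIC(t),}
#' a similarity in `[0, 1]`: identical annotation sets give 1 and sets
#' sharing only uninformative terms (such as a universal root) give 0.  If
#' either protein is unannotated the similarity is undefined (`NA`).
#'
#' @param a,b Protein identifiers.
#' @param annot An `annotation_data` object.
#' @param sic SIC table from [term_sic()] (computed from `annot` if
#'   missing).
#' @return The functional similarity, or `NA_real_`.
#' @export
functional_similarity <- function(a, b, annot, sic = term_sic(annot)) {
  ga <- annot$annotations[[a]]
  gb <- annot$annotations[[b]]
  if (is.null(ga) || is.null(gb)) return(NA_real_)
  num <- sum(sic[intersect(ga, gb)], na.rm = TRUE)
  den <- sum(sic[union(ga, gb)], na.rm = TRUE)
  if (den == 0) {
    # every shared or distinguishing term is uninformative; only identical
    # annotation sets count as similar
    return(as.numeric(setequal(ga, gb)))
  }
  num / den
}

#' Per-link table of betweenness, co-expression and functional similarity
#'
#' Joins, for every interaction in the network, its link betweenness
#' centrality, the expression correlation of the two interactors (when
#' expression data is available) and their SIC-weighted functional
#' similarity (when annotations are available).  Missing information
#' propagates as `NA` rather than failing.
#'
#' @param net An undirected named `igraph` graph.
#' @param expr Optional expression matrix (rows named by node).
#' @param annot Optional `annotation_data` object.
#' @return Data frame with columns `from`, `to`, `betweenness`, `pcc`,
#'   `functional_similarity`.
#' @export
link_similarity_table <- function(net, expr = NULL, annot = NULL) {
  tab <- link_betweenness(net)
  tab$pcc <- NA_real_
  tab$functional_similarity <- NA_real_
  if (!is.null(expr)) {
    tab$pcc <- mapply(function(a, b) {
      if (a %in% rownames(expr) && b %in% rownames(expr)) {
        pairwise_pcc(expr[a, ], expr[b, ])
      } else NA_real_
    }, tab$from, tab$to)
  }
  if (!is.null(annot)) {
    sic <- term_sic(annot)
    tab$functional_similarity <- mapply(function(a, b) {
      functional_similarity(a, b, annot, sic)
    }, tab$from, tab$to)
  }
  tab
}

#' Correlation of log link betweenness with co-expression or similarity
#'
#' Correlates `log(link betweenness)` with either the interactor expression
#' correlation or the functional similarity, over the links where both
#' quantities are defined and betweenness is positive.  Reports the
#' correlation coefficient together with its Fisher z-score
#' \eqn{z = \mathrm{atanh}(r)\sqrt{n-3}} and the two-sided normal p-value.
#'
#' @param records Data frame from [link_similarity_table()].
#' @param target `"functional_similarity"` or `"pcc"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `z`, `p_value`, `n` and the `target`/`method`
#'   used.
#' @export
betweenness_similarity_correlation <- function(records,
                                               target = c("functional_similarity", "pcc"),
                                               method = c("pearson", "spearman")) {
  target <- match.arg(target)
  method <- match.arg(method)
  y <- records[[target]]
  ok <- !is.na(y) & is.finite(records$betweenness) & records$betweenness > 0
  x <- log(records$betweenness[ok])
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 links with both variables defined")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant variable; correlation undefined")
  r <- stats::cor(x, y, method = method)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(length(x) - 3)
  list(r = r, z = z, p_value = 2 * stats::pnorm(-abs(z)), n = length(x),
       target = target, method = method)
}
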