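#' Read an undirected interaction network from a two-column edge list
#'
#' Parses a whitespace/tab separated edge list into an undirected, simple
#' [igraph][igraph::igraph-package] graph.  Lines starting with `#` are
#' comments.  Self-loops are dropped and duplicate edges (including reversed
#' duplicates) are collapsed; the number of records removed this way is
#' reported with a message.  The node set is the set of all identifiers seen,
#' so a protein that only ever appears in a self-loop is kept as an isolated
#' node.
#'
#' @param path Path to the edge-list file.
#' @param quiet Suppress the messages about dropped self-loops/duplicates.
#' @return An undirected `igraph` graph with character vertex names.
#' @export
read_edge_list <- function(path, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    badi <- which(nf != 2L)[1L]
    stop(sprintf("malformed edge-list line %d: expected 2 fields, got %d",
                 lineno[badi], nf[badi]))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  nodes <- sort(unique(c(from, to)))
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  n_dup <- sum(duplicated(key))
  keep_e <- !duplicated(key)
  if (!quiet && (n_self > 0L || n_dup > 0L)) {
    message(sprintf("read_edge_list: dropped %d self-loop(s), collapsed %d duplicate edge(s)",
                    n_self, n_dup))
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (any(keep_e)) {
    g <- igraph::add_edges(g, rbind(pmin(from, to)[keep_e], pmax(from, to)[keep_e]))
  }
  g
}

#' Write a network as a two-column tab-separated edge list
#'
#' @param net An undirected `igraph` graph with named vertices.
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected component.  If
#' several components tie for the largest size, the component containing the
#' lexicographically smallest vertex name among the tied components is
#' returned, so the result is deterministic.
#'
#' @param net An undirected `igraph` graph.
#' @return The induced subgraph on the selected component (an empty graph is
#'   returned unchanged).
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) return(net)
  comp <- igraph::components(net)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1L) {
    nm <- igraph::V(net)$name
    smallest <- vapply(cand, function(ci) min(nm[comp$membership == ci]), "")
    cand <- cand[order(smallest)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == cand[1L]))
}

#' Read a genes-by-conditions expression matrix
#'
#' Expects a tab-separated file with a header row of condition labels and
#' gene/protein identifiers in the first column.  Empty cells and the tokens
#' in `missing` become `NA`.
#'
#' @param path Path to the TSV file.
#' @param missing Character vector of tokens treated as missing values.
#' @return A numeric matrix with gene identifiers as row names.
#' @export
read_expression_matrix <- function(path, missing = c("", "NA")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("expression file must have an id column and >= 1 condition")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated gene identifier in expression matrix: '%s'",
                 ids[duplicated(ids)][1L]))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals %in% missing] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value '%s' for gene '%s'",
                 vals[bad][1L], ids[w[1L]]))
  }
  num
}

#' Construct an annotation-data object
#'
#' Bundles an ontology (a DAG of terms given as child -> parents links) with
#' protein annotations, and closes every annotation set under the ancestor
#' relation: each protein's set contains all ancestors of its direct terms.
#'
#' @param parents Named list mapping each term to a character vector of its
#'   parent terms (empty vector or absent for roots).
#' @param annotations Named list mapping each protein to a character vector of
#'   directly annotated terms.
#' @param terms Optional character vector of all term identifiers; defaults to
#'   every term mentioned in `parents`.
#' @return An object of class `annotation_data` with elements `terms`,
#'   `parents` and `annotations` (ancestor-closed).
#' @export
annotation_data <- function(parents, annotations, terms = NULL) {
  if (is.null(terms)) {
    terms <- sort(unique(c(names(parents), unlist(parents, use.names = FALSE))))
  }
  parents <- parents[lengths(parents) > 0L]
  unknown_parent <- setdiff(unlist(parents, use.names = FALSE), terms)
  if (length(unknown_parent)) {
    stop(sprintf("parent term '%s' not in term set", unknown_parent[1L]))
  }
  anc <- term_ancestors(parents, terms)  # errors on cycles
  annotations <- lapply(annotations, function(ts) {
    unknown <- setdiff(ts, terms)
    if (length(unknown)) {
      stop(sprintf("annotation refers to unknown term '%s'", unknown[1L]))
    }
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  structure(list(terms = terms, parents = parents, annotations = annotations),
            class = "annotation_data")
}

# ancestors of every term (excluding the term itself); errors on cycles
term_ancestors <- function(parents, terms) {
  anc <- stats::setNames(vector("list", length(terms)), terms)
  state <- stats::setNames(integer(length(terms)), terms)  # 0 new, 1 active, 2 done
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop(sprintf("cycle in ontology at term '%s'", t))
    state[[t]] <<- 1L
    ps <- parents[[t]]
    out <- character(0)
    for (p in ps) out <- c(out, p, visit(p))
    anc[[t]] <<- sort(unique(out))
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in terms) visit(t)
  anc
}

#' Read an ontology and protein annotations from TSV files
#'
#' The ontology file has one `child<TAB>parent` pair per line; the annotation
#' file one `protein<TAB>term` pair per line.  Lines starting with `#` are
#' comments.  Annotations are closed over ancestors (a protein annotated with
#' a term is also annotated with every ancestor of that term).
#'
#' @param ontology_path Path to the child-parent TSV.
#' @param annotation_path Path to the protein-term TSV.
#' @return An `annotation_data` object; see [annotation_data()].
#' @export
read_annotations <- function(ontology_path, annotation_path) {
  ont <- read_pairs(ontology_path, "ontology")
  ann <- read_pairs(annotation_path, "annotation")
  parents <- lapply(split(ont[[2L]], ont[[1L]]), unique)
  terms <- sort(unique(c(ont[[1L]], ont[[2L]])))
  annotations <- lapply(split(ann[[2L]], ann[[1L]]), unique)
  annotation_data(parents, annotations, terms = terms)
}

read_pairs <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    badi <- which(nf != 2L)[1L]
    stop(sprintf("malformed %s line %d: expected 2 fields", what, lineno[badi]))
  }
  data.frame(a = vapply(fields, `[[`, "", 1L),
             b = vapply(fields, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}
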