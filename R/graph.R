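#' Construct a scored evidence graph
#'
#' An evidence graph is an undirected, non-negatively scored protein pair
#' list from one data source (e.g. PPI reliabilities, functional-association
#' scores, or literature co-occurrence scores). Pairs are canonicalized,
#' duplicate pairs are collapsed to their maximum score, and zero-score pairs
#' are dropped.
#'
#' @param edges A data.frame with columns `protein_a`, `protein_b`, `score`.
#' @param source Label of the data source (e.g. `"PPI"`, `"STRING"`, `"LIT"`).
#' @param min_score Optional strict lower bound: only pairs with
#'   `score > min_score` are kept (e.g. 0.5 for functional-association
#'   scores).
#' @return An object of class `evidence_graph`: a list with the canonical
#'   sorted edge table, the protein universe, a sparse weighted adjacency
#'   matrix `W`, and an adjacency list `adj`.
#' @examples
#' g <- evidence_graph(data.frame(protein_a = c("A", "B"),
#'                                protein_b = c("B", "C"),
#'                                score = c(0.8, 0.5)))
#' graph_neighbors(g, "B")
#' @export
evidence_graph <- function(edges, source = "PPI", min_score = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("protein_a", "protein_b", "score")
  if (!all(need %in% names(edges))) {
    stop("'edges' must have columns protein_a, protein_b, score")
  }
  score <- as.numeric(edges$score)
  if (anyNA(score) || any(score < 0)) stop("edge scores must be non-negative numbers")
  cp <- canonical_pairs(edges$protein_a, edges$protein_b)
  if (!is.null(min_score)) {
    keep <- score > min_score
    cp <- cp[keep, , drop = FALSE]
    score <- score[keep]
  }
  key <- pair_keys(cp)
  if (anyDuplicated(key)) {
    ord <- order(key, -score)
    first <- !duplicated(key[ord])
    cp <- cp[ord, , drop = FALSE][first, , drop = FALSE]
    score <- score[ord][first]
    key <- key[ord][first]
  }
  keep <- score > 0
  cp <- cp[keep, , drop = FALSE]
  score <- score[keep]
  key <- key[keep]
  ord <- order(key)
  df <- data.frame(protein_a = cp$protein_a[ord], protein_b = cp$protein_b[ord],
                   score = score[ord], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  build_graph(df, source)
}

# Assemble the graph object from an already-canonical, sorted edge table.
build_graph <- function(df, source, extra = list(), class = "evidence_graph") {
  proteins <- sort(unique(c(df$protein_a, df$protein_b)))
  n <- length(proteins)
  ia <- match(df$protein_a, proteins)
  ib <- match(df$protein_b, proteins)
  W <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(df$score, df$score),
                            dims = c(n, n), dimnames = list(proteins, proteins))
  nb <- split(c(df$protein_b, df$protein_a), c(df$protein_a, df$protein_b))
  adj <- stats::setNames(vector("list", n), proteins)
  adj[names(nb)] <- nb
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(character(0))
  g <- c(list(source = source, edges = df, proteins = proteins, W = W, adj = adj),
         extra)
  structure(g, class = class)
}

#' @export
print.evidence_graph <- function(x, ...) {
  cat(sprintf("Evidence graph [%s]: %d proteins, %d edges\n",
              x$source, length(x$proteins), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  score range: [%.4g, %.4g]\n",
                min(x$edges$score), max(x$edges$score)))
  }
  invisible(x)
}

#' Edge scores for protein pairs in an evidence graph
#'
#' Vectorized lookup; pairs absent from the graph (including pairs with
#' unknown proteins) score 0, the convention used throughout the feature
#' table.
#'
#' @param g An `evidence_graph`.
#' @param a,b Character vectors of protein IDs (need not be canonical).
#' @return Numeric vector of scores.
#' @export
graph_weight <- function(g, a, b) {
  ia <- match(as.character(a), g$proteins)
  ib <- match(as.character(b), g$proteins)
  out <- numeric(length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) out[ok] <- g$W[cbind(ia[ok], ib[ok])]
  out
}

#' Neighbours of a protein in an evidence graph
#'
#' @param g An `evidence_graph`.
#' @param p A single protein ID.
#' @return Character vector of neighbouring protein IDs (empty if `p` is
#'   unknown or isolated).
#' @export
graph_neighbors <- function(g, p) {
  nb <- g$adj[[as.character(p)]]
  if (is.null(nb)) character(0) else nb
}

# Weighted degree of every protein (named vector).
weighted_degrees <- function(g) {
  d <- Matrix::rowSums(g$W)
  names(d) <- g$proteins
  d
}
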