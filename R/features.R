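#' Literature co-occurrence score of a protein pair
#'
#' Jaccard similarity of the sets of publications that mention each protein:
#' `|A_a n A_b| / |A_a u A_b|`, 0 when the union is empty. Proteins absent
#' from `paper_sets` have the empty set.
#'
#' @param paper_sets Named list: protein ID -> character vector of
#'   publication IDs.
#' @param a,b Protein IDs (vectorized).
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' ps <- list(A = c("p1", "p2"), B = c("p2", "p3"))
#' lit_jaccard(ps, "A", "B")  # 1/3
#' @export
lit_jaccard <- function(paper_sets, a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    sa <- unique(paper_sets[[a[i]]])
    sb <- unique(paper_sets[[b[i]]])
    u <- length(union(sa, sb))
    if (u == 0) 0 else length(intersect(sa, sb)) / u
  }, numeric(1))
}

#' Build a literature co-occurrence graph from protein-publication pairs
#'
#' Scores every protein pair with at least one shared publication by the
#' Jaccard similarity of their publication sets; all nonzero pairs are kept.
#'
#' @param annotations A data.frame with columns `protein` and `publication`.
#' @return An `evidence_graph` with source `"LIT"`.
#' @export
lit_jaccard_graph <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("protein", "publication") %in% names(annotations)))
  ann <- unique(data.frame(protein = as.character(annotations$protein),
                           publication = as.character(annotations$publication),
                           stringsAsFactors = FALSE))
  sets <- split(ann$publication, ann$protein)
  sizes <- lengths(sets)
  by_pub <- split(ann$protein, ann$publication)
  pairs <- lapply(by_pub, function(ps) {
    ps <- sort(unique(ps))
    if (length(ps) < 2) return(NULL)
    cmb <- utils::combn(ps, 2)
    pair_key(cmb[1, ], cmb[2, ])
  })
  keys <- unlist(pairs, use.names = FALSE)
  if (length(keys) == 0) {
    return(evidence_graph(data.frame(protein_a = character(0),
                                     protein_b = character(0),
                                     score = numeric(0)), source = "LIT"))
  }
  inter <- table(keys)  # shared-publication counts per pair
  ab <- do.call(rbind, strsplit(names(inter), "\t", fixed = TRUE))
  ni <- as.numeric(inter)
  un <- sizes[ab[, 1]] + sizes[ab[, 2]] - ni
  evidence_graph(data.frame(protein_a = ab[, 1], protein_b = ab[, 2],
                            score = ni / un, stringsAsFactors = FALSE),
                 source = "LIT")
}

#' Weighted degree of a protein pair
#'
#' Sum of the scores of the edges leaving the pair: outgoing edges of `a`
#' (excluding the edge to `b`) plus outgoing edges of `b` (excluding the
#' edge to `a`).
#'
#' @param g An `evidence_graph`.
#' @param a,b Protein IDs (vectorized).
#' @return Non-negative numeric vector.
#' @export
degree_feature <- function(g, a, b) {
  d <- weighted_degrees(g)
  da <- ifelse(as.character(a) %in% g$proteins, d[as.character(a)], 0)
  db <- ifelse(as.character(b) %in% g$proteins, d[as.character(b)], 0)
  as.numeric(da + db - 2 * graph_weight(g, a, b))
}

#' Neighbourhood connectivity of a protein pair
#'
#' Weighted density of the pair's combined neighbourhood
#' `N_ab = (N_a u N_b) \ {a, b}`: the sum of scores over all ordered pairs
#' of neighbourhood members divided by `min(|N_ab|, lambda) *
#' (min(|N_ab|, lambda) - 1)`. The dampening factor `lambda` caps the
#' denominator so sparse connectivity among many neighbours is not
#' over-penalized. Zero when the neighbourhood has fewer than two members.
#'
#' @param g An `evidence_graph`.
#' @param a,b Protein IDs (vectorized).
#' @param lambda Dampening factor, >= 2.
#' @return Non-negative numeric vector.
#' @export
nbc_feature <- function(g, a, b, lambda = 10) {
  stopifnot(lambda >= 2)
  a <- as.character(a)
  b <- as.character(b)
  vapply(seq_along(a), function(i) {
    nab <- setdiff(union(graph_neighbors(g, a[i]), graph_neighbors(g, b[i])),
                   c(a[i], b[i]))
    m <- length(nab)
    if (m < 2) return(0)
    s <- sum(g$W[nab, nab])  # ordered pairs: each undirected edge counted twice
    mm <- min(m, lambda)
    s / (mm * (mm - 1))
  }, numeric(1))
}

#' Iterated AdjustCD shared-neighbour weights
#'
#' Computes the iterative AdjustCD similarity over a scored graph. Starting
#' from the source scores, each iteration rescores every protein pair by its
#' weighted common-neighbourhood overlap, normalized by the pair's weighted
#' degrees with an average-degree penalty:
#' `w_k(u,v) = sum_{x in N_u n N_v} (w_{k-1}(u,x) + w_{k-1}(v,x)) /
#'  (max(deg_{k-1}(u), davg_{k-1}) + max(deg_{k-1}(v), davg_{k-1}))`
#' where degrees, neighbourhoods and the mean weighted degree `davg` are
#' taken from the current iteration's graph.
#'
#' @param g An `evidence_graph`.
#' @param iterations Number of iterations (>= 1); two by default.
#' @return A sparse symmetric matrix of final-iteration scores over the
#'   graph's protein universe.
#' @export
adjustcd_matrix <- function(g, iterations = 2) {
  stopifnot(iterations >= 1)
  W <- g$W
  for (it in seq_len(iterations)) {
    M <- W
    M@x <- rep(1, length(M@x))  # pattern matrix of the current graph
    deg <- Matrix::rowSums(W)
    davg <- mean(deg)
    pen <- pmax(deg, davg)
    num <- W %*% M + M %*% W
    Tm <- methods::as(num, "TsparseMatrix")
    keep <- Tm@i != Tm@j & Tm@x != 0
    i <- Tm@i[keep] + 1L
    j <- Tm@j[keep] + 1L
    x <- Tm@x[keep] / (pen[i] + pen[j])
    W <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = dim(W),
                              dimnames = dimnames(W))
  }
  W
}

#' Shared-neighbour feature of a protein pair
#'
#' The iterated AdjustCD score (see [adjustcd_matrix()]) of the pair, by
#' default with two iterations.
#'
#' @param g An `evidence_graph`.
#' @param a,b Protein IDs (vectorized).
#' @param iterations Number of AdjustCD iterations.
#' @return Non-negative numeric vector; 0 for pairs with no shared
#'   neighbourhood signal.
#' @export
shared_feature <- function(g, a, b, iterations = 2) {
  A <- adjustcd_matrix(g, iterations)
  ia <- match(as.character(a), g$proteins)
  ib <- match(as.character(b), g$proteins)
  out <- numeric(length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) out[ok] <- A[cbind(ia[ok], ib[ok])]
  out
}

#' Assemble the twelve-feature table over the reliable network's edges
#'
#' One row per edge of the reliable PPI network. For each data source the
#' edge's raw score (0 if the pair is absent from that source) and the three
#' topological features DEG, SHARED and NBC are computed on that source's
#' full graph.
#'
#' @param reliable A `reliable_network` (see [top_k_filter()]).
#' @param graphs Named list of `evidence_graph`s; names are used as feature
#'   suffixes. Conventionally `PPI` (reliability-scored), `STRING` and
#'   `LIT`. The PPI graph's scores must be the reliability scores the
#'   reliable network was filtered from.
#' @param lambda NBC dampening factor.
#' @param adjustcd_iterations Iterations for the SHARED feature.
#' @return A data.frame with `protein_a`, `protein_b` and, per source `S`,
#'   columns `S`, `DEG_S`, `SHARED_S`, `NBC_S`.
#' @export
feature_table <- function(reliable, graphs, lambda = 10,
                          adjustcd_iterations = 2) {
  stopifnot(inherits(reliable, "evidence_graph"), is.list(graphs))
  if (is.null(names(graphs)) || any(names(graphs) == "")) {
    stop("'graphs' must be a named list of evidence graphs")
  }
  a <- reliable$edges$protein_a
  b <- reliable$edges$protein_b
  out <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  for (src in names(graphs)) {
    g <- graphs[[src]]
    stopifnot(inherits(g, "evidence_graph"))
    out[[src]] <- graph_weight(g, a, b)
    out[[paste0("DEG_", src)]] <- degree_feature(g, a, b)
    out[[paste0("SHARED_", src)]] <- shared_feature(g, a, b,
                                                    iterations = adjustcd_iterations)
    out[[paste0("NBC_", src)]] <- nbc_feature(g, a, b, lambda = lambda)
  }
  out
}
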