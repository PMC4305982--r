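# Internal: shared precomputation for the Extract stage. Builds fast
# lookups of P_sm, P_lg keyed by canonical pair, component scores, and the
# per-protein outgoing (P_sm + P_lg) sums used by cohesiveness.
extract_env <- function(posteriors, reliable) {
  edges <- reliable$edges
  key <- pair_keys(edges)
  pkey <- pair_keys(canonical_pairs(posteriors$protein_a, posteriors$protein_b))
  idx <- match(key, pkey)
  if (anyNA(idx)) stop("posteriors missing for some reliable edges")
  p_sm <- stats::setNames(posteriors$P_sm[idx], key)
  p_lg <- stats::setNames(posteriors$P_lg[idx], key)
  psl <- p_sm + p_lg
  # per-protein sum of (P_sm + P_lg) over incident reliable edges
  prot_sum <- tapply(c(psl, psl), c(edges$protein_a, edges$protein_b), sum)
  adj <- reliable$adj
  list(edges = edges, key = key, adj = adj, p_sm = p_sm, p_lg = p_lg,
       psl = psl, prot_sum = prot_sum)
}

ekey <- function(x, y) pair_key(pmin(x, y), pmax(x, y))

#' Disambiguate small-co-complex weights into size-2/size-3 components
#'
#' The small-co-complex posterior `P_sm(a,b)` covers membership in either a
#' size-2 or a size-3 complex. The size-2 component score subtracts the
#' mass of incident triangles,
#' `P'_sm2(a,b) = P_sm(a,b) - sum_x P_sm(a,b) P_sm(a,x) P_sm(b,x)` over
#' common neighbours `x`; the size-3 component for a given triangle
#' `{a,b,c}` subtracts all incident triangles except the one through `c`.
#' The subtractions are not probabilistic and can go negative when several
#' strong triangles are incident; negative scores are clamped to 0.
#'
#' @param posteriors Edge posteriors (data.frame `protein_a`, `protein_b`,
#'   `P_sm`, `P_lg`, `P_non`) or an `sss_weighting`.
#' @param reliable The `reliable_network`.
#' @return A list of class `component_scores`: `sm2` (named numeric by
#'   tab-separated pair key) and `sm3` (named list by pair key; each element
#'   a numeric vector named by the third protein of each incident
#'   triangle).
#' @export
disambiguate_components <- function(posteriors, reliable) {
  if (inherits(posteriors, "sss_weighting")) posteriors <- posteriors$posteriors
  env <- extract_env(posteriors, reliable)
  n <- nrow(env$edges)
  sm2 <- stats::setNames(numeric(n), env$key)
  sm3 <- stats::setNames(vector("list", n), env$key)
  for (i in seq_len(n)) {
    a <- env$edges$protein_a[i]
    b <- env$edges$protein_b[i]
    common <- intersect(env$adj[[a]], env$adj[[b]])
    p <- env$p_sm[[i]]
    if (length(common) == 0) {
      sm2[i] <- p
      sm3[[i]] <- stats::setNames(numeric(0), character(0))
      next
    }
    terms <- p * as.numeric(env$p_sm[ekey(a, common)]) *
      as.numeric(env$p_sm[ekey(b, common)])
    tot <- sum(terms)
    sm2[i] <- max(0, p - tot)
    sm3[[i]] <- stats::setNames(pmax(0, p - (tot - terms)), common)
  }
  structure(list(sm2 = sm2, sm3 = sm3), class = "component_scores")
}

#' Cohesiveness of a size-2 cluster
#'
#' Ratio of the cluster's internal weight (its size-2 component score) over
#' internal plus outgoing weight, where outgoing edges contribute their
#' small plus large co-complex posteriors. Defined as 0 when both parts are
#' 0.
#'
#' @param posteriors Edge posteriors or an `sss_weighting`.
#' @param reliable The `reliable_network`.
#' @param a,b The two member proteins (a single pair).
#' @param components Optional precomputed [disambiguate_components()]
#'   result.
#' @return Cohesiveness in \[0, 1\].
#' @export
cohesiveness2 <- function(posteriors, reliable, a, b, components = NULL) {
  if (inherits(posteriors, "sss_weighting")) posteriors <- posteriors$posteriors
  env <- extract_env(posteriors, reliable)
  if (is.null(components)) components <- disambiguate_components(posteriors, reliable)
  k <- ekey(a, b)
  if (!k %in% env$key) stop("(a, b) is not an edge of the reliable network")
  num <- components$sm2[[k]]
  out <- env$prot_sum[[a]] + env$prot_sum[[b]] - 2 * env$psl[[k]]
  if (num + out == 0) 0 else num / (num + out)
}

#' Cohesiveness of a size-3 cluster
#'
#' Internal weight is the sum of the three triangle-specific size-3
#' component scores; outgoing edges contribute their small plus large
#' co-complex posteriors. All three internal edges must be present in the
#' reliable network. Defined as 0 when both parts are 0.
#'
#' @inheritParams cohesiveness2
#' @param a,b,c The three member proteins.
#' @return Cohesiveness in \[0, 1\].
#' @export
cohesiveness3 <- function(posteriors, reliable, a, b, c, components = NULL) {
  if (inherits(posteriors, "sss_weighting")) posteriors <- posteriors$posteriors
  env <- extract_env(posteriors, reliable)
  if (is.null(components)) components <- disambiguate_components(posteriors, reliable)
  ks <- c(ekey(a, b), ekey(a, c), ekey(b, c))
  if (!all(ks %in% env$key)) {
    stop("all three internal edges must be present in the reliable network")
  }
  third <- c(c, b, a)
  num <- sum(vapply(seq_len(3), function(i)
    components$sm3[[ks[i]]][[third[i]]], numeric(1)))
  out <- env$prot_sum[[a]] + env$prot_sum[[b]] + env$prot_sum[[c]] -
    2 * sum(env$psl[ks])
  if (num + out == 0) 0 else num / (num + out)
}

#' Extract and score candidate small complexes
#'
#' Candidate clusters are every edge (size 2) and every triangle (size 3)
#' of the reliable network. Each candidate's score is its
#' cohesiveness-weighted density: cohesiveness times the mean of its
#' internal component scores (for a size-2 cluster, `Coh(a,b) *
#' P'_sm2(a,b)`; for a size-3 cluster, `Coh(a,b,c)` times the mean of the
#' three size-3 components). A size-3 cluster and its constituent edges may
#' both appear; no overlap filtering is performed.
#'
#' @param posteriors Edge posteriors (data.frame) or an `sss_weighting`.
#' @param reliable The `reliable_network`.
#' @param min_score Strict lower bound on emitted scores; the default 0
#'   emits all candidates with nonzero score.
#' @param cohesiveness If `FALSE`, scores are the plain component-score
#'   densities without the cohesiveness factor (ablation).
#' @return A data.frame of class `small_complex_predictions` with columns
#'   `size`, `member_1`, `member_2`, `member_3` (`NA` for size 2),
#'   `cohesiveness`, `score`, sorted by decreasing score with lexicographic
#'   member-order tie-break.
#' @export
extract_complexes <- function(posteriors, reliable, min_score = 0,
                              cohesiveness = TRUE) {
  if (inherits(posteriors, "sss_weighting")) posteriors <- posteriors$posteriors
  env <- extract_env(posteriors, reliable)
  comp <- disambiguate_components(posteriors, reliable)
  edges <- env$edges
  n <- nrow(edges)
  # size-2 candidates
  out2 <- env$prot_sum[edges$protein_a] + env$prot_sum[edges$protein_b] -
    2 * env$psl
  num2 <- comp$sm2
  coh2 <- ifelse(num2 + out2 == 0, 0, num2 / (num2 + out2))
  score2 <- if (cohesiveness) coh2 * num2 else num2
  res2 <- data.frame(size = rep(2L, n), member_1 = edges$protein_a,
                     member_2 = edges$protein_b, member_3 = NA_character_,
                     cohesiveness = as.numeric(coh2),
                     score = as.numeric(score2), stringsAsFactors = FALSE)
  # size-3 candidates: triangles, each counted once (c beyond both members)
  tri <- list()
  for (i in seq_len(n)) {
    a <- edges$protein_a[i]
    b <- edges$protein_b[i]
    common <- intersect(env$adj[[a]], env$adj[[b]])
    common <- common[common > b]  # a < b < c: one enumeration per triangle
    for (c3 in common) {
      ks <- c(env$key[i], ekey(a, c3), ekey(b, c3))
      third <- c(c3, b, a)
      num <- sum(vapply(seq_len(3), function(j)
        comp$sm3[[ks[j]]][[third[j]]], numeric(1)))
      outg <- env$prot_sum[[a]] + env$prot_sum[[b]] + env$prot_sum[[c3]] -
        2 * sum(env$psl[ks])
      coh <- if (num + outg == 0) 0 else num / (num + outg)
      sc <- if (cohesiveness) coh * num / 3 else num / 3
      tri[[length(tri) + 1L]] <- data.frame(
        size = 3L, member_1 = a, member_2 = b, member_3 = c3,
        cohesiveness = coh, score = sc, stringsAsFactors = FALSE)
    }
  }
  res <- rbind(res2, if (length(tri)) do.call(rbind, tri))
  res <- res[res$score > min_score, , drop = FALSE]
  ord <- order(-res$score, res$member_1, res$member_2, res$member_3,
               na.last = FALSE, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("small_complex_predictions", "data.frame")
  res
}

#' @export
print.small_complex_predictions <- function(x, n = 10, ...) {
  cat(sprintf("Predicted small complexes: %d (size 2: %d, size 3: %d)\n",
              nrow(x), sum(x$size == 2), sum(x$size == 3)))
  if (nrow(x)) {
    cat("Top predictions:\n")
    print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  }
  invisible(x)
}

#' @export
plot.small_complex_predictions <- function(x, ...) {
  if (nrow(x) == 0) stop("no predictions to plot")
  plot(seq_len(nrow(x)), x$score, type = "s", log = "x",
       xlab = "rank", ylab = "cluster score",
       main = "Cohesiveness-weighted density by rank", ...)
  invisible(x)
}

#' Cluster membership sets of predictions
#'
#' @param predictions A `small_complex_predictions` data.frame.
#' @return List of character vectors (sorted member IDs), in ranking order.
#' @export
prediction_members <- function(predictions) {
  lapply(seq_len(nrow(predictions)), function(i) {
    m <- c(predictions$member_1[i], predictions$member_2[i],
           predictions$member_3[i])
    sort(m[!is.na(m)])
  })
}
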