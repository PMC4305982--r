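#' Remove duplicated interaction evidence across datasets
#'
#' High-throughput PPI repositories overlap: the same detection of an
#' interaction can be deposited in several datasets under the same
#' publication ID. To avoid counting one experiment several times in the
#' Noisy-Or combination, for each (pair, publication) group only the records
#' from the highest-priority source present in that group are kept.
#'
#' @param records A data.frame of evidence records with columns `protein_a`,
#'   `protein_b`, `method`, `publication` and `source`.
#' @param priority Character vector of source names, highest priority first.
#'   Defaults to the order sources first appear in `records`.
#' @return The filtered records, canonicalized, with an attribute
#'   `n_dropped` giving the number of removed records. Records with a
#'   missing publication ID cannot be deduplicated and are retained with a
#'   warning.
#' @export
deduplicate_evidence <- function(records, priority = NULL) {
  records <- as_evidence_records(records)
  if (nrow(records) == 0) return(records)
  if (is.null(priority)) priority <- unique(records$source)
  if (!all(records$source %in% priority)) {
    stop("every record source must appear in 'priority'")
  }
  pub <- records$publication
  missing_pub <- is.na(pub) | pub == ""
  if (any(missing_pub)) {
    warning(sprintf("%d record(s) without publication ID retained as-is",
                    sum(missing_pub)))
  }
  keep <- rep(TRUE, nrow(records))
  idx <- which(!missing_pub)
  if (length(idx)) {
    grp <- paste(pair_keys(records)[idx], pub[idx], sep = "\r")
    rank <- match(records$source[idx], priority)
    best <- stats::ave(rank, grp, FUN = min)
    keep[idx] <- rank == best
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Validate/canonicalize an evidence record table.
as_evidence_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("protein_a", "protein_b", "method")
  if (!all(need %in% names(records))) {
    stop("evidence records need columns protein_a, protein_b, method")
  }
  if (nrow(records) == 0) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      method = character(0), publication = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  cp <- canonical_pairs(records$protein_a, records$protein_b)
  out <- data.frame(protein_a = cp$protein_a, protein_b = cp$protein_b,
                    method = as.character(records$method),
                    stringsAsFactors = FALSE)
  out$publication <- if ("publication" %in% names(records)) {
    as.character(records$publication)
  } else {
    NA_character_
  }
  out$source <- if ("source" %in% names(records)) {
    as.character(records$source)
  } else {
    "default"
  }
  out
}

#' Estimate detection-method reliabilities from co-localization
#'
#' The reliability of an experimental detection method is estimated as the
#' fraction of its detected interactions whose two proteins are annotated to
#' a common high-level cellular-component term. The co-localization
#' predicate is supplied by the caller (precomputed from an annotation table
#' at a chosen ontology level); the package performs no ontology traversal.
#'
#' @param records Evidence records (see [deduplicate_evidence()]).
#' @param colocalized Either a data.frame with columns `protein_a`,
#'   `protein_b`, `colocalized` (logical) or a logical vector named by
#'   tab-separated canonical pair keys. Every distinct pair appearing in
#'   `records` must be covered.
#' @return A data.frame with columns `method` and `rel` (fraction in
#'   \[0, 1\]), one row per method, sorted by method.
#' @examples
#' recs <- data.frame(protein_a = c("A", "C"), protein_b = c("B", "D"),
#'                    method = "y2h", publication = c("p1", "p2"))
#' coloc <- data.frame(protein_a = c("A", "C"), protein_b = c("B", "D"),
#'                     colocalized = c(TRUE, FALSE))
#' estimate_method_reliability(recs, coloc)  # rel = 0.5
#' @export
estimate_method_reliability <- function(records, colocalized) {
  records <- as_evidence_records(records)
  if (nrow(records) == 0) {
    return(data.frame(method = character(0), rel = numeric(0)))
  }
  if (is.data.frame(colocalized)) {
    cp <- canonical_pairs(colocalized$protein_a, colocalized$protein_b)
    coloc <- stats::setNames(as.logical(colocalized$colocalized), pair_keys(cp))
  } else {
    coloc <- colocalized
  }
  key <- pair_keys(records)
  if (!all(key %in% names(coloc))) {
    stop("colocalization predicate missing for some pairs in 'records'")
  }
  # distinct detected pairs per method
  dk <- unique(data.frame(method = records$method, key = key,
                          stringsAsFactors = FALSE))
  dk$coloc <- as.logical(coloc[dk$key])
  if (anyNA(dk$coloc)) stop("colocalization predicate contains NA")
  n_pairs <- tapply(dk$coloc, dk$method, length)
  n_coloc <- tapply(dk$coloc, dk$method, sum)
  methods <- sort(names(n_pairs))
  data.frame(method = methods,
             rel = as.numeric(n_coloc[methods] / n_pairs[methods]),
             stringsAsFactors = FALSE)
}

#' Discretize consolidated interaction scores into pseudo-methods
#'
#' Scores in \[0, 1\] from a pre-scored dataset are binned into ten
#' equally-spaced bins, each treated as a separate experimental method
#' (`bin_0` for \[0, 0.1) up to `bin_9` for \[0.9, 1\]). Intervals are
#' left-closed, right-open, except the last which includes 1.
#'
#' @param pairs A data.frame with columns `protein_a`, `protein_b`, `score`.
#' @param source Source label attached to the emitted records.
#' @return Evidence records with pseudo-methods `bin_j` and no publication
#'   IDs.
#' @export
bin_consolidated_scores <- function(pairs, source = "consolidated") {
  stopifnot(is.data.frame(pairs))
  score <- as.numeric(pairs$score)
  if (anyNA(score) || any(score < 0) || any(score > 1)) {
    stop("consolidated scores must lie in [0, 1]")
  }
  cp <- canonical_pairs(pairs$protein_a, pairs$protein_b)
  j <- pmin(floor(score * 10), 9L)
  data.frame(protein_a = cp$protein_a, protein_b = cp$protein_b,
             method = sprintf("bin_%d", j), publication = NA_character_,
             source = source, stringsAsFactors = FALSE)
}

#' Noisy-Or reliability of one interaction
#'
#' Combines independent experimental evidences for a protein pair:
#' `1 - prod_i (1 - rel_i)^(n_i)` where `rel_i` is the reliability of
#' detection method `i` and `n_i` is the number of times it detected the
#' pair.
#'
#' @param counts Named integer vector: detection counts per method
#'   (all >= 1).
#' @param rels Method reliabilities: a data.frame as returned by
#'   [estimate_method_reliability()] or a named numeric vector.
#' @param unknown_method `"skip"` (default) drops methods without an
#'   estimated reliability with a warning; `"error"` fails.
#' @return A single reliability in \[0, 1\].
#' @examples
#' noisy_or_reliability(c(y2h = 1, ms = 1), c(y2h = 0.5, ms = 0.5))  # 0.75
#' @export
noisy_or_reliability <- function(counts, rels,
                                 unknown_method = c("skip", "error")) {
  unknown_method <- match.arg(unknown_method)
  if (is.data.frame(rels)) rels <- stats::setNames(rels$rel, rels$method)
  if (length(counts) == 0) return(0)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("'counts' must be named by method")
  }
  if (any(counts < 1)) stop("detection counts must be >= 1")
  known <- names(counts) %in% names(rels)
  if (!all(known)) {
    msg <- paste0("no reliability estimate for method(s): ",
                  paste(names(counts)[!known], collapse = ", "))
    if (unknown_method == "error") stop(msg)
    warning(msg, "; skipped")
    counts <- counts[known]
    if (length(counts) == 0) return(0)
  }
  r <- rels[names(counts)]
  if (any(r < 0 | r > 1)) stop("method reliabilities must lie in [0, 1]")
  1 - prod((1 - r)^counts)
}

#' Per-pair Noisy-Or reliabilities for an evidence table
#'
#' Aggregates evidence records (one row = one detection) into one
#' reliability score per distinct pair.
#'
#' @inheritParams noisy_or_reliability
#' @param records Evidence records (see [deduplicate_evidence()]).
#' @return A data.frame `protein_a`, `protein_b`, `score`, sorted by pair.
#' @export
pair_reliability <- function(records, rels,
                             unknown_method = c("skip", "error")) {
  unknown_method <- match.arg(unknown_method)
  records <- as_evidence_records(records)
  if (is.data.frame(rels)) rels <- stats::setNames(rels$rel, rels$method)
  if (nrow(records) == 0) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0)))
  }
  known <- records$method %in% names(rels)
  if (!all(known)) {
    msg <- paste0("no reliability estimate for method(s): ",
                  paste(unique(records$method[!known]), collapse = ", "))
    if (unknown_method == "error") stop(msg)
    warning(msg, "; skipped")
    records <- records[known, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0)))
  }
  key <- pair_keys(records)
  lq <- log1p(-pmin(rels[records$method], 1))  # log(1 - rel), -Inf if rel == 1
  s <- tapply(lq, key, sum)
  keys <- sort(names(s))
  ab <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
  data.frame(protein_a = ab[, 1], protein_b = ab[, 2],
             score = as.numeric(1 - exp(s[keys])), stringsAsFactors = FALSE)
}

#' Keep the top-k most reliable edges of a scored network
#'
#' The supervised weighting operates on a highly-reliable subset of the PPI
#' network: the k edges with the highest reliability scores. Ties at the
#' k-th score are broken by lexicographic canonical pair order so the
#' selection is deterministic.
#'
#' @param scored_pairs A data.frame `protein_a`, `protein_b`, `score`, or an
#'   `evidence_graph`.
#' @param k Positive integer; if fewer than `k` edges exist all are kept.
#' @return A `reliable_network` (also an `evidence_graph`) with at most `k`
#'   edges.
#' @export
top_k_filter <- function(scored_pairs, k = 10000) {
  if (inherits(scored_pairs, "evidence_graph")) scored_pairs <- scored_pairs$edges
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  g <- evidence_graph(scored_pairs, source = "PPI")
  df <- g$edges
  ord <- order(-df$score, df$protein_a, df$protein_b)
  keep <- sort(ord[seq_len(min(k, nrow(df)))])
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  build_graph(df, "PPI", extra = list(k = as.integer(k)),
              class = c("reliable_network", "evidence_graph"))
}

#' @export
print.reliable_network <- function(x, ...) {
  cat(sprintf("Reliable PPI network: %d proteins, %d edges (k = %d)\n",
              length(x$proteins), nrow(x$edges), x$k))
  invisible(x)
}
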