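#' Read a scored protein-pair list from TSV
#'
#' Expects columns `protein_a`, `protein_b`, `score` (header required).
#'
#' @param path File path.
#' @param source Source label for the resulting graph.
#' @param min_score Optional strict lower bound applied at load time (e.g.
#'   0.5 for functional-association scores).
#' @return An `evidence_graph`.
#' @export
read_pairs_tsv <- function(path, source = "PPI", min_score = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  evidence_graph(df, source = source, min_score = min_score)
}

#' Write a scored protein-pair list to TSV
#'
#' Rows are canonical pairs in lexicographic order, so outputs are
#' diff-stable.
#'
#' @param x An `evidence_graph` or a data.frame `protein_a`, `protein_b`,
#'   `score`.
#' @param path File path.
#' @export
write_pairs_tsv <- function(x, path) {
  if (inherits(x, "evidence_graph")) x <- x$edges
  cp <- canonical_pairs(x$protein_a, x$protein_b)
  df <- data.frame(protein_a = cp$protein_a, protein_b = cp$protein_b,
                   score = x$score, stringsAsFactors = FALSE)
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read raw PPI evidence records from TSV
#'
#' Expects columns `protein_a`, `protein_b`, `method`, `publication` and
#' optionally `source`.
#'
#' @param path File path.
#' @return A canonicalized evidence record data.frame.
#' @export
read_evidence_tsv <- function(path) {
  as_evidence_records(utils::read.delim(path, stringsAsFactors = FALSE,
                                        colClasses = "character"))
}

#' Read a complex catalogue
#'
#' One complex per line, tab-separated member IDs. Complexes with fewer
#' than two distinct members are rejected.
#'
#' @param path File path.
#' @return A list of class `complex_catalogue`.
#' @export
read_complexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  as_complex_catalogue(strsplit(lines, "\t", fixed = TRUE))
}

#' Coerce to a complex catalogue
#'
#' @param x A list of character vectors of member IDs.
#' @return The validated catalogue (members unique and sorted per complex),
#'   class `complex_catalogue`.
#' @export
as_complex_catalogue <- function(x) {
  if (inherits(x, "complex_catalogue")) return(x)
  stopifnot(is.list(x))
  out <- lapply(x, function(m) sort(unique(as.character(m))))
  bad <- lengths(out) < 2
  if (any(bad)) {
    stop(sprintf("%d complex(es) with fewer than 2 distinct members", sum(bad)))
  }
  structure(out, class = "complex_catalogue")
}

#' @export
print.complex_catalogue <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("Complex catalogue: %d complexes (%d small of size <= 3)\n",
              length(x), sum(sizes <= 3)))
  invisible(x)
}

#' Write a complex catalogue
#'
#' @param complexes A complex catalogue.
#' @param path File path.
#' @export
write_complexes <- function(complexes, path) {
  complexes <- as_complex_catalogue(complexes)
  writeLines(vapply(complexes, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Write edge posteriors to TSV
#'
#' @param x An `sss_weighting` or its `posteriors` data.frame.
#' @param path File path.
#' @export
write_posteriors <- function(x, path) {
  if (inherits(x, "sss_weighting")) x <- x$posteriors
  df <- x[order(x$protein_a, x$protein_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read edge posteriors from TSV
#'
#' @param path File path.
#' @return Data.frame `protein_a`, `protein_b`, `P_sm`, `P_lg`, `P_non`.
#' @export
read_posteriors <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "P_sm", "P_lg", "P_non")
  if (!all(need %in% names(df))) {
    stop("posterior file needs columns ", paste(need, collapse = ", "))
  }
  df
}

#' Write ranked small-complex predictions to TSV
#'
#' @param predictions A `small_complex_predictions` data.frame.
#' @param path File path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(as.data.frame(predictions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted edge model to JSON
#'
#' Cut points, priors, conditional probability tables, smoothing and the
#' removed-feature list are written at full precision so the model
#' round-trips through [read_sss_model()].
#'
#' @param model An `sss_model`.
#' @param path File path.
#' @export
write_sss_model <- function(model, path) {
  stopifnot(inherits(model, "sss_model"))
  obj <- list(features = model$features, removed = model$removed,
              cuts = model$cuts, priors = as.list(model$priors),
              cpt = lapply(model$cpt, function(m) {
                stats::setNames(lapply(rownames(m), function(r) unname(m[r, ])),
                                rownames(m))
              }),
              smoothing = model$smoothing, n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized edge model
#'
#' @param path File path written by [write_sss_model()].
#' @return An `sss_model`.
#' @export
read_sss_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpt <- lapply(obj$cpt, function(rows) {
    m <- do.call(rbind, rows[SSS_CLASSES])
    colnames(m) <- as.character(seq_len(ncol(m)))
    m
  })
  cuts <- lapply(obj$cuts, as.numeric)
  structure(list(features = as.character(obj$features),
                 removed = as.character(obj$removed),
                 cuts = cuts[obj$features],
                 priors = stats::setNames(as.numeric(obj$priors[SSS_CLASSES]),
                                          SSS_CLASSES),
                 cpt = cpt[obj$features],
                 smoothing = obj$smoothing, n = obj$n),
            class = "sss_model")
}
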