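#' Run the full small-complex discovery pipeline
#'
#' Convenience wrapper chaining the stages: build the reliable PPI network
#' (top-k filter of the reliability-scored PPI pairs), assemble the
#' twelve-feature table, weight the edges with the size-specific supervised
#' model, extract and rank candidate small complexes and, when a reference
#' catalogue is supplied, run the cross-validation evaluation.
#'
#' @param ppi PPI pairs scored by reliability: an `evidence_graph`, a
#'   data.frame, or a TSV path.
#' @param string Functional-association pairs (graph, data.frame or path);
#'   scores are filtered to `> string_threshold` at load time. May be
#'   `NULL` (treated as an empty source).
#' @param lit Literature co-occurrence pairs (graph, data.frame or path),
#'   or `NULL`.
#' @param complexes Reference catalogue (catalogue, list or path).
#' @param k Top-k reliability cutoff.
#' @param lambda NBC dampening factor.
#' @param smoothing CPT pseudocount.
#' @param iso Include the isolatedness feature?
#' @param cohesiveness Weight cluster scores by cohesiveness?
#' @param min_score Minimum emitted cluster score.
#' @param string_threshold Strict lower bound on functional-association
#'   scores.
#' @param evaluate Run cross-validation (needs `complexes`)?
#' @param t_percent,rounds,seed Cross-validation design.
#' @param out_dir Optional directory; when given, the weighted network,
#'   predictions and model are written there as TSV/JSON.
#' @return A list of class `sss_pipeline`: `reliable`, `graphs`,
#'   `weighting`, `predictions`, and `evaluation` (a `cv_result` or
#'   `NULL`).
#' @export
run_pipeline <- function(ppi, string = NULL, lit = NULL, complexes,
                         k = 10000, lambda = 10, smoothing = 1, iso = TRUE,
                         cohesiveness = TRUE, min_score = 0,
                         string_threshold = 0.5, evaluate = FALSE,
                         t_percent = 90, rounds = 10, seed = 1,
                         out_dir = NULL) {
  as_graph <- function(x, source, min_score = NULL) {
    if (is.null(x)) {
      return(evidence_graph(data.frame(protein_a = character(0),
                                       protein_b = character(0),
                                       score = numeric(0)),
                            source = source))
    }
    if (inherits(x, "evidence_graph")) return(x)
    if (is.character(x)) return(read_pairs_tsv(x, source, min_score))
    evidence_graph(x, source = source, min_score = min_score)
  }
  ppi_g <- as_graph(ppi, "PPI")
  graphs <- list(PPI = ppi_g,
                 STRING = as_graph(string, "STRING", string_threshold),
                 LIT = as_graph(lit, "LIT"))
  if (is.character(complexes)) complexes <- read_complexes(complexes)
  complexes <- as_complex_catalogue(complexes)
  reliable <- top_k_filter(ppi_g, k = k)
  if (nrow(reliable$edges) == 0) stop("reliable PPI network is empty")
  unknown <- setdiff(unique(unlist(complexes)), ppi_g$proteins)
  if (length(unknown)) {
    warning(sprintf("%d catalogue protein(s) absent from the PPI network",
                    length(unknown)))
  }
  weighting <- sss_weight(reliable, graphs, complexes = complexes,
                          lambda = lambda, smoothing = smoothing, iso = iso)
  predictions <- extract_complexes(weighting, reliable,
                                   min_score = min_score,
                                   cohesiveness = cohesiveness)
  evaluation <- NULL
  if (evaluate) {
    evaluation <- cross_validate(reliable, graphs, complexes,
                                 method = if (iso) "sss" else "sss_noiso",
                                 t_percent = t_percent, rounds = rounds,
                                 seed = seed, lambda = lambda,
                                 smoothing = smoothing,
                                 min_score = min_score,
                                 cohesiveness = cohesiveness)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_posteriors(weighting, file.path(out_dir, "posteriors.tsv"))
    write_predictions(predictions, file.path(out_dir, "predictions.tsv"))
    write_sss_model(weighting$model, file.path(out_dir, "model.json"))
    if (!is.null(evaluation)) {
      auc <- data.frame(round = seq_along(evaluation$auc),
                        auc = evaluation$auc)
      utils::write.table(auc, file.path(out_dir, "cv_auc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  structure(list(reliable = reliable, graphs = graphs, weighting = weighting,
                 predictions = predictions, evaluation = evaluation),
            class = "sss_pipeline")
}

#' @export
print.sss_pipeline <- function(x, ...) {
  print(x$reliable)
  print(x$weighting)
  print(x$predictions, n = 5)
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
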