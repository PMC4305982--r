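#' Random sub-sampling cross-validation splits of a complex catalogue
#'
#' Each round independently samples `floor(t_percent/100 * n)` complexes
#' (large and small) uniformly without replacement as the test set; the
#' remainder are the training set. A large test percentage emulates the
#' real-use scenario where only a few complexes are known and many are to
#' be discovered.
#'
#' @param complexes A complex catalogue (list of member-ID vectors).
#' @param t_percent Percentage of complexes held out for testing
#'   (0 < t < 100; default 90).
#' @param rounds Number of rounds (default 10).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return A list of `rounds` splits, each a list with integer index
#'   vectors `test` and `train` and the `round` number.
#' @export
split_complexes <- function(complexes, t_percent = 90, rounds = 10, seed = 1) {
  complexes <- as_complex_catalogue(complexes)
  stopifnot(t_percent > 0, t_percent < 100, rounds >= 1)
  n <- length(complexes)
  n_test <- floor(t_percent / 100 * n)
  if (n_test < 1 || n_test >= n) {
    stop("t_percent leaves an empty test or training set")
  }
  withr_seed(seed, lapply(seq_len(rounds), function(r) {
    test <- sort(sample.int(n, n_test))
    list(round = r, test = test, train = setdiff(seq_len(n), test))
  }))
}

# Evaluate expr with a local RNG state seeded by `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Exact-match test between a predicted cluster and a reference complex
#'
#' A prediction is correct only if it is identical (as a set) to the
#' reference complex.
#'
#' @param cluster,complex Character vectors of member IDs.
#' @return Logical.
#' @export
match_exact <- function(cluster, complex) {
  setequal(as.character(cluster), as.character(complex))
}

#' Exact-match precision-recall curve with training-complex exclusion
#'
#' At every distinct prediction score `d`:
#' recall is the fraction of test complexes matched by at least one
#' prediction with score >= d; precision is the number of predictions with
#' score >= d matching a test complex, divided by the number of predictions
#' with score >= d that match no training complex (removing the bias of a
#' supervised weighting towards reproducing its training complexes).
#' Thresholds whose precision denominator is zero are omitted. The AUC is
#' the trapezoid area over the (recall, precision) points, anchored at
#' recall 0 with the precision of the highest threshold and not
#' extrapolated beyond the largest achieved recall.
#'
#' @param predictions A `small_complex_predictions` data.frame (or any
#'   data.frame with member columns and `score`).
#' @param test_complexes Catalogue of test reference complexes (only the
#'   small ones are meaningful to match).
#' @param train_complexes Catalogue of training complexes to exclude from
#'   the precision denominator (may be empty).
#' @return An object of class `pr_curve`: list with `points` (data.frame
#'   `threshold`, `recall`, `precision`), `auc`, `n_test`,
#'   `n_predictions`.
#' @export
pr_curve <- function(predictions, test_complexes, train_complexes = list()) {
  test_complexes <- as_complex_catalogue(test_complexes)
  train_complexes <- if (length(train_complexes)) {
    as_complex_catalogue(train_complexes)
  } else {
    list()
  }
  if (length(test_complexes) == 0) stop("test complex set is empty")
  members <- prediction_members(predictions)
  score <- as.numeric(predictions$score)
  memb_key <- vapply(members, paste, character(1), collapse = "\t")
  test_key <- vapply(lapply(test_complexes, function(m) sort(unique(m))),
                     paste, character(1), collapse = "\t")
  train_key <- vapply(lapply(train_complexes, function(m) sort(unique(m))),
                      paste, character(1), collapse = "\t")
  stopifnot(length(intersect(test_key, train_key)) == 0)
  test_hit <- match(memb_key, test_key)        # which test complex, or NA
  train_hit <- memb_key %in% train_key
  ord <- order(-score)
  score <- score[ord]
  test_hit <- test_hit[ord]
  train_hit <- train_hit[ord]
  n <- length(score)
  if (n == 0) {
    pts <- data.frame(threshold = numeric(0), recall = numeric(0),
                      precision = numeric(0))
    return(structure(list(points = pts, auc = 0,
                          n_test = length(test_complexes), n_predictions = 0),
                     class = "pr_curve"))
  }
  # cumulative counts in decreasing-score order
  cum_correct <- cumsum(!is.na(test_hit))
  cum_eligible <- cumsum(!train_hit)
  # distinct matched test complexes up to each position
  first_hit <- !is.na(test_hit) & !duplicated(test_hit, incomparables = NA)
  cum_matched <- cumsum(first_hit)
  last_of_threshold <- c(score[-1] != score[-n], TRUE)
  pos <- which(last_of_threshold)
  pts <- data.frame(threshold = score[pos],
                    recall = cum_matched[pos] / length(test_complexes),
                    precision = ifelse(cum_eligible[pos] == 0, NA_real_,
                                       cum_correct[pos] / cum_eligible[pos]))
  pts <- pts[!is.na(pts$precision), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = pr_auc_points(pts),
                 n_test = length(test_complexes), n_predictions = n),
            class = "pr_curve")
}

# Trapezoid area over achieved PR points sorted by recall, anchored at
# (0, precision of the highest threshold).
pr_auc_points <- function(pts) {
  if (nrow(pts) == 0) return(0)
  r <- c(0, pts$recall)
  p <- c(pts$precision[1], pts$precision)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Area under a precision-recall curve
#'
#' @param x A `pr_curve`.
#' @return The AUC in \[0, 1\].
#' @export
pr_auc <- function(x) {
  stopifnot(inherits(x, "pr_curve"))
  x$auc
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("Precision-recall curve: %d predictions vs %d test complexes\n",
              x$n_predictions, x$n_test))
  cat(sprintf("  %d thresholds, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  plot(x$points$recall, x$points$precision, type = "b", pch = 16, cex = 0.6,
       xlim = c(0, 1), ylim = c(0, 1), xlab = "recall", ylab = "precision",
       main = sprintf("PR curve (AUC = %.3f)", x$auc), ...)
  invisible(x)
}

#' Map cluster scores to cross-validation precision estimates
#'
#' Builds a step function from per-round precision-recall curves: for a
#' query score `s`, each round contributes the precision at its largest
#' threshold `<= s` (queries above the maximum threshold use the maximum
#' threshold's precision; queries below the minimum use the minimum's);
#' the estimate is the mean over rounds. Used to keep only
#' high-confidence novel predictions.
#'
#' @param cv_curves A list of `pr_curve` objects (>= 1).
#' @return A vectorized function score -> estimated precision.
#' @export
score_to_precision_map <- function(cv_curves) {
  stopifnot(length(cv_curves) >= 1)
  lapply(cv_curves, function(x) stopifnot(inherits(x, "pr_curve")))
  tables <- lapply(cv_curves, function(x) {
    pts <- x$points[order(x$points$threshold), , drop = FALSE]
    pts
  })
  function(s) {
    s <- as.numeric(s)
    per_round <- vapply(tables, function(pts) {
      if (nrow(pts) == 0) return(rep(NA_real_, length(s)))
      i <- findInterval(s, pts$threshold)  # largest threshold <= s
      i[i == 0] <- 1                       # below range: lowest threshold
      pts$precision[i]
    }, numeric(length(s)))
    if (length(s) == 1) mean(per_round) else rowMeans(matrix(per_round, nrow = length(s)))
  }
}

#' Cross-validated small-complex prediction performance
#'
#' Runs the full random sub-sampling protocol: in each round the catalogue
#' is split, edges are labelled with the training complexes only, the
#' network is weighted (or not, for the raw-reliability baseline), small
#' complexes are extracted and the exact-match precision-recall curve is
#' computed against the small test complexes, excluding training matches
#' from the precision denominator.
#'
#' @param reliable A `reliable_network`.
#' @param graphs Named list of full source `evidence_graph`s.
#' @param complexes Reference complex catalogue.
#' @param method `"sss"` (full weighting + Extract), `"sss_noiso"`
#'   (isolatedness ablation) or `"density"` (candidates ranked by raw
#'   reliability-weighted density, no supervision).
#' @param t_percent,rounds,seed Cross-validation design (see
#'   [split_complexes()]).
#' @param lambda,smoothing,min_score,cohesiveness Passed to the weighting
#'   and extraction stages.
#' @param size_threshold Largest "small" complex size.
#' @return An object of class `cv_result`: list with `curves` (per-round
#'   `pr_curve`s), `auc` (per-round numeric), `mean_auc`, `method`,
#'   `splits`.
#' @export
cross_validate <- function(reliable, graphs, complexes,
                           method = c("sss", "sss_noiso", "density"),
                           t_percent = 90, rounds = 10, seed = 1,
                           lambda = 10, smoothing = 1, min_score = 0,
                           cohesiveness = TRUE, size_threshold = 3) {
  method <- match.arg(method)
  complexes <- as_complex_catalogue(complexes)
  splits <- split_complexes(complexes, t_percent = t_percent, rounds = rounds,
                            seed = seed)
  features <- if (method != "density") {
    feature_table(reliable, graphs, lambda = lambda)
  }
  dens_preds <- if (method == "density") density_baseline_predictions(reliable)
  curves <- lapply(splits, function(sp) {
    train <- complexes[sp$train]
    test <- complexes[sp$test]
    test_small <- test[vapply(test, function(m) length(unique(m)),
                              integer(1)) <= size_threshold]
    if (length(test_small) == 0) stop("a round has no small test complexes")
    preds <- if (method == "density") {
      dens_preds
    } else {
      w <- sss_weight(reliable, graphs, labels = label_edges(reliable, train,
                                                             size_threshold),
                      smoothing = smoothing, iso = method == "sss",
                      features = features)
      extract_complexes(w, reliable, min_score = min_score,
                        cohesiveness = cohesiveness)
    }
    pr_curve(preds, test_small, train)
  })
  auc <- vapply(curves, pr_auc, numeric(1))
  structure(list(curves = curves, auc = auc, mean_auc = mean(auc),
                 method = method, splits = splits),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation [%s]: %d rounds\n", x$method, length(x$auc)))
  cat(sprintf("  PR-AUC per round: %s\n",
              paste(sprintf("%.3f", x$auc), collapse = ", ")))
  cat(sprintf("  mean PR-AUC: %.4f\n", x$mean_auc))
  invisible(x)
}

#' Raw-reliability density baseline predictions
#'
#' The unsupervised baseline: every edge and triangle of the reliable
#' network, ranked by weighted density under the reliability scores (the
#' edge score for size-2 candidates, the mean of the three edge scores for
#' size-3 candidates).
#'
#' @param reliable A `reliable_network`.
#' @return A `small_complex_predictions` data.frame (cohesiveness is `NA`).
#' @export
density_baseline_predictions <- function(reliable) {
  edges <- reliable$edges
  n <- nrow(edges)
  keys <- pair_keys(edges)
  w <- stats::setNames(edges$score, keys)
  res2 <- data.frame(size = rep(2L, n), member_1 = edges$protein_a,
                     member_2 = edges$protein_b, member_3 = NA_character_,
                     cohesiveness = NA_real_, score = edges$score,
                     stringsAsFactors = FALSE)
  tri <- list()
  for (i in seq_len(n)) {
    a <- edges$protein_a[i]
    b <- edges$protein_b[i]
    common <- intersect(reliable$adj[[a]], reliable$adj[[b]])
    common <- common[common > b]
    for (c3 in common) {
      sc <- (w[[keys[i]]] + w[[ekey(a, c3)]] + w[[ekey(b, c3)]]) / 3
      tri[[length(tri) + 1L]] <- data.frame(
        size = 3L, member_1 = a, member_2 = b, member_3 = c3,
        cohesiveness = NA_real_, score = sc, stringsAsFactors = FALSE)
    }
  }
  res <- rbind(res2, if (length(tri)) do.call(rbind, tri))
  ord <- order(-res$score, res$member_1, res$member_2, res$member_3,
               na.last = FALSE, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("small_complex_predictions", "data.frame")
  res
}
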