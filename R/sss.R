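SSS_CLASSES <- c("sm-comp", "lg-comp", "non-comp")

#' Label network edges against a reference complex catalogue
#'
#' Each edge is labelled `lg-comp` if both proteins co-occur in a large
#' reference complex (size > `size_threshold`), else `sm-comp` if they
#' co-occur in a small reference complex (2 to `size_threshold` distinct
#' members), else `non-comp`. Large-complex membership takes precedence
#' when a pair occurs in both.
#'
#' @param reliable A `reliable_network` (or any `evidence_graph`).
#' @param complexes A complex catalogue: list of character vectors of
#'   member IDs (see [read_complexes()]).
#' @param size_threshold Largest size counted as "small" (default 3).
#' @return Factor of labels (`sm-comp`, `lg-comp`, `non-comp`) aligned with
#'   `reliable$edges`.
#' @export
label_edges <- function(reliable, complexes, size_threshold = 3) {
  complexes <- as_complex_catalogue(complexes)
  sizes <- vapply(complexes, function(m) length(unique(m)), integer(1))
  sm_keys <- unique(unlist(lapply(complexes[sizes <= size_threshold],
                                  complex_pair_keys)))
  lg_keys <- unique(unlist(lapply(complexes[sizes > size_threshold],
                                  complex_pair_keys)))
  key <- pair_keys(reliable$edges)
  lab <- rep("non-comp", length(key))
  lab[key %in% sm_keys] <- "sm-comp"
  lab[key %in% lg_keys] <- "lg-comp"  # precedence: large overrides small
  factor(lab, levels = SSS_CLASSES)
}

#' Fit the size-specific naive-Bayes edge model
#'
#' Fits the supervised weighting model on labelled edges: every feature is
#' discretized by MDL supervised discretization ([mdl_discretize()]);
#' features that cannot be discretized carry no class information and are
#' removed (built-in feature selection). Class priors are the label
#' frequencies and class-conditional probability tables are
#' maximum-likelihood bin frequencies, optionally with an additive
#' pseudocount.
#'
#' @param x Data.frame of numeric feature columns (columns `protein_a` and
#'   `protein_b` are ignored if present), one row per labelled edge.
#' @param labels Factor or character vector of edge class labels with the
#'   three levels `sm-comp`, `lg-comp`, `non-comp`.
#' @param smoothing Pseudocount added to every (class, bin) cell; default 1
#'   (add-one). With 0 the estimates are the pure maximum-likelihood
#'   frequencies, and bins unseen in a class annihilate that class's
#'   posterior.
#' @return An object of class `sss_model` with components `features`
#'   (retained feature names), `removed`, `cuts` (per-feature cut points),
#'   `priors`, `cpt` (per-feature class x bin probability matrices),
#'   `smoothing` and `n` (training edges).
#' @seealso [predict.sss_model()], [sss_weight()]
#' @export
sss_fit <- function(x, labels, smoothing = 1) {
  stopifnot(is.data.frame(x), smoothing >= 0)
  x <- x[setdiff(names(x), c("protein_a", "protein_b"))]
  if (ncol(x) == 0) stop("no feature columns supplied")
  labels <- factor(as.character(labels), levels = SSS_CLASSES)
  if (anyNA(labels)) stop("labels must be sm-comp, lg-comp or non-comp")
  if (nrow(x) != length(labels)) stop("nrow(x) must equal length(labels)")
  n_class <- table(labels)
  if (any(n_class == 0)) {
    stop("training set has no edges of class: ",
         paste(names(n_class)[n_class == 0], collapse = ", "))
  }
  model <- structure(list(features = character(0), removed = character(0),
                          cuts = list(), priors = as.numeric(n_class / sum(n_class)),
                          cpt = list(), smoothing = smoothing,
                          n = length(labels)),
                     class = "sss_model")
  names(model$priors) <- SSS_CLASSES
  for (f in names(x)) {
    model <- sss_add_feature(model, f, x[[f]], labels)
  }
  if (length(model$features) == 0) {
    warning("all features were removed by MDL discretization; ",
            "posteriors will equal the class priors")
  }
  model
}

# Discretize one feature and add its CPT to the model; records removal when
# MDL finds no admissible cut.
sss_add_feature <- function(model, name, values, labels) {
  cuts <- mdl_discretize(values, labels)
  if (is.null(cuts)) {
    model$removed <- c(model$removed, name)
    return(model)
  }
  bins <- apply_cuts(values, cuts)
  nbin <- length(cuts) + 1L
  cpt <- matrix(0, nrow = 3, ncol = nbin,
                dimnames = list(SSS_CLASSES, as.character(seq_len(nbin))))
  for (cl in SSS_CLASSES) {
    cnt <- tabulate(bins[labels == cl], nbins = nbin)
    cpt[cl, ] <- (cnt + model$smoothing) /
      (sum(cnt) + model$smoothing * nbin)
  }
  model$features <- c(model$features, name)
  model$cuts[[name]] <- cuts
  model$cpt[[name]] <- cpt
  model
}

#' @export
print.sss_model <- function(x, ...) {
  cat("Size-specific naive-Bayes edge model\n")
  cat(sprintf("  training edges: %d  (priors sm/lg/non = %.3f/%.3f/%.3f)\n",
              x$n, x$priors[1], x$priors[2], x$priors[3]))
  cat(sprintf("  features retained: %d (%s)\n", length(x$features),
              paste(x$features, collapse = ", ")))
  if (length(x$removed)) {
    cat(sprintf("  removed by MDL: %s\n", paste(x$removed, collapse = ", ")))
  }
  cat(sprintf("  smoothing pseudocount: %g\n", x$smoothing))
  invisible(x)
}

#' @export
summary.sss_model <- function(object, ...) {
  structure(list(model = object), class = "summary.sss_model")
}

#' @export
print.summary.sss_model <- function(x, ...) {
  m <- x$model
  print(m)
  for (f in m$features) {
    cat(sprintf("\n  %s: cuts at %s\n", f,
                paste(signif(m$cuts[[f]], 6), collapse = ", ")))
    print(round(m$cpt[[f]], 4))
  }
  invisible(x)
}

#' @export
coef.sss_model <- function(object, ...) {
  list(priors = object$priors, cpt = object$cpt)
}

#' Posterior class probabilities for edges
#'
#' Applies the fitted model's discretization to new feature rows and
#' evaluates the naive-Bayes posterior of each class in log space:
#' `P(class | f) = prod_i P(F_i = f_i | class) P(class) / Z`.
#'
#' @param object An `sss_model`.
#' @param newdata Data.frame containing at least the model's retained
#'   feature columns.
#' @param type `"posterior"` (default) returns a data.frame `P_sm`, `P_lg`,
#'   `P_non`; `"class"` returns the maximum-posterior label.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.sss_model <- function(object, newdata, type = c("posterior", "class"),
                              ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata))
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("newdata lacks model feature(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(newdata)
  logp <- matrix(rep(log(object$priors), each = n), nrow = n,
                 dimnames = list(NULL, SSS_CLASSES))
  for (f in object$features) {
    bins <- apply_cuts(newdata[[f]], object$cuts[[f]])
    logp <- logp + t(log(object$cpt[[f]][, bins, drop = FALSE]))
  }
  # log-sum-exp normalization per edge
  mx <- apply(logp, 1, max)
  if (any(!is.finite(mx))) {
    stop("all class likelihoods are zero for some edge; ",
         "use smoothing > 0 to avoid zero-frequency annihilation")
  }
  w <- exp(logp - mx)
  post <- w / rowSums(w)
  if (type == "class") {
    return(factor(SSS_CLASSES[max.col(post, ties.method = "first")],
                  levels = SSS_CLASSES))
  }
  data.frame(P_sm = post[, "sm-comp"], P_lg = post[, "lg-comp"],
             P_non = post[, "non-comp"])
}

#' Isolatedness feature of reliable-network edges
#'
#' Posterior-weighted evidence that an edge is an isolated edge or part of
#' an isolated triangle in the network being weighted:
#' `ISO(a,b) = ISO2(a,b) + ISO3(a,b)` with
#' `ISO2(a,b) = P_sm(a,b) * prod P_non(x,y)` over reliable edges `(x,y)`
#' leaving the pair (`x` in `{a,b}`, `y` a neighbour outside the pair), and
#' `ISO3(a,b) = sum_c P_sm(a,b) P_sm(a,c) P_sm(b,c) * prod P_non(x,y)` over
#' common neighbours `c` and edges leaving the triangle `{a,b,c}`. Empty
#' products equal 1.
#'
#' @param posteriors Data.frame with columns `protein_a`, `protein_b`,
#'   `P_sm`, `P_lg`, `P_non`, one row per reliable edge.
#' @param reliable The `reliable_network` the posteriors live on.
#' @return Numeric vector of ISO values aligned with `reliable$edges`.
#' @export
iso_feature <- function(posteriors, reliable) {
  edges <- reliable$edges
  key <- pair_keys(edges)
  pkey <- pair_keys(canonical_pairs(posteriors$protein_a, posteriors$protein_b))
  idx <- match(key, pkey)
  if (anyNA(idx)) stop("posteriors missing for some reliable edges")
  p_sm <- stats::setNames(posteriors$P_sm[idx], key)
  p_non <- stats::setNames(posteriors$P_non[idx], key)
  adj <- reliable$adj
  get_non <- function(x, ys) {
    if (length(ys) == 0) return(1)
    prod(p_non[pair_key(pmin(x, ys), pmax(x, ys))])
  }
  vapply(seq_len(nrow(edges)), function(i) {
    a <- edges$protein_a[i]
    b <- edges$protein_b[i]
    na <- adj[[a]]
    nb <- adj[[b]]
    iso2 <- p_sm[i] * get_non(a, setdiff(na, b)) * get_non(b, setdiff(nb, a))
    common <- intersect(na, nb)
    iso3 <- 0
    for (c3 in common) {
      k_ac <- pair_key(min(a, c3), max(a, c3))
      k_bc <- pair_key(min(b, c3), max(b, c3))
      leave <- get_non(a, setdiff(na, c(b, c3))) *
        get_non(b, setdiff(nb, c(a, c3))) *
        get_non(c3, setdiff(adj[[c3]], c(a, b)))
      iso3 <- iso3 + p_sm[i] * p_sm[k_ac] * p_sm[k_bc] * leave
    }
    as.numeric(iso2 + iso3)
  }, numeric(1))
}

#' Size-specific supervised weighting of a reliable PPI network
#'
#' Runs the full weighting procedure: (1) MDL-discretize the twelve
#' source/topology features on the labelled edges, (2) learn the
#' maximum-likelihood class-conditional tables, (3) compute naive-Bayes
#' posteriors for every edge, (4) derive the isolatedness feature from
#' those posteriors, (5) MDL-discretize it and learn its table, and
#' (6) recompute the posteriors with ISO included. Steps 4-6 are skipped
#' with `iso = FALSE` (the no-isolatedness ablation), in which case the
#' returned posteriors are exactly the step-3 posteriors. ISO may also be
#' dropped by MDL itself when it carries no class information.
#'
#' @param reliable A `reliable_network`.
#' @param graphs Named list of full source `evidence_graph`s (see
#'   [feature_table()]).
#' @param complexes Reference complex catalogue used for training labels;
#'   ignored when `labels` is given.
#' @param labels Optional precomputed edge labels (factor, aligned with
#'   `reliable$edges`).
#' @param lambda NBC dampening factor.
#' @param smoothing CPT pseudocount (see [sss_fit()]).
#' @param iso Include the isolatedness feature (steps 4-6)?
#' @param features Optional precomputed [feature_table()] (to avoid
#'   recomputation across cross-validation rounds).
#' @return An object of class `sss_weighting`: list with `posteriors`
#'   (data.frame `protein_a`, `protein_b`, `P_sm`, `P_lg`, `P_non`),
#'   `model` (final `sss_model`), `model_initial` (step-2 model), `iso`
#'   (ISO values or `NULL`), `features`, `labels`.
#' @export
sss_weight <- function(reliable, graphs, complexes = NULL, labels = NULL,
                       lambda = 10, smoothing = 1, iso = TRUE,
                       features = NULL) {
  if (is.null(labels)) {
    if (is.null(complexes)) stop("supply 'complexes' or precomputed 'labels'")
    labels <- label_edges(reliable, complexes)
  }
  if (is.null(features)) {
    features <- feature_table(reliable, graphs, lambda = lambda)
  }
  m1 <- sss_fit(features, labels, smoothing = smoothing)
  p1 <- predict(m1, features)
  out <- list(posteriors = cbind(features[c("protein_a", "protein_b")], p1),
              model = m1, model_initial = m1, iso = NULL,
              features = features, labels = labels)
  class(out) <- "sss_weighting"
  if (!iso) return(out)
  iso_v <- iso_feature(out$posteriors, reliable)
  m2 <- sss_add_feature(m1, "ISO", iso_v, labels)
  out$iso <- iso_v
  out$model <- m2
  if ("ISO" %in% m2$features) {
    p2 <- predict(m2, cbind(features, ISO = iso_v))
    out$posteriors <- cbind(features[c("protein_a", "protein_b")], p2)
  }
  out
}

#' @export
print.sss_weighting <- function(x, ...) {
  cat(sprintf("SSS-weighted network: %d edges\n", nrow(x$posteriors)))
  cat(sprintf("  mean P_sm/P_lg/P_non = %.3f/%.3f/%.3f\n",
              mean(x$posteriors$P_sm), mean(x$posteriors$P_lg),
              mean(x$posteriors$P_non)))
  cat(sprintf("  isolatedness feature: %s\n",
              if (is.null(x$iso)) "disabled" else if ("ISO" %in% x$model$features)
                "included" else "removed by MDL"))
  invisible(x)
}

#' @export
summary.sss_weighting <- function(object, ...) {
  by_class <- split(object$posteriors$P_sm, object$labels)
  structure(list(weighting = object,
                 mean_p_sm = vapply(by_class, function(v)
                   if (length(v)) mean(v) else NA_real_, numeric(1))),
            class = "summary.sss_weighting")
}

#' @export
print.summary.sss_weighting <- function(x, ...) {
  print(x$weighting)
  cat("  mean P_sm by training label:\n")
  print(round(x$mean_p_sm, 4))
  print(x$weighting$model)
  invisible(x)
}
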