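#' Configuration for the synthetic PPI benchmark generator
#'
#' Describes a benchmark interactome with planted complexes: a protein
#' universe, counts of size-2, size-3 and larger complexes (large sizes
#' drawn from a truncated power law, matching the empirical size
#' distribution of complex catalogues), per-source Beta score distributions
#' conditioned on edge class, an edge false-negative rate, and per-source
#' spurious-edge rates.
#'
#' Default score shapes give small- and large-co-complex edges similar raw
#' source scores but clearly higher scores than background edges: raw
#' scores separate co-complex from non-co-complex pairs, while the
#' small/large distinction must come from topology (degree, shared
#' neighbourhood, isolation), the regime the size-specific model is built
#' for.
#'
#' @param n_proteins Size of the protein universe.
#' @param n_small2,n_small3 Numbers of planted size-2 and size-3 complexes.
#' @param n_large Number of planted large complexes (size > 3).
#' @param large_size_exponent,large_size_max Power-law exponent and cap for
#'   large complex sizes (support 4..`large_size_max`, P(s) ~ s^-exponent).
#' @param overlap_prob Probability that a new complex reuses one protein of
#'   an earlier complex (mimicking core-attachment overlap).
#' @param fn_rate False-negative rate: probability a co-complex pair is
#'   missing from the PPI source.
#' @param spurious_rate Erdos-Renyi rate of spurious PPI edges over
#'   non-co-complex pairs.
#' @param string_coverage,lit_coverage Probability that a co-complex pair
#'   is observed in the functional-association / literature source.
#' @param string_spurious,lit_spurious Spurious-pair rates of those
#'   sources.
#' @param score_shapes Nested list source -> class (`sm`, `lg`, `non`) ->
#'   `c(shape1, shape2)` of the Beta score distribution.
#' @param k Top-k cutoff used to build the reliable network.
#' @param seed Mandatory RNG seed; generation is fully determined by it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 300,
                         n_small2 = 15, n_small3 = 15, n_large = 12,
                         large_size_exponent = 2.5, large_size_max = 12,
                         overlap_prob = 0.1,
                         fn_rate = 0.1, spurious_rate = 0.005,
                         string_coverage = 0.75, lit_coverage = 0.5,
                         string_spurious = 0.004, lit_spurious = 0.003,
                         score_shapes = NULL, k = 10000, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(score_shapes)) {
    score_shapes <- list(
      PPI    = list(sm = c(7, 2.2), lg = c(7, 2.2), non = c(2.5, 4)),
      STRING = list(sm = c(5, 2),   lg = c(5, 2),   non = c(2, 4)),
      LIT    = list(sm = c(4, 2),   lg = c(3.5, 2), non = c(1.2, 5)))
  }
  cfg <- list(n_proteins = n_proteins, n_small2 = n_small2,
              n_small3 = n_small3, n_large = n_large,
              large_size_exponent = large_size_exponent,
              large_size_max = large_size_max, overlap_prob = overlap_prob,
              fn_rate = fn_rate, spurious_rate = spurious_rate,
              string_coverage = string_coverage, lit_coverage = lit_coverage,
              string_spurious = string_spurious, lit_spurious = lit_spurious,
              score_shapes = score_shapes, k = as.integer(k),
              seed = as.integer(seed))
  rates <- c(cfg$overlap_prob, cfg$fn_rate, cfg$spurious_rate,
             cfg$string_coverage, cfg$lit_coverage, cfg$string_spurious,
             cfg$lit_spurious)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$large_size_max < 4) stop("large_size_max must be >= 4")
  if (cfg$n_proteins < 10) stop("n_proteins too small")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic interactome with planted small and large complexes
#'
#' Plants the configured complexes over the protein universe (optionally
#' sharing one protein with an earlier complex), then builds three scored
#' evidence sources: the PPI source contains every within-complex pair
#' except false negatives plus Erdos-Renyi spurious pairs, with
#' class-conditional Beta scores standing in for Noisy-Or reliabilities;
#' the functional-association and literature sources observe co-complex
#' pairs with their coverage probabilities plus their own spurious pairs.
#' The reliable network is the top-k of the PPI source.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_ppi_data`: `graphs` (named list `PPI`,
#'   `STRING`, `LIT` of `evidence_graph`s), `reliable`
#'   (`reliable_network`), `complexes` (the planted catalogue),
#'   `edge_classes` (named character vector: true class per generated PPI
#'   pair) and `config`.
#' @export
simulate_ppi_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  withr_seed(cfg$seed, {
    proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
    sizes2 <- rep(2L, cfg$n_small2)
    sizes3 <- rep(3L, cfg$n_small3)
    large_support <- 4:cfg$large_size_max
    large_sizes <- if (cfg$n_large > 0) {
      sample(large_support, cfg$n_large, replace = TRUE,
             prob = large_support^(-cfg$large_size_exponent))
    } else {
      integer(0)
    }
    sizes <- c(sizes2, sizes3, large_sizes)
    if (sum(sizes) > cfg$n_proteins) {
      stop("complex membership exceeds the protein universe; ",
           "increase n_proteins or reduce complex counts")
    }
    free <- sample(proteins)  # random assignment order
    complexes <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      s <- sizes[i]
      shared <- character(0)
      if (i > 1 && stats::runif(1) < cfg$overlap_prob) {
        donor <- complexes[[sample.int(i - 1, 1)]]
        shared <- sample(donor, 1)
      }
      fresh <- free[seq_len(s - length(shared))]
      free <- free[-seq_len(s - length(shared))]
      complexes[[i]] <- sort(c(shared, fresh))
    }
    # true class of every co-complex pair (large overrides small)
    sm_keys <- unique(unlist(lapply(complexes[sizes <= 3], complex_pair_keys)))
    lg_keys <- unique(unlist(lapply(complexes[sizes > 3], complex_pair_keys)))
    co_keys <- union(sm_keys, lg_keys)
    co_class <- stats::setNames(ifelse(co_keys %in% lg_keys, "lg", "sm"),
                                co_keys)
    # candidate background pairs
    all_pairs <- utils::combn(proteins, 2)
    all_keys <- pair_key(all_pairs[1, ], all_pairs[2, ])
    bg_keys <- setdiff(all_keys, co_keys)

    draw_source <- function(src, coverage, spurious) {
      shapes <- cfg$score_shapes[[src]]
      keep_co <- co_keys[stats::runif(length(co_keys)) < coverage]
      keep_bg <- bg_keys[stats::runif(length(bg_keys)) < spurious]
      keys <- c(keep_co, keep_bg)
      cls <- c(co_class[keep_co], rep("non", length(keep_bg)))
      score <- numeric(length(keys))
      for (cl in c("sm", "lg", "non")) {
        sel <- cls == cl
        if (any(sel)) {
          score[sel] <- stats::rbeta(sum(sel), shapes[[cl]][1], shapes[[cl]][2])
        }
      }
      ab <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
      df <- data.frame(protein_a = ab[, 1], protein_b = ab[, 2],
                       score = score, stringsAsFactors = FALSE)
      list(graph = evidence_graph(df, source = src), keys = keys, class = cls)
    }

    ppi <- draw_source("PPI", coverage = 1 - cfg$fn_rate,
                       spurious = cfg$spurious_rate)
    string <- draw_source("STRING", coverage = cfg$string_coverage,
                          spurious = cfg$string_spurious)
    lit <- draw_source("LIT", coverage = cfg$lit_coverage,
                       spurious = cfg$lit_spurious)

    edge_classes <- stats::setNames(ppi$class, ppi$keys)
    reliable <- top_k_filter(ppi$graph, k = cfg$k)
    structure(list(graphs = list(PPI = ppi$graph, STRING = string$graph,
                                 LIT = lit$graph),
                   reliable = reliable,
                   complexes = as_complex_catalogue(complexes),
                   edge_classes = edge_classes,
                   config = cfg),
              class = "synth_ppi_data")
  })
}

#' @export
print.synth_ppi_data <- function(x, ...) {
  sizes <- vapply(x$complexes, length, integer(1))
  cat(sprintf("Synthetic interactome: %d proteins, seed %d\n",
              x$config$n_proteins, x$config$seed))
  cat(sprintf("  complexes: %d size-2, %d size-3, %d large (max size %d)\n",
              sum(sizes == 2), sum(sizes == 3), sum(sizes > 3),
              max(sizes)))
  for (src in names(x$graphs)) {
    cat(sprintf("  %-6s: %d edges\n", src, nrow(x$graphs[[src]]$edges)))
  }
  cat(sprintf("  reliable network: %d edges (k = %d)\n",
              nrow(x$reliable$edges), x$config$k))
  invisible(x)
}
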