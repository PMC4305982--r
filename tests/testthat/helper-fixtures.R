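# Fixture builders shared across the suite. All fixtures are constructed in
# code; no data files.

# evidence graph from triples: make_graph(c("A", "B", 0.5), ...)
make_graph <- function(..., source = "PPI") {
  e <- list(...)
  df <- data.frame(protein_a = vapply(e, function(x) x[1], character(1)),
                   protein_b = vapply(e, function(x) x[2], character(1)),
                   score = as.numeric(vapply(e, function(x) x[3], character(1))),
                   stringsAsFactors = FALSE)
  evidence_graph(df, source = source)
}

make_reliable <- function(..., k = 10000) {
  top_k_filter(make_graph(...)$edges, k = k)
}

# posterior table for a reliable network; sm/lg/non recycled over edges,
# non defaulting to the complement
make_posteriors <- function(reliable, p_sm, p_lg = NULL) {
  n <- nrow(reliable$edges)
  p_sm <- rep_len(p_sm, n)
  p_lg <- if (is.null(p_lg)) rep(0, n) else rep_len(p_lg, n)
  data.frame(protein_a = reliable$edges$protein_a,
             protein_b = reliable$edges$protein_b,
             P_sm = p_sm, P_lg = p_lg, P_non = 1 - p_sm - p_lg,
             stringsAsFactors = FALSE)
}

# a small random weighted network plus random posteriors, for oracle checks
random_posterior_network <- function(n_nodes, edge_prob, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  cmb <- combn(ids, 2)
  keep <- runif(ncol(cmb)) < edge_prob
  df <- data.frame(protein_a = cmb[1, keep], protein_b = cmb[2, keep],
                   score = runif(sum(keep), 0.1, 1), stringsAsFactors = FALSE)
  reliable <- top_k_filter(df, k = 10000)
  m <- nrow(reliable$edges)
  raw <- matrix(runif(3 * m), ncol = 3)
  raw <- raw / rowSums(raw)
  post <- data.frame(protein_a = reliable$edges$protein_a,
                     protein_b = reliable$edges$protein_b,
                     P_sm = raw[, 1], P_lg = raw[, 2], P_non = raw[, 3],
                     stringsAsFactors = FALSE)
  list(reliable = reliable, posteriors = post)
}

# name-indexed posterior lookup helpers used by test-side oracles
posterior_lookup <- function(post) {
  key <- paste(pmin(post$protein_a, post$protein_b),
               pmax(post$protein_a, post$protein_b), sep = "\t")
  list(sm = setNames(post$P_sm, key), lg = setNames(post$P_lg, key),
       non = setNames(post$P_non, key))
}

pkey <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\t")
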