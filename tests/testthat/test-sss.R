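test_that("edge labelling follows catalogue size classes with large precedence", {
  rel <- make_reliable(c("A", "B", "0.9"), c("C", "D", "0.8"),
                       c("E", "F", "0.7"))
  complexes <- list(c("A", "B"),                      # small (size 2)
                    c("C", "D", "X", "Y", "Z"),       # large (size 5)
                    c("C", "D", "W"))                 # small (size 3)
  lab <- label_edges(rel, complexes)
  expect_equal(as.character(lab), c("sm-comp", "lg-comp", "non-comp"))
  expect_error(as_complex_catalogue(list(c("A", "A"))), "fewer than 2")
})

test_that("maximum-likelihood parameters are the class-conditional frequencies", {
  # sm edges split evenly over the two feature values; lg all low, non all
  # high, so the two-value feature is informative enough to be retained
  x <- data.frame(f = c(rep(c(0.1, 0.9), each = 10), rep(0.1, 20),
                        rep(0.9, 20)))
  labels <- c(rep("sm-comp", 20), rep("lg-comp", 20), rep("non-comp", 20))
  m <- sss_fit(x, labels, smoothing = 0)
  expect_equal(m$cuts$f, 0.5)
  # sm: half of its edges at each value -> 0.5 each
  expect_equal(unname(m$cpt$f["sm-comp", ]), c(0.5, 0.5))
  # lg never shows the high value: ML probability 0 without smoothing
  expect_equal(unname(m$cpt$f["lg-comp", ]), c(1, 0))
  # priors are the label frequencies
  expect_equal(unname(m$priors), c(1, 1, 1) / 3)
  labels10 <- c(rep("sm-comp", 1), rep("lg-comp", 3), rep("non-comp", 6))
  m10 <- suppressWarnings(sss_fit(data.frame(f = c(rep(0, 4), rep(1, 6))),
                                  labels10))
  expect_equal(unname(m10$priors), c(0.1, 0.3, 0.6))
  expect_error(sss_fit(x, rep(c("sm-comp", "non-comp"), 30)), "lg-comp")
})

test_that("posteriors equal priors when features carry no information", {
  # all features removed by MDL -> posterior = prior
  x <- data.frame(f = rep(0.5, 30))
  labels <- rep(c("sm-comp", "lg-comp", "non-comp"), 10)
  expect_warning(m <- sss_fit(x, labels), "removed")
  p <- predict(m, x)
  expect_equal(unname(as.matrix(p)),
               matrix(rep(1 / 3, 90), ncol = 3), tolerance = 1e-12)
})

test_that("a perfectly separating feature drives the posterior to certainty", {
  x <- data.frame(f = c(rep(0, 10), rep(1, 20)))
  labels <- c(rep("sm-comp", 10), rep("lg-comp", 10), rep("non-comp", 10))
  m <- sss_fit(x, labels, smoothing = 0)
  p <- predict(m, data.frame(f = 0))
  expect_equal(p$P_sm, 1)
  expect_equal(p$P_lg, 0)
  expect_equal(p$P_non, 0)
})

test_that("naive-Bayes posteriors match exhaustive factored-joint enumeration", {
  set.seed(21)
  for (trial in 1:5) {
    n <- 30
    x <- data.frame(f1 = runif(n), f2 = rnorm(n), f3 = rexp(n))
    labels <- factor(c("sm-comp", "lg-comp", "non-comp")[
      sample.int(3, n, replace = TRUE)],
      levels = c("sm-comp", "lg-comp", "non-comp"))
    # force informative structure so MDL keeps at least one feature
    x$f1 <- x$f1 + 2 * (labels == "sm-comp")
    m <- sss_fit(x, labels, smoothing = 1)
    p <- predict(m, x)
    # oracle: direct product over the model's tables, no log-space
    for (i in seq_len(n)) {
      un <- m$priors
      for (f in m$features) {
        bin <- apply_cuts(x[[f]][i], m$cuts[[f]])
        un <- un * m$cpt[[f]][, bin]
      }
      expect_equal(as.numeric(p[i, ]), as.numeric(un / sum(un)),
                   tolerance = 1e-12)
    }
  }
})

test_that("posteriors are normalized on every edge", {
  set.seed(3)
  x <- data.frame(a = runif(50), b = runif(50))
  labels <- factor(rep(c("sm-comp", "lg-comp", "non-comp"), length.out = 50))
  x$a <- x$a + as.integer(labels)
  m <- sss_fit(x, labels)
  p <- predict(m, x)
  expect_equal(p$P_sm + p$P_lg + p$P_non, rep(1, 50), tolerance = 1e-9)
})

test_that("isolatedness of isolated edges and simple chains is exact", {
  rel <- make_reliable(c("A", "B", "0.9"))
  post <- make_posteriors(rel, p_sm = 0.8)
  expect_equal(iso_feature(post, rel), 0.8)  # empty products
  # one adjacent edge with P_non = 0.5, no common neighbour
  rel2 <- make_reliable(c("A", "B", "0.9"), c("B", "C", "0.9"))
  post2 <- make_posteriors(rel2, p_sm = c(0.8, 0.5))  # P_non(B,C) = 0.5
  expect_equal(iso_feature(post2, rel2)[1], 0.8 * 0.5)
})

test_that("isolatedness of an isolated triangle matches the full expression", {
  rel <- make_reliable(c("A", "B", "0.9"), c("A", "C", "0.9"),
                       c("B", "C", "0.9"))
  post <- make_posteriors(rel, p_sm = 0.9, p_lg = 0.05)  # P_non = 0.05
  iso <- iso_feature(post, rel)
  # oracle for edge (A,B): ISO2 = P_sm * P_non(A,C) * P_non(B,C);
  # ISO3 over the single common neighbour C has no leaving edges
  expected <- 0.9 * 0.05 * 0.05 + 0.9^3
  expect_equal(iso, rep(expected, 3), tolerance = 1e-12)
})

test_that("raising a surrounding edge's P_non never decreases ISO", {
  set.seed(31)
  net <- random_posterior_network(9, 0.4, seed = 31)
  iso0 <- iso_feature(net$posteriors, net$reliable)
  for (trial in 1:10) {
    post <- net$posteriors
    j <- sample.int(nrow(post), 1)
    # move mass from P_lg to P_non on edge j (P_sm untouched, so only the
    # surrounding-edge P_non factors of other edges' ISO terms change)
    bump <- 0.9 * post$P_lg[j]
    post$P_lg[j] <- post$P_lg[j] - bump
    post$P_non[j] <- post$P_non[j] + bump
    iso1 <- iso_feature(post, net$reliable)
    others <- setdiff(seq_len(nrow(post)), j)
    expect_true(all(iso1[others] >= iso0[others] - 1e-12))
  }
})

test_that("disabling the isolatedness step reproduces the initial posteriors", {
  d <- simulate_ppi_data(synth_config(n_proteins = 120, n_small2 = 8,
                                      n_small3 = 8, n_large = 6, seed = 5))
  w_iso <- sss_weight(d$reliable, d$graphs, complexes = d$complexes)
  w_no <- sss_weight(d$reliable, d$graphs, complexes = d$complexes,
                     iso = FALSE)
  p1 <- predict(w_iso$model_initial, w_iso$features)
  expect_identical(w_no$posteriors$P_sm, p1$P_sm)
  expect_identical(w_no$posteriors$P_lg, p1$P_lg)
  expect_identical(w_no$posteriors$P_non, p1$P_non)
})

test_that("weighting separates planted small-complex edges from background", {
  d <- simulate_ppi_data(synth_config(n_proteins = 150, n_small2 = 10,
                                      n_small3 = 10, n_large = 6, seed = 9))
  w <- sss_weight(d$reliable, d$graphs, complexes = d$complexes)
  truth <- d$edge_classes[pair_key(w$posteriors$protein_a,
                                   w$posteriors$protein_b)]
  expect_gt(mean(w$posteriors$P_sm[truth == "sm"]),
            mean(w$posteriors$P_sm[truth == "non"]))
  expect_equal(w$posteriors$P_sm + w$posteriors$P_lg + w$posteriors$P_non,
               rep(1, nrow(w$posteriors)), tolerance = 1e-9)
})

test_that("learned conditional tables approach the generating distributions", {
  # KL(true bin distribution || learned CPT) for one feature shrinks with n
  gen <- function(n, seed) {
    set.seed(seed)
    labels <- factor(rep(c("sm-comp", "lg-comp", "non-comp"),
                         length.out = n),
                     levels = c("sm-comp", "lg-comp", "non-comp"))
    shapes <- list("sm-comp" = c(7, 2), "lg-comp" = c(4, 4),
                   "non-comp" = c(2, 6))
    f <- numeric(n)
    for (cl in levels(labels)) {
      idx <- labels == cl
      f[idx] <- rbeta(sum(idx), shapes[[cl]][1], shapes[[cl]][2])
    }
    m <- sss_fit(data.frame(f = f), labels, smoothing = 0)
    kl <- 0
    for (cl in levels(labels)) {
      edges <- c(0, m$cuts$f, 1)
      p_true <- diff(pbeta(edges, shapes[[cl]][1], shapes[[cl]][2]))
      p_hat <- m$cpt$f[cl, ]
      ok <- p_true > 0 & p_hat > 0
      kl <- kl + sum(p_true[ok] * log(p_true[ok] / p_hat[ok]))
    }
    kl
  }
  kl_small <- mean(vapply(1:3, function(s) gen(150, s), numeric(1)))
  kl_large <- mean(vapply(1:3, function(s) gen(4000, s), numeric(1)))
  expect_lt(kl_large, kl_small)
})

test_that("a fitted model round-trips through its JSON serialization", {
  set.seed(13)
  x <- data.frame(f1 = runif(60), f2 = runif(60))
  labels <- factor(rep(c("sm-comp", "lg-comp", "non-comp"), 20))
  x$f1 <- x$f1 + 2 * as.integer(labels)
  m <- sss_fit(x, labels)
  path <- tempfile(fileext = ".json")
  write_sss_model(m, path)
  m2 <- read_sss_model(path)
  expect_equal(m2$features, m$features)
  expect_equal(m2$cuts, m$cuts)
  expect_equal(m2$priors, m$priors)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
})
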