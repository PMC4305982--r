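test_that("disambiguation subtracts incident-triangle mass with clamping", {
  # edge with no common neighbours keeps its full small-co-complex weight
  rel <- make_reliable(c("A", "B", "0.9"), c("B", "C", "0.8"))
  post <- make_posteriors(rel, p_sm = 0.7)
  comp <- disambiguate_components(post, rel)
  expect_equal(unname(comp$sm2["A\tB"]), 0.7)
  # single triangle: sm2 = 0.9 - 0.9*0.8*0.8; sm3 w.r.t. the triangle = 0.9
  rel2 <- make_reliable(c("A", "B", "0.9"), c("A", "C", "0.9"),
                        c("B", "C", "0.9"))
  post2 <- make_posteriors(rel2, p_sm = c(0.9, 0.8, 0.8))  # AB, AC, BC
  comp2 <- disambiguate_components(post2, rel2)
  expect_equal(unname(comp2$sm2["A\tB"]), 0.9 - 0.9 * 0.8 * 0.8)
  expect_equal(unname(comp2$sm3[["A\tB"]]["C"]), 0.9)
  # two unit-weight triangles: raw sm2 = 1 - 2 -> clamped to 0
  rel3 <- make_reliable(c("A", "B", "1"), c("A", "C", "1"), c("B", "C", "1"),
                        c("A", "D", "1"), c("B", "D", "1"))
  post3 <- make_posteriors(rel3, p_sm = 1)
  comp3 <- disambiguate_components(post3, rel3)
  expect_equal(unname(comp3$sm2["A\tB"]), 0)
})

test_that("cohesiveness of size-2 clusters follows the internal/outgoing ratio", {
  rel <- make_reliable(c("A", "B", "0.9"))
  post <- make_posteriors(rel, p_sm = 0.7)
  expect_equal(cohesiveness2(post, rel, "A", "B"), 1)  # isolated edge
  # outgoing (P_sm + P_lg) mass equal to the component score -> 0.5
  rel2 <- make_reliable(c("A", "B", "0.9"), c("B", "C", "0.8"))
  post2 <- make_posteriors(rel2, p_sm = c(0.5, 0.3), p_lg = c(0, 0.2))
  expect_equal(cohesiveness2(post2, rel2, "A", "B"), 0.5 / (0.5 + 0.5))
  # zero numerator with nonzero outgoing -> 0
  post3 <- make_posteriors(rel2, p_sm = c(0, 0.3), p_lg = c(0, 0.2))
  expect_equal(cohesiveness2(post3, rel2, "A", "B"), 0)
})

test_that("cohesiveness of size-3 clusters handles isolated and degenerate cases", {
  rel <- make_reliable(c("A", "B", "0.9"), c("A", "C", "0.9"),
                       c("B", "C", "0.9"))
  post <- make_posteriors(rel, p_sm = 0.9)
  expect_equal(cohesiveness3(post, rel, "A", "B", "C"), 1)
  post0 <- make_posteriors(rel, p_sm = 0)
  expect_equal(cohesiveness3(post0, rel, "A", "B", "C"), 0)
  rel2 <- make_reliable(c("A", "B", "0.9"), c("A", "C", "0.9"))
  expect_error(cohesiveness3(make_posteriors(rel2, 0.5), rel2, "A", "B", "C"),
               "internal edges")
})

test_that("cluster scores on hand-checked fixtures are exact", {
  # isolated edge with P_sm = 0.7: Coh = 1, score = 0.7
  rel <- make_reliable(c("A", "B", "0.9"))
  preds <- extract_complexes(make_posteriors(rel, p_sm = 0.7), rel)
  expect_equal(nrow(preds), 1)
  expect_equal(preds$score, 0.7)
  expect_equal(preds$cohesiveness, 1)
  # empty network -> no candidates
  rel0 <- make_reliable(c("A", "B", "1"))
  empty <- extract_complexes(make_posteriors(rel0, p_sm = 0), rel0)
  expect_equal(nrow(empty), 0)
})

test_that("an isolated strong triangle outranks its constituent edges", {
  rel <- make_reliable(c("A", "B", "1"), c("A", "C", "1"), c("B", "C", "1"))
  post <- make_posteriors(rel, p_sm = 0.9, p_lg = 0.05)
  preds <- extract_complexes(post, rel)
  tri <- preds[preds$size == 3, ]
  ed <- preds[preds$size == 2, ]
  # size-3 components all equal P_sm (no other triangles): score = Coh * 0.9
  # triangle internal sum = 2.7, outgoing = 0 -> Coh = 1, score = 0.9
  expect_equal(tri$score, 0.9)
  # each member edge: sm2 = 0.9 - 0.9^3 = 0.171; the within-triangle edges
  # leaving the pair carry P_sm + P_lg = 0.95 each
  sm2 <- 0.9 - 0.9^3
  coh <- sm2 / (sm2 + 2 * 0.95)
  expect_equal(ed$score, rep(coh * sm2, 3), tolerance = 1e-12)
  expect_true(all(tri$score > ed$score))
})

test_that("extracted scores match an independent brute-force oracle", {
  for (seed in c(41, 42, 43)) {
    net <- random_posterior_network(12, 0.45, seed = seed)
    rel <- net$reliable
    post <- net$posteriors
    lk <- posterior_lookup(post)
    adj <- lapply(setNames(rel$proteins, rel$proteins),
                  function(p) graph_neighbors(rel, p))
    psl <- function(x, y) lk$sm[[pkey(x, y)]] + lk$lg[[pkey(x, y)]]
    sm2_or <- function(a, b) {
      common <- intersect(adj[[a]], adj[[b]])
      s <- lk$sm[[pkey(a, b)]]
      max(0, s - sum(vapply(common, function(x)
        s * lk$sm[[pkey(a, x)]] * lk$sm[[pkey(b, x)]], numeric(1))))
    }
    sm3_or <- function(a, b, c3) {
      common <- setdiff(intersect(adj[[a]], adj[[b]]), c3)
      s <- lk$sm[[pkey(a, b)]]
      max(0, s - sum(vapply(common, function(x)
        s * lk$sm[[pkey(a, x)]] * lk$sm[[pkey(b, x)]], numeric(1))))
    }
    out_sum <- function(members) {
      tot <- 0
      for (x in members) {
        for (y in setdiff(adj[[x]], members)) tot <- tot + psl(x, y)
      }
      tot
    }
    preds <- extract_complexes(post, rel, min_score = -1)
    for (i in seq_len(nrow(preds))) {
      if (preds$size[i] == 2) {
        a <- preds$member_1[i]; b <- preds$member_2[i]
        num <- sm2_or(a, b)
        out <- out_sum(c(a, b))
        coh <- if (num + out == 0) 0 else num / (num + out)
        expect_equal(preds$score[i], coh * num, tolerance = 1e-12)
      } else {
        a <- preds$member_1[i]; b <- preds$member_2[i]; c3 <- preds$member_3[i]
        num <- sm3_or(a, b, c3) + sm3_or(a, c3, b) + sm3_or(b, c3, a)
        out <- out_sum(c(a, b, c3))
        coh <- if (num + out == 0) 0 else num / (num + out)
        expect_equal(preds$score[i], coh * num / 3, tolerance = 1e-12)
        expect_equal(preds$cohesiveness[i], coh, tolerance = 1e-12)
      }
    }
    # triangle census cross-check against igraph
    skip_if_not_installed("igraph")
    ig <- igraph::graph_from_data_frame(rel$edges[1:2], directed = FALSE)
    expect_equal(sum(preds$size == 3),
                 sum(igraph::count_triangles(ig)) / 3)
  }
})

test_that("cluster scores stay within [0, 1]", {
  net <- random_posterior_network(11, 0.5, seed = 77)
  preds <- extract_complexes(net$posteriors, net$reliable, min_score = -1)
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_true(all(preds$cohesiveness >= 0 & preds$cohesiveness <= 1))
})

test_that("adding an outgoing edge strictly decreases cohesiveness", {
  rel <- make_reliable(c("A", "B", "0.9"))
  post <- make_posteriors(rel, p_sm = 0.7)
  c0 <- cohesiveness2(post, rel, "A", "B")
  rel2 <- make_reliable(c("A", "B", "0.9"), c("B", "C", "0.8"))
  post2 <- make_posteriors(rel2, p_sm = c(0.7, 0.4))
  expect_lt(cohesiveness2(post2, rel2, "A", "B"), c0)
})

test_that("triangle context lowers the size-2 component of an edge", {
  rel_tri <- make_reliable(c("A", "B", "1"), c("A", "C", "1"),
                           c("B", "C", "1"))
  rel_iso <- make_reliable(c("A", "B", "1"))
  comp_tri <- disambiguate_components(make_posteriors(rel_tri, 0.8), rel_tri)
  comp_iso <- disambiguate_components(make_posteriors(rel_iso, 0.8), rel_iso)
  expect_lt(comp_tri$sm2[["A\tB"]], comp_iso$sm2[["A\tB"]])
})

test_that("disabling cohesiveness weighting yields plain component densities", {
  net <- random_posterior_network(10, 0.4, seed = 55)
  comp <- disambiguate_components(net$posteriors, net$reliable)
  preds <- extract_complexes(net$posteriors, net$reliable, min_score = -1,
                             cohesiveness = FALSE)
  p2 <- preds[preds$size == 2, ]
  expect_equal(p2$score,
               unname(comp$sm2[pkey(p2$member_1, p2$member_2)]),
               tolerance = 1e-12)
  p3 <- preds[preds$size == 3, ]
  if (nrow(p3)) {
    dens <- vapply(seq_len(nrow(p3)), function(i) {
      a <- p3$member_1[i]; b <- p3$member_2[i]; c3 <- p3$member_3[i]
      (comp$sm3[[pkey(a, b)]][[c3]] + comp$sm3[[pkey(a, c3)]][[b]] +
          comp$sm3[[pkey(b, c3)]][[a]]) / 3
    }, numeric(1))
    expect_equal(p3$score, dens, tolerance = 1e-12)
  }
})
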