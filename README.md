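# smallcomplex

Discovery of **small protein complexes** (two or three distinct proteins)
from protein-protein interaction (PPI) networks, for computational and
systems biologists working on complex prediction and interactome analysis.

Small complexes dominate curated catalogues but defeat generic
dense-cluster algorithms: a fully dense size-2 or size-3 cluster is just an
edge or a triangle, of which a PPI network has thousands, and a single
missing or spurious interaction destroys or fakes one. `smallcomplex`
implements a two-stage supervised approach:

1. **SSS (size-specific supervised weighting).** Every edge of a reliable
   PPI network (top-k edges by Noisy-Or reliability,
   `reliability(a,b) = 1 − ∏_i (1 − rel_i)^(n_i,a,b)`) is weighted with
   three posterior probabilities — in a small complex (`P_sm`), in a large
   complex (`P_lg`), in none (`P_non`) — by a naive-Bayes
   maximum-likelihood model over MDL-discretized features: three data
   sources (PPI reliability, functional association, literature
   co-occurrence by Jaccard similarity of publication sets) and, per
   source, the pair degree DEG, the iterated AdjustCD shared-neighbour
   score SHARED, and the neighbourhood connectivity NBC. An isolatedness
   feature (`ISO = ISO2 + ISO3`, the posterior-weighted evidence of being
   an isolated edge or an isolated triangle) is derived from an initial
   posterior pass and folded into a second pass. Small-complex edges get
   their own class because their topology (sparse, isolated) is the
   opposite of large-complex edges, which otherwise dominate training.
2. **Extract.** Each edge's `P_sm` is disambiguated into a size-2 component
   `P′_sm2(a,b) = P_sm(a,b) − Σ_x P_sm(a,b) P_sm(a,x) P_sm(b,x)` (over
   common neighbours `x`, clamped at 0) and triangle-specific size-3
   components. Every edge and triangle is then scored by its
   **cohesiveness-weighted density**: cohesiveness (internal component
   score over internal plus outgoing `P_sm + P_lg`) times the mean internal
   component score.

The package also provides the evaluation protocol (random sub-sampling
cross-validation, exact-match precision-recall with training-complex
exclusion, PR-AUC) and a synthetic benchmark generator with planted
complexes, so the whole method is testable without external downloads.

## Worked example

On a synthetic benchmark (300 proteins; 15 size-2, 15 size-3 and 12 large
planted complexes; 10% missing and 0.5% spurious edges):

```r
library(smallcomplex)

d <- simulate_ppi_data(synth_config(seed = 42))
w <- sss_weight(d$reliable, d$graphs, complexes = d$complexes)
summary(w)
#> SSS-weighted network: 504 edges
#>   mean P_sm/P_lg/P_non = 0.130/0.408/0.462
#>   isolatedness feature: included
#>   mean P_sm by training label:
#>  sm-comp  lg-comp non-comp
#>   0.9590   0.0212   0.0351
```

Edges from planted small complexes average `P_sm = 0.96` versus `0.04` for
background edges: the model has learned the size-specific signature.
Extraction ranks candidate clusters by cohesiveness-weighted density:

```r
preds <- extract_complexes(w, d$reliable)
preds
#> Predicted small complexes: 850 (size 2: 504, size 3: 346)
#> Top predictions:
#>   size member_1 member_2 member_3 cohesiveness  score
#> 1    2    P0089    P0165     <NA>       1.0000 1.0000
#> 2    2    P0130    P0262     <NA>       1.0000 1.0000
#> 3    3    P0016    P0220    P0248       1.0000 1.0000
```

A score near 1 means an isolated, high-`P_sm` edge or triangle — maximal
evidence for a small complex. Cross-validated performance (train on half
the catalogue, test exact matches against held-out small complexes):

```r
cv <- cross_validate(d$reliable, d$graphs, d$complexes, "sss",
                     t_percent = 50, rounds = 3, seed = 7)
cv
#> Cross-validation [sss]: 3 rounds
#>   PR-AUC per round: 0.408, 0.655, 0.541
#>   mean PR-AUC: 0.5347

f <- score_to_precision_map(cv$curves)
f(0.9)   # estimated precision of a novel prediction scoring 0.9
#> [1] 0.723
```

The same protocol with `method = "density"` (candidates ranked by raw
reliability-weighted density, no supervision) yields a mean PR-AUC of about
0.03 on these conditions — an order of magnitude below SSS + Extract.

A command-line front end is installed at
`system.file("exec", "sssx", package = "smallcomplex")` with subcommands
`simulate`, `reliability`, `features`, `weight`, `extract`, `evaluate` and
`run` over plain TSV files.

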