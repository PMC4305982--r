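#' Supervised discretization by the minimum description length criterion
#'
#' Recursive entropy-based binary splitting of a numeric feature against
#' class labels. At each step the candidate cut minimizing the weighted
#' class entropy is chosen among boundary points (midpoints between
#' consecutive distinct values whose class composition differs) and accepted
#' only if its information gain passes the MDL criterion
#' `gain > log2(n - 1)/n + delta/n` with
#' `delta = log2(3^k - 2) - (k*Ent(S) - k1*Ent(S1) - k2*Ent(S2))`,
#' where `k`, `k1`, `k2` count the classes present in the full set and the
#' two subsets. If no initial cut is accepted the feature carries no class
#' information at this resolution and is removed.
#'
#' @param values Numeric feature values, one per training edge.
#' @param labels Class labels (factor or character), same length.
#' @return Sorted numeric vector of cut points, or `NULL` when the feature
#'   cannot be discretized (including constant features).
#' @examples
#' mdl_discretize(c(1:10) / 10, rep(c("x", "y"), each = 5))
#' @export
mdl_discretize <- function(values, labels) {
  values <- as.numeric(values)
  labels <- as.integer(factor(labels))
  stopifnot(length(values) == length(labels))
  if (anyNA(values) || anyNA(labels)) stop("values/labels must not contain NA")
  if (length(unique(labels)) < 2) return(NULL)
  ord <- order(values)
  cuts <- mdl_split(values[ord], labels[ord], max(labels))
  if (length(cuts) == 0) NULL else sort(cuts)
}

# Shannon entropy (bits) of a class count vector.
class_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Recursive splitter on values sorted ascending. Returns accepted cut values.
mdl_split <- function(v, y, nclass) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  # collapse to runs of equal value with per-class counts
  blk <- cumsum(c(TRUE, v[-1] != v[-n]))
  nb <- blk[n]
  if (nb < 2) return(numeric(0))
  cnt <- matrix(0, nrow = nb, ncol = nclass)
  cnt[cbind(blk, y)] <- 0  # ensure allocation
  for (cl in seq_len(nclass)) {
    t <- tabulate(blk[y == cl], nbins = nb)
    cnt[, cl] <- t
  }
  vals <- v[!duplicated(blk)]
  cum <- apply(cnt, 2, cumsum)            # nb x nclass, counts up to block i
  cum <- matrix(cum, nrow = nb)
  tot <- cum[nb, ]
  ent_s <- class_entropy(tot)
  # boundary candidates: between blocks i, i+1 unless both are pure in the
  # same single class (Fayyad-Irani boundary-point theorem)
  cand <- integer(0)
  for (i in seq_len(nb - 1)) {
    ci <- cnt[i, ]
    cj <- cnt[i + 1, ]
    same_pure <- sum(ci > 0) == 1 && sum(cj > 0) == 1 &&
      which(ci > 0) == which(cj > 0)
    if (!same_pure) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(numeric(0))
  best <- NULL
  best_e <- Inf
  for (i in cand) {
    left <- cum[i, ]
    right <- tot - left
    nl <- sum(left)
    e <- (nl * class_entropy(left) + (n - nl) * class_entropy(right)) / n
    if (e < best_e - 1e-12) {
      best_e <- e
      best <- i
    }
  }
  left <- cum[best, ]
  right <- tot - left
  gain <- ent_s - best_e
  k <- sum(tot > 0)
  k1 <- sum(left > 0)
  k2 <- sum(right > 0)
  delta <- log2(3^k - 2) -
    (k * ent_s - k1 * class_entropy(left) - k2 * class_entropy(right))
  if (gain <= log2(n - 1) / n + delta / n) return(numeric(0))
  cut <- (vals[best] + vals[best + 1]) / 2
  nl <- sum(left)
  c(mdl_split(v[seq_len(nl)], y[seq_len(nl)], nclass),
    cut,
    mdl_split(v[(nl + 1):n], y[(nl + 1):n], nclass))
}

#' Apply discretization cut points to feature values
#'
#' Maps values to integer bins `1..(length(cuts) + 1)`; values equal to a
#' cut fall in the lower bin (cuts are midpoints between observed training
#' values, so ties can only arise on new data).
#'
#' @param values Numeric vector.
#' @param cuts Sorted numeric cut points (possibly empty).
#' @return Integer bin indices.
#' @export
apply_cuts <- function(values, cuts) {
  if (length(cuts) == 0) return(rep(1L, length(values)))
  as.integer(cut(as.numeric(values), c(-Inf, cuts, Inf), labels = FALSE,
                 right = TRUE))
}
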