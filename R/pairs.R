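#' Canonicalize undirected protein pairs
#'
#' Protein pairs are undirected; every pair is stored with its two member IDs
#' in lexicographic order so that an edge has exactly one representation.
#' Self-pairs are rejected.
#'
#' @param a,b Character vectors of protein IDs (recycled to common length is
#'   not supported; they must have equal length).
#' @return A data.frame with columns `protein_a`, `protein_b` where
#'   `protein_a < protein_b` row-wise.
#' @examples
#' canonical_pairs(c("B", "A"), c("A", "C"))
#' @export
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (anyNA(a) || anyNA(b)) stop("protein IDs must not be NA")
  if (any(a == b)) stop("self-pairs (a == b) are not allowed")
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

# Single string key for a canonical pair. IDs may not contain tab (enforced
# implicitly by the TSV interfaces).
pair_key <- function(a, b) paste(a, b, sep = "\t")

# Keys for the rows of a canonical pair data.frame.
pair_keys <- function(pairs) pair_key(pairs$protein_a, pairs$protein_b)

# All unordered pairs within a set of members, canonicalized. Returns a
# character vector of keys.
complex_pair_keys <- function(members) {
  members <- unique(as.character(members))
  if (length(members) < 2) return(character(0))
  cmb <- utils::combn(sort(members), 2)
  pair_key(cmb[1, ], cmb[2, ])
}
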