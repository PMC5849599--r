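#' Derive a reproducible sub-stream seed
#'
#' A single root seed drives every stochastic component of a run.  Each
#' component derives its own seed deterministically from the root seed and a
#' component label, so adding or re-ordering components does not perturb the
#' random streams of the others.
#'
#' @param seed Integer root seed.
#' @param component Character label of the consuming component.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "signatures")
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  m <- 2147483399
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(component)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two clusterings of the same items, corrected for chance;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Cosine similarity of two non-negative vectors
#'
#' @param a,b Numeric vectors of equal length; neither may be all zero.
#' @return Cosine similarity in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine_similarity() is undefined for an all-zero vector")
  }
  sum(a * b) / (na * nb)
}

# run code under a derived seed without disturbing the caller's RNG state
with_substream <- function(seed, component, code) {
  withr::with_seed(derive_seed(seed, component), code)
}

# reverse complement of a string of ACGT bases
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}
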