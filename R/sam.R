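sam_d_stat <- function(mat, grp1, grp2, s0) {
  n1 <- length(grp1)
  n2 <- length(grp2)
  m1 <- rowMeans(mat[, grp1, drop = FALSE])
  m2 <- rowMeans(mat[, grp2, drop = FALSE])
  ss <- rowSums((mat[, grp1, drop = FALSE] - m1)^2) +
    rowSums((mat[, grp2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  (m2 - m1) / (s + s0)
}

sam_pooled_s <- function(mat, grp1, grp2) {
  m1 <- rowMeans(mat[, grp1, drop = FALSE])
  m2 <- rowMeans(mat[, grp2, drop = FALSE])
  ss <- rowSums((mat[, grp1, drop = FALSE] - m1)^2) +
    rowSums((mat[, grp2, drop = FALSE] - m2)^2)
  sqrt((1 / length(grp1) + 1 / length(grp2)) * ss /
         (length(grp1) + length(grp2) - 2))
}

# exchangeability constant: the percentile of s minimizing the coefficient
# of variation of the d-statistic's spread across s-quantile bins
choose_s0 <- function(mat, grp1, grp2) {
  s <- sam_pooled_s(mat, grp1, grp2)
  if (all(s == 0)) {
    abort("all genes have zero within-group variance")
  }
  candidates <- quantile(s, seq(0, 1, by = 0.05), names = FALSE)
  bins <- cut(s, breaks = unique(quantile(s, seq(0, 1, length.out = 21))),
              include.lowest = TRUE)
  cv <- vapply(candidates, function(s0) {
    d <- sam_d_stat(mat, grp1, grp2, s0)
    spread <- tapply(d, bins, mad)
    spread <- spread[is.finite(spread) & spread > 0]
    if (length(spread) < 2) {
      return(Inf)
    }
    sd(spread) / mean(spread)
  }, numeric(1))
  if (!any(is.finite(cv)) ||
      diff(range(cv[is.finite(cv)])) < 1e-6) {
    return(quantile(s, 0.05, names = FALSE))
  }
  candidates[which.min(cv)]
}

#' Permutation-based differential expression between two groups
#'
#' Computes a moderated t-like statistic
#' `d = (mean2 - mean1) / (s + s0)` per gene, where `s` is the pooled
#' standard error and `s0` an exchangeability constant chosen from the
#' percentiles of `s` to stabilize the variance of `d`.  The null
#' distribution comes from label permutations; q-values are the ratio of
#' the expected (permutation-averaged) to observed number of genes at or
#' beyond each gene's absolute statistic, monotonized.
#'
#' @param expr Normalized expression tibble.
#' @param labels Named two-group labels over the samples; `d > 0` means
#'   higher in the second group (alphabetical order).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return A tibble with `gene`, `d`, `q`, `direction`, `significant`,
#'   sorted by decreasing `|d|`.
#' @export
sam_differential_expression <- function(expr, labels, n_perm = 1000,
                                        seed = 1L, q_threshold = 0.05) {
  mat <- prepare_clustering_matrix(expr)
  labels <- labels[colnames(mat)]
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2 || min(table(labels)) < 2) {
    abort("two groups with at least two samples each are required")
  }
  grp1 <- which(labels == groups[1])
  grp2 <- which(labels == groups[2])
  s0 <- choose_s0(mat, grp1, grp2)
  d_obs <- sam_d_stat(mat, grp1, grp2, s0)

  n <- ncol(mat)
  n1 <- length(grp1)
  d_perm <- with_substream(seed, "sam", {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n, n1)
      abs(sam_d_stat(mat, idx, setdiff(seq_len(n), idx), s0))
    }, numeric(nrow(mat)))
  })

  abs_obs <- abs(d_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  thresholds <- abs_obs[ord]
  perm_sorted <- sort(as.vector(d_perm), decreasing = TRUE)
  # expected exceedances per threshold, averaged over permutations
  exp_exceed <- findInterval(-thresholds, -perm_sorted) / n_perm
  obs_exceed <- seq_along(thresholds)
  fdr <- pmin(exp_exceed / obs_exceed, 1)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(length(d_obs))
  q[ord] <- q_sorted

  tibble(
    gene = rownames(mat), d = d_obs, q = q,
    direction = ifelse(d_obs >= 0, paste0("up_in_", groups[2]),
                       paste0("up_in_", groups[1])),
    significant = q < q_threshold
  ) |>
    arrange(desc(abs(.data$d)))
}

#' Hypergeometric gene-set enrichment of a differential gene list
#'
#' Upper-tail hypergeometric probability of the observed overlap between
#' the differentially expressed genes and each gene set, within the tested
#' background.  Sets disjoint from the background are skipped with a
#' warning.
#'
#' @param de_genes Differentially expressed genes (subset of `background`).
#' @param background All tested genes.
#' @param gene_sets Named list of gene vectors.
#' @param p_threshold Flagging threshold (default 1e-4).
#' @return A tibble with `set`, `n_set`, `n_overlap`, `p`, `enriched`.
#' @export
geneset_enrichment <- function(de_genes, background, gene_sets,
                               p_threshold = 1e-4) {
  if (!all(de_genes %in% background)) {
    abort("de_genes must be a subset of background")
  }
  n_bg <- length(background)
  n_de <- length(de_genes)
  rows <- imap(gene_sets, function(set, name) {
    set_bg <- intersect(set, background)
    if (!length(set_bg)) {
      warn(paste0("gene set '", name, "' is disjoint from the background"))
      return(NULL)
    }
    k <- length(intersect(set_bg, de_genes))
    p <- phyper(k - 1, length(set_bg), n_bg - length(set_bg), n_de,
                lower.tail = FALSE)
    tibble(set = name, n_set = length(set_bg), n_overlap = k, p = p)
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(set = character(), n_set = integer(),
                  n_overlap = integer(), p = numeric(),
                  enriched = logical()))
  }
  mutate(out, enriched = .data$p < p_threshold)
}
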