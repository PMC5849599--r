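#' Upper-quartile normalization of a count matrix
#'
#' Each sample is rescaled so that its 75th percentile of nonzero counts
#' equals the cohort mean of those percentiles, making abundance values
#' comparable across samples.
#'
#' @param expr Raw-count expression tibble.
#' @return The normalized tibble (state `uq_normalized`) with the per-sample
#'   scale factors in the `scale_factors` attribute.
#' @export
normalize_upper_quartile <- function(expr) {
  vals <- expr_to_matrix(expr)
  uq <- apply(vals, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) NA_real_ else quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq)) {
    abort(paste0("sample(s) with all-zero expression: ",
                 toString(colnames(vals)[is.na(uq)])))
  }
  factors <- mean(uq) / uq
  out <- matrix_to_expr(sweep(vals, 2, factors, "*"), "uq_normalized")
  attr(out, "scale_factors") <- setNames(factors, colnames(vals))
  out
}

#' Global expression threshold
#'
#' The median over all gene-by-sample entries of a normalized matrix; used
#' as the reference boundary between low and high expression when scoring
#' marker genes.
#'
#' @param expr Normalized expression tibble.
#' @return A single numeric threshold with the matrix dimensions recorded in
#'   attributes.
#' @export
global_expression_threshold <- function(expr) {
  vals <- expr_to_matrix(expr)
  if (length(vals) == 0) {
    abort("expression matrix is empty")
  }
  out <- median(vals)
  attr(out, "n_genes") <- nrow(vals)
  attr(out, "n_samples") <- ncol(vals)
  out
}

#' Select highly expressed, highly variable clustering genes
#'
#' Computes per-gene `log2(mean)` and `log2(variance)` on the normalized
#' scale and keeps genes at or above both quantile thresholds (quantiles
#' taken over genes with positive mean and variance).
#'
#' @param expr Upper-quartile-normalized expression tibble.
#' @param mean_quantile,var_quantile Quantile thresholds in `[0, 1)`.
#' @return Character vector of selected genes.
#' @export
select_clustering_genes <- function(expr, mean_quantile, var_quantile) {
  stopifnot(mean_quantile >= 0, mean_quantile < 1,
            var_quantile >= 0, var_quantile < 1)
  vals <- expr_to_matrix(expr)
  m <- rowMeans(vals)
  v <- apply(vals, 1, var)
  ok <- m > 0 & v > 0
  lm2 <- log2(m[ok])
  lv2 <- log2(v[ok])
  keep <- lm2 >= quantile(lm2, mean_quantile, names = FALSE) &
    lv2 >= quantile(lv2, var_quantile, names = FALSE)
  genes <- names(which(keep))
  if (!length(genes)) {
    abort("no gene passes the selection; lower the quantile thresholds")
  }
  genes
}

#' Quantile presets for the clustering experiments
#'
#' Named presets pairing the mean-expression and variance quantiles used for
#' gene selection in each comparison of lung tumor subtypes.
#'
#' @return A tibble with `experiment`, `mean_quantile`, `var_quantile`.
#' @export
clustering_presets <- function() {
  tribble(
    ~experiment,        ~mean_quantile, ~var_quantile,
    "all_subtypes",     0.75,           0.90,
    "minus_carcinoids", 0.90,           0.75,
    "lcnec_sclc",       0.90,           0.90,
    "lcnec_adc",        0.925,          0.85,
    "lcnec_sqcc",       0.925,          0.85,
    "lcnec_only",       0.875,          0.975
  )
}

#' Log-transform and median-center an expression matrix by gene
#'
#' `log2(x + 1)` followed by subtraction of each gene's median; the standard
#' preparation before correlation-based clustering.
#'
#' @param expr Normalized expression tibble.
#' @param genes Optional subset of genes to keep.
#' @return A genes x samples numeric matrix (state `median_centered`).
#' @export
prepare_clustering_matrix <- function(expr, genes = NULL) {
  vals <- expr_to_matrix(expr)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(vals))
    if (length(missing_genes)) {
      abort(paste0("gene(s) not in matrix: ",
                   toString(head(missing_genes, 5))))
    }
    vals <- vals[genes, , drop = FALSE]
  }
  lv <- log2(vals + 1)
  lv - apply(lv, 1, median)
}
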