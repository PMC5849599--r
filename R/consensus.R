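cor_distance <- function(mat, method) {
  # samples are columns; distance = 1 - correlation between samples
  d <- 1 - cor(mat, method = method)
  as.dist(d)
}

cluster_once <- function(mat, k, method) {
  if (method == "pam_spearman") {
    cluster::pam(cor_distance(mat, "spearman"), k = k, diss = TRUE,
                 cluster.only = TRUE)
  } else {
    cutree(hclust(cor_distance(mat, "pearson"), method = "average"), k = k)
  }
}

#' Resampling consensus clustering
#'
#' Repeatedly clusters random sample subsets and records how often each pair
#' of samples co-clusters when co-sampled.  The consensus matrix `M` has
#' `M[i, j] = (#co-clustered) / (#co-sampled)`; final class labels come from
#' average-linkage hierarchical clustering of `1 - M`, and the area under
#' the consensus CDF is reported per `k` to guide the choice of class
#' number.
#'
#' @param expr Upper-quartile-normalized expression tibble (log2 transform
#'   and gene median-centering are applied internally).
#' @param genes Clustering genes, e.g. from [select_clustering_genes()].
#' @param k_range Integer vector of class numbers to evaluate.
#' @param n_resamples Resampling iterations per k (default 250).
#' @param subsample_fraction Fraction of samples drawn per iteration
#'   (default 0.8, without replacement).
#' @param method `"pam_spearman"` (partitioning around medoids on a Spearman
#'   correlation distance) or `"hclust_pearson"` (average-linkage
#'   hierarchical clustering on a Pearson correlation distance).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A named list of `consensus_result` objects, one per k, each with
#'   `k`, `labels`, `consensus` (samples x samples), `cdf_area`, `genes`,
#'   `method`.
#' @export
consensus_cluster <- function(expr, genes, k_range = 2:6, n_resamples = 250,
                              subsample_fraction = 0.8,
                              method = c("pam_spearman", "hclust_pearson"),
                              seed = 1L) {
  method <- match.arg(method)
  mat <- prepare_clustering_matrix(expr, genes)
  n <- ncol(mat)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1))
  n_sub <- max(2, floor(subsample_fraction * n))

  results <- with_substream(seed, paste0("consensus-", method), {
    lapply(k_range, function(k) {
      co_clustered <- matrix(0, n, n)
      co_sampled <- matrix(0, n, n)
      for (b in seq_len(n_resamples)) {
        idx <- sort(sample.int(n, n_sub))
        cl <- cluster_once(mat[, idx, drop = FALSE], k, method)
        same <- outer(cl, cl, "==")
        co_clustered[idx, idx] <- co_clustered[idx, idx] + same
        co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      }
      if (any(co_sampled[upper.tri(co_sampled)] == 0)) {
        abort("some sample pairs were never co-sampled; increase n_resamples")
      }
      M <- co_clustered / co_sampled
      diag(M) <- 1
      dimnames(M) <- list(colnames(mat), colnames(mat))
      labels <- cutree(hclust(as.dist(1 - M), method = "average"), k = k)
      upper <- M[upper.tri(M)]
      cdf <- ecdf(upper)
      xs <- sort(unique(upper))
      area <- sum(diff(c(0, xs)) * cdf(xs))
      res <- list(k = k, labels = setNames(labels, colnames(mat)),
                  consensus = M, cdf_area = area, genes = genes,
                  method = method)
      class(res) <- "consensus_result"
      res
    })
  })
  setNames(results, paste0("k", k_range))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering (", x$method, "), k = ", x$k,
      ", CDF area = ", signif(x$cdf_area, 4), "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Merge consensus classes
#'
#' Collapses the listed label groups into single classes (an explicit,
#' logged analyst decision, e.g. when two classes are judged redundant on
#' review) and relabels the classes contiguously.
#'
#' @param result A `consensus_result`.
#' @param merge_spec List of integer vectors; each vector's labels are
#'   unioned into one class.  An empty list is the identity.
#' @return A `consensus_result` with updated `labels`, `k` and a
#'   `merge_history` element.
#' @export
merge_clusters <- function(result, merge_spec = list()) {
  stopifnot(inherits(result, "consensus_result"))
  labels <- result$labels
  unknown <- setdiff(unlist(merge_spec), unique(labels))
  if (length(unknown)) {
    abort(paste0("merge_spec references unknown label(s): ",
                 toString(unknown)))
  }
  for (grp in merge_spec) {
    labels[labels %in% grp] <- min(grp)
  }
  relabeled <- as.integer(factor(labels, levels = sort(unique(labels))))
  out <- result
  out$labels <- setNames(relabeled, names(result$labels))
  out$k <- length(unique(relabeled))
  out$merge_history <- c(result$merge_history, list(merge_spec))
  out
}

#' Simulation test of the separation between two expression classes
#'
#' The cluster index is the within-class sum of squares divided by the total
#' sum of squares of the samples-by-genes matrix.  The null model is a
#' single multivariate Gaussian whose diagonal covariance (in principal
#' components) carries the sample eigenvalue spectrum floored at a
#' background noise variance estimated by the median absolute deviation of
#' the centered data.  Each simulated dataset is split by its best 2-means
#' solution, and the p-value is the fraction of simulated cluster indices at
#' or below the observed one.
#'
#' @param expr Normalized expression tibble.
#' @param labels Named two-class label vector over the samples.
#' @param genes Optional gene subset (the clustering genes).
#' @param n_sim Simulated null datasets (default 1000).
#' @param seed Integer seed.
#' @return A list with `ci_obs` and `p`.
#' @export
test_cluster_significance <- function(expr, labels, genes = NULL,
                                      n_sim = 1000, seed = 1L) {
  mat <- prepare_clustering_matrix(expr, genes)
  labels <- labels[colnames(mat)]
  if (length(unique(labels)) != 2) {
    abort("exactly two classes are required")
  }
  if (min(table(labels)) < 2) {
    abort("each class must contain at least two samples")
  }
  X <- t(mat)                      # samples x genes
  n <- nrow(X)
  d <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  tot_ss <- sum(Xc^2)
  within_ss <- sum(vapply(split(seq_len(n), labels), function(idx) {
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  ci_obs <- within_ss / tot_ss

  sv <- svd(Xc, nu = 0, nv = 0)$d
  ev <- rep(0, d)
  ev[seq_along(sv)] <- sv^2 / (n - 1)
  sigma2 <- mad(Xc)^2
  lambda <- pmax(ev, sigma2)

  ci_sim <- with_substream(seed, "sigclust", {
    vapply(seq_len(n_sim), function(s) {
      Xs <- matrix(rnorm(n * d), n, d) *
        rep(sqrt(lambda), each = n)
      km <- kmeans(Xs, centers = 2, nstart = 3)
      km$tot.withinss / km$totss
    }, numeric(1))
  })
  list(ci_obs = ci_obs, p = mean(ci_sim <= ci_obs))
}
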