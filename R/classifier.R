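#' Train an active-set nearest-centroid subtype classifier
#'
#' For each gene and class a t-like score
#' `(class mean - overall mean) / (pooled within-class SD + s0)` is
#' computed on the log2 median-centered scale.  Each class receives its top
#' `genes_per_class` genes by absolute score, with every gene assigned to at
#' most one class (greedy by descending absolute score).  Class centroids
#' are the mean standardized expression of the class over the union of
#' classifier genes; prediction is by nearest centroid in Euclidean
#' distance.
#'
#' @param expr Normalized expression tibble.
#' @param labels Named class labels over the samples.
#' @param genes_per_class Number of classifier genes per class.
#' @param s0 Exchangeability constant added to the pooled SD; default the
#'   median pooled SD.
#' @return A `centroid_classifier` with `genes` (per-class active sets),
#'   `centroids`, standardization parameters and the training `scores`.
#' @export
train_centroid_classifier <- function(expr, labels, genes_per_class = 10,
                                      s0 = NULL) {
  mat <- prepare_clustering_matrix(expr)
  labels <- labels[colnames(mat)]
  classes <- sort(unique(as.character(labels)))
  k <- length(classes)
  stopifnot(genes_per_class >= 1)
  if (genes_per_class * k > nrow(mat)) {
    abort("genes_per_class x k exceeds the number of genes")
  }
  n <- ncol(mat)
  overall <- rowMeans(mat)
  class_means <- vapply(classes, function(cl) {
    rowMeans(mat[, labels == cl, drop = FALSE])
  }, numeric(nrow(mat)))
  if (k > 1 && n > k) {
    ss_within <- Reduce(`+`, lapply(classes, function(cl) {
      sub <- mat[, labels == cl, drop = FALSE]
      rowSums((sub - rowMeans(sub))^2)
    }))
    pooled_sd <- sqrt(ss_within / (n - k))
  } else {
    pooled_sd <- apply(mat, 1, sd)
  }
  s0 <- s0 %||% median(pooled_sd)
  scores <- (class_means - overall) / (pooled_sd + s0)

  score_tbl <- tibble(
    gene = rep(rownames(mat), k),
    class = rep(classes, each = nrow(mat)),
    score = as.vector(scores)
  ) |>
    arrange(desc(abs(.data$score)))
  active <- setNames(vector("list", k), classes)
  taken <- character(0)
  counts <- setNames(integer(k), classes)
  for (i in seq_len(nrow(score_tbl))) {
    g <- score_tbl$gene[i]
    cl <- score_tbl$class[i]
    if (g %in% taken || counts[cl] >= genes_per_class) next
    active[[cl]] <- c(active[[cl]], g)
    taken <- c(taken, g)
    counts[cl] <- counts[cl] + 1L
    if (all(counts >= genes_per_class)) break
  }
  classifier_genes <- unlist(active, use.names = FALSE)
  z <- (mat[classifier_genes, , drop = FALSE] - overall[classifier_genes]) /
    (pooled_sd[classifier_genes] + s0)
  centroids <- vapply(classes, function(cl) {
    rowMeans(z[, labels == cl, drop = FALSE])
  }, numeric(length(classifier_genes)))
  out <- list(
    genes = active, classes = classes, centroids = centroids,
    center = overall[classifier_genes],
    scale = pooled_sd[classifier_genes] + s0,
    s0 = s0, scores = scores
  )
  class(out) <- "centroid_classifier"
  out
}

#' @export
print.centroid_classifier <- function(x, ...) {
  cat("Nearest-centroid classifier:", length(x$classes), "classes,",
      length(unlist(x$genes)), "classifier genes\n")
  invisible(x)
}

#' Predict classes with a trained centroid classifier
#'
#' @param object A `centroid_classifier`.
#' @param expr Normalized expression tibble containing the classifier genes.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `class` and the distance to each
#'   centroid.
#' @export
predict.centroid_classifier <- function(object, expr, ...) {
  mat <- prepare_clustering_matrix(expr)
  genes <- unlist(object$genes, use.names = FALSE)
  missing_genes <- setdiff(genes, rownames(mat))
  if (length(missing_genes)) {
    abort(paste0("classifier gene(s) missing from matrix: ",
                 toString(head(missing_genes, 5))))
  }
  z <- (mat[genes, , drop = FALSE] - object$center) / object$scale
  d <- vapply(seq_along(object$classes), function(j) {
    colSums((z - object$centroids[, j])^2)
  }, numeric(ncol(z)))
  d <- matrix(d, ncol = length(object$classes),
              dimnames = list(colnames(z), object$classes))
  tibble(
    sample_id = colnames(z),
    class = object$classes[max.col(-d, ties.method = "first")]
  ) |>
    bind_cols(as_tibble(d))
}

#' Correlation of each sample with its own class centroid
#'
#' Pearson correlation of a sample's standardized classifier-gene vector
#' with the centroid of the class it was assigned to; a consistency measure
#' for cluster memberships.
#'
#' @param expr Normalized expression tibble.
#' @param classifier A `centroid_classifier`.
#' @param labels Named class labels consistent with the classifier classes.
#' @return A tibble with `sample_id`, `class`, `correlation` (NA with a
#'   warning for zero-variance samples).
#' @export
centroid_correlation <- function(expr, classifier, labels) {
  mat <- prepare_clustering_matrix(expr)
  genes <- unlist(classifier$genes, use.names = FALSE)
  labels <- labels[colnames(mat)]
  bad <- setdiff(unique(as.character(labels)), classifier$classes)
  if (length(bad)) {
    abort(paste0("label(s) not among classifier classes: ", toString(bad)))
  }
  z <- (mat[genes, , drop = FALSE] - classifier$center) / classifier$scale
  r <- vapply(seq_len(ncol(z)), function(j) {
    v <- z[, j]
    if (sd(v) == 0) {
      return(NA_real_)
    }
    cor(v, classifier$centroids[, as.character(labels[j])])
  }, numeric(1))
  if (anyNA(r)) {
    warn("zero-variance sample vector(s): correlation set to NA")
  }
  tibble(sample_id = colnames(z), class = as.character(labels),
         correlation = r)
}
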