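#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a purity/ploidy fit
#'
#' @param x A `purity_ploidy_fit`.
#' @param ... Unused.
#' @return One row per segment with the fitted absolute copy number.
#' @export
tidy.purity_ploidy_fit <- function(x, ...) {
  as_tibble(x$segments)
}

#' @rdname tidy.purity_ploidy_fit
#' @export
glance.purity_ploidy_fit <- function(x, ...) {
  tibble(sample_id = x$sample_id, purity = x$purity, ploidy = x$ploidy,
         score = x$score, n_segments = nrow(x$segments))
}

#' Tidy a signature set
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return Long tibble of signature weights per channel.
#' @export
tidy.signature_set <- function(x, ...) {
  as_tibble(x$W, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "signature",
                        values_to = "weight")
}

#' @rdname tidy.signature_set
#' @export
glance.signature_set <- function(x, ...) {
  tibble(k = x$k, kl = x$kl,
         min_reproducibility = min(x$reproducibility),
         mean_reproducibility = mean(x$reproducibility))
}

#' Tidy a consensus clustering result
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return One row per sample with its class label.
#' @export
tidy.consensus_result <- function(x, ...) {
  tibble(sample_id = names(x$labels), class = unname(x$labels))
}

#' @rdname tidy.consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(k = x$k, cdf_area = x$cdf_area, n_genes = length(x$genes),
         method = x$method)
}

#' Tidy a centroid classifier
#'
#' @param x A `centroid_classifier`.
#' @param ... Unused.
#' @return One row per classifier gene with its class and selection score.
#' @export
tidy.centroid_classifier <- function(x, ...) {
  list_rbind(imap(x$genes, function(genes, cl) {
    tibble(class = cl, gene = genes,
           score = x$scores[genes, cl])
  }))
}
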