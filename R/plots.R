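#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_boxplot
#'   geom_jitter geom_hline facet_wrap labs scale_fill_gradient theme_minimal
#'   element_text theme
#' @export
ggplot2::autoplot

#' Heatmap of a consensus matrix
#'
#' Samples ordered by the final class labels; blocks of high co-clustering
#' frequency along the diagonal indicate stable classes.
#'
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_result <- function(object, ...) {
  ord <- names(sort(object$labels))
  df <- as_tibble(object$consensus, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "consensus") |>
    mutate(sample_a = factor(.data$sample_a, levels = ord),
           sample_b = factor(.data$sample_b, levels = ord))
  ggplot(df, aes(.data$sample_a, .data$sample_b,
                 fill = .data$consensus)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#08306b", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Consensus",
         title = paste0("Consensus matrix (k = ", object$k, ")")) +
    theme_minimal() +
    theme(axis.text = element_text(size = 4))
}

#' Barplot of signature profiles over the 96 channels
#'
#' @param object A `signature_set`.
#' @param ... Unused.
#' @return A ggplot object faceted by signature.
#' @export
autoplot.signature_set <- function(object, ...) {
  df <- tidy(object) |>
    mutate(substitution = stringr::str_sub(.data$channel, 3, 5),
           channel = factor(.data$channel, levels = signature_channels()))
  ggplot(df, aes(.data$channel, .data$weight, fill = .data$substitution)) +
    geom_col() +
    facet_wrap(~signature, ncol = 1) +
    labs(x = NULL, y = "Channel weight", fill = "Substitution") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, size = 3))
}

#' Per-sample cancer-cell-fraction distributions
#'
#' Box-and-whisker view of the CCF estimates per sample, with clonality
#' calls overlaid; the layout matches the usual clonal-architecture panels
#' of tumor-sequencing studies.
#'
#' @param estimates A `ccf_estimate` tibble (one or more samples).
#' @return A ggplot object.
#' @export
plot_ccf_distribution <- function(estimates) {
  ggplot(estimates, aes(.data$sample_id, .data$ccf)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(aes(colour = .data$status), width = 0.15, size = 0.6,
                alpha = 0.6) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = NULL, y = "Cancer cell fraction", colour = "Call") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90))
}

#' Marker expression against the global threshold
#'
#' @param expr Normalized expression tibble.
#' @param threshold Global expression threshold.
#' @param markers Marker genes to display.
#' @return A ggplot object, one panel per marker, log2 scale, with the
#'   low/high threshold dashed.
#' @export
plot_marker_expression <- function(expr, threshold,
                                   markers = c("ASCL1", "DLL3", "CHGA",
                                               "SYP", "NCAM1", "NOTCH1",
                                               "NOTCH2", "HES1", "REST")) {
  vals <- expr_to_matrix(expr)
  markers <- intersect(markers, rownames(vals))
  df <- as_tibble(vals[markers, , drop = FALSE], rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id",
                        values_to = "expression")
  ggplot(df, aes(.data$gene, log2(.data$expression + 1))) +
    geom_boxplot(outlier.size = 0.4) +
    geom_hline(yintercept = log2(as.numeric(threshold) + 1),
               linetype = "dashed") +
    labs(x = NULL, y = "log2(expression + 1)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
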