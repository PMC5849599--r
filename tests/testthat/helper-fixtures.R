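# shared fixtures, all generated in code

as_expr <- function(mat, state = "uq_normalized") {
  out <- dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                          tibble::as_tibble(mat))
  attr(out, "expr_state") <- state
  out
}

# a log-normal expression matrix with optional class structure planted on
# the log2 scale
make_expr_matrix <- function(n_genes, n_samples, classes = NULL,
                             markers_per_class = 0, effect = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
                dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                sprintf("S%03d", seq_len(n_samples))))
    if (!is.null(classes)) {
      cls <- sort(unique(classes))
      for (j in seq_along(cls)) {
        rows <- ((j - 1) * markers_per_class + 1):(j * markers_per_class)
        m[rows, classes == cls[j]] <- m[rows, classes == cls[j]] + effect
      }
    }
    2^m
  })
}

tiny_mutations <- function() {
  tibble::tibble(
    sample_id = c("T1", "T1", "T2"),
    gene = c("TP53", "RB1", "TP53"),
    chrom = "1",
    pos = c(100L, 2000L, 150L),
    ref_allele = c("C", "G", "T"),
    alt_allele = c("A", "T", "G"),
    context5 = c("A", "T", "C"),
    context3 = c("A", "T", "G"),
    consequence = c("missense", "nonsense", "synonymous"),
    alt_count = c(10L, 20L, 5L),
    depth = c(40L, 60L, 50L)
  )
}

small_cohort <- function(seed = 5, n = 12, ...) {
  simulate_cohort(simulation_config(seed = seed, n_samples = n, ...))
}
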