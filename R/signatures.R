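#' The 96 trinucleotide substitution channels
#'
#' Single-base substitutions are collapsed to the pyrimidine-reference
#' convention (reference base C or T), giving six substitution types, each in
#' 16 flanking-base contexts.  The order is fixed: substitution-major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base, each in
#' A, C, G, T order, with labels like `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
signature_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }))
}

#' Build a 96-channel mutation catalog from SNVs
#'
#' Counts each single-nucleotide variant into one of the 96 trinucleotide
#' channels.  Purine-reference variants are reverse-complemented (variant and
#' both flanking bases) onto the pyrimidine reference.  Non-SNV records and
#' records with missing or non-ACGT context are skipped with a warning.
#'
#' @param mutations Mutation tibble with `ref_allele`, `alt_allele`,
#'   `context5`, `context3`, `sample_id`.
#' @param samples Optional sample order for the catalog columns; defaults to
#'   order of appearance.
#' @return A `mutation_catalog` tibble: `channel` column (96 rows, canonical
#'   order) plus one integer column per sample.
#' @export
build_catalog <- function(mutations, samples = NULL) {
  snv <- mutations |>
    filter(nchar(.data$ref_allele) == 1, nchar(.data$alt_allele) == 1,
           .data$ref_allele %in% c("A", "C", "G", "T"),
           .data$alt_allele %in% c("A", "C", "G", "T"))
  ctx_ok <- !is.na(snv$context5) & !is.na(snv$context3) &
    snv$context5 %in% c("A", "C", "G", "T") &
    snv$context3 %in% c("A", "C", "G", "T")
  n_skipped <- nrow(mutations) - sum(ctx_ok)
  if (n_skipped > 0) {
    warn(paste0(n_skipped,
                " record(s) skipped (non-SNV or invalid context)"))
  }
  snv <- snv[ctx_ok, ]
  purine <- snv$ref_allele %in% c("A", "G")
  ref <- ifelse(purine, chartr("ACGT", "TGCA", snv$ref_allele), snv$ref_allele)
  alt <- ifelse(purine, chartr("ACGT", "TGCA", snv$alt_allele), snv$alt_allele)
  p5 <- ifelse(purine, chartr("ACGT", "TGCA", snv$context3), snv$context5)
  p3 <- ifelse(purine, chartr("ACGT", "TGCA", snv$context5), snv$context3)
  channel <- paste0(p5, "[", ref, ">", alt, "]", p3)
  samples <- samples %||% unique(snv$sample_id)
  channels <- signature_channels()
  counts <- vapply(samples, function(s) {
    tabulate(factor(channel[snv$sample_id == s], levels = channels),
             nbins = 96L)
  }, integer(96))
  counts <- matrix(counts, nrow = 96,
                   dimnames = list(channels, samples))
  out <- bind_cols(tibble(channel = channels), as_tibble(counts))
  class(out) <- c("mutation_catalog", class(out))
  out
}

#' Drop catalog samples with too few variants
#'
#' Cases contribute reliably to signature extraction only with a minimal
#' mutation load; samples below `min_variants` total SNVs are removed.
#'
#' @param catalog A `mutation_catalog`.
#' @param min_variants Minimum per-sample variant count (default 30).
#' @return The filtered catalog; dropped samples are reported in the
#'   `dropped_samples` attribute.
#' @export
filter_catalog <- function(catalog, min_variants = 30) {
  m <- catalog_to_matrix(catalog)
  keep <- colSums(m) >= min_variants
  if (!any(keep)) {
    abort("no sample reaches the minimum variant count")
  }
  out <- matrix_to_catalog(m[, keep, drop = FALSE])
  attr(out, "dropped_samples") <- colnames(m)[!keep]
  out
}

#' Scan factorization ranks
#'
#' Runs [extract_signatures()] over a range of candidate ranks and reports
#' the reproducibility and reconstruction error of each, leaving the
#' choice of k to the analyst.
#'
#' @param catalog A `mutation_catalog`.
#' @param k_range Candidate ranks.
#' @inheritParams extract_signatures
#' @return A tibble with one row per k: `k`, `kl`, `min_reproducibility`,
#'   `mean_reproducibility`.
#' @export
scan_signature_k <- function(catalog, k_range = 2:5, n_restarts = 20,
                             max_iter = 10000, tol = 1e-8, seed = 1L) {
  list_rbind(lapply(k_range, function(k) {
    s <- extract_signatures(catalog, k = k, n_restarts = n_restarts,
                            max_iter = max_iter, tol = tol,
                            seed = derive_seed(seed, paste0("k", k)))
    tibble(k = k, kl = s$kl,
           min_reproducibility = min(s$reproducibility),
           mean_reproducibility = mean(s$reproducibility))
  }))
}

catalog_to_matrix <- function(catalog) {
  stopifnot(identical(catalog$channel, signature_channels()))
  m <- as.matrix(catalog[, setdiff(names(catalog), "channel")])
  storage.mode(m) <- "double"
  rownames(m) <- catalog$channel
  m
}

matrix_to_catalog <- function(m) {
  out <- bind_cols(tibble(channel = rownames(m)), as_tibble(m))
  class(out) <- c("mutation_catalog", class(out))
  out
}

# generalized Kullback-Leibler divergence D(V || WH)
kl_divergence <- function(V, WH) {
  eps <- 1e-12
  sum(ifelse(V > 0, V * log(V / pmax(WH, eps)), 0) - V + WH)
}

# one KL-NMF run from a random initialization (Lee-Seung multiplicative
# updates); returns column-stochastic W, rescaled H and the KL trace
nmf_kl_run <- function(V, k, max_iter, tol) {
  eps <- 1e-12
  n <- ncol(V)
  p <- nrow(V)
  scale0 <- mean(V)
  W <- matrix(runif(p * k, 0.5, 1.5) * scale0, p, k)
  H <- matrix(runif(k * n, 0.5, 1.5), k, n)
  WH <- W %*% H
  kl <- kl_divergence(V, WH)
  trace <- numeric(max_iter + 1)
  trace[1] <- kl
  iters <- 0L
  for (it in seq_len(max_iter)) {
    R <- V / pmax(WH, eps)
    H <- H * (crossprod(W, R) / pmax(colSums(W), eps))
    WH <- W %*% H
    R <- V / pmax(WH, eps)
    W <- W * (R %*% t(H)) / rep(pmax(rowSums(H), eps), each = p)
    WH <- W %*% H
    kl_new <- kl_divergence(V, WH)
    trace[it + 1] <- kl_new
    iters <- it
    if (is.finite(kl) && abs(kl - kl_new) <= tol * max(abs(kl), 1)) {
      kl <- kl_new
      break
    }
    kl <- kl_new
  }
  csum <- pmax(colSums(W), eps)
  W <- sweep(W, 2, csum, "/")
  H <- H * csum
  list(W = W, H = H, kl = kl, trace = trace[seq_len(iters + 1)])
}

#' Extract mutational signatures by KL non-negative matrix factorization
#'
#' Factorizes a 96-channel catalog `V ~ W H` with `W >= 0` column-stochastic
#' (signatures) and `H >= 0` (exposures), minimizing the generalized
#' Kullback-Leibler divergence with multiplicative updates.  The
#' factorization is repeated from `n_restarts` random initializations; the
#' pooled signature vectors are clustered by cosine similarity into `k`
#' consensus signatures (cluster medoids) and exposures are refit against the
#' consensus signatures.  The per-signature reproducibility score is the mean
#' cosine similarity of clustered restart solutions to their medoid.
#'
#' @param catalog A `mutation_catalog` tibble from [build_catalog()] or
#'   [simulate_catalogs()].
#' @param k Number of signatures (`1 <= k <= min(96, n_samples)`).
#' @param n_restarts Number of random initializations (default 50).
#' @param max_iter Maximum multiplicative updates per run (default 10000).
#' @param tol Relative KL change declaring convergence (default 1e-8).
#' @param seed Integer seed; identical seeds give identical results.
#' @return A `signature_set` list with elements `W` (96 x k), `H`
#'   (k x samples), `k`, `reproducibility`, `kl`, `kl_traces`.
#' @export
extract_signatures <- function(catalog, k, n_restarts = 50, max_iter = 10000,
                               tol = 1e-8, seed = 1L) {
  V <- catalog_to_matrix(catalog)
  if (all(V == 0)) {
    abort("catalog is all zero; nothing to factorize")
  }
  if (k < 1 || k > min(96, ncol(V))) {
    abort("k must lie in [1, min(96, n_samples)]")
  }
  runs <- with_substream(seed, "nmf", {
    lapply(seq_len(n_restarts), function(i) {
      nmf_kl_run(V, k, max_iter, tol)
    })
  })
  sigs <- do.call(cbind, lapply(runs, `[[`, "W"))
  if (k == 1 || n_restarts == 1) {
    cl <- rep(seq_len(k), n_restarts)
  } else {
    cs <- crossprod(sigs) /
      tcrossprod(sqrt(colSums(sigs^2)))
    cl <- cluster::pam(as.dist(pmax(1 - cs, 0)), k = k,
                       diss = TRUE, cluster.only = TRUE)
  }
  W <- matrix(0, nrow(V), k, dimnames = list(rownames(V), NULL))
  reproducibility <- numeric(k)
  for (j in seq_len(k)) {
    members <- sigs[, cl == j, drop = FALSE]
    # medoid: member with the highest mean cosine to the others
    cs_m <- crossprod(members) / tcrossprod(sqrt(colSums(members^2)))
    medoid <- which.max(colMeans(cs_m))
    W[, j] <- members[, medoid]
    reproducibility[j] <- mean(cs_m[, medoid])
  }
  colnames(W) <- paste0("signature_", seq_len(k))
  H <- refit_exposures(V, W, max_iter = max_iter, tol = tol)
  rownames(H) <- colnames(W)
  res <- list(
    W = W, H = H, k = k, reproducibility = reproducibility,
    kl = kl_divergence(V, W %*% H),
    kl_traces = lapply(runs, `[[`, "trace")
  )
  class(res) <- "signature_set"
  res
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Mutational signature set: k =", x$k,
      "| final KL divergence =", signif(x$kl, 5), "\n")
  cat("Reproducibility:", paste(signif(x$reproducibility, 4),
                                collapse = ", "), "\n")
  invisible(x)
}

refit_exposures <- function(V, W, max_iter = 10000, tol = 1e-10) {
  eps <- 1e-12
  k <- ncol(W)
  H <- matrix(rep(colSums(V) / k, each = k), k, ncol(V))
  kl <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    H <- H * (crossprod(W, V / pmax(WH, eps)) / pmax(colSums(W), eps))
    kl_new <- kl_divergence(V, W %*% H)
    if (is.finite(kl) && abs(kl - kl_new) <= tol * max(abs(kl), 1)) break
    kl <- kl_new
  }
  H[, colSums(V) == 0] <- 0
  H
}

#' Refit exposures against a fixed signature matrix
#'
#' Multiplicative KL updates on the exposure matrix only, with the signature
#' matrix frozen.  With column-stochastic signatures the per-sample
#' reconstruction totals match the catalog totals at convergence.
#'
#' @param catalog A `mutation_catalog`.
#' @param fixed_W Column-stochastic 96 x k signature matrix (channels in
#'   canonical order).
#' @return A k x samples exposure matrix.
#' @export
estimate_exposures <- function(catalog, fixed_W) {
  V <- catalog_to_matrix(catalog)
  if (nrow(fixed_W) != 96) {
    abort("fixed_W must have 96 channel rows")
  }
  if (!is.null(rownames(fixed_W)) &&
      !identical(rownames(fixed_W), signature_channels())) {
    abort("fixed_W channels do not match the canonical channel order")
  }
  H <- refit_exposures(V, fixed_W)
  dimnames(H) <- list(colnames(fixed_W) %||%
                        paste0("signature_", seq_len(ncol(fixed_W))),
                      colnames(V))
  H
}
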