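#' Expected allelic fraction of a clonal mutation
#'
#' For a mutation present in every tumor cell at multiplicity `m` on a locus
#' of total tumor copy number `c_t`, in a specimen of purity `rho` with
#' diploid contaminating normal cells, the expected fraction of mutant reads
#' is `m * rho / (c_t * rho + 2 * (1 - rho))`.
#'
#' @param rho Tumor purity in (0, 1].
#' @param c_t Local total copy number in the tumor (>= 1).
#' @param m Mutation multiplicity, integer in `[1, c_t]`.
#' @return Expected allelic fraction.
#' @export
#' @examples
#' expected_allele_fraction(1, 2, 1)    # 0.5
#' expected_allele_fraction(0.5, 2, 1)  # 0.25
expected_allele_fraction <- function(rho, c_t, m) {
  if (any(rho <= 0 | rho > 1)) {
    abort("purity must lie in (0, 1]")
  }
  if (any(c_t < 1)) {
    abort("local copy number must be >= 1")
  }
  if (any(m < 1) || any(m > c_t)) {
    abort("multiplicity must lie in [1, c_t]")
  }
  m * rho / (c_t * rho + 2 * (1 - rho))
}

#' Fit tumor purity, ploidy and absolute copy numbers
#'
#' Grid search over purity and ploidy.  For each candidate `(rho, psi)` the
#' implied real-valued copy number of segment `i` is
#' `c_i = (ratio_i * (rho * psi + 2 * (1 - rho)) - 2 * (1 - rho)) / rho`; the
#' fit score is the segment-length-weighted mean squared distance of `c_i`
#' to the nearest non-negative integer.  Solutions related by integer
#' copy-number shifts can score identically, so near-ties (within a factor
#' of two of the best score) are resolved toward the lowest-ploidy solution
#' mode, then the highest purity.
#'
#' @param segments Segment tibble for one sample (linear-scale `ratio`).
#' @param purity_grid,ploidy_grid Candidate grids.
#' @param min_seg_length Segments shorter than this are ignored.
#' @return A `purity_ploidy_fit` list: `sample_id`, `purity`, `ploidy`,
#'   `score`, and `segments` (input plus integer `abs_cn`).
#' @export
fit_purity_ploidy <- function(segments,
                              purity_grid = seq(0.10, 1.00, by = 0.01),
                              ploidy_grid = seq(1.5, 5.5, by = 0.05),
                              min_seg_length = 1e4) {
  stopifnot(nrow(segments) >= 1)
  if (length(unique(segments$sample_id)) > 1) {
    abort("fit_purity_ploidy() expects segments from a single sample")
  }
  len <- segments$end - segments$start + 1
  use <- len >= min_seg_length & is.finite(segments$ratio)
  if (!any(use)) {
    abort("insufficient segment support: all segments below minimum length")
  }
  r <- segments$ratio[use]
  w <- len[use] / sum(len[use])

  score_at <- function(rho, psi) {
    d2 <- 2 * (1 - rho)
    c_real <- (r * (rho * psi + d2) - d2) / rho
    c_int <- pmax(round(c_real), 0)
    sum(w * (c_real - c_int)^2)
  }
  grid <- tidyr::expand_grid(rho = purity_grid, psi = ploidy_grid)
  score <- vapply(seq_len(nrow(grid)), function(i) {
    score_at(grid$rho[i], grid$psi[i])
  }, numeric(1))
  pick <- which.min(score)
  rho <- grid$rho[pick]
  psi <- grid$psi[pick]
  best <- score[pick]

  # Solutions whose implied copy numbers are an integer affine image
  # c' = a * c + m of the argmin's score identically on noiseless data;
  # enumerate that family and prefer its lowest-ploidy feasible member.
  twins <- tidyr::expand_grid(a = c(0.5, 1, 2), m = -3:3) |>
    mutate(
      inv_rho = 1 - .data$a + .data$a / rho - .data$m / 2,
      rho_t = 1 / .data$inv_rho,
      psi_t = .data$a * psi + .data$m
    ) |>
    filter(.data$inv_rho >= 1, .data$rho_t >= min(purity_grid) - 1e-9,
           .data$rho_t <= max(purity_grid) + 1e-9,
           .data$psi_t >= min(ploidy_grid) - 1e-9,
           .data$psi_t <= max(ploidy_grid) + 1e-9)
  twins$score <- vapply(seq_len(nrow(twins)), function(i) {
    score_at(twins$rho_t[i], twins$psi_t[i])
  }, numeric(1))
  ok <- twins$score <= 1.5 * best + 1e-12
  if (any(ok)) {
    cand <- twins[ok, ]
    sel <- order(cand$psi_t, -cand$rho_t)[1]
    rho <- cand$rho_t[sel]
    psi <- cand$psi_t[sel]
    best <- cand$score[sel]
  }
  d2 <- 2 * (1 - rho)
  c_real <- (segments$ratio * (rho * psi + d2) - d2) / rho
  out_segments <- mutate(segments,
                         abs_cn = pmax(as.integer(round(c_real)), 0L))
  fit <- list(sample_id = segments$sample_id[1], purity = rho, ploidy = psi,
              score = best, segments = out_segments)
  class(fit) <- "purity_ploidy_fit"
  fit
}

#' @export
print.purity_ploidy_fit <- function(x, ...) {
  cat("Purity/ploidy fit for", x$sample_id, "- purity", x$purity,
      "ploidy", x$ploidy, "(score", signif(x$score, 4), ")\n")
  invisible(x)
}

#' Posterior clonality classification of one mutation
#'
#' Places a uniform prior on a cancer-cell-fraction grid (0.01 to 1.00 in
#' steps of 0.01) and scores each CCF with the binomial likelihood
#' `Binom(alt_count; depth, CCF * AF_exp)`.  `p_clonal` is the posterior
#' mass on CCF >= 0.90; the call is `clonal` above 0.90, `subclonal` below
#' 0.10, otherwise `ambiguous`.
#'
#' @param alt_count,depth Mutant read count and total depth.
#' @param af_exp Expected allelic fraction of a clonal mutation (> 0).
#' @return A tibble with `p_clonal` and `status`.
#' @export
classify_clonality <- function(alt_count, depth, af_exp) {
  if (any(af_exp <= 0)) {
    abort("expected allelic fraction must be positive")
  }
  stopifnot(all(depth > 0), all(alt_count >= 0), all(alt_count <= depth))
  grid <- seq(0.01, 1, by = 0.01)
  p_clonal <- vapply(seq_along(alt_count), function(i) {
    lik <- dbinom(alt_count[i], depth[i], pmin(grid * af_exp[i], 1))
    if (sum(lik) == 0) {
      return(NA_real_)
    }
    post <- lik / sum(lik)
    sum(post[grid >= 0.90])
  }, numeric(1))
  status <- dplyr::case_when(
    is.na(p_clonal) ~ "ambiguous",
    p_clonal > 0.90 ~ "clonal",
    p_clonal < 0.10 ~ "subclonal",
    TRUE ~ "ambiguous"
  )
  tibble(p_clonal = p_clonal, status = status)
}

#' Mixture-model clonality classification for one sample
#'
#' Classifies all mutations of a sample jointly, using the sample's overall
#' CCF distribution: each mutation is modeled as coming from a clonal
#' component (point mass at CCF 1) or a subclonal component (CCF uniform on
#' (0, 1)), with the binomial read-count likelihood and a per-sample mixing
#' weight estimated by expectation-maximization.  `p_clonal` is the
#' posterior probability of the clonal component; calls use the same > 90%
#' probability bands as [classify_clonality()].
#'
#' @param alt_count,depth,af_exp Per-mutation vectors (one sample).
#' @param max_iter,tol EM controls.
#' @return A tibble with `p_clonal` and `status`.
#' @export
classify_clonality_mixture <- function(alt_count, depth, af_exp,
                                       max_iter = 100, tol = 1e-8) {
  if (any(af_exp <= 0)) {
    abort("expected allelic fraction must be positive")
  }
  stopifnot(all(depth > 0), all(alt_count >= 0), all(alt_count <= depth))
  n <- length(alt_count)
  if (n == 0) {
    return(tibble(p_clonal = numeric(), status = character()))
  }
  grid <- seq(0.005, 0.995, by = 0.01)
  lik_clonal <- dbinom(alt_count, depth, pmin(af_exp, 1))
  lik_sub <- vapply(seq_len(n), function(i) {
    mean(dbinom(alt_count[i], depth[i], pmin(grid * af_exp[i], 1)))
  }, numeric(1))
  pi_clonal <- 0.9
  for (it in seq_len(max_iter)) {
    num <- pi_clonal * lik_clonal
    den <- num + (1 - pi_clonal) * lik_sub
    post <- ifelse(den > 0, num / den, NA_real_)
    pi_new <- mean(post, na.rm = TRUE)
    if (abs(pi_new - pi_clonal) < tol) break
    pi_clonal <- min(max(pi_new, 1e-3), 1 - 1e-3)
  }
  status <- dplyr::case_when(
    is.na(post) ~ "ambiguous",
    post > 0.90 ~ "clonal",
    post < 0.10 ~ "subclonal",
    TRUE ~ "ambiguous"
  )
  tibble(p_clonal = post, status = status)
}

#' Cancer cell fractions for the mutations of one sample
#'
#' Maps each mutation onto the fitted copy-number segment covering it,
#' selects the multiplicity `m` in `[1, max(1, c_t)]` whose expected clonal
#' allelic fraction is closest to the observed fraction, and reports
#' `CCF = AF_obs / AF_exp(m)`.  Estimates above `ccf_max` are capped and
#' flagged.  Mutations on uncovered or homozygously deleted loci are skipped
#' with a warning.
#'
#' @param mutations Mutation tibble for one sample.
#' @param fit A [fit_purity_ploidy()] result for the same sample.
#' @param ccf_max Cap applied to the point estimate (default 1.5).
#' @param method Clonality call: `"mixture"` (default, sample-level
#'   [classify_clonality_mixture()]) or `"grid"` (per-mutation
#'   [classify_clonality()]).
#' @return A `ccf_estimate` tibble: mutation coordinates plus `c_t`,
#'   `multiplicity`, `af_obs`, `af_exp`, `ccf`, `capped`, `p_clonal`,
#'   `status`.
#' @export
compute_ccf <- function(mutations, fit, ccf_max = 1.5,
                        method = c("mixture", "grid")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "purity_ploidy_fit"), all(mutations$depth > 0))
  segs <- fit$segments |> arrange(.data$chrom, .data$start)
  rho <- fit$purity

  per_chrom <- split(seq_len(nrow(mutations)), mutations$chrom)
  c_t <- rep(NA_integer_, nrow(mutations))
  for (chr in names(per_chrom)) {
    idx <- per_chrom[[chr]]
    s <- segs[segs$chrom == chr, ]
    if (!nrow(s)) next
    si <- findInterval(mutations$pos[idx], s$start)
    hit <- si >= 1 & mutations$pos[idx] <= s$end[pmax(si, 1)]
    c_t[idx[hit]] <- s$abs_cn[si[hit]]
  }
  usable <- !is.na(c_t) & c_t >= 1
  n_skip <- sum(!usable)
  if (n_skip > 0) {
    warn(paste0(n_skip, " mutation(s) skipped: no overlapping segment with ",
                "copy number >= 1"))
  }
  mut <- mutations[usable, ]
  c_t <- c_t[usable]
  af_obs <- mut$alt_count / mut$depth
  m_best <- vapply(seq_len(nrow(mut)), function(i) {
    mm <- seq_len(max(1L, c_t[i]))
    af <- expected_allele_fraction(rho, max(1L, c_t[i]), mm)
    mm[which.min(abs(af_obs[i] - af))]
  }, integer(1))
  af_exp <- expected_allele_fraction(rho, pmax(c_t, 1L), m_best)
  ccf_raw <- af_obs / af_exp
  capped <- ccf_raw > ccf_max
  cls <- if (method == "mixture") {
    classify_clonality_mixture(mut$alt_count, mut$depth, af_exp)
  } else {
    classify_clonality(mut$alt_count, mut$depth, af_exp)
  }
  out <- bind_cols(
    mut |> select(any_of(c("sample_id", "gene", "chrom", "pos",
                           "consequence", "alt_count", "depth"))),
    tibble(c_t = c_t, multiplicity = m_best, af_obs = af_obs,
           af_exp = af_exp, ccf = pmin(ccf_raw, ccf_max), capped = capped),
    cls
  )
  class(out) <- c("ccf_estimate", class(out))
  out
}

#' Per-sample subclonal mutation fraction
#'
#' Fraction of classified (non-ambiguous) mutations called subclonal.
#'
#' @param estimates A `ccf_estimate` tibble (one or more samples).
#' @return A tibble with `sample_id`, `n_clonal`, `n_subclonal`,
#'   `subclonal_fraction` (NA when no mutation is classified).
#' @export
subclonal_fraction <- function(estimates) {
  estimates |>
    group_by(.data$sample_id) |>
    summarise(
      n_clonal = sum(.data$status == "clonal"),
      n_subclonal = sum(.data$status == "subclonal"),
      subclonal_fraction = ifelse(
        .data$n_clonal + .data$n_subclonal == 0, NA_real_,
        .data$n_subclonal / (.data$n_clonal + .data$n_subclonal)
      ),
      .groups = "drop"
    )
}

#' Test a sample for significant subclonal enrichment
#'
#' Upper-tail binomial test of the subclonal call count against the
#' false-assignment rate expected if every mutation were clonal (the
#' posterior decision band, default 0.10).
#'
#' @param estimates A `ccf_estimate` tibble for one sample.
#' @param null_rate Expected subclonal-call rate under the clonal-only null.
#' @param alpha Significance threshold (default 0.01).
#' @return A tibble with `n_subclonal`, `n_classified`, `p`, `significant`.
#' @export
test_subclonal_enrichment <- function(estimates, null_rate = 0.10,
                                      alpha = 0.01) {
  n_sub <- sum(estimates$status == "subclonal")
  n_cls <- sum(estimates$status %in% c("clonal", "subclonal"))
  stopifnot(n_cls >= 1)
  p <- pbinom(n_sub - 1, n_cls, null_rate, lower.tail = FALSE)
  tibble(n_subclonal = n_sub, n_classified = n_cls, p = p,
         significant = p < alpha)
}
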