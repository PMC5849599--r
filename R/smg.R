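#' Per-gene expected mutation counts under a uniform background
#'
#' Assumes somatic mutations are uniformly distributed over the callable
#' coding territory, so the expected count for a gene is proportional to its
#' coding length: `lambda_g = N_total * L_g / territory_bases`.
#'
#' @param mutations Cohort mutation tibble (all somatic mutations).
#' @param gene_models Tibble with `gene` and `coding_length`.
#' @param territory_bases Callable coding territory (default 3e7).
#' @return A tibble with `gene`, `coding_length`, `lambda`.
#' @export
estimate_background_rate <- function(mutations, gene_models,
                                     territory_bases = 3e7) {
  stopifnot(all(gene_models$coding_length > 0))
  if (territory_bases < sum(gene_models$coding_length)) {
    abort("territory_bases is smaller than the summed gene coding lengths")
  }
  n_total <- nrow(mutations)
  gene_models |>
    select("gene", "coding_length") |>
    mutate(lambda = n_total * .data$coding_length / territory_bases)
}

# upper-tail probability P(X >= x); midp replaces half the mass at x
poisson_upper_tail <- function(x, lambda, midp = FALSE) {
  p <- ppois(x - 1, lambda, lower.tail = FALSE)
  if (midp) p <- p - 0.5 * stats::dpois(x, lambda)
  pmin(pmax(p, 0), 1)
}

binom_upper_tail <- function(x, n, prob, midp = FALSE) {
  p <- pbinom(x - 1, n, prob, lower.tail = FALSE)
  if (midp) p <- p - 0.5 * dbinom(x, n, prob)
  pmin(pmax(p, 0), 1)
}

# Fisher combination statistic of the two component tails
burden_stat <- function(k, t, lambda_ns, ratio) {
  p1 <- poisson_upper_tail(k, lambda_ns)
  p2 <- binom_upper_tail(k, t, ratio)
  p2[t == 0] <- 1
  -2 * (log(pmax(p1, 1e-300)) + log(pmax(p2, 1e-300)))
}

# Exact tail probability of the combined statistic under the joint null
# (total ~ Poisson(lambda), non-synonymous | total ~ Binomial(total, ratio)).
# The two component p-values share the observed non-synonymous count, so a
# chi-squared reference would be doubly wrong (discreteness + dependence);
# full enumeration of the null support is cheap and exact.
exact_combined_p <- function(k_obs, t_obs, lambda, f_ns, ratio,
                             midp = FALSE) {
  t_max <- max(stats::qpois(1e-12, lambda, lower.tail = FALSE), t_obs, 10)
  t_all <- rep.int(0:t_max, 0:t_max + 1L)
  k_all <- sequence(0:t_max + 1L) - 1L
  pmf <- stats::dpois(t_all, lambda) * dbinom(k_all, t_all, ratio)
  stat <- burden_stat(k_all, t_all, lambda * f_ns, ratio)
  s_obs <- burden_stat(k_obs, t_obs, lambda * f_ns, ratio)
  tie <- abs(stat - s_obs) <= 1e-9
  above <- stat > s_obs + 1e-9
  tail_rest <- stats::ppois(t_max, lambda, lower.tail = FALSE)
  if (midp) {
    sum(pmf[above]) + 0.5 * sum(pmf[tie]) + tail_rest
  } else {
    sum(pmf[above | tie]) + tail_rest
  }
}

#' Significantly-mutated-gene burden test
#'
#' Combines two signals per gene: (i) a Poisson upper-tail test of the
#' non-synonymous count against the uniform-background expectation
#' `lambda * f_ns`, and (ii) a binomial upper-tail test of the gene's
#' non-synonymous fraction against the cohort-wide fraction.  The combined
#' p-value is the tail probability of the Fisher combination statistic
#' under the joint null (total count Poisson, non-synonymous count binomial
#' given the total), computed by enumerating the null support; this
#' respects the discreteness and dependence of the two components, which a
#' chi-squared reference would not.  The default is the mid-P version of
#' that enumerated tail (half weight on the observed statistic), which is
#' calibrated on average; `combination = "exact"` gives the strictly
#' conservative tail.
#'
#' @param observed_nonsyn,observed_syn Observed per-gene counts.
#' @param lambda Expected total mutation count from
#'   [estimate_background_rate()].
#' @param f_ns Expected non-synonymous fraction of random coding mutations
#'   (default 0.75).
#' @param cohort_ns_ratio Cohort-wide non-synonymous fraction.
#' @param combination `"midp"` (default) or `"exact"`.
#' @return A tibble with `p_burden`, `p_ratio`, `p_combined` (vectorized
#'   over genes).
#' @export
test_gene_burden <- function(observed_nonsyn, observed_syn, lambda,
                             f_ns = 0.75, cohort_ns_ratio = 0.75,
                             combination = c("midp", "exact")) {
  combination <- match.arg(combination)
  if (any(observed_nonsyn < 0) || any(observed_syn < 0)) {
    abort("observed counts must be non-negative")
  }
  stopifnot(f_ns > 0, f_ns < 1)
  lambda <- rep_len(lambda, length(observed_nonsyn))
  total <- observed_nonsyn + observed_syn
  p_burden <- poisson_upper_tail(observed_nonsyn, lambda * f_ns)
  p_ratio <- binom_upper_tail(observed_nonsyn, total, cohort_ns_ratio)
  # a gene with no mutations at all carries no ratio information
  p_ratio[total == 0] <- 1
  p_combined <- vapply(seq_along(observed_nonsyn), function(i) {
    exact_combined_p(observed_nonsyn[i], total[i], lambda[i],
                     f_ns, cohort_ns_ratio, midp = combination == "midp")
  }, numeric(1))
  tibble(p_burden = p_burden, p_ratio = p_ratio,
         p_combined = pmin(p_combined, 1))
}

#' Enrichment of damaging mutations in a gene
#'
#' Upper-tail binomial probability of observing at least the gene's damaging
#' count (splice site, nonsense, frameshift) among its mutations, at the
#' cohort-wide damaging fraction.
#'
#' @param n_damaging,n_total Per-gene counts.
#' @param background_damaging_fraction Cohort-wide damaging fraction.
#' @param midp Mid-P correction (default FALSE).
#' @return Vector of p-values; a gene with zero mutations gets p = 1 with a
#'   warning.
#' @export
test_damaging_enrichment <- function(n_damaging, n_total,
                                     background_damaging_fraction,
                                     midp = FALSE) {
  stopifnot(all(n_damaging >= 0), all(n_damaging <= n_total),
            background_damaging_fraction >= 0,
            background_damaging_fraction <= 1)
  if (any(n_total == 0)) {
    warn("gene(s) with zero mutations: damaging-enrichment p set to 1")
  }
  p <- binom_upper_tail(n_damaging, n_total, background_damaging_fraction,
                        midp = midp)
  p[n_total == 0] <- 1
  p
}

#' Resampling test for hotspot clustering of mutations
#'
#' The statistic is the maximum number of mutations recurring at a single
#' coding position.  Positions are resampled uniformly over the gene's
#' coding length; the p-value uses the add-one correction
#' `(1 + #\{T* >= T_obs\}) / (n_resamples + 1)`.
#'
#' @param positions Coding positions of the gene's mutations (in
#'   `[1, coding_length]`, at least 2).
#' @param coding_length Gene coding length in bases.
#' @param n_resamples Number of resamples (default 10000).
#' @param seed Integer seed.
#' @return A list with `t_obs` and `p`.
#' @export
test_hotspot_clustering <- function(positions, coding_length,
                                    n_resamples = 10000, seed = 1L) {
  n <- length(positions)
  stopifnot(n >= 2)
  if (any(positions < 1 | positions > coding_length)) {
    abort("mutation position outside [1, coding_length]")
  }
  t_obs <- max(tabulate(positions, nbins = coding_length))
  t_star <- with_substream(seed, "hotspot", {
    draws <- matrix(sample.int(coding_length, n * n_resamples,
                               replace = TRUE), nrow = n)
    apply(draws, 2, function(x) max(tabulate(x, nbins = coding_length)))
  })
  list(t_obs = t_obs, p = (1 + sum(t_star >= t_obs)) / (n_resamples + 1))
}

#' Full significantly-mutated-gene analysis of a cohort
#'
#' Runs the burden/ratio combination, damaging-mutation enrichment and
#' hotspot resampling per gene, then applies the expression filter and
#' Benjamini-Hochberg correction via [apply_smg_filters()].  The damaging
#' and hotspot tests are only reported for genes mutated in more than
#' `affected_threshold` of the samples.
#'
#' @param mutations Cohort mutation tibble; intergenic records (gene ".")
#'   contribute to the background totals only.
#' @param gene_models Tibble with `gene`, `coding_length` and optionally
#'   `start` (genomic gene start used to derive coding positions).
#' @param territory_bases Callable territory.
#' @param f_ns Expected non-synonymous fraction under the background model.
#' @param affected_threshold Minimum fraction of samples mutated for the
#'   damaging and hotspot tests (default 0.10).
#' @param n_resamples,seed Hotspot resampling controls.
#' @return An `smg_result` tibble, one row per modeled gene.
#' @export
smg_analysis <- function(mutations, gene_models, territory_bases = 3e7,
                         f_ns = 0.75, affected_threshold = 0.10,
                         n_resamples = 10000, seed = 1L) {
  bg <- estimate_background_rate(mutations, gene_models, territory_bases)
  n_samples <- dplyr::n_distinct(mutations$sample_id)
  damaging_types <- c("splice_site", "nonsense", "frameshift")

  cohort_ns_ratio <- mean(mutations$consequence != "synonymous")
  bg_damaging <- mean(mutations$consequence %in% damaging_types)

  per_gene <- mutations |>
    filter(.data$gene %in% gene_models$gene) |>
    group_by(.data$gene) |>
    summarise(
      n_nonsyn = sum(.data$consequence != "synonymous"),
      n_syn = sum(.data$consequence == "synonymous"),
      n_damaging = sum(.data$consequence %in% damaging_types),
      n_samples_affected = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    )
  res <- bg |>
    left_join(per_gene, by = "gene") |>
    mutate(across(c("n_nonsyn", "n_syn", "n_damaging",
                    "n_samples_affected"),
                  ~ tidyr::replace_na(.x, 0L)),
           fraction_affected = .data$n_samples_affected / n_samples)
  burden <- test_gene_burden(res$n_nonsyn, res$n_syn, res$lambda,
                             f_ns = f_ns, cohort_ns_ratio = cohort_ns_ratio)
  res <- bind_cols(res, burden)

  gate <- res$fraction_affected > affected_threshold
  res$p_damaging <- NA_real_
  if (any(gate & res$n_nonsyn + res$n_syn > 0)) {
    idx <- which(gate)
    res$p_damaging[idx] <- suppressWarnings(
      test_damaging_enrichment(res$n_damaging[idx],
                               res$n_nonsyn[idx] + res$n_syn[idx],
                               bg_damaging)
    )
  }

  res$p_hotspot <- NA_real_
  hot_idx <- which(gate & (res$n_nonsyn + res$n_syn) >= 2)
  if (length(hot_idx) && "start" %in% names(gene_models)) {
    starts <- gene_models$start[match(res$gene, gene_models$gene)]
    for (i in hot_idx) {
      gmut <- mutations[mutations$gene == res$gene[i], ]
      cpos <- gmut$pos - starts[i] + 1L
      cpos <- cpos[cpos >= 1 & cpos <= res$coding_length[i]]
      if (length(cpos) >= 2) {
        res$p_hotspot[i] <- test_hotspot_clustering(
          cpos, res$coding_length[i], n_resamples = n_resamples,
          seed = derive_seed(seed, res$gene[i])
        )$p
      }
    }
  }
  class(res) <- c("smg_result", class(res))
  res
}

#' Expression filter and multiple-testing correction for SMG results
#'
#' Genes without evidence of expression are removed before the
#' Benjamini-Hochberg correction: a gene passes when its abundance exceeds
#' `min_abundance` in at least `min_fraction` of the samples.  Q-values are
#' then computed over the remaining genes only.
#'
#' @param results An `smg_result` tibble.
#' @param expression Expression tibble in abundance units comparable across
#'   genes; genes absent from it fail the filter.
#' @param min_abundance Abundance threshold (default 1).
#' @param min_fraction Minimum fraction of samples above threshold
#'   (default 35/60).
#' @param q_threshold Significance threshold on Q (default 0.01).
#' @return The filtered tibble with `q_combined`, `q_damaging`, `q_hotspot`
#'   and logical `significant` columns.
#' @export
apply_smg_filters <- function(results, expression, min_abundance = 1,
                              min_fraction = 35 / 60, q_threshold = 0.01) {
  vals <- expr_to_matrix(expression)
  min_samples <- ceiling(min_fraction * ncol(vals))
  if (min_samples > ncol(vals)) {
    abort("min_fraction implies more samples than the cohort contains")
  }
  n_above <- rowSums(vals > min_abundance)
  expressed <- rownames(vals)[n_above >= min_samples]
  out <- results |>
    filter(.data$gene %in% expressed) |>
    mutate(
      q_combined = p.adjust(.data$p_combined, method = "BH"),
      q_damaging = p.adjust(.data$p_damaging, method = "BH"),
      q_hotspot = p.adjust(.data$p_hotspot, method = "BH"),
      significant = .data$q_combined < q_threshold
    )
  class(out) <- c("smg_result", class(out))
  out
}

#' Cohort mutation-rate and substitution-spectrum summary
#'
#' Per-sample non-synonymous mutation rate per megabase and the six
#' pyrimidine-reference substitution-class fractions over SNVs.
#'
#' @param mutations Cohort mutation tibble.
#' @param territory_bases Callable territory in bases.
#' @return A tibble with one row per sample: `rate_per_mb`, and columns
#'   `C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G` (NA when a sample has no SNV).
#' @export
cohort_mutation_summary <- function(mutations, territory_bases = 3e7) {
  mb <- territory_bases / 1e6
  snv_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  is_snv <- nchar(mutations$ref_allele) == 1 &
    nchar(mutations$alt_allele) == 1 &
    mutations$ref_allele %in% c("A", "C", "G", "T") &
    mutations$alt_allele %in% c("A", "C", "G", "T")
  mut <- mutations |>
    mutate(
      is_snv = is_snv,
      sub_class = ifelse(
        is_snv,
        ifelse(.data$ref_allele %in% c("C", "T"),
               paste0(.data$ref_allele, ">", .data$alt_allele),
               paste0(chartr("AG", "TC", .data$ref_allele), ">",
                      chartr("ACGT", "TGCA", .data$alt_allele))),
        NA_character_
      )
    )
  rates <- mut |>
    group_by(.data$sample_id) |>
    summarise(rate_per_mb = sum(.data$consequence != "synonymous") / mb,
              .groups = "drop")
  spectra <- mut |>
    filter(.data$is_snv) |>
    count(.data$sample_id, .data$sub_class) |>
    group_by(.data$sample_id) |>
    mutate(frac = .data$n / sum(.data$n)) |>
    ungroup() |>
    select(-"n") |>
    tidyr::pivot_wider(names_from = "sub_class", values_from = "frac",
                       values_fill = 0)
  for (cls in setdiff(snv_classes, names(spectra))) {
    spectra[[cls]] <- 0
  }
  rates |>
    left_join(spectra[, c("sample_id", snv_classes)], by = "sample_id")
}
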