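test_that("background rates are proportional to coding length", {
  gm <- tibble::tibble(gene = c("A", "B"), coding_length = c(1500L, 3000L))
  mut <- tiny_mutations()[rep(1, 6000), ]
  bg <- estimate_background_rate(mut, gm, territory_bases = 3e7)
  expect_equal(bg$lambda, c(0.3, 0.6))
  # doubling length doubles lambda exactly; zero mutations give zero
  expect_equal(bg$lambda[2], 2 * bg$lambda[1])
  bg0 <- estimate_background_rate(mut[0, ], gm, territory_bases = 3e7)
  expect_equal(bg0$lambda, c(0, 0))
  expect_error(estimate_background_rate(mut, gm, territory_bases = 1000),
               "territory")
})

test_that("burden tail matches a term-by-term Poisson series oracle", {
  # oracle: P(X >= 5) at rate 0.3 by direct summation of the series
  rate <- 0.3
  oracle <- 1 - sum(exp(-rate) * rate^(0:4) / factorial(0:4))
  res <- test_gene_burden(5L, 0L, lambda = rate / 0.75, f_ns = 0.75,
                          cohort_ns_ratio = 0.75)
  expect_equal(res$p_burden, oracle, tolerance = 1e-12)
})

test_that("exact-tail burden identities hold", {
  res0 <- test_gene_burden(0L, 0L, lambda = 1, combination = "exact")
  expect_equal(res0$p_burden, 1)
  expect_equal(res0$p_ratio, 1)
  expect_equal(res0$p_combined, 1)
  expect_error(test_gene_burden(-1L, 0L, lambda = 1), "non-negative")
})

test_that("combined p-value is an exact tail of the enumerated null", {
  # independent oracle: loop over the whole joint null support and sum the
  # probability mass of statistics at or above the observed one
  lambda <- 2
  f <- 0.75
  res <- test_gene_burden(4L, 1L, lambda = lambda, f_ns = f,
                          cohort_ns_ratio = f, combination = "exact")
  s_of <- function(k, t) {
    p1 <- ppois(k - 1, lambda * f, lower.tail = FALSE)
    p2 <- if (t == 0) 1 else pbinom(k - 1, t, f, lower.tail = FALSE)
    -2 * (log(p1) + log(p2))
  }
  s_obs <- s_of(4, 5)
  oracle <- 0
  for (t in 0:60) {
    for (k in 0:t) {
      if (s_of(k, t) >= s_obs - 1e-9) {
        oracle <- oracle + dpois(t, lambda) * dbinom(k, t, f)
      }
    }
  }
  expect_equal(res$p_combined, oracle, tolerance = 1e-9)
})

test_that("damaging-mutation enrichment matches an exact binomial oracle", {
  # oracle: P(X >= 8 | n = 10, p = 0.1) by direct summation
  oracle <- sum(choose(10, 8:10) * 0.1^(8:10) * 0.9^(10 - (8:10)))
  expect_equal(test_damaging_enrichment(8L, 10L, 0.1), oracle,
               tolerance = 1e-12)
  expect_equal(test_damaging_enrichment(0L, 10L, 0.5), 1)
  expect_equal(test_damaging_enrichment(5L, 10L, 1), 1)
  expect_warning(p0 <- test_damaging_enrichment(0L, 0L, 0.1),
                 "zero mutations")
  expect_equal(p0, 1)
})

test_that("hotspot resampling test matches the enumerated tiny-gene case", {
  # L = 3, two mutations at one position: of the 9 equally likely
  # placements, 3 are doubletons, so P(T* >= 2) = 1/3 exactly
  h <- test_hotspot_clustering(c(1L, 1L), 3L, n_resamples = 10000, seed = 7)
  expect_equal(h$t_obs, 2)
  mc_se <- sqrt(1 / 3 * 2 / 3 / 10000)
  expect_lt(abs(h$p - 1 / 3), 3 * mc_se)
  # identical seed, identical p
  expect_equal(h$p,
               test_hotspot_clustering(c(1L, 1L), 3L, 10000, seed = 7)$p)
  # distinct positions in a long gene: T_obs = 1 is the minimum
  h2 <- test_hotspot_clustering(c(1L, 500L, 900L), 100000L,
                                n_resamples = 200, seed = 1)
  expect_equal(h2$t_obs, 1)
  expect_equal(h2$p, 1)
  expect_error(test_hotspot_clustering(c(1L, 5L), 3L), "outside")
})

test_that("Benjamini-Hochberg filtering follows the expression gate", {
  gm <- tibble::tibble(gene = sprintf("G%02d", 1:10),
                       coding_length = 1500L)
  res <- tibble::tibble(
    gene = gm$gene, coding_length = 1500L, lambda = 1,
    n_nonsyn = 0L, n_syn = 0L, n_damaging = 0L, n_samples_affected = 0L,
    fraction_affected = 0,
    p_burden = 1, p_ratio = 1,
    p_combined = c(0.001, rep(1, 9)),
    p_damaging = NA_real_, p_hotspot = NA_real_
  )
  class(res) <- c("smg_result", class(res))
  mat <- matrix(10, 10, 6, dimnames = list(gm$gene, sprintf("S%d", 1:6)))
  mat["G01", ] <- c(10, 10, 0, 0, 0, 0)  # expressed in only 2 of 6
  expr <- as_expr(mat)
  out <- apply_smg_filters(res, expr, min_abundance = 1,
                           min_fraction = 35 / 60, q_threshold = 0.01)
  # G01 fails the expression filter despite p = 0.001
  expect_false("G01" %in% out$gene)
  # hand BH over the remaining nine genes: all p = 1 -> none significant
  expect_equal(sum(out$significant), 0)

  # single tested gene: Q = p
  res1 <- res[2, ]
  res1$p_combined <- 0.005
  class(res1) <- c("smg_result", class(res1))
  out1 <- apply_smg_filters(res1, as_expr(mat[2, , drop = FALSE]))
  expect_equal(out1$q_combined, 0.005)
  expect_true(out1$significant)

  # ten genes, smallest p = 0.001 and the rest 1: BH q = 0.01 exactly for
  # the smallest, which is not below the threshold; boundary stays strict
  res10 <- res
  res10$p_combined <- c(0.001, rep(1, 9))
  mat2 <- matrix(10, 10, 6, dimnames = list(gm$gene, sprintf("S%d", 1:6)))
  out10 <- apply_smg_filters(res10, as_expr(mat2))
  expect_equal(min(out10$q_combined), 0.01)
  expect_equal(sum(out10$significant), 0)
  expect_equal(sum(out10$q_combined < 0.011), 1)
})

test_that("cohort summary reproduces rate and spectrum identities", {
  gm <- tibble::tibble(gene = "A", coding_length = 1500L)
  # 258 non-synonymous mutations over 3e7 bases -> 8.6 per Mb
  mut <- tiny_mutations()[rep(1, 258), ]
  mut$sample_id <- "T1"
  summ <- cohort_mutation_summary(mut, territory_bases = 3e7)
  expect_equal(summ$rate_per_mb, 8.6)
  # all G>T SNVs collapse onto the C>A pyrimidine class
  mut2 <- tiny_mutations()[rep(2, 5), ]
  summ2 <- cohort_mutation_summary(mut2, 3e7)
  expect_equal(summ2$`C>A`, 1)
  expect_equal(summ2$`T>G`, 0)
  # indel-only sample: substitution fractions are missing
  mut3 <- tiny_mutations()[1, ]
  mut3$ref_allele <- "CA"
  mut3$alt_allele <- "C"
  mut3$consequence <- "frameshift"
  summ3 <- cohort_mutation_summary(mut3, 3e7)
  expect_true(is.na(summ3$`C>A`))
})

test_that("hotspot p-values are super-uniform under a uniform null", {
  ps <- vapply(1:40, function(s) {
    pos <- withr::with_seed(3000 + s, sample.int(1500L, 6, replace = TRUE))
    test_hotspot_clustering(pos, 1500L, n_resamples = 300, seed = s)$p
  }, numeric(1))
  # conservative: P(p <= alpha) <= alpha (within binomial noise)
  for (alpha in c(0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha / 40))
  }
})

test_that("smg p-values are invariant under row permutations", {
  coh <- small_cohort(seed = 17, n = 10)
  gm <- coh$gene_models
  res1 <- smg_analysis(coh$mutations, gm, n_resamples = 200, seed = 3)
  perm <- withr::with_seed(1, sample(nrow(coh$mutations)))
  res2 <- smg_analysis(coh$mutations[perm, ], gm, n_resamples = 200,
                       seed = 3)
  expect_equal(res1$p_combined, res2$p_combined)
  expect_equal(res1$p_hotspot, res2$p_hotspot)
})
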