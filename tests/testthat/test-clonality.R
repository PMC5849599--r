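test_that("expected allelic fraction follows the purity/copy-number model", {
  expect_equal(expected_allele_fraction(1, 2, 1), 0.5)
  expect_equal(expected_allele_fraction(0.5, 2, 1), 0.25)
  expect_equal(expected_allele_fraction(0.6, 4, 2), 1.2 / 3.2)
  expect_error(expected_allele_fraction(0.5, 2, 3), "multiplicity")
  expect_error(expected_allele_fraction(0, 2, 1), "purity")
})

test_that("expected allelic fraction is monotone and equals m/c at purity 1", {
  rhos <- seq(0.05, 1, by = 0.05)
  af <- expected_allele_fraction(rhos, 3, 1)
  expect_true(all(diff(af) > 0))
  for (c_t in 1:4) {
    for (m in seq_len(c_t)) {
      expect_equal(expected_allele_fraction(1, c_t, m), m / c_t)
      if (m > 1) {
        expect_gt(expected_allele_fraction(0.7, c_t, m),
                  expected_allele_fraction(0.7, c_t, m - 1))
      }
    }
  }
})

test_that("purity/ploidy fit is exact on noiseless integer-consistent input", {
  # single segment with ratio 1 at psi = 2 implies copy number 2, score 0
  seg <- tibble::tibble(sample_id = "T1", chrom = "1", start = 1L,
                        end = 1000000L, n_markers = 100L, ratio = 1)
  fit <- fit_purity_ploidy(seg, ploidy_grid = 2)
  expect_equal(fit$segments$abs_cn, 2L)
  expect_equal(fit$score, 0)

  # purity grid restricted to 1 with integer-consistent ratios
  cn <- c(1, 2, 3, 4)
  seg2 <- tibble::tibble(
    sample_id = "T1", chrom = "1",
    start = as.integer(c(1, 2e6, 4e6, 6e6)),
    end = as.integer(c(2e6 - 1, 4e6 - 1, 6e6 - 1, 8e6)),
    n_markers = 100L, ratio = cn / 2.5
  )
  fit2 <- fit_purity_ploidy(seg2, purity_grid = 1,
                            ploidy_grid = seq(1.5, 5.5, 0.05))
  expect_equal(fit2$segments$abs_cn, as.integer(cn))
  expect_equal(fit2$score, 0, tolerance = 1e-20)
  expect_equal(fit2$ploidy, 2.5)
})

test_that("purity and ploidy are recovered from noisy segment profiles", {
  coh <- simulate_cohort(simulation_config(
    seed = 19, n_samples = 10, purity_range = c(0.3, 0.95)
  ))
  tru <- coh$truth$samples
  for (sid in tru$sample_id) {
    fit <- fit_purity_ploidy(coh$segments[coh$segments$sample_id == sid, ])
    expect_lt(abs(fit$purity - tru$purity[tru$sample_id == sid]), 0.05)
    expect_lt(abs(fit$ploidy - tru$ploidy[tru$sample_id == sid]), 0.2)
  }
})

test_that("short segments are excluded and can exhaust the input", {
  seg <- tibble::tibble(sample_id = "T1", chrom = "1", start = 1L,
                        end = 100L, n_markers = 1L, ratio = 1)
  expect_error(fit_purity_ploidy(seg), "insufficient segment support")
})

test_that("CCF is the observed over expected allelic fraction, capped", {
  fit <- structure(list(
    sample_id = "T1", purity = 0.5, ploidy = 2, score = 0,
    segments = tibble::tibble(sample_id = "T1", chrom = "1", start = 1L,
                              end = 10000L, n_markers = 10L, ratio = 1,
                              abs_cn = 2L)
  ), class = "purity_ploidy_fit")
  mut <- tibble::tibble(
    sample_id = "T1", gene = "A", chrom = "1", pos = c(100L, 200L, 300L),
    ref_allele = "C", alt_allele = "A", context5 = "A", context3 = "A",
    consequence = "missense",
    alt_count = c(25L, 13L, 90L), depth = c(100L, 104L, 100L)
  )
  cc <- compute_ccf(mut, fit)
  # AF_exp(m=1) = 0.25, AF_exp(m=2) = 0.5: quotients 1.0 and 0.5 at m = 1;
  # the 0.9 observed fraction selects m = 2 and its quotient 1.8 is capped
  expect_equal(cc$ccf[1], 1.0)
  expect_equal(cc$ccf[2], 0.5)
  expect_equal(cc$ccf[3], 1.5)
  expect_true(cc$capped[3])
  expect_false(any(cc$capped[1:2]))
  expect_equal(cc$multiplicity, c(1L, 1L, 2L))
})

test_that("mutations without segment support are skipped with a warning", {
  fit <- structure(list(
    sample_id = "T1", purity = 0.5, ploidy = 2, score = 0,
    segments = tibble::tibble(sample_id = "T1", chrom = "1", start = 1L,
                              end = 1000L, n_markers = 10L, ratio = 1,
                              abs_cn = 2L)
  ), class = "purity_ploidy_fit")
  mut <- tiny_mutations()[1, ]
  mut$pos <- 5000L
  expect_warning(cc <- compute_ccf(mut, fit), "skipped")
  expect_equal(nrow(cc), 0)
})

test_that("grid-posterior clonality matches a brute-force oracle", {
  # independent oracle: explicit normalization over the CCF grid
  oracle <- function(alt, depth, af) {
    grid <- seq(0.01, 1, by = 0.01)
    lik <- choose(depth, alt) * (grid * af)^alt * (1 - grid * af)^(depth - alt)
    sum(lik[grid >= 0.9]) / sum(lik)
  }
  cases <- list(c(50, 100), c(10, 100), c(2, 4))
  for (cs in cases) {
    got <- classify_clonality(cs[1], cs[2], 0.5)
    expect_equal(got$p_clonal, oracle(cs[1], cs[2], 0.5), tolerance = 1e-9)
  }
  # frozen oracle values: deep balanced coverage at the expected fraction
  # leaves appreciable posterior mass below CCF 0.9 (ambiguous); a strongly
  # depleted fraction is confidently subclonal; low depth is uninformative
  expect_equal(classify_clonality(50, 100, 0.5)$status, "ambiguous")
  expect_gt(classify_clonality(50, 100, 0.5)$p_clonal, 0.5)
  expect_equal(classify_clonality(10, 100, 0.5)$status, "subclonal")
  expect_equal(classify_clonality(2, 4, 0.5)$status, "ambiguous")
  expect_error(classify_clonality(5, 10, 0), "positive")
})

test_that("mixture classifier separates planted clonal and subclonal calls", {
  withr::with_seed(11, {
    n <- 300
    clonal <- rep(c(TRUE, FALSE), times = c(270, 30))
    af <- rep(0.35, n)
    ccf <- ifelse(clonal, 1, 0.35)
    alt <- rbinom(n, 100, ccf * af)
  })
  cls <- classify_clonality_mixture(alt, rep(100L, 300), af)
  called <- cls$status != "ambiguous"
  acc <- mean((cls$status[called] == "clonal") == clonal[called])
  expect_gt(acc, 0.95)
  expect_gt(sum(cls$status == "subclonal"), 15)
})

test_that("subclonal fractions count only classified mutations", {
  est <- tibble::tibble(
    sample_id = rep("T1", 110),
    status = rep(c("clonal", "subclonal", "ambiguous"),
                 times = c(93, 7, 10))
  )
  sf <- subclonal_fraction(est)
  expect_equal(sf$subclonal_fraction, 0.07)
  est2 <- tibble::tibble(sample_id = "T1", status = "ambiguous")
  expect_true(is.na(subclonal_fraction(est2)$subclonal_fraction))
  est3 <- tibble::tibble(sample_id = "T1",
                         status = rep("clonal", 10))
  expect_equal(subclonal_fraction(est3)$subclonal_fraction, 0)
})

test_that("subclonal enrichment is an exact binomial upper tail", {
  est <- tibble::tibble(sample_id = "T1",
                        status = rep(c("clonal", "subclonal"),
                                     times = c(70, 30)))
  got <- test_subclonal_enrichment(est, null_rate = 0.10, alpha = 0.01)
  # oracle: direct tail summation P(X >= 30 | n = 100, p = 0.1)
  oracle <- sum(choose(100, 30:100) * 0.1^(30:100) * 0.9^(100 - (30:100)))
  expect_equal(got$p, oracle, tolerance = 1e-12)
  expect_true(got$significant)
  est0 <- tibble::tibble(sample_id = "T1", status = rep("clonal", 100))
  expect_equal(test_subclonal_enrichment(est0)$p, 1)
  est1 <- tibble::tibble(sample_id = "T1",
                         status = c(rep("clonal", 99), "subclonal"))
  expect_true(test_subclonal_enrichment(est1, alpha = 1.0)$significant)
})
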