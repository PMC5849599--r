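test_that("bi-allelic calls follow the two-hit evidence rule", {
  mut <- tibble::tibble(
    sample_id = c("T1", "T2", "T2", "T4"),
    gene = c("STK11", "STK11", "STK11", "RB1"),
    chrom = "1", pos = c(100L, 100L, 200L, 300L),
    ref_allele = "C", alt_allele = "A", context5 = "A", context3 = "A",
    consequence = c("nonsense", "missense", "frameshift", "synonymous"),
    alt_count = 5L, depth = 20L
  )
  samples <- c("T1", "T2", "T3", "T4", "T5")
  res <- call_biallelic_status(
    mut, genes = c("STK11", "RB1"), samples = samples,
    loh = tibble::tibble(sample_id = "T1", gene = "STK11"),
    homdels = tibble::tibble(sample_id = "T3", gene = "RB1"),
    rearrangements = tibble::tibble(sample_id = "T5", gene = "RB1")
  )
  mat <- res$matrix
  # mutation + LOH and two mutations are bi-allelic
  expect_equal(mat$STK11[mat$sample_id == "T1"], "bi_allelic")
  expect_equal(mat$STK11[mat$sample_id == "T2"], "bi_allelic")
  # homozygous deletion alone is bi-allelic
  expect_equal(mat$RB1[mat$sample_id == "T3"], "bi_allelic")
  # synonymous records are not hits
  expect_equal(mat$RB1[mat$sample_id == "T4"], "none")
  # a lone rearrangement is a single hit
  expect_equal(mat$RB1[mat$sample_id == "T5"], "mono_allelic")
  # single mutation without LOH is mono-allelic
  res2 <- call_biallelic_status(mut[1, ], c("STK11"), "T1")
  expect_equal(res2$matrix$STK11, "mono_allelic")
  expect_warning(
    call_biallelic_status(mut, c("STK11"), samples,
                          rearrangements = tibble::tibble(
                            sample_id = "T1", gene = "UNKNOWN")),
    "ignored"
  )
})

test_that("two-sided Fisher matches a from-scratch enumeration oracle", {
  # oracle: enumerate margin-fixed tables, probability by factorials
  oracle <- function(tab) {
    r <- rowSums(tab)
    cl <- colSums(tab)
    n <- sum(tab)
    prob_of <- function(a) {
      b <- r[1] - a
      cc <- cl[1] - a
      d <- r[2] - cc
      if (b < 0 || cc < 0 || d < 0) {
        return(NA_real_)
      }
      exp(lfactorial(r[1]) + lfactorial(r[2]) + lfactorial(cl[1]) +
            lfactorial(cl[2]) - lfactorial(n) - lfactorial(a) -
            lfactorial(b) - lfactorial(cc) - lfactorial(d))
    }
    probs <- vapply(0:min(r[1], cl[1]), prob_of, numeric(1))
    probs <- probs[!is.na(probs)]
    p_obs <- prob_of(tab[1, 1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  t2 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_2x2(t2), oracle(t2), tolerance = 1e-12)
  # transposition symmetry
  t3 <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_exact_2x2(t3), fisher_exact_2x2(t(t3)),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("exhaustive small-table agreement with enumeration and stats", {
  # all 2x2 tables with total at most 16 against the independent reference
  count <- 0
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if (a + b + cc + d > 16 || a + b + cc + d == 0) next
    tab <- matrix(c(a, cc, b, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(p, ref, tolerance = 1e-12)
    count <- count + 1
  }
  expect_gt(count, 1000)
})

test_that("Monte Carlo r x c test agrees with the exact 2x2 tail", {
  tab <- matrix(c(12, 3, 2, 9), 2)
  p_exact <- fisher_exact_2x2(tab)
  p_mc <- fisher_monte_carlo_rxc(tab, n_perm = 10000, seed = 5)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(p_mc - p_exact), 3 * mc_se + 2 / 10001)
  # determinism and degenerate margins
  expect_equal(p_mc, fisher_monte_carlo_rxc(tab, n_perm = 10000, seed = 5))
  expect_warning(p1 <- fisher_monte_carlo_rxc(rbind(tab, 0), 100, 1),
                 "all-zero")
})

test_that("Monte Carlo p-values are roughly uniform under independence", {
  ps <- vapply(1:20, function(s) {
    tab <- withr::with_seed(500 + s, {
      matrix(rpois(12, 8), 3, 4)
    })
    fisher_monte_carlo_rxc(tab, n_perm = 400, seed = s)
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(length(unique(round(ps, 3))), 10)
})

test_that("mutual exclusivity detects a planted exclusive architecture", {
  status <- c(rep("A", 25), rep("B", 24), rep("none", 11))
  mat <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:60),
    STK11 = ifelse(status == "A", "bi_allelic", "none"),
    KEAP1 = "none",
    RB1 = ifelse(status == "B", "mono_allelic", "none")
  )
  res <- test_mutual_exclusivity(mat, c("STK11", "KEAP1"), "RB1")
  expect_equal(res$overlap, 0)
  expect_lt(res$p, 1e-4)
  # everything altered in both arms: p = 1
  mat2 <- dplyr::mutate(mat, STK11 = "bi_allelic", RB1 = "bi_allelic")
  expect_equal(test_mutual_exclusivity(mat2, "STK11", "RB1")$p, 1)
  expect_error(test_mutual_exclusivity(mat, character(0), "RB1"),
               "non-empty")
})

test_that("independent alterations show no exclusivity signal", {
  ps <- vapply(1:10, function(s) {
    withr::with_seed(700 + s, {
      mat <- tibble::tibble(
        sample_id = sprintf("S%02d", 1:60),
        STK11 = sample(c("bi_allelic", "none"), 60, replace = TRUE),
        KEAP1 = "none",
        RB1 = sample(c("bi_allelic", "none"), 60, replace = TRUE)
      )
    })
    test_mutual_exclusivity(mat, c("STK11", "KEAP1"), "RB1")$p
  }, numeric(1))
  expect_gt(median(ps), 0.05)
})

test_that("adding a doubly altered sample cannot strengthen exclusivity", {
  mat <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:30),
    STK11 = c(rep("bi_allelic", 14), rep("none", 16)),
    KEAP1 = "none",
    RB1 = c(rep("none", 14), rep("bi_allelic", 12), rep("none", 4))
  )
  p0 <- test_mutual_exclusivity(mat, c("STK11", "KEAP1"), "RB1")$p
  both <- tibble::tibble(sample_id = "S31", STK11 = "bi_allelic",
                         KEAP1 = "none", RB1 = "bi_allelic")
  p1 <- test_mutual_exclusivity(dplyr::bind_rows(mat, both),
                                c("STK11", "KEAP1"), "RB1")$p
  expect_gte(p1, p0)
})

test_that("type I / type II labels follow the driver rule exactly", {
  mat <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"),
    STK11 = c("bi_allelic", "none", "mono_allelic", "none"),
    KEAP1 = "none",
    RB1 = c("none", "bi_allelic", "bi_allelic", "none")
  )
  lab <- assign_lcnec_type(mat)
  expect_equal(lab$label, c("type_I", "type_II", "ambiguous",
                            "unclassified"))
  # bi-allelic mode ignores the mono-allelic STK11 hit
  lab2 <- assign_lcnec_type(mat, mode = "biallelic")
  expect_equal(lab2$label[3], "type_II")
  expect_error(assign_lcnec_type(mat[, 1:3]), "lacks required")
})

test_that("neuroendocrine profiles use a strict threshold and marker sets", {
  genes <- c("ASCL1", "DLL3", "CHGA", "SYP", "NCAM1",
             "NOTCH1", "NOTCH2", "HES1", "REST", "FILLER")
  m <- matrix(100, length(genes), 2,
              dimnames = list(genes, c("T1", "T2")))
  # T1: classic neuroendocrine-high profile; T2: everything at threshold
  m[c("NOTCH1", "NOTCH2", "HES1", "REST"), "T1"] <- 1
  thr <- 100
  ne <- classify_neuroendocrine_level(as_expr(m), thr)
  p1 <- ne$profiles$profile[ne$profiles$sample_id == "T1"]
  # exact threshold is "low" under the strict rule, so T1 NE markers at
  # exactly 100 are low; raise them above threshold for the classic call
  m2 <- m
  m2[c("ASCL1", "DLL3", "CHGA", "SYP", "NCAM1"), "T1"] <- 400
  ne2 <- classify_neuroendocrine_level(as_expr(m2), thr)
  expect_equal(unname(ne2$profiles$profile[ne2$profiles$sample_id == "T1"]),
               "ASCL1-high/DLL3-high/NOTCH-low")
  # everything exactly at the threshold is low
  states_t2 <- ne2$states[ne2$states$sample_id == "T2", ]
  expect_true(all(states_t2$state == "low"))
  # marker order does not change the profile
  ne3 <- classify_neuroendocrine_level(
    as_expr(m2), thr,
    markers = rev(c("ASCL1", "DLL3", "CHGA", "SYP", "NCAM1")),
    counter_markers = rev(c("NOTCH1", "NOTCH2", "HES1", "REST"))
  )
  expect_equal(ne3$profiles$profile, ne2$profiles$profile)
  expect_warning(
    classify_neuroendocrine_level(as_expr(m[1:4, , drop = FALSE]), thr),
    "omitted"
  )
})
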