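test_that("channel order is canonical and catalogs conserve SNV counts", {
  ch <- signature_channels()
  expect_length(ch, 96)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  expect_false(anyDuplicated(ch) > 0)

  mut <- tiny_mutations()
  catal <- build_catalog(mut)
  counts <- lcnectype:::catalog_to_matrix(catal)
  expect_equal(sum(counts), 3)
  # T1 carries a C>A at A_C_A plus a G>T at T_G_T, which strand-collapses
  # onto the same channel
  expect_equal(unname(counts["A[C>A]A", "T1"]), 2)
  expect_equal(unname(colSums(counts)), c(2, 1))
})

test_that("purine-reference SNVs collapse by reverse complement", {
  mut <- tibble::tibble(
    sample_id = "T1", gene = "A", chrom = "1", pos = 1L,
    ref_allele = "G", alt_allele = "T", context5 = "T", context3 = "T",
    consequence = "missense", alt_count = 1L, depth = 10L
  )
  catal <- build_catalog(mut)
  counts <- lcnectype:::catalog_to_matrix(catal)
  expect_equal(unname(counts["A[C>A]A", 1]), 1)
  expect_equal(sum(counts), 1)
})

test_that("records with unusable context are skipped and counted", {
  mut <- tiny_mutations()
  mut$context5[2] <- "N"
  expect_warning(catal <- build_catalog(mut), "skipped")
  expect_equal(sum(lcnectype:::catalog_to_matrix(catal)), 2)
})

test_that("rank-one catalogs are factorized exactly at k = 1", {
  W <- default_signature_profiles()[, 1, drop = FALSE]
  totals <- c(400, 800, 1200)
  V <- W %*% matrix(totals, 1)
  colnames(V) <- sprintf("S%d", 1:3)
  catal <- lcnectype:::matrix_to_catalog(V)
  sigs <- extract_signatures(catal, k = 1, n_restarts = 3,
                             max_iter = 5000, seed = 2)
  expect_gt(cosine_similarity(sigs$W[, 1], W[, 1]), 1 - 1e-6)
  expect_equal(unname(colSums(sigs$W)), 1, tolerance = 1e-9)
})

test_that("two well-separated planted signatures are recovered", {
  W <- default_signature_profiles()
  expect_lt(cosine_similarity(W[, 1], W[, 2]), 0.3)
  expo <- withr::with_seed(31, {
    w <- runif(30, 0.2, 0.8)
    rbind(w, 1 - w) * 400
  })
  colnames(expo) <- sprintf("S%02d", 1:30)
  rownames(expo) <- colnames(W)
  catal <- simulate_catalogs(W, expo, seed = 6)
  sigs <- extract_signatures(catal, k = 2, n_restarts = 15, seed = 9)
  match_cos <- vapply(1:2, function(j) {
    max(cosine_similarity(sigs$W[, j], W[, 1]),
        cosine_similarity(sigs$W[, j], W[, 2]))
  }, numeric(1))
  expect_true(all(match_cos >= 0.95))
  expect_true(all(sigs$reproducibility > 0.9))
})

test_that("the KL objective never increases within any restart", {
  coh <- small_cohort(seed = 23, n = 8)
  catal <- suppressWarnings(build_catalog(coh$mutations))
  sigs <- extract_signatures(catal, k = 2, n_restarts = 5, seed = 4)
  for (tr in sigs$kl_traces) {
    expect_true(all(diff(tr) <= 1e-8 * max(tr[1], 1)))
  }
  # identical seed, identical factorization
  sigs2 <- extract_signatures(catal, k = 2, n_restarts = 5, seed = 4)
  expect_equal(sigs$W, sigs2$W)
  expect_equal(sigs$kl, sigs2$kl)
})

test_that("permuting catalog samples permutes exposures and nothing else", {
  W <- default_signature_profiles()
  expo <- matrix(c(300, 100, 50, 250, 200, 200), 2,
                 dimnames = list(colnames(W), c("A", "B", "C")))
  catal <- simulate_catalogs(W, expo, seed = 3)
  perm <- c(3, 1, 2)
  catal_p <- lcnectype:::matrix_to_catalog(
    lcnectype:::catalog_to_matrix(catal)[, perm, drop = FALSE])
  H1 <- estimate_exposures(catal, W)
  H2 <- estimate_exposures(catal_p, W)
  expect_equal(unname(H1[, perm]), unname(H2), tolerance = 1e-6)
})

test_that("exposures invert a noiseless mixture and respect totals", {
  W <- default_signature_profiles()
  h <- matrix(c(120, 480), 2, dimnames = list(colnames(W), "A"))
  V <- W %*% h
  catal <- lcnectype:::matrix_to_catalog(V)
  H <- estimate_exposures(catal, W)
  expect_equal(unname(H), unname(h), tolerance = 1e-3 * max(h))
  # per-sample reconstruction totals within 1%
  expect_lt(abs(sum(W %*% H) - sum(V)) / sum(V), 0.01)
  # zero sample -> zero exposures; k = 1 -> exposure equals the total
  V0 <- cbind(V, 0)
  colnames(V0) <- c("A", "B")
  H0 <- estimate_exposures(lcnectype:::matrix_to_catalog(V0), W)
  expect_equal(unname(H0[, 2]), c(0, 0))
  H1 <- estimate_exposures(catal, W[, 1, drop = FALSE])
  expect_equal(unname(H1[1, 1]), sum(V), tolerance = 1e-6)
})

test_that("cosine similarity satisfies its closed forms and guards", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "all-zero")
})

test_that("low-mutation cases are filtered before extraction", {
  W <- default_signature_profiles()
  expo <- matrix(c(100, 50, 10, 5, 0, 0), 2,
                 dimnames = list(colnames(W), c("A", "B", "C")))
  catal <- simulate_catalogs(W, expo, seed = 2)
  filt <- filter_catalog(catal, min_variants = 30)
  expect_equal(setdiff(names(catal), names(filt)), c("B", "C"))
  expect_setequal(attr(filt, "dropped_samples"), c("B", "C"))
  expect_error(filter_catalog(catal, min_variants = 1e6), "minimum variant")
})

test_that("the rank scan reports KL and reproducibility per k", {
  W <- default_signature_profiles()
  expo <- withr::with_seed(5, {
    w <- runif(12, 0.3, 0.7)
    rbind(w, 1 - w) * 300
  })
  dimnames(expo) <- list(colnames(W), sprintf("S%02d", 1:12))
  catal <- simulate_catalogs(W, expo, seed = 3)
  scan <- scan_signature_k(catal, k_range = 1:3, n_restarts = 4, seed = 6)
  expect_equal(scan$k, 1:3)
  # reconstruction error is non-increasing in the rank
  expect_true(all(diff(scan$kl) <= 0))
  expect_true(all(scan$min_reproducibility > 0))
})

test_that("degenerate factorization inputs are rejected", {
  V <- matrix(0, 96, 3,
              dimnames = list(signature_channels(), c("A", "B", "C")))
  catal <- lcnectype:::matrix_to_catalog(V)
  expect_error(extract_signatures(catal, k = 1), "all zero")
  V[1, 1] <- 5
  catal <- lcnectype:::matrix_to_catalog(V)
  expect_error(extract_signatures(catal, k = 10), "k must lie")
})
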