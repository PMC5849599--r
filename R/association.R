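#' Call mono- vs bi-allelic driver alteration status
#'
#' Combines somatic mutations with loss-of-heterozygosity flags,
#' homozygous deletions and disrupting rearrangements into a per-sample,
#' per-gene status.  A homozygous deletion alone is bi-allelic; otherwise
#' bi-allelic status requires two independent hits (two mutations, a
#' mutation or rearrangement plus LOH, or a mutation plus rearrangement).
#' LOH without any somatic hit is not counted as an alteration.
#'
#' @param mutations Mutation tibble (non-synonymous records count as hits).
#' @param genes Genes to call.
#' @param samples Sample universe (so unaltered samples appear).
#' @param loh Optional tibble `(sample_id, gene)` flagging LOH.
#' @param homdels Optional tibble `(sample_id, gene)` of homozygous
#'   deletions.
#' @param rearrangements Optional tibble `(sample_id, gene)` of disrupting
#'   rearrangements; unknown genes are ignored with a warning.
#' @return A list with `matrix` (samples x genes tibble of
#'   none/mono_allelic/bi_allelic) and `calls` (long evidence tibble).
#' @export
call_biallelic_status <- function(mutations, genes, samples,
                                  loh = NULL, homdels = NULL,
                                  rearrangements = NULL) {
  empty <- tibble(sample_id = character(), gene = character())
  loh <- loh %||% empty
  homdels <- homdels %||% empty
  rearrangements <- rearrangements %||% empty
  unknown <- setdiff(unique(rearrangements$gene), genes)
  if (length(unknown)) {
    warn(paste0("rearrangement(s) in unmodeled gene(s) ignored: ",
                toString(unknown)))
    rearrangements <- filter(rearrangements, .data$gene %in% genes)
  }
  hits <- mutations |>
    filter(.data$gene %in% genes, .data$consequence != "synonymous") |>
    count(.data$sample_id, .data$gene, name = "n_mutations")

  grid <- tidyr::expand_grid(sample_id = samples, gene = genes)
  calls <- grid |>
    left_join(hits, by = c("sample_id", "gene")) |>
    mutate(
      n_mutations = tidyr::replace_na(.data$n_mutations, 0L),
      loh = paste(.data$sample_id, .data$gene) %in%
        paste(loh$sample_id, loh$gene),
      homdel = paste(.data$sample_id, .data$gene) %in%
        paste(homdels$sample_id, homdels$gene),
      rearranged = paste(.data$sample_id, .data$gene) %in%
        paste(rearrangements$sample_id, rearrangements$gene),
      n_hits = .data$n_mutations + .data$rearranged,
      status = dplyr::case_when(
        homdel ~ "bi_allelic",
        n_hits >= 2 ~ "bi_allelic",
        n_hits >= 1 & loh ~ "bi_allelic",
        n_hits >= 1 ~ "mono_allelic",
        TRUE ~ "none"
      ),
      evidence = pmap(list(.data$n_mutations, .data$loh, .data$homdel,
                           .data$rearranged), function(nm, lo, hd, re) {
        ev <- character(0)
        if (nm >= 1) ev <- c(ev, "mutation")
        if (nm >= 2) ev <- c(ev, "second_mutation")
        if (lo) ev <- c(ev, "loh")
        if (hd) ev <- c(ev, "homozygous_deletion")
        if (re) ev <- c(ev, "rearrangement")
        ev
      })
    )
  mat <- calls |>
    select("sample_id", "gene", "status") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "status")
  list(matrix = mat, calls = calls)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all margin-fixed tables whose
#' probability does not exceed the observed table's (the conventional
#' probability-ordering definition of the two-sided p).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) {
    abort("table entries must be non-negative")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])      # row-1 total
  n <- sum(tab[2, ])      # row-2 total
  k <- sum(tab[, 1])      # column-1 total
  if (m + n == 0 || k == 0 || k == m + n) {
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

log_table_prob <- function(tab) {
  # multivariate hypergeometric probability of a margin-fixed r x c table
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte Carlo Fisher test for an r x c table
#'
#' Samples margin-preserving tables (equivalent to permuting
#' individual-level labels) and reports the add-one-corrected fraction with
#' probability at or below the observed table's.  Degenerate all-zero rows
#' or columns are dropped with a warning.
#'
#' @param tab r x c matrix of non-negative integer counts.
#' @param n_perm Number of simulated tables (default 10000).
#' @param seed Integer seed.
#' @return Monte Carlo two-sided p-value.
#' @export
fisher_monte_carlo_rxc <- function(tab, n_perm = 10000, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) {
    abort("table entries must be non-negative")
  }
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn("dropping all-zero row(s)/column(s) from the table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (any(dim(tab) < 2)) {
    return(1)
  }
  lp_obs <- log_table_prob(tab)
  hits <- with_substream(seed, "fisher-mc", {
    sims <- stats::r2dtable(n_perm, rowSums(tab), colSums(tab))
    sum(vapply(sims, function(s) {
      log_table_prob(s) <= lp_obs + 1e-7
    }, logical(1)))
  })
  (1 + hits) / (n_perm + 1)
}

#' Mutual exclusivity of two driver gene sets
#'
#' Collapses each gene set to a per-sample altered/unaltered indicator
#' (counting mono- or bi-allelic events, or bi-allelic only) and tests the
#' resulting 2x2 table with the two-sided Fisher test.
#'
#' @param alteration_matrix Samples x genes status tibble from
#'   [call_biallelic_status()].
#' @param geneset_a,geneset_b Non-empty gene sets (columns of the matrix).
#' @param mode Count `"any"` alteration (default) or `"biallelic"` only.
#' @return A list with `table` (2x2), `overlap` (both-altered count) and
#'   `p`.
#' @export
test_mutual_exclusivity <- function(alteration_matrix, geneset_a, geneset_b,
                                    mode = c("any", "biallelic")) {
  mode <- match.arg(mode)
  if (!length(geneset_a) || !length(geneset_b)) {
    abort("gene sets must be non-empty")
  }
  missing_genes <- setdiff(c(geneset_a, geneset_b),
                           names(alteration_matrix))
  if (length(missing_genes)) {
    abort(paste0("gene(s) absent from alteration matrix: ",
                 toString(missing_genes)))
  }
  counted <- if (mode == "any") c("mono_allelic", "bi_allelic") else
    "bi_allelic"
  altered <- function(set) {
    apply(alteration_matrix[, set, drop = FALSE], 1,
          function(x) any(x %in% counted))
  }
  a <- altered(geneset_a)
  b <- altered(geneset_b)
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A_altered", "A_wildtype"),
                                c("B_altered", "B_wildtype")))
  list(table = tab, overlap = tab[1, 1], p = fisher_exact_2x2(tab))
}

#' Assign type I / type II LCNEC labels from driver genotypes
#'
#' Type I requires an STK11 or KEAP1 alteration without an RB1 alteration;
#' type II the reverse; samples altered in both arms are `ambiguous` and
#' samples altered in neither are `unclassified`.
#'
#' @param alteration_matrix Samples x genes status tibble including STK11,
#'   KEAP1 and RB1 columns.
#' @param mode Count any alteration (default) or bi-allelic only.
#' @return A tibble with `sample_id`, `label`, `basis`.
#' @export
assign_lcnec_type <- function(alteration_matrix,
                              mode = c("any", "biallelic")) {
  mode <- match.arg(mode)
  needed <- c("STK11", "KEAP1", "RB1")
  missing_genes <- setdiff(needed, names(alteration_matrix))
  if (length(missing_genes)) {
    abort(paste0("alteration matrix lacks required gene(s): ",
                 toString(missing_genes)))
  }
  counted <- if (mode == "any") c("mono_allelic", "bi_allelic") else
    "bi_allelic"
  a <- alteration_matrix$STK11 %in% counted |
    alteration_matrix$KEAP1 %in% counted
  b <- alteration_matrix$RB1 %in% counted
  tibble(
    sample_id = alteration_matrix$sample_id,
    label = dplyr::case_when(
      a & !b ~ "type_I",
      b & !a ~ "type_II",
      a & b ~ "ambiguous",
      TRUE ~ "unclassified"
    ),
    basis = dplyr::case_when(
      a & !b ~ "STK11/KEAP1 altered, RB1 wild-type",
      b & !a ~ "RB1 altered, STK11/KEAP1 wild-type",
      a & b ~ "both STK11/KEAP1 and RB1 altered",
      TRUE ~ "no STK11/KEAP1 or RB1 alteration"
    )
  )
}

#' Score neuroendocrine marker expression as high or low
#'
#' Each marker is `high` when its expression strictly exceeds the global
#' expression threshold.  The per-sample profile string reports the ASCL1
#' and DLL3 states and an aggregate NOTCH-pathway state (majority vote over
#' the counter-marker set), e.g. `"ASCL1-high/DLL3-high/NOTCH-low"`.
#'
#' @param expr Normalized expression tibble.
#' @param threshold Global threshold from [global_expression_threshold()].
#' @param markers High-set marker genes (default ASCL1, DLL3, CHGA, SYP,
#'   NCAM1).
#' @param counter_markers NOTCH-pathway counter set (default NOTCH1, NOTCH2,
#'   HES1, REST).
#' @return A list with `states` (long tibble: sample, marker, state) and
#'   `profiles` (per-sample profile string).
#' @export
classify_neuroendocrine_level <- function(expr, threshold,
                                          markers = c("ASCL1", "DLL3",
                                                      "CHGA", "SYP",
                                                      "NCAM1"),
                                          counter_markers = c("NOTCH1",
                                                              "NOTCH2",
                                                              "HES1",
                                                              "REST")) {
  vals <- expr_to_matrix(expr)
  wanted <- c(markers, counter_markers)
  absent <- setdiff(wanted, rownames(vals))
  if (length(absent)) {
    warn(paste0("marker(s) absent from matrix, omitted: ",
                toString(absent)))
  }
  markers <- intersect(markers, rownames(vals))
  counter_markers <- intersect(counter_markers, rownames(vals))
  present <- c(markers, counter_markers)
  states <- tibble(
    sample_id = rep(colnames(vals), each = length(present)),
    marker = rep(present, ncol(vals)),
    state = ifelse(as.vector(vals[present, , drop = FALSE]) >
                     as.numeric(threshold), "high", "low")
  )
  profile_of <- function(sid) {
    st <- states[states$sample_id == sid, ]
    get_state <- function(g) st$state[st$marker == g]
    parts <- character(0)
    for (g in intersect(c("ASCL1", "DLL3"), present)) {
      parts <- c(parts, paste0(g, "-", get_state(g)))
    }
    if (length(counter_markers)) {
      notch_high <- mean(st$state[st$marker %in% counter_markers] ==
                           "high") > 0.5
      parts <- c(parts, paste0("NOTCH-", if (notch_high) "high" else "low"))
    }
    paste(parts, collapse = "/")
  }
  profiles <- tibble(
    sample_id = colnames(vals),
    profile = unname(vapply(colnames(vals), profile_of, character(1)))
  )
  list(states = states, profiles = profiles)
}
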