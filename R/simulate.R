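#' Default driver and background gene models
#'
#' A compact exome: the four recurrently inactivated LCNEC driver genes plus
#' `n_background` generic coding genes with log-normally distributed coding
#' lengths, laid out head-to-tail on a single synthetic chromosome.
#'
#' @param n_background Number of background genes.
#' @param seed Integer seed for the length draw.
#' @return A tibble with `gene`, `coding_length`, `chrom`, `start`, `end`.
#' @export
default_gene_models <- function(n_background = 200, seed = 1L) {
  drivers <- tibble(
    gene = c("TP53", "RB1", "STK11", "KEAP1"),
    coding_length = c(1800L, 2800L, 1300L, 1900L)
  )
  bg_len <- with_substream(seed, "gene-lengths", {
    pmax(300L, as.integer(round(exp(rnorm(n_background, log(1400), 0.45)))))
  })
  genes <- bind_rows(
    drivers,
    tibble(gene = sprintf("GENE%04d", seq_len(n_background)),
           coding_length = bg_len)
  )
  gap <- 5000L
  ends <- cumsum(genes$coding_length + gap) + 100000L
  genes |>
    mutate(chrom = "1",
           start = as.integer(ends - .data$coding_length - gap + 1L),
           end = as.integer(.data$start + .data$coding_length - 1L))
}

#' Built-in synthetic signature profiles
#'
#' Two synthetic 96-channel profiles: a tobacco-like profile dominated by
#' C>A transversions and a background profile dominated by C>T transitions.
#' They are constructed, not measured reference signatures, and are chosen to
#' be well separated (low cosine similarity) so that factorization recovery
#' is identifiable.
#'
#' @return A 96 x 2 column-stochastic matrix with channels as row names.
#' @export
default_signature_profiles <- function() {
  channels <- signature_channels()
  sub_of <- rep(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), each = 16)
  # fixed, uneven context weights make the profiles peaky and distinctive
  ctx_a <- rep(c(4, 1, 0.5, 2, 6, 1.5, 0.5, 3, 1, 5, 2, 0.5, 3, 1, 0.5, 2), 6)
  ctx_b <- rev(ctx_a)
  smoking <- c("C>A" = 0.72, "C>G" = 0.10, "C>T" = 0.06,
               "T>A" = 0.06, "T>C" = 0.03, "T>G" = 0.03)
  background <- c("C>A" = 0.04, "C>G" = 0.04, "C>T" = 0.62,
                  "T>A" = 0.04, "T>C" = 0.22, "T>G" = 0.04)
  make_profile <- function(sub_weights, ctx) {
    w <- ctx * sub_weights[sub_of]
    w <- as.vector(vapply(split(w, sub_of), function(x) x / sum(x),
                          numeric(16))[, unique(sub_of)]) *
      rep(sub_weights[unique(sub_of)], each = 16)
    w / sum(w)
  }
  W <- cbind(smoking_like = make_profile(smoking, ctx_a),
             background_like = make_profile(background, ctx_b))
  rownames(W) <- channels
  W
}

#' Configuration of a synthetic LCNEC cohort
#'
#' Defaults reproduce the statistical structure the downstream analyses
#' assume for this tumor type: median purity near 0.6, near-triploid genomes
#' (length-weighted ploidy about 2.75 plus one homozygous deletion per
#' sample), 8.6 non-synonymous mutations per Mb over a 30 Mb coding
#' territory, a tobacco-dominated trinucleotide spectrum with an overall
#' C:G>A:T fraction near 0.39, 7% subclonal mutations, and two mutually
#' exclusive genotype classes (STK11/KEAP1-altered "type_I", RB1-altered
#' "type_II") with matched expression classes and neuroendocrine marker
#' patterns.
#'
#' @param seed Integer root seed (mandatory).
#' @param n_samples Cohort size.
#' @param genes Gene model tibble as from [default_gene_models()].
#' @param territory_bases Callable coding territory (bases).
#' @param nonsyn_per_mb Non-synonymous mutation rate per megabase.
#' @param syn_fraction Fraction of mutations that are synonymous.
#' @param depth Sequencing depth at mutated sites.
#' @param purity_range Uniform range of tumor purity.
#' @param cn_weights Named weights over integer copy-number states for
#'   segments (names are the states).
#' @param n_segments Segments per sample (before the homozygous deletion).
#' @param homdel_length Length of the planted homozygous-deletion segment;
#'   0 disables it.
#' @param segment_noise_sd Gaussian noise SD on segment ratios.
#' @param subclonal_fraction Fraction of mutations in a subclone.
#' @param subclone_ccf_range Uniform range of subclonal cancer cell fraction.
#' @param multiplicity_prob2 Probability that a mutation on a gained segment
#'   (total copy number >= 2) predates the gain and has multiplicity 2.
#' @param signature_profiles 96 x k column-stochastic profile matrix.
#' @param signature_weights Mixing weights over the profiles, one per column.
#' @param class_probs Named class probabilities; classes named `type_I` /
#'   `type_II` receive the corresponding driver genotypes.
#' @param exclusivity Plant mutually exclusive driver genotypes (classes own
#'   their drivers); `FALSE` draws drivers independently of class.
#' @param n_expr_genes,markers_per_class Expression matrix size and number of
#'   planted marker genes per class.
#' @param marker_effect Marker shift in units of the noise SD (log2 scale).
#' @param expr_noise_sd Residual SD of log2 expression.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_samples = 60,
                              genes = NULL,
                              territory_bases = 3e7,
                              nonsyn_per_mb = 8.6,
                              syn_fraction = 0.25,
                              depth = 100,
                              purity_range = c(0.4, 0.9),
                              cn_weights = c("1" = 0.05, "2" = 0.30,
                                             "3" = 0.50, "4" = 0.15),
                              n_segments = 40,
                              homdel_length = 1e6,
                              segment_noise_sd = 0.02,
                              subclonal_fraction = 0.07,
                              subclone_ccf_range = c(0.2, 0.5),
                              multiplicity_prob2 = 0.35,
                              signature_profiles = default_signature_profiles(),
                              signature_weights = c(0.51, 0.49),
                              class_probs = c(type_I = 0.37, type_II = 0.42,
                                              other = 0.21),
                              exclusivity = TRUE,
                              n_expr_genes = 2000,
                              markers_per_class = 50,
                              marker_effect = 2,
                              expr_noise_sd = 1) {
  if (missing(seed) || is.null(seed)) {
    abort("simulation_config() requires an explicit integer seed")
  }
  genes <- genes %||% default_gene_models(seed = seed)
  stopifnot(
    n_samples >= 1, territory_bases > 0, nonsyn_per_mb >= 0,
    syn_fraction >= 0, syn_fraction < 1, depth >= 1,
    length(purity_range) == 2, purity_range[1] > 0, purity_range[2] <= 1,
    all(cn_weights >= 0), sum(cn_weights) > 0, n_segments >= 1,
    segment_noise_sd >= 0, subclonal_fraction >= 0, subclonal_fraction <= 1,
    multiplicity_prob2 >= 0, multiplicity_prob2 <= 1,
    ncol(signature_profiles) == length(signature_weights),
    all(signature_profiles >= 0), all(signature_weights >= 0),
    abs(sum(class_probs) - 1) < 1e-8,
    is.finite(marker_effect), expr_noise_sd > 0
  )
  if (markers_per_class * length(class_probs) > n_expr_genes) {
    abort("marker genes exceed n_expr_genes; enlarge the expression design")
  }
  if (max(genes$end) + homdel_length >= territory_bases) {
    abort("gene layout plus homozygous deletion exceeds the territory")
  }
  cfg <- as.list(environment())
  cfg$signature_weights <- signature_weights / sum(signature_weights)
  class(cfg) <- "simulation_config"
  cfg
}

ne_marker_sets <- function() {
  list(high = c("ASCL1", "DLL3", "CHGA", "SYP", "NCAM1"),
       counter = c("NOTCH1", "NOTCH2", "HES1", "REST"))
}

#' Simulate a cohort with known ground truth
#'
#' Generates the four standard tables (mutations, copy-number segments,
#' expression, annotations) plus a `truth` object holding every planted
#' parameter, so downstream estimators can be scored exactly.  Mutation
#' allele counts are drawn binomially with the expected allelic fraction
#' computed from the planted purity, local absolute copy number,
#' multiplicity and cancer cell fraction (the same model inverted by
#' [compute_ccf()]); segment ratios derive from the planted absolute copy
#' numbers plus Gaussian noise; expression is planted on the log2 scale and
#' exponentiated.  Identical seeds give identical outputs.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `mutations`, `segments`, `expression`,
#'   `annotations`, `gene_models`, and `truth` (class `cohort_truth`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  seed <- cfg$seed
  n <- cfg$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))

  samples <- with_substream(seed, "samples", {
    tibble(
      sample_id = sample_ids,
      purity = runif(n, cfg$purity_range[1], cfg$purity_range[2]),
      class = sample(names(cfg$class_probs), n, replace = TRUE,
                     prob = cfg$class_probs)
    )
  })

  seg <- with_substream(seed, "segments", simulate_segments(cfg, samples))
  samples$ploidy <- seg$ploidy[match(samples$sample_id, seg$ploidy_sample)]

  geno <- with_substream(seed, "genotype", simulate_genotype(cfg, samples))

  mut <- with_substream(seed, "mutations", {
    simulate_mutations(cfg, samples, seg$truth, geno)
  })

  expr <- with_substream(seed, "expression", {
    simulate_expression(cfg, samples)
  })

  annotations <- tibble(sample_id = sample_ids, histology = "LCNEC",
                        combined_component = NA_character_,
                        stage = NA_character_, smoking = NA_character_)

  truth <- list(
    samples = samples |>
      left_join(mut$per_sample, by = "sample_id"),
    segments = seg$truth,
    mutations = mut$truth,
    exposures = mut$exposures,
    signature_profiles = cfg$signature_profiles,
    genotype = geno$genotype,
    loh = geno$loh,
    marker_genes = expr$marker_genes,
    class_probs = cfg$class_probs
  )
  class(truth) <- "cohort_truth"

  list(mutations = mut$table, segments = seg$table, expression = expr$table,
       annotations = annotations, gene_models = cfg$genes, truth = truth)
}

simulate_segments <- function(cfg, samples) {
  G <- cfg$territory_bases
  core_end <- G - cfg$homdel_length
  states <- as.integer(names(cfg$cn_weights))
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    rho <- samples$purity[i]
    bp <- sort(sample.int(core_end - 1, cfg$n_segments - 1))
    start <- c(1, bp + 1)
    end <- c(bp, core_end)
    cn <- states[sample.int(length(states), cfg$n_segments, replace = TRUE,
                            prob = cfg$cn_weights)]
    if (cfg$homdel_length > 0) {
      start <- c(start, core_end + 1)
      end <- c(end, G)
      cn <- c(cn, 0L)
    }
    len <- end - start + 1
    psi <- sum(len * cn) / sum(len)
    denom <- rho * psi + 2 * (1 - rho)
    ratio <- (rho * cn + 2 * (1 - rho)) / denom +
      rnorm(length(cn), 0, cfg$segment_noise_sd)
    tibble(sample_id = samples$sample_id[i], chrom = "1",
           start = as.integer(start), end = as.integer(end),
           n_markers = pmax(1L, as.integer(len %/% 10000)),
           ratio = pmax(ratio, 1e-4), cn_true = cn, ploidy = psi)
  })
  all <- list_rbind(rows)
  list(
    table = all |> select("sample_id", "chrom", "start", "end",
                          "n_markers", "ratio"),
    truth = all |> select("sample_id", "chrom", "start", "end",
                          "cn_true", "ploidy"),
    ploidy = all$ploidy[!duplicated(all$sample_id)],
    ploidy_sample = all$sample_id[!duplicated(all$sample_id)]
  )
}

simulate_genotype <- function(cfg, samples) {
  drivers <- c("TP53", "RB1", "STK11", "KEAP1")
  rows <- list()
  loh_rows <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    cls <- samples$class[i]
    hit <- character(0)
    if (cfg$exclusivity) {
      # class-defining drivers are bi-allelically inactivated, matching the
      # definition of the genotype subgroups
      if (cls == "type_I") {
        hit <- drivers[c(FALSE, FALSE, runif(1) < 0.75, runif(1) < 0.60)]
        if (!length(hit)) hit <- "STK11"
      } else if (cls == "type_II") {
        hit <- "RB1"
      }
    } else {
      hit <- drivers[c(FALSE, runif(1) < 0.42, runif(1) < 0.30,
                       runif(1) < 0.22)]
    }
    if (runif(1) < 0.92) hit <- c("TP53", hit)
    for (g in hit) {
      class_defining <- cfg$exclusivity && g != "TP53"
      has_loh <- runif(1) < if (class_defining) 0.9 else 0.85
      second_hit <- !has_loh && class_defining
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, gene = g,
        n_hits = if (second_hit) 2L else 1L,
        status = if (has_loh || second_hit) "bi_allelic" else "mono_allelic"
      )
      if (has_loh) {
        loh_rows[[length(loh_rows) + 1L]] <- tibble(sample_id = sid, gene = g)
      }
    }
  }
  list(
    genotype = if (length(rows)) list_rbind(rows) else
      tibble(sample_id = character(), gene = character(),
             n_hits = integer(), status = character()),
    loh = if (length(loh_rows)) list_rbind(loh_rows) else
      tibble(sample_id = character(), gene = character())
  )
}

# draw trinucleotide channels and convert them to ref/alt/context columns,
# flipping half of the records to the purine reference strand
channels_to_context <- function(channel_idx) {
  channels <- signature_channels()
  lab <- channels[channel_idx]
  p5 <- substr(lab, 1, 1)
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  p3 <- substr(lab, 7, 7)
  flip <- runif(length(lab)) < 0.5
  comp <- function(x) chartr("ACGT", "TGCA", x)
  tibble(
    ref_allele = ifelse(flip, comp(ref), ref),
    alt_allele = ifelse(flip, comp(alt), alt),
    context5 = ifelse(flip, comp(p3), p5),
    context3 = ifelse(flip, comp(p5), p3),
    channel = lab
  )
}

simulate_mutations <- function(cfg, samples, seg_truth, geno) {
  genes <- cfg$genes
  G <- cfg$territory_bases
  core_end <- G - cfg$homdel_length
  mix <- cfg$signature_profiles %*% cfg$signature_weights
  n_sig <- ncol(cfg$signature_profiles)
  total_rate <- cfg$nonsyn_per_mb / (1 - cfg$syn_fraction) *
    cfg$territory_bases / 1e6
  nonsyn_types <- c("missense", "nonsense", "splice_site",
                    "frameshift", "inframe_indel")
  nonsyn_probs <- c(0.78, 0.08, 0.04, 0.07, 0.03)

  out <- vector("list", nrow(samples))
  exposures <- matrix(0, n_sig, nrow(samples),
                      dimnames = list(colnames(cfg$signature_profiles),
                                      samples$sample_id))
  per_sample <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rho <- samples$purity[i]
    segs <- seg_truth[seg_truth$sample_id == sid, ]
    n_mut <- rpois(1, total_rate)

    pos <- sample.int(core_end, n_mut, replace = TRUE)
    gi <- findInterval(pos, genes$start)
    in_gene <- gi >= 1 & pos <= genes$end[pmax(gi, 1)]
    gene <- ifelse(in_gene, genes$gene[pmax(gi, 1)], ".")

    is_syn <- runif(n_mut) < cfg$syn_fraction
    consequence <- ifelse(
      is_syn, "synonymous",
      sample(nonsyn_types, n_mut, replace = TRUE, prob = nonsyn_probs)
    )

    # driver events appended as clonal damaging mutations (only for genes
    # present in the gene models)
    drv <- geno$genotype[geno$genotype$sample_id == sid &
                           geno$genotype$gene %in% genes$gene, ]
    n_drv <- 0L
    if (nrow(drv)) {
      drv_gene <- rep(drv$gene, drv$n_hits)
      n_drv <- length(drv_gene)
      drv_idx <- match(drv_gene, genes$gene)
      drv_pos <- genes$start[drv_idx] +
        floor(runif(n_drv) * genes$coding_length[drv_idx])
      pos <- c(pos, drv_pos)
      gene <- c(gene, drv_gene)
      consequence <- c(consequence,
                       sample(c("nonsense", "frameshift", "splice_site",
                                "missense"), n_drv, replace = TRUE,
                              prob = c(0.4, 0.3, 0.15, 0.15)))
      n_mut <- n_mut + n_drv
    }
    is_driver <- c(rep(FALSE, n_mut - n_drv), rep(TRUE, n_drv))

    si <- findInterval(pos, segs$start)
    c_t <- segs$cn_true[si]
    # mutations cannot be observed on homozygously deleted DNA
    keep <- c_t >= 1
    pos <- pos[keep]; gene <- gene[keep]; consequence <- consequence[keep]
    is_driver <- is_driver[keep]; c_t <- c_t[keep]
    n_mut <- length(pos)

    clonal <- is_driver | (runif(n_mut) >= cfg$subclonal_fraction)
    ccf <- ifelse(clonal, 1,
                  runif(n_mut, cfg$subclone_ccf_range[1],
                        cfg$subclone_ccf_range[2]))
    # only clonal mutations can predate a gain and carry multiplicity 2
    m <- ifelse(clonal & c_t >= 2 & runif(n_mut) < cfg$multiplicity_prob2,
                2L, 1L)
    af_exp <- m * rho / (c_t * rho + 2 * (1 - rho))
    p_obs <- pmin(ccf * af_exp, 1)
    depth <- rep(as.integer(cfg$depth), n_mut)
    alt <- rbinom(n_mut, depth, p_obs)

    is_indel <- consequence %in% c("frameshift", "inframe_indel")
    sig <- sample.int(n_sig, n_mut, replace = TRUE,
                      prob = cfg$signature_weights)
    channel_idx <- vapply(sig, function(s) {
      sample.int(96L, 1L, prob = cfg$signature_profiles[, s])
    }, integer(1))
    ctx <- channels_to_context(channel_idx)
    exposures[, i] <- tabulate(sig[!is_indel], nbins = n_sig)

    bases <- c("A", "C", "G", "T")
    ref <- ctx$ref_allele
    alt_allele <- ctx$alt_allele
    context5 <- ctx$context5
    context3 <- ctx$context3
    channel <- ctx$channel
    if (any(is_indel)) {
      # deletions: two-base reference collapsing to one base
      ref[is_indel] <- paste0(ctx$ref_allele[is_indel],
                              sample(bases, sum(is_indel), replace = TRUE))
      alt_allele[is_indel] <- ctx$ref_allele[is_indel]
      context5[is_indel] <- NA_character_
      context3[is_indel] <- NA_character_
      channel[is_indel] <- NA_character_
    }

    out[[i]] <- tibble(
      sample_id = sid, gene = gene, chrom = "1", pos = as.integer(pos),
      ref_allele = ref, alt_allele = alt_allele,
      context5 = context5, context3 = context3,
      consequence = consequence, alt_count = alt, depth = depth,
      ccf_true = ccf, multiplicity = m, clonal = clonal,
      channel = channel, is_driver = is_driver
    )
    per_sample[[i]] <- tibble(
      sample_id = sid, n_mutations = n_mut,
      true_subclonal_fraction = mean(!clonal)
    )
  }
  all <- list_rbind(out)
  list(
    table = all |> select(all_of(mutation_fields)),
    truth = all |> mutate(mutation_id = row_number()) |>
      select("mutation_id", "sample_id", "gene", "chrom", "pos",
             "consequence", "ccf_true", "multiplicity", "clonal",
             "channel", "is_driver"),
    exposures = exposures,
    per_sample = list_rbind(per_sample)
  )
}

simulate_expression <- function(cfg, samples) {
  classes <- names(cfg$class_probs)
  ne <- ne_marker_sets()
  n_named <- length(ne$high) + length(ne$counter)
  n_filler <- cfg$n_expr_genes - n_named -
    cfg$markers_per_class * length(classes)
  stopifnot(n_filler >= 0)
  marker_genes <- lapply(seq_along(classes), function(j) {
    sprintf("MRK_%s_%03d", classes[j], seq_len(cfg$markers_per_class))
  })
  names(marker_genes) <- classes
  gene_names <- c(ne$high, ne$counter, unlist(marker_genes),
                  sprintf("EXPR%04d", seq_len(n_filler)))
  n_genes <- length(gene_names)
  n <- nrow(samples)

  base <- rnorm(n_genes, 5, 2)
  log2_mat <- matrix(base, n_genes, n) +
    matrix(rnorm(n_genes * n, 0, cfg$expr_noise_sd), n_genes, n)
  rownames(log2_mat) <- gene_names

  shift <- cfg$marker_effect * cfg$expr_noise_sd
  for (j in seq_along(classes)) {
    cols <- which(samples$class == classes[j])
    log2_mat[marker_genes[[j]], cols] <-
      log2_mat[marker_genes[[j]], cols] + shift
  }

  # neuroendocrine program: planted relative to the overall median (about
  # 2^5); type_I high NE / low NOTCH, type_II the reverse
  med <- 5
  plant <- function(genes_set, cols, level) {
    log2_mat[genes_set, cols] <<- matrix(
      rnorm(length(genes_set) * length(cols), level, 0.4),
      length(genes_set), length(cols))
  }
  type1 <- which(samples$class == "type_I")
  type2 <- which(samples$class == "type_II")
  rest <- which(!samples$class %in% c("type_I", "type_II"))
  if (length(type1)) {
    plant(ne$high, type1, med + 2)
    plant(ne$counter, type1, med - 3)
  }
  if (length(type2)) {
    plant(ne$high, type2, med - 3)
    plant(ne$counter, type2, med + 2)
  }
  if (length(rest) && length(c(type1, type2))) {
    plant(c(ne$high, ne$counter), rest, med - 0.5)
  }

  vals <- 2^log2_mat
  colnames(vals) <- samples$sample_id
  tbl <- matrix_to_expr(vals, "raw_counts")
  list(table = tbl, marker_genes = marker_genes)
}

#' Simulate 96-channel catalogs from signature profiles and exposures
#'
#' Each sample's channel counts are drawn multinomially from its
#' exposure-weighted mixture of the profiles.
#'
#' @param profiles 96 x k column-stochastic profile matrix.
#' @param exposures k x n matrix of non-negative per-sample mutation counts
#'   attributed to each profile.
#' @param seed Integer seed.
#' @return A `mutation_catalog` tibble (96 channels x n samples).
#' @export
simulate_catalogs <- function(profiles, exposures, seed) {
  if (any(profiles < 0)) {
    abort("signature profiles must be non-negative")
  }
  if (any(exposures < 0)) {
    abort("exposures must be non-negative")
  }
  stopifnot(nrow(profiles) == 96, ncol(profiles) == nrow(exposures))
  profiles <- sweep(profiles, 2, pmax(colSums(profiles), 1e-300), "/")
  n <- ncol(exposures)
  counts <- with_substream(seed, "catalogs", {
    vapply(seq_len(n), function(j) {
      total <- round(sum(exposures[, j]))
      if (total == 0) {
        return(integer(96))
      }
      mix <- as.vector(profiles %*% exposures[, j])
      as.integer(rmultinom(1, total, mix / sum(mix)))
    }, integer(96))
  })
  rownames(counts) <- signature_channels()
  colnames(counts) <- colnames(exposures) %||% sprintf("S%03d", seq_len(n))
  matrix_to_catalog(counts)
}
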