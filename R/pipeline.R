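#' Configure an end-to-end cohort analysis run
#'
#' Bundles input paths, stage toggles and stage parameters.  Every random
#' stage draws from sub-streams of the single `seed`, and the configuration
#' is serialized beside the outputs, so a rerun with the same configuration
#' reproduces identical files.
#'
#' @param mutations,segments,expression Paths to the input tables.
#' @param gene_models Path to a gene model TSV (`gene`, `coding_length`,
#'   optionally `chrom`, `start`, `end`).
#' @param annotations Optional path to a sample annotation TSV.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer root seed.
#' @param stages Stages to run, in dependency order.
#' @param params Named list of per-stage parameter overrides (`smg`,
#'   `signatures`, `expression`).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(mutations, segments, expression, gene_models,
                            annotations = NULL, out_dir = tempdir(),
                            seed = 1L,
                            stages = c("smg", "clonality", "signatures",
                                       "expression", "association"),
                            params = list()) {
  cfg <- list(
    inputs = list(mutations = mutations, segments = segments,
                  expression = expression, gene_models = gene_models,
                  annotations = annotations),
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    params = utils::modifyList(list(
      smg = list(territory_bases = 3e7, f_ns = 0.75, q_threshold = 0.01,
                 n_resamples = 10000),
      signatures = list(k = 2, n_restarts = 50, min_variants = 30),
      expression = list(mean_quantile = 0.9, var_quantile = 0.9, k = 2,
                        method = "pam_spearman", n_resamples = 250)
    ), params)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (IO, then SMG /
#' clonality / signatures, then expression subtyping, then genotype-subtype
#' association), writes every stage output as TSV into the output
#' directory, and returns a manifest of output files with MD5 checksums.
#' Input availability is validated before any computation; a stage failure
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return A tibble manifest (`file`, `md5`), invisibly also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  needed <- c("mutations", "segments", "gene_models")
  if ("expression" %in% config$stages ||
      "smg" %in% config$stages || "association" %in% config$stages) {
    needed <- c(needed, "expression")
  }
  for (nm in needed) {
    path <- config$inputs[[nm]]
    if (is.null(path) || !file.exists(path)) {
      abort(paste0("input '", nm, "' is missing or does not exist: ",
                   path %||% "<NULL>"))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  mutations <- read_mutation_table(config$inputs$mutations)
  segments <- read_segments(config$inputs$segments)
  expr <- read_expression_matrix(config$inputs$expression)
  gene_models <- read_tsv_quiet(config$inputs$gene_models)
  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, name)
    readr::write_tsv(tbl, path, progress = FALSE)
    outputs <<- c(outputs, path)
  }

  expr_uq <- normalize_upper_quartile(expr)

  if ("smg" %in% config$stages) {
    run_stage("smg", function() {
      pr <- config$params$smg
      res <- smg_analysis(mutations, gene_models,
                          territory_bases = pr$territory_bases,
                          f_ns = pr$f_ns, n_resamples = pr$n_resamples,
                          seed = derive_seed(seed, "smg"))
      res <- apply_smg_filters(res, expr_uq, q_threshold = pr$q_threshold)
      emit(res, "smg_results.tsv")
      emit(cohort_mutation_summary(mutations, pr$territory_bases),
           "mutation_summary.tsv")
    })
  }

  ccf_all <- NULL
  if ("clonality" %in% config$stages) {
    run_stage("clonality", function() {
      fits <- lapply(split(segments, segments$sample_id), fit_purity_ploidy)
      fit_tbl <- list_rbind(lapply(fits, function(f) {
        tibble(sample_id = f$sample_id, purity = f$purity,
               ploidy = f$ploidy, score = f$score)
      }))
      emit(fit_tbl, "purity_ploidy.tsv")
      ccf_all <<- list_rbind(lapply(fits, function(f) {
        suppressWarnings(
          compute_ccf(mutations[mutations$sample_id == f$sample_id, ], f)
        )
      }))
      emit(ccf_all, "ccf_estimates.tsv")
      emit(subclonal_fraction(ccf_all), "subclonal_fractions.tsv")
    })
  }

  if ("signatures" %in% config$stages) {
    run_stage("signatures", function() {
      pr <- config$params$signatures
      catalog <- suppressWarnings(
        build_catalog(mutations, samples = unique(mutations$sample_id))
      )
      catalog <- filter_catalog(catalog, min_variants = pr$min_variants)
      sigs <- extract_signatures(catalog, k = pr$k,
                                 n_restarts = pr$n_restarts,
                                 seed = derive_seed(seed, "signatures"))
      emit(matrix_to_catalog(sigs$W), "signatures.tsv")
      emit(bind_cols(tibble(signature = rownames(sigs$H)),
                     as_tibble(sigs$H)), "exposures.tsv")
      emit(catalog, "catalog_96.tsv")
    })
  }

  subtype_labels <- NULL
  if ("expression" %in% config$stages) {
    run_stage("expression", function() {
      pr <- config$params$expression
      genes <- select_clustering_genes(expr_uq, pr$mean_quantile,
                                       pr$var_quantile)
      cc <- consensus_cluster(expr_uq, genes, k_range = pr$k,
                              n_resamples = pr$n_resamples,
                              method = pr$method,
                              seed = derive_seed(seed, "consensus"))
      res <- cc[[1]]
      subtype_labels <<- res$labels
      emit(tibble(sample_id = names(res$labels),
                  class = res$labels), "expression_classes.tsv")
      emit(as_tibble(res$consensus, rownames = "sample_id"),
           "consensus_matrix.tsv")
    })
  }

  if ("association" %in% config$stages) {
    run_stage("association", function() {
      drivers <- intersect(c("TP53", "RB1", "STK11", "KEAP1"),
                           gene_models$gene)
      bial <- call_biallelic_status(mutations, drivers,
                                    unique(mutations$sample_id))
      emit(bial$matrix, "alteration_matrix.tsv")
      types <- assign_lcnec_type(bial$matrix)
      emit(types, "lcnec_types.tsv")
      me <- test_mutual_exclusivity(bial$matrix, c("STK11", "KEAP1"),
                                    "RB1")
      emit(tibble(comparison = "STK11/KEAP1 vs RB1",
                  overlap = me$overlap, p = me$p),
           "mutual_exclusivity.tsv")
      thr <- global_expression_threshold(expr_uq)
      ne <- suppressWarnings(classify_neuroendocrine_level(expr_uq, thr))
      emit(ne$profiles, "ne_profiles.tsv")
    })
  }

  yaml::write_yaml(unclass(config)[c("inputs", "out_dir", "seed",
                                     "stages", "params")],
                   file.path(config$out_dir, "run_config.yaml"))
  outputs <- c(outputs, file.path(config$out_dir, "run_config.yaml"))
  manifest <- tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs))
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"),
                   progress = FALSE)
  manifest
}
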