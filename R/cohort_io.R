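#' @section File conventions:
#' All tables are UTF-8, tab-delimited text with a header line; lines starting
#' with `#` are skipped.  Genomic coordinates are 1-based and fully closed
#' (MAF/SEG convention).
#' @name cohort-io
NULL

consequence_levels <- c(
  "synonymous", "missense", "nonsense", "splice_site",
  "frameshift", "inframe_indel", "other"
)

nonsynonymous_levels <- setdiff(consequence_levels, "synonymous")

# common annotation spellings mapped onto the internal consequence vocabulary
consequence_aliases <- c(
  "silent" = "synonymous", "synonymous_variant" = "synonymous",
  "missense_mutation" = "missense", "missense_variant" = "missense",
  "nonsense_mutation" = "nonsense", "stop_gained" = "nonsense",
  "splice_site" = "splice_site", "splice_acceptor_variant" = "splice_site",
  "splice_donor_variant" = "splice_site",
  "frame_shift_del" = "frameshift", "frame_shift_ins" = "frameshift",
  "frameshift_variant" = "frameshift",
  "in_frame_del" = "inframe_indel", "in_frame_ins" = "inframe_indel",
  "inframe_deletion" = "inframe_indel", "inframe_insertion" = "inframe_indel"
)

mutation_fields <- c(
  "sample_id", "gene", "chrom", "pos", "ref_allele", "alt_allele",
  "context5", "context3", "consequence", "alt_count", "depth"
)

#' Column dialect for somatic mutation tables
#'
#' Maps the columns of an on-disk mutation table onto the internal field
#' names, so both MAF exports and in-house TSVs load through the same reader.
#' The default mapping is the identity over the internal names;
#' [maf_dialect()] mirrors standard MAF column headers.
#'
#' @param ... Named overrides, `internal_field = "column name in file"`.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_mutation_table()].
#' @export
mutation_dialect <- function(...) {
  dialect <- setNames(mutation_fields, mutation_fields)
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), mutation_fields)
    if (length(bad)) {
      abort(paste0("unknown mutation fields in dialect: ", toString(bad)))
    }
    dialect[names(overrides)] <- overrides
  }
  dialect
}

#' @rdname mutation_dialect
#' @export
maf_dialect <- function() {
  mutation_dialect(
    sample_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
    chrom = "Chromosome", pos = "Start_Position",
    ref_allele = "Reference_Allele", alt_allele = "Tumor_Seq_Allele2",
    consequence = "Variant_Classification",
    alt_count = "t_alt_count", depth = "t_depth"
  )
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read a somatic mutation table
#'
#' Parses a MAF-like TSV into the internal mutation tibble.  Consequence
#' strings are normalized onto the internal vocabulary (`synonymous`,
#' `missense`, `nonsense`, `splice_site`, `frameshift`, `inframe_indel`,
#' `other`); unrecognized strings become `other`.  Rows violating the record
#' invariants (equal ref/alt alleles, non-ACGT alleles, `pos < 1`,
#' `alt_count > depth`) raise an error naming the offending rows.
#'
#' @param path Path to a tab-delimited file with a header.
#' @param dialect Column mapping from [mutation_dialect()] or [maf_dialect()].
#' @return A tibble with one row per somatic mutation and columns
#'   `sample_id`, `gene`, `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `context5`, `context3`, `consequence`, `alt_count`, `depth`.
#' @export
read_mutation_table <- function(path, dialect = mutation_dialect()) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  required <- setdiff(mutation_fields, c("context5", "context3"))
  missing_cols <- setdiff(unname(dialect[required]), names(raw))
  if (length(missing_cols)) {
    abort(paste0("mutation table is missing required column(s): ",
                 toString(missing_cols)))
  }
  present <- dialect[dialect %in% names(raw)]
  tbl <- raw |>
    select(all_of(unname(present))) |>
    rlang::set_names(names(present))
  for (fld in setdiff(c("context5", "context3"), names(tbl))) {
    tbl[[fld]] <- NA_character_
  }
  tbl <- tbl |>
    mutate(
      pos = as.integer(.data$pos),
      alt_count = as.integer(.data$alt_count),
      depth = as.integer(.data$depth),
      consequence = normalize_consequence(.data$consequence),
      ref_allele = toupper(.data$ref_allele),
      alt_allele = toupper(.data$alt_allele)
    ) |>
    select(all_of(mutation_fields))
  validate_mutations(tbl)
  tbl
}

normalize_consequence <- function(x) {
  key <- tolower(trimws(x))
  out <- ifelse(key %in% consequence_levels, key,
                unname(consequence_aliases[key]))
  out[is.na(out)] <- "other"
  out
}

validate_mutations <- function(tbl, allow_indels = TRUE) {
  allele_ok <- function(a) grepl("^[ACGT]+$", a) | (allow_indels & a == "-")
  problems <- character(0)
  flag <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      problems <<- c(problems, paste0(what, " in row(s) ",
                                      toString(head(rows, 10))))
    }
  }
  flag(!allele_ok(tbl$ref_allele) | !allele_ok(tbl$alt_allele),
       "non-ACGT allele")
  flag(tbl$ref_allele == tbl$alt_allele, "ref_allele equals alt_allele")
  flag(is.na(tbl$pos) | tbl$pos < 1, "position < 1")
  flag(is.na(tbl$alt_count) | tbl$alt_count < 0, "negative alt_count")
  flag(is.na(tbl$depth) | tbl$depth < tbl$alt_count, "depth < alt_count")
  if (length(problems)) {
    abort(paste0("invalid mutation record(s): ",
                 paste(problems, collapse = "; ")))
  }
  invisible(tbl)
}

#' Write a somatic mutation table
#'
#' @param mutations Mutation tibble as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  readr::write_tsv(mutations[, mutation_fields], path, progress = FALSE)
  invisible(path)
}

#' Read segmented copy-number profiles
#'
#' Reads a SEG-like TSV of per-sample genomic segments with raw tumor/normal
#' copy-number ratios.  Ratios given on the log2 scale are converted and
#' always stored on the linear scale.  Output rows are sorted by
#' `(sample_id, chrom, start)`; overlapping segments within a sample are kept
#' with a warning.
#'
#' @param path Path to a TSV with columns `sample_id`, `chrom`, `start`,
#'   `end`, `n_markers` and a ratio column.
#' @param scale `"auto"` uses the column name (`log2_ratio` vs `ratio`);
#'   `"log2"` or `"linear"` force the interpretation of the ratio column.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_markers`, `ratio` (linear scale).
#' @export
read_segments <- function(path, scale = c("auto", "log2", "linear")) {
  scale <- match.arg(scale)
  tbl <- read_tsv_quiet(path)
  ratio_col <- intersect(c("log2_ratio", "ratio"), names(tbl))
  required <- c("sample_id", "chrom", "start", "end", "n_markers")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) || !length(ratio_col)) {
    abort(paste0("segment table is missing required column(s): ",
                 toString(c(missing_cols,
                            if (!length(ratio_col)) "ratio/log2_ratio"))))
  }
  ratio_col <- ratio_col[[1]]
  is_log2 <- switch(scale,
    auto = ratio_col == "log2_ratio",
    log2 = TRUE,
    linear = FALSE
  )
  out <- tbl |>
    mutate(
      start = as.integer(.data$start), end = as.integer(.data$end),
      n_markers = as.integer(.data$n_markers),
      ratio = if (is_log2) 2^.data[[ratio_col]] else .data[[ratio_col]]
    ) |>
    select("sample_id", "chrom", "start", "end", "n_markers", "ratio")
  if (any(out$start > out$end)) {
    abort(paste0("segment start > end in row(s) ",
                 toString(head(which(out$start > out$end), 10))))
  }
  if (any(out$ratio <= 0, na.rm = TRUE)) {
    abort("segment ratios must be positive on the linear scale")
  }
  out <- arrange(out, .data$sample_id, .data$chrom, .data$start)
  overlap <- out |>
    group_by(.data$sample_id, .data$chrom) |>
    summarise(any_overlap = any(.data$start[-1] <= head(.data$end, -1)),
              .groups = "drop")
  if (any(overlap$any_overlap, na.rm = TRUE)) {
    warn("overlapping segments within a sample; kept as-is")
  }
  out
}

#' @rdname read_segments
#' @param segments Segment tibble (linear-scale ratios).
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(
    segments[, c("sample_id", "chrom", "start", "end", "n_markers", "ratio")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' Genes are rows, samples are columns; the first column holds the gene
#' identifier.  The result is a tibble whose normalization state is tracked
#' in the `expr_state` attribute (starting at `"raw_counts"`).
#'
#' @param path Path to a TSV matrix.
#' @return A tibble with a `gene` column plus one numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  tbl <- read_tsv_quiet(path)
  if (nrow(tbl) == 0) {
    abort("expression matrix has no data rows")
  }
  names(tbl)[1] <- "gene"
  tbl$gene <- as.character(tbl$gene)
  dup <- unique(tbl$gene[duplicated(tbl$gene)])
  if (length(dup)) {
    abort(paste0("duplicate gene identifier(s): ", toString(head(dup, 10))))
  }
  if (anyDuplicated(names(tbl))) {
    abort("duplicate sample identifiers in expression matrix")
  }
  vals <- as.matrix(tbl[, -1])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    abort("expression matrix contains non-numeric or missing entries")
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(paste0("negative expression value for gene ", tbl$gene[neg[1, 1]],
                 " in sample ", colnames(vals)[neg[1, 2]]))
  }
  out <- bind_cols(tibble(gene = tbl$gene), as_tibble(vals))
  expr_state(out) <- "raw_counts"
  out
}

#' @rdname read_expression_matrix
#' @param expr Expression tibble.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Normalization state of an expression tibble
#'
#' One of `"raw_counts"`, `"uq_normalized"`, `"log2"`, `"median_centered"`.
#'
#' @param expr Expression tibble.
#' @export
expr_state <- function(expr) {
  attr(expr, "expr_state") %||% "raw_counts"
}

#' @rdname expr_state
#' @param value New state string.
#' @export
`expr_state<-` <- function(expr, value) {
  stopifnot(value %in% c("raw_counts", "uq_normalized", "log2",
                         "median_centered"))
  attr(expr, "expr_state") <- value
  expr
}

# expression tibble -> numeric matrix with gene rownames
expr_to_matrix <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

matrix_to_expr <- function(m, state) {
  out <- bind_cols(tibble(gene = rownames(m)), as_tibble(m))
  expr_state(out) <- state
  out
}

#' Read and write sample annotations
#'
#' @param path Path to a TSV with at least a `sample_id` column; `histology`
#'   (LCNEC, SCLC, ADC, SqCC, carcinoid) and free-text `stage` / `smoking` /
#'   `combined_component` columns are carried through when present.
#' @return A tibble of per-sample annotations.
#' @export
read_sample_annotations <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (!"sample_id" %in% names(tbl)) {
    abort("sample annotation table is missing required column(s): sample_id")
  }
  if (anyDuplicated(tbl$sample_id)) {
    abort("duplicate sample_id in annotation table")
  }
  if ("histology" %in% names(tbl)) {
    known <- c("LCNEC", "SCLC", "ADC", "SqCC", "carcinoid")
    bad <- setdiff(unique(tbl$histology), c(known, NA))
    if (length(bad)) {
      abort(paste0("unknown histology value(s): ", toString(bad)))
    }
  }
  tbl
}

#' @rdname read_sample_annotations
#' @param annotations Annotation tibble.
#' @export
write_sample_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}
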