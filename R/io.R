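# On-disk formats. All tables are plain TSV; the signature model is a
# versioned JSON document so frozen classifiers stay diffable.

SIGNATURE_SCHEMA_VERSION <- "1.0"

read_tsv_strict <- function(path, col_types = NULL) {
  out <- readr::read_tsv(
    path,
    col_types = col_types %||% readr::cols(.default = readr::col_guess()),
    na = c("", "NA"),
    show_col_types = FALSE,
    name_repair = "minimal",
    progress = FALSE
  )
  probs <- readr::problems(out)
  ragged <- probs[grepl("columns", probs$expected), , drop = FALSE]
  if (nrow(ragged) > 0L) {
    abort(sprintf(
      "malformed file %s: ragged row at line %d (expected %s, got %s)",
      path, ragged$row[1L], ragged$expected[1L], ragged$actual[1L]
    ))
  }
  out
}

#' Read / write a log-ratio expression matrix
#'
#' Expression data are stored as TSV with one identifier column and one header
#' row. The default orientation puts samples in rows and genes in columns
#' (identifier column `sample_id`); `orientation = "genes_in_rows"` reads the
#' transposed layout (identifier column `gene_id`) and transposes it back.
#' Non-numeric cells are parsed as missing (`NA`); missing values are allowed
#' at read time and must be resolved by [impute_missing()] before analysis.
#'
#' @param path File path.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per gene.
#' @export
read_expression <- function(path,
                            orientation = c("samples_in_rows", "genes_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- read_tsv_strict(path)
  if (ncol(raw) < 2L) abort(sprintf("malformed header in %s: need an id column and at least one data column", path))
  id_col <- names(raw)[1L]
  value_cols <- names(raw)[-1L]
  if (anyDuplicated(value_cols)) {
    abort(sprintf(
      "duplicate %s id(s) in %s: %s",
      if (orientation == "samples_in_rows") "gene" else "sample", path,
      paste(unique(value_cols[duplicated(value_cols)]), collapse = ", ")
    ))
  }
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate %s id(s) in %s: %s",
      if (orientation == "samples_in_rows") "sample" else "gene", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.double(as.character(col)), double(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, value_cols))
  if (orientation == "genes_in_rows") vals <- t(vals)
  matrix_to_expr(vals)
}

#' @rdname read_expression
#' @param expr Wide expression tibble (`sample_id` + gene columns).
#' @export
write_expression <- function(expr, path) {
  expr_to_matrix(expr, require_finite = FALSE) # validates ids
  readr::write_tsv(expr, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a per-sample clinical annotation table
#'
#' Columns: `sample_id`, `msi_hospital` (MSI / MSS / MSI-L / unknown),
#' `stage` (I-IV / unknown), `braf` (mutant / wildtype / unknown),
#' `dmfs_years` (non-negative, may be missing) and `dmfs_event` (0/1, present
#' exactly when `dmfs_years` is). Low-grade instability (MSI-L) is kept
#' distinct on disk but is mapped to MSS by [hospital_msi_binary()] for every
#' analysis.
#'
#' @param path File path.
#' @return A validated clinical tibble.
#' @export
read_clinical <- function(path) {
  tab <- read_tsv_strict(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    msi_hospital = readr::col_character(),
    stage = readr::col_character(),
    braf = readr::col_character(),
    dmfs_years = readr::col_double(),
    dmfs_event = readr::col_integer()
  ))
  validate_clinical(tab)
}

validate_clinical <- function(tab) {
  required <- c("sample_id", "msi_hospital", "stage", "braf",
                "dmfs_years", "dmfs_event")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("clinical table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tab$sample_id)) {
    abort(paste0(
      "duplicate sample id(s) in clinical table: ",
      paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", ")
    ))
  }
  hospital_msi_binary(tab$msi_hospital) # validates the enum
  bad_stage <- !tab$stage %in% c("I", "II", "III", "IV", "unknown")
  if (any(bad_stage)) abort("invalid stage value(s) in clinical table")
  bad_braf <- !tab$braf %in% c("mutant", "wildtype", "unknown")
  if (any(bad_braf)) abort("invalid braf value(s) in clinical table")
  if (any(!is.na(tab$dmfs_years) & tab$dmfs_years < 0)) {
    abort("dmfs_years must be non-negative")
  }
  if (any(xor(is.na(tab$dmfs_years), is.na(tab$dmfs_event)))) {
    abort("dmfs_event must be present exactly when dmfs_years is")
  }
  if (any(!is.na(tab$dmfs_event) & !tab$dmfs_event %in% c(0L, 1L))) {
    abort("dmfs_event must be 0 or 1")
  }
  as_tibble(tab)
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  readr::write_tsv(clinical, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a candidate-variant table
#'
#' One row per candidate variant with the fields the inclusion filters need:
#' `sample_id`, `gene_id`, `position`, `coverage`, `variant_count`,
#' `fwd_variant_count`, `rev_variant_count`, `consequence` (`coding_change` /
#' `other`) and `in_normal_panel` (germline/artefact flag from the
#' normal-sample panel). Strand counts must sum to `variant_count` and
#' `variant_count` cannot exceed `coverage`; offending records are reported
#' by row. An empty file yields an empty table, not an error.
#'
#' @param path File path.
#' @return A validated variant tibble.
#' @export
read_variants <- function(path) {
  if (file.size(path) == 0L) return(empty_variant_table())
  tab <- read_tsv_strict(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    gene_id = readr::col_character(),
    position = readr::col_integer(),
    coverage = readr::col_integer(),
    variant_count = readr::col_integer(),
    fwd_variant_count = readr::col_integer(),
    rev_variant_count = readr::col_integer(),
    consequence = readr::col_character(),
    in_normal_panel = readr::col_logical()
  ))
  validate_variants(tab)
}

empty_variant_table <- function() {
  tibble(
    sample_id = character(), gene_id = character(), position = integer(),
    coverage = integer(), variant_count = integer(),
    fwd_variant_count = integer(), rev_variant_count = integer(),
    consequence = character(), in_normal_panel = logical()
  )
}

validate_variants <- function(tab) {
  required <- names(empty_variant_table())
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("variant table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- tab[c("coverage", "variant_count",
                  "fwd_variant_count", "rev_variant_count")]
  if (any(vapply(counts, function(x) any(!is.na(x) & x < 0), logical(1L)))) {
    abort("variant counts and coverage must be non-negative")
  }
  bad_sum <- which(tab$fwd_variant_count + tab$rev_variant_count !=
                     tab$variant_count)
  if (length(bad_sum)) {
    abort(sprintf(
      "record %d: strand counts (%d + %d) do not sum to variant_count (%d)",
      bad_sum[1L], tab$fwd_variant_count[bad_sum[1L]],
      tab$rev_variant_count[bad_sum[1L]], tab$variant_count[bad_sum[1L]]
    ))
  }
  bad_cov <- which(tab$variant_count > tab$coverage)
  if (length(bad_cov)) {
    abort(sprintf(
      "record %d: variant_count (%d) exceeds coverage (%d)",
      bad_cov[1L], tab$variant_count[bad_cov[1L]], tab$coverage[bad_cov[1L]]
    ))
  }
  if (any(!tab$consequence %in% c("coding_change", "other"))) {
    abort("consequence must be 'coding_change' or 'other'")
  }
  as_tibble(tab)
}

#' @rdname read_variants
#' @param variants Variant tibble.
#' @export
write_variants <- function(variants, path) {
  validate_variants(variants)
  readr::write_tsv(variants, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a frozen MSI signature model
#'
#' Signature models are serialised as versioned JSON (schema
#' `msisig_signature`, version 1.0) holding the gene list, both centroids at
#' full double precision, the two thresholds, the staleness flag and
#' provenance. Round-trips are exact on the binary doubles' printed
#' representation (17 significant digits).
#'
#' @param path File path.
#' @return An [msi_signature()].
#' @export
read_signature <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || doc$schema != "msisig_signature") {
    abort(sprintf("%s is not a signature file (missing schema tag)", path))
  }
  msi_signature(
    gene_ids = doc$gene_ids,
    centroid_msi = doc$centroid_msi,
    centroid_mss = doc$centroid_mss,
    threshold_primary = doc$threshold_primary %||% NA_real_,
    threshold_secondary = doc$threshold_secondary %||% NA_real_,
    thresholds_stale = isTRUE(doc$thresholds_stale),
    provenance = as.list(doc$provenance)
  )
}

#' @rdname read_signature
#' @param model An `msi_signature`.
#' @export
write_signature <- function(model, path) {
  validate_msi_signature(model)
  doc <- list(
    schema = "msisig_signature",
    schema_version = SIGNATURE_SCHEMA_VERSION,
    gene_ids = model$gene_ids,
    centroid_msi = model$centroid_msi,
    centroid_mss = model$centroid_mss,
    threshold_primary = model$threshold_primary,
    threshold_secondary = model$threshold_secondary,
    thresholds_stale = model$thresholds_stale,
    provenance = model$provenance
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}
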