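# Internal helpers shared across modules.

# Valid three-way signature calls, ordered MSS < MSI-like < MSI.
CALL_LEVELS <- c("MSS", "MSI_LIKE", "MSI")

# Hospital MSI status levels as stored; MSI-L maps to MSS for analysis.
HOSPITAL_LEVELS <- c("MSI", "MSS", "MSI-L", "unknown")

#' Map hospital MSI status to the binary reference label
#'
#' Hospital assessment distinguishes MSI, MSS and low-grade instability
#' (MSI-L). For every analysis MSI-L counts as MSS, so the binary reference is
#' `TRUE` only for hospital MSI. `unknown` and `NA` become `NA`.
#'
#' @param msi_hospital Character vector with values among
#'   `"MSI"`, `"MSS"`, `"MSI-L"`, `"unknown"` (or `NA`).
#' @return Logical vector: `TRUE` = hospital MSI, `FALSE` = MSS (incl. MSI-L),
#'   `NA` = unknown.
#' @export
#' @examples
#' hospital_msi_binary(c("MSI", "MSS", "MSI-L", "unknown"))
hospital_msi_binary <- function(msi_hospital) {
  bad <- !is.na(msi_hospital) & !msi_hospital %in% HOSPITAL_LEVELS
  if (any(bad)) {
    abort(paste0(
      "invalid hospital MSI status value(s): ",
      paste(unique(msi_hospital[bad]), collapse = ", ")
    ))
  }
  out <- rep(NA, length(msi_hospital))
  out[msi_hospital %in% c("MSS", "MSI-L")] <- FALSE
  out[msi_hospital %in% "MSI"] <- TRUE
  out
}

# Convert a wide expression tibble (sample_id + one column per gene) to a
# numeric matrix with sample_id rownames. Validates as it goes.
expr_to_matrix <- function(expr, require_finite = TRUE) {
  stopifnot(is.data.frame(expr))
  if (!"sample_id" %in% names(expr)) {
    abort("expression table must have a `sample_id` column")
  }
  ids <- as.character(expr$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate sample id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  genes <- setdiff(names(expr), "sample_id")
  if (anyDuplicated(genes)) {
    abort(paste0(
      "duplicate gene id(s): ",
      paste(unique(genes[duplicated(genes)]), collapse = ", ")
    ))
  }
  m <- as.matrix(expr[genes])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- ids
  if (require_finite && anyNA(m)) {
    abort("expression matrix contains missing values; impute first")
  }
  if (require_finite && any(!is.finite(m))) {
    abort("expression matrix contains non-finite values")
  }
  m
}

# Inverse of expr_to_matrix.
matrix_to_expr <- function(m) {
  tibble(sample_id = rownames(m)) |>
    dplyr::bind_cols(as_tibble(m))
}

# Align a labels tibble (sample_id, msi logical) to the rows of an expression
# matrix; errors on missing or unknown samples.
align_labels <- function(m, labels) {
  stopifnot(is.data.frame(labels))
  if (!all(c("sample_id", "msi") %in% names(labels))) {
    abort("labels must have columns `sample_id` and `msi` (logical)")
  }
  if (anyDuplicated(labels$sample_id)) abort("duplicate sample ids in labels")
  idx <- match(rownames(m), labels$sample_id)
  if (anyNA(idx)) {
    abort(paste0(
      "labels missing for sample(s): ",
      paste(head(rownames(m)[is.na(idx)], 5L), collapse = ", ")
    ))
  }
  lab <- as.logical(labels$msi[idx])
  if (anyNA(lab)) abort("labels contain NA for samples present in the matrix")
  lab
}

# Resolve a column (or expression over columns) from a data frame by
# tidy-eval, with type check.
pull_numeric <- function(data, col, what) {
  v <- rlang::eval_tidy(rlang::enquo(col), data)
  if (!is.numeric(v)) abort(paste0(what, " must be numeric"))
  v
}

pull_logical <- function(data, col, what) {
  v <- rlang::eval_tidy(rlang::enquo(col), data)
  if (is.factor(v) || is.character(v)) {
    abort(paste0(what, " must be logical (TRUE = positive class)"))
  }
  as.logical(v)
}
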