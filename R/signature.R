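#' Construct an MSI signature model
#'
#' An `msi_signature` bundles everything needed to score a new sample: the
#' ordered signature gene list, the MSI and MSS class centroids (per-gene mean
#' log-ratios over the respective training classes, aligned to the gene list),
#' and the two decision thresholds on the MSI index. Samples with index below
#' `threshold_primary` are called MSS; at or above `threshold_secondary`, MSI;
#' in between, MSI-like. Thresholds may be `NA` for a model whose cut-offs
#' have not yet been optimised.
#'
#' @param gene_ids Character vector of unique gene identifiers (development
#'   signatures use 64 genes, but any size is accepted).
#' @param centroid_msi,centroid_mss Numeric vectors aligned to `gene_ids`.
#' @param threshold_primary,threshold_secondary Index thresholds
#'   (`threshold_secondary >= threshold_primary`), or `NA` if unset.
#' @param thresholds_stale Logical; `TRUE` marks thresholds that were
#'   optimised for a different gene set (e.g. before platform reduction) and
#'   must be re-optimised before classification.
#' @param provenance Named list of free-form metadata (training cohort id,
#'   seed, date, dropped genes, ...).
#' @return An object of class `msi_signature`.
#' @seealso [build_centroids()], [classify_samples()], [read_signature()]
#' @export
msi_signature <- function(gene_ids, centroid_msi, centroid_mss,
                          threshold_primary = NA_real_,
                          threshold_secondary = NA_real_,
                          thresholds_stale = FALSE,
                          provenance = list()) {
  x <- structure(
    list(
      gene_ids = as.character(gene_ids),
      centroid_msi = as.double(centroid_msi),
      centroid_mss = as.double(centroid_mss),
      threshold_primary = as.double(threshold_primary),
      threshold_secondary = as.double(threshold_secondary),
      thresholds_stale = isTRUE(thresholds_stale),
      provenance = provenance
    ),
    class = "msi_signature"
  )
  validate_msi_signature(x)
}

validate_msi_signature <- function(x) {
  n <- length(x$gene_ids)
  if (n == 0L) abort("signature must contain at least one gene")
  if (anyDuplicated(x$gene_ids)) {
    abort(paste0(
      "duplicate signature gene id(s): ",
      paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", ")
    ))
  }
  if (length(x$centroid_msi) != n || length(x$centroid_mss) != n) {
    abort(sprintf(
      "centroid length mismatch: %d genes but centroids of length %d and %d",
      n, length(x$centroid_msi), length(x$centroid_mss)
    ))
  }
  if (anyNA(x$centroid_msi) || anyNA(x$centroid_mss)) {
    abort("centroids must not contain missing values")
  }
  tp <- x$threshold_primary
  ts <- x$threshold_secondary
  if (length(tp) != 1L || length(ts) != 1L) {
    abort("thresholds must be scalars")
  }
  if (!is.na(tp) && !is.na(ts) && ts < tp) {
    abort(sprintf(
      "threshold_secondary (%g) must be >= threshold_primary (%g)", ts, tp
    ))
  }
  x
}

has_thresholds <- function(model) {
  !is.na(model$threshold_primary) && !is.na(model$threshold_secondary)
}

#' @export
print.msi_signature <- function(x, ...) {
  cat(sprintf("<msi_signature> %d genes\n", length(x$gene_ids)))
  cat(sprintf(
    "  thresholds: primary %s, secondary %s%s\n",
    format(x$threshold_primary), format(x$threshold_secondary),
    if (x$thresholds_stale) " [stale - re-optimise]" else ""
  ))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an MSI signature into its per-gene centroid table
#'
#' @param x An `msi_signature`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `centroid_msi`, `centroid_mss`.
#' @method tidy msi_signature
#' @export
tidy.msi_signature <- function(x, ...) {
  tibble(
    gene_id = x$gene_ids,
    centroid_msi = x$centroid_msi,
    centroid_mss = x$centroid_mss
  )
}

#' One-row summary of an MSI signature model
#'
#' @param x An `msi_signature`.
#' @param ... Unused.
#' @return A one-row tibble: gene count, thresholds, staleness flag.
#' @method glance msi_signature
#' @export
glance.msi_signature <- function(x, ...) {
  tibble(
    n_genes = length(x$gene_ids),
    threshold_primary = x$threshold_primary,
    threshold_secondary = x$threshold_secondary,
    thresholds_stale = x$thresholds_stale
  )
}
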