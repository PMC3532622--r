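# Nearest-centroid classification. The MSI index of a sample is the cosine
# correlation of its signature-gene profile with the MSI centroid minus the
# cosine correlation with the MSS centroid; two thresholds split the index
# into MSS / MSI-like / MSI.

#' Build class centroids over a signature gene list
#'
#' Each centroid is the per-gene arithmetic mean log-ratio over the samples
#' of one class, restricted and ordered to `gene_list`. The returned model
#' has no thresholds yet; optimise them with [optimize_thresholds()].
#'
#' @inheritParams ttest_rank
#' @param gene_list Character vector of signature genes; all must be present
#'   in `expr`.
#' @param provenance Optional named list stored in the model.
#' @return An [msi_signature()] with `NA` thresholds.
#' @export
build_centroids <- function(expr, labels, gene_list, provenance = list()) {
  m <- expr_to_matrix(expr)
  lab <- align_labels(m, labels)
  if (!any(lab) || all(lab)) {
    abort("both classes must be present to build centroids")
  }
  gene_list <- as.character(gene_list)
  absent <- setdiff(gene_list, colnames(m))
  if (length(absent)) {
    abort(paste0("gene(s) absent from the expression matrix: ",
                 paste(absent, collapse = ", ")))
  }
  sub <- m[, gene_list, drop = FALSE]
  msi_signature(
    gene_ids = gene_list,
    centroid_msi = colMeans(sub[lab, , drop = FALSE]),
    centroid_mss = colMeans(sub[!lab, , drop = FALSE]),
    provenance = provenance
  )
}

cosine_sim <- function(x, c, centered = FALSE) {
  if (centered) {
    x <- x - mean(x)
    c <- c - mean(c)
  }
  nx <- sqrt(sum(x^2))
  nc <- sqrt(sum(c^2))
  if (nx == 0 || nc == 0) abort("cosine similarity undefined for a zero-norm vector")
  sum(x * c) / (nx * nc)
}

#' Compute the MSI index for each sample
#'
#' For every sample, the signature-gene profile is compared with the MSI and
#' MSS centroids by cosine correlation (uncentred cosine similarity on
#' log-ratio vectors; `centered = TRUE` gives Pearson correlation instead,
#' for the reading of "cosine correlation" that centres first). The MSI
#' index is the difference `corr_msi - corr_mss`, bounded in \[-2, 2\].
#'
#' @inheritParams ttest_rank
#' @param model An [msi_signature()]; all its genes must be in `expr`.
#' @param centered Use Pearson (centred) correlation instead of cosine
#'   similarity. Default `FALSE`.
#' @return A tibble `sample_id`, `corr_msi`, `corr_mss`, `index`.
#' @export
msi_index <- function(expr, model, centered = FALSE) {
  m <- expr_to_matrix(expr)
  absent <- setdiff(model$gene_ids, colnames(m))
  if (length(absent)) {
    abort(paste0("signature gene(s) absent from the expression matrix: ",
                 paste(absent, collapse = ", ")))
  }
  x <- m[, model$gene_ids, drop = FALSE]
  c_msi <- model$centroid_msi
  c_mss <- model$centroid_mss
  if (centered) {
    x <- x - rowMeans(x)
    c_msi <- c_msi - mean(c_msi)
    c_mss <- c_mss - mean(c_mss)
  }
  row_norm <- sqrt(rowSums(x^2))
  n_msi <- sqrt(sum(c_msi^2))
  n_mss <- sqrt(sum(c_mss^2))
  if (any(row_norm == 0) || n_msi == 0 || n_mss == 0) {
    abort("cosine similarity undefined for a zero-norm vector")
  }
  corr_msi <- unname(as.vector(x %*% c_msi) / (row_norm * n_msi))
  corr_mss <- unname(as.vector(x %*% c_mss) / (row_norm * n_mss))
  tibble(
    sample_id = rownames(m),
    corr_msi = corr_msi,
    corr_mss = corr_mss,
    index = corr_msi - corr_mss
  )
}

#' Three-way MSS / MSI-like / MSI call from the index
#'
#' A sample whose index reaches `threshold_primary` is signature-positive;
#' among positives, those at or above `threshold_secondary` are MSI and the
#' rest MSI-like. Both boundaries are inclusive upwards ("exceeds" is
#' implemented as `>=`), a convention frozen in the signature file.
#'
#' @param index Numeric vector of MSI indices.
#' @param model An [msi_signature()] with both thresholds set and not stale.
#' @return Factor with levels `MSS`, `MSI_LIKE`, `MSI`.
#' @export
classify_index <- function(index, model) {
  if (!has_thresholds(model)) {
    abort("model thresholds are unset; optimise thresholds first")
  }
  if (model$thresholds_stale) {
    abort("model thresholds are stale (platform reduction); re-optimise before classifying")
  }
  call <- ifelse(index >= model$threshold_secondary, "MSI",
                 ifelse(index >= model$threshold_primary, "MSI_LIKE", "MSS"))
  factor(call, levels = CALL_LEVELS)
}

#' Score and classify an expression cohort
#'
#' Convenience wrapper: [msi_index()] followed by [classify_index()], with a
#' binary `signature_positive` column (any non-MSS call).
#'
#' @inheritParams msi_index
#' @return Tibble `sample_id`, `corr_msi`, `corr_mss`, `index`, `call`,
#'   `signature_positive`.
#' @export
classify_samples <- function(expr, model, centered = FALSE) {
  scores <- msi_index(expr, model, centered = centered)
  scores |>
    mutate(
      call = classify_index(.data$index, model),
      signature_positive = .data$call != "MSS"
    )
}

#' Restrict a signature to the genes available on another platform
#'
#' Cross-platform read-out drops signature genes the target platform does not
#' measure (the study retained 58 of 64 genes on its FFPE platform). The
#' model is restricted to the intersection, preserving centroid order; the
#' dropped genes are recorded in provenance and the thresholds are flagged
#' stale, because the index distribution shifts with dimension — they must be
#' re-optimised on a calibration set before classification.
#'
#' @param model An [msi_signature()].
#' @param available_genes Character vector of genes measurable on the target
#'   platform.
#' @param min_genes Minimum surviving signature size (default 50).
#' @return A reduced [msi_signature()] with `thresholds_stale = TRUE` (unless
#'   nothing was dropped).
#' @export
reduce_to_platform <- function(model, available_genes, min_genes = 50L) {
  keep <- model$gene_ids %in% available_genes
  if (sum(keep) < min_genes) {
    abort(sprintf(
      "only %d of %d signature genes available; below the floor of %d",
      sum(keep), length(model$gene_ids), min_genes
    ))
  }
  dropped <- model$gene_ids[!keep]
  if (length(dropped) == 0L) {
    model$provenance$platform_reduction <- "none (all genes available)"
    return(model)
  }
  msi_signature(
    gene_ids = model$gene_ids[keep],
    centroid_msi = model$centroid_msi[keep],
    centroid_mss = model$centroid_mss[keep],
    threshold_primary = model$threshold_primary,
    threshold_secondary = model$threshold_secondary,
    thresholds_stale = TRUE,
    provenance = c(model$provenance, list(dropped_genes = dropped))
  )
}

#' Re-optimised thresholds for a (possibly reduced) model
#'
#' Sets `threshold_primary` / `threshold_secondary` on a model and clears the
#' staleness flag. Usually called via [optimize_thresholds()].
#'
#' @param model An [msi_signature()].
#' @param primary,secondary New thresholds (`secondary >= primary`).
#' @return The updated model.
#' @export
set_thresholds <- function(model, primary, secondary) {
  model$threshold_primary <- as.double(primary)
  model$threshold_secondary <- as.double(secondary)
  model$thresholds_stale <- FALSE
  validate_msi_signature(model)
}
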