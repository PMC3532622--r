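# Two-channel normalisation: intensity-dependent dye bias is removed per
# array by subtracting a lowess fit of M on A, the standard MA-plot
# correction for common-reference two-colour designs.

#' Lowess-normalise one two-channel array
#'
#' Computes per-gene log-ratios `M = log2(sample / reference)` and average
#' intensities `A = 0.5 * log2(sample * reference)`, fits a locally weighted
#' regression (lowess) of M on A, and returns the residual `M - fit(A)` as
#' the normalised log-ratio. Normalisation is per array: each sample is
#' hybridised against the common reference and corrected independently.
#'
#' @param array A tibble with columns `gene_id`, `sample_intensity`,
#'   `reference_intensity` (strictly positive).
#' @param span Lowess smoother span in (0, 1]; fraction of genes in each
#'   local window. Default 0.3.
#' @param iterations Robustness iterations of the lowess fit. Default 3.
#' @return A tibble `gene_id`, `A`, `M`, `M_normalized`.
#' @export
#' @examples
#' arr <- tibble::tibble(
#'   gene_id = paste0("g", 1:100),
#'   sample_intensity = exp(rnorm(100, 6)),
#'   reference_intensity = exp(rnorm(100, 6))
#' )
#' lowess_normalize(arr)
lowess_normalize <- function(array, span = 0.3, iterations = 3L) {
  stopifnot(is.data.frame(array))
  req <- c("gene_id", "sample_intensity", "reference_intensity")
  if (!all(req %in% names(array))) {
    abort(paste0("array must have columns: ", paste(req, collapse = ", ")))
  }
  if (!(is.numeric(span) && length(span) == 1L && span > 0 && span <= 1)) {
    abort("span must be a single number in (0, 1]")
  }
  s <- array$sample_intensity
  r <- array$reference_intensity
  if (any(!is.finite(s)) || any(!is.finite(r)) || any(s <= 0) || any(r <= 0)) {
    abort("intensities must be finite and strictly positive")
  }
  if (length(s) < 50L) {
    abort("need at least 50 genes for a stable lowess fit")
  }
  M <- log2(s / r)
  A <- 0.5 * log2(s * r)
  fit <- lowess(A, M, f = span, iter = iterations)
  # lowess returns the fit at sorted x; map back to the input order
  trend <- approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  tibble(
    gene_id = as.character(array$gene_id),
    A = A,
    M = M,
    M_normalized = M - trend
  )
}

#' Impute missing expression values by per-gene mean
#'
#' Residual missing values after normalisation are replaced by the mean of
#' the observed values for the same gene across samples. Genes missing in
#' more than `max_missing_fraction` of samples (or missing everywhere) are an
#' error: too little observed signal to impute from.
#'
#' @param expr Wide expression tibble (`sample_id` + gene columns), possibly
#'   containing `NA`.
#' @param method Imputation method; only `"gene_mean"` is implemented.
#' @param max_missing_fraction Per-gene missingness cap in \[0, 1\].
#'   Default 0.2.
#' @return The expression tibble with all values finite; the imputed cells
#'   are recorded in attribute `"imputed"` (tibble `sample_id`, `gene_id`).
#' @export
impute_missing <- function(expr, method = c("gene_mean"),
                           max_missing_fraction = 0.2) {
  method <- match.arg(method)
  m <- expr_to_matrix(expr, require_finite = FALSE)
  miss <- is.na(m)
  if (!any(miss)) {
    out <- as_tibble(expr)
    attr(out, "imputed") <- tibble(sample_id = character(),
                                   gene_id = character())
    return(out)
  }
  frac <- colMeans(miss)
  over <- colnames(m)[frac > max_missing_fraction | frac == 1]
  if (length(over)) {
    abort(paste0(
      "gene(s) exceed the missingness cap (",
      format(max_missing_fraction), "): ", paste(over, collapse = ", ")
    ))
  }
  gene_means <- colMeans(m, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  m[miss] <- gene_means[idx[, "col"]]
  out <- matrix_to_expr(m)
  attr(out, "imputed") <- tibble(
    sample_id = rownames(m)[idx[, "row"]],
    gene_id = colnames(m)[idx[, "col"]]
  )
  out
}
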