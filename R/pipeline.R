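# End-to-end convenience wrappers: train a frozen signature from a labelled
# cohort, and quantify replicate agreement of a trained read-out.

#' Train an MSI signature end-to-end
#'
#' Runs the full development procedure on a labelled cohort: repeated
#' stratified 10-fold CV gene selection ([select_signature_genes()]),
#' centroid construction ([build_centroids()]), index computation
#' ([msi_index()]) and dual-threshold optimisation
#' ([optimize_thresholds()]). Returns the frozen [msi_signature()].
#'
#' @inheritParams select_signature_genes
#' @inheritParams optimize_primary_threshold
#' @param cohort_id Free-text provenance tag.
#' @return An [msi_signature()] with optimised thresholds; the selection
#'   frequency table is attached as attribute `"selection"`.
#' @export
train_msi_signature <- function(expr, labels, n_folds = 10L,
                                n_repeats = 1000L, top_k = NULL,
                                signature_size = 64L, seed = 1L,
                                rule = "max_sens_plus_spec",
                                sens_floor = 0.90,
                                cohort_id = "unnamed") {
  sel <- select_signature_genes(
    expr, labels, n_folds = n_folds, n_repeats = n_repeats,
    top_k = top_k, signature_size = signature_size, seed = seed
  )
  model <- build_centroids(
    expr, labels, sel$genes,
    provenance = list(
      cohort_id = cohort_id, seed = seed,
      n_repeats = n_repeats, n_folds = n_folds,
      date = format(Sys.Date())
    )
  )
  scores <- msi_index(expr, model)
  model <- optimize_thresholds(model, scores, labels,
                               rule = rule, sens_floor = sens_floor)
  attr(model, "selection") <- sel
  model
}

#' Agreement between replicate read-outs of a trained signature
#'
#' Scores two replicate hybridisations of the same samples with the same
#' model and reports the squared Pearson correlation of the indices and the
#' binary (signature-positive) and three-way call concordances.
#'
#' @param expr_a,expr_b Replicate expression tibbles over the same samples.
#' @param model A trained [msi_signature()].
#' @return One-row tibble `r_squared`, `concordance_binary`,
#'   `concordance_threeway`, `n`.
#' @export
replicate_agreement <- function(expr_a, expr_b, model) {
  a <- classify_samples(expr_a, model)
  b <- classify_samples(expr_b, model)
  joined <- dplyr::inner_join(a, b, by = "sample_id",
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0L) abort("replicates share no samples")
  tibble(
    r_squared = stats::cor(joined$index_a, joined$index_b)^2,
    concordance_binary =
      mean(joined$signature_positive_a == joined$signature_positive_b),
    concordance_threeway = mean(joined$call_a == joined$call_b),
    n = nrow(joined)
  )
}
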