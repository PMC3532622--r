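# Gene selection: per-gene two-sample t-tests and frequency-of-appearance
# selection across repeated stratified 10-fold cross-validation.

# Vectorised two-sample t-test over the columns of a samples x genes matrix.
# Equal-variance (Student) by default; Welch via var_equal = FALSE.
# Zero-variance (degenerate) genes get t = 0, p = 1: a constant gene carries
# no usable evidence either way.
ttest_stats <- function(m, lab, var_equal = TRUE) {
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 < 2L || n0 < 2L) {
    abort(sprintf(
      "need at least 2 samples per class (got %d positive, %d negative)",
      n1, n0
    ))
  }
  x1 <- m[lab, , drop = FALSE]
  x0 <- m[!lab, , drop = FALSE]
  mean1 <- colMeans(x1)
  mean0 <- colMeans(x0)
  ss1 <- colSums(x1^2) - n1 * mean1^2
  ss0 <- colSums(x0^2) - n0 * mean0^2
  if (var_equal) {
    pooled <- (ss1 + ss0) / (n1 + n0 - 2L)
    se <- sqrt(pooled * (1 / n1 + 1 / n0))
    df <- rep.int(n1 + n0 - 2L, ncol(m))
  } else {
    v1 <- ss1 / (n1 - 1L)
    v0 <- ss0 / (n0 - 1L)
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  }
  degenerate <- se <= 0 | !is.finite(se)
  tstat <- (mean1 - mean0) / se
  tstat[degenerate] <- 0
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate] <- 1
  list(t = tstat, p = p, df = df, degenerate = degenerate)
}

#' Rank genes by association with a binary class label
#'
#' Two-sided two-sample Student's t-test per gene (positive class minus
#' negative class), ranked by ascending p-value. Ties are broken by
#' descending |t| and then lexicographically by gene id, so the ranking is a
#' deterministic permutation regardless of input gene order. Genes with zero
#' pooled variance are flagged `degenerate` and assigned t = 0, p = 1.
#'
#' @param expr Wide expression tibble (`sample_id` + gene columns), all
#'   values finite.
#' @param labels Tibble with columns `sample_id` and `msi` (logical; `TRUE`
#'   is the positive class). Every matrix sample must be labelled.
#' @param var_equal Equal-variance Student's test (default) or Welch when
#'   `FALSE`.
#' @return A tibble `gene_id`, `t_statistic`, `p_value`, `degenerate`,
#'   `rank`, sorted by rank.
#' @export
ttest_rank <- function(expr, labels, var_equal = TRUE) {
  m <- expr_to_matrix(expr)
  lab <- align_labels(m, labels)
  st <- ttest_stats(m, lab, var_equal = var_equal)
  ord <- order(st$p, -abs(st$t), colnames(m))
  tibble(
    gene_id = colnames(m),
    t_statistic = unname(st$t),
    p_value = unname(st$p),
    degenerate = unname(st$degenerate)
  )[ord, ] |>
    mutate(rank = dplyr::row_number())
}

# Stratified fold assignment: shuffle within each class, deal fold ids
# cyclically so every fold keeps both classes at ~cohort prevalence.
stratified_folds <- function(lab, n_folds) {
  fold <- integer(length(lab))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(lab == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Select signature genes by frequency across repeated cross-validation
#'
#' Runs `n_repeats` rounds of stratified `n_folds`-fold cross-validation. In
#' every round x fold ("loop"), genes are ranked on the training portion only
#' (per [ttest_rank()]) and the `top_k` top-ranking genes are counted. The
#' signature is the `signature_size` genes with the highest appearance count
#' over all `n_repeats * n_folds` loops; count ties are broken by the lower
#' mean p-value across loops, then lexicographically. The full run is
#' deterministic given `seed`.
#'
#' The study-scale configuration is 10-fold CV repeated 1000 times with a
#' 64-gene signature; all sizes are parameters.
#'
#' @inheritParams ttest_rank
#' @param n_folds Folds per repeat (default 10). Must not exceed the minority
#'   class size.
#' @param n_repeats CV repeats (default 1000).
#' @param top_k Genes counted per loop; defaults to `signature_size`.
#' @param signature_size Number of genes selected (default 64).
#' @param seed Integer seed for fold shuffling.
#' @return An object of class `msi_gene_selection`: list with `genes`
#'   (selected ids, ordered by count), `frequency` (tibble `gene_id`,
#'   `appearance_count`, `mean_p`, `n_loops`) and `params`.
#' @export
select_signature_genes <- function(expr, labels, n_folds = 10L,
                                   n_repeats = 1000L, top_k = NULL,
                                   signature_size = 64L, seed = 1L,
                                   var_equal = TRUE) {
  m <- expr_to_matrix(expr)
  lab <- align_labels(m, labels)
  top_k <- as.integer(top_k %||% signature_size)
  n_folds <- as.integer(n_folds)
  n_repeats <- as.integer(n_repeats)
  signature_size <- as.integer(signature_size)
  if (top_k > ncol(m) || signature_size > ncol(m)) {
    abort("top_k and signature_size cannot exceed the number of genes")
  }
  n_minor <- min(sum(lab), sum(!lab))
  if (n_folds > n_minor) {
    abort(sprintf(
      "n_folds (%d) exceeds the minority class size (%d); folds would lose a class",
      n_folds, n_minor
    ))
  }
  genes <- colnames(m)
  counts <- setNames(integer(ncol(m)), genes)
  p_sum <- setNames(numeric(ncol(m)), genes)
  n_loops <- 0L
  withr::local_seed(seed)
  for (rep_i in seq_len(n_repeats)) {
    fold <- stratified_folds(lab, n_folds)
    for (f in seq_len(n_folds)) {
      train <- fold != f
      st <- ttest_stats(m[train, , drop = FALSE], lab[train],
                        var_equal = var_equal)
      # df constant across genes, so ascending p == descending |t|;
      # tie-break mirrors ttest_rank
      ord <- order(st$p, -abs(st$t), genes)
      top <- ord[seq_len(top_k)]
      counts[top] <- counts[top] + 1L
      p_sum <- p_sum + st$p
      n_loops <- n_loops + 1L
    }
  }
  freq <- tibble(
    gene_id = genes,
    appearance_count = unname(counts),
    mean_p = unname(p_sum) / n_loops,
    n_loops = n_loops
  ) |>
    arrange(dplyr::desc(.data$appearance_count), .data$mean_p, .data$gene_id)
  structure(
    list(
      genes = freq$gene_id[seq_len(signature_size)],
      frequency = freq,
      params = list(
        n_folds = n_folds, n_repeats = n_repeats, top_k = top_k,
        signature_size = signature_size, seed = seed, var_equal = var_equal
      )
    ),
    class = "msi_gene_selection"
  )
}

#' @export
print.msi_gene_selection <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<msi_gene_selection> %d genes from %d x %d-fold CV (top_k %d, seed %d)\n",
    p$signature_size, p$n_repeats, p$n_folds, p$top_k, p$seed
  ))
  invisible(x)
}

#' Tidy a gene-selection result into the appearance-frequency table
#'
#' @param x An `msi_gene_selection`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `appearance_count`, `mean_p`, `n_loops`,
#'   `selected`.
#' @method tidy msi_gene_selection
#' @export
tidy.msi_gene_selection <- function(x, ...) {
  x$frequency |> mutate(selected = .data$gene_id %in% x$genes)
}
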