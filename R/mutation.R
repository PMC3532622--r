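# Mutation load over a fixed capture panel: variant inclusion filters,
# per-sample fraction of panel genes mutated, and group comparison.

#' Apply the candidate-variant inclusion filters
#'
#' Keeps records satisfying all of: coverage >= 10, variant count >= 5,
#' at least one variant read on each strand, a protein-coding consequence,
#' and absence from the normal-sample panel (germline/artefact removal).
#' The filter is idempotent and never errors; it can return an empty table.
#'
#' @param variants Validated variant tibble (see [read_variants()]).
#' @param min_coverage Minimum read depth at the site. Default 10.
#' @param min_variant_count Minimum variant-supporting reads. Default 5.
#' @return The surviving records, same columns.
#' @export
filter_variants <- function(variants, min_coverage = 10L,
                            min_variant_count = 5L) {
  validate_variants(variants)
  variants |>
    filter(
      .data$coverage >= min_coverage,
      .data$variant_count >= min_variant_count,
      .data$fwd_variant_count >= 1L,
      .data$rev_variant_count >= 1L,
      .data$consequence == "coding_change",
      !.data$in_normal_panel
    )
}

#' Per-sample mutation frequency over a gene panel
#'
#' For each sample, counts the distinct panel genes carrying at least one
#' surviving variant (multiple variants in one gene count once) and divides
#' by the panel size. Samples listed in `sample_ids` but absent from the
#' table get frequency 0, so unmutated samples are not silently dropped.
#'
#' @param variants Filtered variant tibble (see [filter_variants()]).
#' @param panel Character vector of panel gene ids (615 genes in the study's
#'   cancer-kinome capture). Every variant gene must belong to it.
#' @param sample_ids Optional character vector of all assayed samples.
#' @return Tibble `sample_id`, `n_genes_mutated`, `panel_size`, `frequency`.
#' @export
mutation_frequency <- function(variants, panel, sample_ids = NULL) {
  panel <- unique(as.character(panel))
  outside <- setdiff(unique(variants$gene_id), panel)
  if (length(outside)) {
    abort(paste0("variant gene(s) outside the panel: ",
                 paste(head(outside, 5L), collapse = ", ")))
  }
  counts <- variants |>
    distinct(.data$sample_id, .data$gene_id) |>
    dplyr::count(.data$sample_id, name = "n_genes_mutated")
  ids <- sample_ids %||% counts$sample_id
  tibble(sample_id = as.character(ids)) |>
    left_join(counts, by = "sample_id") |>
    mutate(
      n_genes_mutated = dplyr::coalesce(.data$n_genes_mutated, 0L),
      panel_size = length(panel),
      frequency = .data$n_genes_mutated / length(panel)
    )
}

#' Compare mutation frequencies between two groups
#'
#' Two-sided two-sample Student's t-test on per-sample mutation frequencies,
#' e.g. signature-positive versus MSS. Reports the group means alongside the
#' statistic.
#'
#' @param data Data frame with the frequency and group columns.
#' @param frequency,group Columns of `data` (tidy-eval): numeric per-sample
#'   frequency and logical group indicator (`TRUE` = first group).
#' @param var_equal Equal-variance Student's test (default) or Welch.
#' @return One-row tibble `mean_group1`, `mean_group2`, `estimate`
#'   (difference in means), `statistic`, `p_value`, `n1`, `n2`.
#' @export
compare_mutation_groups <- function(data, frequency, group, var_equal = TRUE) {
  freq <- pull_numeric(data, {{ frequency }}, "frequency")
  grp <- pull_logical(data, {{ group }}, "group")
  if (anyNA(freq) || anyNA(grp)) abort("frequencies and groups must not contain NA")
  if (sum(grp) < 2L || sum(!grp) < 2L) {
    abort("need at least 2 samples per group")
  }
  ht <- stats::t.test(freq[grp], freq[!grp], var.equal = var_equal)
  tibble(
    mean_group1 = mean(freq[grp]),
    mean_group2 = mean(freq[!grp]),
    estimate = mean(freq[grp]) - mean(freq[!grp]),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n1 = sum(grp),
    n2 = sum(!grp)
  )
}
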