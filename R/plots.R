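# ggplot2 displays for the main result types.

#' Plot the per-sample MSI index with classification calls
#'
#' Samples sorted by index, coloured by three-way call, with dashed lines at
#' the model thresholds.
#'
#' @param calls Tibble from [classify_samples()].
#' @param model Optional [msi_signature()]; adds threshold lines.
#' @return A ggplot.
#' @export
plot_msi_index <- function(calls, model = NULL) {
  df <- calls |>
    arrange(.data$index) |>
    mutate(ord = dplyr::row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ord, y = .data$index,
                                        fill = .data$call)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(
      values = c(MSS = "grey65", MSI_LIKE = "#f4a261", MSI = "#c1121f"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "samples (sorted by index)", y = "MSI index",
                  fill = "call") +
    ggplot2::theme_minimal()
  if (!is.null(model) && has_thresholds(model)) {
    p <- p +
      ggplot2::geom_hline(yintercept = model$threshold_primary,
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = model$threshold_secondary,
                          linetype = "dotted")
  }
  p
}

#' Plot an empirical ROC curve of the index against reference labels
#'
#' @inheritParams optimize_primary_threshold
#' @return A ggplot with the AUC in the subtitle.
#' @export
plot_roc_curve <- function(data, index, truth) {
  idx <- pull_numeric(data, {{ index }}, "index")
  lab <- pull_logical(data, {{ truth }}, "labels")
  check_binary_input(idx, lab)
  cand <- threshold_candidates(idx)
  pts <- purrr::map(cand, function(t) {
    cm <- confusion_at(idx, lab, t)
    tibble(fpr = cm[["fp"]] / (cm[["fp"]] + cm[["tn"]]),
           tpr = cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]))
  }) |> bind_rows() |> arrange(.data$fpr, .data$tpr)
  auc <- auc_statistic(idx, lab)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves per signature stratum
#'
#' @param km Tibble from [km_curve()].
#' @return A ggplot of step survival curves.
#' @export
plot_km <- function(km) {
  start <- km |>
    distinct(.data$stratum) |>
    mutate(time = 0, survival = 1)
  df <- bind_rows(start, km |> select("stratum", "time", "survival")) |>
    arrange(.data$stratum, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "distant metastasis-free survival",
                  colour = "stratum") +
    ggplot2::theme_minimal()
}

#' @method autoplot msi_gene_selection
#' @export
autoplot.msi_gene_selection <- function(object, top_n = 100L, ...) {
  df <- tidy(object) |> head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$appearance_count),
    y = .data$appearance_count / .data$n_loops,
    fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "appearance frequency across CV loops",
                  fill = "selected") +
    ggplot2::theme_minimal(base_size = 8)
}
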