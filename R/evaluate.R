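# Threshold optimisation and performance metrics. Candidate thresholds are
# the midpoints between adjacent sorted unique index values plus the two
# infinities, so boundary behaviour (positive = index >= threshold) is never
# ambiguous at an observed value.

threshold_candidates <- function(index) {
  u <- sort(unique(index))
  mids <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else numeric()
  c(-Inf, mids, Inf)
}

confusion_at <- function(index, truth, threshold) {
  pos <- index >= threshold
  c(
    tp = sum(pos & truth), fp = sum(pos & !truth),
    tn = sum(!pos & !truth), fn = sum(!pos & truth)
  )
}

check_binary_input <- function(index, truth) {
  if (length(index) == 0L) abort("empty input")
  if (length(index) != length(truth)) abort("index and labels differ in length")
  if (anyNA(index) || any(!is.finite(index))) abort("indices must be finite")
  if (anyNA(truth)) abort("labels must not contain NA")
  if (all(truth) || !any(truth)) {
    abort("both classes must be present")
  }
}

#' Optimise the primary MSI/MSS decision threshold
#'
#' Evaluates every candidate threshold (midpoints between adjacent sorted
#' unique indices, plus the infinities) and returns the one maximising
#' sensitivity + specificity. With `rule = "max_sens_plus_spec_with_floor"`
#' only candidates reaching `sens_floor` sensitivity compete, the rule used
#' for read-out on an external validation platform. Ties go to the lowest
#' threshold, favouring sensitivity.
#'
#' @param data Data frame holding the index and reference label columns.
#' @param index,truth Columns of `data` (tidy-eval): numeric MSI index, and
#'   logical reference label (`TRUE` = MSI).
#' @param rule Optimisation rule; the floor variant requires
#'   sensitivity >= `sens_floor`.
#' @param sens_floor Minimum sensitivity for the floor rule. Default 0.90.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `sum_sens_spec`.
#' @export
optimize_primary_threshold <- function(data, index, truth,
                                       rule = c("max_sens_plus_spec",
                                                "max_sens_plus_spec_with_floor"),
                                       sens_floor = 0.90) {
  rule <- match.arg(rule)
  idx <- pull_numeric(data, {{ index }}, "index")
  lab <- pull_logical(data, {{ truth }}, "labels")
  check_binary_input(idx, lab)
  cand <- threshold_candidates(idx)
  perf <- vapply(cand, function(t) {
    cm <- confusion_at(idx, lab, t)
    sens <- cm["tp"] / (cm["tp"] + cm["fn"])
    spec <- cm["tn"] / (cm["tn"] + cm["fp"])
    c(sens, spec)
  }, numeric(2L))
  sens <- perf[1L, ]
  spec <- perf[2L, ]
  eligible <- if (rule == "max_sens_plus_spec_with_floor") sens >= sens_floor else rep(TRUE, length(cand))
  if (!any(eligible)) {
    abort(sprintf(
      "sensitivity floor %.2f unattainable (maximum achievable: %.3f)",
      sens_floor, max(sens)
    ))
  }
  total <- sens + spec
  total[!eligible] <- -Inf
  # ties -> lowest threshold; candidates are in increasing order
  best <- which(total == max(total))[1L]
  tibble(
    threshold = cand[best],
    sensitivity = sens[best],
    specificity = spec[best],
    sum_sens_spec = sens[best] + spec[best]
  )
}

#' Optimise the secondary MSI vs MSI-like threshold
#'
#' Among signature-positive samples only, finds the index cut-off that best
#' separates hospital-confirmed MSI from hospital-MSS samples (maximal
#' sensitivity + specificity over the same candidate set as the primary
#' optimiser). Positives below the returned threshold are MSI-like, at or
#' above it MSI. Requires both hospital classes among the positives.
#'
#' @param data Data frame of signature-positive samples.
#' @inheritParams optimize_primary_threshold
#' @return One-row tibble as for [optimize_primary_threshold()].
#' @export
optimize_secondary_threshold <- function(data, index, truth) {
  idx <- pull_numeric(data, {{ index }}, "index")
  lab <- pull_logical(data, {{ truth }}, "labels")
  if (length(idx) == 0L) abort("empty input")
  if (all(lab) || !any(lab)) {
    abort("signature-positive samples contain a single hospital class; secondary threshold undefined")
  }
  optimize_primary_threshold(
    tibble(.index = idx, .truth = lab), .data$.index, .data$.truth,
    rule = "max_sens_plus_spec"
  )
}

auc_statistic <- function(index, truth) {
  n1 <- sum(truth)
  n0 <- sum(!truth)
  r <- rank(index, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area under the curve with confidence interval
#'
#' AUC computed as the Mann-Whitney U statistic divided by the number of
#' positive x negative pairs (ties count one half). The 95% CI is by
#' stratified bootstrap (default; resampling within each class) or by the
#' DeLong variance estimate.
#'
#' @inheritParams optimize_primary_threshold
#' @param ci_method `"bootstrap"` (default) or `"delong"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble `auc`, `ci_low`, `ci_high`, `ci_method`.
#' @export
roc_auc <- function(data, index, truth, ci_method = c("bootstrap", "delong"),
                    n_boot = 2000L, seed = 1L, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  idx <- pull_numeric(data, {{ index }}, "index")
  lab <- pull_logical(data, {{ truth }}, "labels")
  check_binary_input(idx, lab)
  auc <- auc_statistic(idx, lab)
  alpha <- (1 - conf_level) / 2
  if (ci_method == "bootstrap") {
    pos <- which(lab)
    neg <- which(!lab)
    withr::local_seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      take <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      auc_statistic(idx[take], lab[take])
    }, numeric(1L))
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  } else {
    # DeLong placement values
    v10 <- vapply(idx[lab], function(x) mean((idx[!lab] < x) + 0.5 * (idx[!lab] == x)), numeric(1L))
    v01 <- vapply(idx[!lab], function(x) mean((idx[lab] > x) + 0.5 * (idx[lab] == x)), numeric(1L))
    se <- sqrt(var(v10) / sum(lab) + var(v01) / sum(!lab))
    z <- qnorm(1 - alpha)
    ci <- c(auc - z * se, auc + z * se)
  }
  tibble(
    auc = auc,
    ci_low = min(ci[1L], auc),
    ci_high = max(ci[2L], auc),
    ci_method = ci_method
  )
}

#' Confusion counts and accuracy metrics at a threshold
#'
#' Binary positive is `index >= threshold`. Reports the confusion counts and
#' sensitivity, specificity and overall accuracy (fraction correct).
#'
#' @inheritParams optimize_primary_threshold
#' @param threshold Decision threshold.
#' @return One-row tibble `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `overall_accuracy`.
#' @export
performance_report <- function(data, index, truth, threshold) {
  idx <- pull_numeric(data, {{ index }}, "index")
  lab <- pull_logical(data, {{ truth }}, "labels")
  check_binary_input(idx, lab)
  cm <- confusion_at(idx, lab, threshold)
  tibble(
    threshold = threshold,
    tp = cm[["tp"]], fp = cm[["fp"]], tn = cm[["tn"]], fn = cm[["fn"]],
    sensitivity = cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]),
    specificity = cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]),
    overall_accuracy = (cm[["tp"]] + cm[["tn"]]) / sum(cm)
  )
}

#' Optimise both thresholds of a signature model against reference labels
#'
#' Joins model scores with reference labels, optimises the primary threshold
#' on all samples, then the secondary threshold among signature-positive
#' samples (hospital-MSI vs hospital-MSS), and returns the model with both
#' thresholds set and the staleness flag cleared.
#'
#' @param model An [msi_signature()] (thresholds may be unset or stale).
#' @param scores Tibble from [msi_index()] (`sample_id`, `index`).
#' @param labels Tibble `sample_id`, `msi` (logical hospital reference).
#' @inheritParams optimize_primary_threshold
#' @return The model with optimised thresholds.
#' @export
optimize_thresholds <- function(model, scores, labels,
                                rule = c("max_sens_plus_spec",
                                         "max_sens_plus_spec_with_floor"),
                                sens_floor = 0.90) {
  rule <- match.arg(rule)
  joined <- scores |>
    dplyr::inner_join(labels, by = "sample_id")
  if (nrow(joined) < nrow(scores)) {
    abort("labels missing for some scored samples")
  }
  prim <- optimize_primary_threshold(joined, .data$index, .data$msi,
                                     rule = rule, sens_floor = sens_floor)
  positives <- joined |> filter(.data$index >= prim$threshold)
  # With no hospital-MSS samples among the positives there is no MSI-like
  # stratum to delimit: the secondary threshold collapses onto the primary
  # (every positive is MSI). The converse - no hospital-MSI positives -
  # leaves MSI undefined, so everything positive stays MSI-like.
  if (all(positives$msi)) {
    sec_threshold <- prim$threshold
  } else if (!any(positives$msi)) {
    sec_threshold <- Inf
  } else {
    sec <- optimize_secondary_threshold(positives, .data$index, .data$msi)
    sec_threshold <- max(prim$threshold, sec$threshold)
  }
  set_thresholds(model, prim$threshold, sec_threshold)
}
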