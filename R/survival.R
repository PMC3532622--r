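# Survival analysis of signature strata on distant metastasis-free survival
# (DMFS): Kaplan-Meier curves, log-rank tests and Cox proportional-hazards
# ratios, with administrative censoring at a fixed horizon (10 years in the
# study). Estimation is delegated to the survival package; this module owns
# the stratification, horizon handling and tidy interfaces.

#' Administrative censoring at a follow-up horizon
#'
#' Events beyond `horizon` years are censored at the horizon; follow-up times
#' are truncated to it.
#'
#' @param time Non-negative follow-up times (years).
#' @param event 0/1 event indicators.
#' @param horizon Horizon in years. Default 10.
#' @return Tibble `time`, `event` after censoring.
#' @export
censor_at_horizon <- function(time, event, horizon = 10) {
  if (any(time < 0, na.rm = TRUE)) abort("times must be non-negative")
  over <- !is.na(time) & time > horizon
  tibble(
    time = ifelse(over, horizon, time),
    event = as.integer(ifelse(over, 0L, event))
  )
}

#' Kaplan-Meier survival curves per stratum
#'
#' Product-limit estimates with at-risk and event counts, one step row per
#' observed time, per stratum.
#'
#' @param data Data frame with follow-up columns.
#' @param time,event,group Columns of `data` (tidy-eval): follow-up years,
#'   0/1 event, and an optional stratum label (omit for a single curve).
#' @return Tibble `stratum`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_curve <- function(data, time, event, group = NULL) {
  t <- pull_numeric(data, {{ time }}, "time")
  if (length(t) == 0L) abort("empty stratum")
  if (any(t < 0, na.rm = TRUE)) abort("times must be non-negative")
  e <- as.integer(rlang::eval_tidy(rlang::enquo(event), data))
  g <- if (rlang::quo_is_null(rlang::enquo(group))) {
    rep("all", length(t))
  } else {
    as.character(rlang::eval_tidy(rlang::enquo(group), data))
  }
  fit <- survival::survfit(survival::Surv(t, e) ~ g)
  strata <- if (is.null(fit$strata)) {
    rep(unique(g), length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  tibble(
    stratum = strata,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Log-rank test across strata
#'
#' Standard (unweighted) log-rank chi-square over two or more strata.
#'
#' @inheritParams km_curve
#' @return One-row tibble `statistic`, `df`, `p_value`, `n`, `n_events`.
#' @export
logrank_test <- function(data, time, event, group) {
  t <- pull_numeric(data, {{ time }}, "time")
  e <- as.integer(rlang::eval_tidy(rlang::enquo(event), data))
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  if (length(unique(g)) < 2L) abort("need at least 2 strata")
  if (sum(e) < 1L) abort("log-rank undefined with no events (all censored)")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  df <- length(sd$n) - 1L
  tibble(
    statistic = sd$chisq,
    df = df,
    p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
    n = length(t),
    n_events = sum(e)
  )
}

#' Cox hazard ratio for signature-positive versus MSS
#'
#' Fits a univariable Cox proportional-hazards model (Efron tie handling) on
#' horizon-censored follow-up for a binary signature status and reports the
#' hazard ratio with Wald confidence interval and p-value. If one group has
#' no events, the partial likelihood is degenerate: the HR is still reported
#' but with a warning, and the CI is effectively unbounded.
#'
#' @param data Data frame with follow-up and group columns.
#' @param time,event,positive Columns of `data` (tidy-eval): follow-up years,
#'   0/1 event, logical signature-positive indicator.
#' @param horizon Administrative censoring horizon in years (default 10);
#'   `Inf` disables it.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble `hr`, `ci_low`, `ci_high`, `p_value`, `n`,
#'   `n_events`.
#' @export
cox_hr <- function(data, time, event, positive, horizon = 10,
                   conf_level = 0.95) {
  t <- pull_numeric(data, {{ time }}, "time")
  e <- as.integer(rlang::eval_tidy(rlang::enquo(event), data))
  pos <- pull_logical(data, {{ positive }}, "positive")
  keep <- !is.na(t) & !is.na(e) & !is.na(pos)
  t <- t[keep]; e <- e[keep]; pos <- pos[keep]
  if (length(unique(pos)) < 2L) abort("both groups must be present")
  cens <- censor_at_horizon(t, e, horizon)
  if (sum(cens$event[pos]) == 0L || sum(cens$event[!pos]) == 0L) {
    warn("one group has no events within the horizon; HR estimate is degenerate and its CI unbounded")
  }
  fit <- survival::coxph(
    survival::Surv(cens$time, cens$event) ~ pos,
    ties = "efron"
  )
  s <- summary(fit, conf.int = conf_level)
  tibble(
    hr = unname(s$conf.int[1L, "exp(coef)"]),
    ci_low = unname(s$conf.int[1L, 3L]),
    ci_high = unname(s$conf.int[1L, 4L]),
    p_value = unname(s$coefficients[1L, "Pr(>|z|)"]),
    n = length(cens$time),
    n_events = sum(cens$event)
  )
}

#' Compare TYMS expression across signature classes
#'
#' Thymidylate synthase (TYMS), the 5-FU target, is expected to be higher in
#' MSI and MSI-like tumours than in MSS. Reports per-class mean log-ratios
#' and two-sided Student's t-tests of MSI vs MSS and MSI-like vs MSS.
#'
#' @param expr Wide expression tibble containing the `gene` column.
#' @param calls Tibble `sample_id`, `call` (from [classify_samples()]).
#' @param gene Gene id to test. Default `"TYMS"`.
#' @return Tibble with one row per comparison: `comparison`, `mean_case`,
#'   `mean_mss`, `statistic`, `p_value`, `n_case`, `n_mss`.
#' @export
tyms_comparison <- function(expr, calls, gene = "TYMS") {
  if (!gene %in% names(expr)) {
    abort(sprintf("gene %s absent from the expression matrix", gene))
  }
  joined <- expr |>
    select("sample_id", dplyr::all_of(gene)) |>
    dplyr::inner_join(calls |> select("sample_id", "call"), by = "sample_id")
  vals <- joined[[gene]]
  cls <- as.character(joined$call)
  mss <- vals[cls == "MSS"]
  if (length(mss) < 2L) abort("need at least 2 MSS samples")
  one <- function(case_label) {
    case <- vals[cls == case_label]
    if (length(case) < 2L) {
      return(tibble(
        comparison = paste0(case_label, " vs MSS"),
        mean_case = mean(case), mean_mss = mean(mss),
        statistic = NA_real_, p_value = NA_real_,
        n_case = length(case), n_mss = length(mss)
      ))
    }
    ht <- stats::t.test(case, mss, var.equal = TRUE)
    tibble(
      comparison = paste0(case_label, " vs MSS"),
      mean_case = mean(case), mean_mss = mean(mss),
      statistic = unname(ht$statistic), p_value = ht$p.value,
      n_case = length(case), n_mss = length(mss)
    )
  }
  bind_rows(one("MSI"), one("MSI_LIKE"))
}
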