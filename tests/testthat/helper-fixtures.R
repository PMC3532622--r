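# Small in-code fixtures shared across test files.

expr_from_matrix <- function(m) {
  tibble::tibble(sample_id = rownames(m)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

# A tiny labelled cohort: n samples, n_genes genes, the first n_inf genes
# shifted by `effect` in the positive class.
tiny_cohort <- function(n = 40, n_genes = 100, n_inf = 10, effect = 2,
                        prev = 0.3, seed = 42) {
  withr::local_seed(seed)
  ids <- sprintf("s%03d", seq_len(n))
  genes <- sprintf("g%03d", seq_len(n_genes))
  msi <- seq_len(n) <= round(prev * n)
  m <- matrix(rnorm(n * n_genes), nrow = n, dimnames = list(ids, genes))
  m[msi, seq_len(n_inf)] <- m[msi, seq_len(n_inf)] + effect
  list(
    expr = expr_from_matrix(m),
    labels = tibble::tibble(sample_id = ids, msi = msi),
    informative = genes[seq_len(n_inf)]
  )
}

# One fully valid variant record, overridable field by field.
variant_record <- function(...) {
  base <- tibble::tibble(
    sample_id = "s1", gene_id = "KIN001", position = 100L,
    coverage = 12L, variant_count = 6L,
    fwd_variant_count = 4L, rev_variant_count = 2L,
    consequence = "coding_change", in_normal_panel = FALSE
  )
  dplyr::mutate(base, ...)
}

# Independent brute-force cosine similarity (loop form, no linear algebra).
brute_cosine <- function(x, y) {
  num <- 0; nx <- 0; ny <- 0
  for (i in seq_along(x)) {
    num <- num + x[i] * y[i]
    nx <- nx + x[i]^2
    ny <- ny + y[i]^2
  }
  unname(num / (sqrt(nx) * sqrt(ny)))
}

# Independent brute-force AUC: count positive/negative pairs, ties half.
brute_auc <- function(index, truth) {
  pos <- index[truth]
  neg <- index[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Independent threshold search: every midpoint candidate, scored long-hand.
brute_best_threshold <- function(index, truth, sens_floor = -Inf) {
  u <- sort(unique(index))
  cand <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    pred <- index >= t
    sens <- sum(pred & truth) / sum(truth)
    spec <- sum(!pred & !truth) / sum(!truth)
    if (sens < sens_floor) next
    if (is.null(best) || sens + spec > best$total + 1e-12) {
      best <- list(threshold = t, sens = sens, spec = spec,
                   total = sens + spec)
    }
  }
  best
}

# Independent k-sample log-rank: event-time ledger with hypergeometric
# expectations and covariance, chi-square on the first k-1 groups.
brute_logrank <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  times <- sort(unique(time[event == 1]))
  d <- numeric(k - 1)
  V <- matrix(0, k - 1, k - 1)
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (i in seq_len(k - 1)) {
      n_i <- sum(at_risk & group == groups[i])
      o_i <- sum(event == 1 & time == t & group == groups[i])
      d[i] <- d[i] + o_i - d_t * n_i / n_t
      for (j in seq_len(k - 1)) {
        n_j <- sum(at_risk & group == groups[j])
        if (n_t > 1) {
          V[i, j] <- V[i, j] +
            d_t * (n_t - d_t) / (n_t - 1) *
            (n_i * ((i == j) * n_t - n_j)) / n_t^2
        }
      }
    }
  }
  drop(t(d) %*% solve(V) %*% d)
}

# Independent product-limit estimator.
brute_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    n_t <- sum(time >= times[i])
    d_t <- sum(event == 1 & time == times[i])
    s <- s * (1 - d_t / n_t)
    out[i] <- s
  }
  tibble::tibble(time = times, survival = out)
}

# Independent record-wise inclusion predicate for variant filtering.
brute_variant_keep <- function(rec) {
  rec$coverage >= 10 && rec$variant_count >= 5 &&
    rec$fwd_variant_count >= 1 && rec$rev_variant_count >= 1 &&
    rec$consequence == "coding_change" && !rec$in_normal_panel
}
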