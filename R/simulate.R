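# Synthetic study generator. Emulates the statistical structure the analysis
# assumes: a development-sized cohort with a dominant MSI expression program,
# an MSI-like subgroup sharing that program at attenuated strength but
# labelled MSS by the hospital assay, class-dependent mutation rates over a
# fixed gene panel, survival with lower hazard in signature-positive samples,
# and technical replicates with small day/operator offsets. Everything is
# deterministic given the config seed.

#' Configuration for the synthetic-study generator
#'
#' Defaults emulate the study conditions: a 276-sample development cohort at
#' 11% hospital-MSI prevalence with an MSI-like subgroup among the MSS-labelled
#' samples; 64 informative genes out of 1000 shifted by 2 biological SD (full
#' strength in MSI, 0.6x in MSI-like); class mutation rates 8.2% / 6.4% / 1.6%
#' over a 615-gene panel; a positive-class hazard ratio of 0.25 with ~20%
#' 10-year event rate in MSS; and 0.05 SD technical noise.
#'
#' @param n_samples Cohort size. Default 276.
#' @param prevalence_msi Latent MSI fraction. Default 0.11.
#' @param prevalence_msi_like_among_mss MSI-like fraction among latent
#'   non-MSI samples. Default 0.10.
#' @param n_genes Genes on the array (TYMS is added on top). Default 1000.
#' @param n_informative Genes carrying the MSI program. Default 64.
#' @param effect_size_msi Mean shift of informative genes in MSI samples, in
#'   units of the biological SD. Default 2.
#' @param effect_attenuation_msi_like Multiplier on the shift for MSI-like
#'   samples. Default 0.6.
#' @param biological_sd Per-gene log-ratio SD. Default 1.
#' @param tyms_shift_msi,tyms_shift_msi_like Additive TYMS shifts for MSI and
#'   MSI-like samples. Defaults 0.4 and 0.3.
#' @param tyms_sd TYMS within-class SD. Default 0.15, much tighter than the
#'   generic gene SD: the observed MSI-vs-MSS TYMS separation is extreme
#'   (t-test p below 1e-18 at cohort scale), which requires within-class
#'   spread well under the class shifts.
#' @param hospital_error_rate Probability the hospital assay flips a label.
#'   Default 0.02.
#' @param mut_rate_msi,mut_rate_msi_like,mut_rate_mss Per-gene mutation
#'   probabilities by latent class. Defaults 0.082, 0.064, 0.016.
#' @param panel_size Mutation panel size. Default 615.
#' @param decoy_fraction Fraction of extra variant records that each violate
#'   one inclusion filter, so filters are exercised. Default 0.2.
#' @param hazard_ratio_positive Hazard multiplier for latent MSI and MSI-like
#'   samples. Default 0.25.
#' @param event_rate_mss MSS event fraction at 10 years (defines the baseline
#'   exponential rate). Default 0.2.
#' @param censor_range Uniform administrative-censoring window in years.
#'   Default `c(5, 15)`.
#' @param tech_noise_sd Technical replicate noise SD. Default 0.05.
#' @param day_sd,operator_sd SDs of whole-array day and operator offsets.
#'   Defaults 0.02.
#' @param seed Integer seed for the cohort-level sampling; every simulation
#'   derives its stream from it.
#' @param program_seed Integer seed fixing the biology shared across cohorts:
#'   which genes carry the MSI program and in which direction. Distinct from
#'   `seed` so that independently sampled cohorts (development, validation)
#'   express the same program, as real cohorts would.
#' @return A validated list of class `msi_sim_config`.
#' @export
sim_config <- function(n_samples = 276L,
                       prevalence_msi = 0.11,
                       prevalence_msi_like_among_mss = 0.10,
                       n_genes = 1000L,
                       n_informative = 64L,
                       effect_size_msi = 2.0,
                       effect_attenuation_msi_like = 0.6,
                       biological_sd = 1.0,
                       tyms_shift_msi = 0.4,
                       tyms_shift_msi_like = 0.3,
                       tyms_sd = 0.15,
                       hospital_error_rate = 0.02,
                       mut_rate_msi = 0.082,
                       mut_rate_msi_like = 0.064,
                       mut_rate_mss = 0.016,
                       panel_size = 615L,
                       decoy_fraction = 0.2,
                       hazard_ratio_positive = 0.25,
                       event_rate_mss = 0.2,
                       censor_range = c(5, 15),
                       tech_noise_sd = 0.05,
                       day_sd = 0.02,
                       operator_sd = 0.02,
                       seed = 1L,
                       program_seed = 20121L) {
  cfg <- structure(
    list(
      n_samples = as.integer(n_samples),
      prevalence_msi = prevalence_msi,
      prevalence_msi_like_among_mss = prevalence_msi_like_among_mss,
      n_genes = as.integer(n_genes),
      n_informative = as.integer(n_informative),
      effect_size_msi = effect_size_msi,
      effect_attenuation_msi_like = effect_attenuation_msi_like,
      biological_sd = biological_sd,
      tyms_shift_msi = tyms_shift_msi,
      tyms_shift_msi_like = tyms_shift_msi_like,
      tyms_sd = tyms_sd,
      hospital_error_rate = hospital_error_rate,
      mut_rate_msi = mut_rate_msi,
      mut_rate_msi_like = mut_rate_msi_like,
      mut_rate_mss = mut_rate_mss,
      panel_size = as.integer(panel_size),
      decoy_fraction = decoy_fraction,
      hazard_ratio_positive = hazard_ratio_positive,
      event_rate_mss = event_rate_mss,
      censor_range = as.double(censor_range),
      tech_noise_sd = tech_noise_sd,
      day_sd = day_sd,
      operator_sd = operator_sd,
      seed = as.integer(seed),
      program_seed = as.integer(program_seed)
    ),
    class = "msi_sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$prevalence_msi, cfg$prevalence_msi_like_among_mss,
    cfg$hospital_error_rate, cfg$mut_rate_msi, cfg$mut_rate_msi_like,
    cfg$mut_rate_mss, cfg$decoy_fraction, cfg$event_rate_mss
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$n_informative > cfg$n_genes) {
    abort("n_informative cannot exceed n_genes")
  }
  rates <- c(cfg$effect_size_msi, cfg$effect_attenuation_msi_like,
             cfg$biological_sd, cfg$tyms_sd, cfg$hazard_ratio_positive,
             cfg$tech_noise_sd, cfg$day_sd, cfg$operator_sd)
  if (any(rates < 0)) abort("rates and SDs must be non-negative")
  if (cfg$n_samples < 1L || cfg$panel_size < 1L) {
    abort("n_samples and panel_size must be positive")
  }
  if (length(cfg$censor_range) != 2L || diff(cfg$censor_range) < 0 ||
      any(cfg$censor_range < 0)) {
    abort("censor_range must be an increasing non-negative pair")
  }
  cfg
}

#' Built-in synthetic mutation panel gene ids
#'
#' @param config A [sim_config()]; only `panel_size` is used.
#' @return Character vector of panel gene ids.
#' @export
sim_panel <- function(config) sprintf("KIN%03d", seq_len(config$panel_size))

#' Simulate a full synthetic cohort
#'
#' Draws latent classes (MSS / MSI-like / MSI) per the configured
#' prevalences, generates log-ratio expression — informative genes shifted by
#' the class effect with a random but seed-fixed direction per gene, null
#' genes pure noise, plus a dedicated TYMS gene with its own class shifts —
#' hospital labels (MSI-like and MSS report as hospital-MSS, then labels flip
#' at the assay error rate), survival outcomes, and a clinical table with
#' stage and BRAF status at class-typical rates.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (wide tibble, genes + `TYMS`), `clinical`
#'   (see [read_clinical()]), `truth` (tibble `sample_id`, `latent_class`,
#'   `signature_positive`) and `informative` (tibble `gene_id`, `direction`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  # the MSI program is fixed biology: same genes and directions in every
  # cohort drawn under the same program_seed
  program <- withr::with_seed(cfg$program_seed, {
    informative <- sort(sample(genes, cfg$n_informative))
    list(informative = informative,
         direction = sample(c(-1, 1), cfg$n_informative, replace = TRUE))
  })
  informative <- program$informative
  direction <- program$direction
  withr::local_seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  is_msi <- runif(n) < cfg$prevalence_msi
  is_like <- !is_msi & runif(n) < cfg$prevalence_msi_like_among_mss
  latent <- ifelse(is_msi, "MSI", ifelse(is_like, "MSI_LIKE", "MSS"))

  m <- matrix(rnorm(n * cfg$n_genes, sd = cfg$biological_sd),
              nrow = n, dimnames = list(ids, genes))
  shift <- cfg$effect_size_msi * cfg$biological_sd
  class_mult <- ifelse(latent == "MSI", 1,
                       ifelse(latent == "MSI_LIKE",
                              cfg$effect_attenuation_msi_like, 0))
  inf_idx <- match(informative, genes)
  m[, inf_idx] <- m[, inf_idx] +
    outer(class_mult * shift, direction)
  tyms <- rnorm(n, sd = cfg$tyms_sd) +
    ifelse(latent == "MSI", cfg$tyms_shift_msi,
           ifelse(latent == "MSI_LIKE", cfg$tyms_shift_msi_like, 0))
  expression <- matrix_to_expr(cbind(m, TYMS = tyms))

  hospital <- ifelse(latent == "MSI", "MSI", "MSS")
  flip <- runif(n) < cfg$hospital_error_rate
  hospital[flip] <- ifelse(hospital[flip] == "MSI", "MSS", "MSI")

  surv <- simulate_survival(latent, cfg, seed = cfg$seed + 1L)
  braf_rate <- ifelse(latent == "MSI", 0.64,
                      ifelse(latent == "MSI_LIKE", 0.17, 0.02))
  clinical <- tibble(
    sample_id = ids,
    msi_hospital = hospital,
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.14, 0.57, 0.28, 0.01)),
    braf = ifelse(runif(n) < braf_rate, "mutant", "wildtype"),
    dmfs_years = surv$time,
    dmfs_event = surv$event
  )
  list(
    expression = expression,
    clinical = validate_clinical(clinical),
    truth = tibble(
      sample_id = ids,
      latent_class = factor(latent, levels = CALL_LEVELS),
      signature_positive = latent != "MSS"
    ),
    informative = tibble(gene_id = informative, direction = direction)
  )
}

#' Simulate survival outcomes per latent class
#'
#' Exponential event times whose baseline rate reproduces the configured MSS
#' event fraction at 10 years; latent MSI and MSI-like samples have their
#' hazard multiplied by `hazard_ratio_positive`. Administrative censoring is
#' uniform over `censor_range`.
#'
#' @param latent_class Character vector of latent classes (`MSS`, `MSI_LIKE`,
#'   `MSI`).
#' @param config A [sim_config()].
#' @param seed Seed; defaults to the config seed.
#' @return Tibble `time` (years), `event` (0/1).
#' @export
simulate_survival <- function(latent_class, config = sim_config(),
                              seed = config$seed) {
  cfg <- validate_sim_config(config)
  withr::local_seed(seed)
  n <- length(latent_class)
  base_rate <- -log(1 - cfg$event_rate_mss) / 10
  rate <- base_rate *
    ifelse(latent_class == "MSS", 1, cfg$hazard_ratio_positive)
  if (cfg$event_rate_mss == 0) {
    t_event <- rep(Inf, n)
  } else {
    t_event <- rexp(n, rate)
  }
  t_cens <- runif(n, cfg$censor_range[1L], cfg$censor_range[2L])
  tibble(
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}

decoy_record <- function(kind, sample_id, gene_id) {
  # each decoy violates exactly one inclusion filter
  base <- tibble(
    sample_id = sample_id, gene_id = gene_id,
    position = sample.int(100000L, length(sample_id), replace = TRUE),
    coverage = 40L, variant_count = 12L,
    fwd_variant_count = 6L, rev_variant_count = 6L,
    consequence = "coding_change", in_normal_panel = FALSE
  )
  switch(kind,
    low_coverage = base |> mutate(
      coverage = 9L, variant_count = 5L,
      fwd_variant_count = 3L, rev_variant_count = 2L
    ),
    low_count = base |> mutate(
      variant_count = 4L, fwd_variant_count = 2L, rev_variant_count = 2L
    ),
    single_strand = base |> mutate(
      fwd_variant_count = 12L, rev_variant_count = 0L
    ),
    non_coding = base |> mutate(consequence = "other"),
    germline = base |> mutate(in_normal_panel = TRUE),
    abort("unknown decoy kind")
  )
}

#' Simulate a candidate-variant table
#'
#' Per sample, each panel gene mutates with its latent-class rate. A mutated
#' gene emits 1-3 variant records with negative-binomial coverage (>= 10),
#' variant counts >= 5 and binomial strand split, so genuine mutations
#' survive the inclusion filters. On top, `decoy_fraction` x (number of real
#' records) decoys are injected, each violating exactly one filter; they are
#' marked in a bookkeeping column `decoy` so filter behaviour is checkable.
#'
#' @param truth Tibble `sample_id`, `latent_class` (as from
#'   [simulate_cohort()]).
#' @param config A [sim_config()].
#' @param panel Panel gene ids; defaults to the built-in `panel_size`-gene
#'   panel.
#' @param seed Seed; defaults to the config seed.
#' @return Variant tibble (see [read_variants()]) plus a `decoy` column.
#' @export
simulate_variants <- function(truth, config = sim_config(),
                              panel = sim_panel(config),
                              seed = config$seed) {
  cfg <- validate_sim_config(config)
  withr::local_seed(seed)
  rate_of <- c(MSI = cfg$mut_rate_msi, MSI_LIKE = cfg$mut_rate_msi_like,
               MSS = cfg$mut_rate_mss)
  cls <- as.character(truth$latent_class)
  n_panel <- length(panel)
  real <- purrr::map2(truth$sample_id, cls, function(sid, cl) {
    hit <- panel[runif(n_panel) < rate_of[[cl]]]
    if (length(hit) == 0L) return(NULL)
    n_rec <- sample(1:3, length(hit), replace = TRUE)
    g <- rep(hit, n_rec)
    k <- length(g)
    coverage <- 10L + rnbinom(k, size = 10, mu = 70)
    vc <- 5L + rbinom(k, pmax(coverage - 5L, 0L), 0.3)
    fwd <- rbinom(k, vc, 0.5)
    tibble(
      sample_id = sid, gene_id = g,
      position = sample.int(100000L, k, replace = TRUE),
      coverage = coverage, variant_count = vc,
      fwd_variant_count = fwd, rev_variant_count = vc - fwd,
      consequence = "coding_change", in_normal_panel = FALSE
    )
  }) |> bind_rows()
  n_real <- nrow(real)
  n_decoy <- round(cfg$decoy_fraction * n_real)
  decoys <- if (n_decoy > 0L) {
    kinds <- rep_len(c("low_coverage", "low_count", "single_strand",
                       "non_coding", "germline"), n_decoy)
    sids <- sample(truth$sample_id, n_decoy, replace = TRUE)
    gids <- sample(panel, n_decoy, replace = TRUE)
    purrr::map(split(seq_len(n_decoy), kinds), function(i) {
      decoy_record(kinds[i[1L]], sids[i], gids[i])
    }) |> bind_rows()
  } else {
    NULL
  }
  out <- bind_rows(
    if (n_real > 0L) real |> mutate(decoy = FALSE),
    if (!is.null(decoys)) decoys |> mutate(decoy = TRUE)
  )
  if (nrow(out) == 0L) {
    return(empty_variant_table() |> mutate(decoy = logical()))
  }
  validate_variants(out)
  out
}

#' Simulate technical replicate hybridisations
#'
#' Each replicate is the input expression matrix plus i.i.d. Gaussian
#' technical noise and small whole-array day and operator offsets (days and
#' operators assigned cyclically across replicates).
#'
#' @param expr Wide expression tibble.
#' @param n_replicates Number of replicate matrices. Default 2.
#' @param tech_noise_sd Per-cell noise SD. Default 0.05.
#' @param n_days,n_operators Number of distinct days / operators. Default 1.
#' @param day_sd,operator_sd SDs of the whole-array offsets. Default 0.02.
#' @param seed Seed.
#' @return List of `n_replicates` expression tibbles; attribute `"design"`
#'   maps replicate to day and operator.
#' @export
simulate_replicates <- function(expr, n_replicates = 2L,
                                tech_noise_sd = 0.05,
                                n_days = 1L, n_operators = 1L,
                                day_sd = 0.02, operator_sd = 0.02,
                                seed = 1L) {
  m <- expr_to_matrix(expr)
  withr::local_seed(seed)
  day_offset <- rnorm(n_days, sd = day_sd)
  op_offset <- rnorm(n_operators, sd = operator_sd)
  design <- tibble(
    replicate = seq_len(n_replicates),
    day = rep_len(seq_len(n_days), n_replicates),
    operator = rep_len(seq_len(n_operators), n_replicates)
  )
  out <- purrr::pmap(design, function(replicate, day, operator) {
    noise <- matrix(rnorm(length(m), sd = tech_noise_sd), nrow = nrow(m))
    matrix_to_expr(m + noise + day_offset[day] + op_offset[operator])
  })
  names(out) <- sprintf("rep%d", design$replicate)
  attr(out, "design") <- design
  out
}
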