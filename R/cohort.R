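#' Generator configuration for a synthetic claims cohort
#'
#' Defaults emulate the study conditions of a small anticoagulation safety
#' cohort: 1727 records, a 71.5/28.5 exposed/comparator split, age ~ 74.7
#' (SD 11.7) years, 20 correlated rare-to-common binary comorbidity flags
#' with per-group prevalences, exponential outcome and censoring times whose
#' rates yield tens of death and major-bleeding events (fewer in the
#' comparator arm) with a group rate ratio of 1.25, and calendar dates
#' anchored on a first-VTE diagnosis date.
#'
#' @param n_records number of records.
#' @param group_probability probability of the exposed (first) group label.
#' @param age_mean,age_sd age distribution in years (rounded, clipped to
#'   18..110).
#' @param female_probability length-2 vector, per group (exposed first).
#' @param comorbidity_prevalences 20 x 2 matrix of per-flag per-group
#'   prevalences in `[0,1]`; rownames must match the schema's comorbidity
#'   flags, columns are (exposed, comparator).
#' @param flag_correlation 20 x 20 latent Gaussian correlation matrix
#'   (symmetric PSD, unit diagonal) shared by both groups.
#' @param outcome_hazards named list with elements `death`, `major_bleeding`,
#'   `hospitalization`, each a length-2 vector of exponential rates
#'   (events/day) for (exposed, comparator).
#' @param censoring_rate exponential dropout rate (events/day).
#' @param max_follow_up_days administrative censoring horizon.
#' @param date_anchor_window length-2 Date vector: earliest and latest
#'   first-VTE date.
#' @param seed integer RNG seed.
#' @param schema the [cohort_schema()] the cohort should conform to.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_records = 1727,
                          group_probability = 0.715,
                          age_mean = 74.7, age_sd = 11.7,
                          female_probability = c(0.42, 0.47),
                          comorbidity_prevalences = default_prevalences(),
                          flag_correlation = default_flag_correlation(),
                          outcome_hazards = list(
                            death = c(1.15e-4, 0.92e-4),
                            major_bleeding = c(0.85e-4, 0.68e-4),
                            hospitalization = c(6.0e-4, 7.5e-4)),
                          censoring_rate = 1 / 365,
                          max_follow_up_days = 1080,
                          date_anchor_window = as.Date(c("2016-01-01",
                                                         "2019-12-31")),
                          seed = 1L,
                          schema = default_schema()) {
  cfg <- list(n_records = n_records, group_probability = group_probability,
              age_mean = age_mean, age_sd = age_sd,
              female_probability = female_probability,
              comorbidity_prevalences = comorbidity_prevalences,
              flag_correlation = flag_correlation,
              outcome_hazards = outcome_hazards,
              censoring_rate = censoring_rate,
              max_follow_up_days = max_follow_up_days,
              date_anchor_window = as.Date(date_anchor_window),
              seed = as.integer(seed), schema = schema)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_records < 2) stop("n_records must be at least 2")
  probs <- c(cfg$group_probability, cfg$female_probability,
             cfg$comorbidity_prevalences)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  R <- cfg$flag_correlation
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
      any(abs(diag(R) - 1) > 1e-8)) {
    stop("flag_correlation must be symmetric with unit diagonal")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("flag_correlation must be positive semi-definite")
  }
  rates <- c(unlist(cfg$outcome_hazards), cfg$censoring_rate)
  if (any(rates <= 0)) stop("hazards and censoring rate must be positive")
  invisible(TRUE)
}

#' Default per-group comorbidity prevalences
#'
#' Calibrated to the magnitudes typical of an elderly VTE population on
#' concomitant antiplatelet therapy: hypertension is near-ubiquitous, the
#' obesity flag is deliberately near-zero (a handful of expected cases), and
#' several cardiovascular flags are more common in the comparator arm.
#'
#' @return 20 x 2 matrix (rows = flags, columns = exposed/comparator).
#' @export
default_prevalences <- function() {
  p <- rbind(
    arterial_hypertension     = c(0.70, 0.78),
    varicose_veins_pts        = c(0.14, 0.11),
    stroke                    = c(0.07, 0.10),
    liver_disease_mod_severe  = c(0.015, 0.025),
    obesity                   = c(0.002, 0.002),
    myocardial_infarction     = c(0.05, 0.08),
    oral_contraception        = c(0.012, 0.006),
    tamoxifen                 = c(0.005, 0.004),
    diabetes_mellitus         = c(0.28, 0.33),
    chronic_heart_failure     = c(0.18, 0.26),
    renal_disease             = c(0.17, 0.24),
    copd                      = c(0.12, 0.14),
    cancer                    = c(0.10, 0.12),
    atrial_fibrillation       = c(0.15, 0.30),
    peripheral_artery_disease = c(0.06, 0.09),
    prior_major_bleeding      = c(0.04, 0.05),
    anemia                    = c(0.08, 0.10),
    alcohol_abuse             = c(0.03, 0.03),
    thrombophilia             = c(0.05, 0.04),
    nsaid_use                 = c(0.20, 0.18))
  colnames(p) <- c("exposed", "comparator")
  p
}

#' Default latent correlation between comorbidity flags
#'
#' Identity plus modest positive cardio-metabolic blocks (e.g. hypertension
#' with diabetes and heart failure, heart failure with atrial fibrillation
#' and renal disease). Verified positive definite.
#'
#' @return 20 x 20 correlation matrix.
#' @export
default_flag_correlation <- function() {
  flags <- rownames(default_prevalences())
  R <- diag(length(flags))
  dimnames(R) <- list(flags, flags)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("arterial_hypertension", "diabetes_mellitus", 0.30)
  set_r("arterial_hypertension", "chronic_heart_failure", 0.25)
  set_r("chronic_heart_failure", "atrial_fibrillation", 0.30)
  set_r("chronic_heart_failure", "renal_disease", 0.25)
  set_r("stroke", "atrial_fibrillation", 0.20)
  set_r("myocardial_infarction", "peripheral_artery_disease", 0.25)
  set_r("cancer", "anemia", 0.20)
  set_r("renal_disease", "diabetes_mellitus", 0.20)
  R
}

#' Generate a synthetic claims cohort
#'
#' Deterministic given the config seed. Treatment groups are Bernoulli draws;
#' correlated binary comorbidity flags come from a latent Gaussian threshold
#' model (one latent draw per record, thresholded at per-group normal
#' quantiles); outcome times are exponential with per-group rates, right
#' censored by an exponential dropout time and an administrative follow-up
#' horizon. Major bleeding and hospitalization are additionally truncated at
#' death. Dates are anchored on a uniformly drawn first-VTE diagnosis date;
#' day offsets are integers relative to that anchor (offset 0 = anchor).
#'
#' @param config a [cohort_config()].
#' @return data.frame conforming to `config$schema`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  schema <- config$schema
  n <- config$n_records
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(config$seed)

  grp <- ifelse(stats::runif(n) < config$group_probability, 1L, 2L)
  labels <- schema$group_labels

  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                   18L), 110L)
  female <- stats::runif(n) < config$female_probability[grp]
  gender <- ifelse(female, "female", "male")

  # latent Gaussian threshold draws for the 20 flags
  R <- config$flag_correlation
  ev <- eigen(R, symmetric = TRUE)
  rootR <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Z <- matrix(stats::rnorm(n * ncol(R)), n) %*% rootR
  prev <- config$comorbidity_prevalences
  flags <- matrix(0L, n, nrow(prev), dimnames = list(NULL, rownames(prev)))
  for (j in seq_len(nrow(prev))) {
    thr <- stats::qnorm(prev[j, ])        # per-group threshold
    flags[, j] <- as.integer(Z[, j] < thr[grp])
  }

  anchor_days <- as.integer(config$date_anchor_window[1]) +
    floor(stats::runif(n) * (as.integer(diff(config$date_anchor_window)) + 1))
  first_vte <- as.Date(anchor_days, origin = "1970-01-01")
  index_date <- first_vte + sample.int(31L, n, replace = TRUE) - 1L

  admin <- config$max_follow_up_days
  censor <- stats::rexp(n, config$censoring_rate)
  draw_event <- function(rates) stats::rexp(n, rates[grp])
  t_death <- draw_event(config$outcome_hazards$death)
  t_bleed <- draw_event(config$outcome_hazards$major_bleeding)
  t_hosp <- draw_event(config$outcome_hazards$hospitalization)

  end_death <- pmin(t_death, censor, admin)
  death_flag <- as.integer(t_death <= pmin(censor, admin))
  death_time <- round(pmax(end_death, 1))
  # bleeding/hospitalization end at the earliest of their event, death,
  # dropout and the administrative horizon
  end_bleed <- pmin(t_bleed, t_death, censor, admin)
  bleed_flag <- as.integer(t_bleed <= pmin(t_death, censor, admin))
  bleed_time <- round(pmax(end_bleed, 1))
  end_hosp <- pmin(t_hosp, t_death, censor, admin)
  hosp_flag <- as.integer(t_hosp <= pmin(t_death, censor, admin))
  hosp_time <- round(pmax(end_hosp, 1))

  follow_up_end <- index_date + round(pmax(end_death, 1))
  exposure <- round(pmin(stats::rexp(n, 1 / 180), pmax(end_death, 1)))
  antiplatelet <- round(pmin(stats::rexp(n, 1 / 240), pmax(end_death, 1)))

  birth_year <- as.integer(format(first_vte, "%Y")) - age
  birth_quarter <- as.Date(sprintf("%d-%02d-01", birth_year,
                                   (sample.int(4L, n, replace = TRUE) - 1L) * 3L + 1L))

  out <- data.frame(
    age = age, gender = gender, birth_quarter = birth_quarter,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  out$insured_id <- sprintf("P%06d", seq_len(n))
  out$treatment_group <- labels[grp]
  out$first_vte_date <- first_vte
  out$index_date <- index_date
  out$follow_up_end_date <- follow_up_end
  out$index_offset <- as.numeric(index_date - first_vte)
  out$follow_up_end_offset <- as.numeric(follow_up_end - first_vte)
  out$exposure_duration_days <- exposure
  out$antiplatelet_duration_days <- antiplatelet
  out$death_flag <- death_flag
  out$death_time_days <- death_time
  out$major_bleeding_flag <- bleed_flag
  out$major_bleeding_time_days <- bleed_time
  out$censored_flag <- 1L - death_flag
  out$hospitalization_flag <- hosp_flag
  out$hospitalization_time_days <- hosp_time

  out <- out[, schema$attributes$name]
  validate_cohort(out, schema)
  out
}

#' Serialize / load a generator configuration as YAML
#'
#' The schema itself is stored separately (see [write_schema_yaml()]); the
#' loader reattaches [default_schema()] unless another schema is supplied.
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @param schema schema to attach on read.
#' @export
write_cohort_config_yaml <- function(config, path) {
  prev <- config$comorbidity_prevalences
  yaml::write_yaml(list(
    n_records = config$n_records,
    group_probability = config$group_probability,
    age_mean = config$age_mean, age_sd = config$age_sd,
    female_probability = as.list(config$female_probability),
    comorbidity_prevalences = list(flags = rownames(prev),
                                   exposed = as.list(unname(prev[, 1])),
                                   comparator = as.list(unname(prev[, 2]))),
    flag_correlation = apply(config$flag_correlation, 1, as.list,
                             simplify = FALSE),
    outcome_hazards = lapply(config$outcome_hazards, as.list),
    censoring_rate = config$censoring_rate,
    max_follow_up_days = config$max_follow_up_days,
    date_anchor_window = format(config$date_anchor_window, "%Y-%m-%d"),
    seed = config$seed), path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_config_yaml
#' @export
read_cohort_config_yaml <- function(path, schema = default_schema()) {
  y <- yaml::read_yaml(path)
  prev <- cbind(exposed = unlist(y$comorbidity_prevalences$exposed),
                comparator = unlist(y$comorbidity_prevalences$comparator))
  rownames(prev) <- unlist(y$comorbidity_prevalences$flags)
  R <- do.call(rbind, lapply(y$flag_correlation, unlist))
  dimnames(R) <- list(rownames(prev), rownames(prev))
  cohort_config(
    n_records = y$n_records, group_probability = y$group_probability,
    age_mean = y$age_mean, age_sd = y$age_sd,
    female_probability = unlist(y$female_probability),
    comorbidity_prevalences = prev, flag_correlation = R,
    outcome_hazards = lapply(y$outcome_hazards, unlist),
    censoring_rate = y$censoring_rate,
    max_follow_up_days = y$max_follow_up_days,
    date_anchor_window = as.Date(unlist(y$date_anchor_window)),
    seed = y$seed, schema = schema)
}

#' Partition a cohort into train / control / attacker-pool splits
#'
#' Disjoint row partition, reproducible given the seed. The train split feeds
#' protected-data generation, the control split feeds control attacks, and
#' the attacker pool feeds shadow-model reference sampling.
#'
#' @param cohort data.frame.
#' @param fractions length-3 numeric (train, control, attacker_pool), each
#'   positive, summing to at most 1.
#' @param seed integer.
#' @return named list of three data.frames (`train`, `control`, `pool`) with
#'   a `row_indices` attribute each.
#' @export
split_cohort <- function(cohort, fractions = c(0.5, 0.25, 0.25), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            sum(fractions) <= 1 + 1e-9)
  n <- nrow(cohort)
  sizes <- floor(fractions * n + 1e-9)
  if (any(sizes == 0)) stop("a split would be empty")
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  perm <- sample.int(n)
  idx <- list(train = perm[seq_len(sizes[1])],
              control = perm[sizes[1] + seq_len(sizes[2])],
              pool = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  out <- lapply(idx, function(i) {
    d <- cohort[sort(i), , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "row_indices") <- sort(i)
    d
  })
  out
}
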