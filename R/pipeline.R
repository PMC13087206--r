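#' Reporting helpers: percentages and relative changes
#'
#' `pct_of_original` expresses a retained count as a percentage of the
#' original count at one decimal; `relative_change` expresses a protected
#' mean as a percent change from the original mean at two decimals;
#' `proportion_shift` is the difference between two group percentages in
#' percentage points at one decimal.
#'
#' @param n,n0 retained / original counts.
#' @param new,old protected / original means.
#' @param p_new,p_old group shares in percent.
#' @return rounded numeric.
#' @export
pct_of_original <- function(n, n0) round(100 * n / n0, 1)

#' @rdname pct_of_original
#' @export
relative_change <- function(new, old) round(100 * (new - old) / old, 2)

#' @rdname pct_of_original
#' @export
proportion_shift <- function(p_new, p_old) round(p_new - p_old, 1)

#' Population summary of a protected dataset versus the original
#'
#' Emits the descriptive comparison used for dataset characteristics: total
#' records with percent of original, per-group counts with percent of group
#' total, female counts, age mean (SD) and the relative mean-age change.
#'
#' @param original,protected data.frames sharing the schema.
#' @param schema a [cohort_schema()].
#' @return data.frame with one row per dataset.
#' @export
summarize_table1 <- function(original, protected, schema = default_schema()) {
  tc <- schema$treatment_column
  gl <- schema$group_labels
  row <- function(d, n0, age0) {
    tr <- d[[tc]]
    n <- nrow(d)
    n1 <- sum(tr == gl[1], na.rm = TRUE)
    n2 <- sum(tr == gl[2], na.rm = TRUE)
    fem <- sum(d$gender == "female", na.rm = TRUE)
    age <- as.numeric(d$age)
    data.frame(
      n = n, pct_of_original = pct_of_original(n, n0),
      n_exposed = n1, pct_exposed = round(100 * n1 / (n1 + n2), 1),
      n_comparator = n2, pct_comparator = round(100 * n2 / (n1 + n2), 1),
      n_female = fem, pct_female = round(100 * fem / n, 1),
      age_mean = round(mean(age, na.rm = TRUE), 2),
      age_sd = round(stats::sd(age, na.rm = TRUE), 2),
      age_change_pct = relative_change(mean(age, na.rm = TRUE), age0))
  }
  age0 <- mean(as.numeric(original$age), na.rm = TRUE)
  out <- rbind(cbind(dataset = "original",
                     row(original, nrow(original), age0)),
               cbind(dataset = "protected",
                     row(protected, nrow(original), age0)))
  out
}

#' Pipeline run configuration
#'
#' Bundles the stage configurations for a full three-way comparison. The two
#' anonymization configurations share `k` and `t` and differ only in the
#' protected-attribute sets (all attributes versus the threat-modeled ones).
#'
#' @param cohort_cfg a [cohort_config()].
#' @param split_fractions train/control/pool fractions.
#' @param profiles threat profiles (default [default_profiles()]).
#' @param threshold indirect-identifier threshold.
#' @param k,t shared anonymization parameters.
#' @param synth_cfg a [synth_config()].
#' @param repetitions attack repetitions per dataset.
#' @param include_mia run shadow-model membership inference (expensive;
#'   context-independent scenario only).
#' @param mia_cfg an [mia_config()].
#' @param seed stage seed.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort_cfg = cohort_config(),
                       split_fractions = c(0.5, 0.25, 0.25),
                       profiles = default_profiles(),
                       threshold = default_threshold(),
                       k = 2L, t = 0.5,
                       synth_cfg = synth_config(),
                       repetitions = 10L,
                       include_mia = FALSE,
                       mia_cfg = mia_config(),
                       seed = 1L) {
  structure(list(cohort_cfg = cohort_cfg,
                 split_fractions = split_fractions,
                 profiles = profiles, threshold = threshold,
                 k = k, t = t, synth_cfg = synth_cfg,
                 repetitions = repetitions,
                 include_mia = include_mia, mia_cfg = mia_cfg,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full comparison pipeline
#'
#' Simulates a cohort, splits it, protects the train split three ways
#' (context-independent anonymization, context-dependent anonymization,
#' synthetization), and evaluates every protected dataset on fidelity,
#' study-level utility and empirical privacy risk under both adversary
#' scenarios (context-dependent attacks use the classified indirect
#' identifiers as auxiliary knowledge, context-independent attacks use all
#' attributes). The original train split is attacked as a baseline.
#' Membership inference, when enabled, runs in the context-independent
#' scenario only.
#'
#' @param config a [run_config()].
#' @return a `run_bundle` list with per-stage artifacts and report tables.
#' @export
run_all <- function(config = run_config()) {
  schema <- config$cohort_cfg$schema
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  cohort <- stage("simulate", generate_cohort(config$cohort_cfg))
  splits <- stage("split", split_cohort(cohort, config$split_fractions,
                                        seed = config$seed))
  classification <- stage("threat-model",
                          classify_attributes(config$profiles,
                                              config$threshold, schema))
  hiers <- default_hierarchies(schema)
  cfg_ci <- scenario_anon_config(classification, "context-independent",
                                 schema, k = config$k, t = config$t)
  cfg_cd <- scenario_anon_config(classification, "context-dependent",
                                 schema, k = config$k, t = config$t)
  anon_ci <- stage("anonymize-independent",
                   anonymize(splits$train, cfg_ci, hiers))
  anon_cd <- stage("anonymize-dependent",
                   anonymize(splits$train, cfg_cd, hiers))
  model <- stage("synthesize-fit",
                 synth_fit(splits$train, config$synth_cfg, schema))
  synth <- stage("synthesize-sample",
                 synth_sample(model, nrow(splits$train),
                              seed = config$seed + 1L))

  protected <- list("independent_anonymization" = anon_ci$table,
                    "dependent_anonymization" = anon_cd$table,
                    "synthetization" = synth)

  table1 <- lapply(protected, function(p)
    summarize_table1(splits$train, harmonize_cohort(p, schema), schema))
  fidelity <- stage("fidelity", lapply(protected, function(p)
    fidelity_report(harmonize_cohort(splits$train, schema),
                    harmonize_cohort(p, schema), schema$treatment_column)))
  utility <- stage("utility", c(
    list(original = run_utility(splits$train, schema)),
    lapply(protected, function(p) run_utility(p, schema))))

  indirect <- classified_as(classification, "indirect")
  scenarios <- list(
    "context-dependent" = indirect,
    "context-independent" = setdiff(schema$attributes$name, "insured_id"))
  attacked <- c(list(original = splits$train), protected)
  risks <- stage("attacks", lapply(names(scenarios), function(sc) {
    aux <- scenarios[[sc]]
    lapply(names(attacked), function(ds) {
      rel <- harmonize_cohort(attacked[[ds]], schema)
      acfg <- attack_config(aux_attributes = aux,
                            repetitions = config$repetitions,
                            seed = config$seed + 7L)
      list(dataset = ds,
           linkage = linkage(rel, splits$train, splits$control,
                             config = acfg),
           singling_out_uni = singling_out(rel, splits$train, splits$control,
                                           "univariate", acfg),
           singling_out_multi = singling_out(rel, splits$train,
                                             splits$control, "multivariate",
                                             acfg))
    })
  }))
  names(risks) <- names(scenarios)

  mia <- NULL
  if (config$include_mia) {
    mia <- stage("membership-inference", {
      tg <- select_targets(splits$pool, config$mia_cfg$n_average_targets,
                           config$mia_cfg$n_outlier_targets)
      protectors <- list(
        independent_anonymization = protector_anonymizer(cfg_ci, hiers),
        dependent_anonymization = protector_anonymizer(cfg_cd, hiers),
        synthetization = protector_synthesizer(config$synth_cfg, schema))
      lapply(protectors, function(pr) {
        lapply(c(average = "average", outlier = "outlier"), function(kind) {
          idx <- tg[[kind]]
          vapply(idx, function(i)
            membership_inference(splits$pool[i, , drop = FALSE], pr,
                                 splits$pool[-i, , drop = FALSE],
                                 config$mia_cfg)$risk, 0)
        })
      })
    })
  }

  structure(list(cohort = cohort, splits = splits,
                 classification = classification,
                 anon_independent = anon_ci, anon_dependent = anon_cd,
                 synth_model_diagnostics = model$diagnostics,
                 protected = protected,
                 table1 = table1, fidelity = fidelity, utility = utility,
                 risks = risks, mia = mia, seed = config$seed),
            class = "run_bundle")
}

#' Write the report tables of a pipeline run
#'
#' Emits CSV/JSON artifacts (population summaries, fidelity metrics, utility
#' table, risk matrix) under an output directory.
#'
#' @param bundle a `run_bundle` from [run_all()].
#' @param dir output directory (created if needed).
#' @return invisibly the directory.
#' @export
write_run_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- do.call(rbind, lapply(names(bundle$table1), function(nm) {
    d <- bundle$table1[[nm]]
    d$comparison <- nm
    d
  }))
  utils::write.csv(t1, file.path(dir, "table1_population.csv"),
                   row.names = FALSE)
  fid <- do.call(rbind, lapply(names(bundle$fidelity), function(nm) {
    f <- bundle$fidelity[[nm]]
    data.frame(dataset = nm, correlation_distance = f$correlation_distance,
               ip_alpha = f$ip_alpha, ir_beta = f$ir_beta,
               authenticity = f$authenticity)
  }))
  utils::write.csv(fid, file.path(dir, "table2_fidelity.csv"),
                   row.names = FALSE)
  ut <- do.call(rbind, lapply(names(bundle$utility), function(nm) {
    d <- bundle$utility[[nm]]$outcomes
    d$dataset <- nm
    d
  }))
  ut$hr <- round(ut$hr, 2)
  ut$ci_low <- round(ut$ci_low, 2)
  ut$ci_high <- round(ut$ci_high, 2)
  utils::write.csv(ut, file.path(dir, "table3_utility.csv"),
                   row.names = FALSE)
  rk <- do.call(rbind, lapply(names(bundle$risks), function(sc) {
    do.call(rbind, lapply(bundle$risks[[sc]], function(entry) {
      do.call(rbind, lapply(c("linkage", "singling_out_uni",
                              "singling_out_multi"), function(att) {
        r <- entry[[att]]
        data.frame(scenario = sc, dataset = entry$dataset, attack = att,
                   risk = round(r$risk, 2), sd = round(r$risk_sd, 2),
                   valid = r$valid)
      }))
    }))
  }))
  utils::write.csv(rk, file.path(dir, "table4_risks.csv"), row.names = FALSE)
  if (!is.null(bundle$mia)) {
    mi <- do.call(rbind, lapply(names(bundle$mia), function(pr) {
      do.call(rbind, lapply(names(bundle$mia[[pr]]), function(kind) {
        data.frame(protector = pr, target_kind = kind,
                   mean_risk = round(mean(bundle$mia[[pr]][[kind]]), 3))
      }))
    }))
    utils::write.csv(mi, file.path(dir, "table5_mia.csv"), row.names = FALSE)
  }
  invisible(dir)
}
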