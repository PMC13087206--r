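#' Harmonize a cohort to the analysis schema
#'
#' Single standardized preprocessing applied identically to every dataset
#' before utility and fidelity evaluation: types are cast per the schema,
#' the treatment column is restricted to the group labels, and redundant
#' date/offset representations are recomputed from whichever representation
#' survived protection (offsets from dates when offsets are missing, dates
#' from the anchor plus offsets when dates are missing).
#'
#' @param table data.frame.
#' @param schema a [cohort_schema()].
#' @return harmonized data.frame.
#' @export
harmonize_cohort <- function(table, schema = default_schema()) {
  out <- table
  for (i in seq_len(nrow(schema$attributes))) {
    nm <- schema$attributes$name[i]
    if (!nm %in% names(out)) {
      out[[nm]] <- NA
      next
    }
    v <- out[[nm]]
    out[[nm]] <- switch(schema$attributes$type[i],
      "integer-age-years" = as.integer(round(as.numeric(v))),
      "binary-flag" = as.integer(round(as.numeric(v))),
      "day-offset" = as.numeric(v),
      "event-time-days" = as.numeric(v),
      "date" = as.Date(v, origin = "1970-01-01"),
      as.character(v))
  }
  tc <- schema$treatment_column
  out[[tc]][!out[[tc]] %in% schema$group_labels] <- NA
  # recompute redundant representations
  anchor <- out[["first_vte_date"]]
  pairs <- list(c("index_date", "index_offset"),
                c("follow_up_end_date", "follow_up_end_offset"))
  for (p in pairs) {
    if (!all(p %in% names(out)) || is.null(anchor)) next
    d <- out[[p[1]]]
    o <- out[[p[2]]]
    fill_off <- is.na(o) & !is.na(d) & !is.na(anchor)
    o[fill_off] <- as.numeric(d[fill_off] - anchor[fill_off])
    fill_date <- is.na(d) & !is.na(o) & !is.na(anchor)
    d[fill_date] <- anchor[fill_date] + round(o[fill_date])
    out[[p[1]]] <- d
    out[[p[2]]] <- o
  }
  out[, schema$attributes$name]
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Fits a logistic propensity model of treatment on the covariates and
#' returns stabilized ATE weights: `P(T=1)/e` for the exposed group and
#' `P(T=0)/(1-e)` for the comparator. Covariates that are constant or fully
#' missing are dropped; remaining missing covariate values are imputed with
#' the column median so that protected datasets with suppressed cells remain
#' analyzable.
#'
#' @param cohort data.frame.
#' @param covariates covariate column names (numeric or binary).
#' @param treatment treatment column; the first `group_labels` entry (or
#'   factor level) is the exposed group.
#' @param group_labels length-2 labels (exposed, comparator).
#' @param truncate optional quantile in (0.5, 1] at which weights are capped
#'   (default `NULL`, no truncation).
#' @return list with `weights`, `propensity`, `exposed` (logical), and
#'   `covariates_used`.
#' @export
propensity_weights <- function(cohort, covariates, treatment,
                               group_labels, truncate = NULL) {
  tr <- cohort[[treatment]]
  keep_rows <- !is.na(tr) & tr %in% group_labels
  if (!any(keep_rows)) {
    warning("treatment column carries no usable values; weights are NA")
    return(list(weights = rep(NA_real_, length(tr)),
                propensity = rep(NA_real_, length(tr)),
                exposed = rep(NA, length(tr)), covariates_used = character()))
  }
  exposed <- tr == group_labels[1]
  X <- list()
  used <- character()
  for (nm in covariates) {
    v <- cohort[[nm]]
    if (inherits(v, "Date")) v <- as.numeric(v)
    if (is.character(v) || is.factor(v)) {
      v <- as.numeric(as.factor(v)) - 1
    }
    v <- as.numeric(v)
    if (all(is.na(v))) next
    med <- stats::median(v, na.rm = TRUE)
    v[is.na(v)] <- med
    if (stats::var(v) <= 0) next
    X[[nm]] <- v
    used <- c(used, nm)
  }
  if (!length(X)) {
    # no usable covariates: propensity is the marginal rate, all weights 1
    e <- rep(mean(exposed[keep_rows]), length(tr))
  } else {
    df <- as.data.frame(X)
    df$.treat <- as.integer(exposed)
    fit <- suppressWarnings(
      stats::glm(.treat ~ ., data = df[keep_rows, , drop = FALSE],
                 family = stats::binomial()))
    e <- rep(NA_real_, length(tr))
    e[keep_rows] <- stats::predict(fit, newdata = df[keep_rows, , drop = FALSE],
                                   type = "response")
    if (any(e[keep_rows] < 1e-10 | e[keep_rows] > 1 - 1e-10)) {
      worst <- names(which.max(abs(stats::coef(fit)[-1])))
      stop("perfect separation in propensity model (covariate: ", worst, ")")
    }
  }
  p1 <- mean(exposed[keep_rows])
  w <- ifelse(exposed, p1 / e, (1 - p1) / (1 - e))
  w[!keep_rows] <- NA
  if (!is.null(truncate)) {
    cap <- stats::quantile(w, truncate, na.rm = TRUE)
    w <- pmin(w, cap)
  }
  list(weights = w, propensity = e, exposed = exposed,
       covariates_used = used)
}

#' Standardized mean differences before and after weighting
#'
#' `SMD = (mean_exposed - mean_comparator) / pooled SD`, with the pooled SD
#' as the square root of the average of the two group variances. The
#' weighted version uses weighted means and variances.
#'
#' @param cohort data.frame.
#' @param weights per-record weights (>= 0; `NA` rows are dropped).
#' @param covariates covariate columns.
#' @param treatment,group_labels as in [propensity_weights()].
#' @return data.frame with `covariate`, `smd_before`, `smd_after`.
#' @export
smd_balance <- function(cohort, weights, covariates, treatment,
                        group_labels) {
  tr <- cohort[[treatment]]
  res <- lapply(covariates, function(nm) {
    v <- cohort[[nm]]
    if (inherits(v, "Date")) v <- as.numeric(v)
    if (is.character(v) || is.factor(v)) v <- as.numeric(as.factor(v)) - 1
    v <- as.numeric(v)
    smd_one <- function(w) {
      ok <- !is.na(v) & !is.na(tr) & !is.na(w) & tr %in% group_labels
      g1 <- ok & tr == group_labels[1]
      g0 <- ok & tr == group_labels[2]
      if (!any(g1) || !any(g0)) return(NA_real_)
      wm <- function(idx) stats::weighted.mean(v[idx], w[idx])
      wv <- function(idx) {
        mu <- wm(idx)
        sum(w[idx] * (v[idx] - mu)^2) / sum(w[idx])
      }
      pooled <- sqrt((wv(g1) + wv(g0)) / 2)
      if (!is.finite(pooled) || pooled <= 0) return(NA_real_)
      (wm(g1) - wm(g0)) / pooled
    }
    data.frame(covariate = nm,
               smd_before = smd_one(rep(1, length(v))),
               smd_after = smd_one(weights))
  })
  do.call(rbind, res)
}

#' Weighted Cox hazard ratio for one outcome
#'
#' Weighted partial-likelihood Cox fit with treatment as the sole covariate
#' and a robust (sandwich) variance for the 95% confidence interval. When
#' either arm has zero events the fit is flagged non-estimable and `NA`s are
#' returned.
#'
#' @param cohort data.frame.
#' @param weights per-record weights.
#' @param outcome_flag,outcome_time event indicator / time-to-event columns.
#' @param treatment,group_labels as in [propensity_weights()].
#' @return list with `hr`, `ci_low`, `ci_high`, `events` (named per group),
#'   `estimable`.
#' @export
weighted_cox_hr <- function(cohort, weights, outcome_flag, outcome_time,
                            treatment, group_labels) {
  tr <- cohort[[treatment]]
  flag <- as.integer(round(as.numeric(cohort[[outcome_flag]])))
  time <- as.numeric(cohort[[outcome_time]])
  ok <- !is.na(tr) & tr %in% group_labels & !is.na(flag) & !is.na(time) &
    !is.na(weights)
  time <- pmax(time, 0.5)  # guard against generalized zero times
  events <- c(sum(flag[ok & tr == group_labels[1]]),
              sum(flag[ok & tr == group_labels[2]]))
  names(events) <- group_labels
  if (any(events == 0) || sum(flag[ok]) == 0) {
    return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                events = events, estimable = FALSE))
  }
  d <- data.frame(time = time[ok], flag = flag[ok],
                  exposed = as.integer(tr[ok] == group_labels[1]),
                  w = weights[ok])
  fit <- survival::coxph(survival::Surv(time, flag) ~ exposed, data = d,
                         weights = w, robust = TRUE)
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  list(hr = exp(beta),
       ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se),
       events = events, estimable = TRUE)
}

#' Study-level utility report
#'
#' Reproduces the study analysis on any cohort conforming to the default
#' schema: stabilized IPTW on the 20 comorbidity flags plus age and gender,
#' then weighted Cox hazard ratios with robust 95% CIs for all-cause
#' mortality and major bleeding, with event counts per arm and covariate
#' balance before/after weighting.
#'
#' @param cohort data.frame (harmonized internally).
#' @param schema a [cohort_schema()].
#' @return a `utility_report`: per-outcome rows (`events_exposed`,
#'   `events_comparator`, `hr`, `ci_low`, `ci_high`, `estimable`) and the
#'   SMD balance table.
#' @export
run_utility <- function(cohort, schema = default_schema()) {
  d <- harmonize_cohort(cohort, schema)
  covs <- c(schema_attributes(schema, role = "comorbidity"), "age", "gender")
  tc <- schema$treatment_column
  gl <- schema$group_labels
  # rare flags can separate the arms perfectly; drop them and refit
  active <- covs
  for (attempt in 1:5) {
    pw <- tryCatch(propensity_weights(d, active, tc, gl),
                   error = function(e) e)
    if (!inherits(pw, "error")) break
    bad <- sub("^.*covariate: (.*)\\)$", "\\1", conditionMessage(pw))
    if (!bad %in% active) stop(pw)
    warning("dropping separating covariate from the propensity model: ", bad)
    active <- setdiff(active, bad)
  }
  if (inherits(pw, "error")) stop(pw)
  bal <- smd_balance(d, pw$weights, covs, tc, gl)
  outcomes <- list(
    all_cause_mortality = c("death_flag", "death_time_days"),
    major_bleeding = c("major_bleeding_flag", "major_bleeding_time_days"))
  rows <- lapply(names(outcomes), function(nm) {
    oc <- outcomes[[nm]]
    fit <- weighted_cox_hr(d, pw$weights, oc[1], oc[2], tc, gl)
    data.frame(outcome = nm,
               events_exposed = unname(fit$events[1]),
               events_comparator = unname(fit$events[2]),
               hr = fit$hr, ci_low = fit$ci_low, ci_high = fit$ci_high,
               estimable = fit$estimable)
  })
  structure(list(outcomes = do.call(rbind, rows), balance = bal,
                 covariates_used = pw$covariates_used,
                 weight_summary = summary(pw$weights)),
            class = "utility_report")
}

#' @export
print.utility_report <- function(x, ...) {
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}
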