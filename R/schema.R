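#' Cohort schema
#'
#' A cohort schema fixes the attribute list of a claims cohort: each attribute
#' has a name, a semantic type and a role. The semantic type drives how the
#' anonymizer, the generator and the evaluation stages treat a column; the
#' role (`demographic`, `comorbidity`, `study-info`, `outcome`) mirrors the
#' structure of a per-patient analysis dataset extracted from claims.
#'
#' @param attributes data.frame with columns `name`, `type`, `role` (and
#'   optionally `provenance`).
#' @param treatment_column name of the treatment-group attribute.
#' @param group_labels character vector of length 2, exposed label first.
#' @param event_pairs named character vector mapping outcome event-flag
#'   attributes to their paired event-time attributes.
#' @return an object of class `cohort_schema`.
#' @export
cohort_schema <- function(attributes, treatment_column, group_labels,
                          event_pairs = character()) {
  stopifnot(is.data.frame(attributes),
            all(c("name", "type", "role") %in% names(attributes)))
  if (anyDuplicated(attributes$name)) {
    stop("attribute names must be unique")
  }
  bad_type <- setdiff(attributes$type, c(
    "integer-age-years", "categorical", "binary-flag", "date",
    "day-offset", "event-time-days"))
  if (length(bad_type)) stop("unknown semantic type(s): ",
                             paste(bad_type, collapse = ", "))
  bad_role <- setdiff(attributes$role,
                      c("demographic", "comorbidity", "study-info", "outcome"))
  if (length(bad_role)) stop("unknown role(s): ",
                             paste(bad_role, collapse = ", "))
  if (!treatment_column %in% attributes$name) {
    stop("treatment column not in schema: ", treatment_column)
  }
  if (length(group_labels) != 2L) stop("exactly two group labels required")
  if (length(event_pairs)) {
    missing <- setdiff(c(names(event_pairs), unname(event_pairs)),
                       attributes$name)
    if (length(missing)) stop("event pair attributes not in schema: ",
                              paste(missing, collapse = ", "))
  }
  structure(list(attributes = attributes,
                 treatment_column = treatment_column,
                 group_labels = group_labels,
                 event_pairs = event_pairs),
            class = "cohort_schema")
}

#' Default 39-attribute claims-cohort schema
#'
#' Fixed stand-in schema for a one-row-per-patient anticoagulation cohort:
#' 3 demographic attributes (age, gender, birth quarter), 20 binary
#' comorbidity flags, 9 study-information attributes (pseudonymized patient
#' id, treatment group, anchor and derived dates plus their day-offset
#' copies, exposure durations) and 7 outcome attributes (death and major
#' bleeding flag/time pairs, a censoring indicator and an auxiliary
#' hospitalization flag/time pair).
#'
#' Eight comorbidity flags carry names used in the underlying medication
#' safety study (arterial hypertension, varicose veins / post-thrombotic
#' syndrome, stroke, moderate/severe liver disease, obesity, myocardial
#' infarction, oral contraception, tamoxifen); the remaining twelve are
#' documented synthetic stand-ins for the unpublished attribute list, marked
#' via the `provenance` column.
#'
#' @return a [cohort_schema()] with 39 attributes.
#' @export
default_schema <- function() {
  named <- c("arterial_hypertension", "varicose_veins_pts", "stroke",
             "liver_disease_mod_severe", "obesity", "myocardial_infarction",
             "oral_contraception", "tamoxifen")
  standin <- c("diabetes_mellitus", "chronic_heart_failure", "renal_disease",
               "copd", "cancer", "atrial_fibrillation",
               "peripheral_artery_disease", "prior_major_bleeding", "anemia",
               "alcohol_abuse", "thrombophilia", "nsaid_use")
  attrs <- rbind(
    data.frame(name = c("age", "gender", "birth_quarter"),
               type = c("integer-age-years", "categorical", "date"),
               role = "demographic", provenance = "named"),
    data.frame(name = c(named, standin), type = "binary-flag",
               role = "comorbidity",
               provenance = rep(c("named", "stand-in"),
                                c(length(named), length(standin)))),
    data.frame(name = c("insured_id", "treatment_group", "first_vte_date",
                        "index_date", "follow_up_end_date", "index_offset",
                        "follow_up_end_offset", "exposure_duration_days",
                        "antiplatelet_duration_days"),
               type = c("categorical", "categorical", "date", "date", "date",
                        "day-offset", "day-offset", "day-offset",
                        "day-offset"),
               role = "study-info", provenance = "stand-in"),
    data.frame(name = c("death_flag", "death_time_days",
                        "major_bleeding_flag", "major_bleeding_time_days",
                        "censored_flag", "hospitalization_flag",
                        "hospitalization_time_days"),
               type = c("binary-flag", "event-time-days", "binary-flag",
                        "event-time-days", "binary-flag", "binary-flag",
                        "event-time-days"),
               role = "outcome", provenance = "stand-in"))
  cohort_schema(attrs,
                treatment_column = "treatment_group",
                group_labels = c("DOAC", "VKA"),
                event_pairs = c(death_flag = "death_time_days",
                                major_bleeding_flag = "major_bleeding_time_days",
                                hospitalization_flag = "hospitalization_time_days"))
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("cohort_schema:", nrow(x$attributes), "attributes (",
      paste(sprintf("%s=%d", names(table(x$attributes$role)),
                    table(x$attributes$role)), collapse = ", "),
      ")\n")
  cat("treatment column:", x$treatment_column, "- groups:",
      paste(x$group_labels, collapse = " vs "), "\n")
  invisible(x)
}

#' Names of schema attributes by role or type
#'
#' @param schema a [cohort_schema()].
#' @param role optional role filter.
#' @param type optional semantic-type filter.
#' @return character vector of attribute names.
#' @export
schema_attributes <- function(schema, role = NULL, type = NULL) {
  a <- schema$attributes
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(type)) keep <- keep & a$type %in% type
  a$name[keep]
}

#' Validate a cohort table against its schema
#'
#' Checks that every schema attribute is present, event times are
#' non-negative and treatment values are restricted to the group labels.
#'
#' @param table data.frame holding one record per row.
#' @param schema a [cohort_schema()].
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_cohort <- function(table, schema) {
  missing <- setdiff(schema$attributes$name, names(table))
  if (length(missing)) stop("cohort is missing attributes: ",
                            paste(missing, collapse = ", "))
  tt <- table[[schema$treatment_column]]
  bad <- !is.na(tt) & !(tt %in% schema$group_labels)
  if (any(bad)) stop("treatment values outside group labels")
  for (nm in schema_attributes(schema, type = "event-time-days")) {
    v <- table[[nm]]
    if (any(!is.na(v) & v < 0)) stop("negative event time in ", nm)
  }
  for (nm in schema_attributes(schema, type = "binary-flag")) {
    v <- table[[nm]]
    if (any(!is.na(v) & !(v %in% c(0, 1)))) stop("non-binary flag value in ", nm)
  }
  invisible(TRUE)
}

#' Write / read a cohort as CSV
#'
#' Header row carries the attribute names; the missing marker is an empty
#' field; dates are ISO-8601. Round trips are byte-stable for a fixed table.
#'
#' @param table cohort data.frame.
#' @param schema a [cohort_schema()]; used to restore column types on read.
#' @param path file path.
#' @return `read_cohort_csv` returns the typed data.frame.
#' @export
write_cohort_csv <- function(table, path) {
  out <- table
  for (nm in names(out)) if (inherits(out[[nm]], "Date")) {
    out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, schema) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  for (i in seq_len(nrow(schema$attributes))) {
    nm <- schema$attributes$name[i]
    if (!nm %in% names(raw)) next
    raw[[nm]] <- switch(schema$attributes$type[i],
      "integer-age-years" = as.integer(raw[[nm]]),
      "binary-flag" = as.integer(raw[[nm]]),
      "day-offset" = as.numeric(raw[[nm]]),
      "event-time-days" = as.numeric(raw[[nm]]),
      "date" = as.Date(raw[[nm]]),
      raw[[nm]])
  }
  raw
}

#' Serialize / load a schema as YAML
#' @param schema a [cohort_schema()].
#' @param path file path.
#' @export
write_schema_yaml <- function(schema, path) {
  yaml::write_yaml(list(
    attributes = lapply(seq_len(nrow(schema$attributes)), function(i)
      as.list(schema$attributes[i, , drop = FALSE])),
    treatment_column = schema$treatment_column,
    group_labels = as.list(schema$group_labels),
    event_pairs = as.list(schema$event_pairs)), path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  attrs <- do.call(rbind, lapply(y$attributes, function(a)
    data.frame(name = a$name, type = a$type, role = a$role,
               provenance = if (is.null(a$provenance)) NA else a$provenance)))
  cohort_schema(attrs, y$treatment_column, unlist(y$group_labels),
                unlist(y$event_pairs))
}
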