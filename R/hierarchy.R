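#' Generalization hierarchies
#'
#' A hierarchy is an ordered list of transformation rules for one attribute:
#' level 0 is the identity, intermediate levels coarsen strictly (numeric
#' values map to the midpoint of widening intervals, categories map to group
#' labels), and the final level is full suppression. Binary flags carry
#' exactly two levels (identity, suppressed), so choosing their top level for
#' a whole column equals attribute suppression.
#'
#' @param attribute attribute name.
#' @param widths increasing vector of interval widths (numeric hierarchies);
#'   ages use `c(5, 10)` years, day offsets `c(30, 90, 360)` days.
#' @param domain optional numeric `c(min, max)`; when `NULL` it is taken from
#'   the data at anonymization time.
#' @param groupings optional list of named character vectors mapping category
#'   to group label, one per intermediate level.
#' @param categories optional full category set (for loss normalization).
#' @return a `hierarchy` object.
#' @export
hierarchy_numeric <- function(attribute, widths, domain = NULL) {
  stopifnot(length(widths) >= 1, all(diff(c(0, widths)) > 0))
  structure(list(attribute = attribute, kind = "numeric", widths = widths,
                 domain = domain, n_levels = length(widths) + 2L),
            class = "hierarchy")
}

#' @rdname hierarchy_numeric
#' @export
hierarchy_categorical <- function(attribute, groupings = list(),
                                  categories = NULL) {
  structure(list(attribute = attribute, kind = "categorical",
                 groupings = groupings, categories = categories,
                 n_levels = length(groupings) + 2L),
            class = "hierarchy")
}

#' Apply one hierarchy level to a vector
#'
#' @param hier a `hierarchy`.
#' @param values the original attribute values.
#' @param level integer level (0 = identity, `hier$n_levels - 1` =
#'   suppression).
#' @param domain numeric `c(min, max)` override for numeric hierarchies.
#' @return list with `values` (generalized representation; `NA` when
#'   suppressed), `key` (character class-key tokens, `"*"` when suppressed)
#'   and `loss` (per-cell granularity loss in `[0, 1]`).
#' @export
apply_hierarchy <- function(hier, values, level, domain = NULL) {
  n <- length(values)
  top <- hier$n_levels - 1L
  if (level < 0 || level > top) stop("level out of range for ", hier$attribute)
  if (level == top) {
    return(list(values = rep(NA, n), key = rep("*", n), loss = rep(1, n)))
  }
  if (level == 0L) {
    key <- ifelse(is.na(values), "<NA>", as.character(values))
    return(list(values = values, key = key, loss = rep(0, n)))
  }
  if (hier$kind == "numeric") {
    dom <- domain %||% hier$domain
    if (is.null(dom)) stop("numeric hierarchy for ", hier$attribute,
                           " needs a domain")
    rng <- dom[2] - dom[1]
    w <- hier$widths[level]
    num <- as.numeric(values)
    lower <- dom[1] + floor((num - dom[1]) / w) * w
    mid <- lower + w / 2
    key <- ifelse(is.na(mid), "<NA>", as.character(mid))
    loss <- rep(if (rng <= 0) 0 else min(w / rng, 1), n)
    list(values = mid, key = key, loss = loss)
  } else {
    map <- hier$groupings[[level]]
    cats <- hier$categories %||% names(map)
    d <- length(cats)
    grouped <- unname(map[as.character(values)])
    sizes <- table(map)
    m <- as.numeric(sizes[grouped])
    loss <- if (d <= 1) rep(0, n) else (m - 1) / (d - 1)
    loss[is.na(loss)] <- 0
    key <- ifelse(is.na(grouped), "<NA>", grouped)
    list(values = grouped, key = key, loss = loss)
  }
}

#' Default hierarchies for a schema
#'
#' Ages generalize to 5- then 10-year intervals (midpoint representation);
#' day offsets and event times to 30-, 90- then 360-day intervals; binary
#' flags and categorical attributes have only identity and suppression.
#' Date attributes handled by microaggregation need no hierarchy.
#'
#' @param schema a [cohort_schema()].
#' @return named list of `hierarchy` objects.
#' @export
default_hierarchies <- function(schema = default_schema()) {
  out <- list()
  for (i in seq_len(nrow(schema$attributes))) {
    nm <- schema$attributes$name[i]
    out[[nm]] <- switch(schema$attributes$type[i],
      "integer-age-years" = hierarchy_numeric(nm, c(5, 10)),
      "day-offset" = hierarchy_numeric(nm, c(30, 90, 360)),
      "event-time-days" = hierarchy_numeric(nm, c(30, 90, 360)),
      "binary-flag" = hierarchy_categorical(nm, categories = c("0", "1")),
      "categorical" = hierarchy_categorical(nm),
      NULL)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Read / write hierarchy specifications as YAML
#'
#' Per attribute: `kind` (`numeric`/`categorical`), `widths` or `groupings`,
#' optional `domain`/`categories`.
#'
#' @param hierarchies named list of hierarchies.
#' @param path file path.
#' @export
write_hierarchies_yaml <- function(hierarchies, path) {
  yaml::write_yaml(lapply(hierarchies, function(h) {
    if (h$kind == "numeric") {
      list(attribute = h$attribute, kind = h$kind,
           widths = as.list(h$widths),
           domain = if (is.null(h$domain)) NULL else as.list(h$domain))
    } else {
      list(attribute = h$attribute, kind = h$kind,
           groupings = lapply(h$groupings, as.list),
           categories = if (is.null(h$categories)) NULL else
             as.list(h$categories))
    }
  }), path, precision = 15L)
  invisible(path)
}

#' @rdname write_hierarchies_yaml
#' @export
read_hierarchies_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(h) {
    if (h$kind == "numeric") {
      hierarchy_numeric(h$attribute, unlist(h$widths),
                        domain = if (is.null(h$domain)) NULL else
                          unlist(h$domain))
    } else {
      hierarchy_categorical(h$attribute,
                            groupings = lapply(h$groupings, unlist),
                            categories = if (is.null(h$categories)) NULL else
                              unlist(h$categories))
    }
  })
}
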