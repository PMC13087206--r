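#' Check k-anonymity
#'
#' Every combination of quasi-identifier values shared by at least one
#' record must be shared by at least `k` records. `NA` cells (suppressed
#' values) compare equal to each other.
#'
#' @param table data.frame.
#' @param quasi_identifiers character vector of column names.
#' @param k integer >= 1.
#' @return list with `satisfied`, `class_sizes` (named integer vector) and
#'   `min_class_size`.
#' @export
check_k_anonymity <- function(table, quasi_identifiers, k) {
  if (length(quasi_identifiers) == 0) {
    warning("empty quasi-identifier set: k-anonymity is vacuously satisfied")
    return(list(satisfied = TRUE, class_sizes = integer(), min_class_size = NA))
  }
  key <- class_key(table, quasi_identifiers)
  sizes <- table(key)
  list(satisfied = all(sizes >= k),
       class_sizes = stats::setNames(as.integer(sizes), names(sizes)),
       min_class_size = min(sizes))
}

class_key <- function(table, cols) {
  parts <- lapply(table[cols], function(v) {
    out <- as.character(v)
    out[is.na(v)] <- "<NA>"
    out
  })
  do.call(paste, c(parts, sep = "\r"))
}

#' Check equal-distance t-closeness
#'
#' For each equivalence class (on the quasi-identifiers) the distance between
#' the class-wise distribution of the sensitive attribute and the whole-table
#' distribution must not exceed `t`. Under equal ground distances the
#' earth-mover distance reduces to the total-variation distance
#' `0.5 * sum_v |P_class(v) - P_table(v)|`.
#'
#' @param table data.frame.
#' @param quasi_identifiers character vector.
#' @param sensitive_attribute single column name (treated as categorical).
#' @param t closeness threshold in (0, 1].
#' @return list with `satisfied`, `max_distance` and `distances` per class.
#' @export
check_t_closeness <- function(table, quasi_identifiers, sensitive_attribute,
                              t) {
  if (!sensitive_attribute %in% names(table)) {
    stop("sensitive attribute absent: ", sensitive_attribute)
  }
  key <- if (length(quasi_identifiers)) class_key(table, quasi_identifiers)
         else rep("all", nrow(table))
  d <- t_distances(key, table[[sensitive_attribute]])
  list(satisfied = all(d <= t + 1e-12), max_distance = max(d, 0),
       distances = d)
}

# per-class total-variation distance to the overall distribution
t_distances <- function(key, sens) {
  s <- as.character(sens)
  s[is.na(s)] <- "<NA>"
  tab <- table(key, s)
  class_p <- tab / rowSums(tab)
  table_p <- colSums(tab) / sum(tab)
  0.5 * rowSums(abs(sweep(class_p, 2, table_p)))
}

#' Granularity loss of a transformed table
#'
#' Per-cell loss: 0 for an untouched value, 1 for a suppressed cell,
#' interval width divided by domain range for a numeric value generalized to
#' an interval midpoint, and `(covered - 1)/(domain size - 1)` for a
#' categorical value generalized to a group. The overall loss is the mean
#' over all protected cells. Cells are matched to hierarchy levels by
#' reproducing each level's representation.
#'
#' @param original,transformed data.frames in identical row order; a
#'   transformed table with fewer rows is matched against the leading rows of
#'   the original.
#' @param hierarchies named list of [hierarchy_numeric()] /
#'   [hierarchy_categorical()] objects for the protected attributes.
#' @param protected_attributes columns entering the mean; defaults to
#'   `names(hierarchies)`.
#' @param domains optional named list of numeric domains.
#' @return mean loss in `[0, 1]`.
#' @export
granularity_loss <- function(original, transformed, hierarchies,
                             protected_attributes = names(hierarchies),
                             domains = NULL) {
  losses <- c()
  for (nm in protected_attributes) {
    h <- hierarchies[[nm]]
    if (is.null(h)) stop("no hierarchy for protected attribute ", nm)
    orig <- original[[nm]]
    trans <- transformed[[nm]]
    dom <- domains[[nm]] %||% h$domain %||%
      (if (h$kind == "numeric") range(as.numeric(orig), na.rm = TRUE))
    cell <- rep(NA_real_, length(trans))
    cell[is.na(trans) & !is.na(orig[seq_along(trans)])] <- 1
    cell[is.na(trans) & is.na(orig[seq_along(trans)])] <- 0
    for (lev in 0:(h$n_levels - 2L)) {
      ap <- apply_hierarchy(h, orig[seq_along(trans)], lev, domain = dom)
      same <- is.na(cell) & !is.na(trans) & !is.na(ap$values) &
        as.character(ap$values) == as.character(trans)
      cell[same] <- ap$loss[same]
    }
    if (anyNA(cell)) {
      stop("cell in ", nm, " does not match any hierarchy level")
    }
    losses <- c(losses, cell)
  }
  if (!length(losses)) return(0)
  mean(losses)
}

#' Microaggregate a date attribute within equivalence classes
#'
#' Replaces each class's dates by their mean, rounded to the nearest day.
#' Missing dates are excluded from the mean; an all-missing class stays
#' missing. Singleton classes are unchanged up to rounding.
#'
#' @param table data.frame.
#' @param date_attribute column name (class `Date`).
#' @param equivalence_classes vector of class ids, one per row.
#' @return the table with the date column microaggregated.
#' @export
microaggregate_dates <- function(table, date_attribute, equivalence_classes) {
  d <- as.numeric(as.Date(table[[date_attribute]]))
  means <- tapply(d, equivalence_classes, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else round(mean(x))
  })
  table[[date_attribute]] <- as.Date(
    as.numeric(means[as.character(equivalence_classes)]),
    origin = "1970-01-01")
  table
}

#' Convert dates to day offsets from an anchor (and back)
#'
#' Offsets are integer day differences from the per-record anchor date
#' (offset 0 = the anchor itself). A missing anchor yields missing offsets.
#' The round trip without intermediate generalization is the identity.
#'
#' @param table data.frame.
#' @param anchor_attribute anchor date column name.
#' @param date_attributes date columns to convert (default: all `Date`
#'   columns except the anchor).
#' @return the converted table.
#' @export
dates_to_offsets <- function(table, anchor_attribute,
                             date_attributes = NULL) {
  anchor <- as.Date(table[[anchor_attribute]])
  if (is.null(date_attributes)) {
    date_attributes <- setdiff(
      names(table)[vapply(table, inherits, TRUE, "Date")], anchor_attribute)
  }
  for (nm in date_attributes) {
    table[[nm]] <- as.numeric(as.Date(table[[nm]]) - anchor)
  }
  table
}

#' @rdname dates_to_offsets
#' @param offset_attributes columns holding day offsets to convert back.
#' @export
offsets_to_dates <- function(table, anchor_attribute,
                             offset_attributes) {
  anchor <- as.Date(table[[anchor_attribute]])
  for (nm in offset_attributes) {
    table[[nm]] <- anchor + round(as.numeric(table[[nm]]))
  }
  table
}

#' Anonymization configuration
#'
#' @param k k-anonymity parameter (>= 1).
#' @param t equal-distance t-closeness threshold in (0, 1].
#' @param protected_attributes attributes to protect (granularity loss is
#'   averaged over these).
#' @param sensitive_attributes t-closeness targets (subset of protected; not
#'   generalized themselves).
#' @param direct_attributes direct identifiers, always fully suppressed.
#' @param microaggregate_attributes date attributes replaced by
#'   equivalence-class mean dates after the lattice search.
#' @param derived_dates named list mapping a date attribute to the day-offset
#'   attribute it is recomputed from in postprocessing (generalized offset
#'   midpoint added to the microaggregated anchor).
#' @param anchor_attribute anchor date for derived-date reconstruction.
#' @param record_suppression_limit maximal fraction of records that may be
#'   suppressed (default 1 = unlimited).
#' @param allow_attribute_suppression permit a hierarchy's top level.
#' @param search `"auto"` (exact breadth-first search when the lattice has at
#'   most `exhaustive_limit` nodes, greedy otherwise), `"exhaustive"` or
#'   `"greedy"`.
#' @param exhaustive_limit node-count cap for the exact search.
#' @return an `anon_config` list.
#' @export
anon_config <- function(k = 2L, t = 0.5,
                        protected_attributes,
                        sensitive_attributes = character(),
                        direct_attributes = character(),
                        microaggregate_attributes = character(),
                        derived_dates = list(),
                        anchor_attribute = NULL,
                        record_suppression_limit = 1.0,
                        allow_attribute_suppression = TRUE,
                        search = "auto",
                        exhaustive_limit = 4000L) {
  stopifnot(k >= 1, t > 0, t <= 1,
            record_suppression_limit >= 0, record_suppression_limit <= 1)
  structure(list(k = as.integer(k), t = t,
                 protected_attributes = protected_attributes,
                 sensitive_attributes = sensitive_attributes,
                 direct_attributes = direct_attributes,
                 microaggregate_attributes = microaggregate_attributes,
                 derived_dates = derived_dates,
                 anchor_attribute = anchor_attribute,
                 record_suppression_limit = record_suppression_limit,
                 allow_attribute_suppression = allow_attribute_suppression,
                 search = search,
                 exhaustive_limit = as.integer(exhaustive_limit)),
            class = "anon_config")
}

#' Build an anonymization configuration from a threat classification
#'
#' Context-independent: every attribute is protected and the classified
#' sensitive attributes are the t-closeness targets. Context-dependent: only
#' the direct, indirect and sensitive attributes are protected; the indirect
#' identifiers are the quasi-identifiers.
#'
#' @param classification a `threat_classification` over the schema.
#' @param scenario `"context-independent"` or `"context-dependent"`.
#' @param schema the [cohort_schema()].
#' @param k,t privacy parameters (both scenarios share `k = 2`, `t = 0.5` by
#'   default).
#' @param ... passed on to [anon_config()].
#' @return an `anon_config`.
#' @export
scenario_anon_config <- function(classification, scenario,
                                 schema = default_schema(), k = 2L, t = 0.5,
                                 ...) {
  scenario <- match.arg(scenario,
                        c("context-independent", "context-dependent"))
  direct <- classified_as(classification, "direct")
  indirect <- classified_as(classification, "indirect")
  sensitive <- classified_as(classification, "sensitive")
  protected <- if (scenario == "context-independent") {
    schema$attributes$name
  } else {
    c(direct, indirect, sensitive)
  }
  micro <- intersect(c("birth_quarter", "first_vte_date"), protected)
  derived <- list(index_date = "index_offset",
                  follow_up_end_date = "follow_up_end_offset")
  derived <- derived[names(derived) %in% protected]
  anon_config(k = k, t = t,
              protected_attributes = protected,
              sensitive_attributes = sensitive,
              direct_attributes = direct,
              microaggregate_attributes = micro,
              derived_dates = derived,
              anchor_attribute = if ("first_vte_date" %in% protected)
                "first_vte_date" else NULL,
              ...)
}

#' Anonymize a cohort under k-anonymity and equal-distance t-closeness
#'
#' Searches the generalization lattice spanned by the quasi-identifier
#' hierarchies for the node with minimal granularity loss. At each node,
#' equivalence classes smaller than `k` and classes violating t-closeness
#' for any sensitive attribute are suppressed entirely; suppressed records
#' count with loss 1 per protected cell. Direct identifiers are suppressed
#' up front; microaggregated date attributes are replaced by class means and
#' derived dates are reconstructed from the microaggregated anchor plus the
#' generalized offsets in postprocessing.
#'
#' When the lattice has at most `exhaustive_limit` nodes the search is an
#' exact breadth-first enumeration with a generalization-loss lower bound
#' used for pruning; larger lattices use best-improvement coordinate search
#' from the identity node.
#'
#' @param table data.frame.
#' @param config an [anon_config()].
#' @param hierarchies named list of hierarchies covering every protected
#'   attribute that is neither direct, microaggregated nor derived.
#' @return an `anon_result`: `table` (suppressed records removed), plus
#'   `chosen_levels`, `suppressed_records`, `suppressed_cells`,
#'   `suppressed_attributes`, `loss`, `quasi_identifiers`, `nodes_evaluated`.
#' @export
anonymize <- function(table, config, hierarchies = default_hierarchies()) {
  n <- nrow(table)
  protected <- intersect(config$protected_attributes, names(table))
  direct <- intersect(config$direct_attributes, protected)
  micro <- intersect(config$microaggregate_attributes, protected)
  derived <- config$derived_dates[names(config$derived_dates) %in% protected]
  qis <- setdiff(protected, c(direct, micro, names(derived),
                              config$sensitive_attributes))
  missing_h <- setdiff(qis, names(hierarchies))
  if (length(missing_h)) stop("no hierarchy for protected attribute(s): ",
                              paste(missing_h, collapse = ", "))
  sens <- intersect(config$sensitive_attributes, names(table))

  # cache generalized key/loss columns per (attribute, level)
  domains <- list()
  cache <- list()
  n_levels <- integer(length(qis))
  names(n_levels) <- qis
  for (nm in qis) {
    h <- hierarchies[[nm]]
    if (h$kind == "numeric") {
      v <- as.numeric(table[[nm]])
      domains[[nm]] <- h$domain %||%
        (if (all(is.na(v))) c(0, 0) else range(v, na.rm = TRUE))
    }
    top <- h$n_levels - 1L
    if (!config$allow_attribute_suppression) top <- top - 1L
    levs <- lapply(0:top, function(l)
      apply_hierarchy(h, table[[nm]], l, domain = domains[[nm]]))
    cache[[nm]] <- levs
    n_levels[nm] <- length(levs)
  }

  n_prot_cells <- length(protected)
  base_loss_per_record <- length(direct) / max(n_prot_cells, 1)

  evaluate <- function(node) {
    keys <- lapply(seq_along(qis), function(j) cache[[qis[j]]][[node[j] + 1L]]$key)
    key <- if (length(keys)) do.call(paste, c(keys, sep = "\r"))
           else rep("all", n)
    keep <- rep(TRUE, n)
    sizes <- table(key)
    small <- names(sizes)[sizes < config$k]
    keep[key %in% small] <- FALSE
    # iterate t-closeness suppression until stable
    if (length(sens)) {
      for (iter in 1:10) {
        if (!any(keep)) break
        viol <- character()
        for (s in sens) {
          d <- t_distances(key[keep], table[[s]][keep])
          viol <- union(viol, names(d)[d > config$t + 1e-12])
        }
        if (!length(viol)) break
        keep[key %in% viol] <- FALSE
      }
    }
    n_sup <- sum(!keep)
    if (n_sup / n > config$record_suppression_limit + 1e-12) {
      return(list(feasible = FALSE, n_suppressed = n_sup))
    }
    gen_loss <- 0
    if (length(qis)) {
      for (j in seq_along(qis)) {
        gen_loss <- gen_loss + sum(cache[[qis[j]]][[node[j] + 1L]]$loss[keep])
      }
    }
    total <- (n_sup * n_prot_cells +           # suppressed records
              sum(keep) * length(direct) +     # direct identifiers
              gen_loss) / (n * n_prot_cells)
    list(feasible = TRUE, loss = total, keep = keep, key = key,
         n_suppressed = n_sup)
  }

  # generalization-only lower bound (no suppression), monotone in levels
  lower_bound <- function(node) {
    gen <- 0
    for (j in seq_along(qis)) {
      gen <- gen + sum(cache[[qis[j]]][[node[j] + 1L]]$loss)
    }
    (gen + n * length(direct)) / (n * n_prot_cells)
  }

  lattice_size <- prod(n_levels)
  use_exhaustive <- config$search == "exhaustive" ||
    (config$search == "auto" && (length(qis) == 0 ||
                                 lattice_size <= config$exhaustive_limit))

  best <- NULL
  best_node <- NULL
  n_eval <- 0L
  if (length(qis) == 0) {
    res <- evaluate(integer(0))
    n_eval <- 1L
    if (res$feasible) {
      best <- res
      best_node <- integer(0)
    }
  } else if (use_exhaustive) {
    if (lattice_size > 2e5) stop("lattice too large for exhaustive search")
    grid <- as.matrix(expand.grid(lapply(n_levels, function(m) 0:(m - 1L))))
    ord <- order(rowSums(grid))  # breadth-first by total generalization
    for (i in ord) {
      node <- as.integer(grid[i, ])
      if (!is.null(best) && lower_bound(node) >= best$loss - 1e-12) next
      res <- evaluate(node)
      n_eval <- n_eval + 1L
      if (res$feasible && (is.null(best) || res$loss < best$loss - 1e-12)) {
        best <- res
        best_node <- node
      }
    }
  } else {
    # best-improvement coordinate search, started from the fully generalized
    # top node (always feasible: a single class, no record suppression)
    node <- n_levels - 1L
    cache_res <- new.env()
    eval_cached <- function(nb) {
      kk <- paste(nb, collapse = ",")
      r <- cache_res[[kk]]
      if (is.null(r)) {
        r <- evaluate(nb)
        cache_res[[kk]] <- r
        n_eval <<- n_eval + 1L
      }
      r
    }
    res <- eval_cached(node)
    if (res$feasible) {
      best <- res
      best_node <- node
    }
    current <- if (res$feasible) res$loss else Inf
    repeat {
      cand_best <- NULL
      cand_node <- NULL
      for (j in seq_along(qis)) for (step in c(-1L, 1L)) {
        nb <- node
        nb[j] <- nb[j] + step
        if (nb[j] < 0L || nb[j] >= n_levels[j]) next
        r <- eval_cached(nb)
        if (!r$feasible) next
        if (is.null(cand_best) || r$loss < cand_best$loss) {
          cand_best <- r
          cand_node <- nb
        }
      }
      if (!is.null(cand_best) && cand_best$loss < current - 1e-12) {
        node <- cand_node
        current <- cand_best$loss
        best <- cand_best
        best_node <- node
      } else {
        break
      }
    }
  }

  if (is.null(best)) {
    stop("anonymization infeasible: no lattice node satisfies k=", config$k,
         ", t=", config$t, " within the record suppression limit of ",
         config$record_suppression_limit)
  }

  keep <- best$keep
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  key_keep <- best$key[keep]
  suppressed_attributes <- character()
  suppressed_cells <- 0L

  for (nm in direct) {
    out[[nm]] <- rep(NA, nrow(out))
    suppressed_attributes <- c(suppressed_attributes, nm)
    suppressed_cells <- suppressed_cells + nrow(out)
  }
  chosen <- stats::setNames(if (length(qis)) best_node else integer(0), qis)
  for (j in seq_along(qis)) {
    nm <- qis[j]
    gv <- cache[[nm]][[best_node[j] + 1L]]$values[keep]
    if (best_node[j] == n_levels[nm] - 1L &&
        hierarchies[[nm]]$n_levels - 1L ==
          (n_levels[nm] - 1L)) {  # top = suppression level
      suppressed_attributes <- c(suppressed_attributes, nm)
      suppressed_cells <- suppressed_cells + nrow(out)
    }
    out[[nm]] <- gv
  }
  # microaggregate anchor/birth dates within final classes
  for (nm in micro) {
    out <- microaggregate_dates(out, nm, key_keep)
  }
  # reconstruct derived dates from anchor + generalized offset
  if (length(derived) && !is.null(config$anchor_attribute) &&
      config$anchor_attribute %in% names(out)) {
    anchor <- as.Date(out[[config$anchor_attribute]])
    for (nm in names(derived)) {
      off <- as.numeric(out[[derived[[nm]]]])
      out[[nm]] <- anchor + round(off)
    }
  }

  structure(list(table = out,
                 chosen_levels = chosen,
                 suppressed_records = best$n_suppressed,
                 suppressed_cells = suppressed_cells,
                 suppressed_attributes = unique(suppressed_attributes),
                 loss = best$loss,
                 quasi_identifiers = qis,
                 nodes_evaluated = n_eval,
                 k = config$k, t = config$t,
                 sensitive_attributes = sens),
            class = "anon_result")
}

#' @export
print.anon_result <- function(x, ...) {
  cat("anon_result: k=", x$k, " t=", x$t, " | loss=", round(x$loss, 4),
      " | suppressed records=", x$suppressed_records,
      " | suppressed attributes=", length(x$suppressed_attributes),
      " | nodes evaluated=", x$nodes_evaluated, "\n", sep = "")
  invisible(x)
}
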