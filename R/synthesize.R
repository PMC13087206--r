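#' Synthesizer configuration
#'
#' Controls the three safeguards of the tabular generator: rare categories
#' (fewer than `rare_category_min_count` training occurrences) are pooled
#' into a common label before training, numeric values are clipped to the
#' configured quantiles before discretization, and model complexity (the
#' number of conditioning attributes per step) is grown only while the
#' holdout log-likelihood improves (early stopping).
#'
#' @param rare_category_min_count pooling threshold (default 5).
#' @param clip_quantiles numeric `c(low, high)` in `[0, 1]`.
#' @param holdout_fraction fraction of rows held out for early stopping,
#'   in (0, 0.5).
#' @param smoothing pseudo-count per category (> 0); conditional estimates
#'   shrink towards the attribute's marginal.
#' @param max_parents cap on conditioning attributes per step.
#' @param n_bins number of quantile bins for numeric attributes.
#' @param min_improvement holdout log-likelihood gain (nats) a candidate
#'   parent must deliver to be kept; guards against accepting spurious
#'   dependencies whose chance gains are fractions of a nat.
#' @param holdout_splits number of random holdout splits whose gains are
#'   averaged when scoring a candidate parent (reduces selection noise).
#' @param seed integer RNG seed for the fit (holdout split).
#' @return a `synth_config` list.
#' @export
synth_config <- function(rare_category_min_count = 5L,
                         clip_quantiles = c(0.01, 0.99),
                         holdout_fraction = 0.2,
                         smoothing = 0.5,
                         max_parents = 3L,
                         n_bins = 10L,
                         min_improvement = 2,
                         holdout_splits = 3L,
                         seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 0.5,
            clip_quantiles[1] >= 0, clip_quantiles[1] < clip_quantiles[2],
            clip_quantiles[2] <= 1, smoothing > 0, n_bins >= 2,
            min_improvement >= 0, holdout_splits >= 1)
  structure(list(rare_category_min_count = as.integer(rare_category_min_count),
                 clip_quantiles = clip_quantiles,
                 holdout_fraction = holdout_fraction,
                 smoothing = smoothing,
                 max_parents = as.integer(max_parents),
                 n_bins = as.integer(n_bins),
                 min_improvement = min_improvement,
                 holdout_splits = as.integer(holdout_splits),
                 seed = as.integer(seed)),
            class = "synth_config")
}

POOLED_LABEL <- "_other_"

# discretize one column; returns category labels plus the decode map
encode_attribute <- function(v, config, type = NULL) {
  is_date <- inherits(v, "Date") || identical(type, "date")
  if (is_date) v <- as.numeric(as.Date(v))
  numericish <- is.numeric(v) &&
    !identical(type, "categorical") && !identical(type, "binary-flag")
  if (numericish && length(unique(v[!is.na(v)])) > 2) {
    is_int <- is_date || all(is.na(v) | abs(v - round(v)) < 1e-9)
    qs <- stats::quantile(v, config$clip_quantiles, na.rm = TRUE, names = FALSE)
    clipped <- pmin(pmax(v, qs[1]), qs[2])
    edges <- unique(stats::quantile(clipped, seq(0, 1, length.out =
                                                   config$n_bins + 1),
                                    na.rm = TRUE, names = FALSE))
    if (length(edges) < 2) edges <- c(qs[1], qs[2] + 1e-9)
    bin <- findInterval(clipped, edges, all.inside = TRUE)
    cats <- ifelse(is.na(bin), "<NA>", paste0("b", bin))
    list(kind = "numeric", cats = cats, edges = edges, clip = qs,
         is_date = is_date, is_integer = is_int)
  } else {
    s <- as.character(v)
    s[is.na(s)] <- "<NA>"
    cnt <- table(s)
    rare <- names(cnt)[cnt < config$rare_category_min_count &
                         names(cnt) != "<NA>"]
    pooled <- s
    pooled[pooled %in% rare] <- POOLED_LABEL
    kept <- setdiff(names(cnt), rare)
    mode_cat <- kept[which.max(cnt[kept])] %||% POOLED_LABEL
    list(kind = "categorical", cats = pooled, pooled_from = rare,
         mode = mode_cat,
         binary = identical(type, "binary-flag") ||
           all(s %in% c("0", "1", "<NA>")),
         integerish = is.numeric(v))
  }
}

# smoothed conditional probabilities with marginal backoff
fit_cpt <- function(x, cfg, smoothing) {
  cats <- sort(unique(x))
  K <- length(cats)
  marg_cnt <- table(factor(x, levels = cats))
  p_marg <- (as.numeric(marg_cnt) + smoothing) / (length(x) + smoothing * K)
  names(p_marg) <- cats
  tab <- NULL
  if (!is.null(cfg)) {
    tab <- table(cfg, factor(x, levels = cats))
  }
  list(cats = cats, p_marg = p_marg, tab = tab, alpha = smoothing * K)
}

cpt_prob_rows <- function(cpt, x, cfg) {
  # probability of observed category x[i] given parent config cfg[i]
  xi <- match(x, cpt$cats)
  p <- cpt$p_marg[xi]
  p[is.na(xi)] <- min(cpt$p_marg) * 0.5  # unseen holdout category
  if (!is.null(cpt$tab) && !is.null(cfg)) {
    ri <- match(cfg, rownames(cpt$tab))
    hit <- !is.na(ri) & !is.na(xi)
    if (any(hit)) {
      n_cfg <- rowSums(cpt$tab)[ri[hit]]
      n_v <- cpt$tab[cbind(ri[hit], xi[hit])]
      p[hit] <- (n_v + cpt$alpha * cpt$p_marg[xi[hit]]) /
        (n_cfg + cpt$alpha)
    }
  }
  unname(p)
}

cfg_key <- function(cat_cols, rows = NULL) {
  if (!length(cat_cols)) return(NULL)
  cols <- if (is.null(rows)) cat_cols else lapply(cat_cols, `[`, rows)
  do.call(paste, c(cols, sep = "\r"))
}

#' Fit the autoregressive tabular generator
#'
#' Attributes are modeled in column order: each attribute gets a smoothed
#' conditional frequency table given up to `max_parents` earlier attributes.
#' Numeric attributes are clipped to the configured quantiles and discretized
#' into quantile bins; rare categories are pooled. Parent sets grow greedily
#' and a candidate parent is kept only if it improves the holdout
#' log-likelihood (early stopping); the chosen structure is refit on all
#' rows. The model stores only fitted statistics, never training rows.
#'
#' @param table data.frame with at least 50 rows.
#' @param config a [synth_config()].
#' @param schema optional [cohort_schema()] supplying semantic types.
#' @return a `synth_model` with per-attribute encoders, parent sets,
#'   conditional tables and training diagnostics.
#' @export
synth_fit <- function(table, config = synth_config(), schema = NULL) {
  if (nrow(table) < 50) stop("need at least 50 records to fit")
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(config$seed)
  n <- nrow(table)
  attrs <- names(table)
  types <- NULL
  if (!is.null(schema)) {
    types <- stats::setNames(schema$attributes$type, schema$attributes$name)
  }
  enc <- lapply(attrs, function(nm)
    encode_attribute(table[[nm]], config, type = types[nm]))
  names(enc) <- attrs
  cat_cols <- lapply(enc, `[[`, "cats")

  n_hold <- max(1L, floor(config$holdout_fraction * n))
  splits <- lapply(seq_len(config$holdout_splits), function(s)
    sample.int(n, n_hold))

  # mean holdout log-likelihood of x | parents over the random splits
  holdout_ll <- function(x, parents) {
    mean(vapply(splits, function(hold) {
      train <- setdiff(seq_len(n), hold)
      cfg_tr <- if (length(parents)) cfg_key(cat_cols[parents], train)
      cpt <- fit_cpt(x[train], cfg_tr, config$smoothing)
      cfg_ho <- if (length(parents)) cfg_key(cat_cols[parents], hold)
      sum(log(cpt_prob_rows(cpt, x[hold], cfg_ho)))
    }, 0))
  }

  models <- list()
  diagnostics <- list()
  for (j in seq_along(attrs)) {
    nm <- attrs[j]
    x <- cat_cols[[nm]]
    if (length(unique(x)) < 2) {
      warning("attribute ", nm, " is constant; modeled as constant")
      models[[nm]] <- list(parents = character(),
                           cpt = fit_cpt(x, NULL, config$smoothing))
      diagnostics[[nm]] <- list(parents = character(), trace = numeric())
      next
    }
    parents <- character()
    cur_ll <- holdout_ll(x, parents)
    trace <- cur_ll
    candidates <- attrs[seq_len(j - 1L)]
    while (length(parents) < config$max_parents && length(candidates)) {
      best_ll <- cur_ll + config$min_improvement
      best_c <- NULL
      for (cand in candidates) {
        ll <- holdout_ll(x, c(parents, cand))
        if (ll > best_ll + 1e-9) {
          best_ll <- ll
          best_c <- cand
        }
      }
      if (is.null(best_c)) break
      parents <- c(parents, best_c)
      candidates <- setdiff(candidates, best_c)
      cur_ll <- best_ll
      trace <- c(trace, cur_ll)
    }
    # refit the selected structure on all rows
    final_cfg <- if (length(parents)) cfg_key(cat_cols[parents]) else NULL
    models[[nm]] <- list(parents = parents,
                         cpt = fit_cpt(x, final_cfg, config$smoothing))
    diagnostics[[nm]] <- list(parents = parents, trace = trace,
                              stopping_step = length(parents))
  }
  structure(list(attributes = attrs, encoders = enc, models = models,
                 config = config, n_train = n, diagnostics = diagnostics),
            class = "synth_model")
}

# draw categories for m rows given per-row parent configs
sample_categories <- function(cpt, cfg, m) {
  cats <- cpt$cats
  if (is.null(cpt$tab) || is.null(cfg)) {
    return(sample(cats, m, replace = TRUE, prob = cpt$p_marg))
  }
  out <- character(m)
  groups <- split(seq_len(m), cfg)
  for (g in names(groups)) {
    rows <- groups[[g]]
    ri <- match(g, rownames(cpt$tab))
    p <- if (is.na(ri)) cpt$p_marg else {
      (as.numeric(cpt$tab[ri, ]) + cpt$alpha * cpt$p_marg) /
        (sum(cpt$tab[ri, ]) + cpt$alpha)
    }
    out[rows] <- sample(cats, length(rows), replace = TRUE, prob = p)
  }
  out
}

decode_attribute <- function(cats, e) {
  if (e$kind == "numeric") {
    idx <- suppressWarnings(as.integer(sub("^b", "", cats)))
    lo <- e$edges[idx]
    hi <- e$edges[pmin(idx + 1L, length(e$edges))]
    v <- stats::runif(length(cats), lo, hi)
    v[cats == "<NA>"] <- NA
    if (e$is_integer) v <- round(v)
    v <- pmin(pmax(v, e$clip[1]), e$clip[2])
    if (e$is_date) v <- as.Date(v, origin = "1970-01-01")
    v
  } else {
    out <- cats
    if (isTRUE(e$binary)) out[out == POOLED_LABEL] <- e$mode
    out[out == "<NA>"] <- NA
    if (isTRUE(e$binary) || isTRUE(e$integerish)) {
      suppressWarnings(num <- as.numeric(out))
      if (!any(is.na(num) & !is.na(out))) return(as.integer(num))
    }
    out
  }
}

#' Sample a synthetic cohort from a fitted generator
#'
#' Ancestral sampling in attribute order; numeric values are drawn uniformly
#' within the sampled quantile bin and therefore always lie inside the
#' stored clip bounds. Deterministic given the seed. For binary flags the
#' pooled rare label decodes to the majority value, so flags whose positive
#' category fell under the pooling threshold vanish from the output.
#'
#' @param model a `synth_model`.
#' @param n number of records (> 0); may equal the training size.
#' @param seed integer RNG seed.
#' @return data.frame with the training schema.
#' @export
synth_sample <- function(model, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  cat_draws <- list()
  out <- list()
  for (nm in model$attributes) {
    m <- model$models[[nm]]
    cfg <- if (length(m$parents)) cfg_key(cat_draws[m$parents]) else NULL
    cats <- sample_categories(m$cpt, cfg, n)
    cat_draws[[nm]] <- cats
    out[[nm]] <- decode_attribute(cats, model$encoders[[nm]])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Serialize / load a fitted generator as JSON
#' @param model a `synth_model`.
#' @param path file path.
#' @export
write_synth_model <- function(model, path) {
  ser <- list(attributes = model$attributes, n_train = model$n_train,
              config = unclass(model$config),
              encoders = lapply(model$encoders, function(e) {
                e$cats <- NULL
                e
              }),
              models = lapply(model$models, function(m) {
                tab <- m$cpt$tab
                list(parents = m$parents,
                     cats = m$cpt$cats,
                     p_marg = as.numeric(m$cpt$p_marg),
                     alpha = m$cpt$alpha,
                     tab_rows = if (is.null(tab)) NULL else rownames(tab),
                     tab = if (is.null(tab)) NULL else
                       matrix(as.numeric(tab), nrow = nrow(tab)))
              }),
              diagnostics = model$diagnostics)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_synth_model
#' @export
read_synth_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(ser$models, function(m) {
    tab <- NULL
    if (!is.null(m$tab) && length(m$tab)) {
      tab <- matrix(unlist(m$tab), nrow = length(m$tab_rows), byrow = FALSE)
      rownames(tab) <- m$tab_rows
    }
    list(parents = unlist(m$parents) %||% character(),
         cpt = list(cats = m$cats,
                    p_marg = stats::setNames(m$p_marg, m$cats),
                    tab = tab, alpha = m$alpha))
  })
  encoders <- lapply(ser$encoders, function(e) {
    if (!is.null(e$clip)) e$clip <- unlist(e$clip)
    if (!is.null(e$edges)) e$edges <- unlist(e$edges)
    e
  })
  structure(list(attributes = ser$attributes, encoders = encoders,
                 models = models,
                 config = do.call(synth_config, ser$config[names(formals(synth_config))]),
                 n_train = ser$n_train, diagnostics = ser$diagnostics),
            class = "synth_model")
}
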