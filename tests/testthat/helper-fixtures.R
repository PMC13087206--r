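# shared fixture builders (all generated in code, no stored data)

quick_cohort <- function(n = 300, seed = 1) {
  generate_cohort(cohort_config(n_records = n, seed = seed))
}

default_classification <- function() {
  classify_attributes(default_profiles(), default_threshold(),
                      default_schema())
}

# two columns with exact sample Pearson correlation r
correlated_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  x <- scale(x)[, 1]
  z <- stats::residuals(stats::lm(z ~ x))
  z <- scale(z)[, 1]
  data.frame(a = x, b = r * x + sqrt(1 - r^2) * z)
}

# independent brute-force anonymization oracle for tiny instances:
# enumerates every level combination, applies its own generalization,
# suppresses classes below k and classes violating t-closeness (to a fixed
# point), and scores mean cell granularity (suppressed record cells = 1)
brute_force_anon_loss <- function(table, qis, hierarchies, k, t = NULL,
                                  sensitive = NULL) {
  n <- nrow(table)
  doms <- lapply(qis, function(nm) {
    h <- hierarchies[[nm]]
    if (h$kind == "numeric") range(as.numeric(table[[nm]])) else NULL
  })
  names(doms) <- qis
  gen_col <- function(nm, lev) {
    h <- hierarchies[[nm]]
    v <- table[[nm]]
    top <- h$n_levels - 1L
    if (lev == 0) {
      list(key = as.character(v), loss = rep(0, n))
    } else if (lev == top) {
      list(key = rep("*", n), loss = rep(1, n))
    } else if (h$kind == "numeric") {
      w <- h$widths[lev]
      dom <- doms[[nm]]
      key <- as.character(floor((as.numeric(v) - dom[1]) / w))
      span <- dom[2] - dom[1]
      list(key = key, loss = rep(if (span <= 0) 0 else min(w / span, 1), n))
    } else {
      stop("oracle only handles numeric intermediate levels")
    }
  }
  grid <- expand.grid(lapply(qis, function(nm)
    0:(hierarchies[[nm]]$n_levels - 1L)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    cols <- lapply(seq_along(qis), function(j) gen_col(qis[j], grid[i, j]))
    key <- do.call(paste, c(lapply(cols, `[[`, "key"), sep = "|"))
    keep <- rep(TRUE, n)
    sizes <- table(key)
    keep[key %in% names(sizes)[sizes < k]] <- FALSE
    if (!is.null(sensitive)) {
      repeat {
        if (!any(keep)) break
        sv <- as.character(table[[sensitive]][keep])
        kk <- key[keep]
        tabd <- table(kk, sv)
        pc <- tabd / rowSums(tabd)
        pt <- colSums(tabd) / sum(tabd)
        d <- 0.5 * rowSums(abs(sweep(pc, 2, pt)))
        bad <- names(d)[d > t + 1e-12]
        if (!length(bad)) break
        keep[key %in% bad] <- FALSE
      }
    }
    cell_loss <- rowSums(sapply(cols, `[[`, "loss")) / length(qis)
    cell_loss[!keep] <- 1
    best <- min(best, mean(cell_loss))
  }
  best
}
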