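#' Build and validate an observation table
#'
#' Observation tables hold the per-mouse measurements the model is fitted to:
#' total NSC counts (FACS) and fractions of active NSCs, by age and genotype.
#'
#' @param age_days Age of each mouse in days.
#' @param genotype Genotype label of each measurement (e.g. `"WT"`,
#'   `"IFNAGR_KO"`).
#' @param quantity `"total_nsc"` or `"fraction_active"` for each row.
#' @param value Measured value (cells, or a fraction in `[0, 1]`).
#' @param sd Optional known standard deviation for the row's
#'   (age, genotype, quantity) group; `NA` means "estimate from replicates".
#'
#' @return A validated data frame of class `nsc_observations`.
#' @export
observation_table <- function(age_days, genotype, quantity, value,
                              sd = NA_real_) {
  tab <- data.frame(age_days = as.numeric(age_days),
                    genotype = as.character(genotype),
                    quantity = as.character(quantity),
                    value = as.numeric(value),
                    sd = as.numeric(sd))
  validate_observations(tab)
}

#' @rdname observation_table
#' @param table A data frame with columns `age_days`, `genotype`, `quantity`,
#'   `value` and optionally `sd`.
#' @export
validate_observations <- function(table) {
  need <- c("age_days", "genotype", "quantity", "value")
  if (!all(need %in% names(table))) {
    stop("observation table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(table$sd)) table$sd <- NA_real_
  if (any(!is.finite(table$age_days)) || any(table$age_days < 0)) {
    stop("'age_days' must be finite and >= 0")
  }
  if (!all(table$quantity %in% c("total_nsc", "fraction_active"))) {
    stop("'quantity' must be 'total_nsc' or 'fraction_active'")
  }
  frac <- table$quantity == "fraction_active"
  if (any(table$value[frac] < 0 | table$value[frac] > 1)) {
    stop("fraction_active values must lie in [0, 1]")
  }
  for (g in unique(table$genotype)) {
    if (length(unique(table$age_days[table$genotype == g])) < 2) {
      stop("genotype '", g, "' has fewer than two distinct ages")
    }
  }
  class(table) <- unique(c("nsc_observations", class(table)))
  table
}

#' Per-group dispersion and weights for the least-squares objective
#'
#' Observations are weighted by the inverse standard deviation of their
#' (age, genotype, quantity) group. The SD is the sample SD over the group's
#' replicates, unless the table supplies a known `sd` for the group, which
#' takes precedence. Groups whose dispersion cannot be established (a single
#' replicate without a supplied SD, or zero spread) raise an error rather
#' than being silently down- or up-weighted.
#'
#' @param table An observation table (see [observation_table()]).
#'
#' @return A data frame with one row per (age_days, genotype, quantity) group
#'   and columns `sd` and `weight = 1/sd`.
#' @export
group_dispersion <- function(table) {
  table <- validate_observations(as.data.frame(table))
  key <- interaction(table$age_days, table$genotype, table$quantity,
                     drop = TRUE)
  groups <- split(seq_len(nrow(table)), key)
  out <- lapply(groups, function(idx) {
    rows <- table[idx, ]
    supplied <- unique(rows$sd[!is.na(rows$sd)])
    if (length(supplied) > 1) {
      stop("conflicting supplied SDs within group (age=", rows$age_days[1],
           ", genotype=", rows$genotype[1], ", quantity=", rows$quantity[1], ")")
    }
    if (length(supplied) == 1) {
      s <- supplied
    } else if (nrow(rows) >= 2) {
      s <- stats::sd(rows$value)
    } else {
      stop("group (age=", rows$age_days[1], ", genotype=", rows$genotype[1],
           ", quantity=", rows$quantity[1],
           ") has a single replicate and no supplied SD")
    }
    if (!is.finite(s) || s <= 0) {
      stop("group (age=", rows$age_days[1], ", genotype=", rows$genotype[1],
           ", quantity=", rows$quantity[1],
           ") has zero or invalid dispersion; supply an explicit SD")
    }
    data.frame(age_days = rows$age_days[1], genotype = rows$genotype[1],
               quantity = rows$quantity[1], n = nrow(rows), sd = s,
               weight = 1 / s)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Internal: model predictions at the observed ages of one genotype.
# The simulation always starts at age 0 (where NSC0 is defined), with the
# observation ages appended to the grid.
.predict_genotype <- function(params, variant, ages) {
  grid <- sort(unique(c(0, ages)))
  if (length(grid) == 1) grid <- c(grid, grid + 1)
  traj <- simulate_nsc(params, variant, grid)
  idx <- match(ages, traj$time_days)
  tot <- pmax(traj$qNSC[idx], 0) + pmax(traj$aNSC[idx], 0)
  frac <- ifelse(tot > 0, pmax(traj$aNSC[idx], 0) / tot, NA_real_)
  list(total_nsc = tot, fraction_active = frac)
}

#' Weighted sum of squared residuals of the model against observations
#'
#' The objective minimised by [fit_nsc()]:
#' `sum(((y - yhat) / sd_group)^2)` over every observation of every genotype,
#' where `sd_group` is the group dispersion from [group_dispersion()]. Counts
#' and fractions enter the same objective; the inverse-SD weights are what
#' place them on a common scale. A failed integration contributes a large
#' but finite penalty (with a warning) so that multi-start optimisation can
#' continue past pathological parameter points.
#'
#' @param params_by_genotype Named list of [model_params()], one per genotype
#'   present in the table.
#' @param variants_by_genotype Named list of [model_variant()], same names.
#' @param table An observation table.
#' @param dispersion Optional precomputed [group_dispersion()] table.
#'
#' @return A single non-negative numeric.
#' @export
weighted_sse <- function(params_by_genotype, variants_by_genotype, table,
                         dispersion = group_dispersion(table)) {
  table <- as.data.frame(table)
  key <- function(d) paste(d$age_days, d$genotype, d$quantity, sep = "\r")
  w <- dispersion$weight[match(key(table), key(dispersion))]
  if (anyNA(w)) stop("dispersion table does not cover all observation groups")
  sse <- 0
  for (g in unique(table$genotype)) {
    if (is.null(params_by_genotype[[g]]) || is.null(variants_by_genotype[[g]])) {
      stop("missing parameters or variant for genotype '", g, "'")
    }
    sub <- table$genotype == g
    ages <- table$age_days[sub]
    pred <- tryCatch(
      .predict_genotype(params_by_genotype[[g]], variants_by_genotype[[g]],
                        ages),
      error = function(e) {
        warning("prediction failed for genotype '", g, "' (",
                conditionMessage(e), "); applying penalty", call. = FALSE)
        NULL
      })
    if (is.null(pred)) return(1e12)
    yhat <- ifelse(table$quantity[sub] == "total_nsc",
                   pred$total_nsc, pred$fraction_active)
    if (anyNA(yhat)) return(1e12)
    res <- (table$value[sub] - yhat) * w[sub]
    sse <- sse + sum(res^2)
  }
  sse
}

#' Latin-hypercube start points for multi-start optimisation
#'
#' Draws `n_starts` points from the box given by `bounds`, stratified so that
#' each dimension's range is cut into `n_starts` equal bins containing exactly
#' one sample. Reproducible for a fixed seed; the global RNG state is left
#' untouched.
#'
#' @param bounds Named list of `c(lower, upper)` per free parameter.
#' @param n_starts Number of start points (>= 1).
#' @param seed Integer seed.
#'
#' @return A numeric matrix with `n_starts` rows and one named column per
#'   parameter.
#' @export
latin_hypercube_starts <- function(bounds, n_starts, seed) {
  stopifnot(n_starts >= 1)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    stop("bounds must be finite with lower < upper")
  }
  u <- .with_seed(seed, lhs::randomLHS(n_starts, length(bounds)))
  pts <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(pts) <- names(bounds)
  pts
}

.default_bounds <- function() {
  list(r0 = c(1e-5, 1), beta_r = c(0, 0.1), b0 = c(0, 0.5),
       beta_b = c(0, 0.1), ps = c(0.1, 5), NSC0 = c(10, 1e5),
       kb = c(1e-6, 1), nb = c(-10, -0.1))
}

# Parameters each law actually uses (NSC0 is always free by default).
.params_for_variant <- function(variant) {
  act <- switch(variant$activation,
                constant = "r0",
                exponential_decay = c("r0", "beta_r"))
  sr <- switch(variant$selfrenewal,
               constant = "b0",
               time_logistic = c("b0", "beta_b"),
               hill_population = c("kb", "nb"))
  c(act, sr, "NSC0")
}

#' Specify a model fit: variants, free-parameter layout, bounds, starts
#'
#' A fit specification declares, per genotype, which model variant is fitted,
#' and for every kinetic parameter whether it is `"fixed"` (taken from
#' `init`), `"free_per_genotype"` (one value estimated per genotype) or
#' `"free_shared"` (a single value estimated jointly across genotypes). By
#' default every parameter used by a genotype's variant is free per genotype,
#' except `ps` (fixed from the literature cell-cycle length) and `kb` (shared
#' across genotypes when the population-feedback law is fitted).
#'
#' @param variants Named list of [model_variant()], one per genotype.
#' @param layout Named character vector overriding the default layout; names
#'   among `r0, beta_r, b0, beta_b, ps, NSC0, kb, nb`, values among
#'   `"fixed"`, `"free_per_genotype"`, `"free_shared"`.
#' @param bounds Named list of `c(lower, upper)` overriding the default box
#'   for any free parameter.
#' @param init Named list of [model_params()] per genotype supplying values
#'   for fixed parameters (defaults fix only `ps` at [ps_default()]).
#' @param n_starts Number of Latin-hypercube starts (>= 1).
#' @param seed Integer seed for start sampling.
#' @param control Control list passed to [stats::optim()]'s `L-BFGS-B`
#'   (defaults: `maxit = 500`, `factr = 1000`, i.e. a relative objective
#'   tolerance around `2e-13`; raise `factr` for large simulation studies
#'   where speed matters more than the last digits).
#'
#' @return An object of class `nsc_fitspec`.
#' @export
fit_spec <- function(variants, layout = NULL, bounds = NULL, init = NULL,
                     n_starts = 30, seed = 1L,
                     control = list(maxit = 500, factr = 1000)) {
  if (is.null(names(variants)) || any(names(variants) == "")) {
    stop("'variants' must be a named list (one variant per genotype)")
  }
  stopifnot(n_starts >= 1)
  all_params <- c("r0", "beta_r", "b0", "beta_b", "ps", "NSC0", "kb", "nb")
  lay <- stats::setNames(rep("fixed", length(all_params)), all_params)
  used <- unique(unlist(lapply(variants, .params_for_variant)))
  lay[used] <- "free_per_genotype"
  if ("kb" %in% used) lay["kb"] <- "free_shared"
  lay["ps"] <- "fixed"
  if (!is.null(layout)) {
    bad <- setdiff(names(layout), all_params)
    if (length(bad)) stop("unknown parameters in layout: ",
                          paste(bad, collapse = ", "))
    if (!all(layout %in% c("fixed", "free_per_genotype", "free_shared"))) {
      stop("layout values must be fixed/free_per_genotype/free_shared")
    }
    lay[names(layout)] <- layout
  }
  b <- .default_bounds()
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  for (nm in names(b)) {
    if (lay[[nm]] != "fixed" && (any(!is.finite(b[[nm]])) ||
                                 b[[nm]][1] >= b[[nm]][2])) {
      stop("bounds for free parameter '", nm,
           "' must be finite with lower < upper")
    }
  }
  if (is.null(init)) {
    init <- lapply(variants, function(v) NULL)
  }
  structure(list(variants = variants, layout = lay, bounds = b, init = init,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 control = control),
            class = "nsc_fitspec")
}

# Internal: the free-parameter vector layout implied by a spec.
# Shared parameters appear once ("kb"); per-genotype ones per genotype
# ("r0[WT]"). Returns names, bounds and an index for rebuilding params.
.free_layout <- function(spec, genotypes) {
  entries <- list()
  for (nm in names(spec$layout)) {
    role <- spec$layout[[nm]]
    if (role == "free_shared") {
      entries[[length(entries) + 1L]] <-
        list(label = nm, param = nm, genotype = NA_character_)
    } else if (role == "free_per_genotype") {
      for (g in genotypes) {
        entries[[length(entries) + 1L]] <-
          list(label = sprintf("%s[%s]", nm, g), param = nm, genotype = g)
      }
    }
  }
  if (!length(entries)) stop("fit specification has no free parameters")
  labels <- vapply(entries, `[[`, character(1), "label")
  lower <- vapply(entries, function(e) spec$bounds[[e$param]][1], numeric(1))
  upper <- vapply(entries, function(e) spec$bounds[[e$param]][2], numeric(1))
  list(entries = entries,
       labels = labels,
       lower = stats::setNames(lower, labels),
       upper = stats::setNames(upper, labels))
}

# Internal: assemble per-genotype model_params from a free vector + spec.
.build_params <- function(par, layout, spec, genotypes) {
  out <- list()
  for (g in genotypes) {
    vals <- list(r0 = 0, beta_r = 0, b0 = NA_real_, beta_b = 0,
                 ps = ps_default(), NSC0 = NA_real_,
                 kb = NA_real_, nb = NA_real_)
    base <- spec$init[[g]]
    if (!is.null(base)) vals[names(unclass(base))] <- unclass(base)
    for (i in seq_along(layout$entries)) {
      e <- layout$entries[[i]]
      if (is.na(e$genotype) || identical(e$genotype, g)) {
        vals[[e$param]] <- par[[i]]
      }
    }
    out[[g]] <- do.call(model_params, vals)
  }
  out
}

#' Fit the NSC model to observations by multi-start weighted least squares
#'
#' Runs a box-constrained local optimiser (`L-BFGS-B`) from every
#' Latin-hypercube start point and keeps the converged run with the smallest
#' weighted residual sum of squares. All starts are recorded for diagnostics.
#'
#' @param table An observation table covering every genotype declared in the
#'   fit specification.
#' @param spec A [fit_spec()].
#'
#' @return An object of class `nsc_fit` with elements `params` (named list of
#'   best-fit [model_params()] per genotype), `variants`, `weighted_rss`,
#'   `n_obs`, `k` (number of free parameters), `aicc`, `free` (named best
#'   free-parameter vector), `boundary_active` (logical per free parameter),
#'   and `starts` (per-start data frame with start point, convergence flag
#'   and objective).
#' @export
fit_nsc <- function(table, spec) {
  table <- validate_observations(as.data.frame(table))
  genotypes <- names(spec$variants)
  missing_g <- setdiff(unique(table$genotype), genotypes)
  if (length(missing_g)) {
    stop("observations contain genotypes absent from the fit specification: ",
         paste(missing_g, collapse = ", "))
  }
  genotypes <- intersect(genotypes, unique(table$genotype))
  dispersion <- group_dispersion(table)
  layout <- .free_layout(spec, genotypes)
  bounds_list <- Map(function(l, u) c(l, u), layout$lower, layout$upper)
  starts <- latin_hypercube_starts(bounds_list, spec$n_starts, spec$seed)

  objective <- function(par) {
    pars <- .build_params(par, layout, spec, genotypes)
    suppressWarnings(
      weighted_sse(pars, spec$variants[genotypes], table, dispersion))
  }

  # Optimise in the unit box: parameters are rescaled by their bounds so the
  # finite-difference steps of L-BFGS-B are well-sized for every dimension.
  lo <- layout$lower
  span <- layout$upper - layout$lower
  objective_scaled <- function(u) objective(lo + u * span)

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    u0 <- (starts[i, ] - lo) / span
    res <- tryCatch(
      stats::optim(u0, objective_scaled, method = "L-BFGS-B",
                   lower = rep(0, length(u0)), upper = rep(1, length(u0)),
                   control = c(spec$control,
                               list(ndeps = rep(1e-7, length(u0))))),
      error = function(e) NULL)
    runs[[i]] <- if (is.null(res)) {
      list(par = starts[i, ], value = Inf, converged = FALSE)
    } else {
      list(par = lo + res$par * span, value = res$value,
           converged = res$convergence == 0)
    }
  }
  conv <- vapply(runs, `[[`, logical(1), "converged")
  objs <- vapply(runs, `[[`, numeric(1), "value")
  if (!any(conv)) {
    stop("no optimisation start converged; per-start objectives: ",
         paste(format(objs, digits = 4), collapse = ", "))
  }
  best_i <- which(conv)[which.min(objs[conv])]
  best <- runs[[best_i]]
  tolb <- 1e-8 * pmax(layout$upper - layout$lower, 1)
  boundary <- (best$par - layout$lower < tolb) | (layout$upper - best$par < tolb)

  starts_df <- as.data.frame(starts)
  names(starts_df) <- paste0("start_", layout$labels)
  starts_df$objective <- objs
  starts_df$converged <- conv

  n_obs <- nrow(table)
  k <- length(layout$labels)
  structure(list(
    params = .build_params(best$par, layout, spec, genotypes),
    variants = spec$variants[genotypes],
    weighted_rss = best$value,
    n_obs = n_obs,
    k = k,
    aicc = aicc(best$value, n_obs, k),
    free = stats::setNames(as.numeric(best$par), layout$labels),
    boundary_active = stats::setNames(as.logical(boundary), layout$labels),
    starts = starts_df,
    spec = spec,
    table = table
  ), class = "nsc_fit")
}

#' @export
print.nsc_fit <- function(x, ...) {
  cat(sprintf("NSC model fit: %d free parameters, %d observations\n",
              x$k, x$n_obs))
  cat(sprintf("  weighted RSS = %.6g, AICc = %.4f\n", x$weighted_rss, x$aicc))
  cat("  best free parameters:\n")
  for (nm in names(x$free)) {
    cat(sprintf("    %-14s %-12.6g%s\n", nm, x$free[[nm]],
                if (x$boundary_active[[nm]]) " (at bound)" else ""))
  }
  invisible(x)
}

#' Small-sample corrected Akaike information criterion for a WLS fit
#'
#' Gaussian least-squares form on the weighted residual sum of squares:
#' `n * log(RSS/n) + 2k + 2k(k+1)/(n - k - 1)`. Only differences between
#' models fitted to the same data are meaningful.
#'
#' @param weighted_rss Weighted residual sum of squares (>= 0).
#' @param n_obs Number of observations.
#' @param k Number of free parameters.
#'
#' @return A single numeric; errors if `n_obs <= k + 1` (correction term
#'   undefined).
#' @export
#' @examples
#' aicc(10, n_obs = 10, k = 2)
aicc <- function(weighted_rss, n_obs, k) {
  if (weighted_rss < 0) stop("'weighted_rss' must be >= 0")
  if (n_obs <= k + 1) {
    stop("AICc undefined: need n_obs > k + 1 (got n_obs = ", n_obs,
         ", k = ", k, ")")
  }
  n_obs * log(weighted_rss / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Rank fitted model variants by AICc
#'
#' @param fits A (possibly named) list of [fit_nsc()] results on the same
#'   observation table.
#'
#' @return A data frame sorted by AICc with columns `model`, `k`,
#'   `weighted_rss`, `aicc`, `delta_aicc`. Ties are broken by fewer
#'   parameters, then input order.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("no fits to compare")
  ref <- fits[[1]]$table
  norm <- function(tab) {
    tab <- as.data.frame(tab)[c("age_days", "genotype", "quantity", "value")]
    tab[do.call(order, tab), , drop = FALSE]
  }
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(norm(ref), norm(f$table), check.attributes = FALSE))) {
      stop("fits were not computed on the same observation table")
    }
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  nm[nm == ""] <- paste0("model", which(nm == ""))
  out <- data.frame(model = nm,
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    weighted_rss = vapply(fits, `[[`, numeric(1), "weighted_rss"),
                    aicc = vapply(fits, `[[`, numeric(1), "aicc"))
  out <- out[order(out$aicc, out$k, seq_len(nrow(out))), , drop = FALSE]
  out$delta_aicc <- out$aicc - out$aicc[1]
  rownames(out) <- NULL
  out
}

# Run code with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
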