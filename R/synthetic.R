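#' Noise model for synthetic observations
#'
#' Measurement noise applied by [generate_observations()]: total counts get
#' multiplicative log-normal noise with the given coefficient of variation
#' (mean-preserving), fractions get additive Gaussian noise truncated to
#' `[0, 1]` (by inverse-CDF sampling, so no probability mass piles up at the
#' bounds). The default fraction SD of 0.01 is the counting error of an
#' immunofluorescence quantification scoring on the order of a hundred cells
#' at activity fractions of a few percent (binomial standard error
#' `sqrt(p(1-p)/n)`); activity fractions in old age are below 0.01, so a
#' larger additive error would leave the quantity unmeasured.
#'
#' @param count_cv Coefficient of variation of the multiplicative count noise
#'   (>= 0).
#' @param fraction_sd Standard deviation of the additive fraction noise
#'   (>= 0).
#'
#' @return An object of class `nsc_noise`.
#' @export
noise_model <- function(count_cv = 0.2, fraction_sd = 0.01) {
  if (count_cv < 0 || fraction_sd < 0) stop("noise magnitudes must be >= 0")
  structure(list(count_cv = count_cv, fraction_sd = fraction_sd),
            class = "nsc_noise")
}

# Mean-preserving log-normal draws around mu with coefficient of variation cv.
.rlnorm_cv <- function(n, mu, cv) {
  if (cv == 0) return(rep(mu, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  mu * exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Gaussian draws around mu with sd, truncated to [lo, hi] by inverse CDF.
.rtruncnorm <- function(n, mu, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(pmin(pmax(mu, lo), hi), length.out = n))
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

#' Reference parameter sets for a wild-type / knockout pair
#'
#' A synthetic "truth" used throughout the examples and tests, chosen to
#' mimic the qualitative regime of adult mouse vSVZ counts: a few thousand
#' NSCs at day 60 declining towards a plateau of roughly one to two hundred
#' cells by day 660 in the wild type. The wild type has an exponentially
#' decaying activation rate and time-logistic self-renewal; the knockout has
#' a constant activation rate, below the wild-type initial rate but above
#' its late rate (the two activation curves cross in mid life), and a lower
#' initial self-renewal probability, so that sustained activation without
#' the age-related protection of the pool depletes NSC counts by old age.
#'
#' @return A list with elements `params` (named list of [model_params()] for
#'   `WT` and `IFNAGR_KO`) and `variants` (matching [model_variant()]s).
#' @export
#' @examples
#' truth <- reference_truth()
#' traj <- simulate_nsc(truth$params$WT, truth$variants$WT, seq(0, 700, 10))
#' tail(as_trajectory_table(traj))
reference_truth <- function() {
  list(
    params = list(
      WT = model_params(r0 = 0.065, beta_r = 0.0033, b0 = 0.32,
                        beta_b = 0.003, NSC0 = 6000),
      IFNAGR_KO = model_params(r0 = 0.04, b0 = 0.27, beta_b = 0.003,
                               NSC0 = 6000)
    ),
    variants = list(
      WT = model_variant("exponential_decay", "time_logistic"),
      IFNAGR_KO = model_variant("constant", "time_logistic")
    )
  )
}

#' Generate synthetic per-mouse NSC observations
#'
#' Simulates the model for each genotype and draws noisy per-mouse
#' measurements of both observed quantities (total NSC counts and fraction of
#' active NSCs) at each age, emulating the layout of the real FACS /
#' immunofluorescence data: a handful of mice per age and genotype at roughly
#' 2, 7 and 22 months.
#'
#' @param params_by_genotype Named list of [model_params()].
#' @param variants_by_genotype Named list of [model_variant()], same names.
#' @param ages Measurement ages in days.
#' @param n_per_age Mice per age and genotype.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed (the global RNG state is untouched).
#'
#' @return An observation table (see [observation_table()]).
#' @export
#' @examples
#' truth <- reference_truth()
#' obs <- generate_observations(truth$params, truth$variants, seed = 1)
#' head(obs)
generate_observations <- function(params_by_genotype, variants_by_genotype,
                                  ages = c(60, 210, 660), n_per_age = 5,
                                  noise = noise_model(), seed = 1L) {
  stopifnot(all(ages >= 0), n_per_age >= 1)
  genotypes <- names(params_by_genotype)
  .with_seed(seed, {
    out <- list()
    for (g in genotypes) {
      grid <- sort(unique(c(0, ages)))
      traj <- simulate_nsc(params_by_genotype[[g]], variants_by_genotype[[g]],
                           grid)
      idx <- match(ages, traj$time_days)
      tot <- traj$qNSC[idx] + traj$aNSC[idx]
      frac <- traj$aNSC[idx] / tot
      for (j in seq_along(ages)) {
        out[[length(out) + 1L]] <- data.frame(
          age_days = ages[j], genotype = g, quantity = "total_nsc",
          value = .rlnorm_cv(n_per_age, tot[j], noise$count_cv),
          sd = NA_real_)
        out[[length(out) + 1L]] <- data.frame(
          age_days = ages[j], genotype = g, quantity = "fraction_active",
          value = .rtruncnorm(n_per_age, frac[j], noise$fraction_sd),
          sd = NA_real_)
      }
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    class(tab) <- unique(c("nsc_observations", class(tab)))
    tab
  })
}

#' Generate a synthetic step-response time course
#'
#' Emulates quantified western-blot phospho-signal time courses (log2 fold
#' change versus time 0): a baseline level plus a step effect after a change
#' time, with Gaussian replicate noise. Null data sets use `step_effect = 0`.
#'
#' @param baseline Baseline log2 fold change.
#' @param step_effect Added effect for times strictly greater than
#'   `change_time`.
#' @param change_time Change time (hours).
#' @param times Measurement times (hours).
#' @param n_reps Replicates per time point.
#' @param sd Gaussian noise SD.
#' @param seed Integer seed.
#'
#' @return Data frame with columns `time_hours`, `value`, `replicate`.
#' @export
#' @examples
#' generate_timecourse(0, -1, change_time = 8, times = c(0, 1, 2, 16, 24),
#'                     n_reps = 1, sd = 0, seed = 1)
generate_timecourse <- function(baseline, step_effect, change_time, times,
                                n_reps = 3, sd = 0.2, seed = 1L) {
  stopifnot(sd >= 0, n_reps >= 1)
  .with_seed(seed, {
    tt <- rep(times, each = n_reps)
    rep_id <- rep(seq_len(n_reps), times = length(times))
    mu <- baseline + step_effect * (tt > change_time)
    data.frame(time_hours = tt,
               value = mu + stats::rnorm(length(tt), 0, sd),
               replicate = rep_id)
  })
}

.PYRIMIDINES <- c("C", "T")
.PURINES <- c("A", "G")

#' Generate a labelled set of synthetic 5'UTR sequences
#'
#' Builds a universe of 5'UTRs with known TOP-mRNA status. Positive records
#' start with a cytidine followed by a maximal pyrimidine run whose length is
#' drawn uniformly from 4 to 14, terminated by a purine. Negative records
#' violate exactly one clause of the definition: wrong first base, a run of
#' fewer than 4 pyrimidines, or a run longer than 14.
#'
#' @param n_top Number of TOP-positive records.
#' @param n_non_top Number of negative records.
#' @param length_range Total sequence length range (min 21).
#' @param seed Integer seed.
#'
#' @return Data frame with columns `id`, `sequence`, `is_top`.
#' @export
generate_utr_set <- function(n_top, n_non_top, length_range = c(30, 80),
                             seed = 1L) {
  stopifnot(n_top >= 0, n_non_top >= 0, length_range[1] >= 21)
  .with_seed(seed, {
    make_one <- function(kind) {
      len <- sample(seq(length_range[1], length_range[2]), 1)
      if (kind == "top") {
        first <- "C"; run <- sample(4:14, 1)
      } else if (kind == "first_base") {
        first <- sample(.PURINES, 1); run <- sample(4:14, 1)
      } else if (kind == "short_run") {
        first <- "C"; run <- sample(0:3, 1)
      } else {  # long_run
        first <- "C"; run <- sample(15:19, 1)
      }
      head_seq <- c(first, sample(.PYRIMIDINES, run, replace = TRUE),
                    sample(.PURINES, 1))
      tail_len <- len - length(head_seq)
      tail_seq <- sample(c("A", "C", "G", "T"), tail_len, replace = TRUE)
      paste(c(head_seq, tail_seq), collapse = "")
    }
    kinds <- c(rep("top", n_top),
               if (n_non_top > 0) {
                 sample(c("first_base", "short_run", "long_run"), n_non_top,
                        replace = TRUE)
               })
    seqs <- vapply(kinds, make_one, character(1), USE.NAMES = FALSE)
    data.frame(id = sprintf("utr_%04d", seq_along(kinds)),
               sequence = seqs,
               is_top = kinds == "top")
  })
}

#' Generate a toy single-cell count matrix with a planted signature
#'
#' Draws negative-binomial counts for a small gene-by-cell matrix in which a
#' designated group of cells expresses a signature gene set at an elevated
#' mean (fold change `effect`), emulating the inputs of per-cell gene-set
#' scoring.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param signature_genes Character vector of signature gene ids; must be a
#'   subset of the generated universe `gene0001 ...`. Defaults to the first
#'   20 genes.
#' @param effect Fold change applied to signature genes in the target group
#'   (1 = null).
#' @param groups Cell group labels (length `n_cells`); default splits cells
#'   evenly between `"target"` and `"background"`.
#' @param target_group Label of the group carrying the effect.
#' @param base_mu Baseline negative-binomial mean per gene.
#' @param size Negative-binomial dispersion parameter.
#' @param seed Integer seed.
#'
#' @return List with `counts` (genes x cells integer matrix with dimnames),
#'   `groups` (named by cell id) and `gene_set`.
#' @export
generate_toy_counts <- function(n_genes = 100, n_cells = 60,
                                signature_genes = NULL, effect = 4,
                                groups = NULL, target_group = "target",
                                base_mu = 5, size = 2, seed = 1L) {
  genes <- sprintf("gene%04d", seq_len(n_genes))
  cells <- sprintf("cell%04d", seq_len(n_cells))
  if (is.null(signature_genes)) signature_genes <- genes[seq_len(min(20, n_genes))]
  if (!all(signature_genes %in% genes)) {
    stop("'signature_genes' must be a subset of the generated gene universe")
  }
  if (is.null(groups)) {
    groups <- rep(c(target_group, "background"), length.out = n_cells)
  }
  stopifnot(length(groups) == n_cells, effect > 0)
  .with_seed(seed, {
    mu <- matrix(base_mu, nrow = n_genes, ncol = n_cells,
                 dimnames = list(genes, cells))
    mu[signature_genes, groups == target_group] <-
      mu[signature_genes, groups == target_group] * effect
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = as.vector(mu),
                                    size = size),
                     nrow = n_genes, dimnames = list(genes, cells))
    list(counts = counts, groups = stats::setNames(groups, cells),
         gene_set = signature_genes)
  })
}
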