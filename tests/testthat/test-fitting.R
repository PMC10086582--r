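make_obs <- function(values, ages = NULL, quantity = "total_nsc", sd = NA) {
  n <- length(values)
  if (is.null(ages)) ages <- rep(c(60, 210), length.out = n)
  observation_table(age_days = ages, genotype = "WT", quantity = quantity,
                    value = values, sd = sd)
}

test_that("group dispersion: sample SD, supplied override, degenerate errors", {
  # {90, 110} at one age -> sample SD sqrt(200), weight 1/sqrt(200)
  tab <- make_obs(c(90, 110, 200, 220), ages = c(60, 60, 210, 210))
  disp <- group_dispersion(tab)
  g60 <- disp[disp$age_days == 60, ]
  expect_equal(g60$sd, sqrt(200))
  expect_equal(g60$sd, 14.1421, tolerance = 1e-4)
  expect_equal(g60$weight, 0.070711, tolerance = 1e-4)

  # supplied SD takes precedence
  tab2 <- make_obs(c(90, 110, 200, 220), ages = c(60, 60, 210, 210), sd = 10)
  expect_equal(unique(group_dispersion(tab2)$weight), 0.1)

  # identical replicates have zero spread: explicit error, no silent fallback
  tab3 <- make_obs(c(100, 100, 100, 1, 2), ages = c(60, 60, 60, 210, 210))
  expect_error(group_dispersion(tab3), "zero or invalid dispersion")

  # single replicate without a supplied SD
  tab4 <- make_obs(c(100, 1, 2), ages = c(60, 210, 210))
  expect_error(group_dispersion(tab4), "single replicate")
})

test_that("weighted SSE applies inverse-SD weights and is order-invariant", {
  truth <- reference_truth()
  p <- truth$params["WT"]; v <- truth$variants["WT"]

  # perfect fit: zero-noise observations from the same parameters
  obs <- generate_observations(p, v, noise = noise_model(0, 0), seed = 1)
  obs$sd <- ifelse(obs$quantity == "total_nsc", 25, 0.01)
  expect_lt(weighted_sse(p, v, obs), 1e-14)

  # residual 2 with SD 1 contributes 4; with SD 2 contributes 1
  grid <- sort(unique(c(0, obs$age_days)))
  traj <- simulate_nsc(p$WT, v$WT, grid)
  pred60 <- sum(traj[traj$time_days == 60, c("qNSC", "aNSC")])
  pred210 <- sum(traj[traj$time_days == 210, c("qNSC", "aNSC")])
  one_off <- observation_table(
    age_days = c(60, 210), genotype = "WT", quantity = "total_nsc",
    value = c(pred60 + 2, pred210), sd = c(1, 1))
  expect_equal(weighted_sse(p, v, one_off), 4, tolerance = 1e-6)
  one_off$sd <- c(2, 2)
  expect_equal(weighted_sse(p, v, one_off), 1, tolerance = 1e-6)

  # reordering observation rows leaves the objective unchanged
  obs_noisy <- generate_observations(p, v, seed = 7)
  sse1 <- weighted_sse(p, v, obs_noisy)
  perm <- obs_noisy[rev(seq_len(nrow(obs_noisy))), ]
  expect_equal(weighted_sse(p, v, perm), sse1)
})

test_that("Latin-hypercube starts are stratified and reproducible", {
  bounds <- list(r0 = c(0, 1), NSC0 = c(10, 1010))
  one <- latin_hypercube_starts(bounds, 1, seed = 5)
  expect_true(one[1, "r0"] >= 0 && one[1, "r0"] <= 1)
  expect_true(one[1, "NSC0"] >= 10 && one[1, "NSC0"] <= 1010)

  pts <- latin_hypercube_starts(bounds, 10, seed = 5)
  for (j in colnames(pts)) {
    lo <- bounds[[j]][1]; hi <- bounds[[j]][2]
    bins <- cut(pts[, j], breaks = seq(lo, hi, length.out = 11))
    expect_true(all(table(bins) == 1))
  }
  expect_identical(pts, latin_hypercube_starts(bounds, 10, seed = 5))
  expect_false(identical(pts, latin_hypercube_starts(bounds, 10, seed = 6)))
})

test_that("AICc matches the Gaussian least-squares formula", {
  expect_equal(aicc(10, 10, 2), 10 * log(1) + 4 + 12 / 7)
  expect_equal(aicc(10, 10, 2), 5.7142857, tolerance = 1e-7)
  expect_equal(aicc(37, 37, 0), 0)
  expect_equal(aicc(20, 10, 2) - aicc(10, 10, 2), 10 * log(2))
  expect_error(aicc(10, 3, 2), "undefined")
})

test_that("bounds excluding the truth leave the best fit on a bound, flagged", {
  truth <- reference_truth()
  obs <- generate_observations(truth$params["WT"], truth$variants["WT"],
                               noise = noise_model(0.05, 0.02), seed = 3)
  spec <- fit_spec(truth$variants["WT"],
                   bounds = list(NSC0 = c(10, 1500)),  # truth NSC0 = 6000
                   n_starts = 3, seed = 2, control = fast_control)
  fit <- fit_nsc(obs, spec)
  expect_true(fit$boundary_active[["NSC0[WT]"]])
  expect_equal(fit$free[["NSC0[WT]"]], 1500, tolerance = 1e-6)
})

test_that("more starts never worsen the best objective on noise-free data", {
  truth <- reference_truth()
  obs <- generate_observations(truth$params["WT"], truth$variants["WT"],
                               noise = noise_model(0, 0), seed = 4)
  obs$sd <- ifelse(obs$quantity == "total_nsc", 25, 0.01)
  f1 <- fit_nsc(obs, fit_spec(truth$variants["WT"], n_starts = 1, seed = 9,
                              control = fast_control))
  f8 <- fit_nsc(obs, fit_spec(truth$variants["WT"], n_starts = 8, seed = 9,
                              control = fast_control))
  expect_lte(f8$weighted_rss, f1$weighted_rss * (1 + 1e-8) + 1e-10)
  expect_equal(nrow(f8$starts), 8)
  expect_true(any(f8$starts$converged))
  expect_equal(min(f8$starts$objective[f8$starts$converged]),
               f8$weighted_rss)
})

test_that("a parameter declared shared is structurally shared across genotypes", {
  truth <- reference_truth()
  variants <- list(
    WT = model_variant("exponential_decay", "hill_population"),
    IFNAGR_KO = model_variant("constant", "hill_population"))
  pars <- list(
    WT = model_params(r0 = 0.065, beta_r = 0.0033, NSC0 = 6000,
                      kb = 1 / 300, nb = -3),
    IFNAGR_KO = model_params(r0 = 0.04, NSC0 = 6000, kb = 1 / 300, nb = -3))
  obs <- generate_observations(pars, variants, seed = 21)
  spec <- fit_spec(variants, n_starts = 2, seed = 5, control = fast_control)
  expect_identical(spec$layout[["kb"]], "free_shared")
  fit <- fit_nsc(obs, spec)
  expect_identical(fit$params$WT$kb, fit$params$IFNAGR_KO$kb)
  expect_true("kb" %in% names(fit$free))
  expect_false("kb[WT]" %in% names(fit$free))
})

test_that("model comparison ranks by AICc with documented tie-breaks", {
  tab <- make_obs(c(90, 110, 200, 220), ages = c(60, 60, 210, 210))
  fake_fit <- function(k, rss, aicc_val) {
    structure(list(table = tab, k = k, weighted_rss = rss, aicc = aicc_val),
              class = "nsc_fit")
  }
  single <- compare_models(list(only = fake_fit(2, 5, 1.0)))
  expect_equal(single$delta_aicc, 0)

  tied <- compare_models(list(big = fake_fit(5, 4, 2.0),
                              small = fake_fit(3, 6, 2.0)))
  expect_equal(tied$model, c("small", "big"))  # fewer parameters first

  other <- fake_fit(2, 5, 1.0)
  other$table <- make_obs(c(1, 2, 3, 4), ages = c(60, 60, 210, 210))
  expect_error(compare_models(list(fake_fit(2, 5, 1.0), other)),
               "same observation table")
})

test_that("fit errors are informative for inconsistent specs", {
  truth <- reference_truth()
  obs <- generate_observations(truth$params, truth$variants, seed = 2)
  spec <- fit_spec(truth$variants["WT"], n_starts = 1, seed = 1)
  expect_error(fit_nsc(obs, spec), "absent from the fit specification")
})
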