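test_that("the linking function maps task variables to diffusion parameters", {
  cf <- ddm_coefficients(
    drift_base = 0, drift_reward = 0.1, drift_info = 0,
    bias_base = 0, bias_reward = 0, bias_info = 0,
    threshold = 1.5, nondecision = 0.3, horizon = 1L
  )
  w <- ddm_link(cf, delta_R = 10, delta_I = 0)
  expect_equal(w$drift, 1.0) # linear drift
  expect_equal(w$start_bias, 0) # logistic(0) -> no bias
  expect_equal(w$threshold, 1.5)
  # start bias is bounded in (-1, 1) for extreme inputs
  cf2 <- ddm_coefficients(bias_base = 4, bias_reward = 5, bias_info = 5)
  w2 <- ddm_link(cf2, delta_R = 25, delta_I = 1L)
  expect_lt(w2$start_bias, 1)
  expect_gt(w2$start_bias, -1)
  expect_error(ddm_link(cf, 1, 2L), "delta_I")
  expect_error(ddm_coefficients(threshold = -1), "threshold")
})

test_that("the joint likelihood is the sum of per-observation log densities", {
  cf <- ddm_coefficients(
    drift_base = 0.1, drift_reward = 0.08, drift_info = 0.4,
    bias_base = 0.05, bias_reward = 0.01, bias_info = 0.02,
    threshold = 1.4, nondecision = 0.3, horizon = 1L
  )
  obs <- tibble::tibble(
    delta_R = c(-8, 3, 12, -1, 6),
    delta_I = c(1L, -1L, 0L, 0L, 1L),
    choice_sign = c(1L, -1L, 1L, -1L, 1L),
    rt = c(0.8, 1.2, 0.6, 2.0, 0.95),
    horizon = 1L
  )
  # R-side oracle through the public density API
  ll <- vapply(seq_len(nrow(obs)), function(i) {
    w <- ddm_link(cf, obs$delta_R[i], obs$delta_I[i])
    b <- if (obs$choice_sign[i] > 0) "upper" else "lower"
    log(wfpt_density(obs$rt[i], w, b))
  }, numeric(1))
  expect_equal(ddm_nll(cf, obs), -sum(ll), tolerance = 1e-10)
  # additivity: duplicating an observation adds its own -log density
  expect_equal(
    ddm_nll(cf, obs[c(1:5, 3), ]),
    ddm_nll(cf, obs) - ll[3],
    tolerance = 1e-10
  )
  # T0 above the smallest rt triggers the finite penalty
  cf_hi <- cf
  cf_hi$nondecision <- 0.7 # above rt = 0.6
  expect_gt(ddm_nll(cf_hi, obs), ddm_nll(cf, obs))
  expect_true(is.finite(ddm_nll(cf_hi, obs)))
  expect_error(ddm_nll(cf, obs[0, ]), "empty")
})

test_that("the likelihood is invariant to a full left-right relabelling", {
  cf <- ddm_coefficients(
    drift_base = 0.2, drift_reward = 0.08, drift_info = 0.4,
    bias_base = 0.1, bias_reward = 0.02, bias_info = 0.05,
    threshold = 1.4, nondecision = 0.3, horizon = 1L
  )
  cf_flip <- cf
  for (nm in c("drift_base", "bias_base")) cf_flip[[nm]] <- -cf[[nm]]
  set.seed(71)
  obs <- tibble::tibble(
    delta_R = runif(30, -20, 20),
    delta_I = sample(c(-1L, 0L, 1L), 30, replace = TRUE),
    choice_sign = sample(c(-1L, 1L), 30, replace = TRUE),
    rt = runif(30, 0.5, 2),
    horizon = 1L
  )
  obs_flip <- obs
  obs_flip$delta_R <- -obs$delta_R
  obs_flip$delta_I <- -obs$delta_I
  obs_flip$choice_sign <- -obs$choice_sign
  expect_equal(ddm_nll(cf, obs), ddm_nll(cf_flip, obs_flip), tolerance = 1e-10)
})

test_that("choice marginals of the linked DDM match simulation", {
  cf <- ddm_coefficients(
    drift_base = 0, drift_reward = 0.1, drift_info = 0.3,
    bias_base = 0.2, bias_reward = 0, bias_info = 0,
    threshold = 1.2, nondecision = 0.3, horizon = 1L
  )
  set.seed(72)
  for (case in list(c(-10, 1), c(5, 0), c(15, -1))) {
    w <- ddm_link(cf, case[1], as.integer(case[2]))
    p <- hit_probability(w, "upper")
    sim <- simulate_wiener(w, 2e4)
    frac <- mean(sim$boundary == "upper")
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 2e4))
  }
})

test_that("maximum-likelihood fitting dominates the truth and is deterministic", {
  set.seed(73)
  reg <- age_regime("young")
  cf <- sample_participant(reg)
  sched <- generate_schedule(n_practice = 0, seed = 74)
  dat <- simulate_participant(cf, sched, "p1", "young")
  feats <- first_choice_features(dat)
  fit <- fit_ddm(feats, model_spec("baseline"), ddm_fit_options(restarts = 6))
  expect_true(fit$converged)
  nll_truth <- ddm_nll(cf[["1"]], feats[feats$horizon == 1, ]) +
    ddm_nll(cf[["6"]], feats[feats$horizon == 6, ])
  expect_lte(fit$nll, nll_truth + 1e-3)
  # identical data and options give an identical fit
  fit2 <- fit_ddm(feats, model_spec("baseline"), ddm_fit_options(restarts = 6))
  expect_identical(fit$coefficients, fit2$coefficients)
  # too few observations violate the precondition
  expect_error(
    fit_ddm(feats[1:10, ], model_spec("baseline")),
    "observations per horizon"
  )
})

test_that("yoked fits share the yoked coefficients across horizons", {
  cohort <- cached_cohort()
  feats <- first_choice_features(cohort$data)
  one <- feats[feats$participant_id == feats$participant_id[1], ]
  fit <- fit_ddm(one, model_spec("yoke_both"), ddm_fit_options(restarts = 4))
  expect_equal(
    fit$coefficients[["1"]]$threshold,
    fit$coefficients[["6"]]$threshold
  )
  expect_equal(
    fit$coefficients[["1"]]$drift_reward,
    fit$coefficients[["6"]]$drift_reward
  )
  # baseline has 16 free parameters, yoke_both 14
  expect_equal(model_spec("baseline")$n_par, 16L)
  expect_equal(model_spec("yoke_both")$n_par, 14L)
  # the richer baseline model attains an nll at least as good
  fit_base <- fit_ddm(one, model_spec("baseline"), ddm_fit_options(restarts = 4))
  expect_lte(fit_base$nll, fit$nll + 1e-3)
})

test_that("the DDM-to-softmax noise mapping matches a simulation refit", {
  cf <- ddm_coefficients(
    drift_base = 0, drift_reward = 0.08, drift_info = 0,
    bias_base = 0, bias_reward = 0, bias_info = 0,
    threshold = 1.5, nondecision = 0.3, horizon = 1L
  )
  sigma <- ddm_noise(cf)
  expect_equal(sigma, 1 / (4 * 1.5 * 0.08))
  # homogeneity: doubling the threshold halves the implied noise
  cf2 <- cf
  cf2$threshold <- 3
  expect_equal(ddm_noise(cf2), sigma / 2)
  # simulate choices from the zero-bias DDM choice rule over a delta_R grid,
  # refit the logistic model: fitted noise within 5% of the mapping
  set.seed(75)
  n <- 1e5
  dR <- runif(n, -25, 25)
  # vectorised zero-bias absorption probability (scale-function form),
  # spot-checked against the scalar API before use
  p_up_vec <- function(v, beta) {
    ifelse(abs(v) < 1e-10, 0.5, expm1(-2 * v * beta) / expm1(-4 * v * beta))
  }
  for (v in c(-0.8, 0.01, 1.3)) {
    expect_equal(
      p_up_vec(v, 1.5), hit_probability(wiener_params(v, 1.5), "upper")
    )
  }
  p_up <- p_up_vec(cf$drift_reward * dR, cf$threshold)
  obs <- tibble::tibble(
    participant_id = "s", game_id = seq_len(n), age_group = "synthetic",
    block = 1L, horizon = 1L,
    info_condition = ifelse(seq_len(n) <= 200, "UNEQUAL_13", "EQUAL_22"),
    delta_R = dR,
    delta_I = ifelse(seq_len(n) <= 200, 1L, 0L),
    choice_sign = ifelse(runif(n) < p_up, 1L, -1L),
    rt = 0.8, correct = NA
  )
  fit <- fit_logistic(obs, horizon = 1L)
  expect_lt(abs(fit$params$noise_equal - sigma) / sigma, 0.05)
  # exclusion signal for non-positive reward drift
  cf_neg <- cf
  cf_neg$drift_reward <- -0.01
  expect_true(is.na(ddm_noise(cf_neg)))
})

test_that("the threshold counterfactual changes noise by the threshold ratio", {
  cf <- ddm_coefficients(
    drift_reward = 0.06, threshold = 2.0, nondecision = 0.5, horizon = 1L
  )
  expect_equal(temperature_counterfactual(cf, 2.0), 0)
  # replacing with a lower (young-like) threshold raises noise
  pc <- temperature_counterfactual(cf, 1.5)
  expect_gt(pc, 0)
  expect_equal(pc, 100 * (2.0 / 1.5 - 1))
  expect_error(temperature_counterfactual(cf, -1), "replacement_threshold")
})
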