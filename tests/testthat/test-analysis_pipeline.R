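test_that("choice curves report p(high info) and p(left) in the design bins", {
  # oracle agent: always the higher observed mean; near-step curve
  obs <- make_features(200, seed = 101, choice_fun = function(dR, dI, h) {
    ifelse(dR >= 0, 1L, -1L)
  })
  cc <- choice_curves(obs, se = "pooled")
  eq <- cc[cc$condition == "equal" & cc$horizon == 1, ]
  expect_true(all(eq$mean[eq$bin_center > 0] == 1))
  expect_true(all(eq$mean[eq$bin_center < 0] == 0))
  # at most 8 unequal-condition bins with the design-offset edges
  uneq <- cc[cc$condition == "unequal" & cc$horizon == 1, ]
  expect_lte(nrow(uneq), 8)
  expect_true(all(cc$mean >= 0 & cc$mean <= 1))
  expect_true(all(cc$n > 0))
})

test_that("choice curves from a DDM cohort match the analytic absorption curve", {
  cf <- list(
    "1" = ddm_coefficients(drift_reward = 0.1, drift_info = 0.3,
                           threshold = 1.3, nondecision = 0.3, horizon = 1L),
    "6" = ddm_coefficients(drift_reward = 0.1, drift_info = 0.3,
                           threshold = 1.3, nondecision = 0.3, horizon = 6L)
  )
  set.seed(102)
  sched <- generate_schedule(n_practice = 0, n_test = 2048, seed = 103)
  dat <- simulate_participant(cf, sched, "c1")
  feats <- first_choice_features(dat)
  cc <- choice_curves(feats, se = "pooled")
  df <- prepare_curve_input(feats)
  df$bin <- cut(df$x, default_bin_edges)
  for (i in seq_len(nrow(cc))) {
    rows <- df[df$condition == cc$condition[i] & df$horizon == cc$horizon[i] &
      as.character(df$bin) == as.character(cc$bin[i]), ]
    if (nrow(rows) < 30) next
    p_exp <- mean(vapply(seq_len(nrow(rows)), function(j) {
      w <- ddm_link(cf[[as.character(rows$horizon[j])]],
                    rows$delta_R[j], as.integer(rows$delta_I[j]))
      p_up <- hit_probability(w, "upper")
      if (cc$condition[i] == "unequal" && rows$delta_I[j] == -1L) 1 - p_up else p_up
    }, numeric(1)))
    expect_lt(abs(cc$mean[i] - p_exp), 3 * sqrt(0.25 / nrow(rows)))
  }
})

test_that("RT curves are flat for constant RTs and peak near zero for the DDM", {
  obs_const <- make_features(100, seed = 104, choice_fun = function(dR, dI, h) {
    sample(c(-1L, 1L), length(dR), replace = TRUE)
  })
  rc <- rt_curves(obs_const, se = "pooled")
  expect_true(all(abs(rc$mean - 0.8) < 1e-12))

  cf <- list(
    "1" = ddm_coefficients(drift_reward = 0.15, threshold = 1.5,
                           nondecision = 0.3, horizon = 1L),
    "6" = ddm_coefficients(drift_reward = 0.15, threshold = 1.5,
                           nondecision = 0.3, horizon = 6L)
  )
  set.seed(105)
  sched <- generate_schedule(n_practice = 0, n_test = 1024, seed = 106)
  dat <- simulate_participant(cf, sched, "c1")
  feats <- first_choice_features(dat)
  rc2 <- rt_curves(feats, se = "pooled")
  eq <- rc2[rc2$condition == "equal" & rc2$horizon == 1, ]
  peak <- eq$bin_center[which.max(eq$mean)]
  expect_lte(abs(peak), 6) # hardest (slowest) decisions near delta_R = 0
})

test_that("the trial-position RT profile is slowest on the first free choice", {
  cohort <- cached_cohort()
  rt_by_trial <- dplyr::summarise(
    dplyr::group_by(cohort$data, .data$horizon, .data$trial_index),
    rt = mean(.data$rt), .groups = "drop"
  )
  first_free <- rt_by_trial$rt[rt_by_trial$trial_index == 5]
  instructed <- rt_by_trial$rt[rt_by_trial$trial_index <= 4]
  expect_true(all(first_free > max(instructed)))
})

test_that("parameter recovery returns a complete, reproducible summary", {
  cc <- cohort_config(3, age_regime("young"), n_practice = 0, seed = 107)
  rec <- parameter_recovery(cc, options = ddm_fit_options(restarts = 4))
  expect_setequal(rec$summary$coefficient, horizonDDM:::ddm_coef_names)
  expect_equal(nrow(rec$pairs), 6) # 3 participants x 2 horizons
  expect_true(all(rec$summary$n <= 6))
  rec2 <- parameter_recovery(cc, options = ddm_fit_options(restarts = 4))
  expect_equal(rec$summary, rec2$summary) # end-to-end determinism
})

test_that("posterior predictive output mirrors the observed curve structure", {
  cohort <- cached_cohort()
  feats <- first_choice_features(cohort$data)
  fits <- fit_cohort(feats, options = ddm_fit_options(restarts = 4))
  ppc <- posterior_predictive(fits, feats, n_rep = 3)
  obs_c <- ppc$choice$observed
  pred_c <- ppc$choice$predicted
  expect_true(all(pred_c$mean >= 0 & pred_c$mean <= 1))
  key <- function(x) paste(x$age_group, x$horizon, x$condition, x$bin)
  expect_true(all(key(obs_c) %in% key(pred_c)))
  expect_true(all(ppc$rt$predicted$mean > 0))
})

test_that("block-wise fits recover a threshold trend and skip tiny blocks", {
  # build block-varying data: each block simulated at a different threshold
  thresholds <- c(2.2, 1.9, 1.6, 1.3)
  set.seed(108)
  blocks <- lapply(1:4, function(b) {
    cf <- list(
      "1" = ddm_coefficients(drift_reward = 0.1, threshold = thresholds[b],
                             nondecision = 0.3, horizon = 1L),
      "6" = ddm_coefficients(drift_reward = 0.1, threshold = thresholds[b],
                             nondecision = 0.3, horizon = 6L)
    )
    sched <- generate_schedule(n_practice = 0, n_test = 64,
                               seed = 108 + b,
                               config = horizon_config(block_size = 64))
    d <- simulate_participant(cf, sched, "b1")
    d$block <- b
    d$game_id <- d$game_id + b * 1000L
    d
  })
  dat <- dplyr::bind_rows(blocks)
  feats <- first_choice_features(dat)
  bf <- fit_by_block(feats, options = ddm_fit_options(min_obs = 8, restarts = 4))
  expect_lte(nrow(bf), 4 * 2) # <= blocks x horizons rows per participant
  est <- dplyr::summarise(
    dplyr::group_by(bf, .data$block),
    threshold = mean(.data$threshold), .groups = "drop"
  )
  expect_true(all(diff(est$threshold) < 0)) # decreasing across blocks
  # a block below the minimum-trial guard is skipped with a warning
  feats_small <- feats[feats$block != 1 | seq_len(nrow(feats)) %% 13 == 0, ]
  expect_warning(
    fit_by_block(feats_small,
      options = ddm_fit_options(min_obs = 20, restarts = 2)
    ),
    "skipped"
  )
})

test_that("noise correlation excludes negative-drift participants and counts them", {
  # construct paired fit tables directly
  set.seed(109)
  n <- 20
  thr <- runif(n, 1, 2.5)
  crm <- runif(n, 0.03, 0.15)
  crm[1:4] <- -0.05 # four excluded participant-horizons
  fits_ddm <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n), horizon = 1L,
    threshold = thr, drift_reward = crm
  )
  sigma <- 1 / (4 * thr * crm)
  fits_log <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n), horizon = 1L,
    noise_unequal = sigma * exp(rnorm(n, 0, 0.1)),
    noise_equal = sigma * exp(rnorm(n, 0, 0.1))
  )
  nc <- noise_correlation(fits_ddm, fits_log)
  expect_equal(nc$n_excluded, 4)
  expect_equal(nc$n, 16)
  expect_gt(nc$r, 0.9) # near-identity by construction
  # self-correlation sanity: sigma computed from the same coefficients
  fits_log2 <- fits_log
  fits_log2$noise_unequal <- sigma
  expect_gt(noise_correlation(fits_ddm, fits_log2)$r, 0.999)
  expect_error(
    noise_correlation(fits_ddm[1:5, ], fits_log[1:5, ]),
    "valid"
  )
})

test_that("leave-one-out comparison flags ties between identical specs", {
  cohort <- cached_cohort()
  feats <- first_choice_features(cohort$data)
  one <- feats[feats$participant_id == feats$participant_id[1], ]
  one <- one[one$horizon == 1, ][1:24, ]
  res <- loo_compare(
    one,
    specs = list(model_spec("baseline"), model_spec("baseline")),
    options = ddm_fit_options(restarts = 2, min_obs = 10, maxit = 200)
  )
  pp <- res$per_participant
  expect_true(all(pp$tie))
  expect_equal(unique(pp$best_model), "baseline") # declared order wins
  expect_equal(pp$loo_ll[1], pp$loo_ll[2], tolerance = 1e-9)
  expect_true(all(res$summary$pct_best >= 0 & res$summary$pct_best <= 100))
  expect_error(loo_compare(one, specs = list(model_spec("baseline"))), "2 model")
})
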