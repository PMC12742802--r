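# default delta-R bin edges: between the design offsets +/- {4, 8, 12, 20}
default_bin_edges <- c(-Inf, -16, -10, -6, 0, 6, 10, 16, Inf)

curve_table <- function(df, outcome, edges, se_mode) {
  df$bin <- cut(df$x, breaks = edges)
  df <- df[!is.na(df$bin) & !is.na(df[[outcome]]), ]
  if (se_mode == "participant") {
    per <- dplyr::summarise(
      dplyr::group_by(
        df, .data$age_group, .data$horizon, .data$condition,
        .data$participant_id, .data$bin
      ),
      x = mean(.data$x), y = mean(.data[[outcome]]), .groups = "drop"
    )
    out <- dplyr::summarise(
      dplyr::group_by(
        per, .data$age_group, .data$horizon, .data$condition, .data$bin
      ),
      bin_center = mean(.data$x),
      mean = mean(.data$y),
      se = if (dplyr::n() > 1) sd(.data$y) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(
        df, .data$age_group, .data$horizon, .data$condition, .data$bin
      ),
      bin_center = mean(.data$x),
      mean = mean(.data[[outcome]]),
      se = sd(.data[[outcome]]) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
  }
  out
}

prepare_curve_input <- function(features) {
  uneq <- dplyr::filter(features, .data$delta_I != 0L)
  uneq$condition <- "unequal"
  uneq$x <- uneq$delta_I * uneq$delta_R # R(high info) - R(low info)
  uneq$chose <- as.numeric(uneq$choice_sign == uneq$delta_I) # p(high info)
  eq <- dplyr::filter(features, .data$delta_I == 0L)
  eq$condition <- "equal"
  eq$x <- eq$delta_R
  eq$chose <- as.numeric(eq$choice_sign == 1L) # p(left)
  dplyr::bind_rows(uneq, eq)
}

#' Choice curves on the first free choice
#'
#' Binned choice probabilities as a function of the observed mean reward
#' difference. In the unequal `[1 3]` condition the x-axis is
#' `R(high info) - R(low info)` and the outcome is the probability of
#' choosing the more informative option; in the equal `[2 2]` condition the
#' x-axis is `delta_R` (left - right) and the outcome is the probability of
#' choosing left. Empty bins are dropped.
#'
#' @param features a [first_choice_features()] tibble.
#' @param edges bin edges on the reward-difference axis; the default places
#'   boundaries between the task's design offsets.
#' @param se `"participant"` for across-participant s.e.m. (as in group
#'   figures) or `"pooled"` for pooled binomial/SD standard errors.
#' @return A curve tibble: `age_group`, `horizon`, `condition`, `bin`,
#'   `bin_center`, `mean`, `se`, `n`.
#' @export
choice_curves <- function(features, edges = default_bin_edges,
                          se = c("participant", "pooled")) {
  se <- match.arg(se)
  df <- prepare_curve_input(features)
  if (se == "pooled") {
    out <- curve_table(df, "chose", edges, "pooled")
    out$se <- sqrt(pmax(out$mean * (1 - out$mean), 1e-12) / out$n)
    return(out)
  }
  curve_table(df, "chose", edges, "participant")
}

#' Response-time curves on the first free choice
#'
#' As [choice_curves()] but with mean response time (seconds) as the
#' outcome. Diffusion-generated data peak near a zero reward difference,
#' where decisions are hardest.
#'
#' @inheritParams choice_curves
#' @return A curve tibble as in [choice_curves()].
#' @export
rt_curves <- function(features, edges = default_bin_edges,
                      se = c("participant", "pooled")) {
  se <- match.arg(se)
  df <- prepare_curve_input(features)
  curve_table(df, "rt", edges, if (se == "pooled") "pooled" else "participant")
}

#' Fit the DDM to every participant of a dataset
#'
#' Convenience wrapper running [fit_ddm()] per participant and collecting
#' the coefficient estimates into a tidy table.
#'
#' @param features a [first_choice_features()] tibble (multiple participants).
#' @param spec a [model_spec()].
#' @param options a [ddm_fit_options()].
#' @return A list with `fits` (named list of `ddm_fit` objects) and `coefs`
#'   (tibble: participant x horizon x coefficients, `nll`, `converged`).
#' @export
fit_cohort <- function(features, spec = model_spec("baseline"),
                       options = ddm_fit_options()) {
  ids <- unique(features$participant_id)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  rows <- list()
  for (pid in ids) {
    fit <- fit_ddm(features[features$participant_id == pid, ], spec, options)
    fits[[pid]] <- fit
    for (h in names(fit$coefficients)) {
      v <- as_par_vector(fit$coefficients[[h]])
      rows[[length(rows) + 1L]] <- tibble::add_column(
        tibble::as_tibble(as.list(v)),
        participant_id = pid, horizon = as.integer(h), .before = 1
      )
      rows[[length(rows)]]$nll <- unname(fit$nll_by_horizon[h])
      rows[[length(rows)]]$converged <- fit$converged
    }
  }
  list(fits = fits, coefs = dplyr::bind_rows(rows))
}

#' Fit the logistic choice model to every participant
#'
#' @param features a [first_choice_features()] tibble.
#' @param horizons horizons to fit.
#' @return A tidy tibble: participant x horizon x logistic parameters with
#'   `nll` and `converged`.
#' @export
fit_logistic_cohort <- function(features, horizons = c(1L, 6L)) {
  rows <- list()
  for (pid in unique(features$participant_id)) {
    obs <- features[features$participant_id == pid, ]
    for (h in intersect(horizons, unique(obs$horizon))) {
      f <- fit_logistic(obs, h)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, horizon = h,
        info_bonus = f$params$info_bonus,
        spatial_bias = f$params$spatial_bias,
        noise_unequal = f$params$noise_unequal,
        noise_equal = f$params$noise_equal,
        nll = f$nll, converged = f$converged
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Parameter recovery study
#'
#' Simulates a cohort from known coefficients, refits each participant, and
#' reports the per-coefficient Pearson correlation and mean bias between the
#' generating ("true") and fitted values, pooling participant x horizon
#' rows. Non-converged fits are excluded and counted.
#'
#' @param cc a [cohort_config()], or a list of them (e.g. a young-like and an
#'   old-like config, mirroring a recovery study over a full cohort whose
#'   generating parameters span both age groups).
#' @param spec a [model_spec()].
#' @param options a [ddm_fit_options()].
#' @return A list: `summary` (coefficient, r, bias, n), `pairs` (joined
#'   true/fitted table), `n_nonconverged`.
#' @export
parameter_recovery <- function(cc, spec = model_spec("baseline"),
                               options = ddm_fit_options()) {
  if (inherits(cc, "cohort_config")) cc <- list(cc)
  cohorts <- lapply(cc, simulate_cohort)
  cohort <- list(
    data = dplyr::bind_rows(lapply(cohorts, `[[`, "data")),
    truth = dplyr::bind_rows(lapply(cohorts, `[[`, "truth"))
  )
  if (anyDuplicated(cohort$truth[, c("participant_id", "horizon")]) > 0) {
    stop("cohort configs must use distinct regime names", call. = FALSE)
  }
  feats <- first_choice_features(cohort$data)
  fitted <- fit_cohort(feats, spec, options)
  est <- fitted$coefs
  n_nonconv <- sum(!est$converged) / 2L # counted per participant
  est <- est[est$converged, ]
  pairs <- dplyr::inner_join(
    cohort$truth, est,
    by = c("participant_id", "horizon"), suffix = c("_true", "_fit")
  )
  rows <- lapply(ddm_coef_names, function(nm) {
    x <- pairs[[paste0(nm, "_true")]]
    y <- pairs[[paste0(nm, "_fit")]]
    tibble::tibble(
      coefficient = nm,
      r = if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_,
      bias = mean(y - x),
      n = length(x)
    )
  })
  list(
    summary = dplyr::bind_rows(rows),
    pairs = pairs,
    n_nonconverged = n_nonconv
  )
}

#' Posterior predictive check
#'
#' For each fitted participant, simulates the model on that participant's
#' actual `(delta_R, delta_I)` sequence (replicated `n_rep` times) and
#' returns observed and model-predicted choice and response-time curves for
#' comparison.
#'
#' @param fits output of [fit_cohort()].
#' @param features the [first_choice_features()] the models were fit to.
#' @param n_rep simulated replicates of each observation.
#' @param dt,max_t Euler simulation settings.
#' @param edges curve bin edges.
#' @param se standard-error mode passed to the curve builders.
#' @return A list with elements `choice` and `rt`, each a list of `observed`
#'   and `predicted` curve tibbles.
#' @export
posterior_predictive <- function(fits, features, n_rep = 5, dt = 1e-3,
                                 max_t = 20, edges = default_bin_edges,
                                 se = c("participant", "pooled")) {
  se <- match.arg(se)
  sim_rows <- list()
  for (pid in names(fits$fits)) {
    fit <- fits$fits[[pid]]
    if (!fit$converged) next
    obs <- features[features$participant_id == pid, ]
    for (h in names(fit$coefficients)) {
      oh <- obs[obs$horizon == as.integer(h), ]
      if (nrow(oh) == 0) next
      cf <- fit$coefficients[[h]]
      oh_rep <- oh[rep(seq_len(nrow(oh)), n_rep), ]
      mu <- cf$drift_base + cf$drift_reward * oh_rep$delta_R +
        cf$drift_info * oh_rep$delta_I
      bias <- 2 * plogis(cf$bias_base + cf$bias_reward * oh_rep$delta_R +
        cf$bias_info * oh_rep$delta_I) - 1
      sim <- wiener_sim_obs_cpp(mu, bias, cf$threshold, cf$nondecision,
                                dt, max_t)
      keep <- !sim$censored
      oh_rep$choice_sign <- ifelse(sim$boundary > 0, 1L, -1L)
      oh_rep$rt <- sim$time
      sim_rows[[length(sim_rows) + 1L]] <- oh_rep[keep, ]
    }
  }
  predicted <- dplyr::bind_rows(sim_rows)
  list(
    choice = list(
      observed = choice_curves(features, edges, se),
      predicted = choice_curves(predicted, edges, se)
    ),
    rt = list(
      observed = rt_curves(features, edges, se),
      predicted = rt_curves(predicted, edges, se)
    )
  )
}

#' Block-wise DDM fits
#'
#' Fits the model independently within each task block (consecutive groups
#' of test games) to expose practice or strategy drift over the session.
#' Blocks with fewer observations than the minimum-trial guard are skipped
#' with a warning.
#'
#' @param features a [first_choice_features()] tibble with block labels.
#' @param spec a [model_spec()].
#' @param options a [ddm_fit_options()]; the default lowers `min_obs` to 8
#'   because one block holds only 16 first free choices per horizon.
#' @return A tidy tibble: participant x block x horizon x coefficients.
#' @export
fit_by_block <- function(features, spec = model_spec("baseline"),
                         options = ddm_fit_options(min_obs = 8)) {
  rows <- list()
  for (pid in unique(features$participant_id)) {
    obs_p <- features[features$participant_id == pid, ]
    for (b in sort(unique(obs_p$block))) {
      obs_b <- obs_p[obs_p$block == b, ]
      fit <- tryCatch(fit_ddm(obs_b, spec, options), error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf(
          "participant %s block %d skipped: %s", pid, b, conditionMessage(fit)
        ), call. = FALSE)
        next
      }
      for (h in names(fit$coefficients)) {
        v <- as_par_vector(fit$coefficients[[h]])
        rows[[length(rows) + 1L]] <- tibble::add_column(
          tibble::as_tibble(as.list(v)),
          participant_id = pid, block = b, horizon = as.integer(h),
          .before = 1
        )
        rows[[length(rows)]]$converged <- fit$converged
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Correlation between DDM-implied and logistic decision noise
#'
#' Pearson correlation across participant x horizon pairs between the
#' softmax-equivalent noise implied by the DDM
#' (`1 / (4 * threshold * drift_reward)`, see [ddm_noise()]) and the decision
#' noise fitted by the logistic choice model. Participants with non-positive
#' reward drift are excluded and counted, following the convention of
#' dropping negative-drift subjects from this mapping. The unequal-condition
#' logistic noise is the primary comparison; the equal-condition correlation
#' is also reported.
#'
#' @param fits_ddm tidy DDM coefficient table (from [fit_cohort()]`$coefs`).
#' @param fits_logistic tidy logistic table (from [fit_logistic_cohort()]).
#' @return A list: `r`, `p` (unequal-noise correlation test), `r_equal`,
#'   `n`, `n_excluded`, and the joined `pairs` tibble.
#' @export
noise_correlation <- function(fits_ddm, fits_logistic) {
  pairs <- dplyr::inner_join(
    fits_ddm, fits_logistic,
    by = c("participant_id", "horizon"), suffix = c("_ddm", "_logistic")
  )
  pairs$sigma_ddm <- ifelse(
    pairs$drift_reward > 0,
    1 / (4 * pairs$threshold * pairs$drift_reward),
    NA_real_
  )
  n_excluded <- sum(is.na(pairs$sigma_ddm))
  valid <- pairs[!is.na(pairs$sigma_ddm), ]
  if (nrow(valid) < 3) {
    stop("fewer than 3 valid participant-horizon pairs", call. = FALSE)
  }
  ct <- cor.test(valid$sigma_ddm, valid$noise_unequal)
  list(
    r = unname(ct$estimate),
    p = ct$p.value,
    r_equal = cor(valid$sigma_ddm, valid$noise_equal),
    n = nrow(valid),
    n_excluded = n_excluded,
    pairs = pairs
  )
}

#' Leave-one-game-out model comparison
#'
#' For each participant and each model specification, every first
#' free-choice observation is held out in turn, the model is refitted on the
#' remaining games (warm-started from the full-data fit), and the held-out
#' observation is scored by its log choice + response-time density. Folds in
#' which any model fails to converge are dropped symmetrically across models.
#' The best model per participant maximises the summed held-out
#' log-likelihood; ties are broken by parsimony (fewest free parameters),
#' then by the declared spec order, and flagged.
#'
#' @param features a [first_choice_features()] tibble.
#' @param specs list of [model_spec()] objects (>= 2).
#' @param options a [ddm_fit_options()].
#' @return A list: `per_participant` (participant x model held-out
#'   log-likelihoods, `best_model`, `tie`), `summary` (model, `n_best`,
#'   `pct_best`).
#' @export
loo_compare <- function(features,
                        specs = lapply(
                          c("baseline", "yoke_threshold",
                            "yoke_snr_reward", "yoke_both"),
                          model_spec
                        ),
                        options = ddm_fit_options()) {
  if (length(specs) < 2) stop("need at least 2 model specs", call. = FALSE)
  spec_names <- make.unique(vapply(specs, function(s) s$name, character(1)))
  rows <- list()
  for (pid in unique(features$participant_id)) {
    obs <- features[features$participant_id == pid, ]
    obs <- obs[!is.na(obs$rt), ]
    n <- nrow(obs)
    ll_mat <- matrix(NA_real_, nrow = n, ncol = length(specs))
    for (si in seq_along(specs)) {
      ll_mat[, si] <- loo_one_spec(obs, specs[[si]], options)
    }
    keep <- stats::complete.cases(ll_mat)
    ll_sum <- colSums(ll_mat[keep, , drop = FALSE])
    best_idx <- order(-ll_sum, vapply(specs, function(s) s$n_par, integer(1)))
    tie <- sum(abs(ll_sum - max(ll_sum)) < 1e-9) > 1
    row <- tibble::tibble(
      participant_id = pid,
      model = spec_names,
      loo_ll = ll_sum,
      n_folds = sum(keep)
    )
    row$best_model <- spec_names[best_idx[1]]
    row$tie <- tie
    rows[[length(rows) + 1L]] <- row
  }
  per_participant <- dplyr::bind_rows(rows)
  best <- dplyr::distinct(
    per_participant, .data$participant_id, .data$best_model
  )
  summary <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(
        model = factor(best$best_model, levels = spec_names)
      ),
      .data$model, .drop = FALSE
    ),
    n_best = dplyr::n(), .groups = "drop"
  )
  summary$pct_best <- 100 * summary$n_best / length(unique(best$participant_id))
  list(per_participant = per_participant, summary = summary)
}

# held-out log density per observation for one spec (internal)
loo_one_spec <- function(obs, spec, options) {
  n <- nrow(obs)
  ll <- rep(NA_real_, n)
  full <- tryCatch(fit_ddm(obs, spec, options), error = function(e) NULL)
  if (is.null(full) || !full$converged) {
    return(ll)
  }
  score_one <- function(coeffs, row) {
    -ddm_nll(coeffs, row, tol = options$tol, log_floor = options$log_floor)
  }
  # T0 bound from the participant's full data, so a fold refit cannot place
  # T0 above the held-out response time (which would floor its density)
  min_rt_h <- vapply(
    c("1", "6"),
    function(h) suppressWarnings(min(obs$rt[obs$horizon == as.integer(h)])),
    numeric(1)
  )
  if (spec$name == "baseline") {
    for (h in names(full$coefficients)) {
      idx <- which(obs$horizon == as.integer(h))
      warm <- as_par_vector(full$coefficients[[h]])
      for (i in idx) {
        rest <- obs[setdiff(idx, i), ]
        fh <- fit_one_horizon(rest, options,
          warm_start = warm, min_rt = min_rt_h[[h]]
        )
        if (!fh$converged) next
        ll[i] <- score_one(
          par_to_coeffs(fh$par, horizon = as.integer(h)), obs[i, ]
        )
      }
    }
  } else {
    idx6_free <- match(setdiff(ddm_coef_names, spec$shared), ddm_coef_names)
    warm <- c(
      as_par_vector(full$coefficients[["1"]]),
      as_par_vector(full$coefficients[["6"]])[idx6_free]
    )
    for (i in seq_len(n)) {
      rest <- obs[-i, ]
      fj <- fit_joint(
        rest[rest$horizon == 1L, ], rest[rest$horizon == 6L, ],
        spec$shared, options,
        warm_start = warm,
        min_rt1 = min_rt_h[["1"]], min_rt6 = min_rt_h[["6"]]
      )
      if (!fj$converged) next
      p <- fj$expand(fj$theta)
      h <- as.character(obs$horizon[i])
      coeffs <- par_to_coeffs(if (h == "1") p$p1 else p$p6,
        horizon = obs$horizon[i]
      )
      ll[i] <- score_one(coeffs, obs[i, ])
    }
  }
  ll
}
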