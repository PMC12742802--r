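# truncated-normal draws by inverse-CDF (degenerate sd = 0 returns the mean)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  pmin(pmax(qnorm(p, mean, sd), lower), upper)
}

# truncation bounds for regime draws: the fit bounds, with T0 floored at
# 0.1 s (a plausible physiological minimum)
regime_bounds <- function() {
  list(
    lower = c(-10, -1, -10, -5, -5, -5, 0.05, 0.1),
    upper = c(10, 1, 10, 5, 5, 5, 10, 1.5)
  )
}

#' Construct a between-participant parameter regime
#'
#' A regime specifies, per horizon condition, the mean and standard deviation
#' of every DDM linking coefficient; participants are drawn from truncated
#' Gaussians within the fitting bounds (non-decision time floored at 0.1 s).
#' Coefficients named in `yoked` are drawn once (from the horizon-1
#' distribution) and shared across horizons.
#'
#' @param name regime label.
#' @param h1,h6 lists with named numeric vectors `mean` and `sd` over the
#'   coefficients `drift_base`, `drift_reward`, `drift_info`, `bias_base`,
#'   `bias_reward`, `bias_info`, `threshold`, `nondecision`.
#' @param yoked coefficient names drawn once and shared across horizons.
#' @return A list of class `age_regime`.
#' @export
make_regime <- function(name, h1, h6, yoked = character(0)) {
  for (h in list(h1, h6)) {
    stopifnot(
      setequal(names(h$mean), ddm_coef_names),
      setequal(names(h$sd), ddm_coef_names),
      h$mean[["threshold"]] > 0, h$mean[["nondecision"]] >= 0.1
    )
  }
  stopifnot(all(yoked %in% ddm_coef_names))
  structure(
    list(
      name = name,
      h1 = list(mean = h1$mean[ddm_coef_names], sd = h1$sd[ddm_coef_names]),
      h6 = list(mean = h6$mean[ddm_coef_names], sd = h6$sd[ddm_coef_names]),
      yoked = yoked
    ),
    class = "age_regime"
  )
}

#' Built-in young-like and old-like parameter regimes
#'
#' Illustrative regime defaults reproducing the qualitative age pattern of
#' published Horizon-Task DDM fits: relative to the young-like regime, the
#' old-like regime has a higher threshold and longer non-decision time in
#' both horizons, a lower information drift (SNR information) in both
#' horizons, and a lower reward drift (SNR reward) in horizon 1; within the
#' young-like regime threshold and SNR reward decrease from horizon 1 to 6
#' while SNR information increases. The numerical values are NOT published
#' estimates - no parameter means are printed in the source literature - they
#' are package defaults chosen once to respect those orderings (see
#' `vignette("horizon-ddm")`).
#'
#' @param name `"young"` or `"old"`.
#' @return An [make_regime()] object.
#' @export
age_regime <- function(name = c("young", "old")) {
  name <- match.arg(name)
  # Means calibrated with the closed-form mean decision time so that implied
  # response times land in the published group ranges (young roughly
  # 0.7-1.1 s, old roughly 1.1-1.8 s on the first free choice) while keeping
  # the qualitative orderings above.
  sd_common <- c(
    drift_base = 0.05, drift_reward = 0.025, drift_info = 0.12,
    bias_base = 0.1, bias_reward = 0.01, bias_info = 0.05,
    threshold = 0.2, nondecision = 0.08
  )
  if (name == "young") {
    h1 <- list(
      mean = c(
        drift_base = 0, drift_reward = 0.11, drift_info = 0.35,
        bias_base = 0, bias_reward = 0.01, bias_info = 0.05,
        threshold = 0.90, nondecision = 0.35
      ),
      sd = sd_common
    )
    h6 <- list(
      mean = c(
        drift_base = 0, drift_reward = 0.055, drift_info = 0.90,
        bias_base = 0, bias_reward = 0.01, bias_info = 0.10,
        threshold = 0.75, nondecision = 0.32
      ),
      sd = replace(sd_common, c("drift_reward", "drift_info"), c(0.02, 0.25))
    )
  } else {
    h1 <- list(
      mean = c(
        drift_base = 0, drift_reward = 0.075, drift_info = 0.25,
        bias_base = 0, bias_reward = 0.01, bias_info = 0.04,
        threshold = 1.15, nondecision = 0.55
      ),
      sd = replace(sd_common, c("drift_reward", "threshold", "nondecision"),
                   c(0.02, 0.25, 0.1))
    )
    h6 <- list(
      mean = c(
        drift_base = 0, drift_reward = 0.055, drift_info = 0.60,
        bias_base = 0, bias_reward = 0.01, bias_info = 0.08,
        threshold = 1.15, nondecision = 0.56
      ),
      sd = replace(sd_common,
                   c("drift_reward", "drift_info", "threshold", "nondecision"),
                   c(0.02, 0.2, 0.25, 0.1))
    )
  }
  make_regime(name, h1, h6)
}

#' Draw one participant's coefficients from a regime
#'
#' Truncated-Gaussian draws within the fit bounds, one
#' [ddm_coefficients()] set per horizon condition; `yoked` coefficients are
#' drawn once and copied to both horizons. Uses R's RNG.
#'
#' @param regime an [age_regime()] / [make_regime()] object.
#' @return A list with elements `"1"` and `"6"` of [ddm_coefficients()].
#' @export
sample_participant <- function(regime) {
  stopifnot(inherits(regime, "age_regime"))
  b <- regime_bounds()
  draw <- function(h) {
    vapply(seq_along(ddm_coef_names), function(j) {
      rtrunc_norm(1, h$mean[[j]], h$sd[[j]], b$lower[j], b$upper[j])
    }, numeric(1))
  }
  p1 <- draw(regime$h1)
  p6 <- draw(regime$h6)
  names(p1) <- names(p6) <- ddm_coef_names
  if (length(regime$yoked) > 0) p6[regime$yoked] <- p1[regime$yoked]
  list(
    "1" = par_to_coeffs(p1, horizon = 1L),
    "6" = par_to_coeffs(p6, horizon = 6L)
  )
}

# update running observed means for the greedy policy on later free trials
greedy_choice <- function(sum_l, n_l, sum_r, n_r, lapse) {
  greedy <- ifelse(sum_l / n_l >= sum_r / n_r, "left", "right")
  flip <- runif(length(greedy)) < lapse
  ifelse(flip, ifelse(greedy == "left", "right", "left"), greedy)
}

#' Simulate one participant's Horizon Task session
#'
#' Plays the instructed trials of a schedule, then draws the first free
#' choice and its response time from the linked diffusion process via
#' Euler-Maruyama simulation. Later horizon-6 free choices (trials 2-6) are
#' OUTSIDE the model of interest and are filled by a documented placeholder
#' policy - greedy on the observed running mean with a lapse rate - so that
#' accuracy-by-trial curves can be exercised. Instructed trials and later
#' free choices get placeholder response times (non-decision time plus a
#' small gamma-distributed motor latency), qualitatively faster than the
#' modelled first free choice.
#'
#' Diffusion paths censored at `max_t` are resampled once; a path censored
#' twice is assigned the drift-sign choice at `max_t` and counted in the
#' `n_forced` attribute.
#'
#' @param coeffs a list with elements `"1"` and `"6"` of
#'   [ddm_coefficients()], as returned by [sample_participant()].
#' @param schedule a [generate_schedule()] tibble.
#' @param participant_id,age_group identifiers copied into the dataset.
#' @param dt,max_t Euler step and maximum diffusion duration (seconds).
#' @param lapse lapse rate of the later-trial placeholder policy.
#' @param include_practice keep practice games (block 0) in the output.
#' @return A trial-level tibble in the canonical schema.
#' @export
simulate_participant <- function(coeffs, schedule, participant_id = "p1",
                                 age_group = "synthetic", dt = 1e-3,
                                 max_t = 20, lapse = 0.1,
                                 include_practice = FALSE) {
  stopifnot(all(c("1", "6") %in% names(coeffs)) ||
    all(as.character(unique(schedule$horizon)) %in% names(coeffs)))
  if (!include_practice) {
    schedule <- dplyr::filter(schedule, !.data$is_practice)
  }
  n_games <- nrow(schedule)
  sides <- do.call(rbind, strsplit(schedule$forced_sequence, ""))

  # instructed trials, vectorised across games
  g_idx <- rep(seq_len(n_games), each = 4L)
  side_flat <- as.vector(t(sides))
  mean_flat <- ifelse(side_flat == "L",
    schedule$mean_left[g_idx], schedule$mean_right[g_idx]
  )
  reward_flat <- draw_reward(mean_flat, schedule$reward_sd[g_idx])
  t0_flat <- vapply(
    as.character(schedule$horizon[g_idx]),
    function(h) coeffs[[h]]$nondecision, numeric(1)
  )
  instructed <- tibble::tibble(
    game_id = schedule$game_id[g_idx],
    block = schedule$block[g_idx],
    horizon = schedule$horizon[g_idx],
    info_condition = schedule$info_condition[g_idx],
    trial_index = rep(1:4, n_games),
    is_instructed = TRUE,
    choice = ifelse(side_flat == "L", "left", "right"),
    reward = reward_flat,
    rt = round(t0_flat + rgamma(n_games * 4L, shape = 2, scale = 0.05), 3),
    gen_mean_left = schedule$mean_left[g_idx],
    gen_mean_right = schedule$mean_right[g_idx]
  )

  # per-game features feeding the diffusion
  left_mask <- side_flat == "L"
  sum_by <- function(x, mask) {
    as.vector(tapply(x * mask, g_idx, sum))
  }
  sum_l <- sum_by(reward_flat, left_mask)
  n_l <- sum_by(rep(1, length(g_idx)), left_mask)
  sum_r <- sum_by(reward_flat, !left_mask)
  n_r <- sum_by(rep(1, length(g_idx)), !left_mask)
  delta_R <- sum_l / n_l - sum_r / n_r
  delta_I <- ifelse(schedule$info_condition == "EQUAL_22", 0L,
    ifelse(n_l == 1L, 1L, -1L)
  )

  # first free choice by Euler-Maruyama diffusion, one horizon block at a time
  first_choice <- character(n_games)
  first_rt <- numeric(n_games)
  n_forced <- 0L
  for (h in as.character(sort(unique(schedule$horizon)))) {
    idx <- which(schedule$horizon == as.integer(h))
    cf <- coeffs[[h]]
    mu <- cf$drift_base + cf$drift_reward * delta_R[idx] +
      cf$drift_info * delta_I[idx]
    bias <- 2 * plogis(cf$bias_base + cf$bias_reward * delta_R[idx] +
      cf$bias_info * delta_I[idx]) - 1
    sim <- wiener_sim_obs_cpp(mu, bias, cf$threshold, cf$nondecision, dt, max_t)
    cens <- which(sim$censored)
    if (length(cens) > 0) { # resample once
      sim2 <- wiener_sim_obs_cpp(
        mu[cens], bias[cens], cf$threshold, cf$nondecision, dt, max_t
      )
      sim$time[cens] <- sim2$time
      sim$boundary[cens] <- sim2$boundary
      sim$censored[cens] <- sim2$censored
      still <- which(sim$censored)
      if (length(still) > 0) { # forced: drift-sign choice at max_t
        n_forced <- n_forced + length(still)
        sim$boundary[still] <- ifelse(mu[still] >= 0, 1L, -1L)
        sim$time[still] <- cf$nondecision + max_t
      }
    }
    first_choice[idx] <- ifelse(sim$boundary > 0, "left", "right")
    first_rt[idx] <- round(sim$time, 3)
  }
  first_reward <- draw_reward(
    ifelse(first_choice == "left", schedule$mean_left, schedule$mean_right),
    schedule$reward_sd
  )
  free1 <- tibble::tibble(
    game_id = schedule$game_id,
    block = schedule$block,
    horizon = schedule$horizon,
    info_condition = schedule$info_condition,
    trial_index = 5L,
    is_instructed = FALSE,
    choice = first_choice,
    reward = first_reward,
    rt = first_rt,
    gen_mean_left = schedule$mean_left,
    gen_mean_right = schedule$mean_right
  )

  # later horizon-6 free choices: greedy-on-observed-mean placeholder with
  # lapse; not modelled by the DDM (trial_index > 5)
  later <- NULL
  h6 <- which(schedule$horizon == 6L)
  if (length(h6) > 0) {
    sl <- sum_l[h6] + ifelse(first_choice[h6] == "left", first_reward[h6], 0)
    nl <- n_l[h6] + (first_choice[h6] == "left")
    sr <- sum_r[h6] + ifelse(first_choice[h6] == "right", first_reward[h6], 0)
    nr <- n_r[h6] + (first_choice[h6] == "right")
    t0_6 <- coeffs[["6"]]$nondecision
    rows <- list()
    for (tr in 6:10) {
      ch <- greedy_choice(sl, nl, sr, nr, lapse)
      rw <- draw_reward(
        ifelse(ch == "left", schedule$mean_left[h6], schedule$mean_right[h6]),
        schedule$reward_sd[h6]
      )
      rows[[tr - 5L]] <- tibble::tibble(
        game_id = schedule$game_id[h6],
        block = schedule$block[h6],
        horizon = 6L,
        info_condition = schedule$info_condition[h6],
        trial_index = as.integer(tr),
        is_instructed = FALSE,
        choice = ch,
        reward = rw,
        rt = round(t0_6 + rgamma(length(h6), shape = 2, scale = 0.06), 3),
        gen_mean_left = schedule$mean_left[h6],
        gen_mean_right = schedule$mean_right[h6]
      )
      sl <- sl + ifelse(ch == "left", rw, 0)
      nl <- nl + (ch == "left")
      sr <- sr + ifelse(ch == "right", rw, 0)
      nr <- nr + (ch == "right")
    }
    later <- dplyr::bind_rows(rows)
  }

  out <- dplyr::bind_rows(instructed, free1, later)
  out <- dplyr::arrange(out, .data$game_id, .data$trial_index)
  out <- tibble::add_column(out,
    participant_id = as.character(participant_id),
    age_group = age_group, .before = 1
  )
  attr(out, "n_forced") <- n_forced
  out
}

#' Cohort simulation configuration
#'
#' @param n_participants number of synthetic participants (>= 1).
#' @param regime an [age_regime()] / [make_regime()] object.
#' @param n_practice,n_test schedule game counts.
#' @param seed integer master seed; the cohort is bitwise reproducible.
#' @param config task design constants ([horizon_config()]).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants, regime = age_regime("young"),
                          n_practice = 16, n_test = 128, seed = 1L,
                          config = horizon_config()) {
  stopifnot(n_participants >= 1)
  structure(
    list(
      n_participants = n_participants, regime = regime,
      n_practice = n_practice, n_test = n_test, seed = seed, config = config
    ),
    class = "cohort_config"
  )
}

#' Simulate a synthetic cohort
#'
#' Draws per-participant coefficients from the regime, generates each
#' participant an independent counterbalanced schedule, and simulates the
#' session. Returns the trial-level dataset in the canonical schema together
#' with the ground-truth coefficient table (one row per participant x
#' horizon), which joins the dataset exactly on `participant_id`.
#'
#' @param cc a [cohort_config()].
#' @return A list with elements `data` (trial tibble) and `truth`
#'   (coefficient tibble).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(2, seed = 42))
#' nrow(cohort$truth) # 2 participants x 2 horizons
#' }
#' @export
simulate_cohort <- function(cc) {
  stopifnot(inherits(cc, "cohort_config"))
  set.seed(cc$seed)
  part_seeds <- sample.int(.Machine$integer.max - 1L, cc$n_participants)
  data_rows <- vector("list", cc$n_participants)
  truth_rows <- vector("list", cc$n_participants)
  for (i in seq_len(cc$n_participants)) {
    pid <- sprintf("%s_%03d", cc$regime$name, i)
    sched <- generate_schedule(cc$n_practice, cc$n_test,
      seed = part_seeds[i], config = cc$config
    )
    coeffs <- sample_participant(cc$regime)
    data_rows[[i]] <- simulate_participant(
      coeffs, sched,
      participant_id = pid, age_group = cc$regime$name
    )
    truth_rows[[i]] <- dplyr::bind_rows(lapply(c("1", "6"), function(h) {
      v <- as_par_vector(coeffs[[h]])
      tibble::as_tibble(as.list(v))
    }))
    truth_rows[[i]] <- tibble::add_column(truth_rows[[i]],
      participant_id = pid, age_group = cc$regime$name,
      horizon = c(1L, 6L), .before = 1
    )
  }
  list(
    data = dplyr::bind_rows(data_rows),
    truth = dplyr::bind_rows(truth_rows)
  )
}
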