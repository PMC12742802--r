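# Shared fixtures, all generated in code under fixed seeds.

# minimal canonical trial rows for one game
make_game_trials <- function(participant_id = "p1", game_id = 1L, block = 1L,
                             horizon = 1L, info_condition = "UNEQUAL_13",
                             left_rewards, right_rewards, free_choice = "left",
                             free_rt = 0.8, gen_mean_left = 40,
                             gen_mean_right = 44) {
  sides <- c(rep("left", length(left_rewards)), rep("right", length(right_rewards)))
  rewards <- c(left_rewards, right_rewards)
  instructed <- tibble::tibble(
    participant_id = participant_id, age_group = "synthetic",
    game_id = game_id, block = block, horizon = horizon,
    info_condition = info_condition,
    trial_index = seq_along(sides), is_instructed = TRUE,
    choice = sides, reward = rewards, rt = NA_real_,
    gen_mean_left = gen_mean_left, gen_mean_right = gen_mean_right
  )
  free <- tibble::tibble(
    participant_id = participant_id, age_group = "synthetic",
    game_id = game_id, block = block, horizon = horizon,
    info_condition = info_condition,
    trial_index = 5L, is_instructed = FALSE,
    choice = free_choice, reward = 50, rt = free_rt,
    gen_mean_left = gen_mean_left, gen_mean_right = gen_mean_right
  )
  dplyr::bind_rows(instructed, free)
}

# first-free-choice feature rows generated directly from a choice rule,
# bypassing the trial layer (for model-level tests)
make_features <- function(n_per_cell, choice_fun, rt_fun = function(d) 0.8,
                          participant_id = "p1", seed = 1) {
  set.seed(seed)
  rows <- list()
  gid <- 0L
  for (h in c(1L, 6L)) {
    for (cond in c("UNEQUAL_13", "EQUAL_22")) {
      dR <- runif(n_per_cell, -25, 25)
      dI <- if (cond == "EQUAL_22") {
        rep(0L, n_per_cell)
      } else {
        sample(c(-1L, 1L), n_per_cell, replace = TRUE)
      }
      cs <- choice_fun(dR, dI, h)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = participant_id, game_id = gid + seq_len(n_per_cell),
        age_group = "synthetic",
        block = 1L, horizon = h, info_condition = cond,
        delta_R = dR, delta_I = dI, choice_sign = cs,
        rt = rt_fun(dR), correct = NA
      )
      gid <- gid + n_per_cell
    }
  }
  dplyr::bind_rows(rows)
}

# small cached young-like cohort reused across pipeline tests
cached_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(
        cohort_config(4, age_regime("young"), n_practice = 0, seed = 303)
      )
    }
    cache
  }
})
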