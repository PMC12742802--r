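test_that("schedule generation counterbalances horizon x information exactly", {
  sched <- generate_schedule(n_practice = 16, n_test = 128, seed = 1)
  expect_equal(nrow(sched), 144)
  test <- sched[!sched$is_practice, ]
  expect_equal(sum(test$horizon == 1), 64)
  expect_equal(sum(test$horizon == 6), 64)
  tab <- table(test$horizon, test$info_condition)
  expect_true(all(tab == 32))
  # design invariants: anchor mean and offset families
  anchor_ok <- test$mean_left %in% c(40, 60) | test$mean_right %in% c(40, 60)
  expect_true(all(anchor_ok))
  expect_true(all(abs(test$mean_left - test$mean_right) %in% c(4, 8, 12, 20)))
  # blocks: four consecutive blocks of 32 test games; practice marked 0
  expect_equal(as.vector(table(test$block)), rep(32, 4))
  expect_true(all(sched$block[sched$is_practice] == 0L))
  # forced sequences respect the information condition
  n_left <- vapply(
    strsplit(test$forced_sequence, ""),
    function(s) sum(s == "L"), integer(1)
  )
  expect_true(all(n_left[test$info_condition == "EQUAL_22"] == 2))
  expect_true(all(n_left[test$info_condition == "UNEQUAL_13"] %in% c(1, 3)))
})

test_that("schedule generation is deterministic under the seed and errors on bad counts", {
  a <- generate_schedule(seed = 7)
  b <- generate_schedule(seed = 7)
  expect_identical(a, b)
  c <- generate_schedule(seed = 8)
  expect_false(identical(a$mean_left, c$mean_left))
  # practice-only schedule
  p <- generate_schedule(n_practice = 4, n_test = 0, seed = 1)
  expect_equal(nrow(p), 4)
  expect_true(all(p$is_practice))
  expect_error(generate_schedule(n_test = 30, seed = 1), "divisible")
})

test_that("instructed plays draw rounded Gaussian rewards around the side mean", {
  game <- list(
    game_id = 1L, block = 1L, horizon = 1L, info_condition = "EQUAL_22",
    mean_left = 60, mean_right = 40, reward_sd = 0,
    forced_sequence = "LLRR"
  )
  tr <- play_instructed(game)
  expect_equal(tr$reward, c(60, 60, 40, 40)) # degenerate SD
  expect_true(all(tr$is_instructed))
  expect_equal(tr$trial_index, 1:4)

  # UNEQUAL game: exactly one instructed play on the lone side
  set.seed(2)
  g13 <- generate_schedule(n_practice = 0, n_test = 4, seed = 3)
  g13 <- g13[g13$info_condition == "UNEQUAL_13", ][1, ]
  tr13 <- play_instructed(g13)
  expect_true(min(table(tr13$choice)) == 1 && max(table(tr13$choice)) == 3)

  # Monte-Carlo: sample mean of many draws near the generative mean
  set.seed(4)
  gmc <- list(
    game_id = 1L, block = 1L, horizon = 1L, info_condition = "EQUAL_22",
    mean_left = 40, mean_right = 40, reward_sd = 8, forced_sequence = "LLLL"
  )
  draws <- unlist(lapply(1:2500, function(i) play_instructed(gmc)$reward))
  expect_lt(abs(mean(draws) - 40), 3 * 8 / sqrt(length(draws)))
})

test_that("first free-choice features follow the definition", {
  # left rewards {44}, right {38, 50, 47}: delta_R = 44 - 45 = -1, delta_I = +1
  d <- make_game_trials(
    left_rewards = 44, right_rewards = c(38, 50, 47),
    info_condition = "UNEQUAL_13", free_choice = "left",
    gen_mean_left = 40, gen_mean_right = 44
  )
  f <- first_choice_features(d)
  expect_equal(f$delta_R, -1)
  expect_equal(f$delta_I, 1L)
  expect_equal(f$choice_sign, 1L)
  expect_false(f$correct) # left generative mean is lower

  # equal condition: delta_I = 0; identical rewards: delta_R = 0
  d2 <- make_game_trials(
    left_rewards = c(42, 58), right_rewards = c(42, 58),
    info_condition = "EQUAL_22", free_choice = "right"
  )
  f2 <- first_choice_features(d2)
  expect_equal(f2$delta_I, 0L)
  expect_equal(f2$delta_R, 0)
  expect_equal(f2$choice_sign, -1L)

  # structural error names the offending game
  broken <- d[-2, ] # remove one instructed trial
  broken$trial_index <- c(1:3, 5L)
  expect_error(first_choice_features(broken), "game_id")
})

test_that("feature coding negates consistently when sides are relabelled", {
  cohort <- cached_cohort()
  dat <- cohort$data[cohort$data$participant_id ==
    cohort$data$participant_id[1], ]
  f <- first_choice_features(dat)
  flipped <- dat
  flipped$choice <- ifelse(dat$choice == "left", "right", "left")
  flipped[, c("gen_mean_left", "gen_mean_right")] <-
    dat[, c("gen_mean_right", "gen_mean_left")]
  ff <- first_choice_features(flipped)
  expect_equal(ff$delta_R, -f$delta_R)
  expect_equal(ff$delta_I, -f$delta_I)
  expect_equal(ff$choice_sign, -f$choice_sign)
  expect_equal(ff$correct, f$correct)
})

test_that("dataset round-trips through the canonical CSV schema", {
  d <- make_game_trials(
    left_rewards = 44, right_rewards = c(38, 50, 47),
    free_rt = 0.823
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_horizon_data(d, path)
  d2 <- read_horizon_data(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)

  # validation contract
  expect_error(
    read_horizon_data({
      p <- withr::local_tempfile(fileext = ".csv")
      readr::write_csv(d[, setdiff(names(d), "horizon")], p)
      p
    }),
    "horizon"
  )
  bad <- d
  bad$rt[5] <- -0.2
  expect_error(write_horizon_data(bad, path), "non-positive")
})

test_that("proportion correct is 1 for an oracle agent and 0.5 for a random one", {
  set.seed(11)
  n <- 1e4
  gm_left <- sample(c(40, 60), n, replace = TRUE)
  gm_right <- gm_left + sample(c(-1, 1) * c(4, 8, 12, 20), n, replace = TRUE)
  agent_data <- function(choice) {
    tibble::tibble(
      participant_id = "a1", age_group = "synthetic",
      game_id = seq_len(n), block = 1L,
      horizon = 1L, info_condition = "EQUAL_22",
      trial_index = 5L, is_instructed = FALSE,
      choice = choice, reward = 50, rt = 0.5,
      gen_mean_left = gm_left, gen_mean_right = gm_right
    )
  }
  d_oracle <- agent_data(ifelse(gm_left > gm_right, "left", "right"))
  pc <- proportion_correct(d_oracle)
  expect_true(all(pc$mean_correct == 1))

  d_rand <- agent_data(sample(c("left", "right"), n, replace = TRUE))
  pr <- proportion_correct(d_rand, level = "participant")
  expect_lt(abs(pr$prop_correct - 0.5), 3 * sqrt(0.25 / n))

  # empty free-trial input is an error, not NaN propagation
  expect_error(proportion_correct(d_oracle[0, ]), "free-choice")
})
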