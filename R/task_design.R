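#' Horizon Task configuration
#'
#' Design constants of the Horizon Task. One bandit's generative mean is 40
#' or 60 points; the other is offset by plus or minus 4, 8, 12 or 20 points.
#' Rewards are Gaussian with an 8-point standard deviation around the
#' generative mean, rounded to the nearest displayed integer. Optionally the
#' displayed reward can be clipped to a range (the original task's behaviour
#' here is undocumented; no clipping by default).
#'
#' @param base_means candidate generative means for the anchor bandit.
#' @param offsets absolute mean offsets of the second bandit (points).
#' @param reward_sd reward standard deviation (points).
#' @param n_practice,n_test default game counts.
#' @param block_size test games per block for block-wise analyses.
#' @param clip_range optional length-2 numeric range to clip displayed
#'   rewards, or `NULL` for no clipping.
#' @return A list of class `horizon_config`.
#' @export
horizon_config <- function(base_means = c(40, 60), offsets = c(4, 8, 12, 20),
                           reward_sd = 8, n_practice = 16, n_test = 128,
                           block_size = 32, clip_range = NULL) {
  stopifnot(reward_sd >= 0, all(offsets > 0), block_size >= 1)
  structure(
    list(
      base_means = base_means, offsets = offsets, reward_sd = reward_sd,
      n_practice = n_practice, n_test = n_test, block_size = block_size,
      clip_range = clip_range
    ),
    class = "horizon_config"
  )
}

info_levels <- c("UNEQUAL_13", "EQUAL_22")

# one forced sequence of 4 sides as a 4-character string, e.g. "LRRL"
make_forced_sequence <- function(info_condition) {
  sides <- if (info_condition == "UNEQUAL_13") {
    lone <- sample(c("L", "R"), 1)
    c(lone, rep(setdiff(c("L", "R"), lone), 3))
  } else {
    c("L", "L", "R", "R")
  }
  paste(sample(sides), collapse = "")
}

#' Generate a Horizon Task game schedule
#'
#' Builds the full schedule of practice and test games. Test games are
#' counterbalanced exactly across the horizon (1 vs 6) by information
#' (`UNEQUAL_13` vs `EQUAL_22`) cross; which bandit carries the 40/60 anchor
#' mean, the offset magnitude and the offset sign are balanced within each
#' cell and shuffled under the seed. Test games are partitioned into
#' consecutive blocks of `config$block_size`; practice games carry block 0.
#'
#' @param n_practice,n_test number of practice and test games; `n_test` must
#'   be divisible by 4 for the counterbalance.
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @param config a [horizon_config()].
#' @return A tibble with one row per game: `game_id`, `is_practice`, `block`,
#'   `horizon`, `info_condition`, `mean_left`, `mean_right`, `reward_sd`,
#'   `forced_sequence`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' table(sched$horizon[!sched$is_practice], sched$info_condition[!sched$is_practice])
#' @export
generate_schedule <- function(n_practice = 16, n_test = 128, seed = 1L,
                              config = horizon_config()) {
  if (n_test > 0 && n_test %% 4 != 0) {
    stop("`n_test` must be divisible by 4 to counterbalance horizon x information",
      call. = FALSE
    )
  }
  set.seed(seed)
  cells <- expand.grid(
    horizon = c(1L, 6L), info_condition = info_levels,
    stringsAsFactors = FALSE
  )
  design <- expand.grid(
    base_mean = config$base_means,
    offset = config$offsets,
    offset_sign = c(-1, 1),
    base_side = c("L", "R"),
    stringsAsFactors = FALSE
  )
  test_rows <- list()
  if (n_test > 0) {
    per_cell <- n_test / 4L
    for (i in seq_len(nrow(cells))) {
      idx <- rep(seq_len(nrow(design)), length.out = per_cell)
      d <- design[sample(idx), , drop = FALSE]
      other <- d$base_mean + d$offset_sign * d$offset
      test_rows[[i]] <- tibble::tibble(
        horizon = cells$horizon[i],
        info_condition = cells$info_condition[i],
        mean_left = ifelse(d$base_side == "L", d$base_mean, other),
        mean_right = ifelse(d$base_side == "L", other, d$base_mean)
      )
    }
  }
  test <- if (length(test_rows)) dplyr::bind_rows(test_rows) else NULL
  if (!is.null(test)) {
    test <- test[sample(nrow(test)), , drop = FALSE]
    test$is_practice <- FALSE
    test$block <- as.integer(ceiling(seq_len(nrow(test)) / config$block_size))
  }
  practice <- NULL
  if (n_practice > 0) {
    d <- design[sample(nrow(design), n_practice, replace = TRUE), , drop = FALSE]
    other <- d$base_mean + d$offset_sign * d$offset
    practice <- tibble::tibble(
      horizon = sample(c(1L, 6L), n_practice, replace = TRUE),
      info_condition = sample(info_levels, n_practice, replace = TRUE),
      mean_left = ifelse(d$base_side == "L", d$base_mean, other),
      mean_right = ifelse(d$base_side == "L", other, d$base_mean),
      is_practice = TRUE,
      block = 0L
    )
  }
  sched <- dplyr::bind_rows(practice, test)
  sched$game_id <- seq_len(nrow(sched))
  sched$reward_sd <- config$reward_sd
  sched$forced_sequence <- vapply(
    sched$info_condition, make_forced_sequence, character(1)
  )
  dplyr::select(
    sched, "game_id", "is_practice", "block", "horizon", "info_condition",
    "mean_left", "mean_right", "reward_sd", "forced_sequence"
  )
}

draw_reward <- function(mean, sd, clip_range = NULL) {
  r <- round(rnorm(length(mean), mean, sd))
  if (!is.null(clip_range)) r <- pmin(pmax(r, clip_range[1]), clip_range[2])
  r
}

#' Play the four instructed trials of one game
#'
#' Draws rewards for the forced sequence of a single game: Gaussian around
#' the side's generative mean with the game's reward SD, rounded to the
#' nearest integer point. Uses R's RNG (seed upstream for reproducibility).
#'
#' @param game one row of a [generate_schedule()] tibble (as a list or
#'   single-row data frame).
#' @param clip_range optional displayed-reward clipping range.
#' @return A tibble of 4 instructed trial records (`trial_index` 1-4,
#'   `is_instructed = TRUE`, `rt = NA`).
#' @export
play_instructed <- function(game, clip_range = NULL) {
  game <- as.list(game)
  sides <- strsplit(game$forced_sequence, "")[[1]]
  stopifnot(length(sides) == 4L, all(sides %in% c("L", "R")))
  means <- ifelse(sides == "L", game$mean_left, game$mean_right)
  tibble::tibble(
    game_id = game$game_id,
    block = game$block,
    horizon = game$horizon,
    info_condition = game$info_condition,
    trial_index = 1:4,
    is_instructed = TRUE,
    choice = ifelse(sides == "L", "left", "right"),
    reward = draw_reward(means, game$reward_sd, clip_range),
    rt = NA_real_,
    gen_mean_left = game$mean_left,
    gen_mean_right = game$mean_right
  )
}

#' First free-choice features
#'
#' Derives, per test game, the quantities every model consumes: `delta_R`
#' (mean observed instructed reward, left minus right), `delta_I` (+1 if the
#' left bandit is the once-played, more informative option, -1 if the right
#' is, 0 in the equal condition), the first free choice sign (`+1` left,
#' `-1` right), its response time, and whether the chosen side had the higher
#' generative mean. Practice games (block 0) are excluded.
#'
#' @param trials a trial-level dataset in the canonical schema (see
#'   [read_horizon_data()]).
#' @return A tibble with one row per participant x test game.
#' @export
first_choice_features <- function(trials) {
  validate_horizon_data(trials)
  trials <- dplyr::filter(trials, .data$block > 0L)
  grouped <- dplyr::group_by(trials, .data$participant_id, .data$game_id)
  bad <- dplyr::summarise(
    grouped,
    n_instructed = sum(.data$is_instructed),
    n_free = sum(!.data$is_instructed),
    .groups = "drop"
  )
  bad <- dplyr::filter(bad, .data$n_instructed != 4L | .data$n_free < 1L)
  if (nrow(bad) > 0) {
    stop(
      "games without 4 instructed trials and >= 1 free trial: game_id ",
      paste(unique(bad$game_id), collapse = ", "),
      call. = FALSE
    )
  }
  feats <- dplyr::summarise(
    grouped,
    age_group = .data$age_group[1],
    block = .data$block[1],
    horizon = .data$horizon[1],
    info_condition = .data$info_condition[1],
    delta_R = mean(.data$reward[.data$is_instructed & .data$choice == "left"]) -
      mean(.data$reward[.data$is_instructed & .data$choice == "right"]),
    delta_I = {
      n_left <- sum(.data$is_instructed & .data$choice == "left")
      if (.data$info_condition[1] == "EQUAL_22") 0L else if (n_left == 1L) 1L else -1L
    },
    choice_sign = {
      first_free <- which(!.data$is_instructed)[
        which.min(.data$trial_index[!.data$is_instructed])
      ]
      if (.data$choice[first_free] == "left") 1L else -1L
    },
    rt = {
      first_free <- which(!.data$is_instructed)[
        which.min(.data$trial_index[!.data$is_instructed])
      ]
      .data$rt[first_free]
    },
    correct = {
      first_free <- which(!.data$is_instructed)[
        which.min(.data$trial_index[!.data$is_instructed])
      ]
      chosen_mean <- ifelse(.data$choice[first_free] == "left",
        .data$gen_mean_left[1], .data$gen_mean_right[1]
      )
      other_mean <- ifelse(.data$choice[first_free] == "left",
        .data$gen_mean_right[1], .data$gen_mean_left[1]
      )
      chosen_mean > other_mean
    },
    .groups = "drop"
  )
  feats
}

canonical_columns <- c(
  "participant_id", "age_group", "game_id", "block", "horizon",
  "info_condition", "trial_index", "is_instructed", "choice", "reward",
  "rt", "gen_mean_left", "gen_mean_right"
)

#' Validate a trial-level dataset against the canonical schema
#'
#' Checks column presence, label domains, and the structural invariants:
#' `trial_index <= 4` exactly on instructed trials, positive response times
#' where present. Errors name the offending columns or rows.
#'
#' @param data a data frame of trial records.
#' @return The data, invisibly, if valid.
#' @export
validate_horizon_data <- function(data) {
  missing_cols <- setdiff(canonical_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(data$horizon %in% c(1L, 6L))) {
    stop("`horizon` must be 1 or 6; offending rows: ",
      paste(head(which(!data$horizon %in% c(1L, 6L)), 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(data$info_condition %in% info_levels)) {
    stop("unknown `info_condition` labels; offending rows: ",
      paste(head(which(!data$info_condition %in% info_levels), 5),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  if (!all(data$choice %in% c("left", "right"))) {
    stop("`choice` must be 'left' or 'right'; offending rows: ",
      paste(head(which(!data$choice %in% c("left", "right")), 5),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  mismatch <- (data$trial_index <= 4L) != data$is_instructed
  if (any(mismatch)) {
    stop("`is_instructed` must hold exactly when trial_index <= 4; rows: ",
      paste(head(which(mismatch), 5), collapse = ", "),
      call. = FALSE
    )
  }
  bad_rt <- !is.na(data$rt) & data$rt <= 0
  if (any(bad_rt)) {
    stop("non-positive `rt`; offending rows: ",
      paste(head(which(bad_rt), 5), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(data)
}

#' Read and write trial-level Horizon Task data
#'
#' The canonical on-disk format is UTF-8 CSV with a header row and the
#' columns `participant_id`, `age_group`, `game_id`, `block`, `horizon`,
#' `info_condition`, `trial_index`, `is_instructed`, `choice`, `reward`,
#' `rt`, `gen_mean_left`, `gen_mean_right`. Response times are stored in
#' seconds at millisecond precision, so write-then-read round-trips exactly.
#'
#' Data deposited elsewhere (e.g. the study's OSF repository) must first be
#' mapped onto this schema; see `vignette("horizon-ddm")` for the expected
#' column mapping.
#'
#' @param path file path.
#' @param data a validated trial-level dataset.
#' @return `read_horizon_data()` returns a validated tibble;
#'   `write_horizon_data()` returns `path` invisibly.
#' @export
read_horizon_data <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(canonical_columns, hdr)
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(hdr, canonical_columns)
  if (length(extra) > 0) {
    stop("unexpected columns: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      age_group = readr::col_character(),
      game_id = readr::col_integer(),
      block = readr::col_integer(),
      horizon = readr::col_integer(),
      info_condition = readr::col_character(),
      trial_index = readr::col_integer(),
      is_instructed = readr::col_logical(),
      choice = readr::col_character(),
      reward = readr::col_double(),
      rt = readr::col_double(),
      gen_mean_left = readr::col_double(),
      gen_mean_right = readr::col_double()
    )
  )
  validate_horizon_data(data)
  data
}

#' @rdname read_horizon_data
#' @export
write_horizon_data <- function(data, path) {
  validate_horizon_data(data)
  out <- data[, canonical_columns]
  out$rt <- round(out$rt, 3) # millisecond precision
  out$participant_id <- as.character(out$participant_id)
  readr::write_csv(out, path)
  invisible(path)
}

#' Proportion of objectively correct free choices
#'
#' The proportion of free-choice trials on which the bandit with the higher
#' generative mean was chosen (chance level 50%). Computed per participant x
#' horizon x trial index, then optionally summarised across participants with
#' means and standard errors.
#'
#' @param data trial-level dataset in the canonical schema.
#' @param level `"group"` for across-participant means and s.e.m., or
#'   `"participant"` for per-participant proportions.
#' @return A tibble of proportions; empty groups are absent rather than NaN.
#' @export
proportion_correct <- function(data, level = c("group", "participant")) {
  level <- match.arg(level)
  validate_horizon_data(data)
  free <- dplyr::filter(data, !.data$is_instructed, .data$block > 0L)
  if (nrow(free) == 0) stop("no free-choice trials present", call. = FALSE)
  free$correct <- ifelse(free$choice == "left",
    free$gen_mean_left > free$gen_mean_right,
    free$gen_mean_right > free$gen_mean_left
  )
  per_part <- dplyr::summarise(
    dplyr::group_by(
      free, .data$participant_id, .data$age_group, .data$horizon,
      .data$trial_index
    ),
    prop_correct = mean(.data$correct),
    n_games = dplyr::n(),
    .groups = "drop"
  )
  if (level == "participant") {
    return(per_part)
  }
  dplyr::summarise(
    dplyr::group_by(
      per_part, .data$age_group, .data$horizon, .data$trial_index
    ),
    mean_correct = mean(.data$prop_correct),
    se = stats::sd(.data$prop_correct) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
}
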