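#' Logistic bias-noise-bonus choice model
#'
#' Probability of choosing the left bandit on the first free choice:
#' `p(left) = logistic((delta_R + A * delta_I + b) / (2 * sigma))`, where `A`
#' is the information bonus (points), `b` the spatial bias towards the left
#' bandit (points) and `sigma` the decision noise (points). The noise is
#' condition-specific: `noise_unequal` applies on `[1 3]` trials
#' (`delta_I != 0`), `noise_equal` on `[2 2]` trials (`delta_I == 0`).
#'
#' @param info_bonus information bonus A (points).
#' @param spatial_bias spatial bias b towards the left bandit (points).
#' @param noise_unequal,noise_equal decision noise sigma (points), > 0.
#' @param horizon optional horizon label carried along with the parameters.
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(info_bonus, spatial_bias, noise_unequal,
                            noise_equal, horizon = NA_integer_) {
  if (noise_unequal <= 0 || noise_equal <= 0) {
    stop("decision noise must be > 0", call. = FALSE)
  }
  structure(
    list(
      info_bonus = info_bonus, spatial_bias = spatial_bias,
      noise_unequal = noise_unequal, noise_equal = noise_equal,
      horizon = horizon
    ),
    class = "logistic_params"
  )
}

#' @param delta_R observed mean reward difference, left minus right (points).
#' @param delta_I information difference in {-1, 0, +1}.
#' @param params a [logistic_params()] object.
#' @return `choice_probability()` returns the probability of choosing left,
#'   strictly increasing in `delta_R` and tending to 0.5 as sigma grows.
#' @rdname logistic_params
#' @examples
#' p <- logistic_params(info_bonus = 3, spatial_bias = 0, 8, 6)
#' choice_probability(delta_R = -3, delta_I = 1, p) # bonus offsets the deficit
#' @export
choice_probability <- function(delta_R, delta_I, params) {
  stopifnot(inherits(params, "logistic_params"))
  if (!all(delta_I %in% c(-1L, 0L, 1L))) {
    stop("`delta_I` must be -1, 0 or +1", call. = FALSE)
  }
  sigma <- ifelse(delta_I == 0, params$noise_equal, params$noise_unequal)
  plogis((delta_R + params$info_bonus * delta_I + params$spatial_bias) /
    (2 * sigma))
}

logistic_nll <- function(par, dR, dI, y) {
  # par = (A, b, sigma_unequal, sigma_equal)
  sigma <- ifelse(dI == 0, par[4], par[3])
  eta <- (dR + par[1] * dI + par[2]) / (2 * sigma)
  ll <- ifelse(y > 0, plogis(eta, log.p = TRUE), plogis(-eta, log.p = TRUE))
  -sum(pmax(ll, -50))
}

#' Fit the logistic choice model to one participant and horizon
#'
#' Maximum-likelihood fit of the bias-noise-bonus model to first free
#' choices, with the information bonus `A` and spatial bias `b` shared across
#' information conditions and a separate decision noise for the unequal and
#' equal conditions. Bounded quasi-Newton optimisation with dispersed
#' restarts; estimates landing on a bound (e.g. under complete separation)
#' are flagged, not an error.
#'
#' @param obs a [first_choice_features()] tibble (one participant).
#' @param horizon which horizon condition to fit (1 or 6).
#' @param restarts number of dispersed optimizer starts.
#' @param bounds named list of parameter bounds.
#' @return A list of class `logistic_fit` with elements `params`
#'   ([logistic_params()]), `nll`, `n_obs`, `converged`, `at_bound`.
#' @export
fit_logistic <- function(obs, horizon,
                         restarts = 5,
                         bounds = list(
                           info_bonus = c(-40, 40), spatial_bias = c(-40, 40),
                           noise = c(0.1, 100)
                         )) {
  obs <- dplyr::filter(obs, .data$horizon == !!horizon)
  if (length(unique(obs$delta_I == 0)) < 2L) {
    stop("both information conditions must be present for the horizon",
      call. = FALSE
    )
  }
  y <- obs$choice_sign
  lower <- c(bounds$info_bonus[1], bounds$spatial_bias[1],
             bounds$noise[1], bounds$noise[1])
  upper <- c(bounds$info_bonus[2], bounds$spatial_bias[2],
             bounds$noise[2], bounds$noise[2])
  pts <- halton(restarts, 4)
  starts <- rbind(
    c(0, 0, 8, 8),
    sweep(sweep(pts, 2, c(20, 20, 30, 30), "*"), 2,
      c(-10, -10, 0.5, 0.5), "+"
    )
  )
  starts[, 3:4] <- pmax(starts[, 3:4], lower[3])
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(starts[i, ], logistic_nll,
        dR = obs$delta_R, dI = obs$delta_I, y = y,
        lower = lower, upper = upper,
        control = list(iter.max = 500, eval.max = 1000)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("all optimizer restarts failed", call. = FALSE)
  p <- best$par
  tol_b <- 1e-4
  at_bound <- (abs(p - lower) < tol_b) | (abs(p - upper) < tol_b)
  names(at_bound) <- c("info_bonus", "spatial_bias", "noise_unequal",
                       "noise_equal")
  structure(
    list(
      params = logistic_params(p[1], p[2], p[3], p[4], horizon = horizon),
      nll = best$objective,
      n_obs = nrow(obs),
      converged = conv,
      at_bound = at_bound
    ),
    class = "logistic_fit"
  )
}

#' Response-time regression on the first free choice
#'
#' Ordinary least squares of response time on `alpha * delta_R` and
#' `alpha * delta_I` with an intercept, where `alpha` is the choice sign (+1
#' left, -1 right): `RT = b0 + bR * alpha * delta_R + bI * alpha * delta_I`.
#' `b0` is the baseline response time, `bR` the modulation of RT by (signed)
#' reward difference and `bI` the modulation by information.
#'
#' @param obs a [first_choice_features()] tibble (one participant).
#' @param horizon which horizon condition to fit.
#' @return A list of class `rt_regression` with `baseline`, `reward_slope`,
#'   `info_slope`, `horizon`, and the underlying `lm` fit.
#' @export
fit_rt_regression <- function(obs, horizon) {
  obs <- dplyr::filter(obs, .data$horizon == !!horizon, !is.na(.data$rt))
  if (nrow(obs) < 3) {
    stop("need at least 3 observations with response times", call. = FALSE)
  }
  x_r <- obs$choice_sign * obs$delta_R
  x_i <- obs$choice_sign * obs$delta_I
  X <- cbind(1, x_r, x_i)
  qrX <- qr(X)
  if (qrX$rank < 3) {
    cols <- c("(intercept)", "alpha*delta_R", "alpha*delta_I")
    dropped <- cols[setdiff(seq_len(3), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear column(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  fit <- lm(rt ~ x_r + x_i, data = data.frame(rt = obs$rt, x_r = x_r, x_i = x_i))
  cf <- coef(fit)
  structure(
    list(
      baseline = unname(cf[1]), reward_slope = unname(cf[2]),
      info_slope = unname(cf[3]), horizon = horizon, model = fit
    ),
    class = "rt_regression"
  )
}
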