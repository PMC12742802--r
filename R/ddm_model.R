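ddm_coef_names <- c(
  "drift_base", "drift_reward", "drift_info",
  "bias_base", "bias_reward", "bias_info",
  "threshold", "nondecision"
)

#' DDM linking coefficients for one horizon condition
#'
#' The 7 linking coefficients plus non-decision time that tie the task
#' variables to the diffusion parameters of a first free choice: drift is
#' linear in the reward difference and information difference
#' (`drift_base + drift_reward * delta_R + drift_info * delta_I`; the reward
#' and information drift coefficients are the "SNR reward" and "SNR
#' information", since diffusion noise is fixed at 1), the starting bias is a
#' logistic link of the same variables mapped into (-1, 1), and the threshold
#' is constant within a horizon.
#'
#' @param drift_base,drift_reward,drift_info drift linking coefficients
#'   (evidence/s; `drift_reward` per point).
#' @param bias_base,bias_reward,bias_info starting-bias linking coefficients
#'   (logistic link scale).
#' @param threshold boundary half-separation, > 0 (evidence units).
#' @param nondecision non-decision time T0 (seconds), >= 0.
#' @param horizon horizon condition label (1 or 6).
#' @return An object of class `ddm_coefficients`.
#' @export
ddm_coefficients <- function(drift_base = 0, drift_reward = 0.1,
                             drift_info = 0, bias_base = 0, bias_reward = 0,
                             bias_info = 0, threshold = 1.5,
                             nondecision = 0.3, horizon = NA_integer_) {
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (nondecision < 0) stop("`nondecision` must be >= 0", call. = FALSE)
  structure(
    list(
      drift_base = drift_base, drift_reward = drift_reward,
      drift_info = drift_info, bias_base = bias_base,
      bias_reward = bias_reward, bias_info = bias_info,
      threshold = threshold, nondecision = nondecision, horizon = horizon
    ),
    class = "ddm_coefficients"
  )
}

as_par_vector <- function(coeffs) {
  vapply(ddm_coef_names, function(nm) coeffs[[nm]], numeric(1))
}

par_to_coeffs <- function(par, horizon = NA_integer_) {
  args <- as.list(setNames(par, ddm_coef_names))
  args$horizon <- horizon
  do.call(ddm_coefficients, args)
}

#' @export
print.ddm_coefficients <- function(x, ...) {
  cat(sprintf("DDM coefficients (horizon %s):\n", x$horizon))
  v <- as_par_vector(x)
  cat(paste(sprintf("  %-12s %8.4f", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Map task variables to Wiener parameters
#'
#' Applies the linking function for one first free choice: drift linear in
#' `(delta_R, delta_I)`, starting bias `2 * logistic(linear term) - 1`
#' (bounded in (-1, 1)), constant threshold, unit diffusion noise.
#'
#' @param coeffs a [ddm_coefficients()] object.
#' @param delta_R observed mean reward difference (left - right, points).
#' @param delta_I information difference in {-1, 0, +1}.
#' @return A [wiener_params()] object (scalar inputs only).
#' @examples
#' ddm_link(ddm_coefficients(drift_reward = 0.1), delta_R = 10, delta_I = 0)
#' @export
ddm_link <- function(coeffs, delta_R, delta_I) {
  stopifnot(inherits(coeffs, "ddm_coefficients"),
    length(delta_R) == 1L, length(delta_I) == 1L
  )
  if (!delta_I %in% c(-1L, 0L, 1L)) {
    stop("`delta_I` must be -1, 0 or +1", call. = FALSE)
  }
  drift <- coeffs$drift_base + coeffs$drift_reward * delta_R +
    coeffs$drift_info * delta_I
  bias <- 2 * plogis(coeffs$bias_base + coeffs$bias_reward * delta_R +
    coeffs$bias_info * delta_I) - 1
  # the logistic saturates to +/-1 in floating point; keep the open interval
  bias <- min(max(bias, -1 + 1e-9), 1 - 1e-9)
  wiener_params(
    drift = drift, threshold = coeffs$threshold, start_bias = bias,
    nondecision = coeffs$nondecision
  )
}

#' Joint choice and response-time negative log-likelihood
#'
#' Negative sum of log first-passage-time densities of the observed (choice,
#' RT) pairs under the linked DDM: the upper-boundary density for left
#' choices (`choice_sign = +1`), lower for right. Observations with
#' `rt <= nondecision` (where the density is zero) contribute a finite
#' penalty through a per-observation log-density floor rather than `-Inf`,
#' keeping the objective optimizable.
#'
#' @param coeffs a [ddm_coefficients()] object.
#' @param obs a [first_choice_features()] tibble, all rows sharing the
#'   horizon of `coeffs`.
#' @param tol density truncation error bound.
#' @param log_floor per-observation log-density floor.
#' @return The negative log-likelihood (scalar).
#' @export
ddm_nll <- function(coeffs, obs, tol = 1e-7, log_floor = -50) {
  stopifnot(inherits(coeffs, "ddm_coefficients"))
  if (nrow(obs) == 0) stop("`obs` is empty", call. = FALSE)
  ddm_nll_cpp(
    obs$rt, as.integer(obs$choice_sign), obs$delta_R,
    as.numeric(obs$delta_I), as_par_vector(coeffs), tol, log_floor
  )
}

#' Model specification: baseline and yoked variants
#'
#' The baseline model fits all 8 parameters separately per horizon (16 free
#' parameters). Yoked variants share ("yoke") the threshold, the reward drift
#' coefficient (SNR reward), or both across the two horizon conditions,
#' reducing the free-parameter count to 15, 15 and 14.
#'
#' @param name one of `"baseline"`, `"yoke_threshold"`, `"yoke_snr_reward"`,
#'   `"yoke_both"`.
#' @return A list of class `ddm_model_spec` with the shared coefficient set
#'   and free-parameter count.
#' @export
model_spec <- function(name = c("baseline", "yoke_threshold",
                                "yoke_snr_reward", "yoke_both")) {
  name <- match.arg(name)
  shared <- switch(name,
    baseline = character(0),
    yoke_threshold = "threshold",
    yoke_snr_reward = "drift_reward",
    yoke_both = c("threshold", "drift_reward")
  )
  structure(
    list(name = name, shared = shared, n_par = 16L - length(shared)),
    class = "ddm_model_spec"
  )
}

#' Options for DDM maximum-likelihood fitting
#'
#' @param restarts number of dispersed (low-discrepancy) optimizer starts.
#' @param min_obs minimum first-free-choice observations per horizon.
#' @param seed integer recorded with the fit (start points are
#'   deterministic, so fits are reproducible by construction).
#' @param tol density truncation error bound.
#' @param log_floor per-observation log-density floor.
#' @param maxit optimizer iteration cap.
#' @param t0_upper_frac T0 upper bound as a fraction of the smallest RT.
#' @param fold_maxit,fold_reltol iteration cap and relative tolerance for
#'   warm-started leave-one-out fold refits (see [loo_compare()]); folds
#'   start at the full-data optimum, so few iterations are needed.
#' @return A list of class `ddm_fit_options`.
#' @export
ddm_fit_options <- function(restarts = 10, min_obs = 20, seed = 1L,
                            tol = 1e-7, log_floor = -50, maxit = 400,
                            t0_upper_frac = 0.95, fold_maxit = 150,
                            fold_reltol = 1e-8) {
  structure(
    list(
      restarts = restarts, min_obs = min_obs, seed = seed, tol = tol,
      log_floor = log_floor, maxit = maxit, t0_upper_frac = t0_upper_frac,
      fold_maxit = fold_maxit, fold_reltol = fold_reltol
    ),
    class = "ddm_fit_options"
  )
}

# optimizer control for full fits vs warm-started fold refits
nlminb_control <- function(options, warm) {
  if (warm) {
    list(
      iter.max = options$fold_maxit, eval.max = 10 * options$fold_maxit,
      rel.tol = options$fold_reltol
    )
  } else {
    list(iter.max = options$maxit, eval.max = 4 * options$maxit)
  }
}

# parameter bounds for one horizon's 8-vector; T0 upper depends on the data
ddm_bounds <- function(min_rt, options) {
  list(
    lower = c(-10, -1, -10, -5, -5, -5, 0.05, 0),
    upper = c(10, 1, 10, 5, 5, 5, 10, options$t0_upper_frac * min_rt)
  )
}

# dispersed start points within bounds (deterministic)
ddm_starts <- function(n, bounds) {
  d <- length(bounds$lower)
  width <- bounds$upper - bounds$lower
  pts <- halton(n, d)
  starts <- sweep(
    sweep(pts * 0.9 + 0.05, 2, width, "*"), 2, bounds$lower, "+"
  )
  center <- c(0, 0.05, 0.1, 0, 0, 0, 1.5, 0.5 * bounds$upper[8])
  center <- pmin(pmax(center, bounds$lower + 0.01 * width),
                 bounds$upper - 0.01 * width)
  rbind(center, starts)
}

fit_one_horizon <- function(obs_h, options, warm_start = NULL,
                            min_rt = NULL) {
  # min_rt: participant-level smallest RT; leave-one-out fold refits pass the
  # full-data value so the T0 bound cannot cross the held-out response time
  bounds <- ddm_bounds(if (is.null(min_rt)) min(obs_h$rt) else min_rt, options)
  obj <- function(p) {
    ddm_nll_cpp(
      obs_h$rt, as.integer(obs_h$choice_sign), obs_h$delta_R,
      as.numeric(obs_h$delta_I), p, options$tol, options$log_floor
    )
  }
  grad <- function(p) {
    ddm_nll_grad_cpp(
      obs_h$rt, as.integer(obs_h$choice_sign), obs_h$delta_R,
      as.numeric(obs_h$delta_I), p, options$tol, options$log_floor
    )
  }
  warm <- !is.null(warm_start)
  starts <- if (warm) {
    matrix(pmin(pmax(warm_start, bounds$lower), bounds$upper), nrow = 1)
  } else {
    ddm_starts(options$restarts, bounds)
  }
  ctrl <- nlminb_control(options, warm)
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(starts[i, ], obj,
        gradient = grad,
        lower = bounds$lower, upper = bounds$upper, control = ctrl
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
    # a warm-started refit that returns a finite objective is usable even if
    # it stops at the iteration cap
    if (fit$convergence == 0 || (warm && is.finite(fit$objective))) conv <- TRUE
  }
  if (is.null(best)) {
    return(list(par = rep(NA_real_, 8), nll = NA_real_, converged = FALSE,
                n_restarts_used = nrow(starts)))
  }
  list(par = best$par, nll = best$objective, converged = conv,
       n_restarts_used = nrow(starts))
}

# joint fit of both horizons with `shared` coefficients yoked to horizon 1
fit_joint <- function(obs1, obs6, shared, options, warm_start = NULL,
                      min_rt1 = NULL, min_rt6 = NULL) {
  free6 <- setdiff(ddm_coef_names, shared)
  idx6 <- match(free6, ddm_coef_names)
  b1 <- ddm_bounds(if (is.null(min_rt1)) min(obs1$rt) else min_rt1, options)
  b6 <- ddm_bounds(if (is.null(min_rt6)) min(obs6$rt) else min_rt6, options)
  lower <- c(b1$lower, b6$lower[idx6])
  upper <- c(b1$upper, b6$upper[idx6])
  expand <- function(theta) {
    p1 <- theta[1:8]
    p6 <- p1
    p6[idx6] <- theta[8 + seq_along(idx6)]
    list(p1 = p1, p6 = p6)
  }
  obj <- function(theta) {
    p <- expand(theta)
    ddm_nll_cpp(
      obs1$rt, as.integer(obs1$choice_sign), obs1$delta_R,
      as.numeric(obs1$delta_I), p$p1, options$tol, options$log_floor
    ) +
      ddm_nll_cpp(
        obs6$rt, as.integer(obs6$choice_sign), obs6$delta_R,
        as.numeric(obs6$delta_I), p$p6, options$tol, options$log_floor
      )
  }
  shared_idx <- match(shared, ddm_coef_names)
  grad <- function(theta) {
    p <- expand(theta)
    g1 <- ddm_nll_grad_cpp(
      obs1$rt, as.integer(obs1$choice_sign), obs1$delta_R,
      as.numeric(obs1$delta_I), p$p1, options$tol, options$log_floor
    )
    g6 <- ddm_nll_grad_cpp(
      obs6$rt, as.integer(obs6$choice_sign), obs6$delta_R,
      as.numeric(obs6$delta_I), p$p6, options$tol, options$log_floor
    )
    g <- g1
    g[shared_idx] <- g[shared_idx] + g6[shared_idx]
    c(g, g6[idx6])
  }
  warm <- !is.null(warm_start)
  starts <- if (warm) {
    matrix(pmin(pmax(warm_start, lower), upper), nrow = 1)
  } else {
    s1 <- ddm_starts(options$restarts, b1)
    cbind(s1, s1[, idx6, drop = FALSE])
  }
  ctrl <- nlminb_control(options, warm)
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(starts[i, ], obj,
        gradient = grad,
        lower = lower, upper = upper, control = ctrl
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (fit$convergence == 0 || (warm && is.finite(fit$objective))) conv <- TRUE
  }
  if (is.null(best)) {
    return(list(theta = rep(NA_real_, length(lower)), nll = NA_real_,
                converged = FALSE, n_restarts_used = nrow(starts),
                expand = expand))
  }
  list(theta = best$par, nll = best$objective, converged = conv,
       n_restarts_used = nrow(starts), expand = expand)
}

#' Fit the linked DDM to one participant
#'
#' Bounded multi-start maximum-likelihood fit of the choice + response-time
#' likelihood. Under the baseline specification each horizon present in the
#' data is fitted independently (8 parameters per horizon); yoked
#' specifications require both horizons and fit them jointly with the yoked
#' coefficients shared. Deterministic given the data and options.
#'
#' @param obs a [first_choice_features()] tibble for one participant (one or
#'   both horizons for the baseline model; both for yoked variants).
#' @param spec a [model_spec()].
#' @param options a [ddm_fit_options()].
#' @return An object of class `ddm_fit`: per-horizon [ddm_coefficients()],
#'   total and per-horizon negative log-likelihood, observation counts,
#'   convergence flag, restarts used and the recorded seed.
#' @export
fit_ddm <- function(obs, spec = model_spec("baseline"),
                    options = ddm_fit_options()) {
  stopifnot(inherits(spec, "ddm_model_spec"),
            inherits(options, "ddm_fit_options"))
  obs <- dplyr::filter(obs, !is.na(.data$rt))
  horizons <- sort(unique(obs$horizon))
  counts <- table(obs$horizon)
  if (any(counts < options$min_obs)) {
    stop(sprintf(
      "need >= %d first-free-choice observations per horizon (got: %s)",
      options$min_obs,
      paste(sprintf("h%s=%d", names(counts), as.integer(counts)),
        collapse = ", "
      )
    ), call. = FALSE)
  }
  if (spec$name != "baseline" && !all(c(1L, 6L) %in% horizons)) {
    stop("yoked specifications require both horizon conditions", call. = FALSE)
  }

  coefficients <- list()
  nll_by_horizon <- numeric(0)
  converged <- TRUE
  restarts_used <- 0L

  if (spec$name == "baseline") {
    for (h in horizons) {
      obs_h <- obs[obs$horizon == h, ]
      fh <- fit_one_horizon(obs_h, options)
      coefficients[[as.character(h)]] <- par_to_coeffs(fh$par, horizon = h)
      nll_by_horizon[as.character(h)] <- fh$nll
      converged <- converged && fh$converged
      restarts_used <- restarts_used + fh$n_restarts_used
    }
  } else {
    obs1 <- obs[obs$horizon == 1L, ]
    obs6 <- obs[obs$horizon == 6L, ]
    fj <- fit_joint(obs1, obs6, spec$shared, options)
    p <- fj$expand(fj$theta)
    coefficients[["1"]] <- par_to_coeffs(p$p1, horizon = 1L)
    coefficients[["6"]] <- par_to_coeffs(p$p6, horizon = 6L)
    nll1 <- ddm_nll_cpp(
      obs1$rt, as.integer(obs1$choice_sign), obs1$delta_R,
      as.numeric(obs1$delta_I), p$p1, options$tol, options$log_floor
    )
    nll_by_horizon <- c("1" = nll1, "6" = fj$nll - nll1)
    converged <- fj$converged
    restarts_used <- fj$n_restarts_used
  }

  structure(
    list(
      spec = spec,
      coefficients = coefficients,
      nll = sum(nll_by_horizon),
      nll_by_horizon = nll_by_horizon,
      n_obs = nrow(obs),
      converged = converged,
      n_restarts_used = restarts_used,
      seed = options$seed,
      options = options
    ),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "DDM fit (%s): nll = %.3f over %d observations; converged: %s\n",
    x$spec$name, x$nll, x$n_obs, x$converged
  ))
  for (h in names(x$coefficients)) print(x$coefficients[[h]])
  invisible(x)
}

#' Softmax-equivalent decision noise implied by the DDM
#'
#' Under the zero-bias DDM choice rule the probability of choosing left is
#' `logistic(2 * threshold * drift)`, so with drift `drift_reward * delta_R`
#' the implied decision noise of the logistic choice model (which divides by
#' `2 * sigma`) is `sigma_DDM = 1 / (4 * threshold * drift_reward)` points.
#' Participants with non-positive reward drift have no meaningful noise
#' equivalent and return `NA` (the exclusion signal used by
#' [noise_correlation()]).
#'
#' @param coeffs a [ddm_coefficients()] object.
#' @return `sigma_DDM` in points, or `NA_real_` if `drift_reward <= 0`.
#' @export
ddm_noise <- function(coeffs) {
  stopifnot(inherits(coeffs, "ddm_coefficients"))
  if (is.na(coeffs$drift_reward) || coeffs$drift_reward <= 0) {
    return(NA_real_)
  }
  1 / (4 * coeffs$threshold * coeffs$drift_reward)
}

#' Decision-threshold counterfactual for softmax noise
#'
#' Percent change in the softmax-equivalent decision noise when the
#' threshold in [ddm_noise()] is replaced (e.g. replacing the older-adult
#' group-average threshold with the younger-adult average):
#' `100 * (sigma_DDM(replacement) / sigma_DDM(original) - 1)`. A lower
#' replacement threshold yields a positive percent change - more decision
#' noise, hence a likely drop in accuracy.
#'
#' @param coeffs group-average [ddm_coefficients()] (original threshold).
#' @param replacement_threshold the counterfactual threshold, > 0.
#' @return Percent change in decision noise (scalar).
#' @export
temperature_counterfactual <- function(coeffs, replacement_threshold) {
  stopifnot(inherits(coeffs, "ddm_coefficients"))
  if (replacement_threshold <= 0) {
    stop("`replacement_threshold` must be > 0", call. = FALSE)
  }
  if (is.na(coeffs$drift_reward) || coeffs$drift_reward <= 0) {
    stop("`drift_reward` must be > 0 for the noise mapping", call. = FALSE)
  }
  100 * (coeffs$threshold / replacement_threshold - 1)
}
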