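#' Wiener process parameters
#'
#' Parameters of the two-boundary Wiener diffusion used to model a single
#' first free choice: evidence `X(t)` starts at `X0 = start_bias * threshold`,
#' drifts at rate `drift` with unit diffusion noise, and a response is made
#' when it first crosses `+threshold` (upper boundary, left choice) or
#' `-threshold` (lower boundary, right choice). The observed response time is
#' the first-passage time plus the non-decision time.
#'
#' The diffusion coefficient is fixed at 1: one of drift, threshold and noise
#' is redundant, so the noise scale is the conventional parameter to pin down.
#'
#' @param drift drift rate (evidence units per second); positive favours the
#'   upper boundary.
#' @param threshold boundary half-separation (evidence units), must be > 0.
#' @param start_bias relative starting point in (-1, 1); 0 starts midway.
#' @param nondecision non-decision time T0 in seconds, >= 0.
#' @return An object of class `wiener_params`.
#' @examples
#' wiener_params(drift = 1, threshold = 1)
#' @export
wiener_params <- function(drift, threshold, start_bias = 0, nondecision = 0) {
  stopifnot(is.numeric(drift), length(drift) == 1L, is.finite(drift))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  if (abs(start_bias) >= 1) {
    stop("`start_bias` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (nondecision < 0) {
    stop("`nondecision` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      drift = drift, threshold = threshold,
      start_bias = start_bias, nondecision = nondecision,
      noise_scale = 1
    ),
    class = "wiener_params"
  )
}

#' @export
print.wiener_params <- function(x, ...) {
  cat(sprintf(
    "Wiener process: drift = %.4g, threshold = %.4g, start_bias = %.4g, T0 = %.4g s\n",
    x$drift, x$threshold, x$start_bias, x$nondecision
  ))
  invisible(x)
}

#' First-passage-time density of the two-boundary Wiener process
#'
#' Defective density of the first passage through the named boundary at time
#' `t` (seconds, including non-decision time). Computed with small-time and
#' large-time series expansions, switching by a per-evaluation error-bound
#' criterion so the truncation error is below `tol`. Returns 0 for
#' `t <= nondecision`.
#'
#' @param t vector of response times in seconds.
#' @param params a [wiener_params()] object.
#' @param boundary `"upper"` (left choice) or `"lower"` (right choice).
#' @param tol truncation error bound per evaluation.
#' @return Vector of defective densities (1/seconds); integrating the upper
#'   and lower densities over all t sums to 1.
#' @examples
#' p <- wiener_params(drift = 1, threshold = 1)
#' wfpt_density(c(0.5, 1, 2), p, "upper")
#' @export
wfpt_density <- function(t, params, boundary = c("upper", "lower"),
                         tol = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "wiener_params"), tol > 0)
  wfpt_density_cpp(
    as.numeric(t), params$drift, params$threshold, params$start_bias,
    params$nondecision, boundary == "upper", tol
  )
}

#' Absorption probability at a boundary
#'
#' Analytic probability that the diffusion is absorbed at the named boundary.
#' For drift near zero the linear limit `(threshold + X0) / (2 threshold)` is
#' used for the upper boundary.
#'
#' @inheritParams wfpt_density
#' @return Probability in (0, 1).
#' @examples
#' hit_probability(wiener_params(0, 1), "upper") # 0.5 by symmetry
#' @export
hit_probability <- function(params, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "wiener_params"))
  v <- params$drift
  a <- 2 * params$threshold
  z <- params$threshold * (1 + params$start_bias) # start above lower boundary
  p_upper <- if (abs(v * a) < 1e-10) {
    z / a
  } else if (-2 * v * a > 500) {
    # both expm1 terms overflow; ratio reduces to exp(2 v (a - z))
    exp(2 * v * (a - z))
  } else {
    expm1(-2 * v * z) / expm1(-2 * v * a)
  }
  if (boundary == "upper") p_upper else 1 - p_upper
}

#' Mean decision time of the two-boundary Wiener process
#'
#' Closed-form expected first-passage (decision) time, excluding the
#' non-decision time, optionally conditioned on the absorbing boundary. For
#' zero start bias and `conditioning = "all"` this is
#' `(threshold / drift) * tanh(drift * threshold)`, with the diffusion limit
#' `threshold^2` as drift goes to 0.
#'
#' @inheritParams wfpt_density
#' @param conditioning `"all"`, `"upper"` or `"lower"`.
#' @return Expected decision time in seconds.
#' @examples
#' mean_decision_time(wiener_params(1, 1)) # tanh(1)
#' @export
mean_decision_time <- function(params,
                               conditioning = c("all", "upper", "lower")) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(params, "wiener_params"))
  v <- params$drift
  a <- 2 * params$threshold
  z <- params$threshold * (1 + params$start_bias)
  small <- abs(v) * a < 1e-6
  # E[T | hit upper] = (a coth(va) - z coth(vz)) / v ; lower by reflection
  cond_upper <- function(v, a, z) {
    if (abs(v) * a < 1e-6) {
      (a^2 - z^2) / 3
    } else {
      (a / tanh(v * a) - z / tanh(v * z)) / v
    }
  }
  switch(conditioning,
    all = {
      if (small) {
        z * (a - z)
      } else {
        pa <- hit_probability(params, "upper")
        (a * pa - z) / v
      }
    },
    upper = cond_upper(v, a, z),
    lower = cond_upper(-v, a, a - z)
  )
}

#' Simulate first passages of the Wiener process
#'
#' Euler-Maruyama simulation of [wiener_params()] diffusion paths until a
#' boundary is crossed. Returned times include the non-decision time. Paths
#' that have not crossed after `max_t` seconds are censored: they are dropped
#' from the result with a warning, and the number dropped is recorded in the
#' `n_censored` attribute. Uses R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @inheritParams wfpt_density
#' @param n number of paths.
#' @param dt Euler time step in seconds.
#' @param max_t maximum simulated duration per path (seconds).
#' @return A tibble with columns `boundary` (`"upper"`/`"lower"`) and `time`
#'   (seconds), with attribute `n_censored`.
#' @examples
#' set.seed(1)
#' sim <- simulate_wiener(wiener_params(1, 1), n = 100)
#' mean(sim$boundary == "upper")
#' @export
simulate_wiener <- function(params, n, dt = 1e-3, max_t = 20) {
  stopifnot(inherits(params, "wiener_params"), n >= 1, dt > 0, max_t > 0)
  raw <- wiener_sim_cpp(
    as.integer(n), params$drift, params$threshold, params$start_bias,
    params$nondecision, dt, max_t
  )
  n_cens <- sum(raw$censored)
  if (n_cens > 0) {
    warning(sprintf(
      "%d of %d paths censored at max_t = %g s and excluded", n_cens, n, max_t
    ), call. = FALSE)
  }
  keep <- !raw$censored
  out <- tibble::tibble(
    boundary = ifelse(raw$boundary[keep] > 0, "upper", "lower"),
    time = raw$time[keep]
  )
  attr(out, "n_censored") <- n_cens
  out
}
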