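#' Fit the identification psychometric function
#'
#' Maximum-likelihood fit of the two-parameter logistic
#' \deqn{P(\mathrm{HEAD} \mid step) = \frac{1}{1 + e^{(step - x_0)/s}}}
#' to one participant's trial-level identification responses. The function
#' decreases toward the "had" end of the continuum: \eqn{x_0} is the
#' categorical boundary (50% point, in continuum steps) and \eqn{s} the
#' logistic scale. The boundary width — the distance between the 25% and 75%
#' points, \eqn{2 s \ln 3} — is the categorical labeling consistency index
#' (smaller = more consistent).
#'
#' The likelihood is Bernoulli on raw trials (aggregated per step, which
#' leaves it unchanged up to a constant), maximized by box-constrained
#' L-BFGS-B from three deterministic initializations (an unconstrained
#' logistic-regression start when one exists, plus two fixed grid starts);
#' the best likelihood wins, ties broken by the smallest `s`. Response
#' orientation is detected from the data, so relabeling HEAD and HAD, or
#' mirroring the step axis, leaves the width unchanged.
#'
#' @param trials Data frame of one participant's trials with columns `step`
#'   and `response` (values HEAD/HAD), as from [read_identification_table()].
#' @param config An [analysis_config()]; supplies `n_steps` and the
#'   parameter bounds.
#' @return An object of class `"psychometric_fit"` with elements `x0`, `s`,
#'   `width`, `n_trials`, `converged`, `loglik`, `reversed` (TRUE when the
#'   HEAD responses dominated the high end of the continuum), `at_bound`.
#' @seealso [boundary_location()], [labeling_consistency()]
#' @export
#' @examples
#' cfg <- analysis_config()
#' trials <- simulate_identification(listener_params(x0 = 6, s = 0.6), seed = 1)
#' fit <- fit_psychometric(trials, cfg)
#' fit$x0; fit$width
fit_psychometric <- function(trials, config = analysis_config()) {
  if (!all(c("step", "response") %in% names(trials)))
    vpp_schema_error("trials need 'step' and 'response' columns")
  if ("participant_id" %in% names(trials) &&
      length(unique(trials$participant_id)) > 1L)
    vpp_precondition_error("trials must come from a single participant")
  step <- as.numeric(trials$step)
  head_resp <- as.character(trials$response) == "HEAD"
  if (length(unique(step)) < 2L)
    vpp_precondition_error("need responses at >= 2 distinct steps")
  if (all(head_resp) || all(!head_resp))
    vpp_degenerate_error("all responses in one category; psychometric fit undefined")

  # Orientation: the model expects HEAD to dominate the low-step end.
  reversed <- mean(step[head_resp]) > mean(step[!head_resp])
  y <- if (reversed) !head_resp else head_resp

  # Aggregate to per-step counts; Bernoulli and binomial ML coincide.
  agg <- rowsum(cbind(k = as.numeric(y), n = 1), group = step)
  x <- as.numeric(rownames(agg)); k <- agg[, "k"]; n <- agg[, "n"]

  nll <- function(par) {
    # p = plogis((x0 - x)/s); clamp avoids log(0) at extreme parameters
    p <- plogis((par[1] - x) / par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }
  nll_grad <- function(par) {
    eta <- (par[1] - x) / par[2]
    resid <- k - n * plogis(eta)       # d nll / d eta = -resid
    c(-sum(resid) / par[2], sum(resid * eta) / par[2])
  }

  lo <- c(config$x0_bounds[1], config$s_bounds[1])
  hi <- c(config$x0_bounds[2], config$s_bounds[2])
  clamp <- function(par) pmin(pmax(par, lo), hi)

  # crossing guess: steps weighted by binomial variance (peaks near p = 0.5)
  w <- n * (k / n) * (1 - k / n)
  x0_guess <- if (sum(w) > 0) sum(w * x) / sum(w) else mean(range(x))
  starts <- list(
    clamp(c(x0_guess, 1)),
    clamp(c(mean(range(x)), 2))
  )
  glm_start <- tryCatch({
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x), k / n, weights = n, family = binomial()))
    b <- fit$coefficients
    if (all(is.finite(b)) && b[2] < 0) clamp(c(-b[1] / b[2], -1 / b[2])) else NULL
  }, error = function(e) NULL)
  if (!is.null(glm_start)) starts <- c(list(glm_start), starts)

  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    res <- tryCatch(
      optim(st, nll, gr = nll_grad, method = "L-BFGS-B", lower = lo,
            upper = hi, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) ||
        res$value < best$value - 1e-10 ||
        (abs(res$value - best$value) <= 1e-10 && res$par[2] < best$par[2]))
      best <- res
  }
  if (is.null(best)) vpp_degenerate_error("psychometric optimization failed")

  s <- unname(best$par[2]); x0 <- unname(best$par[1])
  structure(list(
    x0 = x0, s = s, width = 2 * s * log(3),
    n_trials = length(y), converged = any_conv && best$convergence == 0,
    loglik = -best$value, reversed = reversed,
    at_bound = s <= lo[2] + 1e-9 || s >= hi[2] - 1e-9,
    steps = x, k_low_category = k, n_per_step = n
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric fit: boundary x0 = %.3f steps, scale s = %.4f\n", x$x0, x$s))
  cat(sprintf("  25-75%% width = %.4f steps over %d trials (%sconverged)%s\n",
              x$width, x$n_trials, if (x$converged) "" else "NOT ",
              if (x$at_bound) " [scale at bound]" else ""))
  invisible(x)
}

#' Categorical boundary location
#'
#' The continuum step at which the fitted identification function crosses
#' 50% probability.
#'
#' @param fit A `"psychometric_fit"`.
#' @param allow_unconverged Return the estimate even if the optimizer did not
#'   report convergence. Default FALSE.
#' @return Boundary location in continuum steps.
#' @export
boundary_location <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged && !allow_unconverged)
    vpp_degenerate_error("fit did not converge; pass allow_unconverged = TRUE to override")
  fit$x0
}

#' Categorical labeling consistency (boundary width)
#'
#' The distance in continuum steps between the 25% and 75% points of the
#' fitted logistic, `2 * s * log(3)`. Smaller width means the listener
#' partitions the continuum more consistently.
#'
#' @inheritParams boundary_location
#' @return Boundary width in continuum steps.
#' @export
labeling_consistency <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged && !allow_unconverged)
    vpp_degenerate_error("fit did not converge; pass allow_unconverged = TRUE to override")
  fit$width
}

#' Evaluate the fitted psychometric function
#' @param fit A `"psychometric_fit"`.
#' @param step Continuum position(s), possibly fractional.
#' @return Probability of the low-step response category at `step`.
#' @export
predict_psychometric <- function(fit, step) {
  stopifnot(inherits(fit, "psychometric_fit"))
  plogis((fit$x0 - step) / fit$s)
}
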