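#' MCMC settings
#'
#' Defaults follow standard practice for this engine: one chain, 30,000
#' iterations with a 50% warmup fraction. Test-scale runs typically use
#' 5,000 iterations.
#'
#' @param iterations total iterations per chain, `>= 1000`.
#' @param chains number of chains (chains beyond the first rerun the same
#'   kernel from the same initial values with fresh randomness and are
#'   pooled).
#' @param warmup_fraction fraction of iterations discarded as warmup,
#'   in (0, 1).
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(iterations = 30000, chains = 1,
                          warmup_fraction = 0.5) {
  stopifnot(iterations >= 1000, chains >= 1,
            warmup_fraction > 0, warmup_fraction < 1)
  structure(list(iterations = as.integer(iterations),
                 chains = as.integer(chains),
                 warmup_fraction = warmup_fraction),
            class = "mcmc_settings")
}

#' Data-adaptive prior hyperparameters
#'
#' Weakly informative defaults, scaled from the observed responses of the
#' probe being fitted: background `a` is normal centered at the control
#' mean with a wide SD (truncated to positive values for the exponential
#' models), effect `b` and residual SD `sigma` are half-normal with scales
#' set from the response range/SD, shape `g` is uniform on [1, 18], and the
#' Hill half-maximal dose `c` uniform on (0, 30] of the rescaled dose axis.
#' The exp4/exp5 asymptote ratio `c` gets an effect-scaled prior:
#' half-normal on the plateau change `|c - 1|` (scale set so the implied
#' response change matches the half-normal effect prior of the other
#' models), truncated to (1, 20] (increasing) or (0, 1) (decreasing).
#'
#' @param model model id.
#' @param y responses for this probe.
#' @param control_mean mean response of the control group.
#' @param direction adversity direction, +1 or -1.
#' @return Named numeric vector of hyperparameters consumed by the sampler.
#' @export
default_priors <- function(model, y, control_mean, direction = 1L) {
  model <- match.arg(model, dr_model_ids())
  rng <- diff(range(y))
  s_y <- sd(y)
  b_scale <- switch(model,
    linear = , power = , hill = 2 * rng + 0.1,
    exp2 = , exp3 = 1.5,
    exp4 = , exp5 = 5)
  c_bounds <- switch(model,
    hill = c(0, 30),
    exp4 = , exp5 = if (direction > 0) c(1, 20) else c(0, 1),
    c(NA_real_, NA_real_))
  c(a_mean = control_mean,
    a_sd = max(5 * s_y, 1),
    b_scale = b_scale,
    g_lo = 1, g_hi = 18,
    c_lo = c_bounds[1], c_hi = c_bounds[2],
    sigma_scale = max(2 * s_y, 0.05),
    a_positive = as.numeric(model %in% c("exp2", "exp3", "exp4", "exp5")),
    c_scale = if (model %in% c("exp4", "exp5"))
      (2 * rng + 0.1) / max(abs(control_mean), 0.5) else 0)
}

initial_values <- function(model, y, x, control_mean, direction, hyper) {
  a0 <- control_mean
  if (hyper[["a_positive"]] > 0.5) a0 <- max(a0, 0.05)
  top <- mean(y[x == max(x)])
  eff <- max(abs(top - control_mean), 0.05)
  s0 <- max(sd(y) / 2, 0.02)
  th <- switch(model,
    linear = c(a0, eff),
    power = c(a0, eff, 1.5),
    hill = c(a0, eff, 1.5, 0.5),
    exp2 = c(a0, max(log1p(eff / a0), 0.01)),
    exp3 = c(a0, max(log1p(eff / a0), 0.01), 1.5),
    exp4 = c(a0, 1, if (direction > 0) 1 + 2 * eff / a0 else
      max(1 - min(eff / a0, 0.9), 0.05)),
    exp5 = c(a0, 1, if (direction > 0) 1 + 2 * eff / a0 else
      max(1 - min(eff / a0, 0.9), 0.05), 1.5))
  c(th, s0)
}

#' Sample the posterior of one dose-response model
#'
#' Adaptive component-wise random-walk Metropolis targeting the posterior
#' `likelihood x prior` of the model parameters and the residual SD for a
#' single probe. Doses are rescaled by their maximum before sampling.
#' Randomness comes from R's RNG, so `set.seed()` before the call makes
#' the draws reproducible.
#'
#' @param ds an [expression_dataset()] (or a numeric response vector, in
#'   which case `doses` must be supplied).
#' @param probe probe id (when `ds` is a dataset).
#' @param model model id, one of [dr_model_ids()].
#' @param settings an [mcmc_settings()] object.
#' @param direction adversity direction; `NULL` picks the sign of
#'   (top-dose mean - control mean).
#' @param doses per-sample doses when `ds` is a plain vector.
#' @param priors optional hyperparameter vector from [default_priors()].
#' @return A `posterior_fit`: `model_id`, `draws` (matrix with named
#'   parameter columns plus `sigma`), `lp` (unnormalized log posterior per
#'   draw), `log_marginal` (Laplace-Metropolis estimate),
#'   `marginal_estimator`, `direction`, `max_dose`, `diagnostics`
#'   (acceptance rates, effective sample size of the log posterior,
#'   convergence flag), `weight` (filled by [estimate_model_weights()]).
#' @export
sample_posterior <- function(ds, probe = NULL, model = "linear",
                             settings = mcmc_settings(), direction = NULL,
                             doses = NULL, priors = NULL) {
  if (inherits(ds, "expression_dataset")) {
    stopifnot(!is.null(probe))
    y <- as.numeric(ds$values[probe, ])
    doses <- ds$doses
  } else {
    y <- as.numeric(ds)
    stopifnot(!is.null(doses), length(doses) == length(y))
  }
  model <- match.arg(model, dr_model_ids())
  stopifnot(inherits(settings, "mcmc_settings"))
  if (!all(is.finite(y))) stop("responses must be finite")
  max_dose <- max(doses)
  x <- doses / max_dose
  control_mean <- mean(y[doses == min(doses)])
  if (is.null(direction)) {
    d <- mean(y[x == max(x)]) - control_mean
    direction <- if (d >= 0) 1L else -1L
  }
  direction <- as.integer(direction)
  if (is.null(priors)) priors <- default_priors(model, y, control_mean, direction)

  spec <- model_specs(model)[[1]]
  init <- initial_values(model, y, x, control_mean, direction, priors)
  init_step <- pmax(abs(init) * 0.25, 0.02)
  warmup <- as.integer(floor(settings$iterations * settings$warmup_fraction))

  draws <- NULL; lp <- NULL; acc <- NULL
  for (ch in seq_len(settings$chains)) {
    res <- cpp_sample_posterior(spec$code, x, y, direction, priors,
                                settings$iterations, warmup, init, init_step)
    draws <- rbind(draws, res$draws)
    lp <- c(lp, res$lp)
    acc <- rbind(acc, res$accept_rate)
  }
  colnames(draws) <- c(spec$params, "sigma")

  lm_est <- bridge_marginal(draws, lp, spec$code, x, y, direction, priors)
  estimator <- "bridge-sampling"
  if (!is.finite(lm_est)) {
    lm_est <- laplace_marginal(draws, lp)
    estimator <- "laplace-metropolis"
  }
  ess <- ess_lp(lp)
  acc_mean <- colMeans(acc)
  converged <- all(acc_mean > 0.05) && is.finite(lm_est) && ess > 50

  structure(list(
    model_id = model, draws = draws, lp = lp,
    log_marginal = lm_est, marginal_estimator = estimator,
    direction = direction, max_dose = max_dose,
    diagnostics = list(accept_rate = stats::setNames(acc_mean,
                                                     c(spec$params, "sigma")),
                       ess_lp = ess, converged = converged),
    weight = NA_real_
  ), class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit [%s]: %d draws, log-marginal %.2f%s\n",
              x$model_id, nrow(x$draws), x$log_marginal,
              if (isTRUE(x$diagnostics$converged)) "" else " (flagged)"))
  invisible(x)
}

# Bridge-sampling estimate (Meng & Wong iteration) of the log marginal
# likelihood. The proposal is a multivariate normal matched to the
# posterior draws; the iteration combines posterior and proposal samples
# through the optimal bridge. Falls back to Laplace-Metropolis when the
# iteration cannot be run (degenerate covariance).
bridge_marginal <- function(draws, lp, spec_code, x, y, direction, hyper,
                            n_prop = 1000, max_iter = 100, tol = 1e-10) {
  d <- ncol(draws)
  n1 <- nrow(draws)
  mu <- colMeans(draws)
  S <- stats::cov(draws)
  diag(S) <- diag(S) + 1e-10 + 1e-8 * diag(S)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)

  z <- matrix(rnorm(n_prop * d), n_prop, d)
  prop <- sweep(z %*% ch, 2, mu, `+`)

  logq <- function(m) {
    zz <- forwardsolve(t(ch), t(sweep(m, 2, mu)))
    -0.5 * colSums(zz^2) - sum(log(diag(ch))) - d / 2 * log(2 * pi)
  }
  lp_prop <- cpp_log_post_mat(spec_code, prop, x, y, direction, hyper)
  l1 <- lp - logq(draws)        # posterior sample
  l2 <- lp_prop - logq(prop)    # proposal sample
  shift <- max(c(l1, l2[is.finite(l2)]))
  l1 <- l1 - shift
  l2 <- l2 - shift
  s1 <- n1 / (n1 + n_prop)
  s2 <- n_prop / (n1 + n_prop)
  r <- exp(max(l1)) # start near the dominant scale
  for (it in seq_len(max_iter)) {
    e2 <- exp(l2)
    num <- mean(ifelse(is.finite(e2), e2 / (s1 * e2 + s2 * r), 0))
    den <- mean(1 / (s1 * exp(l1) + s2 * r))
    r_new <- num / den
    if (!is.finite(r_new) || r_new <= 0) return(NA_real_)
    if (abs(log(r_new) - log(r)) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  log(r) + shift
}

# Laplace-Metropolis estimate of the log marginal likelihood from posterior
# draws: highest log posterior density among the draws plus the Gaussian
# volume term from the posterior covariance (eigenvalues floored to keep
# boundary-pinned parameters from degenerating the determinant).
laplace_marginal <- function(draws, lp) {
  d <- ncol(draws)
  S <- stats::cov(draws)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-12)
  max(lp) + d / 2 * log(2 * pi) + 0.5 * sum(log(ev))
}

# crude initial-sequence ESS of the log posterior trace
ess_lp <- function(lp, max_lag = 100) {
  n <- length(lp)
  if (sd(lp) == 0) return(n)
  a <- acf(lp, lag.max = min(max_lag, n - 1), plot = FALSE)$acf[-1]
  pos <- which(a < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(a)
  n / (1 + 2 * sum(a[seq_len(cut)]))
}

#' Posterior model weights
#'
#' Normalized products of marginal-likelihood estimates and prior model
#' weights: `w_k = m_k p_k / sum_j m_j p_j`. Non-finite marginal estimates
#' receive weight zero.
#'
#' @param fits list of `posterior_fit` objects, or a numeric vector of
#'   log marginal-likelihood estimates.
#' @param prior_weights prior model probabilities (default uniform);
#'   normalized to sum to 1.
#' @return Numeric weights summing to 1, named by model when available. If
#'   `fits` is a list, the same list is returned with `$weight` filled,
#'   carrying the weights as attribute `"weights"`.
#' @export
#' @examples
#' estimate_model_weights(c(0, log(2), log(2))) # 0.2 0.4 0.4
estimate_model_weights <- function(fits, prior_weights = NULL) {
  is_list <- is.list(fits)
  lm <- if (is_list) vapply(fits, `[[`, 0, "log_marginal") else as.numeric(fits)
  K <- length(lm)
  stopifnot(K >= 1)
  if (is.null(prior_weights)) prior_weights <- rep(1 / K, K)
  stopifnot(length(prior_weights) == K, all(prior_weights >= 0))
  prior_weights <- prior_weights / sum(prior_weights)
  lm[!is.finite(lm)] <- -Inf
  if (all(lm == -Inf)) stop("all marginal-likelihood estimates are non-finite")
  lw <- lm + log(prior_weights)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  if (is_list) {
    nm <- vapply(fits, `[[`, "", "model_id")
    names(w) <- nm
    for (k in seq_len(K)) fits[[k]]$weight <- w[[k]]
    attr(fits, "weights") <- w
    return(fits)
  }
  w
}

#' Draws from the model-averaged mixture
#'
#' Realizes the model-averaged posterior `sum_k w_k p(. | M_k)` by drawing
#' a model index from the weights and then a uniform draw from that
#' model's sample, `total_draws` times. Reproducible under `set.seed()`.
#'
#' @param draw_list list of numeric vectors (one per model).
#' @param weights mixture weights summing to 1.
#' @param total_draws number of mixture draws.
#' @return Numeric vector of length `total_draws`.
#' @export
model_average_draws <- function(draw_list, weights, total_draws = 5000) {
  K <- length(draw_list)
  stopifnot(length(weights) == K, abs(sum(weights) - 1) < 1e-6)
  lens <- lengths(draw_list)
  if (any(lens == 0 & weights > 0))
    stop("positively-weighted model has an empty draw set")
  idx <- sample.int(K, total_draws, replace = TRUE, prob = weights)
  out <- numeric(total_draws)
  for (k in seq_len(K)) {
    sel <- idx == k
    if (any(sel))
      out[sel] <- draw_list[[k]][sample.int(lens[k], sum(sel), replace = TRUE)]
  }
  out
}
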