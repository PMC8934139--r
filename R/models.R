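#' The seven continuous dose-response models
#'
#' Mean functions used for benchmark dose estimation, in the standard
#' continuous parameterization. Doses are rescaled to `[0, 1]` by the
#' maximum dose before fitting, and `s` denotes the adversity direction
#' (+1 increasing, -1 decreasing):
#'
#' * `linear`: \eqn{a + s b x}
#' * `power`:  \eqn{a + s b x^g}
#' * `hill`:   \eqn{a + s b x^g / (c^g + x^g)}
#' * `exp2`:   \eqn{a \exp(s b x)}
#' * `exp3`:   \eqn{a \exp(s (b x)^g)}
#' * `exp4`:   \eqn{a (c - (c - 1) e^{-b x})}
#' * `exp5`:   \eqn{a (c - (c - 1) e^{-(b x)^g})}
#'
#' The effect magnitude `b` is positive for every model; the direction of
#' adversity enters through `s` (or, for `exp4`/`exp5`, through `c`: `c > 1`
#' increasing, `0 < c < 1` decreasing). Shape parameters `g` are bounded
#' below by 1, which keeps every curve monotone on the dose axis and avoids
#' infinite slope at dose zero.
#'
#' @param models character vector of model ids; default all seven.
#' @return A named list of model specifications, each with elements
#'   `model_id`, `code` (internal integer code), `params` (parameter names,
#'   excluding the residual SD `sigma`), and `n_params`.
#' @export
#' @examples
#' names(model_specs())
#' model_specs("hill")$hill$params
model_specs <- function(models = dr_model_ids()) {
  models <- match.arg(models, dr_model_ids(), several.ok = TRUE)
  all <- list(
    linear = list(code = 1L, params = c("a", "b")),
    power  = list(code = 2L, params = c("a", "b", "g")),
    hill   = list(code = 3L, params = c("a", "b", "g", "c")),
    exp2   = list(code = 4L, params = c("a", "b")),
    exp3   = list(code = 5L, params = c("a", "b", "g")),
    exp4   = list(code = 6L, params = c("a", "b", "c")),
    exp5   = list(code = 7L, params = c("a", "b", "c", "g"))
  )
  out <- lapply(models, function(m) {
    spec <- all[[m]]
    spec$model_id <- m
    spec$n_params <- length(spec$params)
    spec
  })
  names(out) <- models
  out
}

#' @rdname model_specs
#' @export
dr_model_ids <- function() {
  c("linear", "power", "hill", "exp2", "exp3", "exp4", "exp5")
}

model_code <- function(model) {
  codes <- c(linear = 1L, power = 2L, hill = 3L, exp2 = 4L, exp3 = 5L,
             exp4 = 6L, exp5 = 7L)
  code <- codes[[match.arg(model, names(codes))]]
  code
}

#' Evaluate a dose-response mean function
#'
#' @param model one of `dr_model_ids()`.
#' @param theta named or positional numeric vector of model parameters in
#'   the order given by `model_specs(model)[[1]]$params`.
#' @param x numeric vector of (rescaled) doses, `x >= 0`.
#' @param direction adversity direction, `+1` or `-1`. Ignored by `exp4`
#'   and `exp5`, whose direction is carried by `c`.
#' @return Numeric vector of mean responses at `x`.
#' @export
#' @examples
#' dr_predict("hill", c(a = 5, b = 2, g = 2, c = 0.3), c(0, 0.3, 1), +1)
dr_predict <- function(model, theta, x, direction = 1L) {
  spec <- model_specs(match.arg(model, dr_model_ids()))[[1]]
  theta <- theta_in_order(theta, spec)
  check_theta(spec, theta)
  stopifnot(all(x >= 0), direction %in% c(-1L, 1L))
  cpp_dr_mean(spec$code, theta, as.numeric(x), as.integer(direction))
}

#' Normal log-likelihood of a dose-response model
#'
#' Sum over samples of the normal log-density of the observed responses
#' centered at the model mean with residual standard deviation `sigma`.
#'
#' @inheritParams dr_predict
#' @param sigma residual SD on the response scale, `> 0`.
#' @param y observed responses, same length as `x`.
#' @return Scalar log-likelihood.
#' @export
dr_loglik <- function(model, theta, sigma, x, y, direction = 1L) {
  spec <- model_specs(match.arg(model, dr_model_ids()))[[1]]
  theta <- theta_in_order(theta, spec)
  check_theta(spec, theta)
  stopifnot(sigma > 0, length(x) == length(y))
  cpp_dr_loglik(spec$code, theta, sigma, as.numeric(x), as.numeric(y),
                as.integer(direction))
}

theta_in_order <- function(theta, spec) {
  if (!is.null(names(theta)) && all(spec$params %in% names(theta))) {
    theta <- theta[spec$params]
  }
  if (length(theta) != spec$n_params) {
    stop(sprintf("model '%s' expects %d parameters (%s)", spec$model_id,
                 spec$n_params, paste(spec$params, collapse = ", ")))
  }
  as.numeric(theta)
}

check_theta <- function(spec, theta) {
  names(theta) <- spec$params
  if (!all(is.finite(theta))) stop("non-finite model parameter")
  if (theta[["b"]] <= 0) stop("effect parameter b must be positive")
  if ("g" %in% spec$params && theta[["g"]] < 1)
    stop("shape parameter g must be >= 1")
  if (spec$model_id == "hill" && theta[["c"]] <= 0)
    stop("hill half-maximal dose c must be positive")
  if (spec$model_id %in% c("exp4", "exp5") &&
      (theta[["c"]] <= 0 || theta[["c"]] == 1))
    stop("exp4/exp5 asymptote ratio c must be positive and != 1")
  if (spec$model_id %in% c("exp2", "exp3", "exp4", "exp5") &&
      theta[["a"]] <= 0)
    stop("exponential models require a positive background a")
  invisible(theta)
}
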