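# Matched-prior calibration study helpers: truth is drawn from the same
# priors used in fitting (fixed, moderate scales), under which central
# 90% credible intervals cover the truth at 90% up to Monte Carlo error.

calib_hyper <- function(m, dirn) {
  b_scale <- switch(m, linear = , power = , hill = 1.5,
                    exp2 = , exp3 = 0.15, exp4 = , exp5 = 3)
  cb <- switch(m, hill = c(0.05, 3),
               exp4 = , exp5 = if (dirn > 0) c(1, 3) else c(0.3, 1),
               c(NA_real_, NA_real_))
  c(a_mean = 8, a_sd = 1, b_scale = b_scale, g_lo = 1, g_hi = 5,
    c_lo = cb[1], c_hi = cb[2], sigma_scale = 0.3,
    a_positive = as.numeric(m %in% c("exp2", "exp3", "exp4", "exp5")),
    c_scale = if (m %in% c("exp4", "exp5")) 0.2 else 0)
}

rhalfnorm1 <- function(s) abs(rnorm(1, 0, s))

draw_prior_theta <- function(m, h, dirn) {
  repeat {
    a <- rnorm(1, h[["a_mean"]], h[["a_sd"]])
    if (h[["a_positive"]] < 0.5 || a > 0) break
  }
  th <- c(a = unname(a), b = rhalfnorm1(h[["b_scale"]]) + 1e-6)
  if (m %in% c("power", "hill", "exp3", "exp5"))
    th <- c(th, g = runif(1, h[["g_lo"]], h[["g_hi"]]))
  if (m == "hill") th <- c(th, c = runif(1, h[["c_lo"]], h[["c_hi"]]))
  if (m %in% c("exp4", "exp5")) {
    repeat {
      d <- rhalfnorm1(h[["c_scale"]])
      cc <- if (dirn > 0) 1 + d else 1 - d
      if (cc > h[["c_lo"]] && cc <= h[["c_hi"]] && cc != 1) break
    }
    th <- c(th, c = unname(cc))
  }
  th
}
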