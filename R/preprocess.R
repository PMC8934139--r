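#' Signed fold change from log-scale group means
#'
#' For each non-control dose level the response ratio on the natural scale
#' is `r_i = base^(mean_i - mean_0)`. Ratios below 1 are expressed as a
#' negative reciprocal (`-1/r`), so the magnitude is always `>= 1`; the
#' reported fold change is the candidate with the largest magnitude across
#' dose levels (absmax).
#'
#' @param group_means mean log-scale response per non-control dose level.
#' @param control_mean mean log-scale response of the control group.
#' @param log_base log base of the data (2, 10, or `exp(1)`).
#' @return Signed scalar fold change, `|f| >= 1`.
#' @export
#' @examples
#' compute_fold_change(c(9, 6), control_mean = 8, log_base = 2) # -4
compute_fold_change <- function(group_means, control_mean, log_base = 2) {
  if (length(group_means) < 1) stop("need at least one non-control level")
  stopifnot(all(is.finite(group_means)), is.finite(control_mean))
  base <- parse_log_base(if (identical(log_base, exp(1))) "natural" else log_base)
  r <- base^(group_means - control_mean)
  cand <- ifelse(r >= 1, r, -1 / r)
  cand[which.max(abs(cand))]
}

#' One-way ANOVA p-value for a single probe
#'
#' Classical equal-variance one-way ANOVA F test of any difference among
#' dose-group means.
#'
#' @param y responses.
#' @param groups dose-group factor or index, same length as `y`.
#' @return P-value; `NA` if the pooled within-group variance is zero (the
#'   probe is flagged invalid upstream).
#' @export
anova_pvalue <- function(y, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups each with >= 2 samples")
  if (all(tapply(y, groups, stats::var) == 0)) return(NA_real_)
  stats::oneway.test(y ~ groups, var.equal = TRUE)$p.value
}

#' Isotonic (monotone) maximum-likelihood group means
#'
#' The n-weighted max-min estimator of monotone group means: for the
#' increasing case each fitted mean is the maximum over starting levels
#' `u <= i` of the minimum over ending levels `v` of the weighted mean of
#' the observed group means from `u` to `v` (min/max swapped when
#' decreasing). Computed by weighted pool-adjacent-violators, which yields
#' the identical fit.
#'
#' @param group_means observed group means, in ascending dose order.
#' @param n group sizes.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return Fitted monotone means, same length as `group_means`.
#' @export
#' @examples
#' isotonic_group_means(c(3, 1), n = c(1, 3), "increasing") # 1.5 1.5
isotonic_group_means <- function(group_means, n,
                                 direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(length(group_means) >= 2, length(n) == length(group_means),
            all(n >= 1))
  cpp_isotonic_means(as.numeric(group_means), as.numeric(n),
                     direction == "increasing")
}

#' Williams-type monotone trend statistic
#'
#' Isotonic group means are standardized against the control mean using the
#' unbiased pooled within-group SD over all groups (control included):
#' `T = max_i |mu_i - mean_0| / (s * sqrt(1/n_i + 1/n_0))`, the maximum
#' over treated levels. With `direction = "auto"` both monotone fits are
#' evaluated and the direction with the larger statistic is reported.
#'
#' @param y responses.
#' @param groups dose-group index/factor in ascending dose order; the first
#'   level is the control.
#' @param direction `"auto"`, `"increasing"`, or `"decreasing"`.
#' @return List with `T`, `direction`, `group_means`, `n`, `iso_means`, `s`.
#' @export
williams_statistic <- function(y, groups,
                               direction = c("auto", "increasing",
                                             "decreasing")) {
  direction <- match.arg(direction)
  groups <- as.factor(groups)
  K <- nlevels(groups)
  stopifnot(K >= 2)
  grp0 <- as.integer(groups) - 1L
  dir_code <- switch(direction, auto = 0L, increasing = 1L, decreasing = -1L)
  res <- cpp_williams(as.numeric(y), grp0, K, dir_code)
  if (is.na(res[1])) stop("pooled within-group SD is zero")
  dir_out <- if (res[2] > 0) "increasing" else "decreasing"
  xbar <- as.numeric(tapply(y, groups, mean))
  n <- as.numeric(table(groups))
  list(T = res[1], direction = dir_out, group_means = xbar, n = n,
       iso_means = isotonic_group_means(xbar, n, dir_out),
       s = sqrt(sum((y - xbar[as.integer(groups)])^2) / (length(y) - K)))
}

#' Resampling p-value for the monotone trend statistic
#'
#' The null distribution of the Williams-type statistic is generated by
#' permuting dose labels across all samples (`"permutation"`) or by
#' resampling with replacement from the pooled sample (`"bootstrap"`); the
#' trend direction is re-chosen per replicate to maximize the statistic.
#' The p-value uses the +1 correction, `p = (1 + #(T_b >= T_obs)) / (B + 1)`,
#' so it is bounded below by `1 / (B + 1)`. With `exhaustive = TRUE` (and
#' `<= 8` samples, permutation only) all label permutations are enumerated
#' instead and `p = mean(T_b >= T_obs)` over the complete null.
#'
#' @inheritParams williams_statistic
#' @param method `"permutation"` or `"bootstrap"`.
#' @param B number of resamples, `>= 100`.
#' @param exhaustive enumerate the complete permutation null.
#' @return List with `p`, `T_obs`, `direction`, `B`.
#' @export
resampling_pvalue <- function(y, groups, method = c("permutation", "bootstrap"),
                              B = 1000, exhaustive = FALSE) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  K <- nlevels(groups)
  if (sd(y) == 0) # constant responses: the null reproduces T = 0 always
    return(list(p = 1, T_obs = 0, direction = NA_character_, B = B))
  obs <- williams_statistic(y, groups, "auto")
  grp0 <- as.integer(groups) - 1L
  if (exhaustive) {
    if (method != "permutation")
      stop("exhaustive enumeration applies to the permutation null only")
    if (length(y) > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(length(y))
    Tb <- apply(perms, 1, function(idx)
      cpp_williams(as.numeric(y)[idx], grp0, K, 0L)[1])
    return(list(p = mean(Tb >= obs$T - 1e-12), T_obs = obs$T,
                direction = obs$direction, B = nrow(perms)))
  }
  if (B < 100) stop("B must be >= 100")
  Tb <- cpp_trend_null(as.numeric(y), grp0, K, as.integer(B),
                       method == "bootstrap")
  list(p = (1 + sum(Tb >= obs$T - 1e-12)) / (B + 1), T_obs = obs$T,
       direction = obs$direction, B = B)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order; `adjusted >= raw`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Screening settings
#'
#' @param fold_change_cutoff minimum absolute fold change (inclusive).
#'   Default 2.
#' @param p_cutoff p-value threshold (strict `<`). Default 0.05.
#' @param which_test test whose p-value is filtered on: `"anova"`,
#'   `"williams"` or `"oriogen"`.
#' @param use_adjusted filter on BH-adjusted p-values instead of raw.
#' @param B resampling count for the trend-test nulls, `>= 100`.
#' @param tests which test p-values to compute (the trend tests cost
#'   `B` resamples per probe).
#' @return A `filter_settings` list.
#' @export
filter_settings <- function(fold_change_cutoff = 2, p_cutoff = 0.05,
                            which_test = c("anova", "williams", "oriogen"),
                            use_adjusted = FALSE, B = 1000,
                            tests = c("anova", "williams", "oriogen")) {
  which_test <- match.arg(which_test)
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(fold_change_cutoff > 0, p_cutoff > 0, B >= 100)
  if (!which_test %in% tests) tests <- union(tests, which_test)
  structure(list(fold_change_cutoff = fold_change_cutoff,
                 p_cutoff = p_cutoff, which_test = which_test,
                 use_adjusted = use_adjusted, B = as.integer(B),
                 tests = tests),
            class = "filter_settings")
}

#' Screen probes by fold change and dose-response tests
#'
#' Computes, per valid probe, the signed fold change, the one-way ANOVA
#' p-value, and (optionally) Williams-type permutation and Oriogen-type
#' bootstrap trend-test p-values, with BH-adjusted versions across probes,
#' then applies the pass/fail rule of [filter_probes()].
#'
#' The Oriogen variant shares the monotone isotonic statistic with the
#' Williams test and differs in its resampling null (bootstrap from the
#' pooled sample rather than label permutation), reflecting its monotone
#' dose-response assumption.
#'
#' @param ds an [expression_dataset()].
#' @param settings a [filter_settings()] object.
#' @return Data frame with one row per valid probe: `probe_id`,
#'   `fold_change`, `direction`, `p_anova`, `p_williams`, `p_oriogen`,
#'   `adj_p_*`, `passed`.
#' @export
screen_probes <- function(ds, settings = filter_settings()) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(settings, "filter_settings"))
  probes <- valid_probe_ids(ds)
  grp <- dose_group_index(ds)
  groups <- factor(grp)
  K <- nlevels(groups)
  base <- ds$log_base

  rows <- lapply(probes, function(pid) {
    y <- ds$values[pid, ]
    xbar <- as.numeric(tapply(y, groups, mean))
    f <- compute_fold_change(xbar[-1], xbar[1],
                             if (abs(base - exp(1)) < 1e-12) "natural" else base)
    p_a <- if ("anova" %in% settings$tests) anova_pvalue(y, groups) else NA_real_
    w <- o <- list(p = NA_real_, direction = NA_character_)
    if ("williams" %in% settings$tests)
      w <- resampling_pvalue(y, groups, "permutation", settings$B)
    if ("oriogen" %in% settings$tests)
      o <- resampling_pvalue(y, groups, "bootstrap", settings$B)
    dir <- if (!is.na(w$direction %||% NA)) w$direction else
      williams_statistic(y, groups, "auto")$direction
    data.frame(probe_id = pid, fold_change = f, direction = dir,
               p_anova = p_a, p_williams = w$p, p_oriogen = o$p)
  })
  res <- do.call(rbind, rows)
  res$adj_p_anova <- if (all(is.na(res$p_anova))) NA_real_ else bh_adjust(res$p_anova)
  res$adj_p_williams <- if (all(is.na(res$p_williams))) NA_real_ else bh_adjust(res$p_williams)
  res$adj_p_oriogen <- if (all(is.na(res$p_oriogen))) NA_real_ else bh_adjust(res$p_oriogen)
  res$passed <- res$probe_id %in% filter_probes(res, settings)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the screening filter
#'
#' Keeps probes with `|fold change| >= fold_change_cutoff` (inclusive) AND
#' selected-test p-value `< p_cutoff` (strict), using the adjusted p-value
#' when `use_adjusted` is set.
#'
#' @param results a screening table from [screen_probes()].
#' @param settings a [filter_settings()] object.
#' @return Character vector of retained probe ids.
#' @export
filter_probes <- function(results, settings = filter_settings()) {
  col <- paste0(if (isTRUE(settings$use_adjusted)) "adj_p_" else "p_",
                settings$which_test)
  if (!col %in% names(results)) stop("unknown test column: ", col)
  p <- results[[col]]
  keep <- abs(results$fold_change) >= settings$fold_change_cutoff &
    !is.na(p) & p < settings$p_cutoff
  results$probe_id[keep]
}
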