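#' Simulate one probe from a dose-response model
#'
#' Draws responses `y ~ Normal(f(x | theta), sigma)` at each sample and
#' records the true BMD implied by `(theta, sigma)` under the BMR -- the
#' same inversion used for posterior draws, so recovery tests compare like
#' with like. Uses the current RNG state; call `set.seed()` upstream for
#' reproducibility.
#'
#' @param model model id.
#' @param theta named parameter vector (without `sigma`).
#' @param sigma residual SD (`>= 0`; zero gives noise-free responses).
#' @param doses dose level values (original units).
#' @param n_per_dose samples per dose level (scalar or per-level vector).
#' @param direction adversity direction, +1/-1.
#' @param bmr a [bmr_spec()] used for the recorded true BMD.
#' @return List with `y` (responses, dose-sorted), `doses` (per sample),
#'   `true_bmd` (original dose units, `NA` if the curve never reaches the
#'   BMR within the extrapolation cap).
#' @export
simulate_probe <- function(model, theta, sigma, doses, n_per_dose,
                           direction = 1L, bmr = bmr_spec()) {
  model <- match.arg(model, dr_model_ids())
  stopifnot(sigma >= 0)
  if (length(n_per_dose) == 1) n_per_dose <- rep(n_per_dose, length(doses))
  dose_per_sample <- rep(doses, n_per_dose)
  max_dose <- max(doses)
  x <- dose_per_sample / max_dose
  spec <- model_specs(model)[[1]]
  th <- theta_in_order(theta, spec)
  mu <- cpp_dr_mean(spec$code, th, x, as.integer(direction))
  y <- rnorm(length(x), mu, sigma)
  res <- bmd_from_draw(model, c(stats::setNames(th, spec$params),
                                sigma = max(sigma, 1e-12)),
                       bmr, direction)
  list(y = y, doses = dose_per_sample,
       true_bmd = if (res$capped[1]) NA_real_ else res$bmd[1] * max_dose)
}

# effect parameter b that places the true BMD at t_star (rescaled dose)
solve_effect_b <- function(model, t_star, target, a, g = NULL, cc = NULL,
                           direction = 1L) {
  switch(model,
    linear = target / t_star,
    power = target / t_star^g,
    hill = target * (cc^g + t_star^g) / t_star^g,
    exp2 = exp_change_arg(target, a, direction) / t_star,
    exp3 = exp_change_arg(target, a, direction)^(1 / g) / t_star,
    exp4 = exp45_arg(target, a, cc) / t_star,
    exp5 = exp45_arg(target, a, cc)^(1 / g) / t_star)
}

#' Simulate a complete dose-response experiment with known truth
#'
#' Generates an expression matrix emulating a typical in-vivo
#' transcriptomic design -- five dose levels (control plus four geometric
#' doses) with a few animals per level, log2-scale intensities -- together
#' with a probe-to-gene annotation, gene-set categories, and a truth
#' table.
#'
#' Responsive probes are drawn from the requested model mix with true
#' BMDs spread log-uniformly over `bmd_range` (in multiples of the top
#' dose; the default reaches beyond the dose range so extrapolation
#' flagging is exercised) and effect parameters solved so the true BMD
#' sits exactly at the drawn value under `bmr`. Null probes are pure
#' noise around their background. One designed category
#' (`"responsive_pathway"`) is composed of responsive genes; the remaining
#' categories draw from null genes.
#'
#' @param n_probes total number of probes.
#' @param responsive_fraction fraction of probes carrying a true
#'   dose-response signal.
#' @param model_mix named numeric vector of sampling weights over
#'   [dr_model_ids()] (default uniform over all seven).
#' @param doses dose levels; default `0, 12.5, 25, 50, 100`.
#' @param n_per_dose samples per dose level (default 4).
#' @param bmd_range range of true BMDs, as multiples of the top dose.
#' @param sigma_range residual SD range (log2 intensity units).
#' @param background_range background (control mean) range, log2 scale.
#' @param bmr a [bmr_spec()] defining the recorded true BMDs.
#' @param plateau_margin range of the exp4/exp5 plateau change expressed
#'   as a multiple of the BMR target. Low margins (default) give
#'   saturating curves whose asymptote barely clears the benchmark
#'   response -- the hardest, most weakly identified case; raise it for
#'   strong-responder scenarios.
#' @param max_effect cap on the absolute top-dose effect (log-scale
#'   units); under an sd-shift BMR the residual SD is shrunk until the
#'   implied effect respects it, keeping the drawn true BMD exact.
#' @param min_effect optional floor on the top-dose effect (same
#'   mechanism, scaling the residual SD up); 0 disables it. Use it to
#'   emulate uniformly strong responders that all clear a fold-change
#'   screen.
#' @param n_categories number of gene-set categories (>= 2: one designed
#'   responsive category plus background categories).
#' @param genes_per_category genes per category.
#' @param seed optional integer seed.
#' @return List of class `sim_experiment`: `dataset`
#'   (an [expression_dataset()]), `truth` (data frame: `probe_id`, `gene`,
#'   `responsive`, `model`, `direction`, `a`, `b`, `g`, `c`, `sigma`,
#'   `true_bmd`), `annotation` (a [gene_annotation()]), `bmr`, `seed`.
#' @export
simulate_experiment <- function(n_probes = 200, responsive_fraction = 0.3,
                                model_mix = NULL,
                                doses = c(0, 12.5, 25, 50, 100),
                                n_per_dose = 4,
                                bmd_range = c(0.1, 2),
                                sigma_range = c(0.05, 0.2),
                                background_range = c(6, 10),
                                bmr = bmr_spec(),
                                plateau_margin = c(1.5, 4),
                                max_effect = 4,
                                min_effect = 0,
                                n_categories = 15,
                                genes_per_category = 10,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(responsive_fraction >= 0, responsive_fraction <= 1,
            n_categories >= 2, length(n_per_dose) == 1)
  models <- dr_model_ids()
  if (is.null(model_mix)) model_mix <- stats::setNames(rep(1, 7), models)
  model_mix <- model_mix[models]
  model_mix[is.na(model_mix)] <- 0

  n_resp <- round(n_probes * responsive_fraction)
  resp <- c(rep(TRUE, n_resp), rep(FALSE, n_probes - n_resp))
  probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
  genes <- sprintf("gene_%04d", seq_len(n_probes))

  rows <- vector("list", n_probes)
  ymat <- matrix(NA_real_, n_probes, sum(rep(n_per_dose, length(doses))))
  for (i in seq_len(n_probes)) {
    a <- runif(1, background_range[1], background_range[2])
    sigma <- runif(1, sigma_range[1], sigma_range[2])
    if (resp[i]) {
      m <- sample(models, 1, prob = model_mix)
      dir <- sample(c(1L, -1L), 1)
      t_star <- exp(runif(1, log(bmd_range[1]), log(bmd_range[2])))
      g <- if (m %in% c("power", "hill", "exp3", "exp5"))
        runif(1, 1.2, 3) else NA_real_
      cc <- NA_real_
      if (m == "hill") cc <- min(t_star * runif(1, 1, 3), 5)
      # exp4/5 plateau change = margin x BMR target
      margin <- runif(1, plateau_margin[1], plateau_margin[2])
      # Solve the effect parameter so the true BMD sits at t_star; convex
      # shapes with a low BMD can imply implausible top-dose effects, so
      # the residual SD (hence the 1-SD target) is shrunk until the
      # top-dose effect stays within max_effect log units.
      spec_i <- model_specs(m)[[1]]
      cap_hit <- FALSE
      for (pass in 1:40) {
        target <- if (bmr$kind == "sd_shift") bmr$value * sigma else
          bmr$value * a
        if (m %in% c("exp4", "exp5")) {
          cc <- if (dir > 0) 1 + margin * target / a else
            1 - margin * target / a
        }
        b <- solve_effect_b(m, t_star, target, a, g, cc, dir)
        theta <- c(a = a, b = b,
                   if (!is.na(g)) c(g = g),
                   if (!is.na(cc)) c(c = cc))
        d1 <- abs(cpp_dr_mean(spec_i$code, theta_in_order(theta, spec_i),
                              1, dir) - a)
        if (bmr$kind != "sd_shift") break
        if (!is.finite(d1)) { # curve overflow: shrink hard until finite
          sigma <- sigma / 2
          cap_hit <- TRUE
        } else if (d1 > max_effect * 1.05) {
          sigma <- sigma * max_effect / d1
          cap_hit <- TRUE
        } else if (!cap_hit && min_effect > 0 && d1 < min_effect / 1.05) {
          # the floor never overrides the cap (convex shapes with a low
          # BMD cannot satisfy both; the cap wins)
          sigma <- sigma * min_effect / d1
        } else break
      }
      sp <- simulate_probe(m, theta, sigma, doses, n_per_dose, dir, bmr)
      ymat[i, ] <- sp$y
      rows[[i]] <- data.frame(probe_id = probe_ids[i], gene = genes[i],
                              responsive = TRUE, model = m, direction = dir,
                              a = a, b = b, g = g, c = cc, sigma = sigma,
                              true_bmd = sp$true_bmd)
    } else {
      ymat[i, ] <- rnorm(ncol(ymat), a, sigma)
      rows[[i]] <- data.frame(probe_id = probe_ids[i], gene = genes[i],
                              responsive = FALSE, model = NA_character_,
                              direction = NA_integer_, a = a, b = NA_real_,
                              g = NA_real_, c = NA_real_, sigma = sigma,
                              true_bmd = NA_real_)
    }
  }
  truth <- do.call(rbind, rows)

  dose_per_sample <- rep(doses, each = n_per_dose)
  dimnames(ymat) <- list(probe_ids,
                         sprintf("s%02d_d%g", seq_along(dose_per_sample),
                                 dose_per_sample))
  ds <- expression_dataset(ymat, dose_per_sample, log_base = 2)

  probe_map <- stats::setNames(as.list(genes), probe_ids)
  # The designed category collects the most sensitive (lowest true BMD)
  # responsive genes; the remaining responsive genes scatter across the
  # background categories with the null genes, so background categories
  # carry realistic (higher) BMD signal rather than none at all.
  ri <- which(resp)
  ri <- ri[order(truth$true_bmd[ri])]
  designed <- head(genes[ri], genes_per_category)
  cats <- list()
  if (length(designed) > 0) {
    cats[["responsive_pathway"]] <- list(
      id = "responsive_pathway", name = "designed responsive category",
      genes = designed)
  }
  null_genes <- setdiff(genes, designed)
  pool <- sample(null_genes)
  for (k in seq_len(n_categories - 1)) {
    if (length(pool) < genes_per_category) pool <- null_genes
    if (length(pool) == 0) break # no null genes to form background sets
    pick <- sample(pool, min(genes_per_category, length(pool)))
    pool <- setdiff(pool, pick)
    cats[[sprintf("background_%02d", k)]] <- list(
      id = sprintf("background_%02d", k),
      name = sprintf("background category %d", k), genes = pick)
  }
  ann <- gene_annotation(probe_map, cats, source_label = "synthetic")

  structure(list(dataset = ds, truth = truth, annotation = ann, bmr = bmr,
                 seed = seed),
            class = "sim_experiment")
}

#' Write a simulated experiment to plain-text files
#'
#' Writes `matrix.tsv`, `doses.tsv`, `probe_map.tsv`, `sets.gmt` and
#' `truth.csv` under `dir`, in the formats the readers of this package
#' consume.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$dataset, file.path(dir, "matrix.tsv"),
                          file.path(dir, "doses.tsv"))
  pm <- sim$annotation$probe_to_genes
  write.table(data.frame(probe_id = rep(names(pm), lengths(pm)),
                         gene = unlist(pm, use.names = FALSE)),
              file.path(dir, "probe_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gmt <- vapply(sim$annotation$categories, function(cat)
    paste(c(cat$id, cat$name, cat$genes), collapse = "\t"), "")
  writeLines(gmt, file.path(dir, "sets.gmt"))
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
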