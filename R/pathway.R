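#' Collapse probe-level BMDs to gene-level BMDs
#'
#' Probes mapping to more than one gene are removed; probes with no
#' mapping are dropped; when several probes map to the same gene, the
#' gene's BMD (and BMDL/BMDU) is the arithmetic mean across those probes.
#'
#' @param estimates a [estimate_bmds()] table (needs `probe_id`, `bmd`,
#'   `bmdl`, `bmdu`).
#' @param annotation a [gene_annotation()] with a non-empty probe map.
#' @return Data frame with one row per gene: `gene`, `bmd`, `bmdl`,
#'   `bmdu`, `n_probes`.
#' @export
map_probes_to_genes <- function(estimates, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (length(annotation$probe_to_genes) == 0) stop("empty probe annotation")
  pm <- annotation$probe_to_genes
  uni <- pm[lengths(pm) == 1]
  gene_of <- vapply(uni, `[[`, "", 1)
  keep <- estimates$probe_id %in% names(gene_of)
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est) == 0)
    return(data.frame(gene = character(), bmd = numeric(), bmdl = numeric(),
                      bmdu = numeric(), n_probes = integer()))
  g <- gene_of[est$probe_id]
  agg <- function(v) tapply(v, g, mean)
  out <- data.frame(gene = names(agg(est$bmd)), bmd = as.numeric(agg(est$bmd)),
                    bmdl = as.numeric(agg(est$bmdl)),
                    bmdu = as.numeric(agg(est$bmdu)),
                    n_probes = as.integer(table(g)[names(agg(est$bmd))]))
  rownames(out) <- NULL
  out
}

# all genes on the platform that map uniquely (the Fisher universe)
annotation_universe <- function(annotation) {
  pm <- annotation$probe_to_genes
  unique(unlist(pm[lengths(pm) == 1], use.names = FALSE))
}

#' Fisher's exact two-tailed enrichment p-value
#'
#' Exact two-sided p-value of the 2x2 table contrasting membership in the
#' category (rows) with possession of a BMD estimate (columns): the sum of
#' hypergeometric probabilities of all tables, with the observed margins,
#' whose probability does not exceed the observed table's.
#'
#' @param with_in,without_in genes inside the category with / without a
#'   BMD estimate.
#' @param with_out,without_out genes outside the category with / without a
#'   BMD estimate.
#' @return Two-tailed p-value.
#' @export
#' @examples
#' fisher_enrichment(2, 0, 0, 2) # 1/3
fisher_enrichment <- function(with_in, without_in, with_out, without_out) {
  m <- matrix(c(with_in, without_in, with_out, without_out), 2, 2)
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) == 0) stop("all-zero table")
  fisher.test(m, alternative = "two.sided")$p.value
}

#' Aggregate gene BMDs into category statistics
#'
#' For every category: the number of member genes with BMD estimates, the
#' category percentage (members with BMD / total members), the Fisher
#' enrichment p-value against the annotation universe, and the min, max,
#' mean and median BMD over the category's concentration-responsive genes
#' (plus median BMDL/BMDU). Categories with no BMD-bearing genes carry
#' `NA` dose statistics.
#'
#' @param gene_table output of [map_probes_to_genes()].
#' @param annotation a [gene_annotation()] with categories.
#' @param universe optional character vector of genes forming the Fisher
#'   universe; defaults to all uniquely-mapped genes in the annotation.
#' @return Data frame of class `pathway_results`, one row per category:
#'   `category_id`, `name`, `genes_with_bmd`, `genes_total`, `p_fisher`,
#'   `percentage`, `bmd_min`, `bmd_max`, `bmd_mean`, `bmd_median`,
#'   `bmdl_median`, `bmdu_median`.
#' @export
aggregate_categories <- function(gene_table, annotation, universe = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (length(annotation$categories) == 0) stop("annotation has no categories")
  if (is.null(universe)) universe <- annotation_universe(annotation)
  if (length(universe) == 0) universe <- unique(gene_table$gene)
  genes_bmd <- intersect(gene_table$gene, universe)
  n_uni <- length(universe)
  n_bmd <- length(genes_bmd)

  rows <- lapply(annotation$categories, function(cat) {
    members <- intersect(cat$genes, universe)
    hit <- intersect(members, genes_bmd)
    n_in <- length(members); n_hit <- length(hit)
    p <- if (n_in == 0) NA_real_ else
      fisher_enrichment(n_hit, n_in - n_hit,
                        n_bmd - n_hit, (n_uni - n_in) - (n_bmd - n_hit))
    vals <- gene_table[gene_table$gene %in% hit, , drop = FALSE]
    has <- nrow(vals) > 0
    data.frame(
      category_id = cat$id, name = cat$name,
      genes_with_bmd = n_hit, genes_total = n_in,
      p_fisher = p,
      percentage = if (n_in > 0) n_hit / n_in else NA_real_,
      bmd_min = if (has) min(vals$bmd) else NA_real_,
      bmd_max = if (has) max(vals$bmd) else NA_real_,
      bmd_mean = if (has) mean(vals$bmd) else NA_real_,
      bmd_median = if (has) median(vals$bmd) else NA_real_,
      bmdl_median = if (has) median(vals$bmdl) else NA_real_,
      bmdu_median = if (has) median(vals$bmdu) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pathway_results", class(out))
  out
}

#' Category percentage
#'
#' Ratio of the number of category genes with BMD estimates to the total
#' number of genes in the category.
#'
#' @param genes_with_bmd_in,genes_total_in counts.
#' @return Fraction in `[0, 1]`.
#' @export
percentage <- function(genes_with_bmd_in, genes_total_in) {
  if (genes_total_in < 1) stop("category has no genes")
  stopifnot(genes_with_bmd_in >= 0, genes_with_bmd_in <= genes_total_in)
  genes_with_bmd_in / genes_total_in
}

#' Select enriched categories
#'
#' A category is enriched when its Fisher p-value is below `p_cut`
#' (strict), it has more than `min_genes` genes with BMD estimates
#' (strict), and its percentage is at least `min_pct` (inclusive).
#'
#' @param results a [aggregate_categories()] table.
#' @param p_cut Fisher p-value threshold (default 0.05).
#' @param min_genes genes-with-BMD threshold, exclusive (default 1, i.e.
#'   at least 2 genes).
#' @param min_pct percentage threshold, inclusive (default 0.03).
#' @return The enriched subset of `results`.
#' @export
select_enriched <- function(results, p_cut = 0.05, min_genes = 1,
                            min_pct = 0.03) {
  keep <- !is.na(results$p_fisher) & results$p_fisher < p_cut &
    results$genes_with_bmd > min_genes & results$percentage >= min_pct
  results[keep, , drop = FALSE]
}

#' Biological-effect point of departure (BEPOD)
#'
#' The median of the enriched categories' median BMDs. With an even number
#' of enriched categories the mean of the two middle values is used.
#'
#' @param enriched enriched categories from [select_enriched()].
#' @return A `bepod_result` list: `bepod`, `n_enriched`,
#'   `enriched_categories`, `thresholds`. When no category is enriched,
#'   `bepod` is `NA` and the result prints as "no BEPOD".
#' @export
compute_bepod <- function(enriched, p_cut = 0.05, min_genes = 1,
                          min_pct = 0.03) {
  structure(list(
    bepod = if (nrow(enriched) >= 1) median(enriched$bmd_median) else NA_real_,
    n_enriched = nrow(enriched),
    enriched_categories = enriched$category_id,
    thresholds = list(p_cut = p_cut, min_genes = min_genes,
                      min_pct = min_pct)
  ), class = "bepod_result")
}

#' @rdname compute_bepod
#' @param estimates,annotation inputs forwarded through the whole pathway
#'   stage: probe-level BMD estimates and the annotation.
#' @param p_cut,min_genes,min_pct enrichment thresholds
#'   (see [select_enriched()]).
#' @return `pathway_analysis()`: list with `gene_table`, `categories`
#'   (all categories), `enriched`, `bepod` (a `bepod_result`).
#' @export
pathway_analysis <- function(estimates, annotation, p_cut = 0.05,
                             min_genes = 1, min_pct = 0.03) {
  gene_table <- map_probes_to_genes(estimates, annotation)
  cats <- aggregate_categories(gene_table, annotation)
  enr <- select_enriched(cats, p_cut, min_genes, min_pct)
  list(gene_table = gene_table, categories = cats, enriched = enr,
       bepod = compute_bepod(enr, p_cut, min_genes, min_pct))
}

#' @export
print.bepod_result <- function(x, ...) {
  if (is.na(x$bepod)) {
    cat("no BEPOD: no category passed the enrichment filters\n")
  } else {
    cat(sprintf("BEPOD %.4g (median BMD of %d enriched categories)\n",
                x$bepod, x$n_enriched))
  }
  invisible(x)
}

#' Correlate BEPODs with apical PODs
#'
#' Pearson correlation and root-mean-square deviation between paired
#' transcriptional and apical points of departure, computed on log10
#' values.
#'
#' @param bepods,pods paired positive dose values, length >= 2.
#' @return Named vector `c(pearson_r, rmsd)`.
#' @export
correlate_pod <- function(bepods, pods) {
  stopifnot(length(bepods) == length(pods), length(bepods) >= 2)
  if (any(bepods <= 0) || any(pods <= 0))
    stop("PODs must be positive for log10 comparison")
  lb <- log10(bepods); lp <- log10(pods)
  c(pearson_r = cor(lb, lp), rmsd = sqrt(mean((lb - lp)^2)))
}

#' Empirical cumulative distribution table
#'
#' Sorted (value, cumulative fraction) pairs for cumulative distribution
#' curves of gene or pathway BMDs; duplicated values collapse to one step
#' carrying their combined mass.
#'
#' @param values numeric vector.
#' @return Data frame with `value` and `cum_fraction`, both non-decreasing.
#' @export
cdc_table <- function(values) {
  stopifnot(length(values) >= 1)
  v <- sort(values)
  u <- unique(v)
  data.frame(value = u,
             cum_fraction = cumsum(as.numeric(table(factor(v, levels = u)))) /
               length(v))
}
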