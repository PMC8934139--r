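#' Construct an expression dataset
#'
#' Container for a normalized, log-transformed expression matrix (probes x
#' samples) with a per-sample dose vector. Samples are re-ordered by
#' ascending dose (ties keep their input order); the minimum dose group is
#' treated as the control throughout the package.
#'
#' @param values numeric matrix, probes in rows, samples in columns; all
#'   entries are expected on the log scale declared by `log_base`.
#' @param doses non-negative numeric vector, one dose per sample.
#' @param log_base log base of the transformation applied upstream: `2`,
#'   `10`, or `"natural"`.
#' @param probe_ids,sample_ids unique identifiers; defaults taken from
#'   `dimnames(values)`.
#' @param dose_units free-text dose units label.
#' @return An object of class `expression_dataset` with elements `values`,
#'   `doses`, `log_base` (numeric; `exp(1)` for natural), `probe_ids`,
#'   `sample_ids`, `dose_units`.
#' @export
#' @examples
#' m <- matrix(rnorm(12, 8), 2, 6,
#'             dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
#' ds <- expression_dataset(m, doses = c(0, 0, 1, 1, 10, 10), log_base = 2)
#' ds$doses
expression_dataset <- function(values, doses, log_base = 2,
                               probe_ids = rownames(values),
                               sample_ids = colnames(values),
                               dose_units = "") {
  values <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(probe_ids))
    stop("duplicated probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("values must have one row per probe id and one column per sample id")
  doses <- as.numeric(doses)
  if (length(doses) != ncol(values))
    stop("doses must have one entry per sample")
  if (anyNA(doses) || any(doses < 0))
    stop("doses must be non-negative and complete")
  if (length(unique(doses)) < 2)
    stop("at least 2 distinct dose levels are required")
  base <- parse_log_base(log_base)

  ord <- order(doses) # stable: ties keep input order
  structure(list(
    values = structure(values[, ord, drop = FALSE],
                       dimnames = list(probe_ids, sample_ids[ord])),
    doses = doses[ord],
    log_base = base,
    probe_ids = probe_ids,
    sample_ids = sample_ids[ord],
    dose_units = dose_units
  ), class = "expression_dataset")
}

parse_log_base <- function(log_base) {
  if (identical(log_base, "natural") || identical(log_base, "e"))
    return(exp(1))
  base <- suppressWarnings(as.numeric(log_base))
  if (is.na(base) || !base %in% c(2, 10))
    stop("log_base must be 2, 10 or \"natural\"")
  base
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  lev <- dose_levels(x)
  cat(sprintf("dose levels (%s): %s; n per level: %s\n",
              if (nzchar(x$dose_units)) x$dose_units else "unitless",
              paste(signif(lev$dose, 4), collapse = ", "),
              paste(lev$n, collapse = ", ")))
  invisible(x)
}

#' Dose levels of a dataset
#'
#' @param ds an `expression_dataset`.
#' @return Data frame with one row per distinct dose level (ascending):
#'   `dose`, `n` (samples at that level). The first row is the control.
#' @export
dose_levels <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  lev <- sort(unique(ds$doses))
  data.frame(dose = lev, n = as.integer(table(factor(ds$doses, levels = lev))))
}

dose_group_index <- function(ds) {
  lev <- sort(unique(ds$doses))
  match(ds$doses, lev)
}

#' Read an expression matrix with a dose design
#'
#' Parses a delimited text file (tab or comma, auto-detected from the
#' header line) with a header row of sample ids and probe ids in the first
#' column, attaches per-sample doses, and returns a validated, dose-sorted
#' [expression_dataset()].
#'
#' @param path path to the matrix file.
#' @param dose_map either a named numeric vector (names = sample ids) or a
#'   two-column data frame / file path with columns sample id, dose.
#' @param log_base declared log base of the stored values.
#' @param dose_units free-text units label.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, dose_map, log_base = 2,
                                   dose_units = "") {
  sep <- detect_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
  if (ncol(tab) < 2) stop("matrix file needs a probe column plus samples")
  probe_ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals))
  bad <- which(is.na(num) & !(vals %in% c("NA", "NaN", "")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                 probe_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(probe_ids, colnames(vals))

  doses <- resolve_dose_map(dose_map)
  missing <- setdiff(colnames(num), names(doses))
  if (length(missing) > 0)
    stop("sample(s) missing a dose: ", paste(missing, collapse = ", "))
  expression_dataset(num, doses[colnames(num)], log_base = log_base,
                     dose_units = dose_units)
}

resolve_dose_map <- function(dose_map) {
  if (is.character(dose_map) && length(dose_map) == 1 && file.exists(dose_map)) {
    sep <- detect_sep(dose_map)
    dose_map <- read.table(dose_map, header = TRUE, sep = sep,
                           check.names = FALSE)
  }
  if (is.data.frame(dose_map)) {
    stopifnot(ncol(dose_map) >= 2)
    doses <- as.numeric(dose_map[[2]])
    names(doses) <- as.character(dose_map[[1]])
    return(doses)
  }
  if (is.numeric(dose_map) && !is.null(names(dose_map))) return(dose_map)
  stop("dose_map must be a named numeric vector, data frame, or file path")
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write an expression dataset back to delimited text
#'
#' Writes the matrix (tab-separated, probe ids in the first column) and
#' returns the path invisibly. `read_expression_matrix()` on the result
#' reproduces the values bit-exactly.
#'
#' @param ds an [expression_dataset()].
#' @param path output file path.
#' @param dose_path optional path for a two-column sample/dose table.
#' @export
write_expression_matrix <- function(ds, path, dose_path = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  tab <- data.frame(probe_id = ds$probe_ids,
                    format(ds$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  colnames(tab) <- c("probe_id", ds$sample_ids)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dose_path)) {
    write.table(data.frame(sample_id = ds$sample_ids, dose = ds$doses),
                dose_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Summarize an expression dataset
#'
#' Flags probes that cannot enter dose-response screening: any missing or
#' non-finite value, or zero variance across all samples (a constant probe
#' breaks the pooled within-group SD of the trend statistic).
#'
#' @param ds an [expression_dataset()].
#' @return A list of class `dataset_summary`: `n_dose_levels`,
#'   `n_samples_per_level`, `n_valid_probes`, `n_invalid_probes`, and
#'   `invalid_reasons` (named character vector over invalid probes).
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  lev <- dose_levels(ds)
  nonfinite <- !apply(is.finite(ds$values), 1, all)
  v <- apply(ds$values, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 2) 0 else stats::var(r)
  })
  zerovar <- !nonfinite & v == 0
  reasons <- c(
    stats::setNames(rep("non-finite value", sum(nonfinite)),
                    ds$probe_ids[nonfinite]),
    stats::setNames(rep("zero variance", sum(zerovar)),
                    ds$probe_ids[zerovar])
  )
  structure(list(
    n_dose_levels = nrow(lev),
    n_samples_per_level = stats::setNames(lev$n, lev$dose),
    n_valid_probes = nrow(ds$values) - length(reasons),
    n_invalid_probes = length(reasons),
    invalid_reasons = reasons
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("%d dose levels; samples per level: %s\n", x$n_dose_levels,
              paste(x$n_samples_per_level, collapse = ", ")))
  cat(sprintf("%d valid probes, %d invalid\n", x$n_valid_probes,
              x$n_invalid_probes))
  invisible(x)
}

valid_probe_ids <- function(ds) {
  s <- summarize_dataset(ds)
  setdiff(ds$probe_ids, names(s$invalid_reasons))
}

#' Read gene-set categories from a GMT file
#'
#' One tab-separated line per category: id, description, then one or more
#' gene ids.
#'
#' @param path GMT file path.
#' @param source_label free-text label for the annotation source.
#' @return A `gene_annotation` object with `categories` only; combine with
#'   [read_probe_map()] via [gene_annotation()].
#' @export
read_gmt <- function(path, source_label = "GMT") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cats <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has no genes (id '%s')", i, f[1]))
    genes <- unique(f[-(1:2)])
    if (any(!nzchar(genes))) stop(sprintf("GMT line %d has an empty gene id", i))
    list(id = f[1], name = f[2], genes = genes)
  })
  ids <- vapply(cats, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated category id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(cats) <- ids
  gene_annotation(probe_to_genes = list(), categories = cats,
                  source_label = source_label)
}

#' Read a probe-to-gene map
#'
#' Two-column delimited text (header required), one row per probe-gene
#' pair; probes listed with several gene rows map to a multi-gene set.
#'
#' @param path file path.
#' @return Named list mapping probe id to a character vector of gene ids.
#' @export
read_probe_map <- function(path) {
  sep <- detect_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("probe map needs two columns: probe, gene")
  if (any(!nzchar(tab[[1]])) || any(!nzchar(tab[[2]])))
    stop("probe map contains an empty probe or gene id")
  split(tab[[2]], tab[[1]]) |> lapply(unique)
}

#' Bundle a probe map and gene-set categories
#'
#' @param probe_to_genes named list: probe id -> character vector of genes.
#' @param categories named list of `list(id, name, genes)` entries (as
#'   produced by [read_gmt()]), or an existing `gene_annotation`.
#' @param source_label free text (e.g. `"GO-BP"`, `"REACTOME"`).
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(probe_to_genes = list(), categories = list(),
                            source_label = "") {
  if (inherits(categories, "gene_annotation")) categories <- categories$categories
  for (cat in categories) {
    if (length(cat$genes) < 1)
      stop(sprintf("category '%s' has no genes", cat$id))
  }
  structure(list(probe_to_genes = probe_to_genes, categories = categories,
                 source_label = source_label),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation [%s]: %d probes mapped, %d categories\n",
              x$source_label, length(x$probe_to_genes), length(x$categories)))
  invisible(x)
}
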