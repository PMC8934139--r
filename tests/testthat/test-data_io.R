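test_that("a delimited matrix with a dose map parses into a dose-sorted dataset", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  tab <- data.frame(probe_id = c("a", "b", "c"),
                    s1 = c(1, 2, 3), s4 = c(4, 5, 6), s2 = c(7, 8, 9),
                    s5 = c(1.5, 2.5, 3.5), s3 = c(2, 3, 4), s6 = c(5, 6, 7))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  doses <- c(s1 = 0, s2 = 0, s3 = 1, s4 = 1, s5 = 10, s6 = 10)
  ds <- read_expression_matrix(path, doses, log_base = 2)
  lev <- dose_levels(ds)
  expect_equal(lev$dose, c(0, 1, 10))
  expect_equal(lev$n, c(2L, 2L, 2L))
  # columns re-sorted by ascending dose, ties stable by file column order
  expect_equal(ds$sample_ids, c("s1", "s2", "s4", "s3", "s5", "s6"))
  expect_equal(unname(ds$values["a", "s4"]), 4)
})

test_that("input validation names the offending probe, sample, or cell", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.csv")
  writeLines(c("probe_id,s1,s2", "dup,1,2", "dup,3,4"), path)
  expect_error(read_expression_matrix(path, c(s1 = 0, s2 = 1)), "dup")

  writeLines(c("probe_id,s1,s2", "a,1,oops"), path)
  expect_error(read_expression_matrix(path, c(s1 = 0, s2 = 1)), "non-numeric")

  writeLines(c("probe_id,s1,s2", "a,1,2"), path)
  expect_error(read_expression_matrix(path, c(s1 = 0)), "missing a dose")
  expect_error(read_expression_matrix(path, c(s1 = -1, s2 = 1)),
               "non-negative")
  expect_error(read_expression_matrix(path, c(s1 = 2, s2 = 2)),
               "2 distinct dose levels")
})

test_that("write/read round-trip reproduces values bit-exactly", {
  set.seed(11)
  m <- matrix(rnorm(40, 8, 2), 4, 10,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  ds <- expression_dataset(m, rep(c(0, 1, 5, 25, 100), each = 2))
  dir <- withr::local_tempdir()
  write_expression_matrix(ds, file.path(dir, "m.tsv"),
                          file.path(dir, "d.tsv"))
  ds2 <- read_expression_matrix(file.path(dir, "m.tsv"),
                                file.path(dir, "d.tsv"))
  expect_identical(ds2$values, ds$values)
  expect_identical(ds2$doses, ds$doses)
})

test_that("dataset summary flags non-finite and zero-variance probes with reasons", {
  ds <- toy_dataset()
  s <- summarize_dataset(ds)
  expect_equal(s$n_dose_levels, 3)
  expect_equal(s$n_invalid_probes, 1)
  expect_equal(unname(s$invalid_reasons["p_flat"]), "zero variance")
  expect_equal(s$n_valid_probes + s$n_invalid_probes, nrow(ds$values))

  vals <- matrix(rnorm(100 * 6, 8), 100, 6)
  vals[sample(100, 7), 3] <- NA
  ds2 <- expression_dataset(vals, c(0, 0, 1, 1, 2, 2))
  s2 <- summarize_dataset(ds2)
  expect_equal(s2$n_invalid_probes, 7)
  expect_true(all(s2$invalid_reasons == "non-finite value"))

  ds3 <- expression_dataset(matrix(rnorm(12, 8), 2, 6), c(0, 0, 1, 1, 2, 2))
  expect_equal(summarize_dataset(ds3)$n_invalid_probes, 0)
})

test_that("GMT and probe-map readers build the annotation", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("P1\tdesc one\tg1\tg2", "P2\tdesc two\tg3"), gmt)
  ann <- read_gmt(gmt)
  expect_equal(sort(ann$categories$P1$genes), c("g1", "g2"))
  expect_equal(ann$categories$P2$genes, "g3")

  writeLines(c("P1\tdesc"), gmt)
  expect_error(read_gmt(gmt), "no genes")

  pm_path <- file.path(dir, "map.tsv")
  writeLines(c("probe\tgene", "pA\tg1", "pA\tg2", "pB\tg3"), pm_path)
  pm <- read_probe_map(pm_path)
  expect_equal(sort(pm$pA), c("g1", "g2"))
  expect_equal(pm$pB, "g3")
})

test_that("screening statistics are invariant to input column order", {
  set.seed(21)
  m <- matrix(rnorm(5 * 12, 8), 5, 12,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:12)))
  m[1, ] <- m[1, ] + rep(c(0, 0.5, 1, 2), each = 3)
  doses <- rep(c(0, 1, 5, 25), each = 3)
  perm <- sample(12)
  ds1 <- expression_dataset(m, doses)
  ds2 <- expression_dataset(m[, perm], doses[perm],
                            sample_ids = colnames(m)[perm])
  s1 <- screen_probes(ds1, filter_settings(tests = "anova"))
  s2 <- screen_probes(ds2, filter_settings(tests = "anova"))
  expect_equal(s1$fold_change, s2$fold_change)
  expect_equal(s1$p_anova, s2$p_anova)
  expect_equal(s1$passed, s2$passed)
})
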