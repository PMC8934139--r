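make_ann <- function() {
  pm <- list(p1 = "g1", p2 = "g2", p3 = "g3", p4 = "g4",
             p5 = c("g5", "g6"),        # multi-gene probe: removed
             p6 = "g2",                 # second probe for g2
             p7 = "g7", p8 = "g8")
  cats <- list(
    A = list(id = "A", name = "cat A", genes = c("g1", "g2", "g3")),
    B = list(id = "B", name = "cat B", genes = c("g4", "g7", "g8")),
    C = list(id = "C", name = "cat C", genes = "g7"))
  gene_annotation(pm, cats, "toy")
}

test_that("probe-to-gene collapse removes multi-gene probes and averages duplicates", {
  est <- data.frame(probe_id = c("p1", "p2", "p5", "p6", "px"),
                    bmd = c(5, 2, 9, 4, 1),
                    bmdl = c(2.5, 1, 4, 3, 0.5),
                    bmdu = c(8, 3, 20, 5, 2))
  gt <- map_probes_to_genes(est, make_ann())
  expect_setequal(gt$gene, c("g1", "g2")) # p5 multi-gene out, px unmapped out
  expect_equal(gt$bmd[gt$gene == "g2"], 3)  # mean of 2 and 4
  expect_equal(gt$bmdl[gt$gene == "g2"], 2) # mean of 1 and 3
  expect_equal(gt$n_probes[gt$gene == "g2"], 2L)
  expect_error(map_probes_to_genes(est, gene_annotation()), "empty")
})

test_that("Fisher two-tailed p equals hypergeometric enumeration", {
  expect_equal(fisher_enrichment(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_enrichment(1, 1, 1, 1), 1, tolerance = 1e-12)
  set.seed(221)
  for (r in 1:200) {
    tab <- as.vector(rmultinom(1, sample(4:20, 1), rep(0.25, 4)))
    if (sum(tab) == 0) next
    expect_equal(fisher_enrichment(tab[1], tab[2], tab[3], tab[4]),
                 fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10,
                 info = paste(tab, collapse = ","))
  }
  expect_error(fisher_enrichment(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_enrichment(0, 0, 0, 0), "all-zero")
})

test_that("category aggregation computes BMD statistics over responsive genes", {
  ann <- make_ann()
  gt <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   bmd = c(1, 2, 3, 10), bmdl = c(0.5, 1, 2, 6),
                   bmdu = c(2, 3, 4, 30))
  res <- aggregate_categories(gt, ann)
  a <- res[res$category_id == "A", ]
  expect_equal(a$genes_with_bmd, 3)
  expect_equal(c(a$bmd_min, a$bmd_max, a$bmd_mean, a$bmd_median),
               c(1, 3, 2, 2))
  b <- res[res$category_id == "B", ]
  expect_equal(b$genes_with_bmd, 1) # g7, g8 lack BMDs and stay out
  expect_equal(b$bmd_median, 10)
  cc <- res[res$category_id == "C", ]
  expect_equal(cc$genes_with_bmd, 0)
  expect_true(is.na(cc$bmd_median))
  # single gene category statistics collapse to the value
  gt2 <- data.frame(gene = "g7", bmd = 5, bmdl = 2, bmdu = 9)
  res2 <- aggregate_categories(gt2, ann)
  c2 <- res2[res2$category_id == "C", ]
  expect_equal(c(c2$bmd_min, c2$bmd_max, c2$bmd_mean, c2$bmd_median),
               rep(5, 4))
})

test_that("aggregation is invariant to category and gene ordering", {
  ann <- make_ann()
  ann_rev <- gene_annotation(ann$probe_to_genes,
                             lapply(rev(ann$categories), function(ct) {
                               ct$genes <- rev(ct$genes); ct
                             }), "toy")
  gt <- data.frame(gene = c("g3", "g1", "g2"), bmd = c(3, 1, 2),
                   bmdl = c(2, 0.5, 1), bmdu = c(4, 2, 3))
  r1 <- aggregate_categories(gt, ann)
  r2 <- aggregate_categories(gt[c(2, 3, 1), ], ann_rev)
  r2 <- r2[match(r1$category_id, r2$category_id), ]
  expect_equal(r1$p_fisher, r2$p_fisher)
  expect_equal(r1$bmd_median, r2$bmd_median)
})

test_that("percentage and the enrichment filter apply their boundary rules", {
  expect_equal(percentage(3, 100), 0.03)
  expect_equal(percentage(0, 10), 0)
  expect_equal(percentage(10, 10), 1)
  expect_error(percentage(1, 0), "no genes")

  res <- data.frame(
    category_id = c("only_one_gene", "p_at_cutoff", "pct_at_cutoff", "good"),
    name = "", genes_with_bmd = c(1, 5, 3, 4),
    genes_total = c(10, 50, 100, 40),
    p_fisher = c(0.001, 0.05, 0.01, 0.002),
    percentage = c(0.1, 0.1, 0.03, 0.1),
    bmd_min = 1, bmd_max = 3, bmd_mean = 2, bmd_median = 2,
    bmdl_median = 1, bmdu_median = 4)
  enr <- select_enriched(res)
  # >1 gene strict, p < 0.05 strict, percentage >= 3% inclusive
  expect_setequal(enr$category_id, c("pct_at_cutoff", "good"))
})

test_that("BEPOD is the median of enriched category medians", {
  enr1 <- data.frame(category_id = "A", bmd_median = 7)
  expect_equal(compute_bepod(enr1)$bepod, 7)
  enr3 <- data.frame(category_id = c("A", "B", "C"),
                     bmd_median = c(1, 2, 9))
  expect_equal(compute_bepod(enr3)$bepod, 2)
  enr2 <- data.frame(category_id = c("A", "B"), bmd_median = c(1, 9))
  expect_equal(compute_bepod(enr2)$bepod, 5) # even count: mean of middle two
  none <- compute_bepod(enr2[0, ])
  expect_true(is.na(none$bepod))
  expect_output(print(none), "no BEPOD")
})

test_that("BEPOD scales with the dose units", {
  ann <- make_ann()
  est <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    bmd = c(1, 2, 3, 4), bmdl = c(0.5, 1, 2, 3),
                    bmdu = c(2, 3, 4, 5))
  pa1 <- pathway_analysis(est, ann, p_cut = 1.1, min_pct = 0)
  est10 <- est
  est10[, c("bmd", "bmdl", "bmdu")] <- est[, c("bmd", "bmdl", "bmdu")] * 10
  pa10 <- pathway_analysis(est10, ann, p_cut = 1.1, min_pct = 0)
  expect_equal(pa10$bepod$bepod, 10 * pa1$bepod$bepod)
})

test_that("POD correlation is computed on the log10 scale", {
  b <- c(2, 8, 30, 120)
  expect_equal(unname(correlate_pod(b, b)), c(1, 0))
  expect_equal(unname(correlate_pod(b, 10 * b)), c(1, 1), tolerance = 1e-12)
  set.seed(231)
  x <- rlnorm(20, 2, 1); y <- rlnorm(20, 2, 1)
  r <- correlate_pod(x, y)
  lx <- log10(x); ly <- log10(y)
  r_direct <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(unname(r[["pearson_r"]]), r_direct, tolerance = 1e-10)
  expect_equal(unname(r[["rmsd"]]), sqrt(mean((lx - ly)^2)),
               tolerance = 1e-10)
  expect_error(correlate_pod(c(1, -2), c(1, 2)), "positive")
  expect_error(correlate_pod(1, 1), "length")
})

test_that("cumulative distribution tables are monotone with collapsed ties", {
  t1 <- cdc_table(c(3, 1, 2))
  expect_equal(t1$value, c(1, 2, 3))
  expect_equal(t1$cum_fraction, c(1, 2, 3) / 3)
  t2 <- cdc_table(c(1, 2, 2, 5))
  expect_equal(t2$value, c(1, 2, 5))
  expect_equal(t2$cum_fraction, c(0.25, 0.75, 1))
  expect_true(all(diff(t2$value) > 0) && all(diff(t2$cum_fraction) > 0))
})
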