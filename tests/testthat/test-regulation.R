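test_that("editing-expression regression recovers a planted coefficient", {
  set.seed(21)
  n <- 100
  editing <- runif(n, 0, 0.6)
  age <- rnorm(n, 55, 10)
  logexpr <- 1 + 2 * editing + 0.01 * age + rnorm(n, 0, 0.1)
  fit <- editing_expression_fit(editing, exp(logexpr) - 0.5, age)
  expect_lt(abs(fit$coef - 2), 0.2)
  expect_lt(fit$p, 1e-6)

  # permuted editing: no association
  fit0 <- editing_expression_fit(sample(editing), exp(logexpr) - 0.5, age)
  expect_gt(fit0$p, 1e-4)

  expect_error(editing_expression_fit(rep(0.2, n), exp(logexpr), age),
               "non-informative")
  expect_error(editing_expression_fit(editing[1:5], exp(logexpr[1:5]),
                                      age[1:5]), "fewer than")
})

test_that("knockdown classification follows the 12-case truth table exactly", {
  kd <- function(lfc, padj) structure(
    data.frame(gene = "G", log2fc = lfc, pvalue = padj / 2, padj = padj),
    class = c("de_table", "data.frame"))
  cases <- expand.grid(coef = c(1.5, -1.5, 0),
                       lfc = c(2, -2),
                       padj = c(0.001, 0.2))
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    res <- classify_regulated(cc$coef, "G", kd(cc$lfc, cc$padj))
    expected <- cc$padj < 0.05 && sign(cc$lfc) == -sign(cc$coef) &&
      cc$coef != 0
    expect_identical(res$regulated, expected,
                     label = sprintf("coef=%g lfc=%g padj=%g", cc$coef,
                                     cc$lfc, cc$padj))
    expect_false(res$untested)
  }
  # absent gene: untested, never counted as failing
  res <- classify_regulated(1.5, "ABSENT", kd(-2, 0.001))
  expect_false(res$regulated)
  expect_true(res$untested)
})

test_that("expression-correlated site selection applies FDR and per-gene collapse", {
  rec <- structure(data.frame(
    site_id = sprintf("chr1:%d+", 1:4),
    gene = c("A", "A", "B", "C"), region = "3'UTR",
    coef = c(2, 1, -1, 1), p = c(0.001, 0.005, 0.002, 0.9), n = 50),
    class = c("regulation_records", "data.frame"))
  rec$fdr <- bh_adjust(rec$p)
  sel <- expression_correlated_sites(rec, fdr_threshold = 0.10)
  expect_setequal(sel$sites, sprintf("chr1:%d+", 1:3))
  # gene A collapses to its smallest-FDR site
  expect_equal(sel$per_gene$site_id[sel$per_gene$gene == "A"], "chr1:1+")

  # all p = 1: empty; single p = 0.01: BH identity for n = 1
  rec1 <- rec; rec1$p <- 1; rec1$fdr <- 1
  expect_equal(length(expression_correlated_sites(rec1)$sites), 0)
  rec2 <- rec[1, ]; rec2$p <- 0.01; rec2$fdr <- bh_adjust(rec2$p)
  expect_equal(expression_correlated_sites(rec2)$per_gene$fdr, 0.01)
})

test_that("region enrichment matches exact hypergeometric enumeration", {
  ann <- data.frame(
    site_id = sprintf("chr1:%d+", 1:20),
    gene = "G",
    region = rep(c("3'UTR", "intronic"), each = 10))
  # balanced table: OR 1, p 1
  fg <- sprintf("chr1:%d+", c(1:5, 11:15))
  res <- region_enrichment(fg, ann$site_id, ann)
  expect_equal(res$p, 1)
  expect_equal(unname(res$table), matrix(c(5, 5, 5, 5), 2, byrow = TRUE))

  # skewed table vs. enumeration oracle
  fg <- sprintf("chr1:%d+", c(1:8, 11, 12))
  res <- region_enrichment(fg, ann$site_id, ann)
  expect_equal(unname(res$table[1, ]), c(8, 2))
  expect_equal(res$p, fisher_oracle(res$table), tolerance = 1e-9)

  # intergenic sites are excluded from the background
  ann2 <- ann; ann2$region[20] <- "intergenic"
  res2 <- region_enrichment(fg, ann2$site_id, ann2)
  expect_equal(sum(res2$table), 19)

  expect_error(region_enrichment(c(fg, "chr9:1+"), ann$site_id, ann),
               "subset")
})

test_that("knockdown direction test is the exact two-sided binomial", {
  reg <- data.frame(gene = sprintf("G%d", 1:10), coef = 1,
                    kd_log2fc = -1, kd_padj = 0.001, regulated = TRUE)
  res <- direction_binomial(reg)
  expect_equal(res$fraction_reduced, 1)
  expect_equal(res$p, 2 * 0.5^10)

  reg$kd_log2fc <- rep(c(-1, 1), 5)
  expect_equal(direction_binomial(reg)$p, 1)

  reg$regulated <- FALSE
  expect_message(res0 <- direction_binomial(reg), "no regulated")
  expect_null(res0)
})

test_that("regulation pipeline recovers planted regulated genes on one cohort", {
  sim <- simulate_cohort(sim_config(n_samples = 100, n_sites = 300,
                                    n_informative = 30, n_regulated = 30,
                                    n_genes = 300, seed = 55))
  rec <- fit_regulation(sim$mat, sim$expr, sim$meta, sim$annotation)
  rg <- regulated_genes(rec, sim$kd)
  called <- rg$gene[rg$regulated]
  truth <- names(sim$truth$regulated_genes)
  expect_gte(mean(truth %in% called), 0.9)
  if (length(called)) expect_lte(mean(!(called %in% truth)), 0.1)
})

test_that("prognostic screen finds opposite-sign sites per sex and skips constants", {
  sim <- simulate_cohort(sim_config(n_samples = 150, n_sites = 200,
                                    n_informative = 20, delta_edit = 0.25,
                                    hr_female = 4, hr_male = 1 / 4,
                                    balanced_clusters = TRUE, seed = 66))
  scr <- prognostic_screen(sim$mat, sim$meta, rownames(sim$mat$level))
  hits <- scr[scr$prognostic, ]
  # detected informative sites must carry the planted direction:
  # hyper-editing raises hazard in females, lowers it in males
  inf_hits <- hits[hits$site_id %in% sim$truth$informative_sites, ]
  if (nrow(inf_hits)) {
    fem <- inf_hits[inf_hits$sex == "female", ]
    mal <- inf_hits[inf_hits$sex == "male", ]
    if (nrow(fem)) expect_gte(mean(fem$hr_age_adj > 1), 0.9)
    if (nrow(mal)) expect_gte(mean(mal$hr_age_adj < 1), 0.9)
  }
  # a site constant within a sex is skipped for that sex
  lev <- sim$mat$level
  lev[1, sim$meta$sex == "female"] <- 0.5
  g <- sim$mat$g; cov <- sim$mat$cov
  g[1, sim$meta$sex == "female"] <- 50L
  cov[1, sim$meta$sex == "female"] <- 100L
  m2 <- editing_matrix(lev, g, cov)
  scr2 <- prognostic_screen(m2, sim$meta, rownames(m2$level)[1])
  expect_false("female" %in% scr2$sex)
})
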