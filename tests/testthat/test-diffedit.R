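make_level_matrix <- function(lev) {
  cov <- matrix(1000L, nrow(lev), ncol(lev), dimnames = dimnames(lev))
  g <- round(lev * 1000)
  editing_matrix(g / cov, g, cov)
}

test_that("comparisons validate their sample sets", {
  expect_error(comparison("F1", c("A", "B"), c("B", "C"), "female"),
               "overlap")
  expect_error(comparison("F1", character(0), "C", "female"), "non-empty")
  cmp <- comparison("F1", c("A", "B"), c("C", "D"), "female")
  expect_s3_class(cmp, "comparison")
})

test_that("pre-filter cascade reproduces the fixture truth rule by rule", {
  fx <- make_fixtures()
  out <- prefilter_sites(fx$prefilter, fx$prefilter_comparison)
  expect_identical(rownames(out$level), fx$prefilter_truth)
  log <- attr(out, "removal_log")
  expect_equal(unname(log["low_variation"]), 4)
  expect_equal(unname(log["small_median_diff"]), 2)

  # site at median difference exactly 0.03 is removed ("<= 3%")
  lev <- rbind(`chr1:1+` = c(0.20, 0.21, 0.22, 0.17, 0.18, 0.19),
               `chr1:2+` = c(0.40, 0.45, 0.50, 0.10, 0.15, 0.20))
  colnames(lev) <- c("A", "B", "C", "D", "E", "F")
  m <- make_level_matrix(lev)
  cmp <- comparison("X", c("A", "B", "C"), c("D", "E", "F"), "male")
  out <- prefilter_sites(m, cmp)
  expect_identical(rownames(out$level), "chr1:2+")  # 0.03 case dropped
  expect_error(prefilter_sites(m[1, ], cmp), "no sites")
})

test_that("Mann-Whitney p-values match exhaustive enumeration for small groups", {
  lev <- rbind(`chr1:1+` = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  colnames(lev) <- c("A", "B", "C", "D", "E", "F")
  m <- make_level_matrix(lev)
  cmp <- comparison("X", c("A", "B", "C"), c("D", "E", "F"), "male")
  des <- test_des(m, cmp)
  expect_equal(des$p, 0.1)   # 2 * 1/C(6,3)
  expect_equal(des$p, mw_exact_oracle(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)))
  expect_equal(des$median_diff, -0.3)

  set.seed(77)
  for (sizes in list(c(3, 4), c(4, 4), c(5, 6), c(8, 8))) {
    vals <- sample(seq(0.01, 0.99, by = 0.01), sum(sizes))
    lev <- matrix(vals, 1, dimnames = list("chr1:5+",
                                           sprintf("S%02d", seq_along(vals))))
    m <- make_level_matrix(lev)
    cmp <- comparison("X", colnames(lev)[seq_len(sizes[1])],
                      colnames(lev)[-seq_len(sizes[1])], "male")
    des <- test_des(m, cmp)
    expect_equal(des$p, mw_exact_oracle(vals[seq_len(sizes[1])],
                                        vals[-seq_len(sizes[1])]),
                 tolerance = 1e-12)
  }
})

test_that("identical groups are never differentially edited", {
  lev <- matrix(rep(c(0.1, 0.3, 0.5, 0.7), 2), 1,
                dimnames = list("chr1:9+", sprintf("S%d", 1:8)))
  m <- make_level_matrix(lev)
  cmp <- comparison("X", sprintf("S%d", 1:4), sprintf("S%d", 5:8), "male")
  des <- test_des(m, cmp)
  expect_gte(des$p, 0.9)
  expect_false(des$is_des)
})

test_that("sites with too few observations are skipped and logged", {
  lev <- rbind(`chr1:1+` = c(0.1, NA, NA, 0.5, 0.6, 0.7),
               `chr1:2+` = c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8))
  colnames(lev) <- sprintf("S%d", 1:6)
  cov <- matrix(100L, 2, 6, dimnames = dimnames(lev))
  g <- round(lev * 100)
  cov[is.na(lev)] <- NA; g[is.na(lev)] <- NA
  m <- editing_matrix(g / cov, g, cov)
  cmp <- comparison("X", sprintf("S%d", 1:3), sprintf("S%d", 4:6), "male")
  des <- test_des(m, cmp)
  expect_equal(des$site_id, "chr1:2+")
  expect_identical(attr(des, "skipped_sites"), "chr1:1+")
})

test_that("BH family is the comparison's tested sites only", {
  set.seed(12)
  lev <- matrix(runif(10 * 12, 0.1, 0.9), 10,
                dimnames = list(sprintf("chr1:%d+", 1:10),
                                sprintf("S%02d", 1:12)))
  m <- make_level_matrix(lev)
  cmp <- comparison("X", sprintf("S%02d", 1:6), sprintf("S%02d", 7:12), "male")
  des <- test_des(m, cmp)
  expect_equal(des$padj, bh_oracle(des$p), tolerance = 1e-12)
})

test_that("gene-level aggregation and signed ranking follow the published rules", {
  rec <- structure(data.frame(
    site_id = c("chr1:1+", "chr1:2+", "chr1:3+", "chr1:4+"),
    comparison = "X",
    median_diff = c(0.1, -0.2, 0.15, 0.05),
    u_stat = 1, p = c(0.01, 0.001, 0.04, 0.2),
    padj = c(0.02, 0.004, 0.04, 0.2),
    is_des = c(TRUE, TRUE, TRUE, FALSE)),
    class = c("des_records", "data.frame"))
  ann <- data.frame(site_id = c("chr1:1+", "chr1:2+", "chr1:3+", "chr1:4+"),
                    gene = c("A", "B", "A", ""),
                    region = "3'UTR")
  genes <- genes_with_des(rec, ann)
  expect_identical(as.character(genes), c("A", "B"))
  expect_equal(attr(genes, "unannotated"), 0)

  rk <- rank_genes_signed(rec, ann)
  # gene A is represented by its most significant site (p = 0.01, diff > 0)
  expect_equal(rk$score[rk$gene == "A"], 2)
  expect_equal(rk$site_id[rk$gene == "A"], "chr1:1+")
  expect_equal(rk$score[rk$gene == "B"], -3)
  expect_identical(rk$gene, c("A", "B"))  # descending score

  # all-positive differences reduce to pure significance ordering
  rec2 <- rec; rec2$median_diff <- abs(rec2$median_diff)
  ann2 <- ann; ann2$gene <- c("A", "B", "C", "D")
  rk2 <- rank_genes_signed(rec2, ann2)
  expect_identical(rk2$gene, c("B", "A", "C", "D"))
})

test_that("RRHO grid matches brute-force hypergeometric enumeration", {
  genes <- letters[1:8]
  set.seed(5)
  l1 <- sample(genes); l2 <- sample(genes)
  rr <- rrho_map(l1, l2, step = 2)
  for (a in seq_along(rr$thresholds)) for (b in seq_along(rr$thresholds)) {
    i <- rr$thresholds[a]; j <- rr$thresholds[b]
    k <- length(intersect(head(l1, i), head(l2, j)))
    expect_equal(rr$overlap[a, b], k)
    expect_equal(10^(-rr$neg_log10_p[a, b]), hyper_tail_oracle(k, i, 8 - i, j),
                 tolerance = 1e-9)
  }
  # identical lists: diagonal overlap is complete
  rr_self <- rrho_map(l1, l1, step = 2)
  expect_equal(unname(diag(rr_self$overlap)), rr_self$thresholds)
  expect_error(rrho_map(l1, l2, step = 8), "step")
})
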