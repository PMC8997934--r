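test_that("site identifiers parse, format, and round-trip", {
  s <- parse_site_id("chr8:56069413-")
  expect_equal(s$chrom, "chr8")
  expect_equal(s$pos, 56069413L)
  expect_equal(s$strand, "-")
  s2 <- parse_site_id("chr1:45509673+")
  expect_equal(s2$pos, 45509673L)
  expect_equal(s2$strand, "+")

  tokens <- c("chr8:56069413-", "chr1:45509673+", "chrX:119538709-",
              "chr19:13773078+")
  expect_identical(format_site_id(parse_site_id(tokens)), tokens)

  expect_error(parse_site_id("chr1:123"), "malformed")
  expect_error(parse_site_id("chr1:12.3+"), "malformed")
  expect_error(parse_site_id("1:abc+"), "malformed")
})

test_that("canonical site ordering is natural by chromosome, then position, then strand", {
  tokens <- c("chr10:5+", "chr2:10-", "chr2:10+", "chr2:9-", "chrX:1+",
              "chr1:100+")
  s <- parse_site_id(tokens)
  ord <- order_sites(s)
  expect_identical(s$site_id[ord],
                   c("chr1:100+", "chr2:9-", "chr2:10+", "chr2:10-",
                     "chr10:5+", "chrX:1+"))
})

test_that("editing matrix enforces cell invariants with cell coordinates", {
  g <- matrix(c(2L, 5L, 0L, 1L), 2, 2,
              dimnames = list(c("chr1:10+", "chr1:20-"), c("A", "B")))
  cov <- matrix(c(10L, 10L, 10L, 10L), 2, 2, dimnames = dimnames(g))
  m <- em_from_counts(g, cov)
  expect_s3_class(m, "editing_matrix")
  expect_equal(m$level["chr1:10+", "A"], 0.2)

  bad_cov <- cov; bad_cov["chr1:20-", "A"] <- 3L
  expect_error(em_from_counts(g, bad_cov), "g_reads > coverage.*chr1:20-/A")

  lev <- g / cov; lev[1, 1] <- 0.5   # inconsistent with counts
  expect_error(editing_matrix(lev, g, cov), "level inconsistent")

  g2 <- rbind(g, g[1, , drop = FALSE])
  cov2 <- rbind(cov, cov[1, , drop = FALSE])
  expect_error(em_from_counts(g2, cov2), "duplicate")
})

test_that("editing matrix TSV write/read round-trips cell-identically", {
  set.seed(42)
  cov <- matrix(rpois(12, 30), 3, 4,
                dimnames = list(c("chr2:5+", "chr1:9-", "chr10:2+"),
                                sprintf("S%d", 1:4)))
  g <- matrix(rbinom(12, as.vector(cov), 0.2), 3, 4, dimnames = dimnames(cov))
  cov[2, 3] <- NA; g[2, 3] <- NA          # absent cell
  cov[3, 1] <- 0L; g[3, 1] <- 0L          # zero coverage, level undefined
  m <- em_from_counts(g, cov)
  f <- tempfile(fileext = ".tsv")
  write_editing_matrix(m, f)
  m2 <- read_editing_matrix(f)
  # reader orders sites canonically; compare on the common order
  ord <- rownames(m2$level)
  expect_equal(m2$level, m$level[ord, ])
  expect_equal(m2$g, m$g[ord, ] + 0)
  expect_equal(m2$cov, m$cov[ord, ] + 0)
  # byte-identical re-write
  f2 <- tempfile(fileext = ".tsv")
  write_editing_matrix(m2, f2)
  f3 <- tempfile(fileext = ".tsv")
  write_editing_matrix(read_editing_matrix(f2), f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("matrix reader rejects inconsistent, percent, and duplicate rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("site_id\tsample_id\tg_reads\tcov\tlevel",
               "chr1:10+\tA\t5\t3\t0.5"), f)
  expect_error(read_editing_matrix(f), "g_reads > coverage")

  writeLines(c("site_id\tsample_id\tg_reads\tcov\tlevel",
               "chr1:10+\tA\t2\t10\t0.2",
               "chr1:10+\tA\t2\t10\t0.2"), f)
  expect_error(read_editing_matrix(f), "duplicate")

  writeLines(c("site_id\tsample_id\tg_reads\tcov\tlevel",
               "chr1:10+\tA\t3\t100\t3%"), f)
  expect_error(read_editing_matrix(f), "percent")

  writeLines(c("site_id\tsample_id\tg_reads\tcov\tlevel",
               "chr1:10+\tA\t2\t10\t0.2"), f)
  m <- read_editing_matrix(f)
  expect_equal(m$level[1, 1], 0.2)
})

test_that("metadata, DE-table, and annotation readers validate their inputs", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tage\ttime\tevent",
               "S1\tfemale\t60\t100\t2"), f)
  expect_error(read_cohort_meta(f), "event")

  writeLines(c("sample_id\tsex\tage\ttime", "S1\tfemale\t60\t100"), f)
  expect_error(read_cohort_meta(f), "missing column.*event")

  writeLines(c("sample_id\tsex\tage\ttime\tevent",
               "S1\tfemale\t60\t100\t1", "S2\tmale\t50\t350\t0"), f)
  meta <- read_cohort_meta(f)
  expect_s3_class(meta, "cohort_meta")

  writeLines(c("gene\tlog2fc\tpvalue\tpadj", "GENE1\t-1.2\t0.001\t0.01"), f)
  de <- read_de_table(f)
  expect_equal(de$log2fc, -1.2)
  writeLines(c("gene\tlog2fc\tpvalue\tpadj", "GENE1\t-1.2\t0.05\t0.01"), f)
  expect_error(read_de_table(f), "padj smaller")

  writeLines(c("site_id\tgene\tregion",
               "chr2:100+\tGENE1\t3'UTR",
               "chr2:200-\tGENE2\tweird_label"), f)
  expect_warning(ann <- read_annotation(f), "unknown region")
  expect_equal(ann$region, c("3'UTR", "other"))
})
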