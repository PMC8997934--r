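test_that("generation is byte-identical given the same seed", {
  a <- simulate_cohort(sim_config(n_samples = 40, n_sites = 100, seed = 5,
                                  n_informative = 20))
  b <- simulate_cohort(sim_config(n_samples = 40, n_sites = 100, seed = 5,
                                  n_informative = 20))
  expect_identical(a$mat$level, b$mat$level)
  expect_identical(a$meta, b$meta)
  expect_identical(a$expr, b$expr)
  expect_identical(a$kd, b$kd)
  expect_identical(a$truth, b$truth)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_sites = 10, n_informative = 20))
  expect_error(sim_config(n_regulated = 50, n_informative = 20))
  expect_error(sim_config(delta_edit = 1.2))
})

test_that("generated counts always satisfy the matrix invariants", {
  for (s in 1:3) {
    sim <- simulate_cohort(sim_config(n_samples = 30, n_sites = 150,
                                      n_informative = 30, seed = s))
    expect_silent(validate_editing_matrix(sim$mat))
    lev <- sim$mat$level
    expect_true(all(lev >= 0 & lev <= 1, na.rm = TRUE))
  }
})

test_that("marginal editing at non-informative sites matches the beta mean", {
  cfg0 <- sim_config(n_samples = 50, n_sites = 400, n_informative = 40)
  means <- vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(n_samples = 50, n_sites = 400,
                                      n_informative = 40, seed = s))
    null_sites <- setdiff(rownames(sim$mat$level),
                          sim$truth$informative_sites)
    mean(sim$mat$level[null_sites, ], na.rm = TRUE)
  }, 0)
  expected <- cfg0$base_edit_alpha / (cfg0$base_edit_alpha +
                                        cfg0$base_edit_beta)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * max(se, 1e-4))
})

test_that("planted sex-by-cluster survival directions emerge in KM medians", {
  ok <- vapply(1:10, function(s) {
    sim <- simulate_cohort(sim_config(seed = s, balanced_clusters = TRUE))
    med <- function(sex, cl) {
      idx <- sim$meta$sex == sex & sim$truth$cluster == cl
      km <- km_estimate(sim$meta$time[idx], sim$meta$event[idx])
      below <- km$time[km$surv <= 0.5]
      if (length(below)) min(below) else Inf
    }
    med("female", 2) < med("female", 1) && med("male", 2) > med("male", 1)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("the generator's hazard ratios are recoverable by the Cox machinery", {
  sim <- simulate_cohort(sim_config(n_samples = 500, n_sites = 20,
                                    n_informative = 10, n_regulated = 5,
                                    balanced_clusters = TRUE, seed = 31))
  for (sx in c("female", "male")) {
    idx <- sim$meta$sex == sx
    fit <- cox_fit(sim$meta$time[idx], sim$meta$event[idx],
                   data.frame(cluster2 = as.numeric(
                     sim$truth$cluster[idx] == 2)))
    truth_hr <- if (sx == "female") sim$config$hr_female else
      sim$config$hr_male
    expect_lt(abs(fit$coef_table$coef - log(truth_hr)),
              abs(log(truth_hr)) * 0.5)
  }
})

test_that("knockdown table opposes the planted coupling and validates as a DE table", {
  sim <- simulate_cohort(sim_config(n_samples = 30, n_sites = 100,
                                    n_informative = 20, n_regulated = 10,
                                    seed = 9))
  reg <- sim$kd[sim$kd$gene %in% names(sim$truth$regulated_genes), ]
  expect_true(all(sign(reg$log2fc) == -sign(sim$config$coef_true)))
  expect_true(all(reg$padj < 0.05))
  null_genes <- sim$kd[!(sim$kd$gene %in% names(sim$truth$regulated_genes)), ]
  expect_true(all(null_genes$padj >= 0.2))
})

test_that("fixtures are stable across calls and validate their truth rules", {
  f1 <- make_fixtures()
  f2 <- make_fixtures()
  expect_identical(f1$calling$level, f2$calling$level)
  expect_identical(f1$collinear$level, f2$collinear$level)
  expect_identical(f1$prefilter_truth, f2$prefilter_truth)
  # each fixture's truth is consistent with its generating rule
  expect_true(all(rowSums(f1$calling_truth) ==
                    rowSums(f1$calling$g >= 3 & f1$calling$cov >= 10 &
                              f1$calling_truth)))
  for (b in seq(1, 20, by = 4)) {
    block <- f1$collinear$level[b:(b + 3), ]
    expect_true(all(cor(t(block)) > 0.95))
  }
})
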