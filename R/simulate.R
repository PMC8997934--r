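#' Configuration for the synthetic-cohort generator
#'
#' The generator plants the structure the analysis pipeline is designed to
#' recover: two latent editing clusters differing by `delta_edit` at a subset
#' of informative sites, survival whose hazard depends on the cluster with
#' opposite effect by sex, genes whose log expression is linear in the editing
#' level of an anchor site (plus an age confounder), and a knockdown
#' differential-expression table whose fold changes oppose the planted
#' editing-expression coefficient.
#'
#' @param n_samples,n_sites,n_informative,n_genes,n_regulated cohort sizes.
#' @param delta_edit mean editing difference (fraction) between clusters at
#'   informative sites.
#' @param base_edit_alpha,base_edit_beta beta-distribution shapes for baseline
#'   per-site editing rates (defaults give mean 0.2, the typical bulk of
#'   moderately edited sites).
#' @param mean_cov,cov_dispersion negative-binomial coverage model (mean A+G
#'   reads and size parameter).
#' @param hr_female,hr_male cluster-2 hazard ratios by sex (defaults opposite:
#'   3 and 1/3, mimicking sexually dimorphic risk).
#' @param baseline_hazard,censor_rate exponential event and censoring rates
#'   per day.
#' @param coef_true editing-expression coupling on the log scale for regulated
#'   genes.
#' @param expr_sigma log-scale expression noise SD.
#' @param kd_effect magnitude of the knockdown log2 fold change planted with
#'   sign opposite to `coef_true`.
#' @param balanced_clusters exact 50/50 cluster assignment instead of
#'   Bernoulli(0.5) draws.
#' @param seed master integer seed; per-component sub-seeds are derived from
#'   it so partial regeneration is reproducible.
#' @param panel_seed seed for the site panel (site identities, baseline
#'   rates, informative set, annotation); defaults to `seed`. Two cohorts
#'   generated with the same `panel_seed` but different `seed`s share their
#'   site panel and planted structure while drawing independent patients,
#'   emulating a validation cohort profiled on the same editome.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200L, n_sites = 2000L,
                       n_informative = 200L, n_genes = 300L,
                       n_regulated = min(30L, n_informative), delta_edit = 0.15,
                       base_edit_alpha = 2, base_edit_beta = 8,
                       mean_cov = 50, cov_dispersion = 5,
                       hr_female = 3, hr_male = 1 / 3,
                       baseline_hazard = 1 / 1000, censor_rate = 1 / 2000,
                       coef_true = 2.0, expr_sigma = 0.1, kd_effect = 1,
                       balanced_clusters = FALSE, seed = 1L,
                       panel_seed = seed) {
  stopifnot(n_informative <= n_sites, n_regulated <= n_informative,
            n_regulated <= n_genes, delta_edit >= 0, delta_edit < 1,
            hr_female > 0, hr_male > 0, baseline_hazard > 0)
  structure(as.list(environment()), class = "sim_config")
}

sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic editing cohort
#'
#' Draws a full pipeline input set from a [sim_config()]: an editing matrix
#' (binomial edited-G reads over negative-binomial coverage at beta-drawn
#' per-site rates, cluster-shifted at informative sites), cohort metadata with
#' exponential survival under a cluster-by-sex hazard interaction and
#' independent exponential censoring, an RSEM-like expression table with
#' editing-coupled regulated genes, an ADAR1-knockdown DE table opposing the
#' planted coupling, a site annotation, and the ground truth. Cells drawn
#' with zero coverage are emitted as missing (an editing level is undefined
#' without reads). Byte-identical given the same config.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `mat` ([editing_matrix()]), `meta`
#'   (`cohort_meta`), `expr` (genes x samples matrix), `kd` (`de_table`),
#'   `annotation`, `truth` (cluster per sample, informative sites, regulated
#'   genes with anchor sites, per-sex hazard ratios).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  n <- cfg$n_samples; p <- cfg$n_sites

  set.seed(sub_seed(cfg$seed, 1L))  # samples
  sample_id <- sprintf("S%03d", seq_len(n))
  cluster <- if (cfg$balanced_clusters) sample(rep(1:2, length.out = n))
             else 1L + stats::rbinom(n, 1L, 0.5)
  sex <- c("female", "male")[1L + stats::rbinom(n, 1L, 0.5)]
  age <- stats::rnorm(n, 55, 10)
  while (any(age <= 18)) age[age <= 18] <- stats::rnorm(sum(age <= 18), 55, 10)

  set.seed(sub_seed(cfg$panel_seed, 2L))  # site panel (cohort-shareable)
  chrom <- paste0("chr", sample(1:22, p, replace = TRUE))
  pos <- sample.int(2e8, p)
  strand <- sample(c("+", "-"), p, replace = TRUE)
  sites <- parse_site_id(paste0(chrom, ":", pos, strand))
  informative <- sort(sample.int(p, cfg$n_informative))
  rate_base <- stats::rbeta(p, cfg$base_edit_alpha, cfg$base_edit_beta)

  set.seed(sub_seed(cfg$seed, 2L))  # per-cohort read counts
  rate <- matrix(rate_base, p, n)
  rate[informative, cluster == 2L] <-
    pmin(1, rate[informative, cluster == 2L, drop = FALSE] + cfg$delta_edit)
  cov <- matrix(stats::rnbinom(p * n, mu = cfg$mean_cov,
                               size = cfg$cov_dispersion), p, n)
  g <- matrix(stats::rbinom(p * n, size = cov, prob = rate), p, n)
  level <- ifelse(cov > 0, g / cov, NA_real_)
  zero <- cov == 0
  cov[zero] <- NA_integer_; g[zero] <- NA_integer_
  dimnames(level) <- dimnames(g) <- dimnames(cov) <-
    list(sites$site_id, sample_id)
  mat <- editing_matrix(level, g, cov, sites = sites)

  set.seed(sub_seed(cfg$seed, 3L))  # survival
  loghr <- ifelse(sex == "female", log(cfg$hr_female), log(cfg$hr_male))
  hz <- cfg$baseline_hazard * exp((cluster == 2L) * loghr)
  t_event <- stats::rexp(n, hz)
  t_cens <- stats::rexp(n, cfg$censor_rate)
  meta <- validate_cohort_meta(data.frame(
    sample_id = sample_id, sex = sex, age = age,
    time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens),
    endpoint = "OS", stringsAsFactors = FALSE))
  meta$cluster_true <- cluster

  set.seed(sub_seed(cfg$panel_seed, 4L))  # annotation (cohort-shareable)
  genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  reg_genes <- genes[seq_len(cfg$n_regulated)]
  anchor <- informative[seq_len(cfg$n_regulated)]  # one anchor site per gene
  gene_of <- genes[sample.int(cfg$n_genes, p, replace = TRUE)]
  region_of <- sample(c("3'UTR", "intronic", "exonic", "ncRNA", "5'UTR",
                        "intergenic"), p, replace = TRUE,
                      prob = c(0.5, 0.2, 0.08, 0.08, 0.04, 0.1))
  gene_of[anchor] <- reg_genes
  region_of[anchor] <- sample(c("3'UTR", "intronic"), cfg$n_regulated,
                              replace = TRUE, prob = c(0.85, 0.15))
  gene_of[region_of == "intergenic"] <- ""
  annotation <- data.frame(site_id = sites$site_id, gene = gene_of,
                           region = region_of, stringsAsFactors = FALSE)

  set.seed(sub_seed(cfg$seed, 5L))  # expression
  a_g <- stats::rnorm(cfg$n_genes, 4, 0.3)
  logexpr <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$expr_sigma),
                    cfg$n_genes, n, dimnames = list(genes, sample_id))
  logexpr <- logexpr + a_g + matrix(0.005 * age, cfg$n_genes, n, byrow = TRUE)
  for (k in seq_len(cfg$n_regulated)) {
    lev_k <- level[anchor[k], ]
    lev_k[is.na(lev_k)] <- rate[anchor[k], is.na(lev_k)]
    logexpr[k, ] <- logexpr[k, ] + cfg$coef_true * lev_k
  }
  expr <- exp(logexpr)

  set.seed(sub_seed(cfg$seed, 6L))  # knockdown table
  is_reg <- genes %in% reg_genes
  lfc <- ifelse(is_reg,
                -sign(cfg$coef_true) * abs(cfg$kd_effect) +
                  stats::rnorm(cfg$n_genes, 0, 0.1),
                stats::rnorm(cfg$n_genes, 0, 0.2))
  padj <- ifelse(is_reg, 1e-4, stats::runif(cfg$n_genes, 0.2, 1))
  kd <- read_de_table_df(data.frame(gene = genes, log2fc = lfc,
                                    pvalue = padj / 2, padj = padj,
                                    stringsAsFactors = FALSE))

  truth <- list(cluster = stats::setNames(cluster, sample_id),
                informative_sites = sites$site_id[informative],
                regulated_genes = stats::setNames(sites$site_id[anchor],
                                                  reg_genes),
                hr_female = cfg$hr_female, hr_male = cfg$hr_male,
                coef_true = cfg$coef_true)
  structure(list(mat = mat, meta = meta, expr = expr, kd = kd,
                 annotation = annotation, truth = truth, config = cfg),
            class = "sim_cohort")
}

# validate an in-memory DE table the same way read_de_table() does
read_de_table_df <- function(d) {
  stopifnot(all(c("gene", "log2fc", "pvalue", "padj") %in% names(d)),
            !anyDuplicated(d$gene),
            all(d$padj >= d$pvalue - 1e-12, na.rm = TRUE))
  class(d) <- c("de_table", "data.frame")
  d
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples, %d sites (%d informative), %d genes (%d regulated), seed %d\n",
              x$config$n_samples, x$config$n_sites, x$config$n_informative,
              x$config$n_genes, x$config$n_regulated, x$config$seed))
  invisible(x)
}

#' Hand-constructed fixtures with known truth
#'
#' Deterministic small datasets used to exercise the filter cascades:
#'
#' * `calling`: a 5-site x 4-sample matrix (20 cells) where exactly the
#'   high-evidence cells (coverage >= 10, edited-G reads >= 3, binomial
#'   evidence far beyond a 0.1% error rate) should pass
#'   [call_edited_cells()]; `calling_truth` is the expected pass mask.
#' * `discriminative`: a 10-site matrix of which 4 are constant across
#'   samples, 2 lack editing evidence, and 4 are valid;
#'   `discriminative_truth` names the valid sites.
#' * `prefilter`: a 12-site, 10 vs 10 sample matrix with documented
#'   per-rule outcomes for [prefilter_sites()]; `prefilter_truth` names the
#'   surviving sites and `prefilter_comparison` is the matching
#'   [comparison()].
#' * `collinear`: 5 blocks of 4 near-identical site profiles (within-block
#'   correlation > 0.95) in significance order; `collinear_truth` names the
#'   expected representatives (the first site of each block).
#'
#' @return named list of fixtures and their truth objects; stable across
#'   calls.
#' @export
make_fixtures <- function() {
  out <- list()

  # --- calling fixture: 5 sites x 4 samples -------------------------------
  sid <- sprintf("chr1:%d+", 1000 + 1:5)
  smp <- sprintf("P%02d", 1:4)
  covm <- matrix(20L, 5, 4, dimnames = list(sid, smp))
  gm <- matrix(0L, 5, 4, dimnames = list(sid, smp))
  gm[1, ] <- c(8L, 6L, 5L, 10L)       # strong evidence everywhere
  gm[2, ] <- c(3L, 0L, 4L, 0L)        # passes in samples 1 and 3 only
  covm[3, ] <- 5L                      # coverage below 10: never passes
  gm[3, ] <- 3L
  gm[4, ] <- 2L                        # below min_g everywhere
  covm[5, ] <- 3000L                   # g = 3 but expected errors = 3: weak
  gm[5, ] <- 3L
  levm <- gm / covm
  out$calling <- editing_matrix(levm, gm, covm)
  truth <- matrix(FALSE, 5, 4, dimnames = list(sid, smp))
  truth[1, ] <- TRUE
  truth[2, c(1, 3)] <- TRUE
  out$calling_truth <- truth

  # --- discriminative fixture: 10 sites x 6 samples -----------------------
  sid <- sprintf("chr2:%d-", 2000 + 1:10)
  smp <- sprintf("Q%02d", 1:6)
  covm <- matrix(50L, 10, 6, dimnames = list(sid, smp))
  gm <- matrix(0L, 10, 6, dimnames = list(sid, smp))
  gm[1:4, ] <- 10L                          # constant levels: no variation
  gm[5, ] <- c(0L, 1L, 0L, 2L, 1L, 0L)      # varies but never >= 3 G reads
  gm[6, ] <- c(2L, 1L, 2L, 0L, 1L, 2L)      # same
  gm[7, ] <- c(5L, 10L, 15L, 20L, 8L, 12L)  # valid
  gm[8, ] <- c(25L, 5L, 9L, 14L, 30L, 6L)   # valid
  gm[9, ] <- c(4L, 8L, 16L, 6L, 10L, 20L)   # valid
  gm[10, ] <- c(12L, 6L, 18L, 9L, 7L, 22L)  # valid
  levm <- gm / covm
  out$discriminative <- editing_matrix(levm, gm, covm)
  out$discriminative_truth <- sid[7:10]

  # --- prefilter fixture: 12 sites, 10 case vs 10 ref ---------------------
  sid <- sprintf("chr3:%d+", 3000 + 1:12)
  case <- sprintf("C%02d", 1:10); ref <- sprintf("R%02d", 1:10)
  lev <- matrix(0, 12, 20, dimnames = list(sid, c(case, ref)))
  spread <- seq(-0.045, 0.045, length.out = 10)
  # sites 1-3: identical level in all samples, zero variance -> rule 1
  lev[1, ] <- 0.10; lev[2, ] <- 0.20; lev[3, ] <- 0.05
  # site 4: constant after count quantisation -> rule 1
  lev[4, ] <- 0.10; lev[4, c(1, 11)] <- c(0.101, 0.099)
  # sites 5-6: vary but |median diff| <= 0.03 -> rule 2
  lev[5, ] <- c(0.20 + spread, 0.17 + spread)            # diff exactly 0.03
  lev[6, ] <- c(0.30 + spread, 0.30 + rev(spread))       # diff 0
  # sites 7-12: vary and separate by > 0.03 -> survive
  for (s in 7:12) lev[s, ] <- c(0.30 + 0.01 * s + spread, 0.15 + spread)
  covm <- matrix(100L, 12, 20, dimnames = dimnames(lev))
  gm <- round(lev * 100)
  lev <- gm / covm
  out$prefilter <- editing_matrix(lev, gm, covm)
  out$prefilter_truth <- sid[7:12]
  out$prefilter_comparison <- comparison("FX", case, ref, "female")

  # --- collinearity blocks: 5 blocks of 4 sites ---------------------------
  set.seed(424243L)
  n <- 40L
  base <- matrix(stats::runif(5L * n, 0.1, 0.6), 5L, n)
  sid <- as.vector(vapply(1:5, function(b)
    sprintf("chr%d:%d+", 4 + b, 5000 + 1:4), character(4)))
  lev <- matrix(0, 20L, n, dimnames = list(sid, sprintf("T%02d", 1:n)))
  for (b in 1:5) for (j in 1:4)
    lev[(b - 1L) * 4L + j, ] <- pmin(1, pmax(0,
      base[b, ] + stats::rnorm(n, 0, 0.004)))
  covm <- matrix(1000L, 20L, n, dimnames = dimnames(lev))
  gm <- round(lev * 1000)
  lev <- gm / covm
  out$collinear <- editing_matrix(lev, gm, covm)
  out$collinear_order <- sid                 # significance order: as listed
  out$collinear_truth <- sid[seq(1, 20, by = 4)]
  out
}
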