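#' Regress log expression on editing level, controlling for age
#'
#' Ordinary least squares of `log(expr + 0.5)` on editing level and age (age
#' as a confounder, following the published model of mRNA abundance against
#' editing). The 0.5 pseudo-count guards against zero RSEM abundances.
#'
#' @param editing per-sample editing level at the site.
#' @param expr per-sample RSEM-like abundance of the host gene (linear scale).
#' @param age per-sample age in years.
#' @param min_n minimum complete observations required.
#' @return list with `coef` (editing coefficient on the log scale), `p`
#'   (its t-test p-value), `n`.
#' @export
editing_expression_fit <- function(editing, expr, age, min_n = 10L) {
  ok <- stats::complete.cases(editing, expr, age)
  if (sum(ok) < min_n)
    stop("fewer than ", min_n, " complete observations", call. = FALSE)
  editing <- editing[ok]; expr <- expr[ok]; age <- age[ok]
  if (stats::var(editing) == 0)
    stop("non-informative site: editing level is constant", call. = FALSE)
  fit <- stats::lm(log(expr + 0.5) ~ editing + age)
  cf <- summary(fit)$coefficients
  list(coef = unname(cf["editing", "Estimate"]),
       p = unname(cf["editing", "Pr(>|t|)"]),
       n = sum(ok))
}

#' Fit editing-expression regressions for a set of site-gene pairs
#'
#' Convenience driver over [editing_expression_fit()]: one regression per
#' annotated site against its host gene's expression, with BH adjustment
#' across all tested pairs (the FDR family is the full run).
#'
#' @param mat an [editing_matrix()].
#' @param expr genes x samples abundance matrix.
#' @param meta `cohort_meta` (provides age), aligned by sample ID.
#' @param annotation site annotation (`site_id`, `gene`, `region`); sites with
#'   empty genes or genes absent from `expr` are skipped.
#' @param sites optional site-ID subset (e.g. DESs) to test.
#' @return data.frame of class `regulation_records`: `site_id`, `gene`,
#'   `region`, `coef`, `p`, `fdr`, `n`.
#' @export
fit_regulation <- function(mat, expr, meta, annotation, sites = NULL) {
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "" &
                      annotation$site_id %in% rownames(mat$level) &
                      annotation$gene %in% rownames(expr), ]
  if (!is.null(sites)) ann <- ann[ann$site_id %in% sites, ]
  samples <- intersect(mat$samples, intersect(colnames(expr), meta$sample_id))
  age <- meta$age[match(samples, meta$sample_id)]
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    ed <- mat$level[ann$site_id[i], samples]
    ex <- expr[ann$gene[i], samples]
    f <- tryCatch(editing_expression_fit(ed, ex, age),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(site_id = ann$site_id[i], gene = ann$gene[i],
               region = ann$region[i], coef = f$coef, p = f$p, n = f$n,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) stop("no testable site-gene pairs", call. = FALSE)
  d$fdr <- bh_adjust(d$p)
  class(d) <- c("regulation_records", "data.frame")
  d
}

#' Expression-correlated sites at an FDR threshold
#'
#' Flags sites whose editing-expression regression passes `fdr < threshold`;
#' for genes with several passing sites, the site with the smallest adjusted
#' p represents the gene.
#'
#' @param records `regulation_records` from [fit_regulation()].
#' @param fdr_threshold BH threshold (published value 10%).
#' @return list with `sites` (all passing site IDs) and `per_gene`
#'   (data.frame of the representative site per gene).
#' @export
expression_correlated_sites <- function(records, fdr_threshold = 0.10) {
  hit <- records[!is.na(records$fdr) & records$fdr < fdr_threshold, ]
  hit <- hit[order(hit$fdr, hit$site_id), ]
  per_gene <- hit[!duplicated(hit$gene), ]
  rownames(per_gene) <- NULL
  list(sites = hit$site_id, per_gene = per_gene)
}

#' Classify a gene as editing-regulated using ADAR1 knockdown response
#'
#' A gene already showing an expression-editing correlation is called
#' regulated iff knockdown of ADAR1 significantly changed its expression
#' (adjusted p < `kd_fdr`) in the direction opposite to the correlation
#' coefficient (editing raises expression => knockdown lowers it, and vice
#' versa). Genes absent from the knockdown table are "untested", which is
#' distinct from failing the criteria.
#'
#' @param coef editing-expression regression coefficient.
#' @param gene gene symbol.
#' @param kd_table `de_table` of the ADAR1 knockdown experiment.
#' @param kd_fdr significance threshold on the knockdown adjusted p.
#' @return list `regulated` (logical), `untested` (logical), `kd_log2fc`,
#'   `kd_padj`.
#' @export
classify_regulated <- function(coef, gene, kd_table, kd_fdr = 0.05) {
  i <- match(gene, kd_table$gene)
  if (is.na(i))
    return(list(regulated = FALSE, untested = TRUE,
                kd_log2fc = NA_real_, kd_padj = NA_real_))
  lfc <- kd_table$log2fc[i]; padj <- kd_table$padj[i]
  reg <- !is.na(padj) && padj < kd_fdr && sign(lfc) == -sign(coef) &&
    sign(coef) != 0
  list(regulated = reg, untested = FALSE, kd_log2fc = lfc, kd_padj = padj)
}

#' Editing-regulated genes from correlation plus knockdown evidence
#'
#' Applies [expression_correlated_sites()] then [classify_regulated()] per
#' represented gene: the published two-criterion rule.
#'
#' @param records `regulation_records`.
#' @param kd_table knockdown `de_table`.
#' @param fdr_threshold correlation FDR threshold.
#' @param kd_fdr knockdown significance threshold.
#' @return data.frame per correlated gene: representative `site_id`, `gene`,
#'   `region`, `coef`, `fdr`, `kd_log2fc`, `kd_padj`, `regulated`,
#'   `untested`.
#' @export
regulated_genes <- function(records, kd_table, fdr_threshold = 0.10,
                            kd_fdr = 0.05) {
  pg <- expression_correlated_sites(records, fdr_threshold)$per_gene
  if (!nrow(pg)) return(cbind(pg, kd_log2fc = numeric(0),
                              kd_padj = numeric(0), regulated = logical(0),
                              untested = logical(0)))
  cls <- lapply(seq_len(nrow(pg)), function(i)
    classify_regulated(pg$coef[i], pg$gene[i], kd_table, kd_fdr))
  pg$kd_log2fc <- vapply(cls, `[[`, 0, "kd_log2fc")
  pg$kd_padj <- vapply(cls, `[[`, 0, "kd_padj")
  pg$regulated <- vapply(cls, `[[`, TRUE, "regulated")
  pg$untested <- vapply(cls, `[[`, TRUE, "untested")
  pg
}

#' Region enrichment of a site set by Fisher's exact test
#'
#' Tests whether foreground sites (e.g. expression-correlated DESs) are
#' enriched in a genomic region (default 3'UTR) relative to the remaining
#' background sites. Intergenic sites are excluded from both sets first, and
#' the background is taken minus the foreground, giving the standard 2x2
#' table tested two-sidedly.
#'
#' @param foreground,background character vectors of site IDs; the foreground
#'   must be a subset of the background.
#' @param annotation site annotation (`site_id`, `gene`, `region`).
#' @param region region label of interest.
#' @return list `odds_ratio` (conditional MLE), `p`, `table`.
#' @export
region_enrichment <- function(foreground, background, annotation,
                              region = "3'UTR") {
  if (!all(foreground %in% background))
    stop("foreground sites must be a subset of the background", call. = FALSE)
  reg <- annotation$region[match(background, annotation$site_id)]
  keep <- !is.na(reg) & reg != "intergenic"
  background <- background[keep]; reg <- reg[keep]
  fg <- background %in% foreground
  bg <- !fg
  tab <- matrix(c(sum(fg & reg == region), sum(fg & reg != region),
                  sum(bg & reg == region), sum(bg & reg != region)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("foreground", "background"),
                                c("in_region", "not_in_region")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("degenerate 2x2 table (empty margin)", call. = FALSE)
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Direction of knockdown response among positively correlated genes
#'
#' Among regulated genes with positive editing-expression coefficients,
#' computes the fraction whose expression dropped upon ADAR1 knockdown and an
#' exact two-sided binomial test against 0.5 (the published "reduced upon KD"
#' test).
#'
#' @param reg data.frame from [regulated_genes()] (regulated rows are used).
#' @return list `fraction_reduced`, `n`, `p`; `NULL` (with a message) when no
#'   regulated positive-coefficient gene exists.
#' @export
direction_binomial <- function(reg) {
  d <- reg[reg$regulated & reg$coef > 0, , drop = FALSE]
  if (!nrow(d)) {
    message("no regulated genes with positive coefficients; no test")
    return(NULL)
  }
  x <- sum(d$kd_log2fc < 0)
  bt <- stats::binom.test(x, nrow(d), 0.5)
  list(fraction_reduced = x / nrow(d), n = nrow(d), p = bt$p.value)
}

#' Sex-stratified prognostic screen of editing sites
#'
#' For each site and each sex separately, fits a Cox model of survival on
#' editing level and age, then BH-adjusts the editing-coefficient p-values
#' across sites within the sex. A site is prognostic in a sex when its
#' adjusted p (FDR) is below `fdr_threshold` (published threshold 0.15).
#' Constant or non-convergent sites are skipped for that sex.
#'
#' @param mat an [editing_matrix()].
#' @param meta `cohort_meta`.
#' @param sites site IDs to screen (e.g. DESs).
#' @param fdr_threshold FDR threshold for calling a site prognostic.
#' @param min_events minimum observed events per sex.
#' @return data.frame: `site_id`, `sex`, `hr_age_adj` (HR of editing level),
#'   `p`, `fdr`, `prognostic`; attribute `shared_sites` lists sites
#'   prognostic in both sexes.
#' @export
prognostic_screen <- function(mat, meta, sites, fdr_threshold = 0.15,
                              min_events = 10L) {
  meta <- meta[match(mat$samples, meta$sample_id), ]
  out <- list()
  for (s in c("female", "male")) {
    idx <- which(meta$sex == s)
    if (sum(meta$event[idx]) < min_events) {
      warning("fewer than ", min_events, " events in ", s, "; sex skipped",
              call. = FALSE)
      next
    }
    rows <- lapply(sites, function(site) {
      lev <- mat$level[site, idx]
      ok <- !is.na(lev)
      if (sum(ok) < 10L || stats::var(lev[ok]) == 0) return(NULL)
      fit <- tryCatch(
        cox_fit(meta$time[idx][ok], meta$event[idx][ok],
                data.frame(editing = lev[ok], age = meta$age[idx][ok])),
        error = function(e) NULL)
      if (is.null(fit) || fit$separation) return(NULL)
      ed <- fit$coef_table[fit$coef_table$term == "editing", ]
      data.frame(site_id = site, sex = s, hr_age_adj = ed$hr, p = ed$p,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    if (is.null(d)) next
    d$fdr <- bh_adjust(d$p)
    d$prognostic <- d$fdr < fdr_threshold
    out[[s]] <- d
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no sex evaluable in prognostic screen", call. = FALSE)
  rownames(res) <- NULL
  both <- intersect(res$site_id[res$sex == "female" & res$prognostic],
                    res$site_id[res$sex == "male" & res$prognostic])
  attr(res, "shared_sites") <- both
  res
}
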