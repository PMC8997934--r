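#' Define a case/reference comparison
#'
#' Differential-editing comparisons contrast a high-risk group (case) against
#' the low-risk reference, within one sex (e.g. the published F1: cluster G2
#' vs. G1 in female glioblastoma).
#'
#' @param name comparison label, e.g. `"F1"`.
#' @param case_samples,ref_samples disjoint, non-empty sample ID sets.
#' @param sex `"female"` or `"male"`.
#' @return list of class `comparison`.
#' @export
comparison <- function(name, case_samples, ref_samples, sex) {
  case_samples <- unique(as.character(case_samples))
  ref_samples <- unique(as.character(ref_samples))
  if (!length(case_samples) || !length(ref_samples))
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(case_samples, ref_samples)))
    stop("case and reference samples overlap", call. = FALSE)
  stopifnot(sex %in% c("female", "male"))
  structure(list(name = name, case_samples = case_samples,
                 ref_samples = ref_samples, sex = sex),
            class = "comparison")
}

#' Pre-filter sites before differential-editing testing
#'
#' Two-stage cascade over the comparison's samples:
#'
#' 1. low-variation removal: a site is dropped when its modal editing value
#'    occurs in more than 70% of samples *and* its variance lies in the bottom
#'    20% of the per-site variance distribution (the conjunctive reading;
#'    `conjunctive = FALSE` applies the two conditions as independent
#'    filters);
#' 2. effect-size removal: sites with absolute case-minus-reference median
#'    difference at or below 3% editing are dropped.
#'
#' @param mat an [editing_matrix()].
#' @param cmp a [comparison()].
#' @param same_level_frac modal-value frequency above which a site counts as
#'   near-constant.
#' @param low_var_quantile variance quantile defining "bottom" variances.
#' @param min_median_diff absolute median-difference threshold (inclusive).
#' @param conjunctive whether rule 1 requires both conditions.
#' @return an `editing_matrix` of surviving sites (comparison samples only),
#'   with attribute `removal_log`.
#' @export
prefilter_sites <- function(mat, cmp, same_level_frac = 0.70,
                            low_var_quantile = 0.20, min_median_diff = 0.03,
                            conjunctive = TRUE) {
  samp <- c(cmp$case_samples, cmp$ref_samples)
  missing_samp <- setdiff(samp, mat$samples)
  if (length(missing_samp))
    stop("samples absent from matrix: ",
         paste(utils::head(missing_samp, 5L), collapse = ", "), call. = FALSE)
  sub <- mat[, samp]
  lev <- sub$level
  mode_frac <- apply(lev, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(1)
    max(table(v)) / length(v)
  })
  vars <- apply(lev, 1, stats::var, na.rm = TRUE)
  vars[is.na(vars)] <- 0
  low_var <- vars <= stats::quantile(vars, low_var_quantile, type = 7,
                                     names = FALSE)
  near_const <- mode_frac > same_level_frac
  rule1 <- if (conjunctive) near_const & low_var else near_const | low_var
  in_case <- colnames(lev) %in% cmp$case_samples
  md <- apply(lev, 1, function(v)
    stats::median(v[in_case], na.rm = TRUE) -
      stats::median(v[!in_case], na.rm = TRUE))
  rule2 <- is.na(md) | abs(md) <= min_median_diff + 1e-12  # "<=" at the
  # printed precision; tolerance guards binary representation of fractions
  keep <- !rule1 & !rule2
  log <- c(low_variation = sum(rule1),
           small_median_diff = sum(!rule1 & rule2),
           kept = sum(keep))
  if (!any(keep))
    stop("no sites survive pre-filtering for comparison ", cmp$name,
         call. = FALSE)
  out <- sub[which(keep), ]
  attr(out, "removal_log") <- log
  out
}

# two-sided Mann-Whitney; exact when both groups <= 8 with no ties,
# otherwise normal approximation with continuity and tie correction
mw_test <- function(case, ref) {
  exact <- length(case) <= 8L && length(ref) <= 8L &&
    !anyDuplicated(c(case, ref))
  wt <- suppressWarnings(stats::wilcox.test(case, ref, exact = exact,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Test differential editing between case and reference groups
#'
#' Two-sided Mann-Whitney U per site on non-missing editing levels, BH
#' adjustment across the comparison's tested sites, and the published
#' significance rule: sites with adjusted p < `fdr` are differentially edited
#' sites (DESs). Sites with fewer than two non-missing values in either group
#' are skipped and logged.
#'
#' @param mat an `editing_matrix` (typically from [prefilter_sites()]).
#' @param cmp a [comparison()].
#' @param fdr adjusted-p threshold declaring a DES.
#' @return data.frame of class `des_records`: `site_id`, `comparison`,
#'   `median_diff`, `u_stat`, `p`, `padj`, `is_des`; attribute
#'   `skipped_sites`.
#' @export
test_des <- function(mat, cmp, fdr = 0.05) {
  lev <- mat$level[, intersect(c(cmp$case_samples, cmp$ref_samples),
                               mat$samples), drop = FALSE]
  in_case <- colnames(lev) %in% cmp$case_samples
  res <- lapply(rownames(lev), function(s) {
    case <- lev[s, in_case]; case <- case[!is.na(case)]
    ref <- lev[s, !in_case]; ref <- ref[!is.na(ref)]
    if (length(case) < 2L || length(ref) < 2L) return(NULL)
    mw <- mw_test(case, ref)
    data.frame(site_id = s, comparison = cmp$name,
               median_diff = stats::median(case) - stats::median(ref),
               u_stat = mw$u, p = mw$p, stringsAsFactors = FALSE)
  })
  skipped <- rownames(lev)[vapply(res, is.null, TRUE)]
  d <- do.call(rbind, res)
  if (is.null(d)) stop("no testable sites", call. = FALSE)
  d$padj <- bh_adjust(d$p)
  d$is_des <- d$padj < fdr
  class(d) <- c("des_records", "data.frame")
  attr(d, "skipped_sites") <- skipped
  d
}

#' Genes with at least one differentially edited site
#'
#' @param records `des_records` from [test_des()].
#' @param annotation site annotation data.frame (`site_id`, `gene`, `region`).
#' @return character vector of gene symbols; DESs without annotation (or with
#'   empty gene) are counted under attribute `unannotated`.
#' @export
genes_with_des <- function(records, annotation) {
  des <- records$site_id[records$is_des]
  gene <- annotation$gene[match(des, annotation$site_id)]
  unann <- sum(is.na(gene) | gene == "")
  out <- sort(unique(gene[!is.na(gene) & gene != ""]))
  attr(out, "unannotated") <- unann
  out
}

#' Signed significance ranking of differentially edited genes
#'
#' For each gene the most significant site represents it; the gene score is
#' `sign(median_diff) * (-log10 p)` of that site, so hyper-edited-in-case
#' genes rank at the top and hypo-edited genes at the bottom. Raw (not
#' BH-adjusted) p-values are used. Zero p-values are capped at
#' `-log10 p = 300` and logged. Ties are broken by gene symbol.
#'
#' @param records `des_records` from [test_des()].
#' @param annotation site annotation (`site_id`, `gene`, `region`).
#' @return data.frame `gene`, `site_id`, `score`, sorted by decreasing score;
#'   attribute `capped` counts score-capped genes.
#' @export
rank_genes_signed <- function(records, annotation) {
  d <- records
  d$gene <- annotation$gene[match(d$site_id, annotation$site_id)]
  d <- d[!is.na(d$gene) & d$gene != "", ]
  if (!nrow(d)) stop("no annotated sites to rank", call. = FALSE)
  d <- d[order(d$p, d$site_id), ]
  d <- d[!duplicated(d$gene), ]          # most significant site per gene
  neglog <- -log10(d$p)
  capped <- !is.finite(neglog) | neglog > 300
  neglog[capped] <- 300
  d$score <- sign(d$median_diff) * neglog
  d <- d[order(-d$score, d$gene), c("gene", "site_id", "score")]
  rownames(d) <- NULL
  attr(d, "capped") <- sum(capped)
  d
}

#' Rank-rank hypergeometric overlap map
#'
#' Compares two ranked gene lists by sliding threshold pairs: at grid point
#' (i, j) the overlap between the top-i genes of list 1 and the top-j genes of
#' list 2 is scored with a one-sided hypergeometric enrichment p-value. The
#' lists are restricted to their common universe first.
#'
#' @param list1,list2 character vectors of genes, best rank first.
#' @param step threshold increment in genes; default `max(1, floor(N/100))`.
#' @return list with `neg_log10_p` and `overlap` matrices (rows = list-1
#'   thresholds, columns = list-2 thresholds), `thresholds`, and `universe`
#'   size.
#' @export
rrho_map <- function(list1, list2, step = NULL) {
  universe <- intersect(list1, list2)
  N <- length(universe)
  l1 <- list1[list1 %in% universe]
  l2 <- list2[list2 %in% universe]
  if (is.null(step)) step <- max(1L, floor(N / 100))
  if (step >= N) stop("step must be smaller than the common universe (", N,
                      " genes)", call. = FALSE)
  th <- seq(step, N, by = step)
  ranks2 <- match(l1, l2)  # rank in list2 of each list1 gene
  logp <- ov <- matrix(0, length(th), length(th),
                       dimnames = list(th, th))
  for (a in seq_along(th)) {
    r2 <- ranks2[seq_len(th[a])]
    for (b in seq_along(th)) {
      k <- sum(r2 <= th[b])
      ov[a, b] <- k
      logp[a, b] <- -stats::phyper(k - 1, th[a], N - th[a], th[b],
                                   lower.tail = FALSE, log.p = TRUE) / log(10)
    }
  }
  list(neg_log10_p = logp, overlap = ov, thresholds = th, universe = N)
}
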