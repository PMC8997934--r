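#' Filter configuration for editing-site calling
#'
#' Defaults follow the published cascade: sequencing error rate 0.1%, minimum
#' A+G coverage 10, minimum edited-G reads 3, editing-rate null bound 0.1%,
#' BH threshold 0.05, and tolerance for at most 20% low-coverage sites per
#' sample.
#'
#' @param error_rate assumed per-base sequencing error probability.
#' @param min_cov minimum A+G read coverage for a cell to be testable.
#' @param min_g minimum edited-G reads as evidence of editing.
#' @param level_floor null editing rate for the binomial evidence test.
#' @param fdr BH-adjusted p-value threshold.
#' @param max_lowcov_frac per-sample fraction of low-coverage sites tolerated;
#'   samples with strictly more are dropped.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(error_rate = 0.001, min_cov = 10L, min_g = 3L,
                          level_floor = 0.001, fdr = 0.05,
                          max_lowcov_frac = 0.20) {
  stopifnot(error_rate > 0, error_rate < 1, level_floor > 0, level_floor < 1,
            fdr > 0, fdr < 1, max_lowcov_frac > 0, max_lowcov_frac < 1,
            min_cov >= min_g, min_g >= 0)
  structure(list(error_rate = error_rate, min_cov = as.integer(min_cov),
                 min_g = as.integer(min_g), level_floor = level_floor,
                 fdr = fdr, max_lowcov_frac = max_lowcov_frac),
            class = "filter_config")
}

#' Upper-tail binomial probability P(X >= g)
#'
#' Exact upper tail of the binomial distribution, used to test whether the
#' observed edited-G reads exceed what sequencing error alone would produce.
#' Vectorised over `g` and `n`.
#'
#' @param g observed edited-G reads (0 <= g <= n).
#' @param n A+G coverage.
#' @param p0 null editing rate.
#' @return P(X >= g) for X ~ Binomial(n, p0).
#' @export
binomial_tail <- function(g, n, p0) {
  stopifnot(p0 > 0, p0 < 1)
  if (any(g < 0 | n < 0 | g > n)) stop("need 0 <= g <= n", call. = FALSE)
  stats::pbinom(g - 1, n, p0, lower.tail = FALSE)
}

#' Call edited cells against sequencing error
#'
#' A cell passes iff its coverage is at least `min_cov`, its edited-G reads at
#' least `min_g`, and its BH-adjusted upper-tail binomial p (null rate
#' `level_floor`) is below `fdr`. The BH family is all cells tested in the run
#' (cells with missing counts are excluded, not imputed).
#'
#' @param mat an [editing_matrix()].
#' @param cfg a [filter_config()].
#' @return logical sites x samples matrix; `NA` where the cell was untestable
#'   (missing counts).
#' @export
call_edited_cells <- function(mat, cfg = filter_config()) {
  if (nrow(mat$level) == 0L || ncol(mat$level) == 0L)
    stop("empty editing matrix", call. = FALSE)
  g <- mat$g; cov <- mat$cov
  tested <- !is.na(cov)
  p <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  p[tested] <- binomial_tail(g[tested], cov[tested], cfg$level_floor)
  padj <- p
  padj[tested] <- bh_adjust(p[tested])
  pass <- tested & cov >= cfg$min_cov & g >= cfg$min_g & padj < cfg$fdr
  pass[!tested] <- NA
  pass
}

#' Median absolute deviation from the third quartile
#'
#' The discriminative-site variation statistic: `median(|x - Q3(x)|)` with Q3
#' the 0.75 quantile under the linear-interpolation (type-7) convention.
#' A value of 0 means the upper half of the distribution carries no spread
#' worth keeping.
#'
#' @param values numeric vector; `NA`s dropped.
#' @return non-negative scalar.
#' @export
mad_from_q3 <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("all values missing", call. = FALSE)
  q3 <- stats::quantile(values, 0.75, type = 7, names = FALSE)
  stats::median(abs(values - q3))
}

#' Select discriminative editing sites
#'
#' Retains sites whose non-missing editing levels vary among patients
#' (`mad_from_q3 > 0`) and that carry evidence of editing in at least one cell
#' per [call_edited_cells()]. Site order is preserved.
#'
#' @param mat an [editing_matrix()].
#' @param cfg a [filter_config()].
#' @param quiet suppress the per-criterion removal message.
#' @return an `editing_matrix` restricted to surviving sites, with attribute
#'   `removal_log` (counts removed per criterion).
#' @export
select_discriminative_sites <- function(mat, cfg = filter_config(),
                                        quiet = FALSE) {
  pass <- call_edited_cells(mat, cfg)
  has_evidence <- apply(pass, 1, function(z) any(z, na.rm = TRUE))
  varied <- apply(mat$level, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0L && mad_from_q3(v) > 0
  })
  keep <- has_evidence & varied
  log <- c(no_evidence = sum(!has_evidence),
           constant = sum(has_evidence & !varied),
           kept = sum(keep))
  if (!quiet)
    message(sprintf("discriminative sites: kept %d/%d (%d no evidence, %d constant)",
                    log[["kept"]], nrow(mat$level), log[["no_evidence"]],
                    log[["constant"]]))
  if (!any(keep)) stop("no sites survive discriminative filtering", call. = FALSE)
  out <- mat[which(keep), ]
  attr(out, "removal_log") <- log
  out
}

#' Drop samples with widespread low coverage
#'
#' Removes samples for which strictly more than `max_lowcov_frac` of sites
#' have coverage below `min_cov` (missing cells count as low coverage).
#' A sample at exactly the threshold is retained.
#'
#' @param mat an [editing_matrix()].
#' @param cfg a [filter_config()].
#' @return an `editing_matrix` restricted to surviving samples, with attribute
#'   `dropped_samples`.
#' @export
drop_lowcov_samples <- function(mat, cfg = filter_config()) {
  lowcov <- is.na(mat$cov) | mat$cov < cfg$min_cov
  frac <- colMeans(lowcov)
  keep <- frac <= cfg$max_lowcov_frac
  out <- mat[, which(keep)]
  attr(out, "dropped_samples") <- mat$samples[!keep]
  out
}
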