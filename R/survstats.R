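#' Kaplan-Meier product-limit estimate
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators (1 = observed).
#' @return data.frame with columns `time`, `surv` giving the right-continuous
#'   step function, starting at `S(0) = 1`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival data", call. = FALSE)
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
}

#' Unweighted log-rank test
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param groups group labels (>= 2 non-empty groups required).
#' @return list with `statistic` (chi-square), `df` (k - 1), `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L)
    stop("log-rank test needs at least two groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, rho = 0)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Efron tie handling
#'
#' Wraps a partial-likelihood fit and reports, per covariate, the hazard
#' ratio, 95% Wald confidence interval and Wald p-value. Covariates with
#' effectively infinite estimates (complete separation) are flagged rather
#' than silently reported.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators (at least one event required).
#' @param covariates data.frame or matrix of numeric covariates; no column may
#'   be constant.
#' @return object of class `cox_fit`: data.frame `coef_table` (columns
#'   `term`, `coef`, `hr`, `ci_low`, `ci_high`, `p`), plus `n`, `events`,
#'   `separation` flag.
#' @export
cox_fit <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  if (sum(events) < 1L) stop("no observed events", call. = FALSE)
  if (any(vapply(covariates, function(v) stats::var(as.numeric(v)) == 0,
                 TRUE)))
    stop("constant covariate", call. = FALSE)
  d <- cbind(data.frame(.time = times, .event = events), covariates)
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                               paste(sprintf("`%s`", names(covariates)),
                                     collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(f, data = d, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.null(fit$info) && any(is.na(stats::coef(fit))))
    stop("Cox fit did not converge", call. = FALSE)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  sep <- any(abs(beta) > 15 | se > 100)
  z <- beta / se
  tab <- data.frame(term = names(covariates),
                    coef = unname(beta),
                    hr = unname(exp(beta)),
                    ci_low = unname(exp(beta - 1.96 * se)),
                    ci_high = unname(exp(beta + 1.96 * se)),
                    p = unname(2 * stats::pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  structure(list(coef_table = tab, n = length(times),
                 events = sum(events), separation = sep),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d%s\n", x$n, x$events,
              if (x$separation) " [possible separation]" else ""))
  tab <- x$coef_table
  tab$hr <- signif(tab$hr, 3); tab$ci_low <- signif(tab$ci_low, 3)
  tab$ci_high <- signif(tab$ci_high, 3); tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "hr", "ci_low", "ci_high", "p")], row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; monotone and clipped at 1. `NA`s are preserved and
#' excluded from the family.
#'
#' @param pvalues numeric vector in `[0,1]`.
#' @return adjusted p-values, same length/order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Sex-dependent high/low dichotomization of editing levels
#'
#' The published split used for per-site Kaplan-Meier curves: within females
#' the top 30% of values are labelled `high`; within males the top 70% are
#' `high`. The cut is rank-based; ties at the boundary are resolved by stable
#' sample order. A sex with fewer than 4 samples is skipped (labels `NA`) with
#' a warning.
#'
#' @param values numeric vector (e.g. per-sample editing level at one site).
#' @param sex character vector, `"female"`/`"male"`, same length.
#' @return character vector of `"high"`/`"low"` (or `NA` for skipped sexes),
#'   with attribute `non_informative` TRUE when all values in an evaluated sex
#'   are identical.
#' @export
dichotomize_editing <- function(values, sex) {
  stopifnot(length(values) == length(sex), all(sex %in% c("female", "male")))
  out <- rep(NA_character_, length(values))
  flat <- FALSE
  for (s in c("female", "male")) {
    idx <- which(sex == s)
    if (length(idx) == 0L) next
    if (length(idx) < 4L) {
      warning("fewer than 4 ", s, " samples; sex skipped", call. = FALSE)
      next
    }
    frac_high <- if (s == "female") 0.30 else 0.70
    k <- floor(frac_high * length(idx) + 1e-9)
    ord <- idx[order(-values[idx], seq_along(idx))]
    out[ord] <- "low"
    if (k >= 1L) out[ord[seq_len(k)]] <- "high"
    if (length(unique(values[idx])) == 1L) flat <- TRUE
  }
  attr(out, "non_informative") <- flat
  out
}
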