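#' Specification for a sex-specific editing-based subtype classifier
#'
#' Defaults mirror the published model development: sex-specific initial
#' feature thresholds on the DES adjusted p (5e-4 for females, 1e-5 for
#' males), aggressive collinearity pruning, five-fold cross-validation, and a
#' small random-forest hyperparameter grid including the number of features.
#'
#' @param sex `"female"` or `"male"`.
#' @param init_p_threshold DES adjusted-p cut for initial features; default
#'   depends on `sex`.
#' @param collinearity_r absolute Pearson correlation above which sites are
#'   considered collinear.
#' @param cv_folds number of cross-validation folds.
#' @param ntree,nodesize,n_features vectors defining the tuning grid
#'   (`n_features` = how many top-importance sites the forest uses).
#' @param seed integer seed controlling fold assignment and forest training.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(sex,
                            init_p_threshold = if (sex == "female") 5e-4 else 1e-5,
                            collinearity_r = 0.9, cv_folds = 5L,
                            ntree = 500L, nodesize = c(1L, 5L),
                            n_features = c(10L, 25L, 50L), seed = 1L) {
  stopifnot(sex %in% c("female", "male"), collinearity_r > 0,
            collinearity_r <= 1, cv_folds >= 2L)
  grid <- expand.grid(ntree = as.integer(ntree),
                      nodesize = as.integer(nodesize),
                      n_features = as.integer(n_features))
  structure(list(sex = sex, init_p_threshold = init_p_threshold,
                 collinearity_r = collinearity_r,
                 cv_folds = as.integer(cv_folds), grid = grid,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Initial classifier features from DES records
#'
#' Sites below the sex-specific adjusted-p threshold, intersected with the
#' sites shared by the target cohort, ordered by increasing adjusted p (ties
#' by canonical site string).
#'
#' @param des_records `des_records` from [test_des()] on the training
#'   comparison.
#' @param shared_sites site IDs present in both cohorts.
#' @param spec a [classifier_spec()].
#' @return ordered character vector of site IDs.
#' @export
initial_features <- function(des_records, shared_sites, spec) {
  d <- des_records[des_records$padj < spec$init_p_threshold &
                     des_records$site_id %in% shared_sites, ]
  if (!nrow(d))
    stop("no shared sites below adjusted p ", spec$init_p_threshold,
         "; consider relaxing the threshold", call. = FALSE)
  d$site_id[order(d$padj, d$site_id)]
}

#' Greedy collinearity pruning of candidate sites
#'
#' One pass over sites in significance order: a site is kept iff its absolute
#' Pearson correlation (pairwise-complete editing levels) with every
#' already-kept site is below `r_cut`, so each collinear block is represented
#' by its most significant member. Deterministic for a fixed input order.
#'
#' @param mat an [editing_matrix()].
#' @param sites ordered site IDs (most significant first).
#' @param r_cut absolute correlation cut.
#' @return character vector of representative site IDs (input order).
#' @export
prune_collinear <- function(mat, sites, r_cut = 0.9) {
  lev <- t(mat$level[sites, , drop = FALSE])
  kept <- integer(0)
  for (i in seq_along(sites)) {
    if (!length(kept)) { kept <- i; next }
    r <- suppressWarnings(abs(stats::cor(lev[, i], lev[, kept, drop = FALSE],
                                         use = "pairwise.complete.obs")))
    r[is.na(r)] <- 0
    if (all(r < r_cut)) kept <- c(kept, i)
  }
  sites[kept]
}

# stratified fold assignment by class label, seed-controlled
make_folds <- function(labels, k, seed) {
  if (min(table(labels)) < 2L)
    stop("a class has fewer than 2 samples; stratified folding impossible",
         call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune a subtype classifier by cross-validated survival separation
#'
#' Feature importances are first estimated as the average random-forest
#' importance (mean decrease in Gini) over the cross-validation folds using
#' all candidate sites; this ranking defines the top-k feature sets. Each
#' grid point is then scored by pooling its out-of-fold predicted labels and
#' computing the log-rank p of survival across them; the grid point with the
#' smallest p wins (ties broken by smaller grid index). The full audit table
#' is returned because minimum-p selection is a multiple-looking procedure.
#'
#' @param mat training [editing_matrix()].
#' @param labels named integer subtype labels (noise label 0 excluded).
#' @param meta training `cohort_meta`.
#' @param sites candidate site IDs (after [prune_collinear()]).
#' @param spec a [classifier_spec()]; only samples of `spec$sex` are used.
#' @return list `best_params`, `best_p`, `audit`, `importance` (named mean
#'   importances, decreasing), `sites_by_rank`.
#' @export
tune_by_survival <- function(mat, labels, meta, sites, spec) {
  samp <- names(labels)[labels > 0L]
  meta <- meta[match(samp, meta$sample_id), ]
  samp <- samp[meta$sex == spec$sex]
  meta <- meta[meta$sex == spec$sex, ]
  y <- factor(labels[samp])
  if (nlevels(y) < 2L) stop("need >= 2 subtype labels", call. = FALSE)
  x <- t(mat$level[sites, samp, drop = FALSE])
  x[is.na(x)] <- apply(mat$level[sites, samp, drop = FALSE], 1,
                       stats::median, na.rm = TRUE)[col(x)[is.na(x)]]
  fold <- make_folds(as.integer(y), spec$cv_folds, spec$seed)

  imp <- matrix(0, length(sites), spec$cv_folds, dimnames = list(sites, NULL))
  for (f in seq_len(spec$cv_folds)) {
    set.seed(spec$seed + f)
    rf <- randomForest::randomForest(x[fold != f, , drop = FALSE],
                                     y[fold != f], ntree = 500L)
    imp[, f] <- rf$importance[, 1]
  }
  mean_imp <- sort(rowMeans(imp), decreasing = TRUE)
  ranked <- names(mean_imp)

  audit <- spec$grid
  audit$p <- NA_real_
  for (gidx in seq_len(nrow(audit))) {
    k <- min(audit$n_features[gidx], length(ranked))
    feats <- ranked[seq_len(k)]
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(spec$cv_folds)) {
      set.seed(spec$seed + 100L * gidx + f)
      rf <- randomForest::randomForest(
        x[fold != f, feats, drop = FALSE], y[fold != f],
        ntree = audit$ntree[gidx], nodesize = audit$nodesize[gidx])
      pred[fold == f] <- stats::predict(rf, x[fold == f, feats, drop = FALSE])
    }
    if (length(unique(pred)) < 2L) next
    audit$p[gidx] <- logrank_test(meta$time, meta$event, pred)$p
  }
  if (all(is.na(audit$p)))
    stop("no grid point produced two predicted classes", call. = FALSE)
  win <- which.min(audit$p)
  list(best_params = audit[win, setdiff(names(audit), "p"), drop = FALSE],
       best_p = audit$p[win], audit = audit, importance = mean_imp,
       sites_by_rank = ranked)
}

#' Fit the final editing-based subtype classifier
#'
#' Trains a random forest on the full training cohort (samples of the
#' specified sex with non-noise labels) using the tuned hyperparameters and
#' the top-ranked feature set.
#'
#' @param mat training [editing_matrix()].
#' @param labels named subtype labels.
#' @param meta training `cohort_meta`.
#' @param tuned result of [tune_by_survival()].
#' @param spec the [classifier_spec()] used for tuning.
#' @return object of class `editing_classifier` with elements `forest`,
#'   `sites`, `spec`, `tuned`.
#' @export
fit_editing_classifier <- function(mat, labels, meta, tuned, spec) {
  samp <- names(labels)[labels > 0L]
  meta <- meta[match(samp, meta$sample_id), ]
  samp <- samp[meta$sex == spec$sex]
  y <- factor(labels[samp])
  feats <- tuned$sites_by_rank[seq_len(min(tuned$best_params$n_features,
                                           length(tuned$sites_by_rank)))]
  x <- t(mat$level[feats, samp, drop = FALSE])
  x[is.na(x)] <- apply(mat$level[feats, samp, drop = FALSE], 1,
                       stats::median, na.rm = TRUE)[col(x)[is.na(x)]]
  set.seed(spec$seed)
  forest <- randomForest::randomForest(x, y,
                                       ntree = tuned$best_params$ntree,
                                       nodesize = tuned$best_params$nodesize)
  structure(list(forest = forest, sites = feats, spec = spec, tuned = tuned),
            class = "editing_classifier")
}

#' @export
print.editing_classifier <- function(x, ...) {
  cat(sprintf("editing_classifier (%s): %d sites, ntree = %d, CV log-rank p = %.3g\n",
              x$spec$sex, length(x$sites), x$tuned$best_params$ntree,
              x$tuned$best_p))
  invisible(x)
}

#' Predict subtype labels for a new cohort
#'
#' @param object an `editing_classifier`.
#' @param newdata an [editing_matrix()] containing all classifier sites.
#' @param ... ignored.
#' @return factor of predicted subtype labels, named by sample.
#' @export
predict.editing_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$sites, rownames(newdata$level))
  if (length(miss))
    stop("target matrix lacks classifier site(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  x <- t(newdata$level[object$sites, , drop = FALSE])
  x[is.na(x)] <- apply(newdata$level[object$sites, , drop = FALSE], 1,
                       stats::median, na.rm = TRUE)[col(x)[is.na(x)]]
  pred <- stats::predict(object$forest, x)
  names(pred) <- newdata$samples
  pred
}

#' Evaluate transferred subtype labels on a target cohort
#'
#' Per sex: Kaplan-Meier tables, log-rank p, and effect direction across
#' predicted labels (via [sex_stratified_eval()]); optionally an age (and
#' further covariate) adjusted Cox fit of the predicted high-risk label.
#'
#' @param pred predicted labels (factor/int, named by sample).
#' @param meta target `cohort_meta`.
#' @param covariates optional data.frame of extra Cox covariates (e.g. MGMT
#'   promoter methylation), rownames = sample IDs.
#' @return list `per_sex` and (when covariates given or age present) `cox`
#'   per sex.
#' @export
evaluate_transfer <- function(pred, meta, covariates = NULL) {
  labels <- as.integer(as.character(pred))
  names(labels) <- names(pred)
  per_sex <- sex_stratified_eval(labels, meta)
  meta <- meta[match(names(pred), meta$sample_id), ]
  cox <- list()
  for (s in c("female", "male")) {
    idx <- which(meta$sex == s)
    if (length(idx) < 10L || length(unique(labels[idx])) < 2L) next
    cv <- data.frame(cluster2 = as.numeric(labels[idx] == max(labels)),
                     age = meta$age[idx])
    if (!is.null(covariates))
      cv <- cbind(cv, covariates[names(pred)[idx], , drop = FALSE])
    cox[[s]] <- tryCatch(cox_fit(meta$time[idx], meta$event[idx], cv),
                         error = function(e) NULL)
  }
  list(per_sex = per_sex, cox = cox)
}
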