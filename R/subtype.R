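#' Configuration for editing-profile stratification
#'
#' @param n_neighbors UMAP neighbourhood size.
#' @param min_dist UMAP minimum embedding distance.
#' @param seed integer seed controlling the embedding (and recorded in all
#'   outputs); the whole stratification is deterministic given it.
#' @param min_cluster_size,cluster_selection_epsilon,min_samples vectors
#'   defining the HDBSCAN hyperparameter grid (expanded as a full cross).
#' @param impute missing-cell policy before embedding; currently
#'   `"site_median"` (per-site median of observed levels).
#' @param max_features refuse to embed more than this many sites (advise
#'   discriminative pre-filtering instead).
#' @return list of class `stratify_config`.
#' @export
stratify_config <- function(n_neighbors = 15L, min_dist = 0.1, seed = 1L,
                            min_cluster_size = c(10L, 20L),
                            cluster_selection_epsilon = c(0, 0.5),
                            min_samples = c(5L, 10L),
                            impute = "site_median",
                            max_features = 50000L) {
  stopifnot(length(min_cluster_size) >= 1L, length(min_samples) >= 1L,
            length(cluster_selection_epsilon) >= 1L,
            impute == "site_median")
  grid <- expand.grid(min_cluster_size = as.integer(min_cluster_size),
                      cluster_selection_epsilon = cluster_selection_epsilon,
                      min_samples = as.integer(min_samples))
  structure(list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 seed = as.integer(seed), grid = grid, impute = impute,
                 max_features = as.integer(max_features)),
            class = "stratify_config")
}

# per-site median imputation of missing editing levels, samples x sites
impute_levels <- function(mat) {
  x <- t(mat$level)
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- med[j]
  x
}

#' Embed samples into two dimensions by UMAP
#'
#' Missing cells are imputed per `cfg$impute`, then samples are embedded with
#' UMAP (deterministic given `cfg$seed`; single-threaded optimisation).
#'
#' @param mat an [editing_matrix()] (typically discriminative-filtered).
#' @param cfg a [stratify_config()].
#' @return numeric samples x 2 coordinate matrix, rownames sample IDs.
#' @export
embed_samples <- function(mat, cfg = stratify_config()) {
  if (nrow(mat$level) > cfg$max_features)
    stop("more than ", cfg$max_features,
         " sites; apply select_discriminative_sites() before embedding",
         call. = FALSE)
  x <- impute_levels(mat)
  n <- nrow(x)
  if (n == 1L) {
    coords <- matrix(0, 1L, 2L)
  } else {
    nb <- max(2L, min(cfg$n_neighbors, n - 1L))
    set.seed(cfg$seed)
    coords <- uwot::umap(x, n_neighbors = nb, min_dist = cfg$min_dist,
                         n_components = 2L, n_threads = 1,
                         n_sgd_threads = 0, verbose = FALSE)
  }
  rownames(coords) <- mat$samples
  colnames(coords) <- c("umap1", "umap2")
  coords
}

#' Survival-guided editing-profile subtyping
#'
#' Fits the package's core stratification model: samples are embedded with
#' UMAP, clustered with HDBSCAN at every point of the hyperparameter grid, and
#' the labelling whose clusters best separate survival (smallest log-rank p,
#' noise samples excluded; ties broken by smaller grid index) is selected.
#' Because minimum-p selection looks at the data many times, the full audit
#' table of evaluated grid points is always returned.
#'
#' @param mat an [editing_matrix()] of discriminative sites.
#' @param meta a `cohort_meta` data.frame covering all samples of `mat`.
#' @param cfg a [stratify_config()].
#' @return object of class `editing_subtypes`: `coords`, `labels` (named
#'   integer; 0 = noise), `chosen_params`, `selection_p`, `audit`
#'   (all evaluated grid points with their p), `per_sex` (see
#'   [sex_stratified_eval()]), `seed`.
#' @export
fit_editing_subtypes <- function(mat, meta, cfg = stratify_config()) {
  meta <- meta[match(mat$samples, meta$sample_id), ]
  if (any(is.na(meta$sample_id)))
    stop("every sample needs survival metadata", call. = FALSE)
  coords <- embed_samples(mat, cfg)
  audit <- cfg$grid
  audit$n_clusters <- NA_integer_
  audit$p <- NA_real_
  labelings <- vector("list", nrow(audit))
  for (i in seq_len(nrow(audit))) {
    lab <- hdbscan_cluster(coords,
                           min_cluster_size = audit$min_cluster_size[i],
                           min_samples = audit$min_samples[i],
                           cluster_selection_epsilon =
                             audit$cluster_selection_epsilon[i])
    labelings[[i]] <- lab
    keep <- lab > 0L
    if (length(unique(lab[keep])) < 2L) next  # grid point skipped
    audit$n_clusters[i] <- length(unique(lab[keep]))
    audit$p[i] <- logrank_test(meta$time[keep], meta$event[keep],
                               lab[keep])$p
  }
  if (all(is.na(audit$p)))
    stop("no grid point produced >= 2 clusters", call. = FALSE)
  win <- which.min(audit$p)  # ties: smaller grid index
  labels <- labelings[[win]]
  names(labels) <- mat$samples
  res <- structure(list(coords = coords, labels = labels,
                        chosen_params = cfg$grid[win, , drop = FALSE],
                        selection_p = audit$p[win], audit = audit,
                        seed = cfg$seed),
                   class = "editing_subtypes")
  res$per_sex <- tryCatch(sex_stratified_eval(labels, meta),
                          error = function(e) NULL)
  res
}

#' Per-sex survival evaluation of cluster labels
#'
#' For each sex separately: Kaplan-Meier estimates per cluster, the log-rank
#' p across clusters, and the direction of the cluster effect, defined by the
#' ordering of cluster median survival (`"cluster2_worse"` when the highest
#' cluster label has the shorter median survival than cluster 1). A sex in
#' which fewer than two clusters are populated is reported as not evaluable.
#'
#' @param labels integer cluster labels (0 = noise, excluded), named by
#'   sample, or unnamed and aligned with `meta`.
#' @param meta `cohort_meta` rows aligned with (or containing) the samples.
#' @return list keyed by sex: each `NULL` if absent, or a list with
#'   `evaluable`, `p`, `direction`, `km` (per-cluster KM tables),
#'   `median_surv` (per-cluster median survival).
#' @export
sex_stratified_eval <- function(labels, meta) {
  if (!is.null(names(labels)))
    meta <- meta[match(names(labels), meta$sample_id), ]
  stopifnot(length(labels) == nrow(meta))
  out <- list()
  for (s in c("female", "male")) {
    idx <- which(meta$sex == s & labels > 0L)
    if (length(idx) == 0L) { out[[s]] <- NULL; next }
    labs <- labels[idx]
    cl <- sort(unique(labs))
    if (length(cl) < 2L || min(table(labs)) < 1L ||
        length(cl[table(labs) > 0]) < 2L) {
      out[[s]] <- list(evaluable = FALSE)
      next
    }
    lr <- logrank_test(meta$time[idx], meta$event[idx], labs)
    med <- vapply(cl, function(k) {
      km <- km_estimate(meta$time[idx][labs == k], meta$event[idx][labs == k])
      below <- km$time[km$surv <= 0.5]
      if (length(below)) min(below) else Inf
    }, 0)
    names(med) <- paste0("cluster", cl)
    direction <-
      if (med[length(med)] < med[1]) "cluster2_worse"
      else if (med[length(med)] > med[1]) "cluster2_better"
      else "none"
    km_tabs <- lapply(cl, function(k)
      km_estimate(meta$time[idx][labs == k], meta$event[idx][labs == k]))
    names(km_tabs) <- paste0("cluster", cl)
    out[[s]] <- list(evaluable = TRUE, p = lr$p, direction = direction,
                     km = km_tabs, median_surv = med)
  }
  out
}

#' @export
print.editing_subtypes <- function(x, ...) {
  k <- length(unique(x$labels[x$labels > 0L]))
  cat(sprintf("editing_subtypes: %d samples, %d clusters (+%d noise), seed %d\n",
              length(x$labels), k, sum(x$labels == 0L), x$seed))
  cat(sprintf("  selection log-rank p = %.3g at grid point (mcs=%d, eps=%.2g, ms=%d)\n",
              x$selection_p, x$chosen_params$min_cluster_size,
              x$chosen_params$cluster_selection_epsilon,
              x$chosen_params$min_samples))
  invisible(x)
}

#' @export
summary.editing_subtypes <- function(object, ...) {
  print(object)
  cat("cluster sizes:\n")
  print(table(labels = object$labels))
  for (s in names(object$per_sex)) {
    e <- object$per_sex[[s]]
    if (isTRUE(e$evaluable))
      cat(sprintf("  %s: log-rank p = %.3g, direction = %s\n", s, e$p,
                  e$direction))
    else cat(sprintf("  %s: not evaluable\n", s))
  }
  cat("audit (grid evaluations):\n")
  print(object$audit, row.names = FALSE)
  invisible(object)
}

#' Plot an editing-subtypes embedding
#'
#' @param x an `editing_subtypes` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.editing_subtypes <- function(x, ...) {
  lab <- x$labels
  graphics::plot(x$coords, col = ifelse(lab == 0L, "grey60", lab + 1L),
                 pch = ifelse(lab == 0L, 4L, 19L),
                 xlab = "UMAP 1", ylab = "UMAP 2", ...)
  invisible(x)
}
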