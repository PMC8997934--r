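#' Construct an editing matrix
#'
#' The central container of the package: a sites x samples triplet of matrices
#' holding the editing level (fraction of reads carrying the edited G), the
#' edited-G read count, and the A+G read coverage. Cells may be missing
#' (sample not measurable at a site). Invariants enforced:
#'
#' * for every cell with coverage present and positive: `0 <= g <= cov` and
#'   `|level - g/cov| <= 1e-9`;
#' * a cell with `cov == 0` must have `g == 0` and a missing level (an editing
#'   fraction is undefined without reads; zero coverage is still distinct from
#'   an absent cell);
#' * `g` is missing exactly where `cov` is missing.
#'
#' @param level numeric matrix of editing fractions in `[0,1]`, rows are
#'   canonical site IDs, columns sample IDs.
#' @param g integer matrix of edited-G read counts, same dimnames.
#' @param cov integer matrix of A+G read coverage, same dimnames.
#' @param sites optional site data.frame (from [parse_site_id()]); parsed from
#'   the row names when omitted.
#' @return An object of class `editing_matrix`.
#' @export
editing_matrix <- function(level, g, cov, sites = NULL) {
  if (is.null(rownames(level)) || is.null(colnames(level)))
    stop("level matrix must carry site-ID rownames and sample colnames", call. = FALSE)
  stopifnot(identical(dim(level), dim(g)), identical(dim(level), dim(cov)))
  dimnames(g) <- dimnames(cov) <- dimnames(level)
  if (anyDuplicated(rownames(level)))
    stop("duplicate site IDs in editing matrix", call. = FALSE)
  if (is.null(sites)) sites <- parse_site_id(rownames(level))
  x <- structure(list(sites = sites, samples = colnames(level),
                      level = level, g = g, cov = cov),
                 class = "editing_matrix")
  validate_editing_matrix(x)
  x
}

#' Validate an editing matrix's cell invariants
#'
#' @param x an `editing_matrix`.
#' @return `x`, invisibly; stops with a message naming offending cells
#'   otherwise.
#' @export
validate_editing_matrix <- function(x) {
  g <- x$g; cov <- x$cov; level <- x$level
  bad_cell <- function(mask, what) {
    if (any(mask, na.rm = TRUE)) {
      idx <- which(mask, arr.ind = TRUE)
      cells <- paste0(rownames(g)[idx[, 1]], "/", colnames(g)[idx[, 2]])
      stop(what, " at cell(s): ", paste(utils::head(cells, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  bad_cell(is.na(g) != is.na(cov), "g/cov missingness inconsistent")
  bad_cell(!is.na(cov) & cov < 0, "negative coverage")
  bad_cell(!is.na(g) & g < 0, "negative edited-G count")
  bad_cell(!is.na(g) & !is.na(cov) & g > cov, "g_reads > coverage")
  bad_cell(!is.na(cov) & cov > 0 & is.na(level), "missing level at covered cell")
  bad_cell(!is.na(cov) & cov == 0 & (!is.na(level) | g != 0),
           "zero-coverage cell must have g = 0 and missing level")
  pos <- !is.na(cov) & cov > 0
  bad_cell(pos & abs(level - g / cov) > 1e-9, "level inconsistent with g/cov")
  bad_cell(!is.na(level) & (level < 0 | level > 1), "level outside [0,1]")
  invisible(x)
}

#' @export
dim.editing_matrix <- function(x) dim(x$level)

#' @export
dimnames.editing_matrix <- function(x) dimnames(x$level)

#' Subset an editing matrix by sites and/or samples
#'
#' @param x an `editing_matrix`.
#' @param i site index (integer, logical, or site-ID character).
#' @param j sample index.
#' @param ... ignored.
#' @return an `editing_matrix` restricted to the selected sites/samples.
#' @export
`[.editing_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$level))
  if (missing(j)) j <- seq_len(ncol(x$level))
  if (is.character(i)) i <- match(i, rownames(x$level))
  lev <- x$level[i, j, drop = FALSE]
  structure(list(sites = x$sites[match(rownames(lev), x$sites$site_id), ,
                                 drop = FALSE],
                 samples = colnames(lev),
                 level = lev,
                 g = x$g[i, j, drop = FALSE],
                 cov = x$cov[i, j, drop = FALSE]),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$cov))
  cat(sprintf("editing_matrix: %d sites x %d samples (%.1f%% cells missing)\n",
              nrow(x$level), ncol(x$level),
              100 * n_missing / length(x$cov)))
  cat("  sites: ", paste(utils::head(x$sites$site_id, 3L), collapse = ", "),
      if (nrow(x$sites) > 3L) ", ..." else "", "\n", sep = "")
  cat("  samples: ", paste(utils::head(x$samples, 3L), collapse = ", "),
      if (length(x$samples) > 3L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
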