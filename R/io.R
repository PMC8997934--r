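#' Read an editing matrix from long-format TSV
#'
#' Expects a tab-separated file with header `site_id`, `sample_id`, `g_reads`,
#' `cov`, `level`. Missing cells are written as `NA` (or omitted rows); a
#' stored cell with `cov = 0` must carry `g_reads = 0` and `level = NA`.
#' Editing levels must be fractions in `[0,1]`; percent-formatted values
#' (e.g. `"3%"`) are rejected rather than converted.
#'
#' @param path file path.
#' @return an [editing_matrix()].
#' @export
read_editing_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  need <- c("site_id", "sample_id", "g_reads", "cov", "level")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("editing matrix file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(grepl("%", d$level, fixed = TRUE)))
    stop("editing levels must be fractions in [0,1]; percent values found",
         call. = FALSE)
  if (anyDuplicated(d[c("site_id", "sample_id")]))
    stop("duplicate (site_id, sample_id) rows", call. = FALSE)
  sites <- parse_site_id(unique(d$site_id))
  sites <- sites[order_sites(sites), , drop = FALSE]
  samples <- sort(unique(d$sample_id))
  shape <- function(v) {
    m <- matrix(NA_real_, nrow(sites), length(samples),
                dimnames = list(sites$site_id, samples))
    m[cbind(match(d$site_id, sites$site_id), match(d$sample_id, samples))] <-
      suppressWarnings(as.numeric(v))
    m
  }
  editing_matrix(level = shape(d$level), g = shape(d$g_reads),
                 cov = shape(d$cov), sites = sites)
}

#' Write an editing matrix to long-format TSV
#'
#' Emits one row per non-absent cell in site-major order; round-trips through
#' [read_editing_matrix()] cell-identically.
#'
#' @param x an `editing_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_editing_matrix <- function(x, path) {
  keep <- !is.na(x$cov)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  d <- data.frame(site_id = rownames(x$cov)[idx[, 1]],
                  sample_id = colnames(x$cov)[idx[, 2]],
                  g_reads = x$g[idx],
                  cov = x$cov[idx],
                  level = x$level[idx],
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read per-sample cohort metadata
#'
#' Tab-separated with header; required columns `sample_id`, `sex`
#' (`female`/`male`), `age` (years), `time` (days), `event` (0/1). Extra
#' columns (e.g. endpoint, MGMT status) are carried through as covariates.
#'
#' @param path file path.
#' @return a validated data.frame of class `cohort_meta`.
#' @export
read_cohort_meta <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cohort_meta(d)
}

#' Validate cohort metadata
#'
#' @param d data.frame with columns `sample_id`, `sex`, `age`, `time`, `event`.
#' @return `d` with class `cohort_meta`.
#' @export
validate_cohort_meta <- function(d) {
  need <- c("sample_id", "sex", "age", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample IDs", call. = FALSE)
  if (!all(d$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  if (any(!is.na(d$age) & d$age <= 0)) stop("age must be positive", call. = FALSE)
  if (any(d$time <= 0)) stop("survival time must be positive", call. = FALSE)
  if (!all(d$event %in% c(0, 1)))
    stop("event must be 0 or 1", call. = FALSE)
  class(d) <- c("cohort_meta", "data.frame")
  d
}

#' Read a genes x samples expression table
#'
#' Tab-separated, first column `gene`, remaining columns one per sample,
#' values RSEM-like non-negative abundances.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene") stop("expression table must start with a 'gene' column",
                                  call. = FALSE)
  if (anyDuplicated(d$gene)) stop("duplicate gene symbols", call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$gene
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance values", call. = FALSE)
  m
}

#' Read a differential-expression table
#'
#' Tab-separated with columns `gene`, `log2fc`, `pvalue`, `padj` (one row per
#' gene; adjusted p must be >= raw p and both in `[0,1]`). This is the format
#' consumed for both between-group comparisons and ADAR1-knockdown results.
#'
#' @param path file path.
#' @return data.frame of class `de_table`.
#' @export
read_de_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$gene)) stop("duplicate genes in DE table", call. = FALSE)
  if (any(d$pvalue < 0 | d$pvalue > 1 | d$padj < 0 | d$padj > 1, na.rm = TRUE))
    stop("p-values outside [0,1]", call. = FALSE)
  if (any(d$padj < d$pvalue - 1e-12, na.rm = TRUE))
    stop("padj smaller than raw p", call. = FALSE)
  class(d) <- c("de_table", "data.frame")
  d
}

.regions <- c("3'UTR", "5'UTR", "exonic", "intronic", "ncRNA", "intergenic",
              "other")

#' Read a site -> (gene, region) annotation table
#'
#' Tab-separated with columns `site_id`, `gene` (may be empty for intergenic
#' sites), `region`. Unknown region labels are mapped to `"other"` with a
#' warning.
#'
#' @param path file path.
#' @return data.frame with columns `site_id`, `gene`, `region`.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site_id", "gene", "region")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unknown <- !(d$region %in% .regions)
  if (any(unknown)) {
    warning(sum(unknown), " unknown region label(s) mapped to 'other'",
            call. = FALSE)
    d$region[unknown] <- "other"
  }
  parse_site_id(d$site_id)  # validates tokens
  d
}
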