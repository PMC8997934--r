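#' Parse canonical editing-site identifiers
#'
#' An A-to-I editing site is identified by the string `"<chrom>:<pos><strand>"`
#' with no separators around the strand, e.g. `"chr8:56069413-"` or
#' `"chr1:45509673+"`. Coordinates are 1-based and fully closed; the strand is
#' explicit because A-to-I events are read as A>G on the edited strand.
#'
#' @param token character vector of site identifiers.
#' @return A data.frame with columns `site_id` (the canonical form), `chrom`,
#'   `pos` (integer), `strand` (`"+"` or `"-"`).
#' @examples
#' parse_site_id(c("chr8:56069413-", "chr1:45509673+"))
#' @export
parse_site_id <- function(token) {
  token <- as.character(token)
  m <- regmatches(token, regexec("^([A-Za-z0-9_.]+):([0-9]+)([+-])$", token))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed site identifier(s): ",
         paste(utils::head(token[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  chrom <- vapply(m, `[[`, "", 2L)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  if (any(pos < 1L)) stop("site positions must be >= 1", call. = FALSE)
  strand <- vapply(m, `[[`, "", 4L)
  data.frame(site_id = paste0(chrom, ":", pos, strand),
             chrom = chrom, pos = pos, strand = strand,
             stringsAsFactors = FALSE)
}

#' Format editing sites back into canonical identifiers
#'
#' @param sites data.frame with columns `chrom`, `pos`, `strand` (as returned
#'   by [parse_site_id()]).
#' @return character vector of canonical `"chrom:pos[+-]"` identifiers.
#' @export
format_site_id <- function(sites) {
  paste0(sites$chrom, ":", as.integer(sites$pos), sites$strand)
}

#' Order editing sites canonically
#'
#' Orders by chromosome in natural order (chr1, chr2, ..., chr10, ..., chrX,
#' chrY, chrM, then anything else alphabetically), then position, then strand
#' (`+` before `-`). Used to make site orderings deterministic.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`.
#' @return integer permutation ordering the rows.
#' @export
order_sites <- function(sites) {
  chrom <- as.character(sites$chrom)
  body <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(body))
  key <- ifelse(!is.na(num), num,
                ifelse(body == "X", 1000L,
                       ifelse(body == "Y", 1001L,
                              ifelse(body %in% c("M", "MT"), 1002L, 2000L))))
  order(key, chrom, as.integer(sites$pos), match(sites$strand, c("+", "-")))
}
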