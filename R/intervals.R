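#' Genomic intervals
#'
#' All coordinates inside the package are 0-based, half-open: an interval
#' covers bases `start .. end - 1`. GTF and WIG use 1-based inclusive
#' coordinates; conversion happens only at the file boundary.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return A `genomic_interval` (a named list).
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop(sprintf("invalid interval [%s,%s): need 0 <= start < end", start, end))
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

interval_width <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)%s\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

# exon table helpers: exons are stored as a data.frame with integer
# `start`/`end` columns (0-based half-open), sorted, pairwise disjoint.
validate_exon_table <- function(exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) < 1L) stop("transcript needs at least one exon")
  if (any(exons$start < 0L) || any(exons$end <= exons$start))
    stop("exon with end <= start or negative start")
  if (is.unsorted(exons$start, strictly = TRUE) && nrow(exons) > 1L)
    stop("exons must be sorted by start")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons overlap")
  invisible(exons)
}
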