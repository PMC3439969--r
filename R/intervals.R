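#' Genomic intervals in the internal 0-based half-open convention
#'
#' `svarch` stores every interval 0-based half-open (`[start, end)`), the
#' BED convention; positions printed in the literature and in VCF are
#' 1-based inclusive and are converted at the I/O boundary only.
#'
#' @param chrom Chromosome (contig) name.
#' @param start,end Integer-valued positions, 0-based half-open; `start < end`.
#' @return An object of class `gint`: a list with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' g <- gint("chr10", 20467347, 20467894)
#' interval_length(g)  # 547
#' @export
gint <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("gint() is scalar; build data.frames of intervals for collections")
  if (is.na(start) || is.na(end) || start < 0)
    stop("invalid interval: start must be >= 0 and coordinates non-NA")
  if (start >= end)
    stop(sprintf("invalid interval: start (%s) must be < end (%s)", start, end))
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "gint")
}

#' @export
print.gint <- function(x, ...) {
  cat(sprintf("<gint> %s:[%s, %s) length %s\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$end - x$start))
  invisible(x)
}

#' Length of a genomic interval
#'
#' Under the half-open convention the length is `end - start`, which equals
#' `end1 - start1 + 1` of the equivalent 1-based inclusive printed span.
#'
#' @param interval A [gint()].
#' @return Number of bases spanned.
#' @export
interval_length <- function(interval) {
  stopifnot(inherits(interval, "gint"))
  interval$end - interval$start
}

#' Convert printed 1-based inclusive coordinates to an internal interval
#'
#' Published SV tables print spans 1-based inclusive (e.g.
#' `chr10:20,467,348-20,467,894` for a 547 bp deletion).  This converts to
#' the internal 0-based half-open representation; [to_paper_coords()] is the
#' exact inverse.
#'
#' @param chrom Chromosome name.
#' @param start1,end1 1-based inclusive positions, `1 <= start1 <= end1`.
#' @return A [gint()].
#' @export
from_paper_coords <- function(chrom, start1, end1) {
  if (any(is.na(c(start1, end1))) || start1 < 1 || start1 > end1)
    stop("conversion error: need 1 <= start1 <= end1")
  gint(chrom, start1 - 1, end1)
}

#' @rdname from_paper_coords
#' @param interval A [gint()].
#' @return For `to_paper_coords`, a list with `chrom`, `start1`, `end1`.
#' @export
to_paper_coords <- function(interval) {
  stopifnot(inherits(interval, "gint"))
  list(chrom = interval$chrom, start1 = interval$start + 1, end1 = interval$end)
}
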