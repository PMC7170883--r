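#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`, the BED convention used
#' throughout the package for regions, CNV calls and masks.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Integer-like base coordinates; `end` is exclusive and must
#'   exceed `start`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' genomic_intervals("chr1", 10, 20)
genomic_intervals <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chrom must be non-empty")
  }
  if (any(is.na(start)) || any(is.na(end)) || any(end <= start)) {
    stop("intervals require end > start")
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Convert a 1-based variant position to interval form
#'
#' A variant at 1-based position `pos` with reference allele `ref` occupies
#' the 0-based half-open interval `[pos - 1, pos - 1 + nchar(ref))`.
#'
#' @param pos 1-based position(s).
#' @param ref Reference allele string(s); defaults to a single base.
#' @return An interval `data.frame` (without `chrom`): columns `start`, `end`.
#' @export
vcf_pos_to_interval <- function(pos, ref = "N") {
  data.frame(start = pos - 1, end = pos - 1 + nchar(ref))
}

# length of the intersection of [s1,e1) and [s2,e2); 0 when disjoint
interval_intersection <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# does any row of `x` overlap any row of `mask` (same chrom, >0 bases)?
overlaps_mask <- function(chrom, start, end, mask) {
  if (is.null(mask) || nrow(mask) == 0) {
    return(rep(FALSE, length(chrom)))
  }
  vapply(seq_along(chrom), function(i) {
    same <- mask$chrom == chrom[i]
    any(interval_intersection(start[i], end[i],
                              mask$start[same], mask$end[same]) > 0)
  }, logical(1))
}

# Jaccard index of two interval sets restricted to one chromosome each row
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  inter <- 0
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    inter <- inter + sum(interval_intersection(a$start[i], a$end[i],
                                               b$start[same], b$end[same]))
  }
  # union via lengths minus intersection (valid when each set is disjoint)
  len <- function(x) sum(x$end - x$start)
  u <- len(a) + len(b) - inter
  if (u <= 0) return(1)
  inter / u
}
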