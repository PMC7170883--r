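#' Sample-level CNV calling quality control
#'
#' Pass criteria combine both callers' per-sample intensity metrics: from the
#' confidence-based caller (source A) the log R ratio SD must be below 0.35,
#' B-allele frequency drift below 0.002 and the waviness factor strictly
#' between -0.04 and 0.04; from the Bayes-factor caller (source B) the LRR SD
#' must be below 0.3 and the BAF SD below 0.15. All bounds are strict, so a
#' waviness of exactly 0.04 fails.
#'
#' @param metrics Named list or one-row data.frame with `lrr_sd_a`,
#'   `baf_drift_a`, `waviness_a`, `lrr_sd_b`, `baf_sd_b`.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty on pass).
#' @export
cnv_sample_qc <- function(metrics) {
  need <- c("lrr_sd_a", "baf_drift_a", "waviness_a", "lrr_sd_b", "baf_sd_b")
  for (m in need) {
    if (is.null(metrics[[m]]) || is.na(metrics[[m]])) {
      stop("missing CNV sample metric: ", m)
    }
  }
  reasons <- character(0)
  if (!(metrics$lrr_sd_a < 0.35)) reasons <- c(reasons, "lrr_sd_a")
  if (!(metrics$baf_drift_a < 0.002)) reasons <- c(reasons, "baf_drift_a")
  if (!(metrics$waviness_a > -0.04 && metrics$waviness_a < 0.04)) {
    reasons <- c(reasons, "waviness_a")
  }
  if (!(metrics$lrr_sd_b < 0.3)) reasons <- c(reasons, "lrr_sd_b")
  if (!(metrics$baf_sd_b < 0.15)) reasons <- c(reasons, "baf_sd_b")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Reciprocal overlap of two intervals
#'
#' @param a,b Single intervals: lists or one-row data.frames with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return Numeric vector `c(frac_a, frac_b)`: the intersection length as a
#'   fraction of each interval's own length; `c(0, 0)` on different
#'   chromosomes.
#' @export
#' @examples
#' reciprocal_overlap(list(chrom = "1", start = 0, end = 100),
#'                    list(chrom = "1", start = 50, end = 150))
reciprocal_overlap <- function(a, b) {
  if (a$end <= a$start || b$end <= b$start) {
    stop("zero-length interval in reciprocal_overlap")
  }
  if (a$chrom != b$chrom) return(c(0, 0))
  inter <- interval_intersection(a$start, a$end, b$start, b$end)
  c(inter / (a$end - a$start), inter / (b$end - b$start))
}

#' High-confidence consensus over two CNV call sets
#'
#' A consensus call requires a pair of calls, one from each caller, with the
#' same state, reciprocal overlap of at least `min_ro` each way, at least
#' `min_snps` supporting SNPs in each member, and a caller score strictly
#' greater than `min_score` in each member. The consensus interval takes the
#' innermost boundaries `[max(starts), min(ends))`. When overlaps are
#' many-to-many, pairs are assigned greedily by descending product of the two
#' overlap fractions, leftmost pair on ties; each input call enters at most
#' one consensus. Consensus calls overlapping any mask interval (e.g.
#' centromeres/telomeres) are removed.
#'
#' @param calls_a,calls_b Call tables: `chrom`, `start`, `end`, `state`
#'   (`"del"`/`"dup"`), `score`, `n_snps`.
#' @param mask Optional interval `data.frame` of excluded regions.
#' @param min_snps Minimum supporting SNPs per member call (default 3).
#' @param min_score Score each member must strictly exceed (default 10).
#' @param min_ro Minimum reciprocal overlap each way (default 0.5).
#' @return A consensus call table (`chrom`, `start`, `end`, `state`, `score`
#'   = min of the pair, `n_snps` = min of the pair, `idx_a`, `idx_b` row
#'   indices of the parent calls); zero rows when no pair qualifies.
#' @export
consensus_calls <- function(calls_a, calls_b, mask = NULL, min_snps = 3,
                            min_score = 10, min_ro = 0.5) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), state = character(0),
                      score = numeric(0), n_snps = numeric(0),
                      idx_a = integer(0), idx_b = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(calls_a) || is.null(calls_b) ||
      nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty)

  ok_a <- which(calls_a$n_snps >= min_snps & calls_a$score > min_score)
  ok_b <- which(calls_b$n_snps >= min_snps & calls_b$score > min_score)
  pairs <- list()
  for (i in ok_a) {
    for (j in ok_b) {
      if (calls_a$state[i] != calls_b$state[j]) next
      ro <- reciprocal_overlap(calls_a[i, ], calls_b[j, ])
      if (ro[1] >= min_ro && ro[2] >= min_ro) {
        pairs[[length(pairs) + 1]] <- data.frame(
          i = i, j = j, prod = ro[1] * ro[2],
          a_start = calls_a$start[i], b_start = calls_b$start[j])
      }
    }
  }
  if (length(pairs) == 0) return(empty)
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(-pairs$prod, pairs$a_start, pairs$b_start), , drop = FALSE]

  used_a <- logical(nrow(calls_a))
  used_b <- logical(nrow(calls_b))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE
    used_b[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      chrom = calls_a$chrom[i],
      start = max(calls_a$start[i], calls_b$start[j]),
      end = min(calls_a$end[i], calls_b$end[j]),
      state = calls_a$state[i],
      score = min(calls_a$score[i], calls_b$score[j]),
      n_snps = min(calls_a$n_snps[i], calls_b$n_snps[j]),
      idx_a = i, idx_b = j, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  masked <- overlaps_mask(res$chrom, res$start, res$end, mask)
  res <- res[!masked, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
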