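#' Construct and validate a pedigree
#'
#' @param id Character vector of individual ids (unique).
#' @param father,mother Parent ids or `NA`; when present they must exist in
#'   `id`, and no individual may be its own ancestor.
#' @param sex Integer sex codes (1 = male, 2 = female, 0 = unknown).
#' @param affected `"yes"`, `"no"` or `"unknown"` per individual.
#' @return A `data.frame` with columns `id`, `father`, `mother`, `sex`,
#'   `affected`, `founder` (both parents absent), of class `"pedigree"`.
#' @export
pedigree <- function(id, father, mother, sex, affected) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  affected[is.na(affected)] <- "unknown"
  if (!all(affected %in% c("yes", "no", "unknown"))) {
    stop("affected must be yes/no/unknown")
  }
  for (p in list(father, mother)) {
    known <- !is.na(p)
    if (!all(p[known] %in% id)) {
      stop("parent id(s) not present in pedigree: ",
           paste(setdiff(p[known], id), collapse = ", "))
    }
  }
  ped <- data.frame(id = id, father = as.character(father),
                    mother = as.character(mother), sex = as.integer(sex),
                    affected = affected,
                    founder = is.na(father) & is.na(mother),
                    stringsAsFactors = FALSE)
  # cycle check: walk ancestors of each individual
  for (i in seq_len(nrow(ped))) {
    seen <- character(0)
    frontier <- ped$id[i]
    while (length(frontier)) {
      rows <- ped[ped$id %in% frontier, , drop = FALSE]
      frontier <- stats::na.omit(c(rows$father, rows$mother))
      if (ped$id[i] %in% frontier) stop("individual ", ped$id[i],
                                        " is its own ancestor")
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Construct an array-genotype object
#'
#' @param map `data.frame` with columns `snp`, `chrom`, `pos` (1-based,
#'   strictly increasing within chromosome), `gentrain` (clustering-quality
#'   score in `[0, 1]`).
#' @param geno Numeric matrix of dosage codes 0/1/2/`NA`, samples in rows
#'   (rownames = individual ids), SNPs in columns (colnames = `map$snp`).
#' @return A list of class `"array_genotypes"` with elements `map`, `geno`.
#' @export
array_genotypes <- function(map, geno) {
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno))
  if (!all(geno %in% c(0, 1, 2) | is.na(geno))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  ord_ok <- all(tapply(map$pos, map$chrom, function(p) all(diff(p) > 0)))
  if (!isTRUE(ord_ok)) stop("map positions must be strictly increasing within chromosome")
  colnames(geno) <- map$snp
  structure(list(map = map, geno = geno), class = "array_genotypes")
}

#' Array genotype quality control
#'
#' Removes SNPs whose clustering-quality (gentrain) score is below
#' `gentrain_min` or whose call rate is below `snp_callrate_min`, then
#' removes samples whose call rate over the surviving SNPs is at or below
#' `sample_callrate_min`. Thresholds are strict: a SNP with gentrain exactly
#' 0.5 and full call rate is retained.
#'
#' @param ag An [array_genotypes()] object.
#' @param gentrain_min Minimum gentrain score (default 0.5).
#' @param snp_callrate_min Minimum per-SNP call rate (default 0.95).
#' @param sample_callrate_min Minimum per-sample call rate (default 0.95);
#'   samples at or below it are removed.
#' @return A filtered `array_genotypes` object; removal counts are reported
#'   via `message()`.
#' @export
qc_array <- function(ag, gentrain_min = 0.5, snp_callrate_min = 0.95,
                     sample_callrate_min = 0.95) {
  snp_cr <- colMeans(!is.na(ag$geno))
  drop_snp <- ag$map$gentrain < gentrain_min | snp_cr < snp_callrate_min
  message("qc_array: removing ", sum(drop_snp), " of ", length(drop_snp), " SNPs")
  if (all(drop_snp)) stop("no SNPs survive QC")
  geno <- ag$geno[, !drop_snp, drop = FALSE]
  map <- ag$map[!drop_snp, , drop = FALSE]
  sample_cr <- rowMeans(!is.na(geno))
  drop_sample <- sample_cr <= sample_callrate_min
  message("qc_array: removing ", sum(drop_sample), " of ", length(drop_sample),
          " samples")
  array_genotypes(map, geno[!drop_sample, , drop = FALSE])
}

#' Is a SNP compatible with a single dominantly shared haplotype?
#'
#' Under a dominant single-founder model every affected individual carries
#' the shared haplotype, so at each SNP there must exist an allele present in
#' every affected genotype. The test is permissive towards missing data:
#' missing genotypes impose no constraint, and a fully missing SNP is
#' vacuously compatible. Unaffected (married-in) genotypes are not used:
#' they cannot exclude sharing among the affecteds, and ignoring them keeps
#' the test monotone under genotype removal.
#'
#' @param genotypes Named numeric vector of 0/1/2/`NA` codes at one SNP
#'   (names = individual ids).
#' @param ped A [pedigree()].
#' @return `TRUE` if some allele is carried by every non-missing affected
#'   individual.
#' @export
snp_sharing_compatible <- function(genotypes, ped) {
  aff <- ped$id[ped$affected == "yes"]
  if (length(aff) == 0) stop("affected set is empty")
  g <- genotypes[names(genotypes) %in% aff]
  g <- g[!is.na(g)]
  if (length(g) == 0) return(TRUE)
  all(g <= 1) || all(g >= 1)  # all carry ref, or all carry alt
}

#' Scan for regions consistent with a shared dominant haplotype
#'
#' Replaces multipoint identity-by-descent inference with a per-SNP
#' obligate-sharing test followed by run-length smoothing: maximal runs of at
#' least `min_run` consecutive compatible SNPs are reported per chromosome
#' as 0-based half-open intervals spanning the outermost compatible SNPs,
#' `[pos(first) - 1, pos(last))` in half-open form (the last SNP base is
#' included).
#'
#' @param ag An [array_genotypes()] object (after [qc_array()]).
#' @param ped A [pedigree()].
#' @param min_run Minimum number of consecutive compatible SNPs (default 3).
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `n_support_snps`, sorted and non-overlapping; zero rows when no run
#'   qualifies.
#' @export
sharing_scan <- function(ag, ped, min_run = 3) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_support_snps = integer(0),
                      stringsAsFactors = FALSE)
  if (ncol(ag$geno) == 0) return(empty)
  aff_rows <- rownames(ag$geno) %in% ped$id[ped$affected == "yes"]
  sub <- ag$geno[aff_rows, , drop = FALSE]
  # vectorized form of snp_sharing_compatible over columns
  any2 <- colSums(sub == 2, na.rm = TRUE) > 0
  any0 <- colSums(sub == 0, na.rm = TRUE) > 0
  compat <- !any2 | !any0
  out <- list()
  for (ch in unique(ag$map$chrom)) {
    sel <- ag$map$chrom == ch
    comp <- compat[sel]
    pos <- ag$map$pos[sel]
    r <- rle(comp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_run
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch,
                              start = pos[starts[keep]] - 1,
                              end = pos[ends[keep]],
                              n_support_snps = r$lengths[keep],
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Score recovery of a known region by a sharing scan
#'
#' Jaccard index (intersection over union of base-pair extents) between a
#' known interval and the best-matching reported region; 0 when no region
#' overlaps it.
#'
#' @param regions Region table from [sharing_scan()].
#' @param truth A one-row interval `data.frame` (`chrom`, `start`, `end`).
#' @return The maximum Jaccard index over reported regions, in `[0, 1]`.
#' @export
region_recovery_jaccard <- function(regions, truth) {
  if (nrow(regions) == 0) return(0)
  jac <- vapply(seq_len(nrow(regions)), function(i) {
    if (regions$chrom[i] != truth$chrom[1]) return(0)
    inter <- interval_intersection(regions$start[i], regions$end[i],
                                   truth$start[1], truth$end[1])
    u <- (regions$end[i] - regions$start[i]) +
      (truth$end[1] - truth$start[1]) - inter
    inter / u
  }, numeric(1))
  max(jac)
}
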