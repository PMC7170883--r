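#' Read a VCF file into a variant table
#'
#' Parses a minimal VCF v4.x subset (CHROM, POS, ID, REF, ALT, QUAL, FILTER,
#' FORMAT/GT). Multi-allelic records are split into one biallelic row per ALT
#' allele, sharing the position; genotype codes count copies of that ALT
#' allele (0, 1, 2, or `NA` when missing). Phased separators (`|`) are
#' treated as unphased.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt`, `qual` and one 0/1/2/`NA` genotype column per sample; sample names
#'   are stored in `attr(x, "samples")` in file order.
#' @export
read_vcf <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !startsWith(first, "##fileformat=VCF")) {
    stop("malformed VCF header at line 1: expected '##fileformat=VCF...', got '",
         if (length(first)) first else "", "'")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  gt_raw <- if (length(samples)) {
    vcfR::extract.gt(v, element = "GT")
  } else {
    matrix(character(0), nrow = n, ncol = 0)
  }
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = n)

  bad <- gt_raw[!is.na(gt_raw) & !grepl("^[0-9.]+([/|][0-9.]+)?$", gt_raw)]
  if (length(bad)) {
    stop("unknown genotype separator in GT value '", bad[[1]], "'")
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- lapply(gt_raw[i, ], function(g) {
      if (is.na(g)) return(NA_character_)
      g
    })
    rows <- lapply(seq_along(alts), function(k) {
      codes <- vapply(unlist(alleles), function(g) {
        if (is.na(g)) return(NA_real_)
        parts <- strsplit(g, "[/|]")[[1]]
        if (any(parts == ".")) return(NA_real_)
        sum(parts == as.character(k))
      }, numeric(1))
      c(list(chrom = fix[i, "CHROM"],
             pos = as.numeric(fix[i, "POS"]),
             id = ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]),
             ref = fix[i, "REF"],
             alt = alts[k],
             qual = suppressWarnings(as.numeric(fix[i, "QUAL"]))),
        as.list(codes))
    })
    out[[i]] <- rows
  }
  rows <- unlist(out, recursive = FALSE)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (length(samples)) names(df)[-(1:6)] <- samples
  rownames(df) <- NULL
  attr(df, "samples") <- samples
  df
}

#' Write a variant table as a minimal VCF
#'
#' Inverse of [read_vcf()] for the fields this package uses; a write/read
#' round trip reproduces `chrom`, `pos`, `id`, `ref`, `alt`, `qual` and the
#' genotype codes exactly. Genotype codes 0/1/2 are rendered as `0/0`, `0/1`,
#' `1/1`; `NA` as `./.`.
#'
#' @param variants Variant table as returned by [read_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- attr(variants, "samples")
  if (is.null(samples)) samples <- setdiff(names(variants),
                                           c("chrom", "pos", "id", "ref", "alt",
                                             "qual", "consequence"))
  gt_str <- function(code) {
    ifelse(is.na(code), "./.", c("0/0", "0/1", "1/1")[code + 1])
  }
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    gts <- vapply(samples, function(s) gt_str(variants[[s]][i]), character(1))
    paste(c(variants$chrom[i], format(variants$pos[i], scientific = FALSE),
            variants$id[i], variants$ref[i], variants$alt[i],
            ifelse(is.na(variants$qual[i]), ".",
                   sprintf("%.17g", variants$qual[i])),
            "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED's 0-based half-open semantics are preserved verbatim. Records with
#' `start >= end` are skipped with a warning. `track`, `browser` and comment
#' lines are ignored.
#'
#' @param path Path to a BED file (3+ columns).
#' @return An interval `data.frame` (`chrom`, `start`, `end`); zero rows for
#'   an empty file.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.numeric(vapply(fields, `[`, character(1), 2)),
    end = as.numeric(vapply(fields, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end
  if (any(bad)) {
    warning(sum(bad), " BED record(s) with start >= end skipped")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' @param intervals Interval `data.frame` (`chrom`, `start`, `end`, further
#'   columns appended as extra BED fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  write.table(intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pedigree from a PED/FAM file
#'
#' Expects whitespace-delimited columns family, individual, father, mother,
#' sex, phenotype. `0` parent codes become missing; phenotype 2 = affected,
#' 1 = unaffected, anything else unknown. Founders are individuals with both
#' parents absent.
#'
#' @param path Path to a PED or FAM file.
#' @return A pedigree `data.frame`; see [pedigree()].
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ped) < 6) stop("PED/FAM file needs at least 6 columns")
  pedigree(
    id = as.character(ped[[2]]),
    father = ifelse(ped[[3]] %in% c("0", 0), NA_character_, as.character(ped[[3]])),
    mother = ifelse(ped[[4]] %in% c("0", 0), NA_character_, as.character(ped[[4]])),
    sex = as.integer(ped[[5]]),
    affected = c("no", "yes")[match(ped[[6]], c(1, 2))]
  )
}

#' Read / write a tab-separated trait or call table
#'
#' Thin wrappers fixing the dialect used throughout: tab separator, header
#' row, no quoting, UTF-8, `NA` for missing.
#'
#' @param path File path.
#' @return `read_tsv_table()`: a `data.frame`; `write_tsv_table()`: `path`,
#'   invisibly.
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             quote = "", comment.char = "", fileEncoding = "UTF-8")
}

#' @param x Table to write.
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
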