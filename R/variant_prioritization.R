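#' Variants shared by two sequenced family members
#'
#' Retains variants where both samples carry at least one alternate allele
#' (non-missing) and the PHRED site quality is at least `qual_min`.
#'
#' @param variants Variant table from [read_vcf()].
#' @param sample_a,sample_b Sample column names; an absent sample is an error.
#' @param qual_min Minimum PHRED quality (default 20; a variant at exactly 20
#'   is retained).
#' @return The filtered variant table.
#' @export
shared_variants <- function(variants, sample_a, sample_b, qual_min = 20) {
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(variants)) stop("sample not present in VCF: ", s)
  }
  ga <- variants[[sample_a]]
  gb <- variants[[sample_b]]
  keep <- !is.na(ga) & !is.na(gb) & ga >= 1 & gb >= 1 &
    !is.na(variants$qual) & variants$qual >= qual_min
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(variants, "samples")
  out
}

#' Attach consequence and database-frequency annotations
#'
#' Joins annotation and per-database allele-frequency tables onto a variant
#' table by exact `(chrom, pos, ref, alt)` key, so a novel allele at a known
#' site is not matched to the database record of a different allele.
#'
#' @param variants Variant table.
#' @param annotation `data.frame` with `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`.
#' @param freqs Named list of `data.frame`s (`chrom`, `pos`, `ref`, `alt`,
#'   `maf`), one per database; a variant absent from a table gets `NA`
#'   frequency (meaning "not described").
#' @return The variant table with a `consequence` column and one
#'   `freq_<db>` column per database.
#' @export
annotate_variants <- function(variants, annotation, freqs = list()) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  vkey <- key(variants)
  variants$consequence <- annotation$consequence[match(vkey, key(annotation))]
  for (db in names(freqs)) {
    variants[[paste0("freq_", db)]] <- freqs[[db]]$maf[match(vkey, key(freqs[[db]]))]
  }
  variants
}

# consequence classes counted as a coding change
coding_consequences <- c("frameshift", "missense", "canonical_splice",
                         "stop_gain", "stop_loss", "start_gain", "start_loss")

#' Step-wise prioritization cascade for shared variants
#'
#' Applies, in order: (1) the variant position falls inside a shared-haplotype
#' region; (2) the annotated consequence is a coding change (frameshift,
#' missense, canonical splice, stop/start gain/loss); (3, 4, ...) the variant
#' is absent from each frequency database in turn, or recorded there with a
#' minor allele frequency of exactly 0. Per-stage survivor counts are
#' reported alongside the survivors, and counts are non-increasing by
#' construction.
#'
#' @param shared Variant table (output of [shared_variants()]), annotated via
#'   [annotate_variants()]; an unannotated variant (missing consequence) is an
#'   error.
#' @param regions Region table from [sharing_scan()] (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param dbs Ordered database labels; each needs a `freq_<db>` column.
#' @param consequence_set Consequence classes kept at the coding stage.
#' @return A list of class `"cascade_report"`: `counts` (named integer vector
#'   starting at `shared_qual`), `survivors` (final variant table), and
#'   `stage_survivors` (list of tables per stage).
#' @export
filter_cascade <- function(shared, regions, dbs = c("db1", "db2"),
                           consequence_set = coding_consequences) {
  if (is.null(shared$consequence) || anyNA(shared$consequence)) {
    bad <- if (is.null(shared$consequence)) shared$pos else
      shared$pos[is.na(shared$consequence)]
    stop("unannotated variant(s) at position(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  for (db in dbs) {
    if (!paste0("freq_", db) %in% names(shared)) {
      stop("missing frequency column for database: ", db)
    }
  }
  stages <- list()
  counts <- c(shared_qual = nrow(shared))
  cur <- shared

  in_region <- vapply(seq_len(nrow(cur)), function(i) {
    sel <- regions$chrom == cur$chrom[i]
    any(cur$pos[i] - 1 >= regions$start[sel] & cur$pos[i] - 1 < regions$end[sel])
  }, logical(1))
  cur <- cur[in_region, , drop = FALSE]
  counts["in_shared_regions"] <- nrow(cur)
  stages$in_shared_regions <- cur

  cur <- cur[cur$consequence %in% consequence_set, , drop = FALSE]
  counts["coding_change"] <- nrow(cur)
  stages$coding_change <- cur

  for (k in seq_along(dbs)) {
    f <- cur[[paste0("freq_", dbs[k])]]
    cur <- cur[is.na(f) | f == 0, , drop = FALSE]
    nm <- paste0("absent_db", k)
    counts[nm] <- nrow(cur)
    stages[[nm]] <- cur
  }
  rownames(cur) <- NULL
  structure(list(counts = counts, survivors = cur, stage_survivors = stages),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Variant prioritization cascade:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
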