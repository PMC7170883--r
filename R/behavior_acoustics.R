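#' Prepulse-inhibition attenuation scores
#'
#' For each (subject, task, day, cue level) cell the attenuation score is
#' `100 * mean(cued amplitudes) / mean(uncued amplitudes)`: 100 means the cue
#' was not detected (the startle was unattenuated), lower values mean better
#' cue detection. The score is invariant to rescaling all amplitudes of a
#' cell by a common positive factor.
#'
#' @param trials Startle trial table: `subject`, `task`, `day`, `cue`,
#'   `condition` (`"cued"`/`"uncued"`), `amplitude` (>= 0), and optionally
#'   `genotype` (carried through).
#' @return `data.frame` with one row per cell: `subject`, (`genotype`,)
#'   `task`, `day`, `cue`, `att`. A cell lacking cued or uncued trials is an
#'   error naming the cell; a cell with zero uncued mean gets `att = NA` and
#'   a note.
#' @export
attenuation_scores <- function(trials) {
  stopifnot(all(trials$condition %in% c("cued", "uncued")),
            all(trials$amplitude >= 0))
  cell <- interaction(trials$subject, trials$task, trials$day, trials$cue,
                      drop = TRUE)
  rows <- lapply(levels(cell), function(lv) {
    sub <- trials[cell == lv, , drop = FALSE]
    cued <- sub$amplitude[sub$condition == "cued"]
    uncued <- sub$amplitude[sub$condition == "uncued"]
    if (length(cued) == 0 || length(uncued) == 0) {
      stop("cell without both cued and uncued trials: subject ",
           sub$subject[1], ", task ", sub$task[1], ", day ", sub$day[1],
           ", cue ", sub$cue[1])
    }
    att <- if (mean(uncued) == 0) NA_real_ else 100 * mean(cued) / mean(uncued)
    out <- data.frame(subject = sub$subject[1], task = sub$task[1],
                      day = sub$day[1], cue = sub$cue[1], att = att,
                      note = if (is.na(att)) "zero uncued mean" else "",
                      stringsAsFactors = FALSE)
    if ("genotype" %in% names(sub)) out$genotype <- sub$genotype[1]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Group comparison of attenuation scores
#'
#' Scores are first averaged to one value per subject (over cells). Without a
#' covariate, a one-way ANOVA F-test across groups; with a covariate, the
#' group F from the linear model `score ~ covariate + group` (Type-II sum of
#' squares, i.e. the group effect after the covariate), mirroring the use of
#' a simple-tone detection score as a hearing covariate for complex tasks.
#'
#' @param scores Attenuation-score table from [attenuation_scores()] (or any
#'   table with `subject`, `att` and a group column).
#' @param group_col Name of the grouping column (default `"genotype"`).
#' @param covariate Optional named numeric vector of per-subject covariate
#'   values (names = subject ids), e.g. baseline detection scores.
#' @return List: `F`, `df1`, `df2`, `p`, `means` (adjusted group means; at
#'   the covariate mean when a covariate is used), `n_per_group`.
#' @export
group_compare <- function(scores, group_col = "genotype", covariate = NULL) {
  agg <- stats::aggregate(scores$att,
                          by = list(subject = scores$subject,
                                    group = scores[[group_col]]),
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "att"
  if (length(unique(agg$group)) < 2) stop("need at least two groups")
  if (any(table(agg$group) < 2)) stop("need at least two subjects per group")
  agg$group <- factor(agg$group)
  if (is.null(covariate)) {
    fit <- aov(att ~ group, data = agg)
    s <- summary(fit)[[1]]
    means <- tapply(agg$att, agg$group, mean)
    list(F = s["group", "F value"], df1 = s["group", "Df"],
         df2 = s["Residuals", "Df"], p = s["group", "Pr(>F)"],
         means = means, n_per_group = table(agg$group))
  } else {
    agg$cov <- covariate[as.character(agg$subject)]
    if (anyNA(agg$cov)) stop("covariate missing for subject(s): ",
                             paste(agg$subject[is.na(agg$cov)], collapse = ", "))
    if (var(agg$cov) == 0) stop("singular design: covariate has zero variance")
    X <- stats::model.matrix(~ cov + group, data = agg)
    if (qr(X)$rank < ncol(X)) stop("singular design: covariate collinear with groups")
    full <- lm(att ~ cov + group, data = agg)
    red <- lm(att ~ cov, data = agg)
    a <- anova(red, full)
    cm <- mean(agg$cov)
    nd <- data.frame(cov = cm, group = levels(agg$group))
    means <- setNames(predict(full, nd), levels(agg$group))
    list(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2], p = a$`Pr(>F)`[2],
         means = means, n_per_group = table(agg$group))
  }
}

#' Filter ultrasonic-vocalization syllables
#'
#' Retains syllables with mean frequency in `[fmin, fmax]` kHz and duration
#' in `[dmin, dmax]` ms (bounds inclusive), then removes syllables closer
#' than `min_gap` ms to an adjacent retained syllable. By default both
#' members of an offending pair are removed; `gap_removal = "later"` keeps
#' the earlier one. The output is a subset of the input and the filter is
#' idempotent (gaps between survivors only grow when neighbours are removed).
#'
#' @param syllables Table with `onset` (seconds), `duration` (ms),
#'   `frequency` (kHz), `volume` (dB) and optionally `category`, `subject`,
#'   `genotype`.
#' @param fmin,fmax Frequency band in kHz (defaults 35, 110).
#' @param dmin,dmax Duration bounds in ms (defaults 8, 200).
#' @param min_gap Minimum inter-syllable gap in ms (default 5).
#' @param gap_removal `"both"` (default) or `"later"`.
#' @return The filtered syllable table, sorted by onset (within subject when
#'   a `subject` column is present).
#' @export
usv_filter <- function(syllables, fmin = 35, fmax = 110, dmin = 8, dmax = 200,
                       min_gap = 5, gap_removal = c("both", "later")) {
  gap_removal <- match.arg(gap_removal)
  keep <- syllables$frequency >= fmin & syllables$frequency <= fmax &
    syllables$duration >= dmin & syllables$duration <= dmax
  out <- syllables[keep, , drop = FALSE]
  split_by <- if ("subject" %in% names(out)) out$subject else
    rep(1, nrow(out))
  pieces <- lapply(split(seq_len(nrow(out)), split_by), function(idx) {
    sub <- out[idx[order(out$onset[idx])], , drop = FALSE]
    if (nrow(sub) < 2) return(sub)
    # microsecond rounding so onset arithmetic cannot blur the 5 ms boundary
    gap_ms <- round((sub$onset[-1] - sub$onset[-nrow(sub)]) * 1000 -
                      sub$duration[-nrow(sub)], 6)
    close_pair <- which(gap_ms < min_gap)
    drop <- if (gap_removal == "both") {
      unique(c(close_pair, close_pair + 1))
    } else {
      close_pair + 1
    }
    if (length(drop)) sub[-drop, , drop = FALSE] else sub
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Per-group syllable summaries
#'
#' Group means and standard errors of syllable frequency, duration and
#' volume, collapsed across syllable categories.
#'
#' @param syllables Filtered syllable table with a grouping column.
#' @param group_col Name of the grouping column (default `"genotype"`).
#' @return `data.frame`: `group`, `n`, then `mean`/`sem` for `frequency`,
#'   `duration`, `volume`. SEM is `NA` (flagged) for groups of one syllable;
#'   a group level with no syllables yields an all-`NA` row.
#' @export
usv_summaries <- function(syllables, group_col = "genotype") {
  groups <- if (is.factor(syllables[[group_col]]))
    levels(syllables[[group_col]]) else unique(syllables[[group_col]])
  sem <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  rows <- lapply(groups, function(g) {
    sub <- syllables[syllables[[group_col]] == g, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(group = g, n = 0L, frequency_mean = NA_real_,
                        frequency_sem = NA_real_, duration_mean = NA_real_,
                        duration_sem = NA_real_, volume_mean = NA_real_,
                        volume_sem = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(group = g, n = nrow(sub),
               frequency_mean = mean(sub$frequency),
               frequency_sem = sem(sub$frequency),
               duration_mean = mean(sub$duration),
               duration_sem = sem(sub$duration),
               volume_mean = mean(sub$volume),
               volume_sem = sem(sub$volume), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
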