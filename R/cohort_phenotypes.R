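ac_cols <- c("ac_l_500", "ac_r_500", "ac_l_1000", "ac_r_1000",
             "ac_l_2000", "ac_r_2000", "ac_l_4000", "ac_r_4000")

#' Cohort inclusion filters
#'
#' Base mode keeps individuals of British ethnicity, born after 32 weeks
#' gestation with a birth weight above 1500 g, and with at least one analysis
#' phenotype present (vocabulary, nonword repetition or comprehension).
#' Boundaries are strict: gestation exactly 32 weeks or birth weight exactly
#' 1500 g is excluded, as is a missing value in any filter field.
#' `common_variant` mode additionally excludes nonverbal IQ below 65 and any
#' air-conduction threshold above 40 dB HL at any ear/frequency (overt
#' pathology that could confound language development). Exclusion counts per
#' criterion are reported via `message()`.
#'
#' @param traits Trait table; see [sim_cohort()] for the column layout.
#' @param mode `"base"` or `"common_variant"`.
#' @return The filtered trait table. Idempotent.
#' @export
cohort_filter <- function(traits, mode = c("base", "common_variant")) {
  mode <- match.arg(mode)
  n0 <- nrow(traits)
  crit <- list(
    gestation = !is.na(traits$gestation_weeks) & traits$gestation_weeks > 32,
    birthweight = !is.na(traits$birthweight_g) & traits$birthweight_g > 1500,
    ethnicity = !is.na(traits$ethnicity) & traits$ethnicity == "British",
    phenotype_present = !(is.na(traits$vocab) & is.na(traits$nwr) &
                            is.na(traits$wold))
  )
  if (mode == "common_variant") {
    crit$nviq <- is.na(traits$nviq) | traits$nviq >= 65
    present <- intersect(ac_cols, names(traits))
    thr <- as.matrix(traits[, present, drop = FALSE])
    crit$hearing <- !apply(thr > 40, 1, any, na.rm = TRUE)
  }
  keep <- Reduce(`&`, crit)
  for (nm in names(crit)) {
    message("cohort_filter: ", sum(!crit[[nm]]), " of ", n0,
            " excluded by ", nm)
  }
  out <- traits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Low-frequency hearing phenotype (MinLow)
#'
#' The minimum air-conduction threshold across the left and right ears at
#' 0.5 kHz, in dB HL; `NA` when both ears are missing.
#'
#' @param traits Trait table with `ac_l_500`, `ac_r_500`.
#' @return Numeric vector, one value per individual.
#' @export
min_low <- function(traits) {
  out <- pmin(traits$ac_l_500, traits$ac_r_500, na.rm = TRUE)
  out[is.na(traits$ac_l_500) & is.na(traits$ac_r_500)] <- NA
  out
}

#' Mid-frequency hearing phenotype (MinMid)
#'
#' Each ear's thresholds at 1, 2 and 4 kHz are averaged (only ears with a
#' complete triple contribute), then the minimum across ears is taken; `NA`
#' when neither ear is complete.
#'
#' @param traits Trait table with `ac_{l,r}_{1000,2000,4000}`.
#' @return Numeric vector in dB HL, one value per individual.
#' @export
min_mid <- function(traits) {
  ear_mean <- function(side) {
    m <- (traits[[paste0("ac_", side, "_1000")]] +
            traits[[paste0("ac_", side, "_2000")]] +
            traits[[paste0("ac_", side, "_4000")]]) / 3
    m  # NA whenever any of the three is missing
  }
  l <- ear_mean("l"); r <- ear_mean("r")
  out <- pmin(l, r, na.rm = TRUE)
  out[is.na(l) & is.na(r)] <- NA
  out
}

# any 1/2/4 kHz air-conduction threshold above 20 dB HL (either ear)
hearing_impaired <- function(traits) {
  cols <- c("ac_l_1000", "ac_r_1000", "ac_l_2000", "ac_r_2000",
            "ac_l_4000", "ac_r_4000")
  thr <- as.matrix(traits[, intersect(cols, names(traits)), drop = FALSE])
  apply(thr > 20, 1, any, na.rm = TRUE)
}

#' Classify developmental language disorder status
#'
#' Cases score at least 1 SD below the cohort mean on comprehension (WOLD),
#' or more than 1 SD below the mean on both communication-checklist fluency
#' and syntax, with no evidence of autism spectrum disorder and no hearing
#' impairment (any 1/2/4 kHz air-conduction threshold above 20 dB HL).
#' Controls score strictly above the cohort mean on all three language
#' measures, have nonverbal IQ above 80, and carry neither an ASD nor a
#' special-educational-needs flag. Individuals missing a defining language
#' measure or flag (or, for controls, nonverbal IQ) are excluded. Case,
#' control and excluded partition the cohort.
#'
#' @param traits Trait table with `wold`, `ccc_fluency`, `ccc_syntax`,
#'   `asd_flag`, `sen_flag`, `nviq` and the audiometric columns.
#' @param stats Optional list of `c(mean, sd)` for `wold`, `ccc_fluency`,
#'   `ccc_syntax`; computed from the non-missing values of `traits` when
#'   `NULL` (compute them on the filtered cohort).
#' @return Character vector `"case"`/`"control"`/`"excluded"`.
#' @export
classify_dld <- function(traits, stats = NULL) {
  measures <- c("wold", "ccc_fluency", "ccc_syntax")
  if (is.null(stats)) {
    stats <- lapply(traits[measures], function(x) {
      c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
    })
  }
  m <- lapply(stats, `[[`, "mean")
  s <- lapply(stats, `[[`, "sd")
  imp <- hearing_impaired(traits)
  ok_case <- complete.cases(traits[measures]) & !is.na(traits$asd_flag)
  ok_ctrl <- ok_case & !is.na(traits$sen_flag) & !is.na(traits$nviq)

  low_wold <- traits$wold <= m$wold - s$wold
  low_ccc <- traits$ccc_fluency < m$ccc_fluency - s$ccc_fluency &
    traits$ccc_syntax < m$ccc_syntax - s$ccc_syntax
  is_case <- ok_case & (low_wold | low_ccc) & !traits$asd_flag & !imp

  above <- traits$wold > m$wold & traits$ccc_fluency > m$ccc_fluency &
    traits$ccc_syntax > m$ccc_syntax
  is_ctrl <- ok_ctrl & above & traits$nviq > 80 &
    !traits$asd_flag & !traits$sen_flag

  out <- rep("excluded", nrow(traits))
  out[which(is_ctrl)] <- "control"
  out[which(is_case)] <- "case"  # disjoint from controls by construction
  out
}

#' Carrier versus non-carrier contrast
#'
#' For a quantitative measure: difference of group means and Cohen's d with
#' pooled SD and a normal-approximation 95 percent confidence interval. For a
#' binary measure: additionally the relative risk carrier/non-carrier with a
#' log-scale 95 percent interval; a zero non-carrier risk makes the relative
#' risk undefined and it is reported as `NA`.
#'
#' @param traits Trait table with a logical `carrier_flag` column.
#' @param measure Column name to contrast.
#' @param binary Is the measure 0/1?
#' @return A list: `n_carrier`, `n_noncarrier`, `mean_carrier`,
#'   `mean_noncarrier`, `mean_diff`, `cohens_d`, `d_ci`; for binary measures
#'   also `relative_risk`, `rr_ci`.
#' @export
carrier_contrast <- function(traits, measure, binary = FALSE) {
  x <- traits[[measure]][traits$carrier_flag & !is.na(traits[[measure]])]
  y <- traits[[measure]][!traits$carrier_flag & !is.na(traits[[measure]])]
  if (length(x) < 1 || length(y) < 1) {
    stop("need at least one carrier and one non-carrier with data")
  }
  n1 <- length(x); n2 <- length(y)
  diff <- mean(x) - mean(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  d <- if (sp > 0) diff / sp else 0
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  out <- list(n_carrier = n1, n_noncarrier = n2,
              mean_carrier = mean(x), mean_noncarrier = mean(y),
              mean_diff = diff, cohens_d = d,
              d_ci = d + c(-1, 1) * qnorm(0.975) * se_d)
  if (binary) {
    r1 <- mean(x); r2 <- mean(y)
    if (r2 == 0) {
      out$relative_risk <- NA_real_
      out$rr_ci <- c(NA_real_, NA_real_)
      out$rr_note <- "undefined: zero non-carrier risk"
    } else {
      rr <- r1 / r2
      a <- sum(x); b <- sum(y)
      se_log <- sqrt(max(0, 1 / a - 1 / n1 + 1 / b - 1 / n2))
      out$relative_risk <- rr
      out$rr_ci <- if (a == 0) c(NA_real_, NA_real_) else
        exp(log(rr) + c(-1, 1) * qnorm(0.975) * se_log)
    }
  }
  out
}

#' Carrier frequency as a printed percentage
#'
#' @param n_carriers,n_total Counts.
#' @param digits Decimal places for the percentage (default 2).
#' @return Percentage of carriers, rounded.
#' @export
#' @examples
#' carrier_percent(14, 1646)  # 0.85
carrier_percent <- function(n_carriers, n_total, digits = 2) {
  if (n_total < 1) stop("n_total must be positive")
  round(100 * n_carriers / n_total, digits)
}
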