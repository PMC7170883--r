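#' Simulate a discovery family with a planted dominant haplotype
#'
#' Generates a 12-member, 4-generation pedigree in which every descendant of
#' the first founder is affected, with 7 genotyped members (5 affected, 2
#' married-in unaffected). A dominant haplotype is transmitted to all
#' affecteds over a planted region of one chromosome: inside the region every
#' affected individual is forced to carry the alternate allele, while outside
#' it genotypes are independent Hardy-Weinberg draws, so incompatible SNPs
#' break up spurious runs. A stop-gain variant is planted inside the region
#' in the two sequenced members, absent from both frequency tables, together
#' with decoy variants that each fail exactly one step of the prioritization
#' cascade (low quality, not shared, outside the region, synonymous, known in
#' database 1, known in database 2).
#'
#' @param seed Integer RNG seed; identical seeds give identical outputs.
#' @param n_snps Array markers per chromosome (default 300).
#' @param n_chrom Number of chromosomes (default 2; the region sits on the
#'   first).
#' @param region_span Planted region width in bases (default 5e6).
#' @param spacing Marker spacing in bases (default 5e4, i.e. 1 SNP / 50 kb).
#' @param n_bulk Background sequencing variants (default 30), all present in
#'   database 1 so none survive the cascade.
#' @return A list: `pedigree`, `array` ([array_genotypes()]), `variants`
#'   (table for the two sequenced members `II.2`, `IV.1`), `annotation`,
#'   `freqs` (list `db1`, `db2`), and `truth` (`region` interval, `causal`
#'   variant key).
#' @export
sim_family <- function(seed, n_snps = 300, n_chrom = 2, region_span = 5e6,
                       spacing = 5e4, n_bulk = 30) {
  set.seed(seed)
  ped <- pedigree(
    id = c("I.1", "I.2", "II.1", "II.2", "II.3", "II.4",
           "III.1", "III.2", "III.3", "III.4", "IV.1", "IV.2"),
    father = c(NA, NA, "I.1", "I.1", NA, NA,
               "II.2", "II.2", "II.1", NA, "III.4", "III.4"),
    mother = c(NA, NA, "I.2", "I.2", NA, NA,
               "II.3", "II.3", "II.4", NA, "III.3", "III.3"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2, 2, 1, 2, 2),
    affected = c("yes", "no", "yes", "yes", "no", "no",
                 "yes", "yes", "yes", "no", "yes", "yes"))
  genotyped <- c("II.1", "II.2", "III.3", "IV.1", "IV.2", "II.4", "III.4")
  affected_g <- c("II.1", "II.2", "III.3", "IV.1", "IV.2")

  stopifnot(region_span < (n_snps - 10) * spacing)
  chroms <- paste0("chr", seq_len(n_chrom))
  map <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(snp = paste0(ch, "_snp", seq_len(n_snps)), chrom = ch,
               pos = 1e6 + spacing * (seq_len(n_snps) - 1),
               gentrain = runif(n_snps, 0.6, 0.95), stringsAsFactors = FALSE)
  }))
  m <- nrow(map)
  maf <- runif(m, 0.3, 0.5)
  geno <- sapply(seq_len(m), function(j) {
    sample(0:2, length(genotyped), replace = TRUE,
           prob = c((1 - maf[j])^2, 2 * maf[j] * (1 - maf[j]), maf[j]^2))
  })
  rownames(geno) <- genotyped

  # plant the shared region mid-chromosome on chr1
  region_snps <- n_snps %/% 2 + seq_len(round(region_span / spacing) + 1) -
    round(region_span / spacing / 2)
  in_region <- map$chrom == chroms[1] & seq_len(m) %in% region_snps
  geno[affected_g, in_region] <- pmax(geno[affected_g, in_region], 1)
  region_pos <- map$pos[in_region]
  truth_region <- data.frame(chrom = chroms[1], start = min(region_pos) - 1,
                             end = max(region_pos), stringsAsFactors = FALSE)
  ag <- array_genotypes(map, geno)

  # sequencing variants for II.2 and IV.1
  mkvar <- function(chrom, pos, ref, alt, qual, g_a, g_b, cons, f1, f2) {
    data.frame(chrom = chrom, pos = pos, id = ".", ref = ref, alt = alt,
               qual = qual, II.2 = g_a, IV.1 = g_b, consequence_ = cons,
               f1 = f1, f2 = f2, stringsAsFactors = FALSE)
  }
  mid <- round(mean(range(region_pos)))
  chr1_end <- max(map$pos[map$chrom == chroms[1]])
  bases <- c("A", "C", "G", "T")
  causal <- mkvar(chroms[1], mid, "C", "T", 60, 1, 1, "stop_gain", NA, NA)
  decoys <- rbind(
    mkvar(chroms[1], mid + 1e4, "A", "G", 15, 1, 1, "missense", NA, NA),
    mkvar(chroms[1], mid + 2e4, "G", "A", 50, 0, 1, "missense", NA, NA),
    mkvar(chroms[1], chr1_end + 5e6, "T", "C", 50, 1, 1, "missense", NA, NA),
    mkvar(chroms[1], mid + 3e4, "C", "G", 50, 1, 1, "synonymous", NA, NA),
    mkvar(chroms[1], mid + 4e4, "A", "T", 50, 1, 1, "missense", 0.01, NA),
    mkvar(chroms[1], mid + 5e4, "G", "T", 50, 1, 1, "missense", 0, 0.02))
  bulk <- do.call(rbind, lapply(seq_len(n_bulk), function(i) {
    ch <- sample(chroms, 1)
    al <- sample(bases, 2)
    mkvar(ch, sample(1e6:(1e6 + n_snps * spacing), 1), al[1], al[2],
          runif(1, 25, 90), sample(0:1, 1), sample(1:2, 1),
          sample(c("missense", "synonymous", "noncoding"), 1),
          runif(1, 0.01, 0.3), runif(1, 0.01, 0.3))
  }))
  allv <- rbind(causal, decoys, bulk)
  allv <- allv[!duplicated(paste(allv$chrom, allv$pos)), , drop = FALSE]
  allv <- allv[order(allv$chrom, allv$pos), , drop = FALSE]

  annotation <- data.frame(chrom = allv$chrom, pos = allv$pos, ref = allv$ref,
                           alt = allv$alt, consequence = allv$consequence_,
                           stringsAsFactors = FALSE)
  freq_tab <- function(col) {
    keep <- !is.na(allv[[col]])
    data.frame(chrom = allv$chrom[keep], pos = allv$pos[keep],
               ref = allv$ref[keep], alt = allv$alt[keep],
               maf = allv[[col]][keep], stringsAsFactors = FALSE)
  }
  variants <- allv[, c("chrom", "pos", "id", "ref", "alt", "qual",
                       "II.2", "IV.1")]
  rownames(variants) <- NULL
  attr(variants, "samples") <- c("II.2", "IV.1")

  list(pedigree = ped, array = ag, variants = variants,
       annotation = annotation,
       freqs = list(db1 = freq_tab("f1"), db2 = freq_tab("f2")),
       truth = list(region = truth_region,
                    causal = list(chrom = chroms[1], pos = mid,
                                  ref = "C", alt = "T")))
}

#' Simulate dual-caller CNV call sets with planted consensus calls
#'
#' Plants `n_true` call pairs that satisfy every consensus criterion and
#' `n_decoy` calls/pairs that each violate exactly one criterion (score not
#' above 10, fewer than 3 supporting SNPs, reciprocal overlap below 50
#' percent, predicted by a single caller only, or overlapping the
#' centromere/telomere mask). Each pair lives in its own 2-Mb slot so decoys
#' cannot pair with true calls.
#'
#' @param seed Integer RNG seed.
#' @param n_true,n_decoy Numbers of planted consensus pairs and of decoys.
#' @return A list: `calls_a`, `calls_b`, `mask`, `truth` (`consensus`
#'   expected intervals; `decoys` with the violated criterion per decoy).
#' @export
sim_cnv <- function(seed, n_true = 5, n_decoy = 5) {
  set.seed(seed)
  slot <- 2e6
  kinds <- rep(c("low_score", "few_snps", "low_ro", "single_caller", "masked"),
               length.out = n_decoy)
  rows_a <- list(); rows_b <- list(); truth <- list(); decoy_log <- list()
  mask <- NULL
  for (k in seq_len(n_true + n_decoy)) {
    s <- k * slot + round(runif(1, 0, 2e5))
    len <- round(runif(1, 2e5, 8e5))
    st <- sample(c("del", "dup"), 1)
    shift <- round(0.1 * len)
    a <- data.frame(chrom = "chr1", start = s, end = s + len, state = st,
                    score = runif(1, 12, 30), n_snps = sample(5:50, 1),
                    stringsAsFactors = FALSE)
    b <- a
    b$start <- s + shift; b$end <- s + len + shift
    b$score <- runif(1, 12, 30); b$n_snps <- sample(5:50, 1)
    if (k <= n_true) {
      rows_a[[k]] <- a; rows_b[[k]] <- b
      truth[[k]] <- data.frame(chrom = "chr1", start = b$start, end = a$end,
                               state = st, stringsAsFactors = FALSE)
    } else {
      kind <- kinds[k - n_true]
      if (kind == "low_score") {
        b$score <- 10  # not strictly greater than 10
      } else if (kind == "few_snps") {
        a$n_snps <- 2
      } else if (kind == "low_ro") {
        b$start <- s + round(0.7 * len); b$end <- b$start + len
      } else if (kind == "single_caller") {
        b <- NULL
      } else if (kind == "masked") {
        mask <- rbind(mask, data.frame(chrom = "chr1", start = s - 1e4,
                                       end = s + len + 1e4,
                                       stringsAsFactors = FALSE))
      }
      rows_a[[k]] <- a
      if (!is.null(b)) rows_b[[k]] <- b
      decoy_log[[k - n_true]] <- data.frame(slot = k, violated = kind,
                                            stringsAsFactors = FALSE)
    }
  }
  if (is.null(mask)) {
    mask <- data.frame(chrom = "chr1", start = (n_true + n_decoy + 2) * slot,
                       end = (n_true + n_decoy + 3) * slot,
                       stringsAsFactors = FALSE)
  }
  list(calls_a = do.call(rbind, rows_a), calls_b = do.call(rbind, rows_b),
       mask = mask,
       truth = list(consensus = if (n_true) do.call(rbind, truth) else
                      data.frame(),
                    decoys = if (n_decoy) do.call(rbind, decoy_log) else
                      data.frame()))
}

#' Simulate a population cohort under a gene-by-hearing interaction model
#'
#' Genotypes are Hardy-Weinberg draws at the stated minor allele frequencies.
#' The low-frequency hearing threshold is normal with a planted carrier shift
#' (default +1.2 dB HL at a carrier frequency of 0.85 percent) plus optional
#' per-SNP additive effects. Vocabulary follows the interaction model
#' `vocab = b0 + b1*g + b2*MinLow + b3*g*MinLow + N(0, noise_sd)` on the
#' first SNP's dosage `g`, truncated to the instrument range `[0, 246]` (a
#' warning is issued if more than 10 percent of values are truncated).
#' Language measures used for case/control classification are generated with
#' fixed correlations to vocabulary; audiometric columns are generated so
#' that [min_low()] recovers the planted threshold.
#'
#' @param seed Integer RNG seed.
#' @param n Cohort size (default 2000, a desk-scale stand-in for a
#'   several-thousand-child cohort).
#' @param maf Vector of minor allele frequencies, one per simulated SNP.
#' @param b Interaction-model coefficients `c(b0, b1, b2, b3)`.
#' @param carrier_freq Pathogenic-carrier frequency (default 0.0085).
#' @param delta_minlow Carrier shift of the 0.5-kHz threshold in dB HL
#'   (default 1.2).
#' @param noise_sd Residual SD of vocabulary (default 20).
#' @param snp_effects Optional per-allele additive effects of each SNP on the
#'   threshold (default all zero).
#' @param minlow_mean,minlow_sd Non-carrier threshold distribution (defaults
#'   9.96 and 5.81 dB HL).
#' @return A list: `genotypes` ([genotype_matrix()]), `traits` (trait table),
#'   `truth` (planted parameters).
#' @export
sim_cohort <- function(seed, n = 2000, maf = 0.3,
                       b = c(b0 = 200, b1 = 0, b2 = -0.5, b3 = -0.15),
                       carrier_freq = 0.0085, delta_minlow = 1.2,
                       noise_sd = 20, snp_effects = NULL,
                       minlow_mean = 9.96, minlow_sd = 5.81) {
  set.seed(seed)
  m <- length(maf)
  if (is.null(snp_effects)) snp_effects <- rep(0, m)
  geno <- sapply(maf, function(p) rbinom(n, 2, p))
  geno <- matrix(geno, nrow = n)
  rownames(geno) <- paste0("id", seq_len(n))
  map <- data.frame(snp = paste0("snp", seq_len(m)), chrom = "chr1",
                    pos = 1e6 + 1e4 * seq_len(m), maf = maf,
                    stringsAsFactors = FALSE)

  carrier <- rbinom(n, 1, carrier_freq) == 1
  minlow <- rnorm(n, minlow_mean, minlow_sd) + delta_minlow * carrier +
    as.vector(geno %*% snp_effects)
  g1 <- geno[, 1]
  vocab <- b[1] + b[2] * g1 + b[3] * minlow + b[4] * g1 * minlow +
    rnorm(n, 0, noise_sd)
  n_trunc <- sum(vocab < 0 | vocab > 246)
  if (n_trunc > 0.1 * n) {
    warning("more than 10% of vocabulary values truncated to [0, 246]; ",
            "coefficients will not be recoverable by least squares")
  }
  vocab <- pmin(pmax(vocab, 0), 246)
  zv <- as.vector(scale(vocab))

  corr_trait <- function(mu, s, rho, lo = -Inf, hi = Inf) {
    x <- mu + s * (rho * zv + sqrt(1 - rho^2) * rnorm(n))
    pmin(pmax(x, lo), hi)
  }
  wold <- corr_trait(7.76, 1.95, 0.5, lo = 0)
  ccc_fluency <- corr_trait(10, 3, 0.4, lo = 0)
  ccc_syntax <- corr_trait(10, 3, 0.4, lo = 0)
  nwr <- corr_trait(7.3, 2.5, 0.4, lo = 0, hi = 12)
  nviq <- rnorm(n, 100, 15)

  # ear-level 0.5 kHz thresholds whose across-ear minimum is exactly minlow
  left_is_min <- runif(n) < 0.5
  extra <- abs(rnorm(n, 0, 2))
  ac_l_500 <- ifelse(left_is_min, minlow, minlow + extra)
  ac_r_500 <- ifelse(left_is_min, minlow + extra, minlow)
  ear_thr <- function() rnorm(n, 8, 5)

  traits <- data.frame(
    id = rownames(geno), vocab = vocab, nwr = nwr, wold = wold,
    ccc_fluency = ccc_fluency, ccc_syntax = ccc_syntax, nviq = nviq,
    asd_flag = runif(n) < 0.01, sen_flag = runif(n) < 0.03,
    ethnicity = ifelse(runif(n) < 0.95, "British", "Other"),
    gestation_weeks = rnorm(n, 39.5, 1.8),
    birthweight_g = rnorm(n, 3400, 550),
    ac_l_500 = ac_l_500, ac_r_500 = ac_r_500,
    ac_l_1000 = ear_thr(), ac_r_1000 = ear_thr(),
    ac_l_2000 = ear_thr(), ac_r_2000 = ear_thr(),
    ac_l_4000 = ear_thr(), ac_r_4000 = ear_thr(),
    carrier_flag = carrier, stringsAsFactors = FALSE)

  list(genotypes = genotype_matrix(geno, map), traits = traits,
       truth = list(b = setNames(as.numeric(b), c("b0", "b1", "b2", "b3")),
                    carrier_freq = carrier_freq,
                    delta_minlow = delta_minlow, maf = maf,
                    snp_effects = snp_effects))
}

#' Simulate startle-trial and vocalization-syllable tables
#'
#' Startle amplitudes are log-normal per trial; cued-trial amplitudes are
#' scaled by a subject-level attenuation target so that genotype- and
#' frequency-specific detection deficits (by default a heterozygote deficit
#' on the low-frequency task and a knockout deficit on the high-frequency
#' task) raise the attenuation score on the affected task only. The raw
#' syllable table carries planted frequency/duration/volume shifts per
#' genotype plus out-of-band, out-of-duration and close-pair decoy syllables
#' for the filter to remove.
#'
#' @param seed Integer RNG seed.
#' @param n_per_genotype Named counts of subjects (default `c(WT = 12,
#'   HT = 12, KO = 11)`).
#' @param effects Named list of per-task attenuation-score shifts (score
#'   units) per genotype; default plants a 1-SD (12-point) HT deficit on the
#'   15-kHz task and a 1-SD KO deficit on the 40-kHz task.
#' @param usv_shift List of per-genotype shifts of syllable frequency (kHz),
#'   duration (ms) and volume (dB).
#' @param n_trials Cued (and uncued) trials per subject/task/day (default
#'   20).
#' @param days Testing days (default 1).
#' @param att_baseline,att_subject_sd Baseline attenuation score and
#'   between-subject SD (defaults 55 and 8).
#' @param n_syll Mean syllables per subject (default 150).
#' @return A list: `trials` (startle trial table), `syllables` (raw syllable
#'   table), `truth` (planted effects).
#' @export
sim_ppi_usv <- function(seed, n_per_genotype = c(WT = 12, HT = 12, KO = 11),
                        effects = list(HT = c(NST15 = 12, NST40 = 0),
                                       KO = c(NST15 = 0, NST40 = 12)),
                        usv_shift = list(HT = c(frequency = 5, duration = -5,
                                                volume = 4),
                                         KO = c(frequency = 3, duration = -2,
                                                volume = 2)),
                        n_trials = 20, days = 1, att_baseline = 55,
                        att_subject_sd = 8, n_syll = 150) {
  set.seed(seed)
  genos <- rep(names(n_per_genotype), n_per_genotype)
  subjects <- paste0(genos, seq_along(genos))
  tasks <- c("NST15", "NST40")
  trial_rows <- list()
  for (i in seq_along(subjects)) {
    base <- rlnorm(1, log(500), 0.2)
    re <- rnorm(1, 0, att_subject_sd)
    for (task in tasks) {
      eff <- if (genos[i] %in% names(effects)) effects[[genos[i]]][[task]] else 0
      att_t <- min(max(att_baseline + re + eff, 5), 140)
      for (d in seq_len(days)) {
        amp_unc <- base * exp(rnorm(n_trials, 0, 0.35))
        amp_cue <- base * (att_t / 100) * exp(rnorm(n_trials, 0, 0.35))
        trial_rows[[length(trial_rows) + 1]] <- data.frame(
          subject = subjects[i], genotype = genos[i], task = task, day = d,
          cue = sub("NST", "", task),
          condition = rep(c("uncued", "cued"), each = n_trials),
          amplitude = c(amp_unc, amp_cue), stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, trial_rows)

  categories <- c("Short", "Down-FM", "Up-FM", "Chevron", "Flat",
                  "1-Freq Step", "Noisy", "Complex")
  syll_rows <- list()
  for (i in seq_along(subjects)) {
    k <- max(10, stats::rpois(1, n_syll))
    sh <- if (genos[i] %in% names(usv_shift)) usv_shift[[genos[i]]] else
      c(frequency = 0, duration = 0, volume = 0)
    dur <- pmax(2, rnorm(k, 40 + sh[["duration"]], 12))
    freq <- rnorm(k, 75 + sh[["frequency"]], 9)
    # decoys: out-of-band frequencies and out-of-range durations
    oob <- runif(k) < 0.04
    freq[oob] <- sample(c(runif(sum(oob), 20, 34), runif(sum(oob), 111, 130)),
                        sum(oob))
    ood <- runif(k) < 0.04
    dur[ood] <- sample(c(runif(sum(ood), 2, 7), runif(sum(ood), 201, 250)),
                       sum(ood))
    gaps <- rexp(k, rate = 1 / 0.3)
    close <- runif(k) < 0.03
    gaps[close] <- runif(sum(close), 0, 0.004)  # < 5 ms apart
    onset <- cumsum(gaps + dur / 1000)
    syll_rows[[i]] <- data.frame(
      subject = subjects[i], genotype = genos[i], onset = onset,
      duration = dur, frequency = freq,
      volume = rnorm(k, 55 + sh[["volume"]], 5),
      category = sample(categories, k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  syllables <- do.call(rbind, syll_rows)
  rownames(trials) <- rownames(syllables) <- NULL
  list(trials = trials, syllables = syllables,
       truth = list(effects = effects, usv_shift = usv_shift,
                    att_baseline = att_baseline))
}
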