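mk_trials <- function(cued, uncued, subject = "m1", task = "NST15",
                      day = 1, cue = "15") {
  data.frame(subject = subject, task = task, day = day, cue = cue,
             condition = rep(c("cued", "uncued"), c(length(cued),
                                                    length(uncued))),
             amplitude = c(cued, uncued), stringsAsFactors = FALSE)
}

test_that("attenuation is 100 at equal means and follows the ratio formula", {
  t1 <- mk_trials(cued = c(40, 60), uncued = c(30, 70))
  expect_equal(attenuation_scores(t1)$att, 100)
  t2 <- mk_trials(cued = c(40, 60), uncued = c(80, 120))
  expect_equal(attenuation_scores(t2)$att, 50)
})

test_that("attenuation is scale-invariant within a cell (fuzzed)", {
  set.seed(41)
  for (i in 1:30) {
    cued <- runif(sample(2:8, 1), 1, 100)
    uncued <- runif(sample(2:8, 1), 1, 100)
    tr <- mk_trials(cued, uncued)
    a1 <- attenuation_scores(tr)$att
    k <- runif(1, 0.1, 10)
    tr$amplitude <- tr$amplitude * k
    expect_equal(attenuation_scores(tr)$att, a1, tolerance = 1e-9)
  }
})

test_that("cells without both conditions or with zero uncued mean are handled", {
  bad <- mk_trials(cued = c(10, 20), uncued = numeric(0))
  expect_error(attenuation_scores(bad), "m1")
  z <- mk_trials(cued = c(10, 20), uncued = c(0, 0))
  r <- attenuation_scores(z)
  expect_true(is.na(r$att))
  expect_match(r$note, "zero uncued mean")
})

test_that("one-way ANOVA on attenuation matches textbook arithmetic", {
  # 3 groups, n = 3, integer scores with hand-computable sums of squares
  sc <- data.frame(subject = paste0("m", 1:9),
                   genotype = rep(c("WT", "HT", "KO"), each = 3),
                   att = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  # SSB = 3*((2-5)^2 + (5-5)^2 + (8-5)^2) = 54; SSW = 6; F = 27/1 = 27
  r <- group_compare(sc)
  expect_equal(r$F, 27)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 6)
  expect_equal(r$p, pf(27, 2, 6, lower.tail = FALSE))
})

test_that("identical groups give F = 0 and p = 1", {
  sc <- data.frame(subject = paste0("m", 1:6),
                   genotype = rep(c("WT", "KO"), each = 3),
                   att = rep(c(50, 60, 70), 2))
  r <- group_compare(sc)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
})

test_that("covariate adjustment uses the group F after the covariate", {
  set.seed(42)
  sc <- data.frame(subject = paste0("m", 1:12),
                   genotype = rep(c("WT", "HT", "KO"), each = 4),
                   att = rnorm(12, 60, 5))
  cov <- setNames(rnorm(12, 50, 10), sc$subject)
  r <- group_compare(sc, covariate = cov)
  full <- lm(sc$att ~ cov[sc$subject] + sc$genotype)
  red <- lm(sc$att ~ cov[sc$subject])
  a <- anova(red, full)
  expect_equal(r$F, a$F[2])
  expect_equal(r$p, a$`Pr(>F)`[2])
  # zero-variance covariate is a singular design, not a silent fallback
  expect_error(group_compare(sc, covariate = setNames(rep(5, 12),
                                                      sc$subject)),
               "singular")
})

test_that("USV filter applies inclusive band/duration bounds exactly", {
  syl <- data.frame(onset = seq(0, by = 1, length.out = 8),
                    duration = c(50, 50, 50, 50, 7, 8, 200, 201),
                    frequency = c(34, 35, 110, 111, 60, 60, 60, 60),
                    volume = 55)
  out <- usv_filter(syl)
  expect_equal(out$frequency, c(35, 110, 60, 60))
  expect_equal(out$duration, c(50, 50, 8, 200))
})

test_that("close syllable pairs are removed (both members) and the filter is idempotent", {
  syl <- data.frame(onset = c(0, 0.053, 1, 1.055, 2),
                    duration = c(50, 50, 50, 50, 50),
                    frequency = 60, volume = 55)
  # gaps: 3 ms (pair removed), 5 ms exactly (kept), isolated kept
  out <- usv_filter(syl)
  expect_equal(out$onset, c(1, 1.055, 2))
  expect_equal(usv_filter(out), out)
  out_later <- usv_filter(syl, gap_removal = "later")
  expect_equal(out_later$onset, c(0, 1, 1.055, 2))
  # subset property
  expect_true(all(out$onset %in% syl$onset))
})

test_that("group summaries recover planted vocalization shifts", {
  sim <- sim_ppi_usv(55)
  filt <- usv_filter(sim$syllables)
  s <- usv_summaries(filt)
  expect_setequal(s$group, c("WT", "HT", "KO"))
  wt <- s[s$group == "WT", ]; ht <- s[s$group == "HT", ]
  shift <- ht$frequency_mean - wt$frequency_mean
  sem <- sqrt(wt$frequency_sem^2 + ht$frequency_sem^2)
  expect_lt(abs(shift - sim$truth$usv_shift$HT[["frequency"]]), 4 * sem)
  one <- data.frame(genotype = "WT", frequency = 60, duration = 50,
                    volume = 55)
  s1 <- usv_summaries(one)
  expect_equal(s1$frequency_mean, 60)
  expect_true(is.na(s1$frequency_sem))  # SEM undefined for n = 1
})

test_that("planted genotype-by-frequency detection deficits are detected in the right band", {
  hits_low <- 0; hits_high <- 0; worst_low <- 0; worst_high <- 0
  n_rep <- 15
  for (s in seq_len(n_rep)) {
    sim <- sim_ppi_usv(770 + s)
    att <- attenuation_scores(sim$trials)
    low <- group_compare(att[att$task == "NST15", ])
    high <- group_compare(att[att$task == "NST40", ])
    hits_low <- hits_low + (low$p < 0.05)
    hits_high <- hits_high + (high$p < 0.05)
    worst_low <- worst_low + (names(which.max(low$means)) == "HT")
    worst_high <- worst_high + (names(which.max(high$means)) == "KO")
  }
  expect_gte(hits_low / n_rep, 0.6)   # planted 1-SD HT deficit at 15 kHz
  expect_gte(hits_high / n_rep, 0.6)  # planted 1-SD KO deficit at 40 kHz
  expect_gte(worst_low / n_rep, 0.8)
  expect_gte(worst_high / n_rep, 0.8)
})
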