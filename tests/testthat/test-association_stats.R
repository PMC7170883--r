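mk_gm <- function(geno, pos = NULL) {
  m <- ncol(geno)
  rownames(geno) <- paste0("id", seq_len(nrow(geno)))
  genotype_matrix(geno, data.frame(snp = paste0("s", seq_len(m)),
                                   chrom = "chr1",
                                   pos = if (is.null(pos)) seq_len(m) * 1e4
                                         else pos,
                                   stringsAsFactors = FALSE))
}

test_that("HWE chi-square matches hand computation", {
  expect_equal(hwe_chisq(25, 50, 25)$chisq, 0)
  r <- hwe_chisq(30, 40, 30)
  expect_equal(r$chisq, 4)
  expect_equal(r$p, pchisq(4, 1, lower.tail = FALSE))
})

test_that("SNP QC removes low-MAF, high-missingness and HWE-violating SNPs", {
  set.seed(1)
  n <- 300
  geno <- sapply(rep(0.3, 30), function(p) rbinom(n, 2, p))
  geno[, 2] <- rbinom(n, 2, 0.02)            # MAF < 5%
  # 10% missingness on SNP 3, spread so no sample drops below 95% call rate
  geno[seq(1, n, by = 10), 3] <- NA
  geno[, 4] <- c(rep(0, n / 2), rep(2, n / 2))  # gross HWE violation
  gm <- suppressMessages(snp_qc(mk_gm(geno)))
  expect_false(any(c("s2", "s3", "s4") %in% gm$map$snp))
  expect_true("s1" %in% gm$map$snp)
})

test_that("sample call-rate and heterozygosity-outlier filters act first", {
  set.seed(2)
  geno <- sapply(rep(0.4, 200), function(p) rbinom(60, 2, p))
  geno[1, ] <- NA                      # empty sample
  geno[2, ] <- rep(c(0, 2), 100)       # het rate 0 while others ~ 0.48
  gm <- suppressMessages(snp_qc(mk_gm(geno)))
  expect_false("id1" %in% rownames(gm$geno))
  expect_false("id2" %in% rownames(gm$geno))
  expect_true("id3" %in% rownames(gm$geno))
})

test_that("differential missingness between cases and controls is screened", {
  set.seed(3)
  n <- 400
  geno <- sapply(rep(0.4, 40), function(p) rbinom(n, 2, p))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  geno[1:150, 2] <- NA  # missing only in cases; samples keep 39/40 calls
  gm <- suppressMessages(snp_qc(mk_gm(geno), labels = labels,
                                miss_max = 0.5))
  expect_false("s2" %in% gm$map$snp)
  expect_true("s1" %in% gm$map$snp)
})

test_that("ld_r2 is the squared dosage correlation", {
  g <- c(0, 1, 2, 0, 1, 2)
  expect_equal(ld_r2(g, g), 1)
  g1 <- c(0, 1, 2, 0); g2 <- c(0, 1, 2, 2)
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  set.seed(4)
  r2 <- replicate(300, ld_r2(rbinom(1e3, 2, 0.3), rbinom(1e3, 2, 0.3)))
  expect_equal(mean(r2), 1 / 1e3, tolerance = 0.2)  # null E[r2] ~ 1/n
})

test_that("greedy tagging covers all SNPs without redundant tags", {
  set.seed(6)
  base <- rbinom(300, 2, 0.4)
  flip <- function(g, k) { i <- sample(300, k); g[i] <- 2 - g[i]; g }
  geno <- cbind(base, flip(base, 10), rbinom(300, 2, 0.4), base)
  gm <- mk_gm(geno)
  tags <- greedy_tag(gm)
  # coverage: every non-tag correlated >= 0.8 with some tag
  for (s in setdiff(gm$map$snp, tags)) {
    r2s <- vapply(tags, function(t) ld_r2(gm$geno[, s], gm$geno[, t]),
                  numeric(1))
    expect_gte(max(r2s), 0.8)
  }
  # no two tags linked at >= 0.8
  if (length(tags) > 1) {
    for (i in 1:(length(tags) - 1)) for (j in (i + 1):length(tags)) {
      expect_lt(ld_r2(gm$geno[, tags[i]], gm$geno[, tags[j]]), 0.8)
    }
  }
  # exact duplicates collapse to one tag
  expect_false(all(c("s1", "s4") %in% tags))
  # independent SNPs are all tags
  ind <- mk_gm(sapply(c(0.2, 0.3, 0.4), function(p) rbinom(500, 2, p)))
  expect_equal(greedy_tag(ind), c("s1", "s2", "s3"))
})

test_that("three-SNP chain r2(1,2), r2(2,3) high picks the middle tag", {
  # construct dosages with known correlation structure
  set.seed(8)
  mid <- rbinom(4000, 2, 0.5)
  mk_corr <- function(g, k) { i <- sample(4000, k); g[i] <- sample(0:2, k,
    replace = TRUE); g }
  g1 <- mk_corr(mid, 250); g3 <- mk_corr(mid, 250)
  gm <- mk_gm(cbind(g1, mid, g3))
  stopifnot(ld_r2(g1, mid) >= 0.8, ld_r2(mid, g3) >= 0.8,
            ld_r2(g1, g3) < 0.8)
  expect_equal(greedy_tag(gm), "s2")
})

test_that("additive association solves the noiseless model exactly", {
  g <- rep(0:2, each = 10)
  y <- 2 + 3 * g
  r <- suppressWarnings(assoc_additive(y, g))  # noiseless: perfect fit
  expect_equal(r$beta, 3, tolerance = 1e-12)
  expect_error(assoc_additive(y, rep(1, 30)), "constant dosage")
  expect_error(assoc_additive(y[1:5], g[1:5]), "fewer than 10")
})

test_that("logistic association flags perfect separation", {
  g <- rep(0:2, each = 10)
  y <- as.numeric(g > 0)
  r <- assoc_additive(y, g, trait_kind = "binary")
  expect_equal(r$flag, "separation")
  expect_true(is.na(r$p))
  set.seed(10)
  y2 <- rbinom(30, 1, 0.4)
  r2 <- assoc_additive(y2, g, trait_kind = "binary")
  expect_equal(r2$flag, "")
})

test_that("interaction fit recovers noiseless coefficients to machine precision", {
  set.seed(12)
  g <- rbinom(100, 2, 0.4); c_ <- rnorm(100, 10, 3)
  y <- 1 + 0.5 * g + 0.2 * c_ + 0.3 * g * c_
  f <- suppressWarnings(fit_interaction(y, g, c_))  # noiseless: perfect fit
  expect_equal(unname(f$coef), c(1, 0.5, 0.2, 0.3), tolerance = 1e-9)
})

test_that("interaction fit equals the normal-equations solution", {
  set.seed(13)
  for (i in 1:5) {
    g <- rbinom(80, 2, 0.3); c_ <- rnorm(80, 5, 2)
    y <- rnorm(80, 2 + 0.1 * g - 0.2 * c_ + 0.15 * g * c_, 1)
    f <- fit_interaction(y, g, c_)
    o <- oracle_ols(y, cbind(1, g, c_, g * c_))
    expect_equal(unname(f$coef), o$beta, tolerance = 1e-9)
    expect_equal(unname(f$se), o$se, tolerance = 1e-9)
  }
})

test_that("rank-deficient interaction designs are rejected with the column named", {
  g <- rbinom(50, 2, 0.4)
  expect_error(fit_interaction(rnorm(50), g, rep(2, 50)), "collinear")
  expect_error(fit_interaction(rnorm(15), g[1:15], rnorm(15)),
               "fewer than 20")
})

test_that("type-I error of the interaction test is nominal under b3 = 0", {
  set.seed(14)
  rej <- vapply(1:600, function(i) {
    g <- rbinom(300, 2, 0.3); c_ <- rnorm(300, 10, 3)
    y <- 1 + 0.5 * g + 0.2 * c_ + rnorm(300)
    fit_interaction(y, g, c_)$p["b3"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("single common variant with flat weights reduces to the score test", {
  set.seed(15)
  for (i in 1:3) {
    g <- rbinom(2000, 2, 0.3)
    y <- rnorm(2000) + 0.02 * g
    sk <- skat_test(y, matrix(g, ncol = 1), weights = "flat")
    aa <- assoc_additive(y, g)
    expect_equal(sk$p, aa$p, tolerance = 5e-4)
  }
})

test_that("skat_test handles degenerate input and covariates", {
  y <- rnorm(100)
  expect_error(skat_test(y, matrix(0, 100, 3)), "zero polymorphic")
  set.seed(16)
  G <- sapply(runif(5, 0.1, 0.4), function(p) rbinom(100, 2, p))
  x <- rnorm(100)
  r <- skat_test(y + 0.5 * x, G, covariates = cbind(x))
  expect_true(r$p > 0 && r$p <= 1)
  expect_gte(r$Q, 0)
})

test_that("small samples fall back to a seeded permutation p-value", {
  set.seed(17)
  G <- sapply(runif(4, 0.2, 0.4), function(p) rbinom(30, 2, p))
  y <- rnorm(30)
  set.seed(99); r1 <- skat_test(y, G)
  set.seed(99); r2 <- skat_test(y, G)
  expect_equal(r1$method, "permutation")
  expect_identical(r1$p, r2$p)
})

test_that("skat p is invariant under joint sample relabeling", {
  set.seed(18)
  G <- sapply(runif(6, 0.1, 0.4), function(p) rbinom(200, 2, p))
  y <- rnorm(200) + 0.2 * G[, 1]
  r1 <- skat_test(y, G)
  perm <- sample(200)
  r2 <- skat_test(y[perm], G[perm, ])
  expect_equal(r1$Q, r2$Q, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("maf_range restricts the tested variant set", {
  set.seed(19)
  G <- cbind(c(rep(1, 3), rep(0, 297)),  # MAF 0.005
             rbinom(300, 2, 0.3))
  y <- rnorm(300)
  rare <- skat_test(y, G, maf_range = c(0, 0.01))
  common <- skat_test(y, G, maf_range = c(0.05, 0.5))
  expect_equal(rare$n_variants, 1)
  expect_equal(common$n_variants, 1)
})

test_that("Bonferroni thresholds behave as alpha/n", {
  expect_equal(bonferroni(1), 0.05)
  expect_equal(bonferroni(635), 0.05 / 635)
  expect_true(all(diff(sapply(1:20, bonferroni)) < 0))
  expect_error(bonferroni(0), "n_tests")
})

test_that("power limits: r2 = 0 gives alpha; alpha -> 1 gives power 1", {
  expect_equal(power_variance_explained(1000, 0, 0.05), 0.05, tolerance = 1e-9)
  expect_equal(power_variance_explained(1000, 0.01, 1), 1)
  p1 <- power_variance_explained(500, 0.02, 0.001)
  p2 <- power_variance_explained(2000, 0.02, 0.001)
  expect_gt(p2, p1)  # monotone in n
})

test_that("analytic power matches the seeded simulation", {
  set.seed(20)
  a <- power_variance_explained(800, 0.01, 0.01)
  s <- power_variance_explained(800, 0.01, 0.01, method = "simulation",
                                nsim = 2000)
  expect_lt(abs(a - s), 0.03)
})

test_that("enrichment p equals the hypergeometric tail and BH behaves", {
  # 2x2 (a=8 hits in term, 2 hits out; 10 non-hit in term, 80 out)
  hits <- paste0("h", 1:10)
  bg <- c(hits, paste0("n", 1:90))
  term <- c(paste0("h", 1:8), paste0("n", 1:10))
  sets <- list(T1 = term)
  r <- enrich_fisher_fdr(hits, bg, sets)
  tail_p <- sum(dhyper(8:10, 18, 82, 10))
  expect_equal(r$p, tail_p, tolerance = 1e-12)
  expect_equal(r$q, r$p)  # single term: q = p
  # term equal to the hit set is the most enriched among terms
  sets2 <- list(exact = hits, half = c(hits[1:5], paste0("n", 1:40)),
                none = paste0("n", 41:80))
  r2 <- enrich_fisher_fdr(hits, bg, sets2)
  expect_equal(r2$term[which.min(r2$p)], "exact")
  expect_true(all(diff(r2$q[order(r2$p)]) >= -1e-12))  # q monotone in p
  expect_warning(r3 <- enrich_fisher_fdr(hits, bg, list(T1 = term,
                                                        empty = "zzz")),
                 "zero background overlap")
  expect_equal(nrow(r3), 1)
  expect_error(suppressWarnings(
    enrich_fisher_fdr(hits, bg, list(empty = "zzz"))), "no testable")
})
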