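#' Construct a genotype matrix object
#'
#' @param geno Numeric matrix of dosages 0/1/2/`NA`, samples in rows
#'   (rownames = ids), SNPs in columns.
#' @param map `data.frame` with `snp`, `chrom`, `pos` (and optionally allele
#'   columns), one row per SNP column.
#' @return List of class `"genotype_matrix"` with `geno`, `map`.
#' @export
genotype_matrix <- function(geno, map) {
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno))
  colnames(geno) <- map$snp
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

# minor allele frequency per SNP from dosage codes
snp_maf <- function(geno) {
  f <- colMeans(geno, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts with
#' the proportions expected from the estimated allele frequency.
#'
#' @param n0,n1,n2 Counts of reference-homozygote, heterozygote and
#'   alternate-homozygote genotypes.
#' @return List with `chisq` and `p`.
#' @export
#' @examples
#' hwe_chisq(30, 40, 30)  # chi-square 4, p ~ 0.0455
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(list(chisq = NA_real_, p = NA_real_))
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(e == 0)) return(list(chisq = 0, p = 1))
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  list(chisq = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
}

#' SNP and sample quality control for association analyses
#'
#' Sample filters are applied first: samples with a genotype call rate below
#' `sample_callrate_min`, or with an autosomal heterozygosity rate more than
#' `het_sd` standard deviations from the sample mean, are removed. SNP
#' filters follow on the surviving samples: minor allele frequency below
#' `maf_min`, missingness above `miss_max`, Hardy-Weinberg chi-square
#' p below `hwe_p_min`, or (when case/control labels are supplied)
#' differential missingness between cases and controls at Fisher exact
#' p below `diff_miss_p`.
#'
#' @param gm A [genotype_matrix()].
#' @param labels Optional logical/0-1 case labels for differential
#'   missingness.
#' @param maf_min,miss_max,hwe_p_min,diff_miss_p,sample_callrate_min,het_sd
#'   Thresholds; defaults are the standard array-QC values (MAF 5 percent,
#'   5 percent missingness, HWE p 5e-7, Fisher p 1e-5, 95 percent sample call
#'   rate, 3 SD heterozygosity).
#' @return Filtered `genotype_matrix`; an error if nothing survives.
#' @export
snp_qc <- function(gm, labels = NULL, maf_min = 0.05, miss_max = 0.05,
                   hwe_p_min = 5e-7, diff_miss_p = 1e-5,
                   sample_callrate_min = 0.95, het_sd = 3) {
  geno <- gm$geno
  cr <- rowMeans(!is.na(geno))
  het <- rowMeans(geno == 1, na.rm = TRUE)
  het_mu <- mean(het, na.rm = TRUE)
  het_s <- sd(het, na.rm = TRUE)
  het_ok <- if (is.na(het_s) || het_s == 0) rep(TRUE, nrow(geno)) else
    abs(het - het_mu) <= het_sd * het_s
  het_ok[is.na(het_ok)] <- TRUE  # all-missing samples fail on call rate
  keep_s <- cr >= sample_callrate_min & het_ok
  message("snp_qc: removing ", sum(!keep_s), " of ", length(keep_s), " samples")
  geno <- geno[keep_s, , drop = FALSE]
  if (!is.null(labels)) labels <- as.logical(labels)[keep_s]

  maf <- snp_maf(geno)
  miss <- colMeans(is.na(geno))
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    hwe_chisq(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
              sum(g == 2, na.rm = TRUE))$p
  }, numeric(1))
  drop <- is.na(maf) | maf < maf_min | miss > miss_max |
    (!is.na(hwe_p) & hwe_p < hwe_p_min)
  if (!is.null(labels) && any(labels) && any(!labels)) {
    dm_p <- vapply(seq_len(ncol(geno)), function(j) {
      mis <- is.na(geno[, j])
      tab <- table(factor(mis, c(FALSE, TRUE)), factor(labels, c(FALSE, TRUE)))
      fisher.test(tab)$p.value
    }, numeric(1))
    drop <- drop | dm_p < diff_miss_p
  }
  message("snp_qc: removing ", sum(drop), " of ", length(drop), " SNPs")
  if (all(drop) || nrow(geno) == 0) stop("no SNPs survive QC")
  genotype_matrix(geno[, !drop, drop = FALSE], gm$map[!drop, , drop = FALSE])
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Composite (genotypic) LD: the squared Pearson correlation of dosages over
#' complete pairs; no phasing is attempted.
#'
#' @param g1,g2 Dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA` when fewer than 2 complete pairs or
#'   either SNP has zero variance.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  if (var(g1[ok]) == 0 || var(g2[ok]) == 0) return(NA_real_)
  cor(g1[ok], g2[ok])^2
}

#' Greedy pairwise tag-SNP selection
#'
#' Selects a tag set such that every non-tag SNP has r-squared at least
#' `r2_max` with some tag and no two tags reach `r2_max` with each other.
#' SNPs are chosen greedily by descending count of not-yet-covered neighbours
#' (r-squared >= `r2_max`), breaking ties by map position.
#'
#' @param gm A [genotype_matrix()] (after [snp_qc()]).
#' @param r2_max Tagging threshold (default 0.8); the retained tag set is the
#'   pruned "R2 < 0.8" panel.
#' @return Character vector of tag SNP ids.
#' @export
greedy_tag <- function(gm, r2_max = 0.8) {
  m <- ncol(gm$geno)
  if (m == 0) return(character(0))
  r2 <- suppressWarnings(cor(gm$geno, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  diag(r2) <- 1
  neighbour <- r2 >= r2_max
  uncovered <- rep(TRUE, m)
  ord <- order(gm$map$chrom, gm$map$pos)
  pos_rank <- match(seq_len(m), ord)
  tags <- integer(0)
  while (any(uncovered)) {
    counts <- colSums(neighbour[uncovered, , drop = FALSE])
    counts[!uncovered] <- -1
    best <- which(counts == max(counts))
    best <- best[which.min(pos_rank[best])]
    tags <- c(tags, best)
    uncovered <- uncovered & !neighbour[best, ]
  }
  gm$map$snp[sort(tags)]
}

#' Single-SNP additive association
#'
#' Slope test of `y ~ dosage`: ordinary least squares (identity link) for a
#' quantitative trait, logistic regression for a binary trait; two-sided Wald
#' p-value.
#'
#' @param y Trait vector (0/1 when `trait_kind = "binary"`).
#' @param g Dosage vector.
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @return One-row `data.frame`: `beta` (log odds ratio for binary), `se`,
#'   `stat`, `p`, `n_used`, `flag` (e.g. `"separation"` for a logistic fit
#'   with no finite estimate, in which case `p` is `NA`).
#' @export
assoc_additive <- function(y, g, trait_kind = c("quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  ok <- !is.na(y) & !is.na(g)
  if (sum(ok) < 10) stop("fewer than 10 complete observations")
  y <- y[ok]; g <- g[ok]
  if (var(g) == 0) stop("constant dosage")
  if (trait_kind == "quantitative") {
    fit <- lm(y ~ g)
    s <- summary(fit)$coefficients
    data.frame(beta = s["g", 1], se = s["g", 2], stat = s["g", 3],
               p = s["g", 4], n_used = length(y), flag = "",
               stringsAsFactors = FALSE)
  } else {
    fit <- suppressWarnings(glm(y ~ g, family = binomial()))
    s <- summary(fit)$coefficients
    sep <- !fit$converged || s["g", 2] > 50 || abs(s["g", 1]) > 20
    data.frame(beta = s["g", 1], se = s["g", 2], stat = s["g", 3],
               p = if (sep) NA_real_ else s["g", 4], n_used = length(y),
               flag = if (sep) "separation" else "", stringsAsFactors = FALSE)
  }
}

#' Additive association across a genotype matrix
#'
#' Applies [assoc_additive()] per SNP; SNPs with constant dosage or too few
#' complete observations are reported with `NA` statistics and a flag rather
#' than stopping the scan.
#'
#' @param y Trait vector.
#' @param gm A [genotype_matrix()].
#' @inheritParams assoc_additive
#' @return `data.frame` with one row per SNP (`snp`, `beta`, `se`, `stat`,
#'   `p`, `n_used`, `flag`).
#' @export
assoc_scan <- function(y, gm, trait_kind = c("quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  rows <- lapply(seq_len(ncol(gm$geno)), function(j) {
    r <- tryCatch(assoc_additive(y, gm$geno[, j], trait_kind),
                  error = function(e) {
                    data.frame(beta = NA_real_, se = NA_real_, stat = NA_real_,
                               p = NA_real_, n_used = NA_integer_,
                               flag = conditionMessage(e),
                               stringsAsFactors = FALSE)
                  })
    cbind(snp = gm$map$snp[j], r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genotype-by-covariate interaction regression
#'
#' Ordinary least squares on the design `Y = b0 + b1*ADD + b2*COV1 +
#' b3*ADD:COV1 + e`, where ADD is the additive dosage and COV1 the
#' interacting covariate (e.g. a hearing threshold). The interaction
#' coefficient `b3` carries the gene-by-environment signal; all four
#' coefficients are reported with Wald statistics.
#'
#' @param y Outcome vector.
#' @param g Dosage vector (ADD).
#' @param cov Covariate vector (COV1).
#' @return List of class `"interaction_fit"`: `coef` (b0..b3), `se`, `stat`,
#'   `p`, `n_used`.
#' @export
fit_interaction <- function(y, g, cov) {
  ok <- !is.na(y) & !is.na(g) & !is.na(cov)
  if (sum(ok) < 20) stop("fewer than 20 complete observations")
  y <- y[ok]; g <- g[ok]; cov <- cov[ok]
  X <- cbind(b0 = 1, b1_add = g, b2_cov = cov, b3_add_x_cov = g * cov)
  q <- qr(X)
  if (q$rank < 4) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):4]]
    stop("rank-deficient interaction design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm(y ~ g + cov + g:cov)
  s <- summary(fit)$coefficients
  structure(list(coef = setNames(s[, 1], c("b0", "b1", "b2", "b3")),
                 se = setNames(s[, 2], c("b0", "b1", "b2", "b3")),
                 stat = setNames(s[, 3], c("b0", "b1", "b2", "b3")),
                 p = setNames(s[, 4], c("b0", "b1", "b2", "b3")),
                 n_used = length(y)),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Interaction model Y = b0 + b1.ADD + b2.COV1 + b3.ADDxCOV1 (n =",
      x$n_used, ")\n")
  print(data.frame(coef = x$coef, se = x$se, stat = x$stat, p = x$p))
  invisible(x)
}

# p-value for Q ~ sum(lambda_i * chisq_1) by moment matching
# (match skewness/kurtosis to a (non)central chi-square)
liu_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- 1 / s1^2
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2) * a
  t_star <- (q - c1) / sqrt(2 * c2)
  p <- pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Variance-component (SKAT-style) gene-based association test
#'
#' Score-type quadratic-form test aggregating weighted variant effects within
#' a gene, robust to mixed effect directions: `Q = r' G W^2 G' r` with `r`
#' the residuals of the null model (intercept plus covariates) and `W` a
#' diagonal weight matrix. Missing genotypes are mean-imputed. The p-value
#' comes from a moment-matched mixture-of-chi-squares approximation to the
#' null distribution of Q; with fewer than `n_asymp` samples (or if the
#' approximation fails) a residual-permutation p-value is used instead, which
#' depends on the caller-set RNG seed.
#'
#' @param y Quantitative trait vector.
#' @param G Genotype submatrix (samples x variants, dosages 0/1/2/`NA`).
#' @param weights `"beta"` for the standard Beta(1, 25) density on the minor
#'   allele frequency, or `"flat"` for unweighted.
#' @param covariates Optional numeric matrix/data.frame of null-model
#'   covariates.
#' @param maf_range Optional `c(lo, hi)` to subset variants by MAF, e.g.
#'   `c(0, 0.01)` for rare or `c(0.05, 0.5)` for common variants.
#' @param n_asymp Minimum sample size for the asymptotic p-value (default 50).
#' @param n_perm Permutations for the small-sample fallback (default 1000).
#' @return List of class `"skat_result"`: `Q`, `p`, `n_variants`, `weights`,
#'   `method` (`"asymptotic"` or `"permutation"`).
#' @export
skat_test <- function(y, G, weights = c("beta", "flat"), covariates = NULL,
                      maf_range = NULL, n_asymp = 50, n_perm = 1000) {
  weights <- match.arg(weights)
  G <- as.matrix(G)
  ok <- !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  y <- y[ok]
  G <- G[ok, , drop = FALSE]
  n <- length(y)
  # mean-impute missing dosages, then drop monomorphic columns
  for (j in seq_len(ncol(G))) {
    mis <- is.na(G[, j])
    if (any(mis)) G[mis, j] <- mean(G[, j], na.rm = TRUE)
  }
  maf <- snp_maf(G)
  keep <- apply(G, 2, var) > 0
  if (!is.null(maf_range)) keep <- keep & maf >= maf_range[1] & maf <= maf_range[2]
  if (!any(keep)) stop("zero polymorphic variants in the tested set")
  G <- G[, keep, drop = FALSE]
  maf <- maf[keep]
  w <- if (weights == "beta") dbeta(maf, 1, 25) else rep(1, ncol(G))

  X <- cbind(rep(1, n), covariates)
  fit <- lm.fit(X, y)
  r <- fit$residuals
  s2 <- sum(r^2) / (n - ncol(X))
  Gw <- sweep(G, 2, w, `*`)
  Q <- sum(crossprod(Gw, r)^2)

  XtXi <- solve(crossprod(X))
  XtGw <- crossprod(X, Gw)
  M <- crossprod(Gw) - t(XtGw) %*% XtXi %*% XtGw
  lambda <- s2 * eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-12]

  method <- "asymptotic"
  p <- if (length(lambda)) tryCatch(liu_pvalue(Q, lambda),
                                    error = function(e) NA_real_) else NA_real_
  if (n < n_asymp || is.na(p)) {
    method <- "permutation"
    qs <- vapply(seq_len(n_perm), function(b) {
      rp <- sample(r)
      sum(crossprod(Gw, rp)^2)
    }, numeric(1))
    p <- (1 + sum(qs >= Q)) / (n_perm + 1)
  }
  structure(list(Q = Q, p = p, n_variants = ncol(G), weights = weights,
                 method = method), class = "skat_result")
}

#' @export
print.skat_result <- function(x, ...) {
  cat("SKAT-style test: Q =", signif(x$Q, 4), " p =", signif(x$p, 4),
      " (", x$n_variants, "variants,", x$weights, "weights,", x$method, ")\n")
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise alpha (default 0.05).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni(635)  # 7.87e-05 to three significant figures
bonferroni <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a single integer >= 1")
  }
  alpha / n_tests
}

#' Power to detect a variant explaining a fraction of trait variance
#'
#' Analytic method: the additive test statistic under the alternative is a
#' 1-df noncentral chi-square with noncentrality `n * r2 / (1 - r2)`; power
#' is the probability it exceeds the central critical value at `alpha`. The
#' simulation method draws a standardized predictor and a trait with the
#' stated variance explained and counts rejections of the slope test.
#'
#' @param n Sample size.
#' @param r2 Fraction of trait variance explained (0 gives power = alpha).
#' @param alpha Significance level.
#' @param method `"ncp_chi2_1df"` or `"simulation"`.
#' @param nsim Simulation replicates (default 5000); the caller controls the
#'   seed.
#' @return Estimated power in `[0, 1]`.
#' @export
power_variance_explained <- function(n, r2, alpha,
                                     method = c("ncp_chi2_1df", "simulation"),
                                     nsim = 5000) {
  stopifnot(r2 >= 0, r2 < 1, alpha > 0, alpha <= 1)
  method <- match.arg(method)
  if (method == "ncp_chi2_1df") {
    if (alpha == 1) return(1)
    ncp <- n * r2 / (1 - r2)
    crit <- qchisq(1 - alpha, df = 1)
    pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  } else {
    hits <- vapply(seq_len(nsim), function(i) {
      x <- rnorm(n)
      y <- sqrt(r2) * x + sqrt(1 - r2) * rnorm(n)
      rho <- cor(x, y)
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(abs(tval), df = n - 2, lower.tail = FALSE) < alpha
    }, logical(1))
    mean(hits)
  }
}

#' Gene-set over-representation by Fisher exact test with FDR correction
#'
#' One-sided (enrichment) Fisher exact test on the 2x2 table of hit/term
#' membership over the background, with Benjamini-Hochberg q-values across
#' the tested terms. Terms with zero background overlap are skipped with a
#' warning.
#'
#' @param hits Character vector of hit genes (must be a subset of
#'   `background`).
#' @param background Character vector of background genes.
#' @param term_sets Named list of character vectors, one per term.
#' @return `data.frame`: `term`, `n_term` (background overlap), `n_hit`
#'   (hits in term), `odds_ratio`, `p`, `q`.
#' @export
enrich_fisher_fdr <- function(hits, background, term_sets) {
  hits <- unique(hits); background <- unique(background)
  if (!all(hits %in% background)) stop("hits must be a subset of background")
  if (length(term_sets) == 0) stop("no terms supplied")
  rows <- lapply(names(term_sets), function(term) {
    tg <- intersect(term_sets[[term]], background)
    if (length(tg) == 0) {
      warning("term with zero background overlap skipped: ", term)
      return(NULL)
    }
    a <- sum(hits %in% tg)
    b <- length(hits) - a
    c_ <- length(tg) - a
    d <- length(background) - length(hits) - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2), alternative = "greater")
    data.frame(term = term, n_term = length(tg), n_hit = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) stop("no testable terms")
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
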