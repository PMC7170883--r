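# Independent brute-force oracles used to cross-check the pipeline.
# These deliberately re-derive each result with plain loops and one-shot
# predicates rather than calling the implementation's code paths.

# one-shot conjunction of all cascade predicates (no staging)
oracle_cascade_final <- function(shared, regions,
                                 consequence_set = c("frameshift", "missense",
                                                     "canonical_splice",
                                                     "stop_gain", "stop_loss",
                                                     "start_gain", "start_loss"),
                                 dbs = c("db1", "db2")) {
  keep <- logical(nrow(shared))
  for (i in seq_len(nrow(shared))) {
    p0 <- shared$pos[i] - 1
    in_reg <- FALSE
    for (r in seq_len(nrow(regions))) {
      if (regions$chrom[r] == shared$chrom[i] &&
          p0 >= regions$start[r] && p0 < regions$end[r]) in_reg <- TRUE
    }
    coding <- shared$consequence[i] %in% consequence_set
    novel <- TRUE
    for (db in dbs) {
      f <- shared[[paste0("freq_", db)]][i]
      if (!is.na(f) && f != 0) novel <- FALSE
    }
    keep[i] <- in_reg && coding && novel
  }
  shared[keep, , drop = FALSE]
}

# random variant fixture for cascade property tests
rand_cascade_fixture <- function(seed, n_max = 200) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  pos <- sample(1:5e6, n)
  df <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = pos, id = ".", ref = "A", alt = "T",
    qual = runif(n, 0, 60),
    s1 = sample(c(0, 1, 2, NA), n, replace = TRUE),
    s2 = sample(c(0, 1, 2, NA), n, replace = TRUE),
    consequence = sample(c("missense", "synonymous", "stop_gain", "noncoding"),
                         n, replace = TRUE),
    freq_db1 = sample(c(NA, 0, 0.01, 0.2), n, replace = TRUE),
    freq_db2 = sample(c(NA, 0, 0.05), n, replace = TRUE),
    stringsAsFactors = FALSE)
  attr(df, "samples") <- c("s1", "s2")
  nreg <- sample(1:4, 1)
  st <- sort(sample(1:4e6, nreg))
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), nreg, replace = TRUE),
                        start = st, end = st + sample(1e5:1e6, nreg,
                                                      replace = TRUE),
                        stringsAsFactors = FALSE)
  list(variants = df, regions = regions)
}

# all-pairs brute-force consensus: qualifying pairs, greedy best first
oracle_consensus <- function(calls_a, calls_b, mask = NULL, min_snps = 3,
                             min_score = 10, min_ro = 0.5) {
  cand <- list()
  for (i in seq_len(nrow(calls_a))) {
    for (j in seq_len(nrow(calls_b))) {
      a <- calls_a[i, ]; b <- calls_b[j, ]
      if (a$chrom != b$chrom || a$state != b$state) next
      if (a$n_snps < min_snps || b$n_snps < min_snps) next
      if (!(a$score > min_score) || !(b$score > min_score)) next
      ov <- min(a$end, b$end) - max(a$start, b$start)
      if (ov <= 0) next
      fa <- ov / (a$end - a$start); fb <- ov / (b$end - b$start)
      if (fa < min_ro || fb < min_ro) next
      cand[[length(cand) + 1]] <- c(i = i, j = j, prod = fa * fb,
                                    sa = a$start, sb = b$start)
    }
  }
  out <- NULL
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "prod"], cand[, "sa"], cand[, "sb"]), ,
                 drop = FALSE]
    ua <- rep(FALSE, nrow(calls_a)); ub <- rep(FALSE, nrow(calls_b))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, "i"]; j <- cand[k, "j"]
      if (ua[i] || ub[j]) next
      ua[i] <- TRUE; ub[j] <- TRUE
      s <- max(calls_a$start[i], calls_b$start[j])
      e <- min(calls_a$end[i], calls_b$end[j])
      drop <- FALSE
      if (!is.null(mask)) {
        for (r in seq_len(nrow(mask))) {
          if (mask$chrom[r] == calls_a$chrom[i] &&
              min(e, mask$end[r]) > max(s, mask$start[r])) drop <- TRUE
        }
      }
      if (!drop) {
        out <- rbind(out, data.frame(chrom = calls_a$chrom[i], start = s,
                                     end = e, state = calls_a$state[i],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), state = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random CNV call sets for the consensus property test
rand_callset <- function(seed, n_max = 20) {
  set.seed(seed)
  mk <- function() {
    n <- sample(0:n_max, 1)
    if (n == 0) {
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), state = character(0),
                        score = numeric(0), n_snps = numeric(0),
                        stringsAsFactors = FALSE))
    }
    s <- sample(1:1e6, n)
    data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = s, end = s + sample(1e3:1e5, n, replace = TRUE),
               state = sample(c("del", "dup"), n, replace = TRUE),
               score = runif(n, 0, 30), n_snps = sample(1:20, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  ms <- sample(1:9e5, 2)
  list(a = mk(), b = mk(),
       mask = data.frame(chrom = c("chr1", "chr2"), start = ms,
                         end = ms + 5e4, stringsAsFactors = FALSE))
}

# normal-equations OLS with classical SEs
oracle_ols <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  r <- y - X %*% beta
  s2 <- sum(r^2) / (length(y) - ncol(X))
  list(beta = as.vector(beta), se = unname(sqrt(diag(XtXi) * s2)))
}
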