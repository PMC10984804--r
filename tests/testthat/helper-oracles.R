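# Independent oracles used to check the package implementations. These are
# deliberately written as plain step-by-step code (loops, explicit formulas)
# and share nothing with the package internals.

# Benjamini-Hochberg step-up: reject the hypotheses with the k smallest
# p-values where k is the largest index with p_(k) <= k/m * alpha.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) {
    if (ps[i] <= i / m * alpha) k <- i
  }
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Trimmed mean of M-values, recomputed step by step from the published
# recipe: reference by upper-quartile/library-size closest to the mean,
# double trim on M and A, inverse-variance weighted mean of M.
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  counts <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    uq[j] <- quantile(counts[, j], 0.75) / lib[j]
  }
  ref <- which.min(abs(uq - mean(uq)))
  fac <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    obs <- counts[, j]; rf <- counts[, ref]
    ok <- obs > 0 & rf > 0
    m <- log2((obs[ok] / lib[j]) / (rf[ok] / lib[ref]))
    a <- 0.5 * (log2(obs[ok] / lib[j]) + log2(rf[ok] / lib[ref]))
    w <- (lib[j] - obs[ok]) / (lib[j] * obs[ok]) +
      (lib[ref] - rf[ok]) / (lib[ref] * rf[ok])
    if (max(abs(m)) < 1e-6) {
      fac[j] <- 1
      next
    }
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    fac[j] <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }
  fac / exp(mean(log(fac)))
}

# Single-component PLS1 (NIPALS form): w ~ X'y, t = Xw, b = t'y/t't.
oracle_pls1 <- function(X, y, Xnew = X) {
  mx <- colMeans(X)
  sx <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  yc <- y - mean(y)
  w <- drop(t(Xs) %*% yc)
  w <- w / sqrt(sum(w^2))
  t1 <- drop(Xs %*% w)
  b <- sum(t1 * yc) / sum(t1^2)
  Xn <- sweep(sweep(Xnew, 2, mx), 2, sx, "/")
  drop(Xn %*% w) * b + mean(y)
}

# AUROC by brute-force enumeration over all (positive, negative) pairs,
# ties counted one half.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) {
    for (b in sn) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(sp) * length(sn))
}

# Small simulation configuration used throughout the tests: four planted
# communities, one of them (community 2) tissue-discordant.
test_cfg <- function(...) {
  defaults <- list(
    n_genes = 200L, community_sizes = c(40L, 35L, 30L, 25L),
    n_ref_subjects_per_tissue = 80L, n_int_subjects = 16L,
    time_effect = rbind(c(0, 0), c(0.8, -0.8), c(0, 0), c(0, 0)),
    trait_links = list(`2` = c(continuous = -1.0, binary = 2.0))
  )
  do.call(sim_config, modifyList(defaults, list(...)))
}

# A complete 2x2 paired sample sheet for n subjects.
test_paired_annotations <- function(n) {
  grid <- expand.grid(timepoint = c("pre", "post"), tissue = c("SM", "SAT"),
                      subject_id = sprintf("S%02d", seq_len(n)),
                      stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_%s", grid$subject_id, grid$tissue,
                                 grid$timepoint),
             subject_id = grid$subject_id, tissue = grid$tissue,
             timepoint = grid$timepoint, cohort = "test",
             stringsAsFactors = FALSE)
}
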