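test_that("eigengene of a rank-1 community is the standardized common vector", {
  set.seed(1)
  v <- rnorm(30)
  x <- rbind(g1 = 2 * v + 5, g2 = -0.5 * v + 1, g3 = v)
  x <- rbind(x[1, ], x[1, ], x[3, ]) # all genes proportional to v
  rownames(x) <- c("g1", "g2", "g3")
  colnames(x) <- sprintf("s%02d", 1:30)
  eg <- eigengene(x)
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$scores, v)), 1, tolerance = 1e-10)
  expect_equal(sum(eg$scores^2), 1, tolerance = 1e-12) # unit norm
  # sign: aligned with the community mean expression
  expect_gt(cor(eg$scores, v), 0)
})

test_that("two exactly opposite genes trigger the documented sign tie-break", {
  set.seed(2)
  v <- rnorm(20)
  x <- rbind(g1 = v, g2 = -v)
  colnames(x) <- sprintf("s%02d", 1:20)
  eg <- eigengene(x)
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  # positive loading on the first gene
  expect_gt(cor(eg$scores, v), 0)
})

test_that("the eigengene is the optimal one-dimensional summary", {
  set.seed(3)
  x <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30)))
  eg <- eigengene(x)
  z <- t(scale(t(x)))
  total <- sum(z^2)
  ve_dir <- function(u) sum((z %*% u)^2) / total
  for (i in 1:1000) {
    u <- rnorm(30)
    u <- u / sqrt(sum(u^2))
    expect_gte(eg$variance_explained + 1e-12, ve_dir(u))
  }
})

test_that("eigengene scores ignore gene order and per-gene scaling", {
  set.seed(4)
  x <- matrix(rnorm(10 * 15), 10, 15,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:15)))
  eg <- eigengene(x)
  eg_perm <- eigengene(x[sample(rownames(x)), ])
  expect_equal(eg$scores, eg_perm$scores, tolerance = 1e-10)
  y <- x
  y[3, ] <- 100 * y[3, ] + 7
  expect_equal(eigengene(y)$scores, eg$scores, tolerance = 1e-10)
})

test_that("constant genes are dropped and tiny communities rejected", {
  x <- rbind(g1 = rnorm(10), g2 = rep(1, 10), g3 = rnorm(10))
  colnames(x) <- sprintf("s%02d", 1:10)
  expect_warning(eg <- eigengene(x), "constant")
  expect_equal(eg$n_genes_used, 2L)
  expect_identical(eg$dropped, "g2")
  expect_error(suppressWarnings(eigengene(x[1:2, ])), "fewer than 2")
})

test_that("a flat eigengene yields zero F statistics and p = 1", {
  ann <- test_paired_annotations(6)
  scores <- matrix(0.25, 1, nrow(ann), dimnames = list("1", ann$sample_id))
  res <- interaction_anova(scores, ann)
  expect_equal(res$F_time, 0)
  expect_equal(res$F_interaction, 0)
  expect_equal(res$p_interaction, 1)
  expect_equal(res$fc_sm, 0)
  expect_equal(res$p_sm, 1)
})

test_that("interaction F equals the squared paired t on the difference of differences", {
  set.seed(10)
  ann <- test_paired_annotations(9)
  scores <- matrix(rnorm(40 * nrow(ann)), 40, nrow(ann),
                   dimnames = list(as.character(1:40), ann$sample_id))
  res <- interaction_anova(scores, ann)
  for (i in 1:40) {
    y <- scores[i, ]
    d <- function(tissue) {
      post <- y[ann$sample_id[ann$tissue == tissue & ann$timepoint == "post"]]
      pre <- y[ann$sample_id[ann$tissue == tissue & ann$timepoint == "pre"]]
      unname(post - pre)
    }
    w <- d("SM") - d("SAT")
    tt <- t.test(w)
    expect_equal(res$F_interaction[i], unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res$p_interaction[i], tt$p.value, tolerance = 1e-8)
    expect_equal(res$fc_sm[i], mean(d("SM")), tolerance = 1e-12)
    # per-tissue paired tests
    expect_equal(res$p_sm[i], t.test(d("SM"))$p.value, tolerance = 1e-10)
    expect_equal(res$p_sat[i], t.test(d("SAT"))$p.value, tolerance = 1e-10)
  }
})

test_that("the within-subject ANOVA matches aov() error strata", {
  set.seed(11)
  ann <- test_paired_annotations(8)
  scores <- matrix(rnorm(nrow(ann)), 1, nrow(ann),
                   dimnames = list("1", ann$sample_id))
  res <- interaction_anova(scores, ann)
  df <- data.frame(y = scores[1, ann$sample_id],
                   subject = factor(ann$subject_id),
                   tissue = factor(ann$tissue),
                   time = factor(ann$timepoint))
  fit <- aov(y ~ time * tissue + Error(subject / (time * tissue)), data = df)
  s <- summary(fit)
  p_time <- s[["Error: subject:time"]][[1]]["time", "Pr(>F)"]
  p_tissue <- s[["Error: subject:tissue"]][[1]]["tissue", "Pr(>F)"]
  p_int <- s[["Error: subject:time:tissue"]][[1]]["time:tissue", "Pr(>F)"]
  expect_equal(res$p_time, p_time, tolerance = 1e-8)
  expect_equal(res$p_tissue, p_tissue, tolerance = 1e-8)
  expect_equal(res$p_interaction, p_int, tolerance = 1e-8)
})

test_that("the sums of squares decompose the total exactly", {
  set.seed(12)
  ann <- test_paired_annotations(7)
  scores <- matrix(rnorm(5 * nrow(ann)), 5, nrow(ann),
                   dimnames = list(as.character(1:5), ann$sample_id))
  res <- interaction_anova(scores, ann)
  recomposed <- with(res, ss_subject + ss_time + ss_tissue + ss_interaction +
                       ss_err_time + ss_err_tissue + ss_err_interaction)
  expect_equal(recomposed, res$ss_total, tolerance = 1e-8)
})

test_that("incomplete subjects are excluded with a warning", {
  ann <- test_paired_annotations(5)
  scores <- matrix(rnorm(nrow(ann)), 1, nrow(ann),
                   dimnames = list("1", ann$sample_id))
  ann_miss <- ann[-1, ]
  expect_warning(res <- interaction_anova(scores[, ann_miss$sample_id,
                                                 drop = FALSE], ann_miss),
                 "complete")
  expect_equal(res$n_subjects, 4L)
  ann_tiny <- ann[ann$subject_id %in% c("S01", "S02"), ]
  expect_error(suppressWarnings(
    interaction_anova(scores[, ann_tiny$sample_id, drop = FALSE], ann_tiny)),
    "fewer than 3")
})

test_that("paired community test matches the textbook formula", {
  d <- c(0.5, -0.2, 0.3, 0.8, 0.1)
  pre <- rep(0, 5)
  post <- d
  names(pre) <- names(post) <- sprintf("S%d", 1:5)
  res <- paired_community_test(pre, post)
  n <- length(d)
  t_hand <- mean(d) / (sd(d) / sqrt(n))
  p_hand <- 2 * pt(abs(t_hand), n - 1, lower.tail = FALSE)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$fc, mean(d))
  expect_false(res$degenerate)
})

test_that("degenerate paired differences are flagged", {
  pre <- c(S1 = 0, S2 = 0, S3 = 0, S4 = 0)
  expect_identical(paired_community_test(pre, pre),
                   list(t = 0, p = 1, fc = 0, n = 4L, degenerate = TRUE))
  post <- pre + 1
  res <- paired_community_test(pre, post)
  expect_equal(res$p, 0)
  expect_true(res$degenerate)
  expect_error(paired_community_test(pre, post[c("S1", "S2", "S3")]),
               "unmatched")
  expect_error(paired_community_test(pre[1:2], pre[1:2] + 1), "3 pairs")
})

test_that("trait correlations recover exact and null relationships", {
  n <- 1000
  ann <- data.frame(sample_id = sprintf("smp%04d", 1:n),
                    subject_id = sprintf("S%04d", 1:n),
                    tissue = "SAT", timepoint = "pre")
  set.seed(20)
  scores <- matrix(rnorm(n), 1, n, dimnames = list("1", ann$sample_id))
  traits <- data.frame(subject_id = ann$subject_id,
                       exact = scores[1, ],
                       null = rnorm(n))
  res <- trait_correlations(scores, ann, traits, tissue = "SAT",
                            timepoint = "pre",
                            trait_cols = c("exact", "null"))
  expect_equal(res$r[res$trait == "exact"], 1, tolerance = 1e-12)
  expect_lt(abs(res$r[res$trait == "null"]), 0.1)
  expect_equal(res$n, c(n, n))
  # zero-variance trait skipped with a warning
  traits$flat <- 1
  expect_warning(res2 <- trait_correlations(scores, ann, traits,
                                            trait_cols = c("exact", "flat")),
                 "zero variance")
  expect_identical(res2$trait, "exact")
})
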