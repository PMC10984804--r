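#' Time x Tissue repeated-measures ANOVA on community eigengenes
#'
#' Per community, fits the fully within-subject 2 x 2 repeated-measures
#' ANOVA (factors Time = pre/post and Tissue = SM/SAT, error strata the
#' subject x factor interactions) through its exact sums-of-squares
#' decomposition. In this balanced 2 x 2 design each F statistic equals the
#' squared paired t statistic on the corresponding within-subject contrast;
#' in particular `F_interaction` equals the squared paired t on the
#' difference-of-differences `(post - pre)_SM - (post - pre)_SAT`.
#' Per-tissue mean paired eigengene changes (`fc_sm`, `fc_sat`) and paired
#' t-test p-values are reported alongside.
#'
#' @param eig an `xt_eigengenes` object, a community x sample score matrix,
#'   or a single named score vector.
#' @param annotations sample sheet with columns `sample_id`, `subject_id`,
#'   `tissue` (SM/SAT) and `timepoint` (pre/post). Subjects lacking any of
#'   the four cells are excluded with a warning; at least 3 complete
#'   subjects are required.
#' @return data frame, one row per community: F and p for Time, Tissue and
#'   the Time x Tissue interaction, `fc_sm`, `p_sm`, `fc_sat`, `p_sat`,
#'   `n_subjects`, plus the sums-of-squares columns of the within-subject
#'   decomposition (`ss_*`).
#' @export
interaction_anova <- function(eig, annotations) {
  scores <- .eig_scores(eig)
  ann <- annotations
  .assert(all(c("sample_id", "subject_id", "tissue", "timepoint") %in% names(ann)),
          "annotations must have sample_id, subject_id, tissue, timepoint")
  ann <- ann[ann$sample_id %in% colnames(scores), , drop = FALSE]
  cells <- with(ann, table(subject_id, paste(tissue, timepoint, sep = ".")))
  need <- c("SM.pre", "SM.post", "SAT.pre", "SAT.post")
  .assert(all(need %in% colnames(cells)), "annotations must cover SM/SAT x pre/post")
  complete <- rownames(cells)[rowSums(cells[, need, drop = FALSE] == 1) == 4]
  if (length(complete) < nrow(cells)) {
    warning(nrow(cells) - length(complete),
            " subject(s) without a complete 2x2 design excluded")
  }
  .assert(length(complete) >= 3, "fewer than 3 complete subjects")
  idx <- function(tissue, time) {
    vapply(complete, function(s) {
      ann$sample_id[ann$subject_id == s & ann$tissue == tissue &
                      ann$timepoint == time][1]
    }, character(1))
  }
  cols <- list(sm_pre = idx("SM", "pre"), sm_post = idx("SM", "post"),
               sat_pre = idx("SAT", "pre"), sat_post = idx("SAT", "post"))
  out <- lapply(rownames(scores), function(comm) {
    y <- vapply(cols, function(s) scores[comm, s], numeric(length(complete)))
    res <- .rm_anova_2x2(y)
    cbind(data.frame(community = comm, stringsAsFactors = FALSE), res)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# y: subjects x 4 matrix with columns sm_pre, sm_post, sat_pre, sat_post.
.rm_anova_2x2 <- function(y) {
  n <- nrow(y)
  grand <- mean(y)
  subj_mean <- rowMeans(y)
  cell_mean <- colMeans(y) # sm_pre, sm_post, sat_pre, sat_post
  time_mean <- c(pre = mean(cell_mean[c(1, 3)]), post = mean(cell_mean[c(2, 4)]))
  tissue_mean <- c(SM = mean(cell_mean[1:2]), SAT = mean(cell_mean[3:4]))
  time_of <- c(1, 2, 1, 2) # pre, post, pre, post
  tissue_of <- c(1, 1, 2, 2)

  ss_subject <- 4 * sum((subj_mean - grand)^2)
  ss_time <- 2 * n * sum((time_mean - grand)^2)
  ss_tissue <- 2 * n * sum((tissue_mean - grand)^2)
  ss_interaction <- n * sum((cell_mean - tissue_mean[tissue_of] -
                               time_mean[time_of] + grand)^2)
  # subject x time means (over tissues), subject x tissue means (over times)
  st_mean <- cbind(pre = rowMeans(y[, c(1, 3), drop = FALSE]),
                   post = rowMeans(y[, c(2, 4), drop = FALSE]))
  sT_mean <- cbind(SM = rowMeans(y[, 1:2, drop = FALSE]),
                   SAT = rowMeans(y[, 3:4, drop = FALSE]))
  ss_err_time <- 2 * sum((sweep(sweep(st_mean, 1, subj_mean), 2, time_mean) + grand)^2)
  ss_err_tissue <- 2 * sum((sweep(sweep(sT_mean, 1, subj_mean), 2, tissue_mean) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err_interaction <- ss_total - ss_subject - ss_time - ss_tissue -
    ss_interaction - ss_err_time - ss_err_tissue

  fstat <- function(ss_eff, ss_err) {
    if (ss_err <= 0) {
      if (ss_eff <= 0) return(c(F = 0, p = 1))
      return(c(F = Inf, p = 0))
    }
    f <- (ss_eff / 1) / (ss_err / (n - 1))
    c(F = f, p = pf(f, 1, n - 1, lower.tail = FALSE))
  }
  zero_tol <- 1e-12 * max(ss_total, 1)
  clamp <- function(x) if (abs(x) < zero_tol) 0 else x
  f_time <- fstat(clamp(ss_time), clamp(ss_err_time))
  f_tissue <- fstat(clamp(ss_tissue), clamp(ss_err_tissue))
  f_int <- fstat(clamp(ss_interaction), clamp(ss_err_interaction))

  d_sm <- y[, 2] - y[, 1]
  d_sat <- y[, 4] - y[, 3]
  paired_p <- function(d) {
    if (sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    t.test(d)$p.value
  }
  data.frame(
    F_time = f_time["F"], p_time = f_time["p"],
    F_tissue = f_tissue["F"], p_tissue = f_tissue["p"],
    F_interaction = f_int["F"], p_interaction = f_int["p"],
    fc_sm = mean(d_sm), p_sm = paired_p(d_sm),
    fc_sat = mean(d_sat), p_sat = paired_p(d_sat),
    n_subjects = n,
    ss_subject = ss_subject, ss_time = ss_time, ss_tissue = ss_tissue,
    ss_interaction = ss_interaction, ss_err_time = ss_err_time,
    ss_err_tissue = ss_err_tissue, ss_err_interaction = ss_err_interaction,
    ss_total = ss_total,
    row.names = NULL
  )
}

.eig_scores <- function(eig) {
  if (inherits(eig, "xt_eigengenes")) return(eig$scores)
  if (is.matrix(eig)) return(eig)
  .assert(!is.null(names(eig)), "scores must be named by sample")
  matrix(eig, 1, dimnames = list("1", names(eig)))
}

#' Paired community test
#'
#' Standard two-sided paired t-test on post - pre eigengene scores, matched
#' by subject (vector names). Used for single-tissue validation cohorts.
#'
#' @param pre,post named score vectors (names = subject ids, >= 3 pairs).
#' @return list with `t`, `p`, `fc` (mean difference), `n` and `degenerate`
#'   (`TRUE` when the differences have zero variance; then `p` is 0 for a
#'   nonzero shift and 1 for no shift).
#' @export
paired_community_test <- function(pre, post) {
  .assert(!is.null(names(pre)) && !is.null(names(post)),
          "`pre` and `post` must be named by subject")
  if (!setequal(names(pre), names(post))) {
    stop("unmatched subjects between pre and post", call. = FALSE)
  }
  d <- post[names(pre)] - pre
  n <- length(d)
  .assert(n >= 3, "need at least 3 pairs")
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, fc = 0, n = n, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, fc = mean(d), n = n,
                degenerate = TRUE))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, fc = mean(d), n = n,
       degenerate = FALSE)
}

#' Pearson correlations between eigengenes and clinical traits
#'
#' Correlates each community eigengene with each clinical trait on one
#' tissue x timepoint slice of the samples (one value per subject).
#'
#' @param eig an `xt_eigengenes` object or community x sample score matrix.
#' @param annotations sample sheet (`sample_id`, `subject_id`, `tissue`,
#'   `timepoint`).
#' @param traits data frame with `subject_id` and numeric trait columns.
#' @param tissue,timepoint the sample slice to use (defaults SAT, pre).
#' @param trait_cols trait columns to test; defaults to every numeric
#'   column other than `subject_id`.
#' @return data frame with `community`, `trait`, `r`, `p`, `n`. Zero-variance
#'   traits are skipped with a warning; missing trait values are dropped
#'   pairwise.
#' @export
trait_correlations <- function(eig, annotations, traits,
                               tissue = "SAT", timepoint = "pre",
                               trait_cols = NULL) {
  scores <- .eig_scores(eig)
  sel <- annotations$tissue == tissue & annotations$timepoint == timepoint &
    annotations$sample_id %in% colnames(scores)
  ann <- annotations[sel, , drop = FALSE]
  .assert(nrow(ann) >= 4, "need at least 4 subjects in the requested slice")
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                          "subject_id")
  }
  tr <- traits[match(ann$subject_id, traits$subject_id), , drop = FALSE]
  out <- list()
  for (comm in rownames(scores)) {
    y <- scores[comm, ann$sample_id]
    for (tc in trait_cols) {
      x <- tr[[tc]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4) next
      if (sd(x[ok]) == 0) {
        warning("trait '", tc, "' has zero variance; skipped")
        next
      }
      ct <- cor.test(y[ok], x[ok], method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        community = comm, trait = tc,
        r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
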