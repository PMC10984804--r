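#' Simulation configuration for synthetic two-tissue cohorts
#'
#' Bundles all parameters of the synthetic-cohort generator. The defaults
#' describe the study conditions the package is validated under: seven planted
#' communities whose sizes follow the published community sizes of the
#' cross-tissue network (233, 147, 178, 41, 106, 32 and 19 genes) plus
#' background genes, a large cross-sectional two-tissue reference cohort and a
#' small paired pre/post intervention cohort of 16 subjects. Community 2 (the
#' glucose--insulin--AMPK analogue) carries a tissue-discordant time effect
#' (+0.8 in SM, -0.8 in SAT, in eigengene standard-deviation units) and is
#' linked to a continuous BMI-like trait (slope -1.0) and a binary T2D-like
#' trait (log-odds slope +2.0).
#'
#' @param n_genes total number of genes (planted communities plus background).
#' @param community_sizes integer vector of planted community sizes; their sum
#'   must not exceed `n_genes`. Remaining genes are unstructured background.
#' @param n_ref_subjects_per_tissue cross-sectional reference subjects per
#'   tissue (each reference subject contributes one sample in one tissue).
#' @param n_int_subjects paired intervention subjects; each contributes four
#'   samples (SM/SAT x pre/post).
#' @param within_community_cor target expected pairwise Pearson correlation of
#'   latent log2CPM values within a community; strictly in (0, 1).
#' @param time_effect numeric matrix with one row per community and columns
#'   `SM` and `SAT`: the planted post-minus-pre shift of the community factor
#'   per tissue, in factor standard-deviation units.
#' @param trait_links named list mapping community index (as character) to
#'   `c(continuous = ..., binary = ...)`: the slope of the BMI-like trait and
#'   the log-odds slope of the T2D-like trait on the standardized community
#'   eigengene.
#' @param nb_dispersion negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); must be positive.
#' @param lib_size_range range (low, high) of per-sample library sizes,
#'   sampled uniformly.
#' @param baseline_log2cpm_range range of per-gene baseline expression on the
#'   relative log2 scale.
#' @param noise_sd gene-level residual standard deviation on the log2 scale.
#' @param within_subject_sd standard deviation of the per-sample community
#'   factor noise in the intervention cohort. The subject random intercept SD
#'   is `subject_sd`; the defaults split the unit factor variance as 25%
#'   subject intercept and 75% within-subject, so the factor keeps the same
#'   marginal variance as in the reference cohort.
#' @param subject_sd standard deviation of the subject random intercept on
#'   the community factor.
#' @param trait_noise_sd residual SD of the continuous traits.
#' @param t2d_base_prevalence baseline prevalence of the binary trait at an
#'   average eigengene value.
#'
#' @return an object of class `xt_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 120, community_sizes = c(30, 25, 20),
#'                   n_ref_subjects_per_tissue = 50, n_int_subjects = 8)
#' cfg$community_sizes
sim_config <- function(n_genes = 1000L,
                       community_sizes = c(233L, 147L, 178L, 41L, 106L, 32L, 19L),
                       n_ref_subjects_per_tissue = 400L,
                       n_int_subjects = 16L,
                       within_community_cor = 0.5,
                       time_effect = NULL,
                       trait_links = list(`2` = c(continuous = -1.0, binary = 2.0)),
                       nb_dispersion = 0.1,
                       lib_size_range = c(5e6, 1.5e7),
                       baseline_log2cpm_range = c(4, 9),
                       noise_sd = 1,
                       within_subject_sd = sqrt(0.75),
                       subject_sd = sqrt(0.25),
                       trait_noise_sd = 1,
                       t2d_base_prevalence = 0.15) {
  community_sizes <- as.integer(community_sizes)
  k <- length(community_sizes)
  if (is.null(time_effect)) {
    time_effect <- matrix(0, k, 2, dimnames = list(NULL, c("SM", "SAT")))
    # Defaults mirror the qualitative exercise response of the study system:
    # several SM-only shifts and one discordant community (index 2).
    if (k >= 1) time_effect[1, ] <- c(0.6, 0)
    if (k >= 2) time_effect[2, ] <- c(0.8, -0.8)
    if (k >= 3) time_effect[3, ] <- c(0.6, 0)
    if (k >= 4) time_effect[4, ] <- c(0.6, 0)
    if (k >= 5) time_effect[5, ] <- c(-0.6, 0)
    if (k >= 6) time_effect[6, ] <- c(-0.6, 0)
  }
  time_effect <- as.matrix(time_effect)
  if (is.null(colnames(time_effect))) colnames(time_effect) <- c("SM", "SAT")
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    community_sizes = community_sizes,
    n_ref_subjects_per_tissue = as.integer(n_ref_subjects_per_tissue),
    n_int_subjects = as.integer(n_int_subjects),
    within_community_cor = within_community_cor,
    time_effect = time_effect,
    trait_links = trait_links,
    nb_dispersion = nb_dispersion,
    lib_size_range = lib_size_range,
    baseline_log2cpm_range = baseline_log2cpm_range,
    noise_sd = noise_sd,
    within_subject_sd = within_subject_sd,
    subject_sd = subject_sd,
    trait_noise_sd = trait_noise_sd,
    t2d_base_prevalence = t2d_base_prevalence
  ), class = "xt_sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg an `xt_sim_config` object (or a bare list with the same fields).
#' @return `cfg`, invisibly unchanged, or an error describing the violation.
#' @export
validate_sim_config <- function(cfg) {
  .assert(sum(cfg$community_sizes) <= cfg$n_genes,
          "sum of community_sizes exceeds n_genes")
  .assert(all(cfg$community_sizes >= 2L), "all community sizes must be >= 2")
  .assert(cfg$within_community_cor > 0 && cfg$within_community_cor < 1,
          "within_community_cor must be strictly between 0 and 1")
  .assert(cfg$nb_dispersion > 0, "nb_dispersion must be positive")
  .assert(length(cfg$lib_size_range) == 2 &&
            cfg$lib_size_range[1] <= cfg$lib_size_range[2] &&
            all(cfg$lib_size_range > 0),
          "lib_size_range must be a positive (low, high) pair")
  .assert(nrow(cfg$time_effect) == length(cfg$community_sizes) &&
            ncol(cfg$time_effect) == 2,
          "time_effect must have one row per community and columns (SM, SAT)")
  .assert(cfg$noise_sd > 0, "noise_sd must be positive")
  .assert(cfg$within_subject_sd > 0 && cfg$subject_sd >= 0,
          "factor noise SDs must be positive")
  cfg
}

# Gene -> community assignment (0 = background), gene ids and per-gene
# baseline/loading vectors shared by both generators.
.sim_genes <- function(cfg) {
  k <- length(cfg$community_sizes)
  community <- rep.int(c(seq_len(k), 0L),
                       c(cfg$community_sizes, cfg$n_genes - sum(cfg$community_sizes)))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  names(community) <- gene_ids
  rho <- cfg$within_community_cor
  # One-factor model: x = baseline + loading * f + eps, f ~ N(0,1),
  # eps ~ N(0, noise_sd^2). Pairwise within-community correlation is
  # loading^2 / (loading^2 + noise_sd^2) = rho.
  loading <- ifelse(community > 0L, cfg$noise_sd * sqrt(rho / (1 - rho)), 0)
  baseline <- runif(cfg$n_genes, cfg$baseline_log2cpm_range[1],
                    cfg$baseline_log2cpm_range[2])
  names(loading) <- names(baseline) <- gene_ids
  list(community = community, loading = loading, baseline = baseline)
}

# Latent log2-scale expression for a block of samples given the community
# factor matrix (communities x samples).
.sim_latent <- function(cfg, genes, fmat) {
  n <- ncol(fmat)
  lat <- matrix(rnorm(cfg$n_genes * n, sd = cfg$noise_sd), cfg$n_genes, n)
  lat <- lat + genes$baseline
  in_comm <- genes$community > 0L
  lat[in_comm, ] <- lat[in_comm, ] +
    genes$loading[in_comm] * fmat[genes$community[in_comm], , drop = FALSE]
  rownames(lat) <- names(genes$community)
  lat
}

# Negative-binomial counts from latent relative log2 abundances.
.sim_counts <- function(cfg, latent) {
  rel <- 2^latent
  prop <- sweep(rel, 2, colSums(rel), "/")
  libsize <- round(runif(ncol(latent), cfg$lib_size_range[1], cfg$lib_size_range[2]))
  mu <- sweep(prop, 2, libsize, "*")
  counts <- matrix(rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu),
                   nrow(mu), ncol(mu), dimnames = dimnames(latent))
  storage.mode(counts) <- "integer"
  counts
}

.sim_traits <- function(cfg, zmat, subject_ids) {
  n <- length(subject_ids)
  bmi <- rep(27, n)
  logit <- rep(qlogis(cfg$t2d_base_prevalence), n)
  for (kk in names(cfg$trait_links)) {
    ki <- as.integer(kk)
    link <- cfg$trait_links[[kk]]
    bmi <- bmi + link[["continuous"]] * zmat[ki, ]
    logit <- logit + link[["binary"]] * zmat[ki, ]
  }
  bmi <- bmi + rnorm(n, sd = cfg$trait_noise_sd)
  fat <- 30 + 0.8 * (bmi - 27) + rnorm(n, sd = cfg$trait_noise_sd)
  t2d <- rbinom(n, 1L, plogis(logit))
  data.frame(subject_id = subject_ids,
             bmi_like = bmi,
             fatmass_like = fat,
             t2d_like = t2d,
             sex = sample(c("F", "M"), n, replace = TRUE),
             age = round(runif(n, 20, 70), 1),
             stringsAsFactors = FALSE)
}

.new_cohort <- function(counts, annotations, traits, truth) {
  .check_count_matrix(counts)
  .assert(identical(sort(colnames(counts)), sort(annotations$sample_id)),
          "annotations must cover exactly the samples in counts")
  structure(list(counts = counts, annotations = annotations,
                 traits = traits, truth = truth),
            class = "xt_cohort")
}

#' @export
print.xt_cohort <- function(x, ...) {
  cat(sprintf("<xt_cohort '%s'>: %d genes x %d samples, %d subjects\n",
              x$annotations$cohort[1], nrow(x$counts), ncol(x$counts),
              length(unique(x$annotations$subject_id))))
  invisible(x)
}

#' Simulate a cross-sectional two-tissue reference cohort
#'
#' Generates the large reference cohort used for network construction. For
#' each tissue independently, genes in community *k* follow a one-factor
#' Gaussian model on the latent log2 scale,
#' `x_g = baseline_g + loading_g * f_k + eps_g`, with loadings chosen so the
#' expected within-community pairwise correlation equals
#' `within_community_cor`; background genes carry noise only. Counts are drawn
#' from a negative-binomial model on the implied per-sample expected counts.
#' Subject traits are linked to designated community factors through
#' `cfg$trait_links`.
#'
#' @param cfg an [sim_config()] object.
#' @param seed integer seed; identical `(cfg, seed)` yield identical cohorts.
#' @return an `xt_cohort`: list with `counts` (gene x sample integer matrix),
#'   `annotations` (sample sheet), `traits` (one row per subject) and `truth`
#'   (gene -> community map, loadings, baselines, per-sample community
#'   factors, latent matrices and planted trait slopes).
#' @seealso [simulate_intervention_cohort()]
#' @export
simulate_reference_cohort <- function(cfg, seed = 1L) {
  validate_sim_config(cfg)
  .with_seed(seed, {
    genes <- .sim_genes(cfg)
    k <- length(cfg$community_sizes)
    n <- cfg$n_ref_subjects_per_tissue
    out <- list()
    for (tissue in c("SM", "SAT")) {
      subj <- sprintf("R%s%04d", tissue, seq_len(n))
      samp <- sprintf("%s_%s", subj, tissue)
      fmat <- matrix(rnorm(k * n), k, n, dimnames = list(NULL, samp))
      latent <- .sim_latent(cfg, genes, fmat)
      colnames(latent) <- samp
      counts <- .sim_counts(cfg, latent)
      ann <- data.frame(sample_id = samp, subject_id = subj, tissue = tissue,
                        timepoint = "pre", cohort = "reference",
                        stringsAsFactors = FALSE)
      zmat <- fmat # factors are standard normal already
      traits <- .sim_traits(cfg, zmat, subj)
      out[[tissue]] <- list(counts = counts, ann = ann, fmat = fmat,
                            latent = latent, traits = traits)
    }
    counts <- cbind(out$SM$counts, out$SAT$counts)
    annotations <- rbind(out$SM$ann, out$SAT$ann)
    traits <- rbind(out$SM$traits, out$SAT$traits)
    truth <- list(
      gene_community = genes$community,
      loading = genes$loading,
      baseline = genes$baseline,
      factors = list(SM = out$SM$fmat, SAT = out$SAT$fmat),
      latent = list(SM = out$SM$latent, SAT = out$SAT$latent),
      trait_links = cfg$trait_links,
      time_effect = NULL
    )
    .new_cohort(counts, annotations, traits, truth)
  })
}

#' Simulate a paired pre/post two-tissue intervention cohort
#'
#' Generates the small paired exercise-style cohort: every subject contributes
#' four samples (SM/SAT x pre/post). The community factor of subject *i*,
#' tissue *T* at time *t* is
#' `f = u_i + delta_{k,T} * 1(t = post) + e`, with a subject random intercept
#' `u_i` (SD `subject_sd`), planted per-tissue time shifts from
#' `cfg$time_effect` and within-subject noise `e` (SD `within_subject_sd`).
#' Traits are generated from the pre-timepoint community factors (averaged
#' over the two tissues, then standardized) through `cfg$trait_links`: a
#' Gaussian model for the continuous trait and a logistic model for the
#' binary trait.
#'
#' @inheritParams simulate_reference_cohort
#' @return an `xt_cohort`; `truth$trait_latent` holds the standardized
#'   pre-timepoint eigengene values the traits were generated from, and
#'   `truth$time_effect` the planted per-tissue shifts.
#' @export
simulate_intervention_cohort <- function(cfg, seed = 1L) {
  validate_sim_config(cfg)
  .assert(cfg$n_int_subjects >= 3L, "n_int_subjects must be >= 3")
  .with_seed(seed, {
    genes <- .sim_genes(cfg)
    k <- length(cfg$community_sizes)
    n <- cfg$n_int_subjects
    subj <- sprintf("I%03d", seq_len(n))
    grid <- expand.grid(timepoint = c("pre", "post"), tissue = c("SM", "SAT"),
                        subject_id = subj, stringsAsFactors = FALSE)
    grid <- grid[, c("subject_id", "tissue", "timepoint")]
    samp <- sprintf("%s_%s_%s", grid$subject_id, grid$tissue, grid$timepoint)
    u <- matrix(rnorm(k * n, sd = cfg$subject_sd), k, n, dimnames = list(NULL, subj))
    e <- matrix(rnorm(k * nrow(grid), sd = cfg$within_subject_sd), k, nrow(grid))
    delta <- cfg$time_effect[, grid$tissue, drop = FALSE] *
      rep(as.numeric(grid$timepoint == "post"), each = k)
    fmat <- u[, grid$subject_id, drop = FALSE] + delta + e
    colnames(fmat) <- samp
    latent <- .sim_latent(cfg, genes, fmat)
    colnames(latent) <- samp
    counts <- .sim_counts(cfg, latent)
    annotations <- data.frame(sample_id = samp, subject_id = grid$subject_id,
                              tissue = grid$tissue, timepoint = grid$timepoint,
                              cohort = "intervention", stringsAsFactors = FALSE)
    pre_idx <- annotations$timepoint == "pre"
    zraw <- vapply(subj, function(s) {
      cols <- pre_idx & annotations$subject_id == s
      rowMeans(fmat[, cols, drop = FALSE])
    }, numeric(k))
    zraw <- matrix(zraw, nrow = k, dimnames = list(NULL, subj))
    zmat <- t(scale(t(zraw)))
    traits <- .sim_traits(cfg, zmat, subj)
    truth <- list(
      gene_community = genes$community,
      loading = genes$loading,
      baseline = genes$baseline,
      factors = fmat,
      latent = latent,
      subject_intercepts = u,
      time_effect = cfg$time_effect,
      trait_links = cfg$trait_links,
      trait_latent = zmat
    )
    .new_cohort(counts, annotations, traits, truth)
  })
}
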