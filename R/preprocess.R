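#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors following the canonical
#' recipe: the reference sample is the one whose upper-quartile/library-size
#' ratio is closest to the mean of that ratio; for every other sample the
#' log2 ratios of count fractions versus the reference (M values) and average
#' log2 abundances (A values) are doubly trimmed (`trim_m` on M, `trim_a` on
#' A, both sides), and the factor is two to the power of the precision-weighted
#' mean of the surviving M values, with weights equal to inverse approximate
#' binomial variances. Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative integer matrix, genes x samples, with dimnames.
#' @param trim_m two-sided trim fraction applied to M values (default 0.30).
#' @param trim_a two-sided trim fraction applied to A values (default 0.05).
#' @param ref_sample optional reference sample id or index; chosen
#'   automatically when `NULL`.
#' @param weighted use precision weights (default `TRUE`).
#' @return named numeric vector of positive factors, geometric mean 1.
#' @references Robinson MD, Oshlack A (2010). A scaling normalization method
#'   for differential expression analysis of RNA-seq data. Genome Biology 11:R25.
#' @export
#' @examples
#' counts <- matrix(rpois(600, 50), 100, 6,
#'                  dimnames = list(sprintf("g%02d", 1:100), sprintf("s%d", 1:6)))
#' tmm_factors(counts)
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        ref_sample = NULL, weighted = TRUE) {
  .check_count_matrix(counts)
  .assert(ncol(counts) >= 2, "TMM needs at least 2 samples")
  libsize <- colSums(counts)
  zero_lib <- libsize == 0
  if (any(zero_lib)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero_lib], collapse = ", "), call. = FALSE)
  }
  keep <- rowSums(counts > 0) > 0L
  x <- counts[keep, , drop = FALSE]
  if (is.null(ref_sample)) {
    f75 <- apply(x, 2, quantile, probs = 0.75) / libsize
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(x)) else ref_sample
    .assert(!is.na(ref) && ref >= 1 && ref <= ncol(x), "invalid `ref_sample`")
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], x[, ref], libsize[j], libsize[ref],
              trim_m = trim_m, trim_a = trim_a, weighted = weighted)
  }, numeric(1))
  f <- f / .geomean(f)
  names(f) <- colnames(counts)
  f
}

# One observation-vs-reference TMM factor (pre-rescaling).
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a, weighted) {
  obs <- as.numeric(obs)
  ref <- as.numeric(ref)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # inverse of the approximate (binomial) variance of M
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  f <- if (weighted) {
    sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(m[keep], na.rm = TRUE)
  }
  if (is.na(f)) f <- 0
  2^f
}

#' log2 counts-per-million
#'
#' `log2((count + prior_count) / (libsize * factor) * 1e6)` with the library
#' size taken as the sample's column sum.
#'
#' @inheritParams tmm_factors
#' @param factors named normalization factors covering every sample (e.g.
#'   from [tmm_factors()]); `NULL` for unit factors.
#' @param prior_count small offset avoiding log of zero (default 0.5).
#' @return numeric matrix of log2CPM values with the dimnames of `counts`.
#' @export
log2cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  .check_count_matrix(counts)
  if (is.null(factors)) {
    factors <- rep(1, ncol(counts))
    names(factors) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(factors))
  if (length(missing)) {
    stop("no normalization factor for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eff_lib <- colSums(counts) * factors[colnames(counts)]
  log2(sweep(counts + prior_count, 2, eff_lib, "/") * 1e6)
}

#' Filter genes by average expression and protein evidence
#'
#' Keeps genes whose row-mean log2CPM is at least `min_avg_log2cpm` and, when
#' a protein-evidence list is supplied, whose id appears in it. Gene order is
#' preserved. The threshold uses `>=` semantics.
#'
#' @param expr log2CPM matrix, genes x samples.
#' @param min_avg_log2cpm expression threshold on the row mean (default 4).
#' @param protein_evidence optional character vector of gene ids with
#'   protein-level evidence.
#' @return the filtered expression matrix.
#' @export
filter_genes <- function(expr, min_avg_log2cpm = 4, protein_evidence = NULL) {
  .assert(is.matrix(expr) && !is.null(rownames(expr)),
          "`expr` must be a matrix with gene rownames")
  .assert(is.finite(min_avg_log2cpm), "`min_avg_log2cpm` must be finite")
  pass_expr <- rowMeans(expr) >= min_avg_log2cpm
  pass_prot <- if (is.null(protein_evidence)) rep(TRUE, nrow(expr)) else
    rownames(expr) %in% protein_evidence
  keep <- pass_expr & pass_prot
  if (!any(keep)) {
    stop(sprintf(
      "no genes pass filtering: %d/%d failed the expression filter, %d/%d the protein-evidence filter",
      sum(!pass_expr), nrow(expr), sum(!pass_prot), nrow(expr)), call. = FALSE)
  }
  expr[keep, , drop = FALSE]
}

#' Intersect candidate genes across expression matrices
#'
#' Returns the gene ids present in every supplied (already filtered)
#' expression matrix — typically all tissue x dataset combinations.
#'
#' @param ... two or more expression matrices (or character vectors of gene
#'   ids), or a single list of them.
#' @return character vector of shared gene ids.
#' @export
intersect_candidates <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !is.matrix(mats[[1]])) {
    mats <- mats[[1]]
  }
  .assert(length(mats) >= 2, "need at least 2 matrices to intersect")
  ids <- lapply(mats, function(m) if (is.character(m)) m else rownames(m))
  shared <- Reduce(intersect, ids)
  if (!length(shared)) stop("candidate gene intersection is empty", call. = FALSE)
  shared
}
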