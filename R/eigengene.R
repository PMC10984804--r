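#' Community eigengene
#'
#' The eigengene of a gene community is the first principal component of the
#' community's standardized expression over samples: genes are scaled to mean
#' 0 and SD 1 across samples, and the scores are the first right-singular
#' vector of the standardized matrix (unit norm over samples). The sign is
#' fixed so that the scores correlate non-negatively with the community's
#' mean standardized expression; if that mean is identically zero (e.g. two
#' exactly opposite genes) the tie is broken so the first gene's loading is
#' positive.
#'
#' @param x expression matrix for one community's genes (genes x samples,
#'   >= 2 genes and >= 3 samples). Constant genes are dropped with a warning.
#' @return list with `scores` (named, unit norm), `variance_explained`
#'   (first squared singular value over the total), `n_genes_used`,
#'   `dropped` (ids of constant genes removed).
#' @references Langfelder P, Horvath S (2007). Eigengene networks for
#'   studying the relationships between co-expression modules.
#'   BMC Systems Biology 1:54.
#' @export
eigengene <- function(x) {
  .assert(is.matrix(x), "`x` must be a genes x samples matrix")
  .assert(ncol(x) >= 3, "need at least 3 samples")
  sds <- apply(x, 1, sd)
  dropped <- rownames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning(length(dropped), " constant gene(s) dropped from eigengene computation")
    x <- x[setdiff(rownames(x), dropped), , drop = FALSE]
  }
  .assert(nrow(x) >= 2, "community has fewer than 2 variable genes")
  z <- t(scale(t(x)))
  s <- svd(z)
  scores <- s$v[, 1]
  m <- colMeans(z)
  align <- sum(scores * m)
  if (abs(align) < 1e-12) {
    if (s$u[1, 1] < 0) scores <- -scores
  } else if (align < 0) {
    scores <- -scores
  }
  names(scores) <- colnames(x)
  list(scores = scores,
       variance_explained = s$d[1]^2 / sum(s$d^2),
       n_genes_used = nrow(x),
       dropped = dropped)
}

#' Eigengene matrix for all communities
#'
#' Computes one eigengene per community over a common set of samples.
#'
#' @param expr expression matrix (genes x samples).
#' @param membership named gene -> community vector (an `xt_partition` or its
#'   `membership`); community 0 ("unassigned") is skipped.
#' @param min_genes smallest community evaluated (default 2).
#' @return an `xt_eigengenes` object: list with `scores` (community x sample
#'   matrix), `variance_explained` and `community_sizes` (genes used).
#' @export
eigengene_matrix <- function(expr, membership, min_genes = 2L) {
  if (inherits(membership, "xt_partition")) membership <- membership$membership
  .assert(!is.null(names(membership)), "`membership` must be a named vector")
  comms <- sort(unique(membership[membership != 0]))
  .assert(length(comms) > 0, "no communities in `membership`")
  rows <- list()
  ve <- sizes <- numeric(0)
  for (k in comms) {
    genes <- intersect(names(membership)[membership == k], rownames(expr))
    if (length(genes) < min_genes) next
    eg <- eigengene(expr[genes, , drop = FALSE])
    rows[[as.character(k)]] <- eg$scores
    ve[as.character(k)] <- eg$variance_explained
    sizes[as.character(k)] <- eg$n_genes_used
  }
  .assert(length(rows) > 0, "no community had enough genes in `expr`")
  scores <- do.call(rbind, rows)
  colnames(scores) <- colnames(expr)
  structure(list(scores = scores, variance_explained = ve,
                 community_sizes = sizes),
            class = "xt_eigengenes")
}

#' @export
print.xt_eigengenes <- function(x, ...) {
  cat(sprintf("<xt_eigengenes>: %d communities x %d samples (median var. explained %.2f)\n",
              nrow(x$scores), ncol(x$scores),
              stats::median(x$variance_explained)))
  invisible(x)
}
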