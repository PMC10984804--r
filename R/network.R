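#' Per-tissue co-expression edges
#'
#' For every unordered gene pair computes the Pearson correlation across
#' samples, a two-sided p-value via the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, and Benjamini-Hochberg adjusted
#' q-values across \emph{all} pairs tested in the tissue. Pairs with
#' `r > r_min` (or `|r| > r_min` when `use_abs = TRUE`) and `q < fdr_max` are
#' retained. Constant genes are excluded from pairing and counted.
#'
#' @param expr log2CPM matrix, genes x samples (>= 4 samples).
#' @param r_min correlation threshold (default 0.30, signed).
#' @param fdr_max FDR threshold on BH q-values (default 0.01).
#' @param use_abs threshold `|r|` instead of signed `r`.
#' @param tissue optional tissue label stored with the edge set.
#' @return an `xt_edges` object: list with `edges` (data frame `gene_a`,
#'   `gene_b`, `r`, `p`, `q`, canonical `gene_a < gene_b`), `tissue`,
#'   `n_samples`, `n_genes_tested`, `n_pairs_tested`, `n_dropped_constant`.
#' @export
tissue_edges <- function(expr, r_min = 0.30, fdr_max = 0.01,
                         use_abs = FALSE, tissue = NULL) {
  .assert(is.matrix(expr) && !is.null(rownames(expr)),
          "`expr` must be a matrix with gene rownames")
  n <- ncol(expr)
  .assert(n >= 4, "need at least 4 samples to test correlations")
  sds <- apply(expr, 1, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    message(sum(const), " constant gene(s) excluded from edge testing")
    expr <- expr[!const, , drop = FALSE]
  }
  g <- nrow(expr)
  .assert(g >= 2, "fewer than 2 variable genes")
  rmat <- cor(t(expr))
  iu <- which(upper.tri(rmat), arr.ind = TRUE)
  r <- rmat[upper.tri(rmat)]
  # exact collinearity: |r| may exceed 1 by rounding
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 0
  q <- p.adjust(p, method = "BH")
  keep <- (if (use_abs) abs(r) else r) > r_min & q < fdr_max
  ga <- rownames(expr)[iu[keep, 1]]
  gb <- rownames(expr)[iu[keep, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  edges <- data.frame(gene_a = ga, gene_b = gb,
                      r = r[keep], p = p[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, tissue = tissue, n_samples = n,
                 n_genes_tested = g, n_pairs_tested = length(r),
                 n_dropped_constant = sum(const)),
            class = "xt_edges")
}

#' @export
print.xt_edges <- function(x, ...) {
  cat(sprintf("<xt_edges%s>: %d edges retained of %d pairs tested (%d genes, %d samples)\n",
              if (is.null(x$tissue)) "" else paste0(" ", x$tissue),
              nrow(x$edges), x$n_pairs_tested, x$n_genes_tested, x$n_samples))
  invisible(x)
}

#' Shared two-tissue co-expression network
#'
#' Intersects the SM and SAT edge sets: an edge enters the shared network only
#' if it passes the correlation and FDR thresholds in \emph{both} tissues and
#' (by default) has the same correlation sign in both. Nodes are the
#' endpoints of surviving edges; isolated genes are excluded.
#'
#' @param edges_sm,edges_sat `xt_edges` objects from [tissue_edges()].
#' @param require_sign_concordance drop edges whose correlation signs differ
#'   between tissues (default `TRUE`).
#' @return an `xt_network`: list with `nodes`, `edges` (data frame `gene_a`,
#'   `gene_b`, `r_sm`, `r_sat`) and `summary` (`n_nodes`, `n_edges`,
#'   `mean_r`, the mean over edges of the two-tissue average correlation).
#' @export
intersect_edges <- function(edges_sm, edges_sat, require_sign_concordance = TRUE) {
  .assert(inherits(edges_sm, "xt_edges") && inherits(edges_sat, "xt_edges"),
          "inputs must be xt_edges objects")
  a <- edges_sm$edges
  b <- edges_sat$edges
  key_a <- paste(a$gene_a, a$gene_b, sep = "\r")
  key_b <- paste(b$gene_a, b$gene_b, sep = "\r")
  idx <- match(key_a, key_b)
  hit <- !is.na(idx)
  edges <- data.frame(gene_a = a$gene_a[hit], gene_b = a$gene_b[hit],
                      r_sm = a$r[hit], r_sat = b$r[idx[hit]],
                      stringsAsFactors = FALSE)
  if (require_sign_concordance) {
    edges <- edges[sign(edges$r_sm) == sign(edges$r_sat), , drop = FALSE]
  }
  if (!nrow(edges)) {
    stop("no shared edges between tissues; consider relaxing r_min or fdr_max",
         call. = FALSE)
  }
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  net <- structure(list(nodes = nodes, edges = edges, summary = NULL),
                   class = "xt_network")
  net$summary <- network_summary(net)
  net
}

#' Network summary statistics
#'
#' @param network an `xt_network`.
#' @return list with `n_nodes`, `n_edges` and `mean_r` (mean over edges of
#'   the per-edge average of the two tissue correlations; `NaN` with a
#'   warning for an empty network).
#' @export
network_summary <- function(network) {
  .assert(inherits(network, "xt_network"), "`network` must be an xt_network")
  n_edges <- nrow(network$edges)
  if (n_edges == 0L) {
    warning("empty network: mean_r undefined")
    return(list(n_nodes = 0L, n_edges = 0L, mean_r = NaN))
  }
  list(n_nodes = length(network$nodes), n_edges = n_edges,
       mean_r = mean((network$edges$r_sm + network$edges$r_sat) / 2))
}

#' @export
print.xt_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<xt_network>: %d genes, %d connections, mean r = %.3f\n",
              s$n_nodes, s$n_edges, s$mean_r))
  invisible(x)
}

#' Louvain community detection on the shared network
#'
#' Runs Louvain modularity optimization on the unweighted edge graph
#' (optionally weighted by the two-tissue mean correlation). Communities
#' smaller than `min_size` are relabeled `0` ("unassigned"); the remaining
#' communities are renumbered 1, 2, ... by decreasing size. Deterministic for
#' a fixed seed.
#'
#' @param network an `xt_network`.
#' @param resolution Louvain resolution parameter (default 1).
#' @param min_size smallest community kept (default 10).
#' @param seed integer seed for the (stochastic) Louvain heuristic.
#' @param weighted use mean correlation edge weights (default `FALSE`).
#' @return an `xt_partition`: list with `membership` (named integer vector,
#'   0 = unassigned), `modularity` of the optimized partition, `sizes`,
#'   `min_size`, `resolution`, `seed`.
#' @references Blondel VD et al. (2008). Fast unfolding of communities in
#'   large networks. J Stat Mech P10008.
#' @export
louvain_communities <- function(network, resolution = 1, min_size = 10,
                                seed = 1L, weighted = FALSE) {
  .assert(inherits(network, "xt_network"), "`network` must be an xt_network")
  .assert(nrow(network$edges) > 0, "network has no edges")
  .assert(resolution > 0, "`resolution` must be positive")
  g <- igraph::graph_from_data_frame(network$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE, vertices = network$nodes)
  w <- if (weighted) (network$edges$r_sm + network$edges$r_sat) / 2 else NULL
  cl <- .with_seed(seed, igraph::cluster_louvain(g, weights = w,
                                                 resolution = resolution))
  memb <- igraph::membership(cl)
  modularity <- igraph::modularity(cl)
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < min_size])
  out <- integer(length(memb))
  names(out) <- names(memb)
  big <- setdiff(as.integer(names(sizes)), small)
  big <- big[order(-sizes[as.character(big)])]
  for (i in seq_along(big)) out[memb == big[i]] <- i
  structure(list(membership = out,
                 modularity = modularity,
                 sizes = table(factor(out, levels = sort(unique(out)))),
                 min_size = min_size, resolution = resolution, seed = seed),
            class = "xt_partition")
}

#' @export
print.xt_partition <- function(x, ...) {
  n_comm <- sum(names(x$sizes) != "0")
  cat(sprintf("<xt_partition>: %d communities (modularity %.3f), %d unassigned genes\n",
              n_comm, x$modularity, sum(x$membership == 0L)))
  invisible(x)
}

#' Match detected communities to a reference labeling
#'
#' For each reference (e.g. planted) community, finds the detected community
#' with the largest overlap and reports the overlap fraction. Useful for
#' linking a partition back to simulation ground truth.
#'
#' @param partition an `xt_partition` (or named membership vector).
#' @param reference named vector of reference labels (0 entries are ignored).
#' @return data frame with `reference`, `detected`, `n_reference`,
#'   `n_overlap`, `fraction`.
#' @export
match_communities <- function(partition, reference) {
  memb <- if (inherits(partition, "xt_partition")) partition$membership else partition
  ref <- reference[reference != 0]
  out <- lapply(sort(unique(ref)), function(k) {
    genes <- names(ref)[ref == k]
    hit <- memb[intersect(genes, names(memb))]
    hit <- hit[hit != 0]
    if (!length(hit)) {
      return(data.frame(reference = k, detected = NA_integer_,
                        n_reference = length(genes), n_overlap = 0L,
                        fraction = 0))
    }
    tab <- sort(table(hit), decreasing = TRUE)
    data.frame(reference = k, detected = as.integer(names(tab)[1]),
               n_reference = length(genes), n_overlap = as.integer(tab[1]),
               fraction = as.integer(tab[1]) / length(genes))
  })
  do.call(rbind, out)
}
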