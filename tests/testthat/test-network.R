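rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

test_that("a perfectly duplicated gene is always retained", {
  expr <- rand_expr(6, 100, seed = 2)
  expr["g002", ] <- expr["g001", ]
  es <- tissue_edges(expr, r_min = 0.3, fdr_max = 0.01)
  hit <- es$edges[es$edges$gene_a == "g001" & es$edges$gene_b == "g002", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$r, 1)
  expect_lt(hit$q, 1e-12)
})

test_that("edge selection equals a brute-force all-pairs scan", {
  expr <- rand_expr(5, 10, seed = 11)
  expr[2, ] <- expr[1, ] + rnorm(10, sd = 0.3) # plant correlated pairs
  expr[4, ] <- -expr[3, ] + rnorm(10, sd = 0.3)
  r_min <- 0.3; fdr_max <- 0.2
  es <- tissue_edges(expr, r_min = r_min, fdr_max = fdr_max)
  # oracle: textbook r/p per pair, then step-up BH over all pairs
  pairs <- t(combn(rownames(expr), 2))
  r <- p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ct <- cor.test(expr[pairs[i, 1], ], expr[pairs[i, 2], ])
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  reject <- oracle_bh_reject(p, fdr_max)
  keep <- reject & r > r_min
  expected <- sort(paste(pmin(pairs[keep, 1], pairs[keep, 2]),
                         pmax(pairs[keep, 1], pairs[keep, 2])))
  expect_identical(paste(es$edges$gene_a, es$edges$gene_b), expected)
  # and the retained correlations agree with cor.test
  expect_equal(es$edges$r,
               r[keep][order(paste(pairs[keep, 1], pairs[keep, 2]))],
               tolerance = 1e-12)
})

test_that("BH q-value thresholding equals the brute-force step-up rule", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(1000)^2
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_identical(p.adjust(p, "BH") <= alpha, oracle_bh_reject(p, alpha))
    }
  }
})

test_that("edges are canonical and invariant to gene order", {
  expr <- rand_expr(30, 50, seed = 4)
  expr[2, ] <- expr[9, ] + rnorm(50, sd = 0.4)
  es1 <- tissue_edges(expr, r_min = 0.2, fdr_max = 0.2)
  es2 <- tissue_edges(expr[rev(rownames(expr)), ], r_min = 0.2, fdr_max = 0.2)
  expect_true(all(es1$edges$gene_a < es1$edges$gene_b))
  expect_identical(es1$edges[, c("gene_a", "gene_b")],
                   es2$edges[, c("gene_a", "gene_b")])
})

test_that("constant genes are excluded and tiny designs rejected", {
  expr <- rand_expr(10, 20, seed = 5)
  expr[3, ] <- 7
  expect_message(es <- tissue_edges(expr), "constant")
  expect_equal(es$n_genes_tested, 9L)
  expect_error(tissue_edges(rand_expr(5, 3)), "4 samples")
})

test_that("tissue intersection keeps shared sign-concordant edges only", {
  expr <- rand_expr(12, 80, seed = 6)
  expr[2, ] <- expr[1, ] + rnorm(80, sd = 0.5)
  expr[4, ] <- expr[3, ] + rnorm(80, sd = 0.5)
  es <- tissue_edges(expr, r_min = 0.2, fdr_max = 0.05)
  # identical edge sets intersect to themselves
  net <- intersect_edges(es, es)
  expect_identical(net$edges[, c("gene_a", "gene_b")],
                   es$edges[, c("gene_a", "gene_b")])
  expect_equal(net$edges$r_sm, net$edges$r_sat)
  # disjoint edge sets error
  other <- rand_expr(12, 80, seed = 99)
  other[6, ] <- other[5, ] + rnorm(80, sd = 0.2)
  es2 <- tissue_edges(other, r_min = 0.6, fdr_max = 0.01)
  if (!any(paste(es$edges$gene_a, es$edges$gene_b) %in%
             paste(es2$edges$gene_a, es2$edges$gene_b))) {
    expect_error(intersect_edges(es, es2), "no shared edges")
  }
  # sign concordance: an edge positive in one tissue, negative in the other
  flipped <- expr
  flipped[2, ] <- -flipped[2, ]
  es_flip <- tissue_edges(flipped, r_min = 0.2, fdr_max = 0.05, use_abs = TRUE)
  es_abs <- tissue_edges(expr, r_min = 0.2, fdr_max = 0.05, use_abs = TRUE)
  net2 <- intersect_edges(es_abs, es_flip, require_sign_concordance = TRUE)
  expect_false("g001 g002" %in% paste(net2$edges$gene_a, net2$edges$gene_b))
  net3 <- intersect_edges(es_abs, es_flip, require_sign_concordance = FALSE)
  expect_true("g001 g002" %in% paste(net3$edges$gene_a, net3$edges$gene_b))
})

test_that("network summary is exact arithmetic", {
  fake <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                       r_sm = c(0.5, 0.6), r_sat = c(0.7, 0.6))),
    class = "xt_network")
  s <- network_summary(fake)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 2L)
  expect_equal(s$mean_r, 0.6)
  empty <- structure(list(nodes = character(0),
                          edges = data.frame(gene_a = character(0),
                                             gene_b = character(0),
                                             r_sm = numeric(0),
                                             r_sat = numeric(0))),
                     class = "xt_network")
  expect_warning(s0 <- network_summary(empty), "empty")
  expect_true(is.nan(s0$mean_r))
})

test_that("Louvain separates two cliques and keeps one clique whole", {
  clique_edges <- function(nodes) {
    pairs <- t(combn(nodes, 2))
    data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
               r_sm = 0.8, r_sat = 0.8, stringsAsFactors = FALSE)
  }
  a <- sprintf("a%02d", 1:10)
  b <- sprintf("b%02d", 1:10)
  edges <- rbind(clique_edges(a), clique_edges(b),
                 data.frame(gene_a = "a01", gene_b = "b01",
                            r_sm = 0.8, r_sat = 0.8))
  net <- structure(list(nodes = c(a, b), edges = edges, summary = NULL),
                   class = "xt_network")
  net$summary <- network_summary(net)
  part <- louvain_communities(net, min_size = 5, seed = 1)
  expect_equal(sum(names(part$sizes) != "0"), 2L)
  expect_equal(length(unique(part$membership[a])), 1L)
  expect_equal(length(unique(part$membership[b])), 1L)
  expect_gte(part$modularity, 0) # beats the trivial one-community partition
  single <- structure(list(nodes = a, edges = clique_edges(a), summary = NULL),
                      class = "xt_network")
  single$summary <- network_summary(single)
  part1 <- louvain_communities(single, min_size = 5, seed = 1)
  expect_equal(sum(names(part1$sizes) != "0"), 1L)
})

test_that("communities below min_size become unassigned and runs are deterministic", {
  pairs <- t(combn(sprintf("c%d", 1:4), 2))
  small <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                      r_sm = 0.9, r_sat = 0.9)
  big_nodes <- sprintf("d%02d", 1:12)
  big_pairs <- t(combn(big_nodes, 2))
  big <- data.frame(gene_a = big_pairs[, 1], gene_b = big_pairs[, 2],
                    r_sm = 0.9, r_sat = 0.9)
  net <- structure(list(nodes = c(sprintf("c%d", 1:4), big_nodes),
                        edges = rbind(small, big), summary = NULL),
                   class = "xt_network")
  net$summary <- network_summary(net)
  part <- louvain_communities(net, min_size = 10, seed = 3)
  expect_true(all(part$membership[sprintf("c%d", 1:4)] == 0L))
  expect_true(all(part$membership[big_nodes] == 1L))
  expect_identical(part, louvain_communities(net, min_size = 10, seed = 3))
})

test_that("under the null the shared network is far sparser than either tissue", {
  # independent genes: the two tissues' false edges rarely coincide
  n_shared <- n_single <- 0
  for (seed in 1:5) {
    sm <- rand_expr(100, 60, seed = 100 + seed)
    sat <- rand_expr(100, 60, seed = 200 + seed)
    es_sm <- tissue_edges(sm, r_min = 0.2, fdr_max = 0.3)
    es_sat <- tissue_edges(sat, r_min = 0.2, fdr_max = 0.3)
    n_single <- n_single + max(nrow(es_sm$edges), nrow(es_sat$edges))
    shared <- tryCatch(nrow(intersect_edges(es_sm, es_sat)$edges),
                       error = function(e) 0L)
    n_shared <- n_shared + shared
  }
  expect_lte(n_shared, 0.01 * max(n_single, 1))
})
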