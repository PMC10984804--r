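#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]. Either
#' a `simulate` block (arguments for [sim_config()], an `xt_sim_config`, or
#' `TRUE` for the defaults) or file paths for the reference and intervention
#' cohorts must be supplied.
#'
#' @param simulate `TRUE`, a list of [sim_config()] arguments, or an
#'   `xt_sim_config`; `NULL` to read cohorts from files instead.
#' @param reference_counts,reference_samples,reference_traits paths to the
#'   cross-sectional reference cohort (counts TSV/MTX, sample sheet CSV,
#'   trait CSV) when not simulating.
#' @param intervention_counts,intervention_samples,intervention_traits paths
#'   to the paired pre/post cohort when not simulating.
#' @param protein_evidence optional path to a one-id-per-line gene list.
#' @param min_avg_log2cpm,r_min,fdr_max,use_abs,resolution,min_size network
#'   thresholds (see [filter_genes()], [tissue_edges()],
#'   [louvain_communities()]).
#' @param n_ortho,n_repeats,n_permutations OPLS settings (see [opls_cv()]).
#' @param trait_tissue,trait_timepoint sample slice for trait correlations.
#' @param opls_tissues tissues the OPLS trait models are fitted in.
#' @param opls_community community used for the OPLS models; `NULL` picks the
#'   community with the smallest Time x Tissue interaction p-value.
#' @param with_opls run the OPLS stage (default `TRUE`).
#' @param keep_data also return the intermediate objects (expression
#'   matrices, network, partition, eigengenes, annotations and traits) in the
#'   report's `data` element for further analysis; they are never written to
#'   the JSON report (default `FALSE`).
#' @param seed global integer seed (required).
#' @param outdir optional output directory for all artifacts.
#' @return a validated `xt_pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            reference_counts = NULL, reference_samples = NULL,
                            reference_traits = NULL,
                            intervention_counts = NULL,
                            intervention_samples = NULL,
                            intervention_traits = NULL,
                            protein_evidence = NULL,
                            min_avg_log2cpm = 4, r_min = 0.30, fdr_max = 0.01,
                            use_abs = FALSE, resolution = 1, min_size = 10,
                            n_ortho = 1L, n_repeats = 200L,
                            n_permutations = 200L,
                            trait_tissue = "SAT", trait_timepoint = "pre",
                            opls_tissues = c("SAT", "SM"),
                            opls_community = NULL,
                            with_opls = TRUE, keep_data = FALSE,
                            seed = NULL, outdir = NULL) {
  .assert(!is.null(seed), "`seed` is required")
  if (isTRUE(simulate)) simulate <- list()
  if (is.list(simulate) && !inherits(simulate, "xt_sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  .assert(!is.null(simulate) ||
            (!is.null(reference_counts) && !is.null(intervention_counts)),
          "either a simulate block or cohort paths must be given")
  .assert(r_min >= 0 && r_min < 1, "`r_min` must be in [0, 1)")
  .assert(fdr_max > 0 && fdr_max <= 1, "`fdr_max` must be in (0, 1]")
  .assert(min_size >= 1, "`min_size` must be >= 1")
  structure(list(
    simulate = simulate,
    reference_counts = reference_counts, reference_samples = reference_samples,
    reference_traits = reference_traits,
    intervention_counts = intervention_counts,
    intervention_samples = intervention_samples,
    intervention_traits = intervention_traits,
    protein_evidence = protein_evidence,
    min_avg_log2cpm = min_avg_log2cpm, r_min = r_min, fdr_max = fdr_max,
    use_abs = use_abs, resolution = resolution, min_size = min_size,
    n_ortho = as.integer(n_ortho), n_repeats = as.integer(n_repeats),
    n_permutations = as.integer(n_permutations),
    trait_tissue = trait_tissue, trait_timepoint = trait_timepoint,
    opls_tissues = opls_tissues, opls_community = opls_community,
    with_opls = isTRUE(with_opls), keep_data = isTRUE(keep_data),
    seed = as.integer(seed), outdir = outdir
  ), class = "xt_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments; a
#'   `simulate:` mapping is passed to [sim_config()].
#' @return an `xt_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.config_hash <- function(config) {
  plain <- lapply(unclass(config), function(x) if (is.null(x)) NA else unclass(x))
  js <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

# TMM + log2CPM + expression/protein filter for one tissue slice.
.prep_slice <- function(counts, annotations, tissue, min_cpm, protein) {
  samp <- annotations$sample_id[annotations$tissue == tissue]
  cts <- counts[, samp, drop = FALSE]
  expr <- log2cpm(cts, tmm_factors(cts))
  filter_genes(expr, min_avg_log2cpm = min_cpm, protein_evidence = protein)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full cross-tissue analysis pipeline
#'
#' Executes, in order: preprocessing of the reference and intervention
#' cohorts per tissue (TMM, log2CPM, expression/protein filters), candidate
#' intersection across all dataset x tissue slices, per-tissue correlation
#' edges on the reference cohort, the shared-network intersection, Louvain
#' community detection, intervention-cohort eigengenes, the Time x Tissue
#' repeated-measures ANOVA with per-tissue paired tests, eigengene--trait
#' Pearson correlations, and (optionally) OPLS / OPLS-DA trait models with
#' Monte-Carlo cross-validation and AUROC in the reference cohort. The run
#' is deterministic for a fixed configuration and seed.
#'
#' @param config an `xt_pipeline_config` (or YAML path).
#' @return an `xt_report` list: `network`, `partition` (sizes, modularity),
#'   `communities` (Time x Tissue table), `traits`, `opls` (per tissue),
#'   `truth_matching` (simulated runs only) and `provenance`. When
#'   `config$outdir` is set all intermediate artifacts and a JSON report are
#'   written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .assert(inherits(config, "xt_pipeline_config"),
          "`config` must come from pipeline_config()")
  seed <- config$seed

  if (!is.null(config$simulate)) {
    ref <- .stage("simulate", simulate_reference_cohort(config$simulate, seed))
    int <- .stage("simulate",
                  simulate_intervention_cohort(config$simulate, seed + 1L))
    ref_counts <- ref$counts; ref_ann <- ref$annotations; ref_traits <- ref$traits
    int_counts <- int$counts; int_ann <- int$annotations; int_traits <- int$traits
    truth <- int$truth
  } else {
    ref_counts <- .stage("read", read_counts(config$reference_counts))
    ref_ann <- .stage("read", read_sample_sheet(config$reference_samples))
    ref_traits <- if (!is.null(config$reference_traits))
      read_traits(config$reference_traits) else NULL
    int_counts <- .stage("read", read_counts(config$intervention_counts))
    int_ann <- .stage("read", read_sample_sheet(config$intervention_samples))
    int_traits <- if (!is.null(config$intervention_traits))
      read_traits(config$intervention_traits) else NULL
    truth <- NULL
  }
  protein <- if (!is.null(config$protein_evidence))
    read_gene_list(config$protein_evidence) else NULL

  expr <- .stage("preprocess", list(
    ref_sm = .prep_slice(ref_counts, ref_ann, "SM", config$min_avg_log2cpm, protein),
    ref_sat = .prep_slice(ref_counts, ref_ann, "SAT", config$min_avg_log2cpm, protein),
    int_sm = .prep_slice(int_counts, int_ann, "SM", config$min_avg_log2cpm, protein),
    int_sat = .prep_slice(int_counts, int_ann, "SAT", config$min_avg_log2cpm, protein)
  ))
  candidates <- .stage("candidates", intersect_candidates(expr))

  edges_sm <- .stage("edges", tissue_edges(
    expr$ref_sm[candidates, , drop = FALSE], r_min = config$r_min,
    fdr_max = config$fdr_max, use_abs = config$use_abs, tissue = "SM"))
  edges_sat <- .stage("edges", tissue_edges(
    expr$ref_sat[candidates, , drop = FALSE], r_min = config$r_min,
    fdr_max = config$fdr_max, use_abs = config$use_abs, tissue = "SAT"))
  network <- .stage("network", intersect_edges(edges_sm, edges_sat))
  partition <- .stage("communities", louvain_communities(
    network, resolution = config$resolution, min_size = config$min_size,
    seed = seed))

  # Intervention expression, normalized jointly over all paired samples.
  int_expr <- .stage("eigengenes", {
    e <- log2cpm(int_counts, tmm_factors(int_counts))
    e[intersect(rownames(e), network$nodes), , drop = FALSE]
  })
  eig <- .stage("eigengenes", eigengene_matrix(int_expr, partition))
  communities <- .stage("interaction", interaction_anova(eig, int_ann))
  sizes <- partition$sizes
  communities$n_genes <- as.integer(sizes[communities$community])

  traits_tab <- if (!is.null(int_traits)) {
    .stage("traits", trait_correlations(
      eig, int_ann, int_traits,
      tissue = config$trait_tissue, timepoint = config$trait_timepoint,
      trait_cols = intersect(c("bmi_like", "fatmass_like"), names(int_traits))))
  } else NULL

  truth_matching <- NULL
  if (!is.null(truth)) {
    truth_matching <- match_communities(partition, truth$gene_community)
  }

  opls_comm <- config$opls_community
  if (is.null(opls_comm)) {
    opls_comm <- communities$community[which.min(communities$p_interaction)]
  }
  opls_res <- NULL
  if (config$with_opls && !is.null(ref_traits)) {
    genes <- names(partition$membership)[partition$membership == as.integer(opls_comm)]
    opls_res <- lapply(config$opls_tissues, function(tissue) {
      ex <- if (tissue == "SM") expr$ref_sm else expr$ref_sat
      genes_t <- intersect(genes, rownames(ex))
      X <- t(ex[genes_t, , drop = FALSE])
      ann_t <- ref_ann[match(rownames(X), ref_ann$sample_id), ]
      tr <- ref_traits[match(ann_t$subject_id, ref_traits$subject_id), ]
      .stage(paste0("opls_", tissue), {
        m_bmi <- fit_opls(X, tr$bmi_like, n_ortho = config$n_ortho)
        cv_bmi <- opls_cv(X, tr$bmi_like, n_ortho = config$n_ortho,
                          n_repeats = config$n_repeats,
                          n_permutations = config$n_permutations,
                          seed = seed + 100L)
        da <- fit_oplsda(X, tr$t2d_like, n_ortho = config$n_ortho)
        roc <- auroc(da$scores, da$labels)
        vip_bmi <- sort(opls_vip(m_bmi), decreasing = TRUE)
        list(tissue = tissue, community = as.character(opls_comm),
             n_samples = nrow(X), n_genes = length(genes_t),
             bmi = list(r2y = m_bmi$r2y, r2x = m_bmi$r2x, q2 = cv_bmi$q2,
                        q_value = cv_bmi$q_value,
                        n_vip_gt1 = sum(vip_bmi > 1),
                        top_vip = names(vip_bmi)[seq_len(min(10, length(vip_bmi)))]),
             t2d = list(r2y = da$r2y, auroc = roc$auroc,
                        n_pos = roc$n_pos, n_neg = roc$n_neg,
                        n_vip_gt1 = sum(opls_vip(da) > 1)))
      })
    })
    names(opls_res) <- config$opls_tissues
  }

  report <- structure(list(
    network = c(network$summary,
                list(n_candidates = length(candidates),
                     modularity = partition$modularity,
                     n_communities = sum(names(sizes) != "0"),
                     n_unassigned = sum(partition$membership == 0L))),
    partition_sizes = as.list(sizes),
    communities = communities,
    traits = traits_tab,
    opls = opls_res,
    truth_matching = truth_matching,
    provenance = list(
      package = "xtissue",
      version = as.character(utils::packageVersion("xtissue")),
      seed = seed,
      config_hash = .config_hash(config))
  ), class = "xt_report")

  if (config$keep_data) {
    report$data <- list(expr = expr, network = network, partition = partition,
                        eigengenes = eig, ref_annotations = ref_ann,
                        ref_traits = ref_traits, int_annotations = int_ann,
                        int_traits = int_traits)
  }

  if (!is.null(config$outdir)) {
    .write_report_files(report, network, partition, eig, config$outdir)
  }
  report
}

.report_json <- function(report) {
  report <- unclass(report)
  report$data <- NULL # intermediate objects never enter the JSON report
  jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                   dataframe = "rows", force = TRUE, pretty = TRUE, na = "null")
}

.write_report_files <- function(report, network, partition, eig, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_edges(network, file.path(outdir, "network_edges.tsv"))
  write_communities(partition, file.path(outdir, "communities.tsv"))
  write_eigengenes(eig, file.path(outdir, "eigengenes.csv"))
  res <- report$communities[, c("community", "n_genes", "fc_sm", "p_sm",
                                "fc_sat", "p_sat", "p_interaction")]
  write.table(res, file.path(outdir, "community_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$traits)) {
    write.table(report$traits, file.path(outdir, "trait_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(as.character(.report_json(report)),
             file.path(outdir, "report.json"))
  invisible(outdir)
}

#' @export
print.xt_report <- function(x, ...) {
  n <- x$network
  cat(sprintf("<xt_report>: network of %d genes / %d edges (mean r %.2f), %d communities\n",
              n$n_nodes, n$n_edges, n$mean_r, n$n_communities))
  sig <- x$communities[x$communities$p_interaction < 0.05, "community"]
  cat(sprintf("  Time x Tissue interaction p < 0.05: %s\n",
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' Structurally validate a pipeline report
#'
#' Checks the report against the JSON schema shipped at
#' `system.file("schema", "pipeline_report.schema.json", package = "xtissue")`
#' (required top-level members and their basic types).
#'
#' @param report an `xt_report`.
#' @return `TRUE`, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "pipeline_report.schema.json",
                                            package = "xtissue"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(report))
  .assert(length(missing) == 0,
          "report is missing members: ", paste(missing, collapse = ", "))
  .assert(is.numeric(report$network$n_nodes) && is.numeric(report$network$n_edges),
          "network summary must contain numeric n_nodes/n_edges")
  .assert(is.data.frame(report$communities) &&
            all(c("community", "p_interaction", "fc_sm", "fc_sat") %in%
                  names(report$communities)),
          "communities table malformed")
  .assert(is.list(report$provenance) &&
            all(c("seed", "config_hash", "version") %in% names(report$provenance)),
          "provenance malformed")
  TRUE
}

#' Map an external validation cohort onto the network communities
#'
#' Reports the fraction of network genes present in an external cohort,
#' recomputes community eigengenes on the mapped genes only, and runs the
#' paired pre/post test per community for the cohort's single tissue.
#'
#' @param partition an `xt_partition` from the discovery network.
#' @param expr the external cohort's expression matrix (genes x samples).
#' @param annotations sample sheet with `sample_id`, `subject_id`,
#'   `timepoint` (pre/post).
#' @return list with `mapped_fraction`, `n_mapped`, `n_network` and
#'   `results` (per community: `fc`, `t`, `p`, `n`).
#' @export
validate_external_cohort <- function(partition, expr, annotations) {
  memb <- partition$membership
  mapped <- intersect(names(memb), rownames(expr))
  frac <- length(mapped) / length(memb)
  if (frac < 0.5) {
    warning(sprintf("only %.0f%% of network genes map to the cohort", 100 * frac))
  }
  eig <- eigengene_matrix(expr[mapped, , drop = FALSE], memb[mapped])
  pre <- annotations[annotations$timepoint == "pre", ]
  post <- annotations[annotations$timepoint == "post", ]
  rows <- lapply(rownames(eig$scores), function(comm) {
    s_pre <- eig$scores[comm, pre$sample_id]
    names(s_pre) <- pre$subject_id
    s_post <- eig$scores[comm, post$sample_id]
    names(s_post) <- post$subject_id
    res <- paired_community_test(s_pre, s_post)
    data.frame(community = comm, fc = res$fc, t = res$t, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  list(mapped_fraction = frac, n_mapped = length(mapped),
       n_network = length(memb), results = do.call(rbind, rows))
}
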