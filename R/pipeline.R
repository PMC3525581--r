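#' Pipeline parameter bundle
#'
#' Collects the tunable parameters of the end-to-end analysis with their
#' defaults. All randomness downstream flows from `seed`, split
#' deterministically per stage.
#'
#' @param sdes_threshold inclusive SDES cut-off for a dimorphic call.
#' @param n_perm GSEA permutations per gene set.
#' @param min_set_size minimum effective gene-set size.
#' @param weight GSEA score-weighting exponent.
#' @param cor_method profile-correlation method, "spearman" or "pearson".
#' @param signed_scores sign the log10(1/p) scores by response direction.
#' @param min_network_genes minimum detected genes for a network node.
#' @param top_k treated genes looked up in the control ranking.
#' @param seed master integer seed.
#' @return a named list of parameters.
#' @export
pipeline_config <- function(sdes_threshold = 0.5, n_perm = 10000L,
                            min_set_size = 5L, weight = 1,
                            cor_method = c("spearman", "pearson"),
                            signed_scores = TRUE, min_network_genes = 5L,
                            top_k = 10L, seed = 1L) {
  list(sdes_threshold = sdes_threshold, n_perm = as.integer(n_perm),
       min_set_size = as.integer(min_set_size), weight = weight,
       cor_method = match.arg(cor_method), signed_scores = signed_scores,
       min_network_genes = as.integer(min_network_genes),
       top_k = as.integer(top_k), seed = as.integer(seed))
}

.stage_seed <- function(seed, offset) (seed %% 1000000L) * 1000L + offset

#' Run the full sex-dimorphism analysis pipeline
#'
#' Orchestrates: complete-gene filtering, per-condition signed-significance
#' scoring with Z-normalisation, per-time-point SDES tables and dimorphic
#' calls, temporal overlap, condition-profile clustering with
#' correlation-strength curves, control-baseline dimorphism ranking,
#' treated-vs-control rank-position lookup, GSEA on the SDES-ranked treated
#' lists and on the control p-value rankings, and the annotated pathway
#' cross-talk network per time point. All stage outputs are written to
#' `out_dir` as plain text (TSV, Newick, GraphML) with stage parameters in
#' header comments, plus a YAML manifest with parameters and output
#' checksums; a rerun with identical inputs is bit-identical.
#'
#' When the dataset contains no treated samples, the treated stages (SDES,
#' clustering, treated GSEA) are skipped and the control ranking and its
#' GSEA are still produced.
#'
#' @param dataset an [expression_dataset()].
#' @param gene_sets named list of gene sets (see [parse_gmt()]).
#' @param links optional pathway link table for the network stage.
#' @param categories optional data frame (pathway_id, category).
#' @param out_dir output directory.
#' @param config a [pipeline_config()] list.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(dataset, gene_sets, links = NULL,
                         categories = NULL, out_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  results <- list(config = config)
  hdr <- function(stage_name, ...) {
    c(stage = stage_name, seed = as.character(config$seed), ...)
  }

  ds <- stage("filter", filter_complete_genes(dataset))
  results$dataset <- ds
  write_expression_tsv(ds, file.path(out_dir, "expression_filtered.tsv"))
  write_sample_sheet(ds, file.path(out_dir, "samples.tsv"))

  has_treated <- any(ds$samples$group == "treated")
  times <- sort(unique(ds$samples$time_h))

  if (has_treated) {
    cs <- stage("preprocess", condition_scores(ds, signed = config$signed_scores))
    results$condition_scores <- cs
    write_tsv_commented(
      data.frame(gene = rownames(cs$scores), cs$scores, check.names = FALSE),
      file.path(out_dir, "condition_scores.tsv"),
      hdr("preprocess", signed = as.character(config$signed_scores)))
    write_tsv_commented(cs$significance,
                        file.path(out_dir, "gene_significance.tsv"),
                        hdr("preprocess"))

    results$sdes <- list(); results$dimorphic <- list()
    for (t in times) {
      st <- stage("sdes", sdes_table(cs, t, threshold = config$sdes_threshold))
      results$sdes[[as.character(t)]] <- st
      results$dimorphic[[as.character(t)]] <-
        classify_dimorphic(st, config$sdes_threshold)
      write_tsv_commented(
        st, file.path(out_dir, sprintf("sdes_%gh.tsv", t)),
        hdr("sdes", threshold = as.character(config$sdes_threshold)))
    }
    ov <- stage("sdes", temporal_overlap(
      lapply(results$dimorphic, `[[`, "genes")))
    results$temporal_overlap <- ov
    write_tsv_commented(ov, file.path(out_dir, "temporal_overlap.tsv"),
                        hdr("sdes"))

    results$dendrograms <- list()
    for (t in times) {
      cols <- cs$conditions$condition[cs$conditions$time_h == t]
      d <- stage("clustering",
                 profile_distance(cs$scores[, cols, drop = FALSE],
                                  method = config$cor_method))
      hc <- stage("clustering", average_linkage_dendrogram(d))
      results$dendrograms[[as.character(t)]] <- hc
      write_dendrogram_newick(hc, file.path(out_dir,
                                            sprintf("dendrogram_%gh.nwk", t)))
    }
    strength <- stage("clustering",
                      correlation_strength(cs, method = config$cor_method))
    results$correlation_strength <- strength
    write_tsv_commented(strength,
                        file.path(out_dir, "correlation_strength.tsv"),
                        hdr("clustering", method = config$cor_method))
  }

  # control-baseline ranking per time point + rank-position comparison
  has_controls <- sum(ds$samples$group == "control") > 0
  if (has_controls) {
    results$control_ranking <- list(); results$rank_positions <- list()
    for (t in times) {
      cr <- stage("control_ranking", control_dimorphism_ranking(ds, t))
      results$control_ranking[[as.character(t)]] <- cr
      write_tsv_commented(cr,
                          file.path(out_dir, sprintf("control_ranking_%gh.tsv", t)),
                          hdr("control_ranking"))
      if (has_treated) {
        st <- results$sdes[[as.character(t)]]
        top <- utils::head(st$gene, config$top_k)
        results$rank_positions[[as.character(t)]] <-
          rank_positions_in_reference(top, cr$gene)
      }
    }
    if (has_treated) {
      rp <- do.call(rbind, lapply(names(results$rank_positions), function(tk) {
        x <- results$rank_positions[[tk]]
        data.frame(time_h = as.numeric(tk),
                   positions = paste(x$positions, collapse = ","),
                   median_relative_rank = x$median_relative_rank)
      }))
      write_tsv_commented(rp, file.path(out_dir, "rank_positions.tsv"),
                          hdr("rank_positions",
                              top_k = as.character(config$top_k)))
    }
  }

  # GSEA: treated SDES rankings and control p-value rankings
  results$gsea_treated <- list(); results$gsea_control <- list()
  for (i in seq_along(times)) {
    t <- times[i]
    if (has_treated) {
      st <- results$sdes[[as.character(t)]]
      rl <- ranked_gene_list(stats::setNames(st$sdes, st$gene))
      gt <- stage("gsea", run_gsea(
        rl, gene_sets, min_set_size = config$min_set_size,
        n_perm = config$n_perm, weight = config$weight,
        seed = .stage_seed(config$seed, 100L + i)))
      results$gsea_treated[[as.character(t)]] <- gt
      write_tsv_commented(gt, file.path(out_dir, sprintf("gsea_treated_%gh.tsv", t)),
                          hdr("gsea", ranking = "sdes",
                              n_perm = as.character(config$n_perm),
                              min_set_size = as.character(config$min_set_size),
                              weight = as.character(config$weight)))
    }
    if (has_controls) {
      cr <- results$control_ranking[[as.character(t)]]
      rl <- ranked_gene_list(stats::setNames(log10(1 / cr$p), cr$gene))
      gc <- stage("gsea", run_gsea(
        rl, gene_sets, min_set_size = config$min_set_size,
        n_perm = config$n_perm, weight = config$weight,
        seed = .stage_seed(config$seed, 200L + i)))
      results$gsea_control[[as.character(t)]] <- gc
      write_tsv_commented(gc, file.path(out_dir, sprintf("gsea_control_%gh.tsv", t)),
                          hdr("gsea", ranking = "control_p",
                              n_perm = as.character(config$n_perm),
                              min_set_size = as.character(config$min_set_size),
                              weight = as.character(config$weight)))
    }
  }

  # pathway cross-talk network per time point (treated GSEA annotations)
  if (!is.null(links) && has_treated) {
    genes_present <- rownames(ds$values)
    detected <- lapply(gene_sets, function(m) intersect(m, genes_present))
    results$networks <- list()
    for (t in times) {
      gt <- results$gsea_treated[[as.character(t)]]
      net <- stage("network", build_network(links, detected,
                                            min_genes = config$min_network_genes))
      scored <- intersect(igraph::V(net)$name, gt$set_id)
      net <- igraph::induced_subgraph(net, scored)
      net <- stage("network", annotate_nodes(net, gt, categories))
      results$networks[[as.character(t)]] <- net
      write_pathway_network(
        net, file.path(out_dir, sprintf("network_%gh.graphml", t)),
        file.path(out_dir, sprintf("network_edges_%gh.tsv", t)))
    }
  }

  manifest <- list(
    parameters = config[setdiff(names(config), "seed")],
    seed = config$seed,
    n_genes = nrow(ds$values),
    n_samples = ncol(ds$values),
    outputs = as.list(tools::md5sum(
      sort(list.files(out_dir, full.names = TRUE,
                      pattern = "\\.(tsv|nwk|graphml)$")))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}
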