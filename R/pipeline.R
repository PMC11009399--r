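## End-to-end orchestration: filtering -> segmentation -> neutral-model
## fits (overall and stratified) -> sharing network and permutation tests
## -> enrichment statistics. Stage interfaces are files so any stage can be
## re-run from real upstream tool outputs instead of the simulator.

#' Pipeline configuration
#'
#' Collects every stage threshold with the study defaults, plus seeds and
#' stage toggles. Thresholds: presence coverage 0.70, deduplication
#' identity/coverage 0.95/0.95, segments 1000 bp at 0.80 identity,
#' clustering 0.80 identity at 0.90 mutual coverage, selection quantile
#' 95%, enrichment gene ratio 0.1.
#'
#' @param min_cov presence coverage threshold.
#' @param dedup_id,dedup_cov deduplication thresholds.
#' @param seg_min_len,seg_min_id segment detection thresholds.
#' @param clust_id,clust_cov segment clustering thresholds.
#' @param depth_frac depth-cutoff fraction.
#' @param selection_pct selection quantile percentage.
#' @param selection_rule `"quantile"` or `"ci"`.
#' @param n_perm permutations for the network null (desk-scale default
#'   1000; the study design uses 10,000).
#' @param fdr_edges,fdr_segments,fdr_groups FDR thresholds.
#' @param gene_ratio,enrich_q enrichment filters.
#' @param engine segment search engine.
#' @param seed master seed.
#' @param stages character vector of stages to run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_cov = 0.70, dedup_id = 0.95,
                            dedup_cov = 0.95, seg_min_len = 1000,
                            seg_min_id = 0.80, clust_id = 0.80,
                            clust_cov = 0.90, depth_frac = 0.01,
                            selection_pct = 95,
                            selection_rule = "quantile", n_perm = 1000,
                            fdr_edges = 0.05, fdr_segments = 0.05,
                            fdr_groups = 0.05, gene_ratio = 0.1,
                            enrich_q = 0.01, engine = "seed", seed = 1,
                            stages = c("filter", "segment", "ncm",
                                       "network", "enrich")) {
  .assert(min_cov >= 0 && min_cov <= 1, "min_cov must be in [0, 1]")
  .assert(dedup_id >= 0 && dedup_id <= 1 && dedup_cov >= 0 && dedup_cov <= 1,
          "dedup thresholds must be fractions")
  .assert(seg_min_len >= 1 && seg_min_id > 0 && seg_min_id <= 1,
          "invalid segment thresholds")
  .assert(selection_pct > 0 && selection_pct < 100,
          "selection_pct must be a percentage in (0, 100)")
  .assert(n_perm >= 1, "need at least one permutation")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated or loaded dataset
#'
#' Executes the enabled stages in order on the components of a
#' [simulate_dataset()] result (or an equivalently shaped list loaded from
#' files), writing every intermediate table under `outdir` and returning a
#' run report with per-stage entity counts.
#'
#' @param data list with `sequences`, `plasmids`, `annotations`, `abund`,
#'   `metadata`, `taxa` (as produced by [simulate_dataset()]).
#' @param config a [pipeline_config()].
#' @param outdir output directory for stage files (created if needed);
#'   `NULL` keeps everything in memory.
#' @return list of class `run_report`: stage outputs plus `counts`, the
#'   non-increasing chain of entity counts across filters.
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir = NULL) {
  .assert(inherits(config, "pipeline_config"), "need a pipeline_config")
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(outdir)) {
      if (is.matrix(x)) write_matrix_tsv(x, file.path(outdir, name))
      else write_tsv0(x, file.path(outdir, name))
    }
  }
  report <- list(config = config,
                 counts = c(plasmids_input = ncol(data$abund$counts)))
  on <- function(stage) stage %in% config$stages

  ## --- filtering ---------------------------------------------------------
  presence <- call_presence(data$abund, min_cov = config$min_cov)
  if (on("filter")) {
    dc <- apply_depth_cutoff(data$abund, presence, frac = config$depth_frac)
    presence <- dc$presence
    report$depth_cutoff <- dc$cutoff
    report$counts["plasmids_after_depth"] <-
      sum(colSums(presence) > 0)
    rich <- richness_ratio(presence, data$taxa, data$metadata)
    report$richness <- rich
    emit(rich$per_sample, "richness.tsv")
    report$length_trough <- tryCatch(
      length_trough(data$plasmids$length), error = function(e) NA_real_)
  }
  report$presence <- presence
  emit(presence * 1L, "presence.tsv")

  ## --- segmentation ------------------------------------------------------
  if (on("segment")) {
    hits <- find_shared_segments(data$sequences,
                                 min_len = config$seg_min_len,
                                 min_id = config$seg_min_id,
                                 engine = config$engine,
                                 presence = presence)
    clusters <- cluster_segments(hits, data$sequences,
                                 min_id = config$clust_id,
                                 mutual_cov = config$clust_cov)
    seg_inc <- segment_incidence(clusters, presence)
    report$hits <- hits
    report$clusters <- clusters
    report$segment_incidence <- seg_inc
    report$counts["segment_clusters"] <- ncol(seg_inc)
    emit(as.data.frame(hits), "segment_hits.tsv")
    emit(clusters$members, "segment_members.tsv")
    emit(seg_inc * 1L, "segment_incidence.tsv")
  }

  ## --- neutral model -----------------------------------------------------
  if (on("ncm")) {
    stats <- occurrence_stats(data$abund, presence)
    fit <- fit_ncm(stats)
    selected <- select_deviant(fit, pct = config$selection_pct,
                               rule = config$selection_rule)
    report$ncm <- fit
    report$ncm_selected <- selected
    strata <- stratified_ncm(data$abund, presence, data$metadata,
                             data$annotations, d = fit$d)
    report$ncm_strata <- strata
    tb <- fit$table
    tb$selected <- tb$entity_id %in% selected
    emit(tb, "ncm_fit.tsv")
    if (!is.null(outdir)) {
      jsonlite::write_json(
        list(Nm = fit$Nm, d = fit$d, R2 = fit$R2,
             n_samples = fit$n_samples),
        file.path(outdir, "ncm_summary.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  ## --- network -----------------------------------------------------------
  if (on("network") && !is.null(report$segment_incidence) &&
      ncol(report$segment_incidence) > 0) {
    net <- build_sharing_network(report$segment_incidence, data$metadata)
    ens <- null_ensemble(report$segment_incidence, data$metadata,
                         n_perm = config$n_perm, seed = config$seed)
    report$network <- net
    report$group_tests <- group_connectivity_test(net, ens)
    report$edge_tests <- edge_significance(net, ens,
                                           alpha = config$fdr_edges)
    report$segment_tests <- segment_significance(
      report$segment_incidence, ens, data$metadata,
      alpha = config$fdr_segments)
    if (length(unique(data$metadata$disease)) >= 2) {
      report$strength <- strength_ratio(net)
    }
    report$cross_continental <- cross_continental_summary(
      net, report$edge_tests)
    emit(net$edges, "network_edges.tsv")
    emit(report$group_tests, "group_tests.tsv")
    emit(report$edge_tests, "edge_significance.tsv")
    emit(report$segment_tests, "segment_significance.tsv")
    if (!is.null(outdir)) {
      igraph::write_graph(net$graph,
                          file.path(outdir, "network.graphml"),
                          format = "graphml")
    }
  }

  ## --- enrichment / lifestyle statistics ---------------------------------
  if (on("enrich")) {
    ann <- data$annotations
    ann$entity_id <- ann$plasmid_id
    life <- lifestyle_proportion_tests(presence, ann, data$metadata)
    report$lifestyle <- life
    report$adjusted_length <- adjusted_length_compare(ann)
    mob <- ann$amr_count[ann$lifestyle == "mobilizable"]
    non <- ann$amr_count[ann$lifestyle == "non_mobilizable"]
    if (length(mob) && length(non)) {
      report$amr_ks <- ks_compare(mob, non)
      report$amr_or <- odds_ratio_2x2(sum(mob > 0), sum(mob == 0),
                                      sum(non > 0), sum(non == 0))
    }
    if (!is.null(report$ncm_selected) && length(report$ncm_selected) > 0 &&
        all(report$ncm_selected %in% ann$entity_id)) {
      report$enrichment <- hypergeom_enrich(
        report$ncm_selected, ann$entity_id, ann,
        min_gene_ratio = config$gene_ratio, q_max = config$enrich_q)
      emit(report$enrichment, "enrichment.tsv")
    }
    emit(life$fractions, "lifestyle_stats.tsv")
    emit(report$adjusted_length$per_plasmid, "length_stats.tsv")
  }

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  }
  if (!is.null(x$ncm)) {
    cat(sprintf("  NCM: Nm = %.3g, R^2 = %.3f\n", x$ncm$Nm, x$ncm$R2))
  }
  invisible(x)
}

#' Stratified neutral-model fits
#'
#' Fits the neutral model per disease state (sample strata), per lifestyle
#' (entity strata) and per disease x lifestyle, and reports the ratio of
#' each stratum's goodness of fit to the healthy stratum's.
#'
#' @param abund a [abundance_matrix()].
#' @param presence logical samples x entities matrix.
#' @param metadata data.frame with `sample_id`, `disease`.
#' @param annotations optional data.frame with `plasmid_id` and
#'   `lifestyle` enabling lifestyle strata.
#' @param d shared detection limit (default: derived from the full data).
#' @param min_entities strata with fewer informative entities are skipped.
#' @param reference disease label used as the denominator of R^2 ratios.
#' @return data.frame: stratum, disease, lifestyle, n_entities, Nm, R2,
#'   R2_ratio (versus the reference disease within the same lifestyle
#'   stratum).
#' @export
stratified_ncm <- function(abund, presence, metadata, annotations = NULL,
                           d = NULL, min_entities = 10,
                           reference = "healthy") {
  meta <- metadata[match(rownames(presence), metadata$sample_id), ]
  if (is.null(d)) {
    rel <- relative_abundance(abund)
    d <- min(rel[rel > 0])
  }
  lifestyles <- "all"
  if (!is.null(annotations)) {
    lifestyles <- c("all", sort(unique(annotations$lifestyle)))
  }
  diseases <- c("all", sort(unique(meta$disease)))
  out <- list()
  for (lf in lifestyles) {
    ents <- colnames(presence)
    if (lf != "all") {
      ents <- annotations$plasmid_id[annotations$lifestyle == lf]
      ents <- intersect(ents, colnames(presence))
    }
    for (dz in diseases) {
      rows <- if (dz == "all") rep(TRUE, nrow(presence)) else
        meta$disease == dz
      if (sum(rows) < 2 || length(ents) < min_entities) next
      sub_ab <- abund$counts[rows, ents, drop = FALSE]
      sub_pr <- presence[rows, ents, drop = FALSE]
      st <- tryCatch(
        suppressWarnings(occurrence_stats(sub_ab, sub_pr)),
        error = function(e) NULL)
      if (is.null(st) || length(st$entity_ids) < min_entities) {
        message("stratum ", lf, "/", dz, " skipped (too few entities)")
        next
      }
      fit <- suppressWarnings(fit_ncm(st, d = d))
      out[[length(out) + 1L]] <- data.frame(
        lifestyle = lf, disease = dz, n_entities = length(st$entity_ids),
        n_samples = sum(rows), Nm = fit$Nm, R2 = fit$R2)
    }
  }
  out <- do.call(rbind, out)
  out$R2_ratio <- NA_real_
  for (lf in unique(out$lifestyle)) {
    ref <- out$R2[out$lifestyle == lf & out$disease == reference]
    if (length(ref) == 1 && is.finite(ref) && ref != 0) {
      idx <- out$lifestyle == lf
      out$R2_ratio[idx] <- out$R2[idx] / ref
    }
  }
  out
}
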