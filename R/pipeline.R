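#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow with the canonical
#' defaults: unamplified above CT 50, detection in at least 30 samples,
#' 10 kb cluster chaining, and the three named regions of interest.
#'
#' @param ct_path CT matrix file (CSV/TSV).
#' @param annotations_path miRBase-style GFF3.
#' @param metadata_path sample metadata CSV.
#' @param family_path optional two-column family TSV.
#' @param locus_labels optional data.frame (chromosome, start, end, name)
#'   renaming genomic clusters by cytoband span; `locus_labels_path`
#'   reads the same table from a TSV.
#' @param out_dir output directory.
#' @param unamplified_ct,min_detected,max_gap_bp,regions,min_pairs
#'   stage parameters (see the stage functions).
#' @param renormalize_after_filter recompute the global mean over the
#'   retained miRNAs after the detection filter (default FALSE: the
#'   global mean is taken over all amplified miRNAs, then low-detection
#'   miRNAs are dropped).
#' @param anova_transform passed to [compare_coefficient_sets()].
#' @param efa_n_sim,efa_quantile,efa_seed parallel-analysis settings.
#' @param outcomes outcome columns for the mixed models.
#' @param hemolysis list(red_cell, reference, cutoff) or `NULL` to skip
#'   QC (markers absent from panel).
#' @param seed master seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ct_path, annotations_path, metadata_path,
                            family_path = NULL, locus_labels = NULL,
                            locus_labels_path = NULL,
                            out_dir = ".",
                            unamplified_ct = 50, min_detected = 30,
                            max_gap_bp = 10000,
                            regions = c("c14mc", "c19mc", "miR-17/92"),
                            min_pairs = 10,
                            renormalize_after_filter = FALSE,
                            anova_transform = "none",
                            efa_n_sim = 200, efa_quantile = NULL,
                            efa_seed = 17,
                            outcomes = c("gestational_age_birth",
                                         "birth_weight",
                                         "head_circumference"),
                            hemolysis = list(
                              red_cell = "hsa-miR-451a",
                              reference = "hsa-miR-23a-3p", cutoff = 7),
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full cluster-level analysis pipeline
#'
#' preprocess (QC, normalisation, detection filter) -> cluster assignment
#' -> correlation-structure comparison -> factor analysis and cluster
#' scores -> outcome models, writing every table to `out_dir` and a JSON
#' manifest listing the artifacts with the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with every intermediate object and
#'   `manifest` (the manifest content).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  emit <- function(name) {
    path <- file.path(cfg$out_dir, name)
    art[[length(art) + 1L]] <<- path
    path
  }

  log_stage <- function(...) message("[mircluster] ", sprintf(...))

  log_stage("reading inputs")
  ct <- read_ct_matrix(cfg$ct_path, unamplified_ct = cfg$unamplified_ct)
  ann <- read_annotations(cfg$annotations_path,
                          family_table = cfg$family_path)
  md <- read_metadata(cfg$metadata_path)

  qc <- NULL
  if (!is.null(cfg$hemolysis) &&
      all(c(cfg$hemolysis$red_cell, cfg$hemolysis$reference) %in%
            ct$mirna_ids)) {
    log_stage("hemolysis QC")
    qc <- hemolysis_qc(ct, cfg$hemolysis$red_cell,
                       cfg$hemolysis$reference, cfg$hemolysis$cutoff)
    utils::write.table(qc, emit("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else log_stage("hemolysis QC skipped (markers not on panel)")

  log_stage("global-mean normalisation and detection filter (>= %d samples)",
            cfg$min_detected)
  expr <- normalize_global_mean(ct)
  expr <- detection_filter(expr, min_samples = cfg$min_detected)
  if (cfg$renormalize_after_filter) {
    kept <- expr$mirna_ids
    expr <- normalize_global_mean(
      ct_matrix(ct$ct[, kept, drop = FALSE],
                unamplified_ct = cfg$unamplified_ct))
  }
  write_expression_matrix(expr, emit("expression.csv"))

  log_stage("cluster assignment (max gap %d bp)", cfg$max_gap_bp)
  cmap <- assign_clusters(ann, max_gap = cfg$max_gap_bp)
  labels <- cfg$locus_labels
  if (is.null(labels) && !is.null(cfg$locus_labels_path))
    labels <- utils::read.delim(cfg$locus_labels_path,
                                stringsAsFactors = FALSE)
  cmap <- name_clusters(cmap, labels)
  write_cluster_map(cmap, emit("clusters.tsv"),
                    json_path = emit("clusters.json"))

  regions <- intersect(cfg$regions, names(cmap$clusters))
  if (!length(regions)) regions <- NULL
  log_stage("correlation-structure comparison")
  cmp <- compare_groups(expr, cmap, md, regions = regions,
                        transform = cfg$anova_transform,
                        min_pairs = cfg$min_pairs)
  write_comparison(cmp, json_path = emit("comparison.json"),
                   tsv_path = emit("comparison_anova.tsv"))

  log_stage("factor analysis (parallel analysis, n_sim = %d, seed = %d)",
            cfg$efa_n_sim, cfg$efa_seed)
  choice <- choose_n_factors(expr, n_sim = cfg$efa_n_sim,
                             quantile = cfg$efa_quantile,
                             seed = cfg$efa_seed)
  log_stage("retaining %d factor(s)", choice$n_factors)
  efa <- fit_efa(expr, choice$n_factors)
  write_loadings(efa, emit("loadings.tsv"), cluster_map = cmap)
  scores <- cluster_scores(expr, cmap,
                           clusters = if (is.null(regions))
                             names(cmap$clusters) else regions)
  write_scores(scores, emit("cluster_scores.csv"))

  log_stage("per-miRNA tests and outcome correlations")
  tt <- per_mirna_ttest(expr, md, ct = ct)
  utils::write.table(tt$table, emit("per_mirna_ttest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  oc <- outcome_correlations(expr, md, cluster_map = cmap)
  utils::write.table(oc, emit("outcome_correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("matched-pair mixed models")
  models <- do.call(rbind, lapply(cfg$outcomes, function(oname)
    fit_mixed_outcome(scores, md, oname)))
  logistic <- fit_mixed_outcome(scores, md, "group", family = "logistic")
  model_tab <- rbind(models, logistic)
  utils::write.table(model_tab, emit("outcome_models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(model_tab, emit("outcome_models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")

  manifest <- list(
    package = "mircluster",
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("locus_labels"))],
    n_samples = nrow(expr$dct), n_mirnas = ncol(expr$dct),
    clusters = lapply(cmap$clusters, length),
    artifacts = unlist(art))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(list(ct = ct, qc = qc, expr = expr, cluster_map = cmap,
                 comparison = cmp, factor_choice = choice, efa = efa,
                 scores = scores, ttest = tt, outcome_corr = oc,
                 models = model_tab, manifest = manifest))
}
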