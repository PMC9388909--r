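#' Default end-to-end run configuration
#'
#' Thresholds follow the analysis constants: CPM filter at 1, CV filter at
#' 0.75 with mean CPM > 4, differential calls at adjusted p <= 0.05 and
#' |logFC| > 0.5, TE groups at +0.5 / -0.25 / +/-0.01, top-200 ranking, GMM
#' grid K = 2..9 over the six covariance families.
#'
#' @return named list of configuration values.
#' @export
default_run_config <- function() {
  list(min_cpm = 1, cv_filter = TRUE, cv_max = 0.75, min_mean_cpm = 4,
       require_mean = TRUE, alpha = 0.05, lfc = 0.5, pool_variance = FALSE,
       trend = TRUE, adjust = "BH", te_up = 0.5, te_down = -0.25, te_control = 0.01,
       top_n = 200, K_range = 2:9, families = GMM_FAMILIES, n_init = 10,
       engine = "nussinov", fold = TRUE, top_k = 5, uorf_min_codons = 3,
       seed = 1L)
}

#' Run the full translatome analysis pipeline
#'
#' Stages: normalisation and filtering, per-fraction differential analysis
#' (total RNA plus the three polysome pools), translation ratio/efficiency
#' and top-ranked lists, clustering of the DTG log-ratio matrix with
#' model selection, per-transcript sequence features with grouped
#' statistics, and optional gene-set over-representation. With an
#' \code{out_dir}, every stage writes its TSV plus a deterministic JSON
#' manifest, so reruns with the same configuration and seed are
#' bit-identical.
#'
#' @param cohort a \code{ptrans_cohort}, or any list with \code{counts},
#'   \code{tpm}, \code{sample_sheet} (and optionally \code{transcripts},
#'   \code{lengths}, \code{truth}).
#' @param out_dir optional output directory.
#' @param gmt optional gene-set collection (named list or path to a GMT
#'   file) for the enrichment stage.
#' @param ires_genes optional gene list for the IRES flag.
#' @param config overrides for \code{\link{default_run_config}}.
#' @return result bundle (list) with the per-stage objects.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, gmt = NULL,
                         ires_genes = character(), config = list()) {
  cfg <- modifyList(default_run_config(), config)
  counts <- cohort$counts
  sheet <- validate_sample_sheet(cohort$sample_sheet)
  stages <- list()

  ## --- preprocess ---------------------------------------------------------
  cpm_mat <- cpm(counts)
  keep <- filter_low_expression(cpm_mat, min_cpm = cfg$min_cpm)
  if (!any(keep)) stopf("no genes survive the low-expression (CPM) filter")
  if (isTRUE(cfg$cv_filter)) {
    keep_cv <- filter_by_cv(cpm_mat, sheet, cv_max = cfg$cv_max,
                            min_mean = cfg$min_mean_cpm,
                            require_mean = cfg$require_mean)
    keep <- keep & keep_cv
    if (!any(keep)) stopf("no genes survive the CV/mean-expression filter")
  }
  genes <- rownames(counts)[keep]
  counts_f <- counts[genes, , drop = FALSE]
  tpm_f <- cohort$tpm[genes, , drop = FALSE]
  qc <- qc_sample_clustering(tpm_f)
  stages$preprocess <- list(n_genes_in = nrow(counts), n_genes_kept = length(genes))

  ## --- differential analysis ---------------------------------------------
  diff <- run_diffexpr(counts_f, sheet, alpha = cfg$alpha, lfc = cfg$lfc,
                       pool_variance = cfg$pool_variance, trend = cfg$trend,
                       adjust = cfg$adjust)
  stages$diffexpr <- list(n_dtg = length(diff$dtg), n_deg = length(diff$deg))

  ## --- translation metrics ------------------------------------------------
  tt <- translation_ratio(tpm_f, sheet)
  tt <- translation_efficiency(tt)
  tt$group <- classify_translation_groups(tt$TE, up = cfg$te_up,
                                          down = cfg$te_down,
                                          control = cfg$te_control)
  top <- rank_top_translated(tt, n = min(cfg$top_n, nrow(tt)))
  lrm <- build_log_ratio_matrix(tpm_f, sheet)
  stages$translation <- list(n_up = sum(tt$group == "UP"),
                             n_down = sum(tt$group == "DOWN"),
                             n_control = sum(tt$group == "CONTROL"))

  ## --- clustering of DTGs -------------------------------------------------
  clustering <- NULL
  cluster_summary <- NULL
  dtg_in_lrm <- intersect(diff$dtg, rownames(lrm))
  if (length(dtg_in_lrm) >= 12) {
    M <- lrm[dtg_in_lrm, , drop = FALSE]
    K_range <- cfg$K_range[cfg$K_range < nrow(M)]
    clustering <- compare_clusterings(M, K_range = K_range,
                                      families = cfg$families,
                                      n_init = cfg$n_init, seed = cfg$seed)
    cluster_summary <- summarize_clusters(clustering$best, M)
    stages$clustering <- list(K = clustering$K,
                              best_method = clustering$best$method,
                              silhouette = clustering$best$silhouette)
  }

  ## --- sequence features --------------------------------------------------
  features <- NULL
  feature_stats <- NULL
  if (!is.null(cohort$transcripts)) {
    grp_genes <- tt$gene_id[tt$group %in% c("UP", "DOWN", "CONTROL")]
    feat_genes <- unique(c(diff$dtg, grp_genes))
    tr <- cohort$transcripts
    tr <- tr[tr$gene_id %in% feat_genes, , drop = FALSE]
    if (nrow(tr)) {
      poly_cols <- sheet$sample_id[sheet$fraction %in% POLYSOME_FRACTIONS]
      poly_means <- rowMeans(cohort$tpm[, poly_cols, drop = FALSE])
      abund <- setNames(poly_means[match(tr$gene_id, names(poly_means))],
                        tr$transcript_id)
      rep_tr <- select_representative_transcript(tr, abundance = abund)
      features <- transcript_features(rep_tr, engine = cfg$engine,
                                      fold = cfg$fold,
                                      ires_genes = ires_genes,
                                      top_k = cfg$top_k,
                                      uorf_min_codons = cfg$uorf_min_codons)
      if (!is.null(cluster_summary)) {
        grp <- cluster_summary$assignment
        ok <- tryCatch(feature_group_stats(features, grp), error = function(e) NULL)
        feature_stats <- ok
      }
      stages$features <- list(n_transcripts = nrow(features))
    }
  }

  ## --- enrichment ---------------------------------------------------------
  enrichment <- NULL
  if (!is.null(gmt)) {
    collection <- if (is.character(gmt) && length(gmt) == 1) read_gmt(gmt) else gmt
    if (length(diff$dtg))
      enrichment <- ora_hypergeometric(intersect(diff$dtg, genes),
                                       collection, universe = genes)
    stages$enrichment <- list(n_sets = length(collection),
                              n_significant = if (is.null(enrichment)) 0L
                                              else sum(enrichment$p_adj <= 0.05))
  }

  bundle <- list(genes = genes, qc = qc, diff = diff, translation = tt,
                 top_ranked = top, log_ratio = lrm, clustering = clustering,
                 cluster_summary = cluster_summary, features = features,
                 feature_stats = feature_stats, enrichment = enrichment,
                 config = cfg, stages = stages)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_outputs(bundle, out_dir)
  }
  invisible(bundle)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  wt <- function(df, name) write.table(df, file.path(out_dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  for (f in names(bundle$diff$results)) {
    res <- bundle$diff$results[[f]]
    res <- data.frame(gene = res$gene_id, fraction = f,
                      logFC = res$logFC, AveExpr = res$AveExpr, t = res$t,
                      P.Value = res$P.Value, adj.P.Val = res$adj.P.Val)
    wt(res, sprintf("diff_%s.tsv", f))
  }
  wt(data.frame(gene_id = bundle$diff$dtg), "dtg.tsv")
  wt(bundle$translation, "translation_table.tsv")
  if (!is.null(bundle$cluster_summary)) {
    wt(bundle$cluster_summary$summary, "cluster_summary.tsv")
    wt(data.frame(gene_id = names(bundle$cluster_summary$assignment),
                  cluster = unname(bundle$cluster_summary$assignment),
                  method = bundle$clustering$best$method,
                  K = bundle$clustering$best$K), "cluster_assignments.tsv")
  }
  if (!is.null(bundle$features)) wt(bundle$features, "features.tsv")
  if (!is.null(bundle$feature_stats)) {
    wt(bundle$feature_stats$tests, "feature_tests.tsv")
    wt(bundle$feature_stats$pairwise, "feature_pairwise.tsv")
  }
  if (!is.null(bundle$enrichment)) wt(bundle$enrichment, "enrichment.tsv")
  write_dendrogram_newick(bundle$qc$hclust, file.path(out_dir, "qc_dendrogram.nwk"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = bundle$config, seed = bundle$config$seed,
                 stages = bundle$stages)
  invisible(out_dir)
}
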