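#' Counts per million
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param log if TRUE return \code{log2(CPM + 0.5)}; the 0.5 prior avoids
#'   log of zero.
#' @return matrix of CPM (or log2 CPM) values with a \code{"unit"} attribute.
#' @export
cpm <- function(counts, log = FALSE) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize <= 0))
    stopf("zero library size for sample(s): %s",
          paste(colnames(counts)[libsize <= 0], collapse = ", "))
  out <- sweep(counts, 2, libsize, "/") * 1e6
  if (log) {
    out <- log2(out + 0.5)
    attr(out, "unit") <- "log2CPM"
  } else attr(out, "unit") <- "CPM"
  out
}

#' Transcripts per million from gene counts
#'
#' Length-normalised abundance: per sample, \code{rate = count/length} and
#' \code{TPM = rate / sum(rate) * 1e6}. The effective length is the annotated
#' transcript length (no fragment-length correction).
#'
#' @param counts gene x sample count matrix.
#' @param lengths per-gene effective length in nt, named by gene or in row
#'   order.
#' @return TPM matrix (columns sum to 1e6).
#' @export
tpm_from_counts <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss))
      stopf("missing lengths for gene(s): %s",
            paste(head(miss, 5), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) stopf("lengths do not match gene rows")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stopf("all effective lengths must be positive")
  rate <- counts / lengths
  out <- sweep(rate, 2, colSums(rate), "/") * 1e6
  attr(out, "unit") <- "TPM"
  out
}

#' Remove lowly expressed genes
#'
#' A gene is kept only if its CPM is at least \code{min_cpm} in every sample
#' (genes with CPM below the threshold in even one sample are discarded; a
#' gene exactly at the threshold everywhere is kept).
#'
#' @param expr CPM matrix.
#' @param min_cpm expression threshold (default 1).
#' @return named logical mask over genes with a \code{details} attribute
#'   giving, per gene, the number of samples below threshold.
#' @export
filter_low_expression <- function(expr, min_cpm = 1) {
  expr <- as.matrix(expr)
  n_below <- rowSums(expr < min_cpm)
  keep <- n_below == 0
  names(keep) <- rownames(expr)
  attr(keep, "details") <- data.frame(
    gene_id = rownames(expr), n_samples_below = n_below,
    reason = ifelse(keep, "", sprintf("CPM < %g in %d sample(s)", min_cpm, n_below)),
    row.names = NULL, stringsAsFactors = FALSE)
  keep
}

#' Filter genes by replicate variability
#'
#' Within each replicate group (condition x fraction) the coefficient of
#' variation CV = sd/mean is computed. The default retention rule keeps genes
#' whose maximum within-group CV is below \code{cv_max} and (optionally,
#' default on) whose overall mean CPM exceeds \code{min_mean}. The opposite
#' reading (remove matching genes) is available via \code{mode}.
#'
#' @param expr CPM matrix.
#' @param sample_sheet sample sheet covering the matrix columns.
#' @param cv_max CV threshold (default 0.75).
#' @param min_mean mean-CPM threshold (default 4).
#' @param require_mean apply the mean-CPM clause as a conjunct (default TRUE).
#' @param mode \code{"retain"} (default) keeps genes matching the rule;
#'   \code{"remove"} discards them.
#' @return named logical keep-mask with a \code{details} attribute (per-gene
#'   max CV and mean CPM).
#' @export
filter_by_cv <- function(expr, sample_sheet, cv_max = 0.75, min_mean = 4,
                         require_mean = TRUE, mode = c("retain", "remove")) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  sheet <- sheet_for(expr, sample_sheet)
  grp <- interaction(sheet$condition, sheet$fraction, drop = TRUE)
  sizes <- table(grp)
  if (any(sizes < 2))
    stopf("replicate group(s) of size 1 (CV undefined): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  cvs <- vapply(levels(grp), function(g) {
    sub <- expr[, grp == g, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    ifelse(m == 0, Inf, s / m)
  }, numeric(nrow(expr)))
  max_cv <- apply(cvs, 1, max)
  mean_cpm <- rowMeans(expr)
  match_rule <- max_cv < cv_max & (!require_mean | mean_cpm > min_mean)
  keep <- if (mode == "retain") match_rule else !match_rule
  names(keep) <- rownames(expr)
  attr(keep, "details") <- data.frame(gene_id = rownames(expr),
                                      max_cv = max_cv, mean_cpm = mean_cpm,
                                      row.names = NULL, stringsAsFactors = FALSE)
  keep
}

#' Sample-level QC clustering
#'
#' Hierarchical clustering of samples on the Euclidean distance matrix with
#' Ward's minimum-variance linkage (the \code{ward.D2} convention, i.e.
#' squared distances in the Lance-Williams update), plus the first two
#' principal components of the samples.
#'
#' @param expr expression matrix (typically TPM), genes x samples.
#' @param log_transform log2(x+1)-transform before clustering (default TRUE).
#' @return list with \code{hclust} (the tree), \code{pca} (sample
#'   coordinates, PC1/PC2), and \code{variance_explained}.
#' @export
qc_sample_clustering <- function(expr, log_transform = TRUE) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stopf("need at least 3 samples for QC clustering")
  x <- t(if (log_transform) log2(expr + 1) else expr)
  if (all(apply(x, 2, sd) == 0)) warnf("constant expression matrix; PCA is degenerate")
  hc <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  keep <- apply(x, 2, function(v) sd(v) > 0)
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(hclust = hc, pca = coords, variance_explained = ve)
}

#' Export a sample dendrogram in Newick format
#'
#' @param hc an \code{hclust} object (e.g. from \code{qc_sample_clustering}).
#' @param file output path.
#' @export
write_dendrogram_newick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}
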