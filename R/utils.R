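#' @keywords internal
"_PACKAGE"

#' @importFrom stats cutree dist hclust kmeans prcomp kruskal.test
#'   p.adjust phyper pt qnorm rchisq rlnorm rnbinom rpois runif sd var
#'   complete.cases setNames quantile median
#' @importFrom utils read.delim write.table head modifyList packageVersion
NULL

PYRIMIDINES <- c("C", "T")
FRACTIONS <- c("total", "mono", "light", "heavy")
POLYSOME_FRACTIONS <- c("mono", "light", "heavy")
CONDITIONS <- c("low", "high")

## FNV-1a 32-bit checksum of a character scalar, used to fingerprint run
## configurations in output manifests.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## xor into the low byte (h may exceed the bitwXor integer range)
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    ## 32-bit modular multiply by the FNV prime 16777619, split to keep
    ## every intermediate below 2^53
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_checksum <- function(cfg) {
  flat <- unlist(cfg, use.names = TRUE)
  fnv1a32(paste(names(flat), vapply(flat, format, character(1)), sep = "=",
                collapse = ";"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Validate a sample sheet
#'
#' A sample sheet maps each sequencing library to its experimental cell:
#' glucose condition (\code{low}/\code{high}), gradient fraction
#' (\code{total}, \code{mono}, \code{light}, \code{heavy}) and replicate
#' number.
#'
#' @param sample_sheet data.frame with columns \code{sample_id},
#'   \code{condition}, \code{fraction}, \code{replicate}.
#' @return The validated sample sheet (invisibly usable), with character
#'   columns normalised.
#' @export
validate_sample_sheet <- function(sample_sheet) {
  req <- c("sample_id", "condition", "fraction", "replicate")
  miss <- setdiff(req, names(sample_sheet))
  if (length(miss)) stopf("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  sample_sheet$sample_id <- as.character(sample_sheet$sample_id)
  sample_sheet$condition <- as.character(sample_sheet$condition)
  sample_sheet$fraction <- as.character(sample_sheet$fraction)
  if (anyDuplicated(sample_sheet$sample_id))
    stopf("duplicated sample IDs: %s",
          paste(unique(sample_sheet$sample_id[duplicated(sample_sheet$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(sample_sheet$condition), CONDITIONS)
  if (length(bad)) stopf("unknown condition level(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(sample_sheet$fraction), FRACTIONS)
  if (length(bad)) stopf("unknown fraction level(s): %s", paste(bad, collapse = ", "))
  sample_sheet
}

check_matrix_sheet <- function(x, sample_sheet) {
  if (is.null(colnames(x)) || is.null(rownames(x)))
    stopf("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stopf("duplicated gene IDs in matrix")
  missing <- setdiff(colnames(x), sample_sheet$sample_id)
  if (length(missing))
    stopf("samples absent from sample sheet: %s", paste(missing, collapse = ", "))
  invisible(TRUE)
}

## sample-sheet rows for the matrix columns, in column order
sheet_for <- function(x, sample_sheet) {
  check_matrix_sheet(x, sample_sheet)
  sample_sheet[match(colnames(x), sample_sheet$sample_id), , drop = FALSE]
}

## group means over columns given a factor, preserving gene rows
rowgroup_means <- function(x, groups) {
  groups <- as.factor(groups)
  out <- vapply(levels(groups),
                function(g) rowMeans(x[, groups == g, drop = FALSE]),
                numeric(nrow(x)))
  colnames(out) <- levels(groups)
  out
}
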