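#' Per-gene translation ratio
#'
#' TR(fraction, condition) = mean TPM of the gene across replicates of that
#' polysome fraction and condition, divided by the mean total-RNA TPM in the
#' same condition. A TR of 1 means the gene is represented in the fraction
#' exactly in proportion to its steady-state abundance.
#'
#' @param tpm TPM matrix covering polysome and total-RNA libraries.
#' @param sample_sheet sample sheet for the columns.
#' @return data.frame of class \code{ptrans_tt} with columns
#'   \code{TR_<fraction>_<condition>} for mono/light/heavy x low/high;
#'   genes with zero total-RNA mean get NA (unclassifiable).
#' @export
translation_ratio <- function(tpm, sample_sheet) {
  tpm <- as.matrix(tpm)
  sheet <- sheet_for(tpm, sample_sheet)
  out <- data.frame(gene_id = rownames(tpm), stringsAsFactors = FALSE)
  for (cond in CONDITIONS) {
    tot <- sheet$fraction == "total" & sheet$condition == cond
    if (!any(tot)) stopf("no total-RNA replicates for condition '%s'", cond)
    tot_mean <- rowMeans(tpm[, tot, drop = FALSE])
    for (f in POLYSOME_FRACTIONS) {
      sel <- sheet$fraction == f & sheet$condition == cond
      if (!any(sel)) stopf("no replicates for fraction '%s', condition '%s'", f, cond)
      tr <- rowMeans(tpm[, sel, drop = FALSE]) / tot_mean
      tr[tot_mean == 0] <- NA_real_
      out[[paste("TR", f, cond, sep = "_")]] <- tr
    }
  }
  class(out) <- c("ptrans_tt", "data.frame")
  out
}

#' Translation efficiency between conditions
#'
#' The light- and heavy-polysome translation ratios are averaged per
#' condition, \eqn{A_c = (TR_{light,c} + TR_{heavy,c})/2}, and compared
#' between conditions. The default orientation is positive = more translated
#' in high glucose, on the log2 scale: \eqn{TE = \log_2 A_{high} - \log_2
#' A_{low}}; the literal low-minus-high orientation and a raw-difference
#' scale are available.
#'
#' @param tt output of \code{\link{translation_ratio}}.
#' @param orientation "high_over_low" (default) or "low_over_high".
#' @param scale "log2" (default) or "raw" (plain difference of averages).
#' @return the table with a \code{TE} column added; genes with non-positive
#'   averages in log mode get NA.
#' @export
translation_efficiency <- function(tt, orientation = c("high_over_low", "low_over_high"),
                                   scale = c("log2", "raw")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  a_low <- (tt$TR_light_low + tt$TR_heavy_low) / 2
  a_high <- (tt$TR_light_high + tt$TR_heavy_high) / 2
  te <- if (scale == "log2") {
    bad <- !is.na(a_low) & !is.na(a_high) & (a_low <= 0 | a_high <= 0)
    v <- log2(a_high) - log2(a_low)
    v[bad] <- NA_real_
    v
  } else a_high - a_low
  if (orientation == "low_over_high") te <- -te
  tt$TE <- te
  tt
}

#' Classify genes into translation-behaviour groups
#'
#' Thresholds on the (log-scale) translation-efficiency change: UP at
#' TE >= +0.5 (boundary inclusive), DOWN at TE <= -0.25, CONTROL at
#' |TE| <= 0.01; everything else (including undefined TE) is UNCLASSIFIED.
#'
#' @param te numeric vector of TE values.
#' @param up,down,control the three thresholds.
#' @return factor with levels UP, DOWN, CONTROL, UNCLASSIFIED.
#' @export
classify_translation_groups <- function(te, up = 0.5, down = -0.25,
                                        control = 0.01) {
  lab <- rep("UNCLASSIFIED", length(te))
  lab[!is.na(te) & te >= up] <- "UP"
  lab[!is.na(te) & te <= down] <- "DOWN"
  lab[!is.na(te) & abs(te) <= control] <- "CONTROL"
  factor(lab, levels = c("UP", "DOWN", "CONTROL", "UNCLASSIFIED"))
}

#' Rank the most translated genes per condition
#'
#' Genes are ranked per condition by their translation ratio across the
#' polysome pools (default statistic: max of light and heavy TR; ties broken
#' by gene ID). The overlap of the top-n lists between conditions and the
#' genes with the largest rank shifts are reported.
#'
#' @param tt output of \code{\link{translation_ratio}}.
#' @param n list length (default 200).
#' @param stat "max" (default) or "mean" of the light/heavy TR.
#' @return list: \code{top_low}, \code{top_high} (ranked gene IDs),
#'   \code{overlap} (genes in both), \code{only_high}, \code{only_low},
#'   \code{rank_shift} (data.frame of per-gene ranks and |shift|, sorted).
#' @export
rank_top_translated <- function(tt, n = 200, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  score <- function(cond) {
    m <- cbind(tt[[paste0("TR_light_", cond)]], tt[[paste0("TR_heavy_", cond)]])
    s <- if (stat == "max") pmax(m[, 1], m[, 2]) else rowMeans(m)
    s[is.na(s)] <- -Inf
    s
  }
  rank_of <- function(s) order(-s, tt$gene_id)   # best first, ties by ID
  ord_low <- rank_of(score("low"))
  ord_high <- rank_of(score("high"))
  if (n > nrow(tt)) {
    warnf("n = %d exceeds gene count %d; truncating", n, nrow(tt))
    n <- nrow(tt)
  }
  top_low <- tt$gene_id[ord_low[seq_len(n)]]
  top_high <- tt$gene_id[ord_high[seq_len(n)]]
  rk_low <- rk_high <- integer(nrow(tt))
  rk_low[ord_low] <- seq_len(nrow(tt))
  rk_high[ord_high] <- seq_len(nrow(tt))
  shift <- data.frame(gene_id = tt$gene_id, rank_low = rk_low,
                      rank_high = rk_high,
                      abs_shift = abs(rk_high - rk_low),
                      stringsAsFactors = FALSE)
  shift <- shift[order(-shift$abs_shift, shift$gene_id), ]
  list(top_low = top_low, top_high = top_high,
       overlap = intersect(top_low, top_high),
       only_high = setdiff(top_high, top_low),
       only_low = setdiff(top_low, top_high),
       rank_shift = shift)
}

#' Polysome/monosome ratio from an A254 trace
#'
#' Integrates the absorbance trace by the trapezoid rule over the 80S
#' (monosome) window and the polysome window, after optional constant
#' baseline subtraction (the within-window minimum), and returns the area
#' ratio polysomes / 80S.
#'
#' @param position strictly increasing gradient-depth vector.
#' @param absorbance A254 values at those positions.
#' @param mono_window numeric c(from, to) delimiting the 80S peak.
#' @param poly_window numeric c(from, to) delimiting the polysome region.
#' @param baseline "min" (default, subtract the within-window minimum) or
#'   "none".
#' @return the ratio (scalar); window areas in attributes.
#' @export
polysome_monosome_ratio <- function(position, absorbance, mono_window,
                                    poly_window, baseline = c("min", "none")) {
  baseline <- match.arg(baseline)
  if (length(position) != length(absorbance)) stopf("trace vectors differ in length")
  if (any(diff(position) <= 0)) stopf("positions must be strictly increasing")
  area <- function(win) {
    sel <- position >= win[1] & position <= win[2]
    if (sum(sel) < 2) stopf("window [%g, %g] covers fewer than 2 trace points",
                            win[1], win[2])
    x <- position[sel]; y <- absorbance[sel]
    if (baseline == "min") y <- y - min(y)
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  }
  a80 <- area(mono_window)
  apoly <- area(poly_window)
  if (a80 <= 0) stopf("80S peak area is zero; cannot form ratio")
  structure(apoly / a80, area_mono = a80, area_poly = apoly)
}

#' Log2 ratio matrix of mean TPM, high over low glucose
#'
#' The clustering substrate: per gene and polysome fraction,
#' \eqn{\log_2(\mathrm{mean\ TPM}_{high} / \mathrm{mean\ TPM}_{low})}.
#' Genes with zero mean in either condition of any fraction are excluded
#' (IDs kept in the \code{excluded} attribute).
#'
#' @param tpm TPM matrix.
#' @param sample_sheet sample sheet for the columns.
#' @param fractions fractions forming the columns (default mono/light/heavy).
#' @return genes x fractions numeric matrix with finite entries only.
#' @export
build_log_ratio_matrix <- function(tpm, sample_sheet,
                                   fractions = POLYSOME_FRACTIONS) {
  tpm <- as.matrix(tpm)
  sheet <- sheet_for(tpm, sample_sheet)
  out <- matrix(NA_real_, nrow(tpm), length(fractions),
                dimnames = list(rownames(tpm), fractions))
  for (f in fractions) {
    hi <- sheet$fraction == f & sheet$condition == "high"
    lo <- sheet$fraction == f & sheet$condition == "low"
    if (!any(hi) || !any(lo)) stopf("fraction '%s' missing a condition", f)
    out[, f] <- log2(rowMeans(tpm[, hi, drop = FALSE]) /
                     rowMeans(tpm[, lo, drop = FALSE]))
  }
  bad <- !is.finite(out)
  excluded <- rownames(out)[rowSums(bad) > 0]
  out <- out[rowSums(bad) == 0, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}
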