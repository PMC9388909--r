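#' Gene-wise ordinary least squares
#'
#' Fits the same linear model to every gene by QR decomposition of the shared
#' design matrix. The contrast coefficient is the log2 fold-change when the
#' response is log2-scale expression.
#'
#' @param y genes x samples matrix (typically log2 CPM).
#' @param design samples x coefficients design matrix, full column rank.
#' @param contrast numeric contrast vector over the coefficients (default:
#'   last coefficient).
#' @return list with per-gene \code{coefficients}, \code{logFC}, \code{s2}
#'   (residual variance), \code{df} (residual degrees of freedom),
#'   \code{v_contrast} (unscaled variance of the contrast) and \code{amean}
#'   (average expression).
#' @export
fit_gene_linear_models <- function(y, design, contrast = NULL) {
  y <- as.matrix(y)
  design <- as.matrix(design)
  n <- ncol(y)
  if (nrow(design) != n) stopf("design rows must match samples")
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) stopf("design matrix is rank deficient")
  if (n <= ncol(design)) stopf("need more samples than coefficients")
  if (is.null(contrast)) contrast <- c(rep(0, ncol(design) - 1), 1)
  fit <- lm.fit(design, t(y))
  beta <- t(fit$coefficients)              # genes x p
  res <- fit$residuals                     # samples x genes
  d <- n - qr_x$rank
  s2 <- colSums(res^2) / d
  xtxi <- chol2inv(qr.R(qr_x))
  v <- drop(t(contrast) %*% xtxi %*% contrast)
  list(coefficients = beta, logFC = drop(beta %*% contrast),
       s2 = s2, df = d, v_contrast = v, amean = rowMeans(y),
       gene_ids = rownames(y))
}

## Newton solve of trigamma(y) = x, vectorised
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the variance prior by method of moments
#'
#' Models gene-wise residual variances as scaled F-distributed around a prior
#' \eqn{s_0^2} with prior degrees of freedom \eqn{d_0}: moments of
#' \eqn{\log s^2} involve digamma/trigamma functions of \eqn{d/2} and
#' \eqn{d_0/2}, and \eqn{d_0} is obtained by inverting the trigamma relation.
#' When the observed spread of \eqn{\log s^2} is no larger than expected from
#' chi-square sampling alone, \eqn{d_0 = \infty}.
#'
#' @param s2 vector of residual variances.
#' @param df residual degrees of freedom (scalar or per-gene).
#' @param covariate optional per-gene covariate (typically average log
#'   expression): the prior variance then follows a lowess trend in the
#'   covariate instead of being constant, which calibrates count data whose
#'   variance depends on expression level.
#' @return list(d0, s02); with a covariate, \code{s02} is a per-gene vector.
#' @export
fit_f_dist <- function(s2, df, covariate = NULL) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stopf("need at least two positive variances")
  z <- log(s2[ok])
  if (var(z) < 1e-12) {
    ## no spread at all: the variances are taken at face value
    s02 <- rep(exp(mean(z)), length(s2))
    return(list(d0 = Inf, s02 = if (is.null(covariate)) s02[1] else s02))
  }
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (is.null(covariate)) {
    eloc <- rep(mean(e), length(e))
    evar <- var(e)
  } else {
    ## natural cubic spline regression of e on the covariate (df 4 when
    ## enough genes); plain least squares so the left-skew of log
    ## chi-square does not bias the trend
    x <- covariate[ok]
    sdf <- min(1L + (length(x) >= 3) + (length(x) >= 6) + (length(x) >= 30),
               length(unique(x)))
    design <- splines::ns(x, df = sdf, intercept = TRUE)
    sfit <- lm.fit(design, e)
    eloc <- sfit$fitted.values
    evar <- sum(sfit$residuals^2) / (length(x) - sfit$rank)
  }
  evar <- evar - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02_ok <- exp(eloc + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02_ok <- exp(eloc)
  }
  if (is.null(covariate)) return(list(d0 = d0, s02 = s02_ok[1]))
  s02 <- rep(NA_real_, length(s2))
  s02[ok] <- s02_ok
  s02[!ok] <- mean(s02_ok)
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t statistics
#'
#' Shrinks each gene's residual variance toward the prior,
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}, and tests the contrast
#' with \eqn{\tilde t = \hat\beta / (\tilde s \sqrt{v})} on \eqn{d_0 + d}
#' degrees of freedom.
#'
#' @param fit output of \code{\link{fit_gene_linear_models}}.
#' @param prior_df optional forced prior degrees of freedom: 0 gives the
#'   ordinary t statistic, \code{Inf} full shrinkage to the prior variance;
#'   \code{NULL} (default) estimates \eqn{(d_0, s_0^2)} from the data.
#' @param prior_var optional forced prior variance \eqn{s_0^2} (used with
#'   \code{prior_df}, e.g. for a variance prior pooled across fractions).
#' @param trend if TRUE the prior variance follows a lowess trend in average
#'   expression rather than being constant; recommended for log-CPM of
#'   counts, whose variance depends on expression level.
#' @param adjust multiple-testing method passed to \code{\link{bh_adjust}}.
#' @return data.frame (one row per gene): logFC, AveExpr, t, P.Value,
#'   adj.P.Val, s2, s2_post; hyperparameters in attributes \code{d0},
#'   \code{s02}.
#' @export
ebayes_moderate <- function(fit, prior_df = NULL, prior_var = NULL,
                            trend = FALSE, adjust = "BH") {
  s2 <- fit$s2
  d <- fit$df
  if (length(s2) < 50 && is.null(prior_df))
    warnf("fewer than 50 genes: hyperparameter estimates may be unstable")
  if (is.null(prior_df)) {
    hp <- fit_f_dist(s2, d, covariate = if (trend) fit$amean else NULL)
  } else if (prior_df == 0) {
    hp <- list(d0 = 0, s02 = NA_real_)
  } else {
    hp <- list(d0 = prior_df,
               s02 = prior_var %||% fit_f_dist(s2, d)$s02)
  }
  d0 <- hp$d0; s02 <- hp$s02
  s2_post <- if (is.infinite(d0)) rep_len(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d * s2) / (d0 + d)
  tstat <- fit$logFC / sqrt(s2_post * fit$v_contrast)
  df_total <- d0 + d
  pval <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(gene_id = fit$gene_ids %||% seq_along(s2),
                    logFC = fit$logFC, AveExpr = fit$amean, t = tstat,
                    P.Value = pval, adj.P.Val = bh_adjust(pval, method = adjust),
                    s2 = s2, s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_total") <- df_total
  out
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default (monotonicity enforced); Holm and
#' Benjamini-Yekutieli available.
#'
#' @param p vector of p-values in [0,1].
#' @param method one of "BH", "holm", "BY".
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p, method = c("BH", "holm", "BY")) {
  method <- match.arg(method)
  bad <- p[!is.na(p)]
  if (any(bad < 0 | bad > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Call regulated genes
#'
#' Joint threshold on adjusted p-value and log fold-change: significance is
#' \code{adj.P.Val <= alpha} and effect \code{logFC > lfc} (up) or
#' \code{logFC < -lfc} (down).
#'
#' @param diff a DiffResult data.frame from \code{\link{ebayes_moderate}}.
#' @param alpha adjusted-p threshold (default 0.05, boundary inclusive).
#' @param lfc log2 fold-change threshold (default 0.5, strict).
#' @return list(up, down) of gene IDs.
#' @export
call_regulated <- function(diff, alpha = 0.05, lfc = 0.5) {
  sig <- !is.na(diff$adj.P.Val) & diff$adj.P.Val <= alpha
  list(up = diff$gene_id[sig & diff$logFC > lfc],
       down = diff$gene_id[sig & diff$logFC < -lfc])
}

#' Exact Venn region cardinalities for 2-3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of exclusive region counts, names like
#'   \code{"A"}, \code{"A&B"}.
#' @export
venn_overlap <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3)
    stopf("venn_overlap supports 2 or 3 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  patterns <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  counts <- setNames(integer(length(combos)), combos)
  tab <- table(patterns)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Per-fraction differential analysis of high vs low glucose
#'
#' For each requested fraction, fits a gene-wise linear model with
#' coefficients (intercept, condition) on log2 CPM and applies
#' empirical-Bayes moderation. Differentially translated genes (DTGs) are
#' joint calls in the light/heavy polysome pools; total-RNA calls are DEGs.
#'
#' @param counts gene x sample count matrix covering all libraries.
#' @param sample_sheet sample sheet for the columns.
#' @param fractions fractions to analyse (default all four).
#' @param alpha,lfc calling thresholds, see \code{\link{call_regulated}}.
#' @param pool_variance if TRUE, the variance prior (d0, s0^2) is estimated
#'   once on the residual variances pooled across the analysed fractions
#'   (shared error model, constant prior); default FALSE fits each fraction
#'   separately.
#' @param trend use an expression-dependent variance prior (default TRUE,
#'   appropriate for log-CPM of counts); see \code{\link{ebayes_moderate}}.
#' @param adjust multiple-testing method.
#' @return list of class \code{ptrans_diff}: \code{results} (one DiffResult
#'   per fraction), \code{calls} (up/down per fraction), \code{dtg}
#'   (union of light+heavy calls), \code{deg} (total-RNA calls).
#' @export
run_diffexpr <- function(counts, sample_sheet, fractions = FRACTIONS,
                         alpha = 0.05, lfc = 0.5, pool_variance = FALSE,
                         trend = TRUE, adjust = "BH") {
  sheet <- sheet_for(counts, sample_sheet)
  logcpm <- cpm(counts, log = TRUE)
  fits <- list()
  for (f in fractions) {
    sel <- sheet$fraction == f
    if (!any(sel)) stopf("no samples for fraction '%s'", f)
    sub_sheet <- sheet[sel, , drop = FALSE]
    if (length(unique(sub_sheet$condition)) < 2)
      stopf("fraction '%s' lacks both conditions", f)
    design <- cbind(intercept = 1, high = as.numeric(sub_sheet$condition == "high"))
    fits[[f]] <- fit_gene_linear_models(logcpm[, sel, drop = FALSE], design)
  }
  results <- list()
  if (pool_variance) {
    hp <- fit_f_dist(unlist(lapply(fits, `[[`, "s2")),
                     unlist(lapply(fits, function(x) rep(x$df, length(x$s2)))))
    for (f in names(fits)) results[[f]] <- ebayes_moderate(
      fits[[f]], prior_df = hp$d0, prior_var = hp$s02, adjust = adjust)
  } else {
    for (f in names(fits)) results[[f]] <- ebayes_moderate(fits[[f]],
                                                           trend = trend,
                                                           adjust = adjust)
  }
  calls <- lapply(results, call_regulated, alpha = alpha, lfc = lfc)
  poly <- intersect(c("light", "heavy"), names(calls))
  dtg <- sort(unique(unlist(lapply(calls[poly], unlist), use.names = FALSE)))
  deg <- if ("total" %in% names(calls))
    sort(unique(unlist(calls[["total"]], use.names = FALSE))) else character(0)
  structure(list(results = results, calls = calls, dtg = dtg, deg = deg,
                 alpha = alpha, lfc = lfc),
            class = "ptrans_diff")
}

#' @export
print.ptrans_diff <- function(x, ...) {
  cat(sprintf("differential analysis over %d fraction(s); %d DTGs, %d DEGs\n",
              length(x$results), length(x$dtg), length(x$deg)))
  invisible(x)
}
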