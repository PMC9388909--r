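GMM_FAMILIES <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")
METHOD_PRIORITY <- c(gmm = 3, kmeans = 2, hierarchical = 1)

new_cluster_model <- function(method, K, assignment, M, params = list(),
                              seed = NA_integer_, extra = list()) {
  sil <- if (K >= 2) silhouette_score(M, assignment)$mean else NA_real_
  structure(c(list(method = method, K = K, assignment = assignment,
                   params = params, silhouette = sil, seed = seed), extra),
            class = "ptrans_cluster")
}

#' @export
print.ptrans_cluster <- function(x, ...) {
  cat(sprintf("%s clustering: K = %d, mean silhouette = %.3f\n",
              x$method, x$K, x$silhouette))
  invisible(x)
}

#' Hierarchical clustering of the log-ratio matrix
#'
#' Euclidean distances, Ward minimum-variance linkage (ward.D2), tree cut
#' at K clusters.
#'
#' @param M genes x fractions numeric matrix.
#' @param K number of clusters.
#' @return a \code{ptrans_cluster} model.
#' @export
cluster_hierarchical <- function(M, K) {
  M <- as.matrix(M)
  if (K > nrow(M)) stopf("K exceeds number of genes")
  hc <- hclust(dist(M), method = "ward.D2")
  cl <- cutree(hc, k = K)
  new_cluster_model("hierarchical", K, cl, M, params = list(tree = hc))
}

## k-means++ seeding: first centre uniform, then proportional to squared
## distance to the nearest chosen centre
kmeanspp_centers <- function(M, K) {
  n <- nrow(M)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((M - matrix(M[centers[1], ], n, ncol(M), byrow = TRUE))^2)
  for (k in seq_len(K - 1)) {
    if (all(d2 == 0)) {
      centers[k + 1] <- sample.int(n, 1)
    } else {
      centers[k + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    dn <- rowSums((M - matrix(M[centers[k + 1], ], n, ncol(M), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  M[centers, , drop = FALSE]
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd iterations from k-means++ seedings; the restart with the smallest
#' total within-cluster sum of squares wins.
#'
#' @param M genes x fractions matrix.
#' @param K number of clusters.
#' @param n_init number of restarts (default 10).
#' @param seed RNG seed for the seeding draws.
#' @return a \code{ptrans_cluster} model (centroids and WSS in params).
#' @export
cluster_kmeans <- function(M, K, n_init = 10, seed = 1L) {
  M <- as.matrix(M)
  if (K > nrow(M)) stopf("K exceeds number of genes")
  if (K == 1) {
    cl <- setNames(rep(1L, nrow(M)), rownames(M))
    centers <- matrix(colMeans(M), 1, dimnames = list(NULL, colnames(M)))
    wss <- sum(sweep(M, 2, centers[1, ])^2)
    return(new_cluster_model("kmeans", 1L, cl, M,
                             params = list(centers = centers,
                                           tot_withinss = wss),
                             seed = seed))
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(M, K)
    km <- tryCatch(kmeans(M, centers = centers, iter.max = 100,
                          algorithm = "Lloyd"),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km))
      km <- suppressWarnings(kmeans(M, centers = centers, iter.max = 500,
                                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  cl <- setNames(best$cluster, rownames(M))
  new_cluster_model("kmeans", K, cl, M,
                    params = list(centers = best$centers,
                                  tot_withinss = best$tot.withinss),
                    seed = seed)
}

## per-component Gaussian log density given the family's covariance object
gmm_log_dens <- function(X, mu, cov, family) {
  n <- nrow(X); d <- ncol(X)
  Xc <- X - matrix(mu, n, d, byrow = TRUE)
  switch(family,
    spherical = -0.5 * (d * log(2 * pi * cov) + rowSums(Xc^2) / cov),
    diagonal = -0.5 * (d * log(2 * pi) + sum(log(cov)) +
                       rowSums(sweep(Xc^2, 2, cov, "/"))),
    full = {
      ch <- chol(cov)
      z <- Xc %*% chol2inv(ch) * Xc
      -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + rowSums(z))
    })
}

gmm_family_kind <- function(family) {
  switch(family, EII = , VII = "spherical", EEI = , VVI = "diagonal",
         EEE = , VVV = "full")
}

gmm_n_params <- function(family, K, d) {
  cov_p <- switch(family, EII = 1, VII = K, EEI = d, VVI = K * d,
                  EEE = d * (d + 1) / 2, VVV = K * d * (d + 1) / 2)
  K * d + (K - 1) + cov_p
}

## one EM run from given responsibilities; returns loglik, params, z
gmm_em_run <- function(X, K, family, resp, max_iter, tol, ridge) {
  n <- nrow(X); d <- ncol(X)
  kind <- gmm_family_kind(family)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ## M step
    nk <- pmax(colSums(resp), 1e-10)
    w <- nk / n
    mu <- t(resp) %*% X / nk
    covs <- vector("list", K)
    pooled <- NULL
    for (k in seq_len(K)) {
      Xc <- X - matrix(mu[k, ], n, d, byrow = TRUE)
      wXc2 <- resp[, k] * Xc^2
      covs[[k]] <- switch(kind,
        spherical = sum(wXc2) / (nk[k] * d) + ridge,
        diagonal = colSums(wXc2) / nk[k] + ridge,
        full = crossprod(Xc * sqrt(resp[, k])) / nk[k] + diag(ridge, d))
      sc <- switch(kind,
        spherical = sum(wXc2) / d,
        diagonal = colSums(wXc2),
        full = crossprod(Xc * sqrt(resp[, k])))
      pooled <- if (is.null(pooled)) sc else pooled + sc
    }
    if (family %in% c("EII", "EEI", "EEE")) {
      shared <- switch(kind,
        spherical = pooled / n + ridge,
        diagonal = pooled / n + ridge,
        full = pooled / n + diag(ridge, d))
      covs <- rep(list(shared), K)
    }
    ## E step
    logd <- vapply(seq_len(K), function(k)
      gmm_log_dens(X, mu[k, ], covs[[k]], kind) + log(w[k]), numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(loglik = ll, weights = w, means = mu, covariances = covs,
       resp = resp, ll_trace = ll_trace, n_iter = iter)
}

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits mixtures by EM over a grid of component counts and covariance
#' families (spherical, diagonal, full crossed with equal/varying volume,
#' i.e. EII/VII/EEI/VVI/EEE/VVV) and selects the model with minimal
#' \eqn{BIC = -2\,\log L + p\,\log n}. Hard assignments are by maximum
#' posterior responsibility. Degenerate covariances are regularised with a
#' small ridge.
#'
#' @param M genes x fractions matrix.
#' @param K_range component counts to try (default 2:9).
#' @param families covariance families (subset of EII, VII, EEI, VVI, EEE,
#'   VVV).
#' @param n_init EM restarts per grid cell (k-means++ initialised).
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule (relative log-likelihood).
#' @param ridge covariance regulariser.
#' @return a \code{ptrans_cluster} model; \code{params} holds weights, means,
#'   covariances, family, loglik; \code{bic_table} has one row per grid cell.
#' @export
cluster_gmm <- function(M, K_range = 2:9, families = GMM_FAMILIES,
                        n_init = 10, seed = 1L, max_iter = 500, tol = 1e-6,
                        ridge = 1e-6) {
  M <- as.matrix(M)
  if (!length(K_range)) stopf("K_range must be non-empty")
  families <- match.arg(families, GMM_FAMILIES, several.ok = TRUE)
  set.seed(seed)
  n <- nrow(M); d <- ncol(M)
  best <- NULL
  bic_table <- data.frame()
  for (K in K_range) {
    if (K > n) next
    for (family in families) {
      best_run <- NULL
      for (i in seq_len(max(1, n_init))) {
        ## initial responsibilities: hard assignment to k-means++ centres
        centers <- kmeanspp_centers(M, K)
        dmat <- vapply(seq_len(K), function(k)
          rowSums((M - matrix(centers[k, ], n, d, byrow = TRUE))^2), numeric(n))
        hard <- max.col(-dmat, ties.method = "first")
        resp <- matrix(1e-6, n, K)
        resp[cbind(seq_len(n), hard)] <- 1
        resp <- resp / rowSums(resp)
        run <- gmm_em_run(M, K, family, resp, max_iter, tol, ridge)
        if (is.null(best_run) || run$loglik > best_run$loglik) best_run <- run
      }
      p <- gmm_n_params(family, K, d)
      bic <- -2 * best_run$loglik + p * log(n)
      bic_table <- rbind(bic_table,
                         data.frame(K = K, family = family, bic = bic,
                                    loglik = best_run$loglik, n_params = p))
      if (is.null(best) || bic < best$bic)
        best <- c(best_run, list(K = K, family = family, bic = bic))
    }
  }
  if (is.null(best)) stopf("no feasible (K, family) grid cell")
  cl <- setNames(max.col(best$resp, ties.method = "first"), rownames(M))
  new_cluster_model("gmm", best$K, cl, M,
                    params = list(weights = best$weights, means = best$means,
                                  covariances = best$covariances,
                                  family = best$family, loglik = best$loglik,
                                  ll_trace = best$ll_trace),
                    seed = seed,
                    extra = list(bic = best$bic, bic_table = bic_table))
}

#' Silhouette widths
#'
#' For each point, \eqn{s = (b - a)/\max(a, b)} with \eqn{a} the mean
#' Euclidean distance to its own cluster and \eqn{b} the smallest mean
#' distance to another cluster. Singletons get \eqn{s = 0}.
#'
#' @param M data matrix.
#' @param assignment integer/character cluster labels, one per row.
#' @return list(widths, mean).
#' @export
silhouette_score <- function(M, assignment) {
  M <- as.matrix(M)
  cl <- as.character(assignment)
  if (length(cl) != nrow(M)) stopf("one label per row required")
  labs <- unique(cl)
  if (length(labs) < 2) stopf("silhouette needs at least 2 clusters")
  D <- as.matrix(dist(M))
  n <- nrow(M)
  s <- numeric(n)
  sizes <- table(cl)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[[own]] == 1) { s[i] <- 0; next }
    a <- sum(D[i, cl == own]) / (sizes[[own]] - 1)
    b <- min(vapply(setdiff(labs, own),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(widths = setNames(s, rownames(M)), mean = mean(s))
}

#' Select the best clustering by silhouette
#'
#' Argmax of the mean silhouette; ties (within 1e-10) broken by method,
#' gmm over kmeans over hierarchical.
#'
#' @param models list of \code{ptrans_cluster} models.
#' @return the winning model (with \code{selection} attribute summarising
#'   the comparison).
#' @export
select_best_clustering <- function(models) {
  if (!length(models)) stopf("no models supplied")
  sil <- vapply(models, `[[`, numeric(1), "silhouette")
  pri <- METHOD_PRIORITY[vapply(models, `[[`, character(1), "method")]
  cand <- which(sil >= max(sil, na.rm = TRUE) - 1e-10)
  best <- cand[which.max(pri[cand])]
  out <- models[[best]]
  attr(out, "selection") <- data.frame(
    method = vapply(models, `[[`, character(1), "method"),
    K = vapply(models, `[[`, numeric(1), "K"),
    silhouette = sil, selected = seq_along(models) == best)
  out
}

#' Run and compare the three clustering algorithms
#'
#' The Gaussian mixture picks its K by BIC; hierarchical and k-means are
#' then evaluated at that same K so the silhouette comparison contrasts
#' algorithms rather than cluster counts. The best model by mean silhouette
#' is returned alongside all three.
#'
#' @param M genes x fractions log-ratio matrix.
#' @param K_range grid for the mixture's BIC selection.
#' @param families covariance families for the mixture.
#' @param n_init restarts for k-means and EM.
#' @param seed RNG seed.
#' @return list(models, best, K).
#' @export
compare_clusterings <- function(M, K_range = 2:9, families = GMM_FAMILIES,
                                n_init = 10, seed = 1L) {
  gm <- cluster_gmm(M, K_range = K_range, families = families,
                    n_init = n_init, seed = seed)
  km <- cluster_kmeans(M, K = gm$K, n_init = n_init, seed = seed + 1L)
  hc <- cluster_hierarchical(M, K = gm$K)
  models <- list(gmm = gm, kmeans = km, hierarchical = hc)
  best <- select_best_clustering(models)
  list(models = models, best = best, K = gm$K)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 means identical partitions (up to label permutation), 0 is the
#' chance level.
#'
#' @param a,b cluster label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions must have equal length")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(length(a), 2)
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Summarise clusters for reporting and heatmaps
#'
#' Computes per-cluster mean log ratios over the fractions, assigns a
#' qualitative pattern from the sign of each mean (dead zone +/-0.05), and
#' renumbers clusters canonically: decreasing polysome gain
#' (light + heavy - mono), so the monosome-to-polysome shift comes first.
#' Genes are ordered by cluster and then by decreasing heavy-fraction ratio.
#'
#' @param model a \code{ptrans_cluster}.
#' @param M the matrix the model was fitted on.
#' @param dead_zone below this absolute mean a fraction counts as flat.
#' @return list: \code{summary} (per-cluster table), \code{assignment}
#'   (canonically renumbered, named by gene), \code{gene_order} (row order
#'   for a heatmap).
#' @export
summarize_clusters <- function(model, M, dead_zone = 0.05) {
  M <- as.matrix(M)
  cl <- model$assignment
  labs <- sort(unique(cl))
  means <- t(vapply(labs, function(k) colMeans(M[cl == k, , drop = FALSE]),
                    numeric(ncol(M))))
  rownames(means) <- labs
  sizes <- as.integer(table(factor(cl, levels = labs)))
  sign_of <- function(x) ifelse(x > dead_zone, "up",
                                ifelse(x < -dead_zone, "down", "flat"))
  signs <- apply(means, 2, sign_of)
  if (is.null(dim(signs))) signs <- matrix(signs, nrow = 1,
                                           dimnames = list(labs, colnames(M)))
  pattern <- apply(signs, 1, function(s)
    paste(paste0(colnames(M), ":", s), collapse = " "))
  label <- vapply(seq_along(labs), function(i) {
    s <- signs[i, ]
    if (all(s == "flat")) "flat"
    else if (!is.na(s["mono"]) && s["mono"] == "down" &&
             any(s[setdiff(names(s), "mono")] == "up")) "mono->polysomes shift"
    else if (all(s != "up") && any(s == "down")) "polysome depletion"
    else "mixed/other"
  }, character(1))
  gain <- if (all(c("mono", "light", "heavy") %in% colnames(means)))
    means[, "light"] + means[, "heavy"] - means[, "mono"] else rowMeans(means)
  ord <- order(-gain, -means[, ncol(means)], -sizes)
  canon <- setNames(seq_along(labs), labs[ord])
  new_cl <- setNames(canon[as.character(cl)], names(cl))
  summary <- data.frame(cluster = seq_along(labs), original = labs[ord],
                        n = sizes[ord], means[ord, , drop = FALSE],
                        pattern = pattern[ord], label = label[ord],
                        row.names = NULL, stringsAsFactors = FALSE)
  heavy <- if ("heavy" %in% colnames(M)) M[, "heavy"] else M[, ncol(M)]
  gene_order <- names(new_cl)[order(new_cl, -heavy[names(new_cl)])]
  list(summary = summary, assignment = new_cl, gene_order = gene_order)
}
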