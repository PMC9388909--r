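#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated: name, description, genes.
#'
#' @param file path to a .gmt file.
#' @return named list of character vectors; descriptions in the
#'   \code{"description"} attribute.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stopf("malformed GMT line(s) (need name, description, >=1 gene): %s",
          paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warnf("dropping %d empty gene set(s)", sum(empty))
    sets <- sets[!empty]; desc <- desc[!empty]
  }
  attr(sets, "description") <- setNames(desc, names(sets))
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} of drawing at least the observed overlap \eqn{k} when
#' sampling \code{|query|} genes from the universe containing \code{|set|}
#' successes, with BH adjustment across sets. Sets are intersected with the
#' universe first; empty (post-harmonisation) sets are dropped with a
#' warning.
#'
#' @param query gene set of interest (must lie in the universe).
#' @param collection named list of gene sets (e.g. \code{\link{read_gmt}}).
#' @param universe background gene set (e.g. all genes surviving the
#'   expression filters).
#' @param adjust multiple-testing method across sets (default BH).
#' @return data.frame: set, k (overlap), set_size, query_size, universe_size,
#'   expected, enrichment_ratio, p, p_adj; sorted by p.
#' @export
ora_hypergeometric <- function(query, collection, universe, adjust = "BH") {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stopf("query gene set is empty")
  out <- setdiff(query, universe)
  if (length(out))
    stopf("query gene(s) outside the universe: %s",
          paste(head(out, 5), collapse = ", "))
  sets <- lapply(collection, intersect, universe)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warnf("dropping %d set(s) with no genes in the universe", sum(empty))
    sets <- sets[!empty]
  }
  N <- length(universe); q <- length(query)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    m <- length(sets[[nm]])
    k <- length(intersect(query, sets[[nm]]))
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    expected <- q * m / N
    data.frame(set = nm, k = k, set_size = m, query_size = q,
               universe_size = N, expected = expected,
               enrichment_ratio = if (expected > 0) k / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) stopf("no usable gene sets")
  res$p_adj <- bh_adjust(res$p, method = adjust)
  res[order(res$p, res$set), ]
}
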