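#' @useDynLib polytrans, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

TOP_SCORE_VERSION <- "anchored-kadane-1"

#' GC content of a sequence
#'
#' Fraction (G+C)/(A+C+G+T); N bases are excluded from the denominator.
#' Undefined (empty or all-N) sequences give NA.
#'
#' @param seq character vector of DNA sequences.
#' @return numeric vector in [0,1] (or NA).
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    ch <- ch[ch %in% c("A", "C", "G", "T")]
    if (!length(ch)) return(NA_real_)
    sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Folding score per base
#'
#' Estimates UTR structural complexity as a folding energy normalised by
#' sequence length. The default engine is a Nussinov base-pair maximisation
#' (Watson-Crick plus GU wobble, minimum hairpin loop of 3 nt) scored at -1
#' per pair; the \code{"rnafold"} engine shells out to the ViennaRNA
#' \code{RNAfold} binary and parses the thermodynamic MFE (kcal/mol) from
#' its dot-bracket output. Either way the result is divided by the sequence
#' length, so values are <= 0 and comparable across transcripts within one
#' engine (the engine used is recorded by \code{\link{transcript_features}}).
#'
#' @param seq character vector of sequences (DNA alphabet; T is read as U).
#' @param engine "nussinov" (default) or "rnafold".
#' @param min_loop minimum hairpin loop for the Nussinov engine.
#' @param rules "wc_gu" (default) or "wc" (no wobble pairs).
#' @return numeric vector of score/length values (<= 0).
#' @export
fold_mfe_per_bp <- function(seq, engine = c("nussinov", "rnafold"),
                            min_loop = 3, rules = c("wc_gu", "wc")) {
  engine <- match.arg(engine)
  rules <- match.arg(rules)
  if (engine == "rnafold") {
    if (Sys.which("RNAfold") == "")
      stopf("RNAfold binary not found; use engine = \"nussinov\" for the built-in fallback")
    return(vapply(seq, rnafold_mfe_per_bp, numeric(1), USE.NAMES = FALSE))
  }
  vapply(seq, function(s) {
    s <- toupper(s)
    if (nchar(s) < 4) return(0)
    -nussinov_pairs(s, min_loop = min_loop, allow_gu = rules == "wc_gu") / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Maximum non-crossing base pairs (Nussinov)
#'
#' @param seq single DNA sequence.
#' @param min_loop minimum unpaired bases in a hairpin loop.
#' @param allow_gu allow GU (here GT) wobble pairs.
#' @return integer pair count.
#' @export
nussinov_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  .nussinov_pairs_cpp(toupper(seq), as.integer(min_loop), isTRUE(allow_gu))
}

rnafold_mfe_per_bp <- function(seq) {
  out <- system2("RNAfold", args = "--noPS", input = toupper(seq),
                 stdout = TRUE, stderr = FALSE)
  line <- out[length(out)]
  m <- regmatches(line, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", line))
  if (!length(m)) stopf("could not parse RNAfold output: %s", line)
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE)) / nchar(seq)
}

#' Load the bundled human codon usage table
#'
#' @param file optional path to a two-column TSV (codon, frequency) to use
#'   instead of the packaged table.
#' @return named numeric vector of codon frequencies (per thousand).
#' @export
load_codon_usage <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "human_codon_usage.tsv", package = "polytrans")
  tab <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab[[2]], toupper(tab[[1]]))
}

#' Codon adaptation index
#'
#' Relative adaptiveness \eqn{w_c = f_c / \max f} over synonymous codons;
#' CAI is the geometric mean of \eqn{w} over the CDS codons, excluding the
#' non-degenerate codons ATG and TGG and the stop codons. An internal
#' in-frame stop truncates the computation at that point (flagged in the
#' \code{internal_stop} attribute).
#'
#' @param cds coding sequence (starts ATG, length divisible by 3).
#' @param usage_table named codon-frequency vector, e.g.
#'   \code{\link{load_codon_usage}()}.
#' @return CAI in (0, 1].
#' @export
cai <- function(cds, usage_table = load_codon_usage()) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stopf("CDS length must be divisible by 3")
  w <- cai_weights(usage_table)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  code <- Biostrings::GENETIC_CODE
  aa <- code[codons]
  internal_stop <- FALSE
  stops <- which(aa == "*")
  if (length(stops) && stops[1] < length(codons)) {
    internal_stop <- TRUE
    codons <- codons[seq_len(stops[1] - 1)]
    aa <- aa[seq_len(stops[1] - 1)]
  }
  keep <- !is.na(aa) & !(aa %in% c("M", "W", "*"))
  used <- w[codons[keep]]
  if (!length(used)) return(structure(NA_real_, internal_stop = internal_stop))
  structure(exp(mean(log(used))), internal_stop = internal_stop)
}

cai_weights <- function(usage_table) {
  code <- Biostrings::GENETIC_CODE
  f <- usage_table[names(code)]
  f[is.na(f)] <- 0
  if (any(f == 0) && any(f > 0)) f[f == 0] <- min(f[f > 0]) / 2
  names(f) <- names(code)
  w <- f
  for (a in unique(code)) {
    fam <- names(code)[code == a]
    w[fam] <- f[fam] / max(f[fam])
  }
  w
}

#' Local 5'TOP score
#'
#' Scores each base of the transcript 5' end +1 for a pyrimidine (C/T) and
#' -1 for a purine, then takes the maximum window sum over all windows that
#' start within the first \code{anchor_max} bases and end within the first
#' \code{window} bases (an anchored Kadane scan). Negative optima are
#' floored at 0. The definition is versioned (see the
#' \code{"version"} attribute) so scores are comparable across runs.
#'
#' @param seq 5'-end sequence(s) of the transcript.
#' @param anchor_max latest allowed window start (default 5).
#' @param window latest allowed window end (default 50).
#' @return integer score(s) >= 0, with attribute \code{version}.
#' @export
top_local_score <- function(seq, anchor_max = 5, window = 50) {
  out <- vapply(seq, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    if (!length(ch)) return(0L)
    ch <- ch[seq_len(min(length(ch), window))]
    sc <- ifelse(ch %in% PYRIMIDINES, 1L, -1L)
    cum <- c(0L, cumsum(sc))
    best <- 0L
    for (s0 in seq_len(min(anchor_max, length(sc)))) {
      cand <- max(cum[(s0 + 1):length(cum)]) - cum[s0]
      if (cand > best) best <- cand
    }
    as.integer(best)
  }, integer(1), USE.NAMES = FALSE)
  attr(out, "version") <- TOP_SCORE_VERSION
  out
}

#' Classic 5'TOP motif flag
#'
#' TRUE iff the first base is C and bases 2..k are all pyrimidines.
#'
#' @param utr5 5'UTR sequence(s).
#' @param k minimum tract length including the leading C (default 5).
#' @return logical vector.
#' @export
detect_top_motif <- function(utr5, k = 5) {
  vapply(utr5, function(s) {
    s <- toupper(s)
    if (nchar(s) < k) return(FALSE)
    ch <- strsplit(substr(s, 1, k), "")[[1]]
    ch[1] == "C" && all(ch[-1] %in% PYRIMIDINES)
  }, logical(1), USE.NAMES = FALSE)
}

#' Detect upstream open reading frames
#'
#' Scans all three frames of the 5'UTR for ATG...in-frame-stop ORFs fully
#' contained in the sequence. Every start with a reachable stop counts, so
#' overlapping/nested uORFs are counted separately. Coordinates are 0-based
#' half-open on the given sequence.
#'
#' @param utr5 a single 5'UTR sequence.
#' @param min_codons minimum ORF length in codons, start and stop included
#'   (default 3, i.e. at least ATG + 1 codon + stop).
#' @return list(count, orfs) where orfs is a data.frame(start, end, n_codons).
#' @export
detect_uorfs <- function(utr5, min_codons = 3) {
  if (min_codons < 2) stopf("min_codons must be >= 2")
  s <- toupper(utr5)
  n <- nchar(s)
  starts <- integer(0); ends <- integer(0)
  if (n >= 3 * min_codons) {
    codon_at <- function(i) substr(s, i, i + 2)
    atg <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    atg <- atg[atg > 0]
    for (p in atg) {
      q <- p + 3
      while (q + 2 <= n) {
        if (codon_at(q) %in% STOP_CODONS) {
          if ((q + 3 - p) / 3 >= min_codons) {
            starts <- c(starts, p - 1L)
            ends <- c(ends, q + 2L)      # 0-based half-open end
          }
          break
        }
        q <- q + 3
      }
    }
  }
  orfs <- data.frame(start = starts, end = ends,
                     n_codons = if (length(starts)) (ends - starts) / 3 else integer(0))
  list(count = nrow(orfs), orfs = orfs)
}

#' Choose one representative transcript per gene
#'
#' With abundances: the most expressed transcript (ties: longest CDS, then
#' lexicographically smallest ID). Without: the best annotation flag
#' (smallest \code{annotation_level} if present), then longest CDS, then ID.
#'
#' @param transcripts data.frame with transcript_id, gene_id, cds (and
#'   optionally annotation_level).
#' @param abundance optional named numeric (by transcript_id), e.g. mean TPM
#'   over the polysomal libraries.
#' @return data.frame with one row per gene.
#' @export
select_representative_transcript <- function(transcripts, abundance = NULL) {
  stopifnot(all(c("transcript_id", "gene_id", "cds") %in% names(transcripts)))
  cds_len <- nchar(transcripts$cds)
  key <- if (!is.null(abundance)) {
    ab <- abundance[transcripts$transcript_id]
    ab[is.na(ab)] <- -Inf
    order(transcripts$gene_id, -ab, -cds_len, transcripts$transcript_id)
  } else if ("annotation_level" %in% names(transcripts)) {
    order(transcripts$gene_id, transcripts$annotation_level, -cds_len,
          transcripts$transcript_id)
  } else {
    order(transcripts$gene_id, -cds_len, transcripts$transcript_id)
  }
  ordered <- transcripts[key, , drop = FALSE]
  ordered[!duplicated(ordered$gene_id), , drop = FALSE]
}

#' Per-transcript sequence and structure features
#'
#' Builds the feature table used to characterise translation-behaviour
#' groups: UTR/CDS lengths, UTR GC content, folding score per base, codon
#' adaptation index, local TOP score, TOP motif flag, uORF count, and an
#' IRES flag taken from a user-supplied gene list.
#'
#' @param transcripts data.frame with gene_id, transcript_id, utr5, cds,
#'   utr3 (e.g. \code{\link{simulate_transcripts}} or
#'   \code{\link{read_transcript_annotation}} output).
#' @param usage_table codon usage for the CAI.
#' @param engine folding engine, see \code{\link{fold_mfe_per_bp}}.
#' @param fold compute folding scores (the slowest feature; default TRUE).
#' @param ires_genes character vector of gene IDs flagged as IRES-containing.
#' @param top_k TOP-motif tract length.
#' @param uorf_min_codons minimum uORF length.
#' @return data.frame of class \code{ptrans_features}, one row per
#'   transcript, with engine and TOP-score version columns.
#' @export
transcript_features <- function(transcripts, usage_table = load_codon_usage(),
                                engine = "nussinov", fold = TRUE,
                                ires_genes = character(), top_k = 5,
                                uorf_min_codons = 3) {
  tr <- transcripts
  n <- nrow(tr)
  cai_v <- numeric(n); stop_flag <- logical(n)
  for (i in seq_len(n)) {
    v <- cai(tr$cds[i], usage_table)
    cai_v[i] <- as.numeric(v)
    stop_flag[i] <- attr(v, "internal_stop")
  }
  uorf <- vapply(tr$utr5, function(u) detect_uorfs(u, uorf_min_codons)$count,
                 numeric(1), USE.NAMES = FALSE)
  out <- data.frame(
    gene_id = tr$gene_id, transcript_id = tr$transcript_id,
    len5 = nchar(tr$utr5), lenCDS = nchar(tr$cds), len3 = nchar(tr$utr3),
    gc5 = gc_content(tr$utr5), gc3 = gc_content(tr$utr3),
    mfe5_bp = if (fold) fold_mfe_per_bp(tr$utr5, engine = engine) else NA_real_,
    mfe3_bp = if (fold) fold_mfe_per_bp(tr$utr3, engine = engine) else NA_real_,
    cai = cai_v, internal_stop = stop_flag,
    top_local_score = as.integer(top_local_score(paste0(tr$utr5, substr(tr$cds, 1, 3)))),
    n_uorf = as.integer(uorf),
    has_top_motif = detect_top_motif(tr$utr5, k = top_k),
    has_ires = tr$gene_id %in% ires_genes,
    engine = if (fold) engine else "none",
    top_score_version = TOP_SCORE_VERSION,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ptrans_features", "data.frame")
  out
}

#' Dunn's post-hoc pairwise test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with the
#' tie correction, and multiplicity adjustment (Holm by default).
#'
#' @param x numeric response.
#' @param g group labels.
#' @param p_adjust adjustment method for the pairwise p-values.
#' @return data.frame(group1, group2, z, p, p_adj).
#' @export
dunn_test <- function(x, g, p_adjust = "holm") {
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(p2) {
    (rbar[[p2[1]]] - rbar[[p2[2]]]) /
      sqrt(v0 * (1 / ns[[p2[1]]] + 1 / ns[[p2[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p.adjust(p, method = p_adjust),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Grouped feature statistics
#'
#' For each numeric feature, a Kruskal-Wallis H test across the groups
#' (tie-corrected, via \code{stats::kruskal.test}) and Dunn's pairwise
#' post-hoc z tests with Holm correction, plus per-group medians. Constant
#' features are reported as NA.
#'
#' @param features a \code{\link{transcript_features}} table.
#' @param groups named vector (by gene_id) of group labels (e.g. cluster or
#'   UP/DOWN/CONTROL).
#' @param feature_cols features to test (default: the numeric feature set).
#' @param p_adjust pairwise adjustment method.
#' @return list(tests, pairwise, medians).
#' @export
feature_group_stats <- function(features, groups,
                                feature_cols = c("len5", "lenCDS", "len3",
                                                 "gc5", "gc3", "mfe5_bp",
                                                 "mfe3_bp", "cai",
                                                 "top_local_score", "n_uorf"),
                                p_adjust = "holm") {
  g <- groups[features$gene_id]
  keep <- !is.na(g)
  if (sum(keep) < 4) stopf("too few genes with group labels")
  g <- factor(g[keep])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stopf("need >= 2 groups with >= 2 members each")
  tests <- data.frame(); pairwise <- data.frame(); medians <- data.frame()
  for (fc in feature_cols) {
    x <- as.numeric(features[[fc]])[keep]
    med <- tapply(x, g, median, na.rm = TRUE)
    medians <- rbind(medians,
                     data.frame(feature = fc, group = names(med),
                                median = as.numeric(med), row.names = NULL))
    if (length(unique(x[is.finite(x)])) < 2) {
      tests <- rbind(tests, data.frame(feature = fc, H = NA_real_,
                                       df = NA_integer_, p = NA_real_))
      next
    }
    kw <- kruskal.test(x, g)
    tests <- rbind(tests, data.frame(feature = fc,
                                     H = unname(kw$statistic),
                                     df = unname(kw$parameter),
                                     p = kw$p.value))
    dn <- dunn_test(x, g, p_adjust = p_adjust)
    dn <- cbind(feature = fc, dn)
    pairwise <- rbind(pairwise, dn)
  }
  list(tests = tests, pairwise = pairwise, medians = medians)
}

#' Overlap of clusters with known TOP-RNA lists
#'
#' Per cluster: how many members are previously reported TOP-RNAs, the
#' fraction of the known list captured, and the remaining (non-reported)
#' members ranked by their local TOP score as candidate new TOP-RNAs.
#'
#' @param cluster_sets named list of gene-ID vectors.
#' @param known_top character vector (union of published TOP-RNA lists).
#' @param scores optional named numeric of \code{\link{top_local_score}}
#'   values used to rank the remaining genes.
#' @return list(summary, candidates).
#' @export
top_rna_overlap <- function(cluster_sets, known_top, scores = NULL) {
  if (!length(known_top)) stopf("known TOP-RNA list is empty")
  summary <- do.call(rbind, lapply(names(cluster_sets), function(nm) {
    cl <- cluster_sets[[nm]]
    k <- length(intersect(cl, known_top))
    data.frame(cluster = nm, n = length(cl), n_known_top = k,
               frac_of_known = k / length(unique(known_top)),
               frac_of_cluster = if (length(cl)) k / length(cl) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  candidates <- lapply(cluster_sets, function(cl) {
    rest <- setdiff(cl, known_top)
    if (!is.null(scores)) rest <- rest[order(-scores[rest], rest)]
    rest
  })
  list(summary = summary, candidates = candidates)
}
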