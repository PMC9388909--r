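#' Default cluster specification for planted translation behaviours
#'
#' Six behaviours of differential translation between sucrose-gradient
#' fractions, given as per-fraction log2 fold-changes (high vs low glucose)
#' for monosomes, light and heavy polysomes:
#' \enumerate{
#'   \item shift from monosomes into both polysome pools (73 genes),
#'   \item gain in light and heavy polysomes (90),
#'   \item gain in monosomes and light polysomes (79),
#'   \item loss from light polysomes (37),
#'   \item loss from heavy polysomes (21),
#'   \item shift from monosomes into heavy polysomes only (102).
#' }
#' Clusters 1 and 6 carry a planted 5'TOP tract, clusters 4 and 5 a planted
#' uORF, so feature-level analyses have ground truth too.
#'
#' @param magnitude absolute log2 fold-change used for every non-zero entry.
#' @return data.frame with one row per cluster: \code{cluster},
#'   \code{n_genes}, \code{d_mono}, \code{d_light}, \code{d_heavy},
#'   \code{top_len}, \code{n_uorf}.
#' @export
default_cluster_spec <- function(magnitude = 1.2) {
  m <- magnitude
  data.frame(
    cluster = 1:6,
    n_genes = c(73L, 90L, 79L, 37L, 21L, 102L),
    d_mono  = c(-m, 0,  m,  0,  0, -m),
    d_light = c( m, m,  m, -m,  0,  0),
    d_heavy = c( m, m,  0,  0, -m,  m),
    top_len = c(8L, 0L, 0L, 0L, 0L, 8L),
    n_uorf  = c(0L, 0L, 0L, 1L, 1L, 0L)
  )
}

#' Default transcript-architecture distributions
#'
#' Lengths are drawn log-normally around typical human mRNA dimensions
#' (5'UTR ~150 nt, CDS ~400 codons, 3'UTR ~500 nt); UTR base composition is
#' i.i.d. with the given GC targets. A standard deviation of 0 makes the
#' corresponding length exact.
#'
#' @return list of distribution parameters understood by
#'   \code{\link{simulate_transcripts}}.
#' @export
default_transcript_spec <- function() {
  list(utr5_mean = 150, utr5_sdlog = 0.5,
       cds_mean_codons = 400, cds_sdlog = 0.5,
       utr3_mean = 500, utr3_sdlog = 0.6,
       gc5 = 0.60, gc3 = 0.45)
}

#' Build a simulation configuration
#'
#' @param n_genes total number of genes (must cover the cluster spec).
#' @param n_replicates biological replicates per condition (default 3).
#' @param lib_size expected reads per library.
#' @param dispersion negative-binomial dispersion \eqn{\phi \ge 0}
#'   (variance \eqn{\mu + \phi\mu^2}); 0 degenerates to Poisson noise.
#' @param cluster_spec data.frame as \code{\link{default_cluster_spec}};
#'   use a 0-row data.frame for an all-null cohort.
#' @param n_total_deg number of genes whose total-RNA abundance also changes
#'   (default 0: steady-state mRNA levels are condition-invariant).
#' @param total_deg_lfc log2 fold-change applied to those genes' total RNA.
#' @param baseline_sdlog spread (sdlog) of the log-normal baseline expression.
#' @param transcript_spec list as \code{\link{default_transcript_spec}}.
#' @param sequences simulate transcript sequences (default TRUE); FALSE
#'   skips sequence generation (lengths are still drawn) for large
#'   count-only simulations.
#' @param seed RNG seed; all draws derive from it in a documented order
#'   (baseline, lengths, total-RNA DEG choice, counts per library in sample
#'   sheet order, transcripts).
#' @return list of class \code{ptrans_config}.
#' @export
simulation_config <- function(n_genes = 2000, n_replicates = 3, lib_size = 1e6,
                              dispersion = 0.05,
                              cluster_spec = default_cluster_spec(),
                              n_total_deg = 0, total_deg_lfc = 0.7,
                              baseline_sdlog = 1,
                              transcript_spec = default_transcript_spec(),
                              sequences = TRUE, seed = 1L) {
  if (n_genes <= 0 || lib_size <= 0)
    stopf("n_genes and lib_size must be positive")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (n_replicates < 1) stopf("need at least one replicate")
  n_planted <- if (nrow(cluster_spec)) sum(cluster_spec$n_genes) else 0L
  if (n_genes < n_planted)
    stopf("n_genes (%d) smaller than genes demanded by cluster_spec (%d)",
          n_genes, n_planted)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 lib_size = lib_size, dispersion = dispersion,
                 cluster_spec = cluster_spec,
                 n_total_deg = as.integer(n_total_deg),
                 total_deg_lfc = total_deg_lfc,
                 baseline_sdlog = baseline_sdlog,
                 transcript_spec = transcript_spec,
                 sequences = isTRUE(sequences),
                 seed = as.integer(seed)),
            class = "ptrans_config")
}

#' Sample sheet for a full fraction-resolved design
#'
#' Eight library types (total RNA plus monosome, light- and heavy-polysome
#' pools, in low and high glucose), each with \code{n_replicates} replicates.
#'
#' @param n_replicates replicates per library type.
#' @return sample sheet data.frame.
#' @export
full_design_sheet <- function(n_replicates = 3) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      fraction = FRACTIONS, condition = CONDITIONS,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("condition", "fraction", "replicate")]
  grid$sample_id <- paste(grid$condition, grid$fraction, grid$replicate, sep = "_")
  validate_sample_sheet(grid[, c("sample_id", "condition", "fraction", "replicate")])
}

#' Simulate a fraction-resolved polysome-profiling cohort
#'
#' Baseline expression per gene is log-normal; in the high-glucose condition
#' the polysome-fraction means are multiplied by \code{2^delta} for the
#' planted cluster genes, while total-RNA means stay identical between
#' conditions (except for an optional handful of total-RNA DEGs). Counts are
#' negative binomial with variance \eqn{\mu + \phi\mu^2}.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return list of class \code{ptrans_cohort} with elements \code{counts}
#'   (integer matrix), \code{tpm}, \code{lengths}, \code{mu} (expected
#'   counts), \code{sample_sheet}, \code{truth} (per-gene cluster and delta
#'   triple), \code{transcripts} and \code{config}.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "ptrans_config")) stopf("cfg must come from simulation_config()")
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))

  ## stream 1: baseline relative expression
  base <- rlnorm(n, meanlog = 0, sdlog = cfg$baseline_sdlog)
  base_mu <- base / sum(base) * cfg$lib_size

  ## stream 2: per-gene transcript architecture lengths (drawn here so that
  ## count draws are unaffected by transcript details)
  ts <- cfg$transcript_spec
  arch <- draw_architecture(n, ts)

  ## planted truth: first sum(n_genes) genes take the cluster behaviours
  truth <- data.frame(gene_id = gene_ids, cluster = NA_integer_,
                      d_mono = 0, d_light = 0, d_heavy = 0,
                      total_lfc = 0, top_len = 0L, n_uorf = 0L,
                      stringsAsFactors = FALSE)
  cs <- cfg$cluster_spec
  if (!is.null(cs) && nrow(cs)) {
    idx <- 1L
    for (k in seq_len(nrow(cs))) {
      rows <- idx:(idx + cs$n_genes[k] - 1L)
      truth$cluster[rows] <- cs$cluster[k]
      truth$d_mono[rows] <- cs$d_mono[k]
      truth$d_light[rows] <- cs$d_light[k]
      truth$d_heavy[rows] <- cs$d_heavy[k]
      if (!is.null(cs$top_len)) truth$top_len[rows] <- cs$top_len[k]
      if (!is.null(cs$n_uorf)) truth$n_uorf[rows] <- cs$n_uorf[k]
      idx <- idx + cs$n_genes[k]
    }
  }

  ## stream 3: optional total-RNA DEGs among the unplanted genes
  if (cfg$n_total_deg > 0) {
    free <- which(is.na(truth$cluster))
    if (length(free) < cfg$n_total_deg)
      stopf("not enough unplanted genes for n_total_deg")
    chosen <- sample(free, cfg$n_total_deg)
    truth$total_lfc[chosen] <- cfg$total_deg_lfc
  }

  ## stream 4: counts, library by library in sample-sheet order
  sheet <- full_design_sheet(cfg$n_replicates)
  delta <- cbind(total = truth$total_lfc, mono = truth$d_mono,
                 light = truth$d_light, heavy = truth$d_heavy)
  mu <- matrix(0, n, nrow(sheet), dimnames = list(gene_ids, sheet$sample_id))
  counts <- mu
  for (j in seq_len(nrow(sheet))) {
    m <- base_mu
    if (sheet$condition[j] == "high") m <- m * 2^delta[, sheet$fraction[j]]
    mu[, j] <- m
    counts[, j] <- if (cfg$dispersion > 0)
      rnbinom(n, mu = m, size = 1 / cfg$dispersion) else rpois(n, m)
  }
  storage.mode(counts) <- "integer"

  ## stream 5: transcript sequences with planted features
  transcripts <- if (cfg$sequences)
    simulate_transcripts(n = n, transcript_spec = ts, gene_ids = gene_ids,
                         top_len = truth$top_len, n_uorf = truth$n_uorf,
                         lengths = arch)
  else NULL
  lengths <- setNames(arch$utr5 + arch$cds + arch$utr3, gene_ids)

  tpm <- tpm_from_counts(counts, lengths)
  structure(list(counts = counts, tpm = tpm, mu = mu, lengths = lengths,
                 sample_sheet = sheet, truth = truth,
                 transcripts = transcripts, config = cfg),
            class = "ptrans_cohort")
}

#' @export
print.ptrans_cohort <- function(x, ...) {
  cat(sprintf("polysome-profiling cohort: %d genes x %d libraries (%d planted)\n",
              nrow(x$counts), ncol(x$counts), sum(!is.na(x$truth$cluster))))
  invisible(x)
}

## draw integer lengths for utr5 / cds (nt) / utr3 from the spec
draw_architecture <- function(n, ts) {
  draw <- function(mean, sdlog, lo = 1L) {
    if (sdlog == 0) rep(as.integer(round(mean)), n)
    else pmax(lo, as.integer(round(rlnorm(n, log(mean), sdlog))))
  }
  list(utr5 = draw(ts$utr5_mean, ts$utr5_sdlog, lo = 12L),
       cds = 3L * draw(ts$cds_mean_codons, ts$cds_sdlog, lo = 10L),
       utr3 = draw(ts$utr3_mean, ts$utr3_sdlog, lo = 12L))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0))
}

random_seq <- function(len, gc) {
  if (len == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

random_cds <- function(n_codons) {
  sense <- setdiff(all_codons(), STOP_CODONS)
  body <- if (n_codons > 2)
    paste(sample(sense, n_codons - 2, replace = TRUE), collapse = "") else ""
  paste0("ATG", body, sample(STOP_CODONS, 1))
}

## overwrite positions [at, at+len) of seq (1-based 'at') with 'insert'
splice_in <- function(seq, at, insert) {
  paste0(substr(seq, 1, at - 1), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Simulate transcript sequences with planted 5' features
#'
#' Each transcript has a well-formed 5'UTR / CDS / 3'UTR: the CDS starts at
#' ATG, ends at a stop codon and contains no internal in-frame stop. A
#' requested 5'TOP tract (C followed by pyrimidines) is written at position 1
#' of the 5'UTR; requested uORFs (ATG + in-frame stop) are placed fully
#' inside the 5'UTR downstream of the TOP tract.
#'
#' @param n number of transcripts.
#' @param transcript_spec distributions, see \code{\link{default_transcript_spec}}.
#' @param gene_ids optional gene identifiers (one transcript per gene).
#' @param top_len per-transcript TOP-tract length (0 = none), recycled.
#' @param n_uorf per-transcript planted uORF count, recycled.
#' @param lengths optional pre-drawn list(utr5, cds, utr3) of integer vectors.
#' @param uorf_codons codon length (including start and stop) of planted uORFs.
#' @return data.frame of class \code{ptrans_transcripts}: transcript_id,
#'   gene_id, utr5, cds, utr3 plus the true planted feature values.
#' @export
simulate_transcripts <- function(n, transcript_spec = default_transcript_spec(),
                                 gene_ids = sprintf("gene%05d", seq_len(n)),
                                 top_len = 0L, n_uorf = 0L, lengths = NULL,
                                 uorf_codons = 3L) {
  ts <- transcript_spec
  top_len <- rep_len(as.integer(top_len), n)
  n_uorf <- rep_len(as.integer(n_uorf), n)
  if (uorf_codons < 2) stopf("uorf_codons must be >= 2")
  if (is.null(lengths)) lengths <- draw_architecture(n, ts)
  utr5_len <- lengths$utr5; cds_len <- lengths$cds; utr3_len <- lengths$utr3
  if (any(cds_len %% 3 != 0)) stopf("CDS length must be divisible by 3")
  need <- pmax(top_len, 0L) + n_uorf * (3L * uorf_codons + 1L)
  bad <- which(utr5_len < need)
  if (length(bad))
    stopf("5'UTR too short for requested TOP tract/uORFs (first offender: %s, %d nt < %d nt needed)",
          gene_ids[bad[1]], utr5_len[bad[1]], need[bad[1]])

  utr5 <- character(n); cds <- character(n); utr3 <- character(n)
  for (i in seq_len(n)) {
    u5 <- random_seq(utr5_len[i], ts$gc5)
    if (top_len[i] > 0) {
      tract <- paste(sample(PYRIMIDINES, top_len[i], replace = TRUE), collapse = "")
      substr(tract, 1, 1) <- "C"
      u5 <- splice_in(u5, 1L, tract)
    }
    if (n_uorf[i] > 0) {
      ## carve the post-TOP region into equal slots, one uORF per slot
      start0 <- top_len[i] + 1L
      avail <- utr5_len[i] - top_len[i]
      slot <- avail %/% n_uorf[i]
      ulen <- 3L * uorf_codons
      for (k in seq_len(n_uorf[i])) {
        lo <- start0 + (k - 1L) * slot
        hi <- start0 + k * slot - ulen
        at <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1) - 1L else lo
        u5 <- splice_in(u5, at, random_cds(uorf_codons))
      }
    }
    utr5[i] <- u5
    cds[i] <- random_cds(cds_len[i] %/% 3L)
    utr3[i] <- random_seq(utr3_len[i], ts$gc3)
  }
  structure(data.frame(transcript_id = paste0(gene_ids, ".t1"),
                       gene_id = gene_ids, utr5 = utr5, cds = cds, utr3 = utr3,
                       true_top_len = top_len, true_n_uorf = n_uorf,
                       stringsAsFactors = FALSE),
            class = c("ptrans_transcripts", "data.frame"))
}
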