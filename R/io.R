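#' Write a gene x sample matrix as TSV
#'
#' First column \code{gene_id}, then one column per sample.
#'
#' @param x matrix with gene rownames and sample colnames.
#' @param file output path.
#' @export
write_matrix_tsv <- function(x, file) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a gene x sample TSV matrix
#'
#' Accepts LF or CRLF line endings; the first column must be the gene ID.
#'
#' @param file path.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stopf("duplicated gene IDs in %s", file)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a sample sheet TSV
#'
#' @param sample_sheet validated sample sheet.
#' @param file path.
#' @export
write_sample_sheet <- function(sample_sheet, file) {
  write.table(validate_sample_sheet(sample_sheet), file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(file) {
  validate_sample_sheet(read.delim(file, stringsAsFactors = FALSE))
}

#' Read an A254 gradient trace
#'
#' Two-column TSV: position (gradient depth, strictly increasing) and
#' absorbance.
#'
#' @param file path.
#' @return data.frame(position, absorbance).
#' @export
read_trace <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("trace file needs two columns (position, absorbance)")
  names(df)[1:2] <- c("position", "absorbance")
  if (any(diff(df$position) <= 0)) stopf("trace positions must be strictly increasing")
  df[, 1:2]
}

#' Pool 14-fraction tables into monosome/light/heavy pools
#'
#' Sucrose gradients are often collected as 14 fractions; sequencing pools
#' them as monosomes (fractions 5-6), light polysomes (7-9) and heavy
#' polysomes (10-13). This helper sums per-fraction count columns by window.
#'
#' @param counts gene x fraction matrix (one column per gradient fraction).
#' @param fraction_index integer vector giving the gradient fraction number
#'   of each column.
#' @param windows named list of integer vectors (default the pooling above).
#' @return gene x pool matrix.
#' @export
pool_fraction_tables <- function(counts, fraction_index,
                                 windows = list(mono = 5:6, light = 7:9,
                                                heavy = 10:13)) {
  counts <- as.matrix(counts)
  if (length(fraction_index) != ncol(counts))
    stopf("fraction_index must have one entry per column")
  out <- vapply(windows, function(w) {
    sel <- fraction_index %in% w
    if (!any(sel)) stopf("no columns for window %s", paste(range(w), collapse = "-"))
    rowSums(counts[, sel, drop = FALSE])
  }, numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Write transcripts as FASTA + GTF
#'
#' Each transcript becomes its own sequence in the FASTA (so GTF coordinates
#' are 1-based inclusive positions on that sequence, plus strand), annotated
#' with \code{five_prime_utr}, \code{CDS} and \code{three_prime_utr}
#' features carrying \code{gene_id}/\code{transcript_id} attributes.
#'
#' @param transcripts a \code{ptrans_transcripts} data.frame.
#' @param fasta_file,gtf_file output paths.
#' @export
write_transcript_annotation <- function(transcripts, fasta_file, gtf_file) {
  tr <- transcripts
  full <- paste0(tr$utr5, tr$cds, tr$utr3)
  seqs <- Biostrings::DNAStringSet(setNames(full, tr$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_file)
  l5 <- nchar(tr$utr5); lc <- nchar(tr$cds); l3 <- nchar(tr$utr3)
  mk <- function(type, start, end) {
    keep <- end >= start
    GenomicRanges::GRanges(
      seqnames = tr$transcript_id[keep],
      ranges = IRanges::IRanges(start = start[keep], end = end[keep]),
      strand = "+", type = type, source = "polytrans",
      phase = if (type == "CDS") 0L else NA_integer_,
      gene_id = tr$gene_id[keep], transcript_id = tr$transcript_id[keep])
  }
  gr <- c(mk("five_prime_utr", rep(1L, nrow(tr)), l5),
          mk("CDS", l5 + 1L, l5 + lc),
          mk("three_prime_utr", l5 + lc + 1L, l5 + lc + l3))
  gr <- sort(gr)
  rtracklayer::export(gr, gtf_file, format = "gtf")
  invisible(gtf_file)
}

#' Read transcript regions from GTF + FASTA
#'
#' Collects \code{five_prime_utr}, \code{CDS} and \code{three_prime_utr}
#' features per transcript from a GTF (1-based inclusive, standard
#' semantics) and extracts the sequences from the FASTA the coordinates
#' refer to. Minus-strand transcripts are reverse-complemented into
#' transcript orientation, i.e. their 5'UTR is taken from the
#' high-coordinate side.
#'
#' @param gtf_file GTF path.
#' @param fasta_file FASTA of the sequences the GTF coordinates index.
#' @return \code{ptrans_transcripts} data.frame (transcript_id, gene_id,
#'   utr5, cds, utr3).
#' @export
read_transcript_annotation <- function(gtf_file, fasta_file) {
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  genome <- Biostrings::readDNAStringSet(fasta_file)
  names(genome) <- sub("\\s.*$", "", names(genome))
  types <- c(five_prime_utr = "utr5", CDS = "cds", three_prime_utr = "utr3")
  gr <- gr[as.character(gr$type) %in% names(types)]
  if (!length(gr)) stopf("no UTR/CDS features in %s", gtf_file)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stopf("GTF feature(s) without transcript_id")
  piece_seq <- function(g) {
    chr <- as.character(GenomicRanges::seqnames(g))
    if (!chr %in% names(genome)) stopf("sequence '%s' absent from FASTA", chr)
    as.character(Biostrings::subseq(genome[[chr]],
                                    start = GenomicRanges::start(g),
                                    end = GenomicRanges::end(g)))
  }
  tids <- unique(gr$transcript_id)
  rows <- lapply(tids, function(tid) {
    sub <- gr[gr$transcript_id == tid]
    strand <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(strand) > 1) stopf("transcript %s mixes strands", tid)
    parts <- lapply(names(types), function(ty) {
      g <- sub[as.character(sub$type) == ty]
      if (!length(g)) return("")
      g <- g[order(GenomicRanges::start(g))]
      s <- paste(vapply(seq_along(g), function(i) piece_seq(g[i]), character(1)),
                 collapse = "")
      if (strand == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      s
    })
    names(parts) <- unname(types)
    data.frame(transcript_id = tid,
               gene_id = unique(sub$gene_id)[1] %||% tid,
               utr5 = parts$utr5, cds = parts$cds, utr3 = parts$utr3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ptrans_transcripts", "data.frame")
  out
}

#' Write a simulated cohort to disk in the pipeline's interchange formats
#'
#' counts.tsv, tpm.tsv, sample_sheet.tsv, truth.tsv, transcripts.fasta and
#' annotation.gtf under \code{dir}.
#'
#' @param cohort a \code{ptrans_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_matrix_tsv(cohort$tpm, file.path(dir, "tpm.tsv"))
  write_sample_sheet(cohort$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_transcript_annotation(cohort$transcripts,
                              file.path(dir, "transcripts.fasta"),
                              file.path(dir, "annotation.gtf"))
  invisible(dir)
}

#' Write a JSON run manifest
#'
#' Records package and R versions, the seed, a configuration checksum and
#' per-stage gene counts. Content is deterministic for a given run (no
#' timestamps), so reruns with the same configuration are bit-identical.
#'
#' @param file output path.
#' @param config the run configuration (list).
#' @param seed the seed used.
#' @param stages named list of stage statistics.
#' @export
write_manifest <- function(file, config, seed, stages = list()) {
  manifest <- list(
    package = "polytrans",
    package_version = as.character(packageVersion("polytrans")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_checksum = config_checksum(config),
    config = config,
    stages = stages)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
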