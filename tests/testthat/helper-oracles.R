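## Independent brute-force oracles used to validate the package's
## implementations on small instances. These deliberately use naive
## algorithms, not the code paths under test.

## exhaustive non-crossing pairing maximisation (no DP table, plain
## recursion over all structures)
brute_max_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  ch <- strsplit(toupper(seq), "")[[1]]
  pairs_ok <- function(a, b) {
    wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
    gu <- allow_gu && ((a == "G" && b == "T") || (a == "T" && b == "G"))
    wc || gu
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (pairs_ok(ch[i], ch[k])) {
        inner <- if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0L
        outer <- if (k + 1 <= j) rec(k + 1, j) else 0L
        best <- max(best, 1L + inner + outer)
      }
    }
    best
  }
  if (length(ch) < min_loop + 2) return(0L)
  rec(1L, length(ch))
}

## silhouette by direct definition over the pairwise distance matrix
brute_silhouette <- function(M, cl) {
  D <- as.matrix(dist(M))
  n <- nrow(M)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) b <- min(b, mean(D[i, cl == g]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

## BH step-up written from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## upper-tail hypergeometric by summing the pmf written with choose()
brute_hyper_upper <- function(k, set_size, universe_size, query_size) {
  if (k > min(set_size, query_size)) return(0)
  kk <- k:min(set_size, query_size)
  sum(choose(set_size, kk) * choose(universe_size - set_size, query_size - kk)) /
    choose(universe_size, query_size)
}

## uORF scan by explicit triplet loops over all frames
brute_uorf_count <- function(seq, min_codons = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  stops <- c("TAA", "TAG", "TGA")
  count <- 0L
  if (n < 3) return(count)
  for (p in 1:(n - 2)) {
    if (paste(ch[p:(p + 2)], collapse = "") != "ATG") next
    q <- p + 3
    while (q + 2 <= n) {
      codon <- paste(ch[q:(q + 2)], collapse = "")
      if (codon %in% stops) {
        if ((q + 3 - p) / 3 >= min_codons) count <- count + 1L
        break
      }
      q <- q + 3
    }
  }
  count
}

## anchored-window TOP score by double loop over all (start, end) windows
brute_top_score <- function(seq, anchor_max = 5, window = 50) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[seq_len(min(length(ch), window))]
  sc <- ifelse(ch %in% c("C", "T"), 1L, -1L)
  best <- 0L
  for (s in seq_len(min(anchor_max, length(sc)))) {
    for (e in s:length(sc)) best <- max(best, sum(sc[s:e]))
  }
  best
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

## small planted cohort used across tests
make_small_cohort <- function(seed = 42, n_genes = 400, clusters = NULL,
                              sequences = FALSE, dispersion = 0.05) {
  if (is.null(clusters)) {
    clusters <- default_cluster_spec()
    clusters$n_genes <- c(15L, 15L, 15L, 10L, 10L, 15L)
  }
  simulate_cohort(simulation_config(
    n_genes = n_genes, cluster_spec = clusters, dispersion = dispersion,
    sequences = sequences, seed = seed))
}
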