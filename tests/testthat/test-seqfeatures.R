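test_that("gc_content handles the stated edge cases and symmetries", {
  expect_equal(gc_content(c("GCGC", "ATAT", "GCAT", "GCATN")),
               c(1, 0, 0.5, 0.5))
  expect_true(is.na(gc_content("NNN")))
  expect_true(is.na(gc_content("")))
  set.seed(3)
  for (s in random_dna(5, 30)) {
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(gc_content(rev_s), gc_content(s))
    comp <- chartr("ACGT", "TGCA", s)
    expect_equal(gc_content(comp), gc_content(s))
  }
})

test_that("Nussinov fallback matches hand counts and exhaustive enumeration", {
  expect_equal(fold_mfe_per_bp("AAAAAAAA"), 0)
  expect_equal(nussinov_pairs("GGGAAAACCC"), 3)
  expect_equal(fold_mfe_per_bp("GGGAAAACCC"), -0.3)
  set.seed(12)
  for (len in c(8, 10, 12)) {
    for (s in random_dna(12, len)) {
      expect_equal(nussinov_pairs(s), brute_max_pairs(s),
                   info = paste("wc+gu", s))
      expect_equal(nussinov_pairs(s, allow_gu = FALSE),
                   brute_max_pairs(s, allow_gu = FALSE),
                   info = paste("wc", s))
    }
  }
  ## WC-only pairing is reverse-complement symmetric
  for (s in random_dna(10, 10)) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(nussinov_pairs(s, allow_gu = FALSE),
                 nussinov_pairs(rc, allow_gu = FALSE))
  }
})

test_that("CAI follows the Sharp-Li convention", {
  ## hand toy: w(GCT)=1, w(GCC)=0.25; ATG and stop excluded
  expect_equal(as.numeric(cai("ATGGCTGCCTAA", c(GCT = 0.8, GCC = 0.2))), 0.5)
  ## uniform usage: every w = 1
  usage <- load_codon_usage()
  uniform <- setNames(rep(1, length(usage)), names(usage))
  expect_equal(as.numeric(cai("ATGGCTAAACGTTGGTAA", uniform)), 1)
  ## a CDS of only maximal-w codons scores 1 under the real table
  w <- polytrans:::cai_weights(usage)
  best <- names(w)[w == 1]
  best <- setdiff(best, c("ATG", "TGG", "TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(best[1:5], collapse = ""), "TAA")
  expect_equal(as.numeric(cai(cds, usage)), 1)
  ## synonymous recoding between equal-w codons leaves CAI unchanged
  eq <- c(GCT = 0.5, GCC = 0.5, AAA = 1)
  expect_equal(as.numeric(cai("ATGGCTAAATAA", eq)),
               as.numeric(cai("ATGGCCAAATAA", eq)))
  ## internal stop: flagged, computed on the codons before it
  v <- cai("ATGGCTTAAGCCTAA", c(GCT = 0.8, GCC = 0.2))
  expect_true(attr(v, "internal_stop"))
  expect_equal(as.numeric(v), 1)   # only GCT (w = 1) before the stop
  expect_error(cai("ATGGC", usage), "divisible")
})

test_that("TOP local score matches the anchored-window definition", {
  expect_equal(as.integer(top_local_score("CTTTTTCCGGGGAAAA")), 8)
  expect_equal(as.integer(top_local_score("GGGGAAAAGGGG")), 0)
  set.seed(14)
  for (s in random_dna(100, 50)) {
    expect_equal(as.integer(top_local_score(s)), brute_top_score(s), info = s)
  }
  ## replacing a purine with a pyrimidine never lowers the score
  for (s in random_dna(10, 50)) {
    ch <- strsplit(s, "")[[1]]
    pur <- which(ch %in% c("A", "G"))
    if (!length(pur)) next
    i <- sample(pur, 1)
    ch[i] <- "C"
    expect_gte(as.integer(top_local_score(paste(ch, collapse = ""))),
               as.integer(top_local_score(s)))
  }
})

test_that("TOP motif flag is the classic C + pyrimidine-run rule", {
  expect_true(detect_top_motif("CTTTTG"))
  expect_false(detect_top_motif("ACTTTT"))
  expect_false(detect_top_motif("CTTAG"))
  expect_false(detect_top_motif("CTT"))
  expect_true(detect_top_motif("CCCCCCC", k = 7))
  ## implication: motif => local score >= k
  set.seed(15)
  for (s in random_dna(200, 30)) {
    if (detect_top_motif(s, k = 5))
      expect_gte(as.integer(top_local_score(s)), 5)
  }
})

test_that("uORF detection matches a six-frame brute-force scan", {
  hit <- detect_uorfs("GGGATGAAATAAGGG")
  expect_equal(hit$count, 1)
  expect_equal(hit$orfs$start, 3)     # 0-based
  expect_equal(hit$orfs$end, 12)      # half-open
  expect_equal(detect_uorfs("CCCCCCCCCCCC")$count, 0)
  ## overlapping starts sharing a stop are counted separately
  expect_equal(detect_uorfs("ATGATGAAACGTTAA", min_codons = 3)$count, 2)
  set.seed(16)
  for (s in random_dna(60, 200)) {
    expect_equal(detect_uorfs(s)$count, brute_uorf_count(s), info = s)
  }
})

test_that("representative transcript selection follows the tie-break chain", {
  tr <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    gene_id = c("gA", "gA", "gA", "gB"),
    cds = c(strrep("ATG", 100), strrep("ATG", 200), strrep("ATG", 200), "ATGTAA"),
    stringsAsFactors = FALSE)
  ## single transcript gene
  expect_identical(select_representative_transcript(tr[4, ])$transcript_id, "t4")
  ## abundance argmax
  ab <- c(t1 = 5, t2 = 10, t3 = 1, t4 = 1)
  expect_identical(
    select_representative_transcript(tr, ab)$transcript_id[1], "t2")
  ## abundance tie -> longest CDS; CDS tie -> lexicographic ID
  ab2 <- c(t1 = 10, t2 = 10, t3 = 10, t4 = 1)
  expect_identical(
    select_representative_transcript(tr, ab2)$transcript_id[1], "t2")
  ## annotation flag path
  tr$annotation_level <- c(2, 1, 3, 1)
  expect_identical(
    select_representative_transcript(tr)$transcript_id[1], "t2")
})

test_that("feature table carries planted features and engine metadata", {
  set.seed(20)
  tr <- simulate_transcripts(12, top_len = c(rep(8L, 6), rep(0L, 6)),
                             n_uorf = c(rep(0L, 6), rep(2L, 6)))
  ft <- transcript_features(tr, fold = FALSE)
  expect_true(all(ft$has_top_motif[1:6]))
  expect_true(all(ft$n_uorf[7:12] >= 2))
  expect_true(all(ft$top_local_score[1:6] >= 5))
  expect_identical(unique(ft$top_score_version), "anchored-kadane-1")
  ft2 <- transcript_features(tr[1:3, ], fold = TRUE)
  expect_true(all(ft2$mfe5_bp <= 0))
  expect_true(all(ft2$mfe3_bp <= 0))
  expect_true(all(ft2$cai > 0 & ft2$cai <= 1))
})

test_that("group statistics: Kruskal-Wallis/Dunn behave under null and shift", {
  set.seed(22)
  ## two-group identity: H equals the squared standardised rank statistic
  x <- c(rnorm(12), rnorm(12))   # continuous -> tie-free
  g <- rep(c("a", "b"), each = 12)
  H <- kruskal.test(x, factor(g))$statistic
  z <- dunn_test(x, g)$z
  expect_equal(unname(H), z^2, tolerance = 1e-10)
  ## strong shift: Dunn p tiny
  y <- c(rnorm(30), rnorm(30, mean = 5))
  gy <- rep(c("lo", "hi"), each = 30)
  expect_lt(dunn_test(y, gy)$p, 1e-6)
  ## permutation null: H p-values approximately uniform
  feat <- rnorm(36)
  ps <- replicate(400, {
    kruskal.test(feat, factor(sample(rep(1:3, each = 12))))$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("feature_group_stats reports tests, pairwise z and medians", {
  set.seed(23)
  ft <- data.frame(gene_id = sprintf("g%02d", 1:30),
                   len5 = c(rnorm(15, 100, 5), rnorm(15, 300, 5)),
                   cai = runif(30, 0.6, 0.9),
                   constant = rep(1, 30))
  groups <- setNames(rep(c("up", "down"), each = 15), ft$gene_id)
  st <- feature_group_stats(ft, groups, feature_cols = c("len5", "cai", "constant"))
  expect_lt(st$tests$p[st$tests$feature == "len5"], 1e-5)
  expect_true(is.na(st$tests$H[st$tests$feature == "constant"]))
  expect_equal(nrow(st$pairwise[st$pairwise$feature == "len5", ]), 1)
  med <- st$medians[st$medians$feature == "len5", ]
  expect_equal(sort(med$group), c("down", "up"))
  expect_error(feature_group_stats(ft, groups[1:2]), "too few")
})

test_that("TOP-RNA overlap report counts known and candidate genes", {
  clusters <- list(c1 = c("a", "b", "c", "d"), c6 = c("e", "f"))
  known <- c("a", "b", "e", "z")
  scores <- setNames(c(9, 2, 7, 1, 5, 0), c("a", "b", "c", "d", "e", "f"))
  ov <- top_rna_overlap(clusters, known, scores)
  expect_equal(ov$summary$n_known_top, c(2L, 1L))
  expect_equal(ov$summary$frac_of_known, c(0.5, 0.25))
  expect_identical(ov$candidates$c1, c("c", "d"))   # ranked by score
  full <- top_rna_overlap(list(x = known), known)
  expect_equal(full$summary$frac_of_known, 1)
  expect_error(top_rna_overlap(clusters, character(0)), "empty")
})
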