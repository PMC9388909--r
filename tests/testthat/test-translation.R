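## tiny deterministic TPM fixture: 2 genes, full 8-library design, 1 rep
tiny_tt_fixture <- function(tr_scale = 1) {
  sheet <- full_design_sheet(n_replicates = 1)
  tpm <- matrix(10, nrow = 2, ncol = nrow(sheet),
                dimnames = list(c("g1", "g2"), sheet$sample_id))
  list(tpm = tpm, sheet = sheet)
}

test_that("translation ratio is fraction mean over total mean", {
  fx <- tiny_tt_fixture()
  tpm <- fx$tpm
  tpm["g1", "low_heavy_1"] <- 30      # total stays 10 -> TR = 3
  tt <- translation_ratio(tpm, fx$sheet)
  expect_equal(tt$TR_heavy_low[tt$gene_id == "g1"], 3)
  expect_equal(tt$TR_mono_low[tt$gene_id == "g1"], 1)
  ## linearity: scaling every polysome library x2 doubles TR
  tpm2 <- tpm
  poly <- fx$sheet$sample_id[fx$sheet$fraction != "total"]
  tpm2[, poly] <- tpm2[, poly] * 2
  tt2 <- translation_ratio(tpm2, fx$sheet)
  for (cc in grep("^TR_", names(tt), value = TRUE))
    expect_equal(tt2[[cc]], 2 * tt[[cc]])
})

test_that("translation efficiency has the documented conventions", {
  fx <- tiny_tt_fixture()
  tt <- translation_ratio(fx$tpm, fx$sheet)
  expect_equal(translation_efficiency(tt)$TE, c(0, 0))
  ## A_high = 2 A_low -> TE = +1 (positive = more translated in high glucose)
  tpm <- fx$tpm
  hi_poly <- fx$sheet$sample_id[fx$sheet$condition == "high" &
                                fx$sheet$fraction %in% c("light", "heavy")]
  tpm[, hi_poly] <- tpm[, hi_poly] * 2
  te <- translation_efficiency(translation_ratio(tpm, fx$sheet))$TE
  expect_equal(te, c(1, 1))
  ## swapping condition labels flips the sign
  sheet_sw <- fx$sheet
  sheet_sw$condition <- ifelse(sheet_sw$condition == "low", "high", "low")
  te_sw <- translation_efficiency(translation_ratio(tpm, sheet_sw))$TE
  expect_equal(te_sw, -te)
  ## literal low-minus-high orientation and raw scale
  te_lit <- translation_efficiency(translation_ratio(tpm, fx$sheet),
                                   orientation = "low_over_high")$TE
  expect_equal(te_lit, -te)
  te_raw <- translation_efficiency(translation_ratio(tpm, fx$sheet),
                                   scale = "raw")$TE
  expect_equal(te_raw, c(1, 1))   # A_high - A_low = 2 - 1
})

test_that("TE classification uses the three fixed cuts and partitions genes", {
  te <- c(0.6, -0.3, 0.005, 0.2, 0.5, -0.25, -0.01, NA)
  g <- classify_translation_groups(te)
  expect_identical(as.character(g),
                   c("UP", "DOWN", "CONTROL", "UNCLASSIFIED", "UP", "DOWN",
                     "CONTROL", "UNCLASSIFIED"))
  expect_false(anyNA(g))   # labels are exhaustive
})

test_that("top-translated ranking matches brute force on a toy table", {
  set.seed(6)
  n <- 20
  tt <- data.frame(gene_id = sprintf("g%02d", 1:n),
                   TR_light_low = runif(n), TR_heavy_low = runif(n),
                   TR_light_high = runif(n), TR_heavy_high = runif(n))
  rk <- rank_top_translated(tt, n = 10)
  brute_top <- function(l, h, n) {
    s <- pmax(l, h)
    tt$gene_id[order(-s, tt$gene_id)][1:n]
  }
  expect_identical(rk$top_low, brute_top(tt$TR_light_low, tt$TR_heavy_low, 10))
  expect_identical(rk$top_high, brute_top(tt$TR_light_high, tt$TR_heavy_high, 10))
  expect_identical(rk$overlap, intersect(rk$top_low, rk$top_high))
  ## identical tables: full overlap, no rank shifts
  tt2 <- tt
  tt2$TR_light_high <- tt$TR_light_low; tt2$TR_heavy_high <- tt$TR_heavy_low
  rk2 <- rank_top_translated(tt2, n = 10)
  expect_length(rk2$overlap, 10)
  expect_true(all(rk2$rank_shift$abs_shift == 0))
  ## a gene boosted to rank 1 tops the rank-shift list
  tt3 <- tt2
  tt3$TR_heavy_high[tt3$gene_id == rk2$rank_shift$gene_id[20]] <- 100
  worst <- rank_top_translated(tt3, n = 10)$rank_shift$gene_id[1]
  expect_identical(worst, rk2$rank_shift$gene_id[20])
  expect_warning(rank_top_translated(tt, n = 50), "truncating")
})

test_that("polysome/monosome ratio integrates the trace correctly", {
  ## rectangular peaks: 80S area 1 (height 1 x width 1), polysomes area 2
  pos <- c(0, 1, 1.999, 2, 3, 3.999, 4, 6, 6.001, 7)
  abs254 <- c(0, 0, 0, 1, 1, 0, 0, 1, 0, 0)
  pos <- seq(0, 10, by = 0.01)
  abs254 <- numeric(length(pos))
  abs254[pos >= 2 & pos <= 3] <- 1          # 80S peak, area 1
  abs254[pos >= 5 & pos <= 7] <- 1          # polysomes, area 2
  r <- polysome_monosome_ratio(pos, abs254, mono_window = c(1.5, 3.5),
                               poly_window = c(4.5, 7.5), baseline = "none")
  expect_equal(as.numeric(r), 2, tolerance = 0.02)
  ## uniform scaling leaves the ratio unchanged (zero baseline)
  r2 <- polysome_monosome_ratio(pos, 5 * abs254, mono_window = c(1.5, 3.5),
                                poly_window = c(4.5, 7.5), baseline = "none")
  expect_equal(as.numeric(r2), as.numeric(r))
  ## constant offset removed by the min-baseline rule
  r3 <- polysome_monosome_ratio(pos, abs254 + 0.3, mono_window = c(1.5, 3.5),
                                poly_window = c(4.5, 7.5), baseline = "min")
  expect_equal(as.numeric(r3), as.numeric(r))
  ## triangular peaks against the analytic areas
  tri <- pmax(0, 1 - abs(pos - 2)) + pmax(0, 2 - abs(pos - 6))
  rt <- polysome_monosome_ratio(pos, tri, mono_window = c(1, 3),
                                poly_window = c(4, 8), baseline = "none")
  expect_equal(as.numeric(rt), 4 / 1, tolerance = 0.01)
  expect_error(polysome_monosome_ratio(pos, 0 * pos, c(1, 3), c(4, 8)),
               "zero")
  expect_error(polysome_monosome_ratio(rev(pos), abs254, c(1, 3), c(4, 8)),
               "increasing")
})

test_that("log-ratio matrix matches closed forms and recovers planted deltas", {
  fx <- tiny_tt_fixture()
  tpm <- fx$tpm
  tpm["g1", "high_heavy_1"] <- 80; tpm["g1", "low_heavy_1"] <- 20
  lr <- build_log_ratio_matrix(tpm, fx$sheet)
  expect_equal(lr["g1", "heavy"], 2)
  expect_equal(lr["g2", "heavy"], 0)
  expect_equal(lr["g1", "mono"], 0)

  ## planted delta triples recovered within +/-0.15 (phi = 0.05, n = 3)
  cl <- data.frame(cluster = 1L, n_genes = 20L, d_mono = -1, d_light = 1,
                   d_heavy = 1, top_len = 0L, n_uorf = 0L)
  coh <- make_small_cohort(seed = 17, n_genes = 2000, clusters = cl)
  lrm <- build_log_ratio_matrix(coh$tpm, coh$sample_sheet)
  planted <- coh$truth$gene_id[!is.na(coh$truth$cluster)]
  dev <- sweep(lrm[planted, c("mono", "light", "heavy")], 2, c(-1, 1, 1))
  expect_lt(max(abs(colMeans(dev))), 0.15)
})
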