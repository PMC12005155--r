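test_that("V-plot places single fragments at the oriented offset", {
  anchor_p <- data.frame(chrom = "chrT", pos = 1000L, strand = "+",
                         gene_id = "g1", role = "+1")
  anchor_m <- transform(anchor_p, strand = "-")
  f0 <- data.frame(chrom = "chrT", start = 927L, end = 1074L, length = 147L,
                   strand = ".")
  expect_equal(unname(vplot_argmax(build_vplot(f0, anchor_p))), c(0, 147))
  expect_equal(unname(vplot_argmax(build_vplot(f0, anchor_m))), c(0, 147))
  f10 <- data.frame(chrom = "chrT", start = 937L, end = 1084L, length = 147L,
                    strand = ".")
  expect_equal(unname(vplot_argmax(build_vplot(f10, anchor_p))), c(10, 147))
  expect_equal(unname(vplot_argmax(build_vplot(f10, anchor_m))), c(-10, 147))
})

test_that("V-plot counts every (fragment, anchor) pair in the window once", {
  gm <- tiny_genome(10)
  fs <- sim_frags(gm, "WT", n = 5000, seed = 31)
  anch <- dyad_anchors(gm, 1:5)
  max_off <- 200L
  vp <- build_vplot(fs, anch, max_offset = max_off)
  mids <- fragment_midpoint(fs)
  pairs <- 0L
  keep <- fs$length >= 35 & fs$length <= 170
  for (i in seq_len(nrow(anch)))
    pairs <- pairs + sum(abs(mids[keep] - anch$pos[i]) <= max_off &
                         fs$chrom[keep] == anch$chrom[i])
  expect_equal(sum(vp), pairs)
})

test_that("negating anchor strands reflects the V-plot offset axis", {
  gm <- tiny_genome(10)
  fs <- sim_frags(gm, "WT", n = 5000, seed = 32)
  anch <- dyad_anchors(gm, 1:5)
  flip <- transform(anch, strand = ifelse(strand == "+", "-", "+"))
  vp <- build_vplot(fs, anch, max_offset = 100)
  vf <- build_vplot(fs, flip, max_offset = 100)
  expect_equal(unclass(vf), unclass(vp)[nrow(vp):1, ], ignore_attr = TRUE)
})

test_that("V-plot offset marginal equals the un-normalized midpoint metagene", {
  gm <- tiny_genome(10)
  fs <- sim_frags(gm, "WT", n = 20000, seed = 33)
  # interior anchors only, so the profile drops nobody
  anch <- dyad_anchors(gm, 2:4)
  flank <- 150L
  vp <- build_vplot(fs, anch, max_offset = flank, length_range = c(35, 170))
  pr <- metagene_profile(filter_by_length(fs, length_bin(35, 170)), anch,
                         gm$chrom_sizes, flank = flank, mode = "midpoint",
                         norm_factor = 1)
  expect_equal(unname(rowSums(vp)), pr$value * nrow(anch))
})

test_that("single-anchor metagene equals the locus coverage slice", {
  f <- data.frame(chrom = "chrT", start = c(90L, 120L), end = c(140L, 190L),
                  length = c(50L, 70L), strand = ".")
  sizes <- c(chrT = 400L)
  anchor <- data.frame(chrom = "chrT", pos = 120L, strand = "+",
                       gene_id = "g1", role = "TSS")
  pr <- metagene_profile(f, anchor, sizes, flank = 50, norm_factor = 1)
  tr <- fragment_coverage(f, sizes, norm_factor = 1)
  expect_equal(pr$value, tr$values$chrT[(120 - 50 + 1):(120 + 50 + 1)])
  # minus-strand anchor reverses the slice
  anchor$strand <- "-"
  prm <- metagene_profile(f, anchor, sizes, flank = 50, norm_factor = 1)
  expect_equal(prm$value, rev(pr$value))
  expect_error(metagene_profile(f, anchor[0, ], sizes), "empty anchor")
})

test_that("gene-body coverage shows phased nucleosome peaks at the array spacing", {
  gm <- generate_genome(80, seed = 9, spacing_bp = 165)
  fs <- sim_frags(gm, "WT", n = 4e5, seed = 34)
  anch <- dyad_anchors(gm, 1L)
  pr <- metagene_profile(fs, anch, gm$chrom_sizes, flank = 600,
                         bin = length_bin(80, 170), norm_factor = 1)
  # smooth away the 10-bp rotational ripple, keep the nucleosome phasing
  sm <- as.numeric(stats::filter(pr$value, rep(1 / 31, 31)))
  downstream <- sm[pr$offset >= 0 & !is.na(sm)]
  n <- length(downstream)
  loc_max <- which(c(FALSE, downstream[2:(n - 1)] > downstream[1:(n - 2)] &
                     downstream[2:(n - 1)] >= downstream[3:n], FALSE) &
                   downstream > 0.5 * max(downstream))
  spacing <- diff(loc_max)
  expect_equal(median(spacing), 165, tolerance = 0.02)
})

test_that("NDR short-fragment peak is dose-dependently lost in K192N", {
  gm <- generate_genome(80, seed = 9)
  anch <- dyad_anchors(gm, 1L)
  peak <- function(preset, dose, seed) {
    fs <- sim_frags(gm, preset, n = 1e5, seed = seed, mnase_dose = dose)
    pr <- metagene_profile(fs, anch, gm$chrom_sizes, flank = 400,
                           bin = length_bin(0, 60),
                           norm_factor = normalization_factor(nrow(fs)))
    max(pr$value[pr$offset >= -300 & pr$offset <= 0])
  }
  expect_gt(peak("WT", "high", 41) / peak("K192N", "high", 42), 3)
  expect_lt(peak("WT", "low", 43) / peak("K192N", "low", 44), 1.5)
})

test_that("occupancy heatmaps rank genes by length and subtract cleanly", {
  gm <- tiny_genome(12)
  fs <- sim_frags(gm, "WT", n = 3e4, seed = 51)
  hm <- occupancy_heatmap(fs, gm, bin = length_bin(80, 170), flank = 300)
  expect_equal(nrow(hm), nrow(gm$genes))
  lens <- attr(hm, "gene_length")
  expect_true(all(diff(lens) <= 0))
  # identical matrices difference to zero
  d0 <- difference_matrix(hm, hm)
  expect_true(all(d0 == 0))
  expect_error(difference_matrix(hm, hm[, 1:10]), "not congruent")
})

test_that("K192N-minus-WT difference heatmap is negative upstream of +1", {
  gm <- generate_genome(60, seed = 9)
  wt <- sim_frags(gm, "WT", n = 2e5, seed = 61)
  mu <- sim_frags(gm, "K192N", n = 2e5, seed = 62)
  nf <- 1
  hw <- occupancy_heatmap(wt, gm, bin = length_bin(0, 60), flank = 300,
                          norm_factor = nf)
  hm <- occupancy_heatmap(mu, gm, bin = length_bin(0, 60), flank = 300,
                          norm_factor = nf)
  dd <- difference_matrix(hm, hw)
  ndr_cols <- as.numeric(colnames(hw)) >= -250 & as.numeric(colnames(hw)) <= -50
  # the NDR band loses occupancy in nearly every gene row
  row_means <- rowMeans(dd[, ndr_cols])
  expect_gt(mean(row_means < 0), 0.9)
  expect_lt(sum(dd[, ndr_cols]), 0)
})
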