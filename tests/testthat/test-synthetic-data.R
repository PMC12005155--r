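test_that("generated genome has canonical promoter/array geometry", {
  gm <- generate_genome(1, seed = 7, spacing_bp = 165, ndr_width_bp = 140)
  d <- gm$dyads
  g <- gm$genes
  s <- if (g$strand == "+") 1L else -1L
  expect_equal(d$pos[d$index == 1], g$tss + s * 60L)
  expect_equal(d$pos[d$index == 2], d$pos[d$index == 1] + s * 165L)
  # NDR footprints sit between the -1 and +1 dyads
  lohi <- range(d$pos[d$index %in% c(-1L, 1L)])
  expect_true(all(gm$ndr$center > lohi[1] & gm$ndr$center < lohi[2]))
})

test_that("length quartiles of a 400-gene genome are exactly equal", {
  gm <- generate_genome(400, seed = 1)
  q <- stratify_by_length(gm$genes)
  expect_equal(unname(table(q$quartile)), rep(100L, 4L),
               ignore_attr = TRUE)
})

test_that("different seeds move coordinates but preserve invariants", {
  gm1 <- generate_genome(40, seed = 1)
  gm2 <- generate_genome(40, seed = 2)
  expect_false(identical(gm1$genes$tss, gm2$genes$tss))
  # validate_genome() ran inside the constructor for both; indices per gene
  # are consecutive from +1 in both
  for (gm in list(gm1, gm2)) {
    idx <- split(gm$dyads$index[gm$dyads$index > 0], gm$dyads$gene_id[gm$dyads$index > 0])
    expect_true(all(vapply(idx, function(i) all(sort(i) == seq_along(i)),
                           logical(1))))
  }
  expect_true(all(c("+", "-") %in% gm1$genes$strand))
  expect_error(generate_genome(0), "n_genes")
})

test_that("digestion is deterministic and conserves the class mixture", {
  gm <- tiny_genome()
  a <- sim_frags(gm, "WT", n = 20000, seed = 5)
  b <- sim_frags(gm, "WT", n = 20000, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sim_frags(gm, "WT", n = 20000, seed = 6)
  expect_false(identical(a$start, c$start))
  # realized class counts within 3 sigma of the multinomial expectation
  w <- mutant_presets("WT")$class_weights
  counts <- table(factor(a$class, levels = names(w)))
  expectation <- 20000 * w
  sigma <- sqrt(20000 * w * (1 - w))
  expect_true(all(abs(counts - expectation) <= 3 * sigma))
})

test_that("zero-shift full-protection params reproduce WT exactly", {
  gm <- tiny_genome()
  wt <- sim_frags(gm, "WT", n = 5000, seed = 9)
  same <- simulate_digestion(gm, condition_params(
    ndr_protection_scale = 1, shift_magnitude_bp = numeric(10)),
    5000, seed = 9, sample_id = "WT")
  expect_identical(as.data.frame(wt), as.data.frame(same))
})

test_that("all fragments lie within chromosome bounds with positive length", {
  gm <- tiny_genome()
  for (preset in c("WT", "K192N", "141-305")) {
    fs <- sim_frags(gm, preset, n = 10000, seed = 3)
    expect_true(all(fs$start >= 0))
    expect_true(all(fs$end <= gm$chrom_sizes[fs$chrom]))
    expect_true(all(fs$length >= 1))
    expect_equal(fs$length, fs$end - fs$start)
  }
})

test_that("mutant presets encode the strain phenotypes", {
  wt <- mutant_presets("WT")
  expect_true(all(wt$shift_magnitude_bp == 0))
  expect_equal(wt$ndr_protection_scale, 1)
  k <- mutant_presets("K192N")
  expect_false(k$five_prime_shift_enabled)
  expect_lt(k$ndr_protection_scale, 0.5)
  expect_true(all(k$shift_magnitude_bp[1:2] == 0))
  expect_true(all(k$shift_magnitude_bp[3:10] > 0))
  d <- mutant_presets("141-305")
  expect_true(d$five_prime_shift_enabled)
  expect_equal(d$ndr_protection_scale, 1)
  expect_true(all(d$shift_magnitude_bp > 0))
  # body shifts stronger than in K192N
  expect_true(all(d$shift_magnitude_bp[3:10] >= k$shift_magnitude_bp[3:10]))
  expect_error(mutant_presets("nope"), "unknown preset")
})

test_that("condition parameters are validated", {
  expect_error(condition_params(class_weights = c(
    nucleosome = 0.5, hexasome = 0.2, tetrasome = 0.1, ndr_short = 0.1,
    background = 0.2)), "sum to 1")
  expect_error(condition_params(ndr_protection_scale = 1.2), "\\[0, 1\\]")
  expect_error(condition_params(linker_rate_ratio = 0.5), "exceed 1")
})

test_that("strand orientation is symmetric between + and - genes", {
  gm <- generate_genome(60, seed = 11)
  fs <- sim_frags(gm, "WT", n = 2e5, seed = 21)
  anch <- dyad_anchors(gm, 1:6)
  plus <- build_vplot(fs, anch[anch$strand == "+", ], max_offset = 100)
  minus <- build_vplot(fs, anch[anch$strand == "-", ], max_offset = 100)
  expect_equal(unname(vplot_argmax(plus)), c(0, 147))
  expect_equal(unname(vplot_argmax(minus)), c(0, 147))
  # oriented offset marginals agree closely between strands
  p <- rowSums(plus) / sum(plus)
  m <- rowSums(minus) / sum(minus)
  expect_gt(stats::cor(p, m), 0.98)
})

test_that("simulated cuts respect the linker:core rate model", {
  gm <- tiny_genome(40)
  cuts <- simulate_cuts(gm, 2e5, seed = 4, linker_rate_ratio = 25)
  est <- estimate_cut_rate_ratio(cuts, gm)
  expect_gt(est, 25 * 0.85)
  expect_lt(est, 25 * 1.15)
  # a different ratio is recovered too (the estimator is not anchored to 25)
  cuts8 <- simulate_cuts(gm, 2e5, seed = 4, linker_rate_ratio = 8)
  est8 <- estimate_cut_rate_ratio(cuts8, gm)
  expect_gt(est8, 8 * 0.85)
  expect_lt(est8, 8 * 1.15)
})

test_that("genome and fragment writers emit well-formed BED", {
  gm <- tiny_genome(5)
  dir <- withr::local_tempdir()
  paths <- write_genome_tracks(gm, dir)
  expect_true(all(file.exists(paths)))
  dy <- read.table(paths["dyads"], sep = "\t")
  expect_equal(nrow(dy), nrow(gm$dyads))
  expect_true(all(dy$V3 - dy$V2 == 1L))
})
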