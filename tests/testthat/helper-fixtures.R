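# Shared fixtures, built in code at test time.

tiny_genome <- function(n_genes = 20L, seed = 7L, ...) {
  generate_genome(n_genes, seed = seed, ...)
}

sim_frags <- function(gm, preset = "WT", n = 5e4, seed = 101L, ...) {
  simulate_digestion(gm, mutant_presets(preset, ...), n, seed = seed,
                     sample_id = preset)
}

# uniform random fragments on a bare chromosome, for coverage oracles
random_frags <- function(n, chrom_size = 5000L, seed = 1L,
                         len_range = c(30L, 160L)) {
  set.seed(seed)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- sample.int(chrom_size - max(len), n, replace = TRUE) - 1L
  structure(data.frame(chrom = "chrT", start = start, end = start + len,
                       length = len, strand = ".",
                       stringsAsFactors = FALSE),
            sample_id = "rand", seed = seed,
            class = c("fragment_set", "data.frame"))
}

# z-score tables for a fragment set, nucleosome-length midpoints
zscore_table <- function(fs, gm, bin = length_bin(142, 152),
                         indices = 1:10) {
  tr <- midpoint_coverage(fs, gm$chrom_sizes, 1, bin)
  zscore_rows(rotational_occupancy(tr, dyad_anchors(gm, indices)))
}
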