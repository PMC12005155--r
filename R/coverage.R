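#' Depth-normalization factor
#'
#' Coverage is scaled by `N = constant / total mapped reads` so that tracks
#' from libraries of different depths are comparable. The default constant,
#' 139,712,364, is arbitrary and only sets the overall scale.
#'
#' @param total_mapped_reads positive count of mapped reads in the library.
#' @param constant the scale constant.
#' @return The dimensionless factor `constant / total_mapped_reads`.
#' @examples
#' normalization_factor(139712364) # 1
#' @export
normalization_factor <- function(total_mapped_reads, constant = 139712364) {
  if (length(total_mapped_reads) != 1L || !is.finite(total_mapped_reads) ||
      total_mapped_reads < 1)
    stop("`total_mapped_reads` must be a single positive count")
  constant / total_mapped_reads
}

#' Construct a fragment-length bin
#'
#' Bins are inclusive on both ends: a fragment of length L belongs to the
#' bin when `min_len <= L <= max_len`. The conventional bins are 0-60
#' (non-nucleosomal NDR footprints), 61-71 (tetrasome), 83-93 and 102-112
#' (hexasome), 142-152 (nucleosome) and 80-170 (all nucleosome-scale
#' protections).
#'
#' @param min_len,max_len inclusive bounds (bp).
#' @param label optional display label; defaults to `"min-max"`.
#' @return A `length_bin` object.
#' @export
length_bin <- function(min_len, max_len, label = NULL) {
  if (min_len > max_len) stop("`min_len` must be <= `max_len`")
  if (max_len < 1) stop("bin must admit positive lengths")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 label = label %||% sprintf("%d-%d", min_len, max_len)),
            class = "length_bin")
}

#' Filter fragments by length bin
#'
#' @param frags a `fragment_set` or data.frame with a `length` column.
#' @param bin a [length_bin()].
#' @return The fragments whose length falls inside the bin (inclusive).
#' @export
filter_by_length <- function(frags, bin) {
  stopifnot(inherits(bin, "length_bin"))
  out <- frags[frags$length >= bin$min_len & frags$length <= bin$max_len, ,
               drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("sample_id", "seed")] <-
    attributes(frags)[c("sample_id", "seed")]
  class(out) <- class(frags)
  out
}

new_coverage_track <- function(values, bin, norm_factor) {
  structure(list(values = values, bin = bin, norm_factor = norm_factor),
            class = "coverage_track")
}

#' Normalized per-bp fragment coverage
#'
#' Every fragment adds `norm_factor` to each 1-bp window it overlaps, so the
#' genome-wide sum equals `norm_factor * sum(lengths)`.
#'
#' @param frags fragments (pre-filter with [filter_by_length()] or pass
#'   `bin`).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param norm_factor per-read weight, see [normalization_factor()].
#' @param bin optional [length_bin()] applied before accumulation.
#' @return A `coverage_track`: per-chrom numeric vectors (element i is the
#'   0-based position i-1), plus the bin and factor used.
#' @export
fragment_coverage <- function(frags, chrom_sizes, norm_factor = 1,
                              bin = NULL) {
  if (!is.null(bin)) frags <- filter_by_length(frags, bin)
  check_bounds(frags, chrom_sizes)
  values <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]]
    f <- frags[frags$chrom == ch, , drop = FALSE]
    delta <- numeric(n + 1L)
    if (nrow(f)) {
      add <- tabulate(f$start + 1L, nbins = n + 1L)
      rem <- tabulate(f$end + 1L, nbins = n + 1L)
      delta <- add - rem
    }
    cumsum(delta)[seq_len(n)] * norm_factor
  })
  names(values) <- names(chrom_sizes)
  new_coverage_track(values, bin, norm_factor)
}

#' Normalized fragment-midpoint coverage
#'
#' Each fragment adds `norm_factor` at exactly its midpoint window, so the
#' genome-wide sum equals `norm_factor * n_fragments`.
#'
#' @inheritParams fragment_coverage
#' @return A `coverage_track`.
#' @export
midpoint_coverage <- function(frags, chrom_sizes, norm_factor = 1,
                              bin = NULL) {
  if (!is.null(bin)) frags <- filter_by_length(frags, bin)
  check_bounds(frags, chrom_sizes)
  mids <- fragment_midpoint(frags)
  values <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]]
    m <- mids[frags$chrom == ch]
    tabulate(m + 1L, nbins = n) * norm_factor
  })
  names(values) <- names(chrom_sizes)
  new_coverage_track(values, bin, norm_factor)
}

check_bounds <- function(frags, chrom_sizes) {
  if (any(!frags$chrom %in% names(chrom_sizes)))
    stop("fragments on unknown chromosomes")
  if (any(frags$start < 0 | frags$end > chrom_sizes[frags$chrom]))
    stop("fragment outside chromosome bounds")
  invisible(TRUE)
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$values, sum, numeric(1)))
  cat(sprintf("Coverage track (%s, N = %g): %d chrom(s), total signal %g\n",
              if (is.null(x$bin)) "all lengths" else x$bin$label,
              x$norm_factor, length(x$values), tot))
  invisible(x)
}

#' Match fragment-length distributions across samples by subsampling
#'
#' For every fragment length L, each output sample retains exactly
#' `min(count of L across samples)` fragments of that length, drawn
#' uniformly without replacement. After matching, the per-length histograms
#' of all samples are identical, removing digestion-extent differences
#' before cross-sample comparison. Deterministic given `seed`.
#'
#' @param samples list of >= 2 `fragment_set` objects.
#' @param seed integer seed.
#' @return List of subsampled `fragment_set` objects, same order and names.
#' @export
match_length_distributions <- function(samples, seed = 1L) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need at least two samples")
  if (any(vapply(samples, nrow, integer(1)) == 0L))
    stop("empty sample")
  set.seed(as.integer(seed))
  all_len <- sort(unique(unlist(lapply(samples, function(s) s$length))))
  counts <- vapply(samples, function(s)
    tabulate(match(s$length, all_len), nbins = length(all_len)),
    integer(length(all_len)))
  counts <- matrix(counts, nrow = length(all_len))
  target <- apply(counts, 1L, min)
  lapply(samples, function(s) {
    keep <- unlist(lapply(seq_along(all_len), function(i) {
      idx <- which(s$length == all_len[i])
      if (target[i] == 0L) return(integer(0))
      if (length(idx) == target[i]) idx else sample(idx, target[i])
    }))
    out <- s[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    attributes(out)[c("sample_id", "seed")] <-
      attributes(s)[c("sample_id", "seed")]
    class(out) <- class(s)
    out
  })
}
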