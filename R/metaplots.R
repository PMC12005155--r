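#' Anchor sets for dyad- or TSS-centred analyses
#'
#' An anchor set is a data.frame with columns chrom, pos (0-based bp),
#' strand, gene_id and role. Offsets relative to an anchor are always
#' strand-oriented: downstream of the gene is positive.
#'
#' @param genome a `genome_model`.
#' @param indices nucleosome indices to select (e.g. `1L` for the +1 dyads,
#'   `1:10` for the full array; `-1L` selects the -1 dyads).
#' @return An anchor data.frame.
#' @export
dyad_anchors <- function(genome, indices = 1:10) {
  stopifnot(inherits(genome, "genome_model"))
  d <- genome$dyads[genome$dyads$index %in% indices, , drop = FALSE]
  data.frame(chrom = d$chrom, pos = d$pos, strand = d$strand,
             gene_id = d$gene_id, role = sprintf("%+d", d$index),
             index = d$index, stringsAsFactors = FALSE)
}

#' @rdname dyad_anchors
#' @export
tss_anchors <- function(genome) {
  g <- genome$genes
  data.frame(chrom = g$chrom, pos = g$tss, strand = g$strand,
             gene_id = g$gene_id, role = "TSS", index = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Build a V-plot (fragment midpoint vs fragment length)
#'
#' For every (fragment, anchor) pair in which the strand-oriented midpoint
#' offset is within `max_offset`, the matrix cell at (offset, length) is
#' incremented. A fragment near several anchors contributes once per anchor
#' (anchor-centric counting, the metagene convention). The checkered pattern
#' of a V-plot around nucleosome dyads reflects rotational positioning at
#' 10-bp intervals; the cell (0, 147) carries the canonical dyad signal.
#'
#' @param frags a `fragment_set`.
#' @param anchors an anchor data.frame (see [dyad_anchors()]).
#' @param max_offset half-width of the offset axis (bp, default 500).
#' @param length_range inclusive fragment-length range kept (default 35-170).
#' @return A `vplot_matrix`: integer matrix with one row per offset
#'   (-max_offset..max_offset) and one column per length, with attributes
#'   `n_anchors` and `normalized`.
#' @export
build_vplot <- function(frags, anchors, max_offset = 500L,
                        length_range = c(35L, 170L)) {
  if (nrow(anchors) == 0L) stop("empty anchor set")
  keep <- frags$length >= length_range[1] & frags$length <= length_range[2]
  f <- frags[keep, , drop = FALSE]
  mids <- fragment_midpoint(f)
  offsets <- seq(-max_offset, max_offset)
  lengths <- seq(length_range[1], length_range[2])
  counts <- matrix(0L, nrow = length(offsets), ncol = length(lengths),
                   dimnames = list(offset = offsets, length = lengths))
  for (ch in unique(anchors$chrom)) {
    on_ch <- which(f$chrom == ch)
    ord <- on_ch[order(mids[on_ch])]
    m <- mids[ord]
    len <- f$length[ord]
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    lo <- findInterval(a$pos - max_offset - 0.5, m) + 1L
    hi <- findInterval(a$pos + max_offset + 0.5, m)
    n_pair <- pmax(hi - lo + 1L, 0L)
    sel <- which(n_pair > 0L)
    if (!length(sel)) next
    frag_idx <- sequence(n_pair[sel]) + rep(lo[sel] - 1L, n_pair[sel])
    anc_idx <- rep(sel, n_pair[sel])
    sgn <- ifelse(a$strand[anc_idx] == "+", 1L, -1L)
    off <- sgn * (m[frag_idx] - a$pos[anc_idx])
    cell <- (off + max_offset) + (len[frag_idx] - length_range[1]) *
      length(offsets) + 1L
    acc <- tabulate(cell, nbins = length(offsets) * length(lengths))
    counts <- counts + matrix(acc, nrow = length(offsets))
  }
  dimnames(counts) <- list(offset = offsets, length = lengths)
  structure(counts, n_anchors = nrow(anchors), normalized = FALSE,
            class = c("vplot_matrix", "matrix"))
}

#' Locate the maximal-density cell of a V-plot
#'
#' @param vp a `vplot_matrix`.
#' @return Named numeric vector `c(offset=, length=)` of the global argmax.
#' @export
vplot_argmax <- function(vp) {
  ij <- arrayInd(which.max(vp), dim(vp))
  c(offset = as.numeric(rownames(vp)[ij[1]]),
    length = as.numeric(colnames(vp)[ij[2]]))
}

#' @export
print.vplot_matrix <- function(x, ...) {
  am <- vplot_argmax(x)
  cat(sprintf("V-plot: offsets %s..%s x lengths %s..%s, %d anchors, %d pairs\n",
              rownames(x)[1], rownames(x)[nrow(x)],
              colnames(x)[1], colnames(x)[ncol(x)],
              attr(x, "n_anchors"), sum(x)))
  cat(sprintf("  maximal density at offset %g, length %g bp\n",
              am["offset"], am["length"]))
  invisible(x)
}

#' @export
plot.vplot_matrix <- function(x, main = "V-plot", ...) {
  offs <- as.numeric(rownames(x))
  lens <- as.numeric(colnames(x))
  graphics::image(offs, lens, unclass(x)^0.25,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "midpoint offset from anchor (bp)",
                  ylab = "fragment length (bp)", main = main, ...)
  invisible(x)
}

#' Metagene profile around anchors
#'
#' Mean normalized coverage across anchors at each strand-oriented offset in
#' `[-flank, +flank]`. Coverage may be whole-fragment overlap coverage or
#' midpoint coverage.
#'
#' @param frags a `fragment_set`.
#' @param anchors anchor data.frame.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param flank half-window (bp, default 1000).
#' @param bin optional [length_bin()].
#' @param mode `"overlap"` (whole-fragment coverage) or `"midpoint"`.
#' @param norm_factor per-read weight.
#' @return A `metagene_profile` data.frame with columns `offset`, `value`.
#' @export
metagene_profile <- function(frags, anchors, chrom_sizes, flank = 1000L,
                             bin = NULL, mode = c("overlap", "midpoint"),
                             norm_factor = 1) {
  mode <- match.arg(mode)
  if (nrow(anchors) == 0L) stop("empty anchor set")
  track <- if (mode == "overlap")
    fragment_coverage(frags, chrom_sizes, norm_factor, bin)
  else midpoint_coverage(frags, chrom_sizes, norm_factor, bin)
  prof <- anchor_profile_matrix(track, anchors, flank)
  structure(data.frame(offset = seq(-flank, flank),
                       value = colMeans(prof)),
            n_anchors = nrow(prof), bin = bin, mode = mode,
            class = c("metagene_profile", "data.frame"))
}

# matrix of strand-oriented coverage slices, one row per usable anchor
anchor_profile_matrix <- function(track, anchors, flank) {
  values <- track$values
  sz <- vapply(values, length, integer(1))
  usable <- anchors$pos - flank >= 0 &
    anchors$pos + flank < sz[anchors$chrom]
  if (!all(usable)) {
    message(sum(!usable), " anchor(s) too close to a chromosome edge; dropped")
    anchors <- anchors[usable, , drop = FALSE]
  }
  if (nrow(anchors) == 0L) stop("no usable anchors")
  w <- 2L * flank + 1L
  prof <- matrix(0, nrow = nrow(anchors), ncol = w)
  for (i in seq_len(nrow(anchors))) {
    v <- values[[anchors$chrom[i]]][(anchors$pos[i] - flank + 1L):
                                    (anchors$pos[i] + flank + 1L)]
    prof[i, ] <- if (anchors$strand[i] == "-") rev(v) else v
  }
  rownames(prof) <- anchors$gene_id
  prof
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$offset, x$value, type = "l",
                 xlab = "offset from anchor (bp)",
                 ylab = "mean normalized coverage", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Per-gene occupancy heatmap anchored at the +1 dyad
#'
#' One row per gene: normalized coverage over strand-oriented offsets from
#' the +1 nucleosome dyad, rows ordered by descending gene length (ties by
#' gene id). Genes lacking a +1 dyad are dropped with a message.
#'
#' @param frags a `fragment_set`.
#' @param genome a `genome_model`.
#' @param bin optional [length_bin()].
#' @param flank half-window (bp).
#' @param norm_factor per-read weight.
#' @param mode `"overlap"` or `"midpoint"` coverage.
#' @return An `occupancy_heatmap` matrix (genes x offsets) with attributes
#'   `gene_length` and `bin`.
#' @export
occupancy_heatmap <- function(frags, genome, bin = NULL, flank = 1000L,
                              norm_factor = 1,
                              mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  anchors <- dyad_anchors(genome, indices = 1L)
  missing_plus1 <- setdiff(genome$genes$gene_id, anchors$gene_id)
  if (length(missing_plus1))
    message(length(missing_plus1), " gene(s) lack a +1 dyad; dropped")
  track <- if (mode == "overlap")
    fragment_coverage(frags, genome$chrom_sizes, norm_factor, bin)
  else midpoint_coverage(frags, genome$chrom_sizes, norm_factor, bin)
  prof <- anchor_profile_matrix(track, anchors, flank)
  g <- genome$genes[match(rownames(prof), genome$genes$gene_id), ]
  ord <- order(-g$length, g$gene_id)
  mat <- prof[ord, , drop = FALSE]
  colnames(mat) <- seq(-flank, flank)
  structure(mat, gene_length = g$length[ord], bin = bin,
            class = c("occupancy_heatmap", "matrix"))
}

#' Difference matrix (mutant minus wild type)
#'
#' Elementwise `mutant - wt` for two congruent matrices (V-plots or
#' occupancy heatmaps). Negative values mark occupancy lost in the mutant,
#' positive values occupancy gained; a nucleosome-positioning shift appears
#' as paired negative/positive stripes.
#'
#' @param mutant,wt matrices with identical dimensions and dimnames.
#' @return Matrix of differences, preserving the input class and attributes.
#' @export
difference_matrix <- function(mutant, wt) {
  if (!identical(dim(mutant), dim(wt)))
    stop("matrices are not congruent")
  if (!is.null(dimnames(mutant)) && !is.null(dimnames(wt)) &&
      !identical(dimnames(mutant), dimnames(wt)))
    stop("matrix axes do not match")
  out <- unclass(mutant) - unclass(wt)
  attributes(out)[setdiff(names(attributes(mutant)), c("dim", "dimnames"))] <-
    attributes(mutant)[setdiff(names(attributes(mutant)), c("dim", "dimnames"))]
  out
}

#' @export
plot.occupancy_heatmap <- function(x, main = NULL, ...) {
  m <- unclass(x)
  lim <- max(abs(range(m)))
  graphics::image(as.numeric(colnames(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "offset from +1 dyad (bp)",
                  ylab = "genes (ranked by length)",
                  main = main %||% "occupancy", ...)
  invisible(x)
}

#' Write a matrix as TSV with row/column headers
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param row_label name of the leading header column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path, row_label = "row") {
  df <- data.frame(rownames(mat), unclass(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(row_label, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
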