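#' Rotational-position occupancy around nucleosome dyads
#'
#' For every (gene, nucleosome index) dyad, sums fragment-midpoint coverage
#' at the eleven rotational positions -50, -40, ..., +40, +50 bp
#' (strand-oriented; downstream positive), collecting signal within
#' `halfwidth` bp of each position to tolerate digestion jitter. Rotational
#' positions are alternative nucleosome placements ~10 bp apart that
#' preserve the helical orientation of the DNA on the histone surface.
#'
#' @param track a midpoint `coverage_track` built from the fragment-length
#'   bin of interest (e.g. 142-152 bp for nucleosomes).
#' @param dyads an anchor data.frame from [dyad_anchors()].
#' @param halfwidth collection half-window per rotational position (bp).
#' @return A `rotational_table` at stage `"occupancy"`: list with `keys`
#'   (gene_id, index) and `values` (matrix, one row per dyad, columns the
#'   eleven rotational positions).
#' @export
rotational_occupancy <- function(track, dyads, halfwidth = 2L) {
  stopifnot(inherits(track, "coverage_track"))
  positions <- seq(-50L, 50L, by = 10L)
  sz <- vapply(track$values, length, integer(1))
  usable <- dyads$pos - 50L - halfwidth >= 0 &
    dyads$pos + 50L + halfwidth < sz[dyads$chrom]
  if (!all(usable)) {
    message(sum(!usable), " dyad(s) too close to a chromosome edge; dropped")
    dyads <- dyads[usable, , drop = FALSE]
  }
  vals <- matrix(0, nrow = nrow(dyads), ncol = length(positions),
                 dimnames = list(NULL, positions))
  cs <- lapply(track$values, function(v) c(0, cumsum(v)))
  sgn <- ifelse(dyads$strand == "+", 1L, -1L)
  for (j in seq_along(positions)) {
    p <- dyads$pos + sgn * positions[j]
    lo <- p - halfwidth          # 0-based inclusive
    hi <- p + halfwidth
    for (ch in unique(dyads$chrom)) {
      i <- which(dyads$chrom == ch)
      vals[i, j] <- cs[[ch]][hi[i] + 2L] - cs[[ch]][lo[i] + 1L]
    }
  }
  structure(list(keys = data.frame(gene_id = dyads$gene_id,
                                   index = dyads$index,
                                   stringsAsFactors = FALSE),
                 values = vals, stage = "occupancy"),
            class = "rotational_table")
}

#' Row-standardize a rotational table to Z-scores
#'
#' Each dyad's eleven occupancy values are standardized to mean 0 and
#' (population) standard deviation 1. Positive Z-scores denote preferred
#' rotational positions within one nucleosome position of one gene. Rows
#' with zero variance map to all-zero.
#'
#' @param table a `rotational_table` at stage `"occupancy"`.
#' @return The table at stage `"zscore"`.
#' @export
zscore_rows <- function(table) {
  stopifnot(inherits(table, "rotational_table"))
  if (table$stage != "occupancy")
    stop("input must be at stage \"occupancy\"")
  v <- table$values
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans((v - mu)^2))
  z <- (v - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  structure(list(keys = table$keys, values = z, stage = "zscore"),
            class = "rotational_table")
}

#' Per-gene Z-score differences (mutant minus wild type)
#'
#' Subtracts wild-type Z-scores from mutant Z-scores for each (gene,
#' nucleosome index) present in both tables; mismatched keys are dropped
#' with a message.
#'
#' @param mutant,wt `rotational_table`s at stage `"zscore"`.
#' @return A `rotational_table` at stage `"delta_z"`.
#' @export
delta_z <- function(mutant, wt) {
  stopifnot(inherits(mutant, "rotational_table"),
            inherits(wt, "rotational_table"))
  if (mutant$stage != "zscore" || wt$stage != "zscore")
    stop("both inputs must be at stage \"zscore\"")
  km <- paste(mutant$keys$gene_id, mutant$keys$index)
  kw <- paste(wt$keys$gene_id, wt$keys$index)
  common <- intersect(km, kw)
  if (length(common) == 0L) stop("no shared (gene, index) keys")
  dropped <- (length(km) - length(common)) + (length(kw) - length(common))
  if (dropped > 0L) message(dropped, " unmatched dyad entr(ies) dropped")
  im <- match(common, km); iw <- match(common, kw)
  structure(list(keys = mutant$keys[im, , drop = FALSE],
                 values = mutant$values[im, , drop = FALSE] -
                          wt$values[iw, , drop = FALSE],
                 stage = "delta_z"),
            class = "rotational_table")
}

#' @export
print.rotational_table <- function(x, ...) {
  cat(sprintf("Rotational table (stage %s): %d dyads, %d genes, indices %s\n",
              x$stage, nrow(x$values), length(unique(x$keys$gene_id)),
              paste(sort(unique(x$keys$index)), collapse = ",")))
  invisible(x)
}

#' Convert a rotational table to long format
#'
#' @param x a `rotational_table`.
#' @param ... unused.
#' @return data.frame with columns gene_id, index, position, value.
#' @export
as.data.frame.rotational_table <- function(x, ...) {
  pos <- as.integer(colnames(x$values))
  data.frame(gene_id = rep(x$keys$gene_id, times = length(pos)),
             index = rep(x$keys$index, times = length(pos)),
             position = rep(pos, each = nrow(x$values)),
             value = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' Test rotational-position occupancy shifts between conditions
#'
#' At each (nucleosome index, rotational position) cell, compares mutant vs
#' wild-type Z-scores across genes with a two-sided Wilcoxon rank-sum test
#' and reports the median per-gene Z-score difference as the effect size.
#' P-values are Benjamini-Hochberg adjusted across all cells of the
#' comparison. A downstream positioning shift appears as significantly
#' positive median differences downstream of the dyad and negative ones
#' upstream.
#'
#' @param mutant_z,wt_z `rotational_table`s at stage `"zscore"`.
#' @param gene_subset optional character vector restricting the genes used
#'   (e.g. one length quartile).
#' @param alpha significance level on the adjusted p-values.
#' @param min_genes indices with fewer eligible genes are skipped with a
#'   warning.
#' @return A `shift_result` data.frame with columns index, position,
#'   n_genes, median_dz, p_value, p_adj, significant.
#' @export
shift_test <- function(mutant_z, wt_z, gene_subset = NULL, alpha = 0.05,
                       min_genes = 10L) {
  stopifnot(inherits(mutant_z, "rotational_table"),
            inherits(wt_z, "rotational_table"))
  if (mutant_z$stage != "zscore" || wt_z$stage != "zscore")
    stop("both inputs must be at stage \"zscore\"")
  km <- paste(mutant_z$keys$gene_id, mutant_z$keys$index)
  kw <- paste(wt_z$keys$gene_id, wt_z$keys$index)
  common <- intersect(km, kw)
  if (length(common) == 0L) stop("no shared (gene, index) keys")
  im <- match(common, km); iw <- match(common, kw)
  keys <- mutant_z$keys[im, , drop = FALSE]
  mz <- mutant_z$values[im, , drop = FALSE]
  wz <- wt_z$values[iw, , drop = FALSE]
  if (!is.null(gene_subset)) {
    sel <- keys$gene_id %in% gene_subset
    keys <- keys[sel, , drop = FALSE]
    mz <- mz[sel, , drop = FALSE]
    wz <- wz[sel, , drop = FALSE]
  }
  positions <- as.integer(colnames(mz))
  res <- list()
  for (k in sort(unique(keys$index))) {
    if (k < 1L) next
    rows <- which(keys$index == k)
    if (length(rows) < min_genes) {
      warning("index +", k, ": only ", length(rows),
              " gene(s), below the floor of ", min_genes, "; skipped")
      next
    }
    for (j in seq_along(positions)) {
      p <- stats::wilcox.test(mz[rows, j], wz[rows, j], exact = FALSE)$p.value
      res[[length(res) + 1L]] <- data.frame(
        index = k, position = positions[j], n_genes = length(rows),
        median_dz = stats::median(mz[rows, j] - wz[rows, j]),
        p_value = p)
    }
  }
  if (!length(res)) stop("no nucleosome index passed the gene-count floor")
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adj < alpha
  structure(out, alpha = alpha,
            class = c("shift_result", "data.frame"))
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("Rotational-position shift test: %d cells (%d indices x %d positions)\n",
              nrow(x), length(unique(x$index)), length(unique(x$position))))
  cat(sprintf("  significant at BH-adjusted p < %g: %d cells\n",
              attr(x, "alpha"), sum(x$significant)))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  of which downstream (position > 0) with positive shift: %d\n",
                sum(sig$position > 0 & sig$median_dz > 0)))
    cat(sprintf("  of which upstream (position < 0) with negative shift: %d\n",
                sum(sig$position < 0 & sig$median_dz < 0)))
  }
  invisible(x)
}

#' @export
summary.shift_result <- function(object, ...) {
  agg <- stats::aggregate(significant ~ index, data = object, FUN = sum)
  names(agg)[2] <- "n_significant"
  agg$max_abs_median_dz <- vapply(agg$index, function(k)
    max(abs(object$median_dz[object$index == k])), numeric(1))
  agg
}

#' @export
plot.shift_result <- function(x, main = "median ΔZ (mutant - WT)", ...) {
  idx <- sort(unique(x$index))
  pos <- sort(unique(x$position))
  m <- matrix(NA_real_, length(pos), length(idx),
              dimnames = list(pos, idx))
  m[cbind(match(x$position, pos), match(x$index, idx))] <- x$median_dz
  lim <- max(abs(x$median_dz), 1e-12)
  graphics::image(pos, seq_along(idx), m, zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "rotational position (bp)",
                  ylab = "nucleosome index", yaxt = "n", main = main, ...)
  graphics::axis(2, at = seq_along(idx), labels = paste0("+", idx))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig))
    graphics::points(sig$position, match(sig$index, idx), pch = 8, cex = 0.6)
  invisible(x)
}

#' Stratify genes into quartiles
#'
#' Ranks genes by a numeric criterion and splits them into k contiguous
#' groups of equal size (+/- 1), Q1 (lowest) to Qk (highest). Ties are
#' broken by gene id so the assignment is independent of input order.
#'
#' @param genes data.frame with `gene_id` and the ranking column.
#' @param k number of groups (default 4).
#' @return A `gene_stratification` data.frame with columns gene_id,
#'   quartile, plus attribute `criterion`.
#' @export
stratify_by_length <- function(genes, k = 4L) {
  stratify_genes(genes$gene_id, genes$length, k, criterion = "length")
}

#' @rdname stratify_by_length
#' @param gene_id,value parallel vectors of gene ids and ranking values.
#' @param criterion label stored with the result.
#' @export
stratify_genes <- function(gene_id, value, k = 4L, criterion = "value") {
  if (length(gene_id) < k) stop("need at least k genes")
  ord <- order(value, gene_id)
  n <- length(gene_id)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  lab <- rep(paste0("Q", seq_len(k)), times = sizes)
  out <- data.frame(gene_id = gene_id[ord], quartile = lab,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  structure(out, criterion = criterion,
            class = c("gene_stratification", "data.frame"))
}

#' Expression score from per-bp nascent-transcription counts
#'
#' Sums normalized per-bp counts over the strand-oriented window
#' TSS+100 to TSS+200 (inclusive; 101 bp), the early-gene-body window used
#' to rank genes by polymerase occupancy.
#'
#' @param counts named list of per-bp numeric vectors (one per chromosome,
#'   element i is 0-based position i-1).
#' @param genes data.frame with gene_id, chrom, tss, strand.
#' @param from,to window bounds relative to the TSS (oriented).
#' @return Named numeric vector of scores, one per gene.
#' @export
expression_score <- function(counts, genes, from = 100L, to = 200L) {
  vapply(seq_len(nrow(genes)), function(i) {
    v <- counts[[genes$chrom[i]]]
    s <- if (genes$strand[i] == "+") 1L else -1L
    w <- genes$tss[i] + s * (from:to)
    if (any(w < 0 | w >= length(v)))
      stop("expression window outside chromosome for gene ", genes$gene_id[i])
    sum(v[w + 1L])
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(genes$gene_id)
}

#' Aggregate dyad-proximal midpoint profile and peak spacing
#'
#' `dyad_midpoint_profile` sums strand-oriented midpoint coverage over all
#' dyads at 1-bp resolution within `flank` bp; `modal_peak_spacing` calls
#' local maxima on such a profile and returns the most common distance
#' between adjacent peaks — 10 bp when occupancy respects rotational
#' positioning.
#'
#' @param track a midpoint `coverage_track`.
#' @param dyads anchor data.frame.
#' @param flank half-window in bp (default 50).
#' @return `dyad_midpoint_profile`: named numeric vector over offsets
#'   -flank..flank. `modal_peak_spacing`: a single number.
#' @export
dyad_midpoint_profile <- function(track, dyads, flank = 50L) {
  prof <- anchor_profile_matrix(track, dyads, flank)
  stats::setNames(colSums(prof), seq(-flank, flank))
}

#' @rdname dyad_midpoint_profile
#' @param profile named numeric vector as returned by
#'   `dyad_midpoint_profile` (names are offsets).
#' @param min_height peaks below this fraction of the profile maximum are
#'   ignored.
#' @export
modal_peak_spacing <- function(profile, min_height = 0.05) {
  v <- as.numeric(profile)
  off <- as.numeric(names(profile))
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] &
                      v[2:(n - 1)] >= v[3:n], FALSE) &
             v >= min_height * max(v)
  peaks <- off[is_peak]
  if (length(peaks) < 2L) stop("fewer than two peaks found")
  gaps <- diff(peaks)
  as.numeric(names(sort(table(gaps), decreasing = TRUE))[1])
}
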