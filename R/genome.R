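#' Generate a synthetic genome of promoter/gene-body chromatin
#'
#' Builds a toy genome on a single chromosome in which every gene carries the
#' canonical yeast promoter architecture: a nucleosome-depleted region (NDR)
#' flanked by well-positioned -1 and +1 nucleosomes, followed by a regularly
#' spaced array of up to ten nucleosomes (+1..+10) over the gene body. The NDR
#' holds one to three short non-nucleosomal protein footprints. Gene lengths
#' are drawn from a log-normal spanning roughly 0.5--8 kb so that length
#' quartiles are non-degenerate; strands alternate so both orientations are
#' represented.
#'
#' All coordinates are 0-based. A dyad is a single base-pair position; the +1
#' dyad sits 60 bp downstream of the TSS (strand-oriented) and successive
#' dyads are `spacing_bp` apart. The -1 dyad sits upstream of the NDR so that
#' the NDR spans the gap between the -1 and +1 nucleosome cores (a core is
#' dyad +/- 73 bp).
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed; the same seed reproduces the genome exactly.
#' @param spacing_bp distance between adjacent gene-body dyads (>= 147).
#' @param ndr_width_bp width of the nucleosome-depleted region between the
#'   -1 and +1 nucleosome cores.
#' @return An object of class `genome_model`: a list with `chrom_sizes`
#'   (named integer vector), `genes`, `dyads` and `ndr` data frames.
#' @examples
#' gm <- generate_genome(10, seed = 1)
#' gm
#' @export
generate_genome <- function(n_genes, seed = 1L, spacing_bp = 165L,
                            ndr_width_bp = 140L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("`n_genes` must be a single integer >= 1")
  if (spacing_bp < 147) stop("`spacing_bp` must be >= 147")
  if (ndr_width_bp < 40) stop("`ndr_width_bp` must be >= 40")
  n_genes <- as.integer(n_genes)
  spacing_bp <- as.integer(spacing_bp)
  ndr_width_bp <- as.integer(ndr_width_bp)

  set.seed(as.integer(seed))
  chrom <- "chrS"
  margin <- 2000L           # keeps every dyad window clear of chrom edges
  gap <- 700L               # intergenic spacer on top of the promoter region

  lengths <- round(exp(stats::rnorm(n_genes, mean = log(1500), sd = 0.7)))
  lengths <- as.integer(pmin(pmax(lengths, 500L), 8000L))
  strands <- rep_len(c("+", "-"), n_genes)

  promoter_span <- ndr_width_bp + 300L  # room for NDR and -1 nucleosome
  gene_id <- sprintf("g%04d", seq_len(n_genes))

  tss <- integer(n_genes)
  cursor <- margin
  for (i in seq_len(n_genes)) {
    block <- lengths[i] + promoter_span + gap
    if (strands[i] == "+") {
      tss[i] <- cursor + promoter_span
    } else {
      tss[i] <- cursor + promoter_span + lengths[i]
    }
    cursor <- cursor + block
  }
  chrom_size <- cursor + margin

  genes <- data.frame(
    gene_id = gene_id, chrom = chrom, tss = tss,
    strand = strands, length = lengths,
    stringsAsFactors = FALSE
  )

  dyad_list <- vector("list", n_genes)
  ndr_list <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    s <- if (strands[i] == "+") 1L else -1L
    # number of gene-body dyads that fit with a full core inside the gene
    k_max <- (lengths[i] - 60L - 73L) %/% spacing_bp + 1L
    k_max <- max(1L, min(10L, k_max))
    idx <- c(-1L, seq_len(k_max))
    # +1 dyad at TSS+60; -1 dyad upstream so NDR fills the inter-core gap
    off <- ifelse(idx == -1L, -(86L + ndr_width_bp),
                  60L + (idx - 1L) * spacing_bp)
    dyad_list[[i]] <- data.frame(
      gene_id = gene_id[i], chrom = chrom,
      pos = tss[i] + s * off, index = idx, strand = strands[i],
      stringsAsFactors = FALSE
    )
    # NDR spans the gap between the -1 and +1 cores (oriented [-13-ndr, -13])
    ndr_lo <- -13L - ndr_width_bp + 15L
    ndr_hi <- -13L - 15L
    n_fp <- sample(1:3, 1L)
    centers <- tss[i] + s * as.integer(round(stats::runif(n_fp, ndr_lo, ndr_hi)))
    ndr_list[[i]] <- data.frame(
      gene_id = gene_id[i], chrom = chrom, center = centers,
      width = sample(20:50, n_fp, replace = TRUE),
      weight = stats::runif(n_fp, 0.5, 1),
      stringsAsFactors = FALSE
    )
  }

  gm <- structure(list(
    chrom_sizes = stats::setNames(as.integer(chrom_size), chrom),
    genes = genes,
    dyads = do.call(rbind, dyad_list),
    ndr = do.call(rbind, ndr_list)
  ), class = "genome_model")
  validate_genome(gm)
  gm
}

validate_genome <- function(gm) {
  stopifnot(inherits(gm, "genome_model"))
  d <- gm$dyads
  sz <- gm$chrom_sizes[d$chrom]
  if (any(d$pos < 0 | d$pos >= sz))
    stop("dyad positions fall outside chromosome bounds")
  # per gene: dyads strictly ordered along the strand, indices consecutive
  for (g in split(d, d$gene_id)) {
    s <- if (g$strand[1] == "+") 1L else -1L
    body <- g[g$index > 0, ]
    body <- body[order(body$index), ]
    if (!all(body$index == seq_len(nrow(body))))
      stop("gene-body nucleosome indices must be consecutive from +1")
    if (nrow(body) > 1 && any(diff(s * body$pos) <= 0))
      stop("dyads must be strictly ordered along the strand")
  }
  # every NDR footprint lies between its gene's -1 and +1 dyads
  for (i in seq_len(nrow(gm$ndr))) {
    fp <- gm$ndr[i, ]
    g <- d[d$gene_id == fp$gene_id, ]
    lo <- min(g$pos[g$index %in% c(-1L, 1L)])
    hi <- max(g$pos[g$index %in% c(-1L, 1L)])
    if (fp$center <= lo || fp$center >= hi)
      stop("NDR footprint outside the -1/+1 inter-dyad region")
  }
  invisible(gm)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic chromatin genome\n")
  cat(sprintf("  %d chromosome(s), total %s bp\n",
              length(x$chrom_sizes), format(sum(x$chrom_sizes), big.mark = ",")))
  cat(sprintf("  %d genes (length %d-%d bp), %d dyads, %d NDR footprints\n",
              nrow(x$genes), min(x$genes$length), max(x$genes$length),
              nrow(x$dyads), nrow(x$ndr)))
  invisible(x)
}

#' Write genome annotation tracks as BED files
#'
#' Emits three plain-text files: genes as BED6 with the gene length in the
#' score column, dyads as BED6 with name `geneID/+k` and the nucleosome index
#' in the score column, and NDR footprints as BED4.
#'
#' @param gm a `genome_model`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_genome_tracks <- function(gm, dir) {
  stopifnot(inherits(gm, "genome_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- gm$genes
  start <- ifelse(g$strand == "+", g$tss, g$tss - g$length)
  genes_path <- file.path(dir, "genes.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", g$chrom, start,
                     start + g$length, g$gene_id, g$length, g$strand),
             genes_path)
  d <- gm$dyads
  dyads_path <- file.path(dir, "dyads.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s/%+d\t%d\t%s", d$chrom, d$pos,
                     d$pos + 1L, d$gene_id, d$index, d$index, d$strand),
             dyads_path)
  n <- gm$ndr
  ndr_path <- file.path(dir, "ndr.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", n$chrom,
                     n$center - n$width %/% 2L,
                     n$center - n$width %/% 2L + n$width, n$gene_id),
             ndr_path)
  invisible(c(genes = genes_path, dyads = dyads_path, ndr = ndr_path))
}
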