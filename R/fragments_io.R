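#' Apply read-length preprocessing rules
#'
#' Reads longer than 140 bp are truncated to 140 bp and reads shorter than
#' 35 bp are discarded, mirroring the trimming applied to single-stranded
#' MNase libraries before alignment. Input order is preserved and the
#' operation is idempotent.
#'
#' @param reads data.frame with columns `read_id` and `length`
#'   (post-adapter-removal lengths, bp).
#' @param max_len truncation cap (default 140).
#' @param min_len discard threshold; reads with length < `min_len` are
#'   removed (default 35).
#' @return The surviving reads, lengths capped at `max_len`.
#' @examples
#' preprocess_reads(data.frame(read_id = c("a", "b", "c"),
#'                             length = c(160, 34, 100)))
#' @export
preprocess_reads <- function(reads, max_len = 140L, min_len = 35L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "length") %in% names(reads)))
  if (any(reads$length < 0)) stop("read lengths must be non-negative")
  out <- reads[reads$length >= min_len, , drop = FALSE]
  out$length <- pmin(out$length, max_len)
  rownames(out) <- NULL
  out
}

#' Read MNase-protected fragments from a BED file
#'
#' Accepts BED with at least three columns (chrom, start, end; 0-based
#' half-open). A fourth/fifth/sixth column, if present, are kept as name,
#' score and strand. Malformed records are reported with their line numbers.
#'
#' @param path path to a tab-separated BED file.
#' @param genome optional `genome_model`; if supplied, chromosome names and
#'   bounds are validated against it.
#' @return A `fragment_set` data.frame with columns chrom, start, end,
#'   length, strand.
#' @export
read_fragments_bed <- function(path, genome = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = NA, fill = TRUE,
                           col.names = paste0("V", 1:6))
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  start <- suppressWarnings(as.integer(raw$V2))
  end <- suppressWarnings(as.integer(raw$V3))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("malformed BED records (end <= start or non-numeric) at line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (!is.null(genome)) {
    unknown <- which(!(raw$V1 %in% names(genome$chrom_sizes)))
    if (length(unknown))
      stop("unknown chromosome at line(s): ",
           paste(utils::head(unknown, 10L), collapse = ", "))
    oob <- which(end > genome$chrom_sizes[raw$V1] | start < 0)
    if (length(oob))
      stop("fragment outside chromosome bounds at line(s): ",
           paste(utils::head(oob, 10L), collapse = ", "))
  }
  strand <- if (!all(is.na(raw$V6)) && any(nzchar(raw$V6)))
    ifelse(raw$V6 %in% c("+", "-"), raw$V6, ".") else "."
  out <- data.frame(chrom = raw$V1, start = start, end = end,
                    length = end - start, strand = strand,
                    stringsAsFactors = FALSE)
  structure(out, sample_id = if (!all(is.na(raw$V4))) raw$V4[1L] else
              basename(path),
            class = c("fragment_set", "data.frame"))
}

#' Write fragments as 6-column BED
#'
#' Layout: chrom, start, end, sample id (name), fragment length (score),
#' strand. Bit-stable for a fixed input order.
#'
#' @param frags a `fragment_set` or compatible data.frame.
#' @param path output path.
#' @param sample_id name column value; defaults to the set's `sample_id`
#'   attribute.
#' @return Invisibly, `path`.
#' @export
write_fragments_bed <- function(frags, path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- attr(frags, "sample_id") %||% "sample"
  strand <- if ("strand" %in% names(frags)) frags$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", frags$chrom,
                     frags$start, frags$end, sample_id,
                     frags$end - frags$start, strand), path)
  invisible(path)
}

#' Fragment midpoint
#'
#' The midpoint of a 0-based half-open interval, `floor((start + end) / 2)`.
#' Even-length fragments round down; the rule is applied uniformly so
#' relative comparisons are unaffected.
#'
#' @param frags a `fragment_set` or data.frame with `start`/`end` columns.
#' @return Integer vector of midpoint positions (0-based).
#' @examples
#' fragment_midpoint(data.frame(start = 100, end = 247)) # 173
#' @export
fragment_midpoint <- function(frags) {
  as.integer((frags$start + frags$end) %/% 2L)
}

#' Write a per-bp coverage track as bedGraph
#'
#' Runs of equal value are merged into single intervals; values are written
#' with six significant digits.
#'
#' @param track a `coverage_track` (see [fragment_coverage()]) or a named
#'   list of per-bp numeric vectors (element i covers 0-based position i-1).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  values <- if (inherits(track, "coverage_track")) track$values else track
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(values)) {
    v <- values[[chrom]]
    r <- rle(signif(v, 6))
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end,
                       formatC(r$values, digits = 6, format = "g")), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into per-bp vectors
#'
#' @param path bedGraph path.
#' @param chrom_sizes named integer vector of chromosome lengths; intervals
#'   beyond these bounds are an error.
#' @return Named list of per-bp numeric vectors.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  bg <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (any(!bg$chrom %in% names(chrom_sizes)))
    stop("bedGraph contains unknown chromosomes")
  if (any(bg$end > chrom_sizes[bg$chrom] | bg$start < 0))
    stop("bedGraph interval outside chromosome bounds")
  out <- lapply(names(chrom_sizes), function(ch) {
    v <- numeric(chrom_sizes[[ch]])
    sub <- bg[bg$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    v
  })
  names(out) <- names(chrom_sizes)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
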