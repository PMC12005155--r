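#' Simulate MNase digestion of a synthetic genome
#'
#' Draws protected fragments from a five-component mixture over protection
#' classes (nucleosome, hexasome, tetrasome, short NDR footprint,
#' background), placing midpoints at rotational positions spaced 10 bp
#' around annotated dyads and degrading fragment ends with a dose-dependent
#' geometric end-nibbling whose asymmetry jitters the midpoint.
#'
#' Class behaviour:
#' \itemize{
#'   \item nucleosome: length ~ round(Normal(147, 3)) clipped to 142--152 bp
#'     under high dose (140--156, sd 4 under low dose); midpoint at
#'     dyad + rotational offset, offsets multiples of 10 in [-30, +30] with
#'     occupancy weights decaying away from 0.
#'   \item hexasome: length uniform in 102--112 or 83--93 bp (sub-bin chosen
#'     per fragment); midpoint additionally displaced by +/-(147-len)/2,
#'     modelling loss of the proximal or distal H2A-H2B dimer with equal
#'     probability.
#'   \item tetrasome: length uniform in 61--71 bp, same +/-(147-len)/2
#'     displacement rule.
#'   \item ndr_short: lengths 20--60 bp centred on NDR footprints; a draw
#'     survives digestion with probability `ndr_protection_scale` at high
#'     dose, and with probability `scale + (1-scale)*0.95` at low dose
#'     (fragile protections survive gentle digestion). Non-surviving draws
#'     are re-emitted as background so the fragment total is conserved.
#'   \item background: uniform genomic position, length uniform 35--170 bp.
#' }
#'
#' Mutant positioning shift: at every nucleosome index k with nonzero
#' `shift_magnitude_bp[k]` (and k >= 3 unless `five_prime_shift_enabled`),
#' each dyad-anchored fragment moves one 10-bp rotational step downstream
#' (strand-aware) with probability `|magnitude|/10 * coupling(quartile)`,
#' where the coupling is looked up from the owning gene's length quartile.
#'
#' @param genome a `genome_model` from [generate_genome()].
#' @param params a `condition_params` object.
#' @param n_fragments number of fragments to draw (>= 1).
#' @param seed integer master seed; per-class substreams are derived from it
#'   so each class's draws are independent of the other classes' counts.
#' @param sample_id label stored with the output.
#' @return A `fragment_set`: a data.frame with columns chrom, start, end,
#'   length, strand (always "."), class, plus attributes `sample_id` and
#'   `seed`. Coordinates are 0-based half-open.
#' @export
simulate_digestion <- function(genome, params, n_fragments, seed = 1L,
                               sample_id = "sample") {
  stopifnot(inherits(genome, "genome_model"))
  if (!inherits(params, "condition_params"))
    stop("`params` must be a condition_params object")
  if (n_fragments < 1) stop("`n_fragments` must be >= 1")
  if (nrow(genome$genes) == 0L) stop("empty genome")
  if (abs(sum(params$class_weights) - 1) > 1e-8)
    stop("class weights must sum to 1")
  n_fragments <- as.integer(n_fragments)
  seed <- as.integer(seed)

  high <- params$mnase_dose == "high"
  nib_mu <- if (high) 0.7 else 1.4     # mean geometric end-trim, bp
  quart <- stratify_by_length(genome$genes)
  coupling <- params$shift_length_coupling[quart$quartile]
  names(coupling) <- quart$gene_id

  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1L, n_fragments, params$class_weights))
  names(counts) <- names(params$class_weights)

  d <- genome$dyads
  sgn <- ifelse(d$strand == "+", 1L, -1L)
  rot_off <- seq(-30L, 30L, by = 10L)
  rot_w <- params$rotational_weights / sum(params$rotational_weights)

  mid_jitter <- function(n) {
    p <- 1 / (1 + nib_mu)
    as.integer(round((stats::rgeom(n, p) - stats::rgeom(n, p)) / 2))
  }

  # shared placement for the dyad-anchored classes
  place_on_dyads <- function(n, len) {
    i <- sample.int(nrow(d), n, replace = TRUE)
    r <- sample(rot_off, n, replace = TRUE, prob = rot_w)
    idx <- d$index[i]
    mag <- abs(params$shift_magnitude_bp)[pmax(idx, 1L)]
    eligible <- idx >= 1L & mag > 0 &
      (params$five_prime_shift_enabled | idx >= 3L)
    p_shift <- ifelse(eligible,
                      pmin(1, mag / 10 * coupling[d$gene_id[i]]), 0)
    r <- r + 10L * as.integer(stats::runif(n) < p_shift)
    list(i = i, mid = d$pos[i] + sgn[i] * r)
  }

  out <- vector("list", 5L)
  cls <- names(counts)

  ## nucleosome ---------------------------------------------------------
  set.seed(seed + 101L)
  n1 <- counts[["nucleosome"]]
  if (n1 > 0L) {
    pl <- place_on_dyads(n1)
    len <- as.integer(round(stats::rnorm(n1, 147, if (high) 3 else 4)))
    len <- pmin(pmax(len, if (high) 142L else 140L), if (high) 152L else 156L)
    mid <- pl$mid + mid_jitter(n1)
    out[[1L]] <- data.frame(chrom = d$chrom[pl$i], mid = mid, length = len,
                            class = "nucleosome", stringsAsFactors = FALSE)
  }

  ## hexasome -----------------------------------------------------------
  set.seed(seed + 211L)
  n2 <- counts[["hexasome"]]
  if (n2 > 0L) {
    pl <- place_on_dyads(n2)
    hi_bin <- stats::runif(n2) < 0.5
    len <- ifelse(hi_bin, sample(102:112, n2, replace = TRUE),
                  sample(83:93, n2, replace = TRUE))
    disp <- sample(c(-1L, 1L), n2, replace = TRUE) *
      as.integer(round((147L - len) / 2))
    mid <- pl$mid + disp + mid_jitter(n2)
    out[[2L]] <- data.frame(chrom = d$chrom[pl$i], mid = mid,
                            length = as.integer(len), class = "hexasome",
                            stringsAsFactors = FALSE)
  }

  ## tetrasome ----------------------------------------------------------
  set.seed(seed + 307L)
  n3 <- counts[["tetrasome"]]
  if (n3 > 0L) {
    pl <- place_on_dyads(n3)
    len <- sample(61:71, n3, replace = TRUE)
    disp <- sample(c(-1L, 1L), n3, replace = TRUE) *
      as.integer(round((147L - len) / 2))
    mid <- pl$mid + disp + mid_jitter(n3)
    out[[3L]] <- data.frame(chrom = d$chrom[pl$i], mid = mid,
                            length = as.integer(len), class = "tetrasome",
                            stringsAsFactors = FALSE)
  }

  ## ndr_short ----------------------------------------------------------
  set.seed(seed + 401L)
  n4 <- counts[["ndr_short"]]
  n4_lost <- 0L
  if (n4 > 0L) {
    p_surv <- if (high) params$ndr_protection_scale
              else params$ndr_protection_scale +
                   (1 - params$ndr_protection_scale) * 0.95
    keep <- stats::runif(n4) < p_surv
    n_keep <- sum(keep)
    n4_lost <- n4 - n_keep
    if (n_keep > 0L) {
      fp <- sample.int(nrow(genome$ndr), n_keep, replace = TRUE,
                       prob = genome$ndr$weight)
      len <- sample(20:60, n_keep, replace = TRUE)
      mid <- genome$ndr$center[fp] +
        as.integer(round(stats::rnorm(n_keep, 0, genome$ndr$width[fp] / 4)))
      out[[4L]] <- data.frame(chrom = genome$ndr$chrom[fp], mid = mid,
                              length = as.integer(len), class = "ndr_short",
                              stringsAsFactors = FALSE)
    }
  }

  ## background (plus digested-away NDR draws) --------------------------
  set.seed(seed + 503L)
  n5 <- counts[["background"]] + n4_lost
  if (n5 > 0L) {
    chrom <- names(genome$chrom_sizes)[1L]
    size <- genome$chrom_sizes[[1L]]
    pos <- as.integer(floor(stats::runif(n5, 200, size - 400)))
    len <- sample(35:170, n5, replace = TRUE)
    out[[5L]] <- data.frame(chrom = chrom, mid = pos,
                            length = as.integer(len), class = "background",
                            stringsAsFactors = FALSE)
  }

  frags <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  start <- frags$mid - frags$length %/% 2L
  frag_df <- data.frame(
    chrom = frags$chrom,
    start = start,
    end = start + frags$length,
    length = frags$length,
    strand = ".",
    class = frags$class,
    stringsAsFactors = FALSE
  )
  # chrom-bound safety: margins make violations essentially impossible for
  # dyad-anchored classes; clamp background edge cases
  sz <- genome$chrom_sizes[frag_df$chrom]
  bad <- frag_df$start < 0 | frag_df$end > sz
  if (any(bad)) frag_df <- frag_df[!bad, , drop = FALSE]
  rownames(frag_df) <- NULL
  structure(frag_df, sample_id = sample_id, seed = seed,
            class = c("fragment_set", "data.frame"))
}

#' Simulate MNase cut positions on annotated chromatin
#'
#' Models the enzymology directly: MNase cleaves linker DNA at
#' `linker_rate_ratio` times the per-bp rate of nucleosome-protected DNA
#' (dyad +/- 73 bp). Cut positions are drawn in proportion to the per-bp
#' rate of the annotation class they fall in.
#'
#' @param genome a `genome_model`.
#' @param n_cuts number of cut events to draw.
#' @param seed integer seed.
#' @param linker_rate_ratio linker:core per-bp rate ratio (default 25).
#' @return data.frame with columns chrom, pos (0-based), in_core (logical).
#' @seealso [estimate_cut_rate_ratio()] to recover the ratio from cuts.
#' @export
simulate_cuts <- function(genome, n_cuts, seed = 1L, linker_rate_ratio = 25) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_cuts < 1) stop("`n_cuts` must be >= 1")
  if (linker_rate_ratio <= 1) stop("`linker_rate_ratio` must exceed 1")
  set.seed(as.integer(seed))
  cores <- nucleosome_cores(genome)
  chrom <- names(genome$chrom_sizes)[1L]
  size <- genome$chrom_sizes[[1L]]
  core_bp <- sum(cores$end - cores$start)
  linker_bp <- size - core_bp
  # class totals proportional to (rate x footprint); linker rate is the
  # `linker_rate_ratio`-fold one
  p_core <- core_bp / (core_bp + linker_rate_ratio * linker_bp)
  in_core <- stats::runif(n_cuts) < p_core
  pos <- integer(n_cuts)
  n_core <- sum(in_core)
  if (n_core > 0L) {
    widths <- cores$end - cores$start
    iv <- sample.int(nrow(cores), n_core, replace = TRUE, prob = widths)
    pos[in_core] <- cores$start[iv] +
      as.integer(floor(stats::runif(n_core) * widths[iv]))
  }
  n_link <- n_cuts - n_core
  if (n_link > 0L) {
    # rejection-sample uniform genomic positions outside cores
    res <- integer(0)
    while (length(res) < n_link) {
      cand <- as.integer(floor(stats::runif(ceiling(n_link * 1.3), 0, size)))
      cand <- cand[!position_in_core(cand, cores)]
      res <- c(res, cand)
    }
    pos[!in_core] <- res[seq_len(n_link)]
  }
  data.frame(chrom = chrom, pos = pos, in_core = in_core,
             stringsAsFactors = FALSE)
}

#' Estimate the linker:core cleavage-rate ratio from cut positions
#'
#' Classifies each cut by whether it falls in an annotated nucleosome core
#' (dyad +/- 73 bp) and returns the ratio of per-bp cut rates,
#' (cuts/bp in linker) / (cuts/bp in core).
#'
#' @param cuts data.frame with columns chrom, pos (as from [simulate_cuts()]).
#' @param genome the `genome_model` carrying the dyad annotation.
#' @return A single number, the estimated rate ratio.
#' @export
estimate_cut_rate_ratio <- function(cuts, genome) {
  stopifnot(inherits(genome, "genome_model"))
  cores <- nucleosome_cores(genome)
  size <- genome$chrom_sizes[[1L]]
  core_bp <- sum(cores$end - cores$start)
  linker_bp <- size - core_bp
  in_core <- position_in_core(cuts$pos, cores)
  n_core <- sum(in_core)
  if (n_core == 0L) stop("no cuts fall in nucleosome cores; cannot estimate")
  (sum(!in_core) / linker_bp) / (n_core / core_bp)
}

# merged, sorted nucleosome-core intervals (dyad +/- 73), 0-based half-open
nucleosome_cores <- function(genome) {
  d <- genome$dyads
  start <- sort(d$pos - 73L)
  end <- start + 147L
  # merge overlapping/adjacent cores
  keep_s <- integer(0); keep_e <- integer(0)
  cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
           cs <- start[i]; ce <- end[i] }
  }
  data.frame(start = c(keep_s, cs), end = c(keep_e, ce))
}

position_in_core <- function(pos, cores) {
  iv <- findInterval(pos, cores$start)
  iv > 0 & pos < cores$end[pmax(iv, 1L)]
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("Fragment set \"%s\": %d fragments (seed %d)\n",
              attr(x, "sample_id"), nrow(x), attr(x, "seed")))
  cat("  length range: ", min(x$length), "-", max(x$length), " bp\n", sep = "")
  print(table(x$class))
  invisible(x)
}
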