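#' Overlap enrichment of a gene group in a quartile
#'
#' Quantifies whether a gene group (e.g. an expression-change group) is
#' over- or under-represented in one quartile of a stratification.
#' Enrichment is
#' `log2( (|group ∩ quartile| / |group|) / (|quartile| / |universe|) )`;
#' significance comes from the hypergeometric distribution, with the upper
#' tail tested for over-enrichment and the lower tail for depletion (two
#' one-sided tests, both reported, the one matching the sign of the
#' enrichment selected as `p`).
#'
#' @param group character vector of gene ids (non-empty, within universe).
#' @param quartile character vector of gene ids forming the quartile.
#' @param universe background gene set containing both.
#' @return List with `overlap`, `log2_enrichment` (`-Inf` when the overlap
#'   is empty), `p_over`, `p_under`, and `p` (the tail matching the
#'   enrichment sign).
#' @examples
#' u <- sprintf("g%02d", 1:20)
#' overlap_enrichment(u[1:5], u[1:5], u)  # fully inside one quartile of 4
#' @export
overlap_enrichment <- function(group, quartile, universe) {
  group <- unique(group); quartile <- unique(quartile)
  universe <- unique(universe)
  if (length(group) == 0L || length(quartile) == 0L)
    stop("empty group or quartile")
  if (!all(group %in% universe) || !all(quartile %in% universe))
    stop("group and quartile must be subsets of the universe")
  k <- length(intersect(group, quartile))
  m <- length(quartile)                 # "successes" in the urn
  n_u <- length(universe)
  g <- length(group)                    # draws
  enr <- if (k == 0L) -Inf else
    log2((k / g) / (m / n_u))
  p_over <- stats::phyper(k - 1L, m, n_u - m, g, lower.tail = FALSE)
  p_under <- stats::phyper(k, m, n_u - m, g, lower.tail = TRUE)
  list(overlap = k, log2_enrichment = enr,
       p_over = p_over, p_under = p_under,
       p = if (is.infinite(enr) || enr < 0) p_under else p_over)
}

#' Enrichment of gene groups across quartiles
#'
#' Runs [overlap_enrichment()] for every (group, quartile) pair and applies
#' Benjamini-Hochberg correction across all cells of the table. The
#' background universe is the intersection of genes covered by the grouping
#' and by the stratification.
#'
#' @param groups named list of character vectors (gene groups).
#' @param strat a `gene_stratification` (see [stratify_by_length()]).
#' @param universe optional explicit background set (genes eligible for both
#'   the grouping and the stratification); defaults to the stratified genes.
#' @param alpha significance level on adjusted p-values.
#' @return data.frame with columns group, quartile, overlap,
#'   log2_enrichment, p_value, p_adj, significant.
#' @export
enrichment_table <- function(groups, strat, universe = NULL, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            inherits(strat, "gene_stratification"))
  universe <- if (is.null(universe)) strat$gene_id
              else intersect(universe, strat$gene_id)
  quartiles <- lapply(split(strat$gene_id, strat$quartile),
                      intersect, universe)
  rows <- list()
  for (gname in names(groups)) {
    grp <- intersect(groups[[gname]], universe)
    for (qname in names(quartiles)) {
      e <- overlap_enrichment(grp, quartiles[[qname]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, quartile = qname, overlap = e$overlap,
        log2_enrichment = e$log2_enrichment, p_value = e$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adj < alpha
  out
}

#' Label genes into change groups from a per-gene calls table
#'
#' Generic utility to reproduce group definitions of the form "significant
#' in comparison A only", "in A and B", etc. Each unique TRUE/FALSE pattern
#' across the call columns becomes a group; patterns observed in fewer than
#' `min_genes` genes are pooled into `"other"`, and the all-FALSE pattern is
#' dropped.
#'
#' @param calls data.frame whose first column is `gene_id` and remaining
#'   logical columns are significance calls per comparison.
#' @param min_genes patterns smaller than this are pooled (default 20).
#' @return Named list of gene-id vectors, one per group, names of the form
#'   `"A&B"`.
#' @export
group_by_calls <- function(calls, min_genes = 20L) {
  stopifnot(is.data.frame(calls), names(calls)[1] == "gene_id")
  cols <- names(calls)[-1]
  pat <- apply(calls[cols], 1L, function(r)
    paste(cols[as.logical(r)], collapse = "&"))
  keep <- pat != ""
  groups <- split(calls$gene_id[keep], pat[keep])
  small <- names(groups)[vapply(groups, length, integer(1)) < min_genes]
  if (length(small)) {
    pooled <- unlist(groups[small], use.names = FALSE)
    groups <- groups[setdiff(names(groups), small)]
    if (length(pooled)) groups$other <- pooled
  }
  groups
}
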