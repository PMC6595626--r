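#' Fisher's exact over/under-representation of one category
#'
#' Hypergeometric tail probabilities for the overlap between a gene set
#' and an annotation bin within a background universe:
#' `p_over = P(X >= k)`, `p_under = P(X <= k)` with
#' `X ~ Hypergeom(N, K, n)` (universe N, bin K, set n, overlap k).
#'
#' @param setGenes gene set of interest (character).
#' @param binGenes genes annotated to the bin.
#' @param universe background gene universe.
#' @return list: `k`, `n`, `K`, `N`, `fold` (`(k/n)/(K/N)`), `p_over`,
#'   `p_under`.
#' @export
fisherEnrichment <- function(setGenes, binGenes, universe) {
  setGenes <- unique(setGenes); binGenes <- unique(binGenes)
  universe <- unique(universe)
  if (length(setGenes) == 0 || length(universe) == 0)
    stop(germError("empty gene set or universe", "germDataError"))
  if (!all(setGenes %in% universe) || !all(binGenes %in% universe))
    stop(germError("set and bin must be subsets of the universe",
                   "germDataError"))
  k <- length(intersect(setGenes, binGenes))
  n <- length(setGenes); K <- length(binGenes); N <- length(universe)
  list(k = k, n = n, K = K, N = N,
       fold = (k / n) / (K / N),
       p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = phyper(k, K, N - K, n))
}

#' Enrichment of every annotation bin in a gene set
#'
#' One Fisher test per bin against the annotation's gene universe. A bin
#' is significant iff `min(p_over, p_under) <= alpha` (after optional
#' Benjamini-Hochberg adjustment); direction is the smaller tail. No
#' multiple-testing correction is applied by default, matching a raw
#' `p <= 0.05` screening threshold.
#'
#' @param setGenes the gene set (character).
#' @param annotation data.frame with columns `gene_id`, `bin_code` and
#'   optionally `bin_name`; its genes define the universe. Genes listed
#'   under several bins count once per bin.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param setName label for the output's `set` column.
#' @return data.frame: `set`, `bin_code`, `bin_name`, `k`, `n`, `K`,
#'   `N`, `fold`, `p_over`, `p_under`, `direction`, `significant`.
#' @export
enrichAll <- function(setGenes, annotation, alpha = 0.05,
                      adjust = c("none", "BH"), setName = "set") {
  adjust <- match.arg(adjust)
  universe <- unique(annotation$gene_id)
  setGenes <- unique(setGenes)
  if (!all(setGenes %in% universe))
    stop(germError("annotation does not cover the gene set",
                   "germDataError"))
  bins <- unique(annotation$bin_code)
  rows <- lapply(bins, function(b) {
    bg <- annotation$gene_id[annotation$bin_code == b]
    fe <- fisherEnrichment(setGenes, bg, universe)
    nm <- annotation$bin_name[annotation$bin_code == b][1]
    data.frame(set = setName, bin_code = b,
               bin_name = if (is.null(nm)) b else nm,
               k = fe$k, n = fe$n, K = fe$K, N = fe$N, fold = fe$fold,
               p_over = fe$p_over, p_under = fe$p_under,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  po <- out$p_over; pu <- out$p_under
  if (adjust == "BH") {
    po <- p.adjust(po, "BH"); pu <- p.adjust(pu, "BH")
  }
  out$direction <- ifelse(po <= pu, "over", "under")
  out$significant <- pmin(po, pu) <= alpha
  out
}
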