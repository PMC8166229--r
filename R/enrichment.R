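#' Over-representation analysis (hypergeometric)
#'
#' Upper-tail hypergeometric test of each gene set against a query gene
#' list within a fixed universe, with Benjamini-Hochberg adjustment
#' across sets.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]); each
#'   set is intersected with the universe before testing.
#' @param universe Character vector of background genes.
#' @param p_cutoff Significance flag threshold (default 0.05).
#' @return Data frame with `set_name`, `k` (overlap), `K` (set size in
#'   universe), `n` (query size), `N` (universe size), `p_value`,
#'   `p_adjust`, `significant`, sorted by p-value. Empty query gives an
#'   empty result with a warning.
#' @export
ora <- function(query, sets, universe, p_cutoff = 0.05) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  if (length(query) == 0) {
    warning("empty query gene list")
    return(data.frame(set_name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_adjust = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set); k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= p_cutoff
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}

#' Rank-based gene-set enrichment (weighted running sum)
#'
#' Classic weighted Kolmogorov-Smirnov enrichment score: genes are
#' ranked by signed log2 fold change (decreasing); walking down the
#' ranking, hits increment the running sum in proportion to |fold
#' change| weight and misses decrement it uniformly; the enrichment
#' score (ES) is the extremum of the running sum. Significance is by
#' gene-label permutation: the p-value is the fraction of permuted |ES|
#' values of the same sign at least as extreme.
#'
#' @param ranked Data frame with columns `gene` and `stat` (signed
#'   log2 fold change; ranking weight is its absolute value).
#' @param sets Named list of gene sets; sets with no gene in the
#'   ranking are skipped.
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param p_cutoff Significance flag threshold.
#' @return Data frame with `set_name`, `size`, `es`, `p_value`,
#'   `p_adjust`, `direction` (`"up"` for positive ES), `significant`.
#' @export
gsea_lite <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                      p_cutoff = 0.05) {
  stopifnot(all(c("gene", "stat") %in% names(ranked)),
            !any(duplicated(ranked$gene)))
  ord <- order(ranked$stat, decreasing = TRUE)
  genes <- ranked$gene[ord]
  w <- abs(ranked$stat[ord])
  es_for <- function(hit) {
    wh <- sum(w[hit])
    nm <- sum(!hit)
    if (wh == 0) {
      inc <- ifelse(hit, 1 / sum(hit), 0)   # equal weights fallback
    } else {
      inc <- ifelse(hit, w / wh, 0)
    }
    dec <- ifelse(hit, 0, 1 / nm)
    rs <- cumsum(inc - dec)
    rs[which.max(abs(rs))]
  }
  set.seed(seed)
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (length(members) == 0 || length(members) == length(genes)) next
    hit <- genes %in% members
    es <- es_for(hit)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      es_for(sample(hit))
    }, numeric(1))
    same_sign <- perm_es[sign(perm_es) == sign(es) | perm_es == 0]
    p <- (sum(abs(same_sign) >= abs(es)) + 1) / (length(same_sign) + 1)
    rows[[length(rows) + 1L]] <-
      data.frame(set_name = nm, size = length(members), es = es, p_value = p,
                 direction = if (es >= 0) "up" else "down",
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(set_name = character(0), size = integer(0), es = numeric(0),
               p_value = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= p_cutoff
  rownames(out) <- NULL
  out
}
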