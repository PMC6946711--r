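#' Co-abundance network and clusters
#'
#' Builds an undirected taxon network on clr-transformed abundances: taxa
#' `i`, `j` are connected when their Pearson correlation exceeds
#' `rThreshold`, the proportionality statistic
#' `phi(i, j) = var(clr_i - clr_j) / var(clr_i)` (symmetrised by taking the
#' larger of the two directions) is below `phiThreshold`, and the
#' Bonferroni-corrected correlation p-value is below `alpha`. Proportional
#' taxa move together on the log scale, which is the compositionally safe
#' notion of co-abundance. Clusters are the connected components, numbered
#' by decreasing size.
#'
#' @param x clr-mode [CommunityTable-class] with >= 3 samples.
#' @param rThreshold Pearson correlation threshold (default 0.8).
#' @param phiThreshold proportionality threshold (default 0.1).
#' @param alpha cutoff on Bonferroni-corrected correlation p-values.
#' @return list with `edges` (data.frame `taxonA`, `taxonB`, `r`, `phi`,
#'   `pAdjusted`), `clusters` (data.frame `taxon_id`, `cluster`) and the
#'   `igraph` graph.
#' @export
cooccurrenceClusters <- function(x, rThreshold = 0.8, phiThreshold = 0.1,
                                 alpha = 0.001) {
  checkMode(x, "clr", "cooccurrenceClusters")
  m <- abundanceMatrix(x)
  n <- nrow(m)
  if (n < 3L) stop("need >= 3 samples")
  allTaxa <- colnames(m)
  vars <- apply(m, 2L, stats::var)
  constant <- vars < 1e-15
  if (any(constant)) {
    warning(sprintf("excluding %d constant clr column(s) from edge testing",
                    sum(constant)))
    m <- m[, !constant, drop = FALSE]
    vars <- vars[!constant]
  }
  taxa <- colnames(m)
  nt <- length(taxa)
  edges <- NULL
  if (nt >= 2L) {
    r <- stats::cor(m)
    # phi in both directions; an edge requires proportionality whichever
    # taxon is taken as reference, so use the larger (conservative)
    centered <- sweep(m, 2L, colMeans(m))
    cov_ <- crossprod(centered) / (n - 1L)
    vd <- outer(vars, vars, "+") - 2 * cov_  # var(clr_i - clr_j)
    phi <- pmax(vd / vars[row(vd)], vd / vars[col(vd)])
    tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    nPairs <- nt * (nt - 1) / 2
    pAdj <- pmin(1, p * nPairs)
    sel <- which(upper.tri(r) & r > rThreshold & phi < phiThreshold &
                   pAdj < alpha, arr.ind = TRUE)
    if (nrow(sel)) {
      edges <- data.frame(taxonA = taxa[sel[, 1L]], taxonB = taxa[sel[, 2L]],
                          r = r[sel], phi = phi[sel], pAdjusted = pAdj[sel],
                          stringsAsFactors = FALSE)
    }
  }
  if (is.null(edges))
    edges <- data.frame(taxonA = character(0), taxonB = character(0),
                        r = numeric(0), phi = numeric(0),
                        pAdjusted = numeric(0))
  g <- igraph::graph_from_data_frame(
    edges[, c("taxonA", "taxonB")], directed = FALSE,
    vertices = data.frame(name = allTaxa, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  sizeRank <- rank(-comp$csize, ties.method = "first")
  clusters <- data.frame(taxon_id = allTaxa,
                         cluster = as.integer(sizeRank[comp$membership]),
                         stringsAsFactors = FALSE)
  list(edges = edges, clusters = clusters, graph = g)
}
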