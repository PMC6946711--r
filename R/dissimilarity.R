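#' Pairwise community dissimilarity
#'
#' Bray-Curtis and binary Jaccard (via `vegan::vegdist`) require counts or
#' relative abundances; Aitchison distance is Euclidean distance on clr rows
#' and therefore requires a clr-mode table (see [clrTransform()]); plain
#' Euclidean accepts any mode.
#'
#' @param x a [CommunityTable-class].
#' @param metric one of `bray_curtis`, `jaccard_binary`, `aitchison`,
#'   `euclidean`.
#' @return a `dist` with the metric name in its `method` attribute.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
#' pairwiseDissimilarity(communityTable(m), "bray_curtis") # 0.5
#' @export
pairwiseDissimilarity <- function(x, metric = c("bray_curtis",
                                                "jaccard_binary",
                                                "aitchison", "euclidean")) {
  metric <- match.arg(metric)
  m <- abundanceMatrix(x)
  d <- switch(metric,
    bray_curtis = {
      checkMode(x, c("counts", "relative"), "bray_curtis")
      vegan::vegdist(m, method = "bray")
    },
    jaccard_binary = {
      checkMode(x, c("counts", "relative"), "jaccard_binary")
      vegan::vegdist(m, method = "jaccard", binary = TRUE)
    },
    aitchison = {
      checkMode(x, "clr", "aitchison (Euclidean on clr rows)")
      stats::dist(m)
    },
    euclidean = stats::dist(m))
  attr(d, "method") <- metric
  attr(d, "call") <- NULL
  d
}

#' Sorensen partition into turnover and nestedness
#'
#' Presence/absence (binarised at strictly > 0) partition of Sorensen
#' dissimilarity into its richness-free turnover component (Simpson
#' dissimilarity, `bsim`) and the nestedness-resultant component (`bsne`).
#' With `a` shared taxa and `b`, `c` the taxa unique to each sample:
#' `bsim = min(b,c) / (a + min(b,c))`, `bsor = (b+c) / (2a+b+c)`,
#' `bsne = bsor - bsim`. `bsim` is unchanged by taxa added only to the
#' richer sample, which is why it isolates true compositional turnover from
#' richness variation.
#'
#' @param x a [CommunityTable-class] in any mode.
#' @return data.frame with one row per sample pair and columns `sampleA`,
#'   `sampleB`, `bsim`, `bsne`, `bsor`.
#' @export
sorensenPartition <- function(x) {
  pa <- abundanceMatrix(x) > 0
  labels <- sampleIds(x)
  pairs <- samplePairs(labels)
  # shared / unique counts for all pairs at once
  shared <- tcrossprod(pa * 1)           # a
  rich <- rowSums(pa)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$sampleA[k]; j <- pairs$sampleB[k]
    a <- shared[i, j]
    b <- rich[[i]] - a
    c_ <- rich[[j]] - a
    if (a + b + c_ == 0)
      stop(sprintf("both samples empty: %s, %s", i, j))
    bsim <- if (a + min(b, c_) == 0) 0 else min(b, c_) / (a + min(b, c_))
    bsor <- (b + c_) / (2 * a + b + c_)
    c(bsim = bsim, bsne = bsor - bsim, bsor = bsor)
  })
  cbind(pairs, do.call(rbind, res))
}

#' Community Fst (Gst-type differentiation)
#'
#' For each sample pair, with relative abundance vectors `p1`, `p2` and
#' their mean `pbar`: total heterozygosity `H_T = 1 - sum(pbar^2)`, mean
#' within-sample heterozygosity `H_S = mean(1 - sum(p^2))`, and
#' `Fst = (H_T - H_S) / H_T`. Identical communities give 0; two
#' monocultures of different taxa give 1. When `H_T = 0` (both samples the
#' same monoculture) Fst is defined as 0. The `pooled` method replaces the
#' pairwise mean with the grand mean over all samples.
#'
#' @param x counts- or relative-mode [CommunityTable-class].
#' @param method `"pairwise"` (default) or `"pooled"`.
#' @return a `dist` of Fst values in `[0, 1]`.
#' @export
communityFst <- function(x, method = c("pairwise", "pooled")) {
  checkMode(x, c("counts", "relative"), "communityFst")
  method <- match.arg(method)
  m <- abundanceMatrix(x)
  p <- m / rowSums(m)
  n <- nrow(p)
  hWithin <- 1 - rowSums(p * p)
  grand <- colMeans(p)
  hGrand <- 1 - sum(grand * grand)
  out <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      hs <- (hWithin[i] + hWithin[j]) / 2
      ht <- if (method == "pairwise") {
        pbar <- (p[i, ] + p[j, ]) / 2
        1 - sum(pbar * pbar)
      } else hGrand
      fst <- if (ht <= 0) 0 else (ht - hs) / ht
      out[i, j] <- out[j, i] <- min(max(fst, 0), 1)
    }
  }
  asDist(out, paste0("community_fst_", method))
}
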