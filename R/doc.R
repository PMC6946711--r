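# Dissimilarity-overlap curve (DOC) universality analysis.

#' Overlap and shared-taxon dissimilarity for every sample pair
#'
#' For each pair of communities, the overlap is the mean total relative
#' abundance the two samples invest in their shared taxa,
#' `O = sum_{i in S} (a_i + b_i) / 2` with `S` the taxa positive in both.
#' The dissimilarity is the root Jensen-Shannon divergence (natural log) of
#' the two compositions renormalised over `S` only. Pairs with no shared
#' taxon carry no information about shared dynamics and are excluded; the
#' exclusion count is attached as attribute `"excluded"`.
#'
#' @param x relative-mode [CommunityTable-class] with >= 2 samples (see
#'   [transformTable()]).
#' @return data.frame with columns `sampleA`, `sampleB`, `overlap`, `rjsd`;
#'   attribute `"excluded"` counts the dropped zero-overlap pairs. `rjsd`
#'   lies in `[0, sqrt(ln 2)]`.
#' @export
overlapDissimilarityPairs <- function(x) {
  checkMode(x, "relative", "overlapDissimilarityPairs")
  m <- abundanceMatrix(x)
  if (nrow(m) < 2L) stop("need >= 2 samples")
  pairsIdx <- utils::combn(nrow(m), 2L)
  rows <- vector("list", ncol(pairsIdx))
  excluded <- 0L
  for (k in seq_len(ncol(pairsIdx))) {
    i <- pairsIdx[1L, k]; j <- pairsIdx[2L, k]
    a <- m[i, ]; b <- m[j, ]
    S <- a > 0 & b > 0
    if (!any(S)) {
      excluded <- excluded + 1L
      next
    }
    ov <- sum((a[S] + b[S]) / 2)
    ra <- a[S] / sum(a[S]); rb <- b[S] / sum(b[S])
    mid <- (ra + rb) / 2
    kl <- function(p, q) {
      nz <- p > 0
      sum(p[nz] * log(p[nz] / q[nz]))
    }
    jsd <- 0.5 * kl(ra, mid) + 0.5 * kl(rb, mid)
    rows[[k]] <- data.frame(sampleA = rownames(m)[i],
                            sampleB = rownames(m)[j],
                            overlap = ov, rjsd = sqrt(max(0, jsd)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    stop("every sample pair is disjoint; no DOC can be formed")
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# Locally weighted fit of rjsd on overlap; returns the sorted grid, fitted
# values, the start of the terminal negative-slope run (NA when the final
# slope is non-negative), and whether the terminal slope is negative.
docFitOne <- function(overlap, rjsd, span) {
  fit <- stats::lowess(overlap, rjsd, f = span)
  # collapse (near-)tied overlap values, which would otherwise produce
  # spurious near-infinite slopes between floating-point twins
  eps <- 1e-8 * max(diff(range(fit$x)), 1e-12)
  grp <- cumsum(c(TRUE, diff(fit$x) > eps))
  x <- as.numeric(tapply(fit$x, grp, mean))
  y <- as.numeric(tapply(fit$y, grp, mean))
  if (length(x) < 2L) return(list(x = x, y = y, xmin = NA_real_,
                                  negTerminal = FALSE))
  sl <- diff(y) / diff(x)
  nSeg <- length(sl)
  if (sl[nSeg] >= 0)
    return(list(x = x, y = y, xmin = NA_real_, negTerminal = FALSE))
  first <- nSeg
  while (first > 1L && sl[first - 1L] < 0) first <- first - 1L
  list(x = x, y = y, xmin = x[first], negTerminal = TRUE)
}

#' Fit a dissimilarity-overlap curve with bootstrap change point
#'
#' Smooths the pair cloud with locally weighted regression (lowess), then
#' bootstraps at the *sample* level (resampling samples with replacement and
#' rebuilding the pair set, which respects the non-independence of pairs
#' sharing a sample). For each bootstrap curve the change point is the
#' smallest overlap from which the fitted slope stays negative through the
#' maximum overlap; the reported change point `xmin` is the median over
#' bootstrap curves. `Fns` is the fraction of real pairs with overlap beyond
#' `xmin`. The curve is called significant (universal dynamics supported)
#' when at least 95% of bootstrap curves have a negative terminal slope;
#' the p-value is the complementary fraction, multiplied by `bonferroni`
#' when the analysis is one of a family (e.g. per-guild DOCs).
#'
#' @param points pair table from [overlapDissimilarityPairs()] (>= 10
#'   pairs).
#' @param span lowess span in (0, 1].
#' @param bootstrapReps number of sample-level bootstrap curves.
#' @param seed integer seed.
#' @param bonferroni family size for Bonferroni adjustment (default 1).
#' @return a [DOCResult-class].
#' @export
fitDoc <- function(points, span = 0.2, bootstrapReps = 1000L, seed = NULL,
                   bonferroni = 1L) {
  need <- c("sampleA", "sampleB", "overlap", "rjsd")
  if (!all(need %in% names(points)))
    stop("points must come from overlapDissimilarityPairs()")
  if (nrow(points) < 10L) stop("need >= 10 pairs to fit a DOC")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (length(unique(points$overlap)) < 2L)
    stop("all pairs share one overlap value; no slope is estimable")
  bootstrapReps <- as.integer(bootstrapReps)

  full <- docFitOne(points$overlap, points$rjsd, span)
  samples <- unique(c(points$sampleA, points$sampleB))
  lookup <- stats::setNames(seq_len(nrow(points)),
                            paste(points$sampleA, points$sampleB, sep = "\r"))
  idx <- utils::combn(length(samples), 2L)

  xmins <- rep(NA_real_, bootstrapReps)
  negTerm <- logical(bootstrapReps)
  withSeed(seed, {
    for (rb in seq_len(bootstrapReps)) {
      draw <- sample(samples, length(samples), replace = TRUE)
      a <- draw[idx[1L, ]]; b <- draw[idx[2L, ]]
      ok <- a != b # drop self-pairs of resampled duplicates
      k1 <- lookup[paste(a, b, sep = "\r")]
      k2 <- lookup[paste(b, a, sep = "\r")]
      rows <- ifelse(is.na(k1), k2, k1)[ok]
      rows <- rows[!is.na(rows)] # pairs excluded for zero overlap
      if (length(rows) < 10L || length(unique(points$overlap[rows])) < 2L)
        next
      f <- docFitOne(points$overlap[rows], points$rjsd[rows], span)
      xmins[rb] <- f$xmin
      negTerm[rb] <- f$negTerminal
    }
  })
  xmin <- if (any(!is.na(xmins))) stats::median(xmins, na.rm = TRUE) else
    NA_real_
  fns <- if (is.na(xmin)) 0 else mean(points$overlap > xmin)
  p <- mean(!negTerm)
  pAdj <- min(1, p * bonferroni)
  new("DOCResult",
      points = points[, need],
      curve = data.frame(overlap = full$x, fitted = full$y),
      xmin = xmin, fns = fns, pvalue = pAdj,
      significant = pAdj <= 0.05 && mean(negTerm) >= 0.95,
      bootstrapReps = bootstrapReps,
      excluded = as.integer(attr(points, "excluded") %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
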