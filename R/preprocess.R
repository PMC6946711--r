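#' Rarefy a counts table to even depth
#'
#' Random subsampling without replacement (hypergeometric), so each retained
#' sample sums exactly to `depth` and no zero count can become positive.
#' Wraps `vegan::rrarefy` under a local seed.
#'
#' @param x counts-mode [CommunityTable-class].
#' @param depth target depth (positive integer).
#' @param seed integer seed.
#' @param onShort what to do with samples whose total is below `depth`:
#'   `"error"` (default; silent sample loss is a foot-gun) or `"drop"`.
#' @return counts-mode [CommunityTable-class]; when `onShort = "drop"` the
#'   dropped sample count is attached as attribute `"dropped"`.
#' @export
rarefyTable <- function(x, depth, seed = NULL,
                        onShort = c("error", "drop")) {
  checkMode(x, "counts", "rarefyTable")
  onShort <- match.arg(onShort)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  m <- abundanceMatrix(x)
  tot <- rowSums(m)
  short <- tot < depth
  if (any(short)) {
    if (onShort == "error")
      stop(sprintf("sample(s) below depth %d: %s", depth,
                   paste(rownames(m)[short], collapse = ", ")))
    m <- m[!short, , drop = FALSE]
  }
  out <- withSeed(seed, vegan::rrarefy(m, depth))
  res <- communityTable(out, "counts")
  attr(res, "dropped") <- sum(short)
  res
}

#' Zero-imputed centred log-ratio transform
#'
#' The compositional preparation: zeros are replaced by a multiplicative
#' replacement - each zero cell of a sample gets a small pseudo-proportion
#' `delta` (strictly below the sample's smallest observed proportion), and
#' the observed proportions are rescaled by `1 - nZero * delta` so the row
#' stays on the simplex. The centred log-ratio is then
#' `clr(x)_i = ln x_i - mean_j ln x_j`, so every output row sums to zero.
#'
#' Two priors for `delta` are available. The default,
#' `min_fraction_multiplicative`, uses half the sample's minimum observed
#' proportion; because it is defined on the proportion scale, downstream
#' Aitchison distances are exactly invariant to multiplying a sample's raw
#' counts by a constant (compositional perturbation invariance).
#' `czm_multiplicative` is the count-zero multiplicative prior
#' `pseudoCount / rowTotal`, which mirrors detection-limit reasoning on the
#' count scale but breaks exact scale invariance on zero cells.
#'
#' @param x counts-mode [CommunityTable-class]; every sample needs at least
#'   one nonzero taxon.
#' @param zeroMethod zero replacement prior (see Details).
#' @param pseudoCount pseudo-count of the `czm_multiplicative` prior
#'   (default 0.5).
#' @return clr-mode [CommunityTable-class].
#' @export
clrTransform <- function(x, zeroMethod = c("min_fraction_multiplicative",
                                           "czm_multiplicative"),
                         pseudoCount = 0.5) {
  checkMode(x, "counts", "clrTransform")
  zeroMethod <- match.arg(zeroMethod)
  m <- abundanceMatrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop(sprintf("all-zero sample(s): %s",
                 paste(rownames(m)[tot <= 0], collapse = ", ")))
  p <- m / tot
  out <- t(vapply(seq_len(nrow(p)), function(i) {
    row <- p[i, ]
    z <- row == 0
    if (any(z)) {
      minObs <- min(row[!z])
      delta <- if (zeroMethod == "min_fraction_multiplicative")
        minObs / 2 else pseudoCount / tot[i]
      if (delta >= minObs) delta <- minObs / 2 # keep imputed below observed
      row[!z] <- row[!z] * (1 - sum(z) * delta)
      row[z] <- delta
    }
    lg <- log(row)
    lg - mean(lg)
  }, numeric(ncol(p))))
  dimnames(out) <- dimnames(m)
  communityTable(out, "clr")
}

#' Relative-abundance and Hellinger transforms
#'
#' `relative` row-normalises counts to the simplex; `hellinger` takes the
#' element-wise square root of the relative abundances, so each row's
#' squared values sum to 1 (`vegan::decostand(method = "hellinger")`).
#' Because Hellinger rows do not themselves sum to 1, the Hellinger result
#' is returned as a `counts`-mode table holding the Hellinger coordinates,
#' ready for Bray-Curtis or Euclidean distance computation.
#'
#' @param x counts-mode [CommunityTable-class].
#' @param kind `"relative"` or `"hellinger"`.
#' @return a [CommunityTable-class] (`relative` mode for `kind =
#'   "relative"`, `counts` mode holding Hellinger coordinates otherwise).
#' @export
transformTable <- function(x, kind = c("relative", "hellinger")) {
  checkMode(x, "counts", "transformTable")
  kind <- match.arg(kind)
  m <- abundanceMatrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop(sprintf("all-zero sample(s): %s",
                 paste(rownames(m)[tot <= 0], collapse = ", ")))
  if (kind == "relative") {
    communityTable(m / tot, "relative")
  } else {
    communityTable(as.matrix(vegan::decostand(m, "hellinger")), "counts")
  }
}

#' Subset a table to one functional guild
#'
#' Restricts columns to the taxa annotated with the requested guild.
#' Samples left with zero total abundance are dropped, with a message
#' recording how many.
#'
#' @param x a [CommunityTable-class].
#' @param annotation taxon annotation data.frame covering the table's taxa.
#' @param guild guild label (see [validateTaxonAnnotation()] for the
#'   vocabulary).
#' @return a [CommunityTable-class] restricted to that guild; the number of
#'   dropped samples is attached as attribute `"dropped"`.
#' @export
subsetByGuild <- function(x, annotation, guild) {
  annotation <- validateTaxonAnnotation(annotation)
  if (!guild %in% GUILDS)
    stop(sprintf("unknown guild '%s' (valid: %s)", guild,
                 paste(GUILDS, collapse = ", ")))
  keep <- annotation$taxon_id[annotation$guild == guild]
  keep <- intersect(taxonIds(x), keep)
  if (!length(keep))
    stop(sprintf("no taxa of guild '%s' in the table (valid guilds: %s)",
                 guild, paste(GUILDS, collapse = ", ")))
  m <- abundanceMatrix(x)[, keep, drop = FALSE]
  empty <- rowSums(m != 0) == 0
  if (any(empty)) {
    message(sprintf("subsetByGuild: dropping %d sample(s) with no '%s' taxa",
                    sum(empty), guild))
    m <- m[!empty, , drop = FALSE]
  }
  res <- communityTable(m, tableMode(x))
  attr(res, "dropped") <- sum(empty)
  res
}
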