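# bMNTD / bNTI phylogenetic null, Raup-Crick taxonomic null, and the
# five-way assembly-process classification.

# Per-sample presence indices and within-sample weights against a fixed
# taxon order; shared by the observed and null bMNTD computations.
communityProfile <- function(m, weighted) {
  lapply(seq_len(nrow(m)), function(i) {
    idx <- which(m[i, ] > 0)
    w <- if (weighted) m[i, idx] / sum(m[i, idx])
    else rep(1 / length(idx), length(idx))
    list(idx = idx, w = w)
  })
}

# bMNTD for every sample pair given a patristic matrix over the table's
# taxa (rows/cols in table taxon order). Returns the lower-triangle vector
# in combn(n, 2) order.
bmntdPairs <- function(D, prof, pairsIdx) {
  n <- length(prof)
  # nearest-taxon distance from every taxon to each sample's members
  M <- vapply(seq_len(n), function(j)
    rowMins(D[, prof[[j]]$idx, drop = FALSE]), numeric(nrow(D)))
  vapply(seq_len(ncol(pairsIdx)), function(k) {
    a <- pairsIdx[1L, k]; b <- pairsIdx[2L, k]
    pa <- prof[[a]]; pb <- prof[[b]]
    0.5 * (sum(pa$w * M[pa$idx, b]) + sum(pb$w * M[pb$idx, a]))
  }, numeric(1))
}

#' Beta mean nearest taxon distance (bMNTD)
#'
#' For each taxon in sample A, the patristic distance to its nearest taxon
#' in sample B, averaged (abundance-weighted within each sample when
#' `weighted = TRUE`) and symmetrised over both directions. Zero for
#' identical presence sets, since every taxon's nearest neighbour in the
#' other sample is itself.
#'
#' @param x a [CommunityTable-class].
#' @param tree cladogram (`phylo`) containing every table taxon as a tip.
#' @param weighted abundance-weight the per-taxon terms (default `TRUE`).
#' @return a `dist` of bMNTD values.
#' @export
betaMNTD <- function(x, tree, weighted = TRUE) {
  m <- abundanceMatrix(x)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop(sprintf("taxa missing from the tree: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  D <- patristicDistances(tree)[colnames(m), colnames(m), drop = FALSE]
  prof <- communityProfile(m, weighted)
  pairsIdx <- utils::combn(nrow(m), 2L)
  v <- bmntdPairs(D, prof, pairsIdx)
  out <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  out[t(pairsIdx)] <- v
  out[t(pairsIdx[2:1, , drop = FALSE])] <- v
  asDist(out, if (weighted) "bMNTD_weighted" else "bMNTD")
}

#' Beta nearest taxon index (bNTI)
#'
#' Standardises observed bMNTD against a null in which tip labels are
#' shuffled across the whole tree (taxa randomly re-placed on the
#' phylogeny, abundances kept): `bNTI = (observed - null mean) / null sd`
#' per pair. `bNTI <= -2` indicates phylogenetic underdispersion
#' (homogeneous selection), `bNTI >= 2` overdispersion (variable
#' selection). Pairs whose null distribution collapses (sd < 1e-12, e.g. on
#' a star tree where relabelling cannot change any distance) are flagged
#' degenerate and get an `NA` score.
#'
#' @inheritParams betaMNTD
#' @param reps null replicates (default 999).
#' @param seed integer seed for the tip shuffles.
#' @return a [NullModelResult-class] with statistic `"bNTI"`.
#' @export
bNTI <- function(x, tree, reps = 999L, weighted = TRUE, seed = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  reps <- as.integer(reps)
  m <- abundanceMatrix(x)
  if (nrow(m) < 2L) stop("need >= 2 samples")
  tips <- tree$tip.label
  missing <- setdiff(colnames(m), tips)
  if (length(missing))
    stop(sprintf("taxa missing from the tree: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  Dfull <- patristicDistances(tree)
  tabPos <- match(colnames(m), tips)
  D <- Dfull[tabPos, tabPos, drop = FALSE]
  prof <- communityProfile(m, weighted)
  pairsIdx <- utils::combn(nrow(m), 2L)
  obs <- bmntdPairs(D, prof, pairsIdx)

  nTips <- length(tips)
  sums <- numeric(length(obs)); sqs <- numeric(length(obs))
  withSeed(seed, {
    for (r in seq_len(reps)) {
      perm <- sample.int(nTips)
      pos <- perm[tabPos]
      v <- bmntdPairs(Dfull[pos, pos, drop = FALSE], prof, pairsIdx)
      sums <- sums + v
      sqs <- sqs + v * v
    }
  })
  nullMean <- sums / reps
  nullVar <- pmax(0, (sqs - reps * nullMean^2) / max(1L, reps - 1L))
  nullSd <- sqrt(nullVar)
  degenerate <- nullSd < 1e-12
  score <- ifelse(degenerate, NA_real_, (obs - nullMean) / nullSd)
  pairs <- data.frame(sampleA = rownames(m)[pairsIdx[1L, ]],
                      sampleB = rownames(m)[pairsIdx[2L, ]],
                      observed = obs, nullMean = nullMean, nullSd = nullSd,
                      score = score, degenerate = degenerate,
                      stringsAsFactors = FALSE)
  new("NullModelResult", pairs = pairs, statistic = "bNTI", reps = reps,
      variant = if (weighted) "weighted" else "unweighted")
}

#' Raup-Crick index (RCI)
#'
#' Compares each pair's observed compositional similarity with
#' richness-preserving null assemblages and reports the scaled quantile
#' score `RCI = 2 * ((n_null_more_similar + 0.5 * n_ties) / reps) - 1`,
#' oriented so `RCI = -1` means the observed pair is more similar than
#' every null draw (ecological clustering) and `RCI = +1` less similar than
#' every null draw (e.g. dispersal limitation).
#'
#' Variants: `presence_occupancy` (default) assembles each null community
#' by drawing the sample's observed richness from the taxon pool without
#' replacement, with probability proportional to occupancy frequency across
#' all samples, and compares shared-species counts. `abundance_bray`
#' additionally preserves each sample's total abundance, fills the drawn
#' taxa multinomially in proportion to pool relative abundance, and
#' compares observed Bray-Curtis to the null.
#'
#' @param x counts- or relative-mode [CommunityTable-class].
#' @param reps null replicates (default 999).
#' @param variant `"presence_occupancy"` or `"abundance_bray"`.
#' @param seed integer seed.
#' @return a [NullModelResult-class] with statistic `"RCI"`; `observed` is
#'   the shared-species count (presence variant) or Bray-Curtis
#'   dissimilarity (abundance variant).
#' @export
raupCrick <- function(x, reps = 999L, variant = c("presence_occupancy",
                                                  "abundance_bray"),
                      seed = NULL) {
  checkMode(x, c("counts", "relative"), "raupCrick")
  variant <- match.arg(variant)
  if (reps < 1) stop("reps must be >= 1")
  reps <- as.integer(reps)
  m <- abundanceMatrix(x)
  if (nrow(m) < 2L) stop("need >= 2 samples")
  pa <- m > 0
  richness <- rowSums(pa)
  if (any(richness == 0))
    stop(sprintf("sample(s) with zero richness: %s",
                 paste(rownames(m)[richness == 0], collapse = ", ")))
  occ <- colSums(pa)
  pool <- which(occ > 0)
  occProb <- occ[pool]
  poolAb <- colSums(m)[pool]
  poolRel <- poolAb / sum(poolAb)
  paPool <- pa[, pool, drop = FALSE]
  mPool <- m[, pool, drop = FALSE]
  nPool <- length(pool)
  pairsIdx <- utils::combn(nrow(m), 2L)
  nPairs <- ncol(pairsIdx)

  brayPair <- function(u, v) {
    s <- sum(u) + sum(v)
    if (s == 0) return(0)
    1 - 2 * sum(pmin(u, v)) / s
  }

  drawNullCounts <- function(k, total) {
    sel <- sample.int(nPool, k, prob = occProb)
    p <- poolRel[sel]
    cnt <- numeric(nPool)
    cnt[sel] <- stats::rmultinom(1L, total, p / sum(p))[, 1L]
    cnt
  }

  observed <- numeric(nPairs)
  score <- numeric(nPairs)
  nullMean <- numeric(nPairs)
  nullSd <- numeric(nPairs)
  withSeed(seed, {
    for (k in seq_len(nPairs)) {
      i <- pairsIdx[1L, k]; j <- pairsIdx[2L, k]
      if (variant == "presence_occupancy") {
        obsShared <- sum(paPool[i, ] & paPool[j, ])
        nullStat <- vapply(seq_len(reps), function(r) {
          a <- sample.int(nPool, richness[i], prob = occProb)
          b <- sample.int(nPool, richness[j], prob = occProb)
          sum(a %in% b)
        }, numeric(1))
        # similarity = shared count; null more similar <=> more shared
        more <- sum(nullStat > obsShared)
        ties <- sum(nullStat == obsShared)
        observed[k] <- obsShared
      } else {
        obsBray <- brayPair(mPool[i, ], mPool[j, ])
        nullStat <- vapply(seq_len(reps), function(r) {
          brayPair(drawNullCounts(richness[i], round(sum(mPool[i, ]))),
                   drawNullCounts(richness[j], round(sum(mPool[j, ]))))
        }, numeric(1))
        # similarity = 1 - Bray; null more similar <=> smaller null Bray
        more <- sum(nullStat < obsBray - 1e-12)
        ties <- sum(abs(nullStat - obsBray) <= 1e-12)
        observed[k] <- obsBray
      }
      score[k] <- 2 * ((more + 0.5 * ties) / reps) - 1
      nullMean[k] <- mean(nullStat)
      nullSd[k] <- stats::sd(nullStat)
    }
  })
  pairs <- data.frame(sampleA = rownames(m)[pairsIdx[1L, ]],
                      sampleB = rownames(m)[pairsIdx[2L, ]],
                      observed = observed, nullMean = nullMean,
                      nullSd = nullSd, score = score,
                      degenerate = nullSd < 1e-12,
                      stringsAsFactors = FALSE)
  new("NullModelResult", pairs = pairs, statistic = "RCI", reps = reps,
      variant = variant)
}

#' Classify sample pairs into assembly-process classes
#'
#' Joint bNTI/RCI threshold scheme: `bNTI >= 2` = variable selection;
#' `bNTI <= -2` = homogeneous selection; otherwise `RCI >= 0.95` =
#' dispersal limitation, `RCI <= -0.95` = ecological clustering without
#' phylogenetic signal (homogeneous selection or homogenizing dispersal,
#' reported as `selection_or_dispersal_ambiguous`), and `|bNTI| < 2` with
#' `|RCI| < 0.95` = stochastic, undominated assembly. Pairs with a
#' degenerate bNTI null are classified on RCI alone (with a message).
#'
#' @param bnti a [NullModelResult-class] from [bNTI()].
#' @param rci a [NullModelResult-class] from [raupCrick()] over the same
#'   sample pairs.
#' @return list with `pairs` (data.frame: `sampleA`, `sampleB`, `bMNTD`,
#'   `bNTI`, `RCI`, `class`) and `summary` (data.frame of class fractions
#'   over all pairs, summing to 1, plus the pair count as attribute
#'   `"nPairs"`).
#' @export
classifyProcesses <- function(bnti, rci) {
  stopifnot(is(bnti, "NullModelResult"), is(rci, "NullModelResult"))
  if (bnti@statistic != "bNTI" || rci@statistic != "RCI")
    stop("arguments must be a bNTI result and an RCI result, in that order")
  pb <- bnti@pairs; pr <- rci@pairs
  keyB <- paste(pb$sampleA, pb$sampleB, sep = "\r")
  keyR <- paste(pr$sampleA, pr$sampleB, sep = "\r")
  if (!setequal(keyB, keyR) || length(keyB) != length(keyR))
    stop("bNTI and RCI results cover different sample pairs")
  pr <- pr[match(keyB, keyR), , drop = FALSE]

  b <- pb$score; r <- pr$score
  nDeg <- sum(pb$degenerate)
  if (nDeg)
    message(sprintf(
      "classifyProcesses: %d pair(s) with degenerate bNTI null classified on RCI alone",
      nDeg))
  classOne <- function(bi, ri) {
    if (!is.na(bi)) {
      if (bi >= 2) return("variable_selection")
      if (bi <= -2) return("homogeneous_selection")
    }
    if (ri >= 0.95) return("dispersal_limitation")
    if (ri <= -0.95) return("selection_or_dispersal_ambiguous")
    "stochastic_undominated"
  }
  cls <- vapply(seq_along(b), function(k) classOne(b[k], r[k]), "")
  pairs <- data.frame(sampleA = pb$sampleA, sampleB = pb$sampleB,
                      bMNTD = pb$observed, bNTI = b, RCI = r,
                      class = factor(cls, levels = PROCESS_CLASSES),
                      stringsAsFactors = FALSE)
  summary <- data.frame(class = PROCESS_CLASSES,
                        fraction = as.numeric(table(pairs$class)[PROCESS_CLASSES] /
                                                nrow(pairs)))
  attr(summary, "nPairs") <- nrow(pairs)
  list(pairs = pairs, summary = summary)
}

#' Per-group assembly-process fractions
#'
#' Restricts a classified pair table to within-group pairs (both samples
#' share every `groupBy` factor level) and reports the fraction of pairs in
#' each process class per group. Groups with fewer than two samples are
#' skipped with a warning.
#'
#' @param pairs the `pairs` data.frame from [classifyProcesses()].
#' @param metadata sample metadata covering every paired sample.
#' @param groupBy character vector of metadata column names to group by.
#' @return data.frame: one row per group with the `groupBy` columns, one
#'   fraction column per process class (rows sum to 1) and `nPairs`.
#' @export
stochasticFraction <- function(pairs, metadata,
                               groupBy = c("compartment", "week",
                                           "treatment")) {
  miss <- setdiff(groupBy, names(metadata))
  if (length(miss))
    stop(sprintf("metadata lacks grouping column(s): %s",
                 paste(miss, collapse = ", ")))
  samp <- unique(c(pairs$sampleA, pairs$sampleB))
  missS <- setdiff(samp, metadata$sample_id)
  if (length(missS))
    stop(sprintf("metadata lacks sample(s): %s",
                 paste(utils::head(missS, 5), collapse = ", ")))
  key <- do.call(paste, c(metadata[groupBy], sep = "\r"))
  names(key) <- metadata$sample_id
  rows <- list()
  for (g in unique(key)) {
    members <- names(key)[key == g]
    if (length(members) < 2L) {
      warning(sprintf("group '%s' has < 2 samples; skipped",
                      gsub("\r", "/", g)))
      next
    }
    sel <- pairs$sampleA %in% members & pairs$sampleB %in% members
    if (!any(sel)) next
    sub <- pairs[sel, , drop = FALSE]
    fr <- table(factor(sub$class, levels = PROCESS_CLASSES)) / nrow(sub)
    meta1 <- metadata[match(members[1L], metadata$sample_id), groupBy,
                      drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(meta1,
                                       as.data.frame(as.list(fr)),
                                       nPairs = nrow(sub))
  }
  if (!length(rows)) stop("no group with >= 2 samples")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
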