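# Independent oracles shared by the unit and acceptance tests. These stay
# deliberately naive (double loops, complete enumeration) so they cannot
# share a code path with the package implementations they check.

# Weighted bMNTD by direct double loop over taxa.
referenceBmntd <- function(wA, wB, D) {
  ia <- names(wA)[wA > 0]; ib <- names(wB)[wB > 0]
  fa <- wA[ia] / sum(wA[ia]); fb <- wB[ib] / sum(wB[ib])
  s1 <- sum(vapply(ia, function(t) fa[[t]] * min(D[t, ib]), numeric(1)))
  s2 <- sum(vapply(ib, function(t) fb[[t]] * min(D[t, ia]), numeric(1)))
  0.5 * (s1 + s2)
}

# All permutations of 1..n (n <= 5).
allPermutations <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(p) length(unique(p)) == n), , drop = FALSE]
}

# Exact set-inclusion probabilities of k occupancy-weighted draws without
# replacement, by enumerating every ordered draw.
enumSetProbs <- function(w, k) {
  out <- new.env()
  rec <- function(chosen, rest, p) {
    if (length(chosen) == k) {
      key <- paste(sort(chosen), collapse = ",")
      prev <- if (is.null(out[[key]])) 0 else out[[key]]
      out[[key]] <- prev + p
      return()
    }
    tot <- sum(w[rest])
    for (i in rest) rec(c(chosen, i), setdiff(rest, i), p * w[i] / tot)
  }
  rec(integer(0), seq_along(w), 1)
  as.list(out)
}

# Exact Raup-Crick (presence variant) for one pair of a table.
exactRaupCrick <- function(m, i, j) {
  occ <- colSums(m > 0)
  pA <- enumSetProbs(occ, sum(m[i, ] > 0))
  pB <- enumSetProbs(occ, sum(m[j, ] > 0))
  obsShared <- sum(m[i, ] > 0 & m[j, ] > 0)
  more <- 0; tie <- 0
  for (ka in names(pA)) for (kb in names(pB)) {
    sh <- length(intersect(strsplit(ka, ",")[[1]], strsplit(kb, ",")[[1]]))
    pr <- pA[[ka]] * pB[[kb]]
    if (sh > obsShared) more <- more + pr
    else if (sh == obsShared) tie <- tie + pr
  }
  2 * (more + 0.5 * tie) - 1
}

# Classical single-factor PERMANOVA F from the pairwise-distance identity.
referencePermanovaF <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  ssTotal <- sum(D[lower.tri(D)]^2) / n
  ssWithin <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- D[idx, idx, drop = FALSE]
    ssWithin <- ssWithin + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ssTotal - ssWithin) / (a - 1)) / (ssWithin / (n - a))
}

# Synthetic DOC point sets built directly from per-sample scores, so the
# expected curve shape is known by construction.
syntheticDocPoints <- function(n = 16, shape = c("decreasing", "flat"),
                               seed = 1) {
  shape <- match.arg(shape)
  ids <- sprintf("s%02d", seq_len(n))
  v <- seq(0, 1, length.out = n)
  idx <- utils::combn(n, 2L)
  overlap <- (v[idx[1L, ]] + v[idx[2L, ]]) / 2
  set.seed(seed)
  rjsd <- if (shape == "decreasing") {
    0.05 + 0.7 * sqrt(log(2)) * (1 - overlap)
  } else {
    0.3 + stats::rnorm(length(overlap), 0, 0.01)
  }
  pts <- data.frame(sampleA = ids[idx[1L, ]], sampleB = ids[idx[2L, ]],
                    overlap = overlap, rjsd = pmax(0, rjsd))
  attr(pts, "excluded") <- 0L
  pts
}
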