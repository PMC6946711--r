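# Distance-matrix statistics: sequential PERMANOVA, Mantel tests, beta
# dispersion and principal coordinates.

# Align a dist's labels to a metadata table; returns the n x n matrix and
# the matching metadata rows.
alignDist <- function(d, metadata) {
  m <- as.matrix(d)
  labs <- rownames(m)
  if (is.null(labs)) stop("distance matrix must carry sample labels")
  missing <- setdiff(labs, metadata$sample_id)
  if (length(missing))
    stop(sprintf("metadata lacks sample(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  list(m = m, metadata = metadata[match(labs, metadata$sample_id), ,
                                  drop = FALSE])
}

# Gower-centred inner-product matrix of a distance matrix.
gowerCentre <- function(m) {
  a <- -0.5 * m * m
  n <- nrow(a)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% a %*% J
}

#' Sequential (Type-I) PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the Gower-centred inner-product matrix is partitioned over the model
#' terms in the order given (the classic `adonis` convention, so term order
#' matters and is surfaced in the output), with significance from free
#' permutation of sample labels. P-values use `(b + 1) / (m + 1)` with `b`
#' the number of permutations reaching the observed pseudo-F, so p is never
#' exactly zero.
#'
#' @param d a `dist` (or symmetric matrix) with sample labels.
#' @param metadata data.frame with `sample_id` and the model terms.
#' @param terms character vector of metadata columns, in fitting order.
#' @param permutations number of random label permutations, or a matrix
#'   whose rows are explicit permutations of `1..n` (e.g. the complete
#'   enumeration for small n).
#' @param seed integer seed for random permutations.
#' @return data.frame with one row per term plus `Residual` and `Total`:
#'   `df`, `SS`, `R2`, `F`, `p`. Term and residual `R2` sum to 1.
#' @export
permanova <- function(d, metadata, terms, permutations = 999L,
                      seed = NULL) {
  al <- alignDist(d, metadata)
  m <- al$m; md <- al$metadata
  n <- nrow(m)
  G <- gowerCentre(m)
  ssTotal <- sum(diag(G))

  hats <- vector("list", length(terms) + 1L)
  X <- matrix(1, n, 1)
  hats[[1L]] <- X %*% solve(crossprod(X)) %*% t(X)
  dfs <- integer(length(terms))
  for (k in seq_along(terms)) {
    v <- md[[terms[k]]]
    if (is.null(v)) stop(sprintf("metadata lacks term '%s'", terms[k]))
    if (length(unique(v)) < 2L)
      stop(sprintf("term '%s' has a single level", terms[k]))
    col <- if (is.numeric(v)) matrix(v, ncol = 1) else
      stats::model.matrix(~ factor(v))[, -1L, drop = FALSE]
    X <- cbind(X, col)
    q <- qr(X)
    hats[[k + 1L]] <- qr.Q(q)[, seq_len(q$rank), drop = FALSE] %*%
      t(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    dfs[k] <- q$rank - sum(dfs) - 1L
  }
  dfRes <- n - 1L - sum(dfs)
  if (dfRes < 1L) stop("no residual degrees of freedom")

  statsFor <- function(Gp) {
    ssTerm <- vapply(seq_along(terms), function(k)
      sum((hats[[k + 1L]] - hats[[k]]) * Gp), numeric(1))
    ssRes <- sum(diag(Gp)) - sum(ssTerm) - sum(hats[[1L]] * Gp)
    list(ss = ssTerm, ssRes = ssRes,
         F = (ssTerm / dfs) / (ssRes / dfRes))
  }
  obs <- statsFor(G)

  perms <- if (is.matrix(permutations)) permutations else
    withSeed(seed, t(replicate(permutations, sample.int(n))))
  exceed <- numeric(length(terms))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    Fp <- statsFor(G[p, p])$F
    exceed <- exceed + (Fp >= obs$F - 1e-12)
  }
  pvals <- (exceed + 1) / (nrow(perms) + 1)

  out <- data.frame(term = c(terms, "Residual", "Total"),
                    df = c(dfs, dfRes, n - 1L),
                    SS = c(obs$ss, obs$ssRes, ssTotal),
                    R2 = c(obs$ss, obs$ssRes, ssTotal) / ssTotal,
                    F = c(obs$F, NA, NA),
                    p = c(pvals, NA, NA))
  rownames(out) <- NULL
  out
}

#' Mantel test
#'
#' Correlation between the lower triangles of two distance matrices over
#' the same samples, with significance from jointly permuting the rows and
#' columns of the second matrix. One-sided (positive association), p =
#' `(b + 1) / (m + 1)`.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) over identical label
#'   sets.
#' @param method `"pearson"` or `"spearman"`.
#' @param permutations count, or an explicit permutation matrix as in
#'   [permanova()].
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantelTest <- function(d1, d2, method = c("pearson", "spearman"),
                       permutations = 999L, seed = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!setequal(rownames(m1), rownames(m2)))
    stop("distance matrices cover different label sets")
  m2 <- m2[rownames(m1), rownames(m1)]
  n <- nrow(m1)
  lt <- lower.tri(m1)
  rObs <- stats::cor(m1[lt], m2[lt], method = method)

  perms <- if (is.matrix(permutations)) permutations else
    withSeed(seed, t(replicate(permutations, sample.int(n))))
  rPerm <- vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    stats::cor(m1[lt], m2[p, p][lt], method = method)
  }, numeric(1))
  list(r = rObs, p = (sum(rPerm >= rObs - 1e-12) + 1) / (nrow(perms) + 1))
}

#' Beta dispersion (homogeneity of multivariate dispersions)
#'
#' Wraps `vegan::betadisper` (PCoA embedding with Anderson's correction:
#' squared imaginary-axis contributions are subtracted from the distances
#' to group centroids) followed by an ANOVA F on the distances and a
#' permutation test (`vegan::permutest`).
#'
#' @param d a `dist`.
#' @param groups grouping vector aligned with the `dist` labels.
#' @param permutations permutation count for the F test.
#' @param seed integer seed.
#' @return list with `distances` (per sample), `groupMeans`, `F`, `p` and
#'   the underlying `betadisper` object as `model`.
#' @export
betaDispersion <- function(d, groups, permutations = 999L, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L))
    warning("group(s) of size 1 contribute zero dispersion")
  bd <- vegan::betadisper(stats::as.dist(d), groups, type = "centroid")
  pt <- withSeed(seed, vegan::permutest(bd, permutations = permutations))
  list(distances = bd$distances,
       groupMeans = tapply(bd$distances, groups, mean),
       F = pt$tab$F[1L], p = pt$tab$`Pr(>F)`[1L], model = bd)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a symmetric distance matrix (`ape::pcoa`),
#' eigenvalues sorted descending, with an optional Lingoes correction for
#' non-Euclidean matrices. For a Euclidean-embeddable input the pairwise
#' distances among the full set of returned coordinates reproduce the
#' input.
#'
#' @param d a `dist` or symmetric zero-diagonal matrix.
#' @param correction `"none"` or `"lingoes"`.
#' @return list with `coordinates` (samples x axes), `eigenvalues` and the
#'   full `ape::pcoa` result as `model`.
#' @export
pcoaOrdination <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("input must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("input must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  res <- ape::pcoa(d, correction = if (correction == "none") "none" else
    "lingoes")
  list(coordinates = res$vectors, eigenvalues = res$values$Eigenvalues,
       model = res)
}
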