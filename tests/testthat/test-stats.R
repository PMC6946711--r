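test_that("PERMANOVA partitions variance and matches vegan::adonis2", {
  set.seed(71)
  m <- matrix(rpois(80, 8), 10, 8,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:8)))
  tab <- communityTable(m)
  d <- pairwiseDissimilarity(tab, "bray_curtis")
  md <- data.frame(sample_id = paste0("s", 1:10),
                   compartment = rep(c("leaf", "root"), 5),
                   week = rep(1:5, each = 2), treatment = "control")
  res <- permanova(d, md, c("compartment", "week"), permutations = 49,
                   seed = 1)
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-9)

  ad <- vegan::adonis2(d ~ compartment + week, data = md, by = "terms",
                       permutations = 49)
  expect_equal(res$SS[1:2], ad$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(res$F[1:2], ad$F[1:2], tolerance = 1e-10)
  expect_equal(res$R2[1:2], ad$R2[1:2], tolerance = 1e-10)
})

test_that("two separated identical-within groups give R2 = 1", {
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 0; D[3, 4] <- D[4, 3] <- 0
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   compartment = c("leaf", "leaf", "root", "root"),
                   week = 1, treatment = "control")
  res <- permanova(as.dist(D), md, "compartment", permutations = 23,
                   seed = 1)
  expect_equal(res$R2[1], 1, tolerance = 1e-12)
  expect_equal(res$SS[res$term == "Residual"], 0, tolerance = 1e-12)
})

test_that("PERMANOVA permutation p matches complete enumeration at n = 4", {
  set.seed(73)
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  groups <- c("g1", "g1", "g2", "g2")
  md <- data.frame(sample_id = paste0("s", 1:4), compartment = groups,
                   week = 1, treatment = "control")

  allPerms <- allPermutations(4)
  res <- permanova(as.dist(D), md, "compartment",
                   permutations = allPerms)

  # oracle: exceedance fraction of the classical F over the same relabelings
  fObs <- referencePermanovaF(D, groups)
  fPerm <- apply(allPerms, 1, function(p)
    referencePermanovaF(D[p, p], groups))
  pExact <- (sum(fPerm >= fObs - 1e-12) + 1) / (nrow(allPerms) + 1)
  expect_equal(res$F[1], fObs, tolerance = 1e-9)
  expect_equal(res$p[1], pExact, tolerance = 1e-12)
})

test_that("Euclidean single-term PERMANOVA reproduces classical ANOVA F", {
  set.seed(79)
  y <- rnorm(12, mean = rep(c(0, 1, 3), each = 4))
  g <- rep(c("leaf", "root", "soil"), each = 4)
  D <- as.matrix(dist(y))
  dimnames(D) <- list(paste0("s", 1:12), paste0("s", 1:12))
  md <- data.frame(sample_id = paste0("s", 1:12), compartment = g,
                   week = 1, treatment = "control")
  res <- permanova(as.dist(D), md, "compartment", permutations = 9,
                   seed = 1)
  classical <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$F[1], classical, tolerance = 1e-9)
})

test_that("Mantel statistics and enumeration behave", {
  set.seed(83)
  d1 <- dist(matrix(rnorm(12), 6))
  attr(d1, "Labels") <- paste0("s", 1:6)
  expect_equal(mantelTest(d1, d1, permutations = 9, seed = 1)$r, 1)
  expect_equal(mantelTest(d1, 2 * d1, permutations = 9, seed = 1)$r, 1)

  # spearman is invariant to monotone transforms
  d2 <- dist(matrix(rnorm(12), 6))
  attr(d2, "Labels") <- paste0("s", 1:6)
  r1 <- mantelTest(d1, d2, method = "spearman", permutations = 9,
                   seed = 1)$r
  d2cube <- as.dist(as.matrix(d2)^3)
  r2 <- mantelTest(d1, d2cube, method = "spearman", permutations = 9,
                   seed = 1)$r
  expect_equal(r1, r2, tolerance = 1e-12)

  # complete enumeration at n = 4
  da <- as.matrix(dist(matrix(rnorm(8), 4)))
  db <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(da) <- dimnames(db) <- list(paste0("s", 1:4), paste0("s", 1:4))
  allPerms <- allPermutations(4)
  got <- mantelTest(as.dist(da), as.dist(db), permutations = allPerms)
  lt <- lower.tri(da)
  rObs <- cor(da[lt], db[lt])
  rPerm <- apply(allPerms, 1, function(p) cor(da[lt], db[p, p][lt]))
  expect_equal(got$p,
               (sum(rPerm >= rObs - 1e-12) + 1) / (nrow(allPerms) + 1))
  expect_true(abs(got$r) <= 1)

  dx <- d1; attr(dx, "Labels") <- paste0("q", 1:6)
  expect_error(mantelTest(d1, dx), "label")
})

test_that("beta dispersion recognises degenerate and symmetric groups", {
  # a group of identical samples has zero dispersion
  pts <- rbind(matrix(0, 4, 2), matrix(rnorm(8), 4, 2))
  rownames(pts) <- paste0("s", 1:8)
  d <- dist(pts)
  g <- rep(c("flat", "cloud"), each = 4)
  res <- betaDispersion(d, g, permutations = 99, seed = 1)
  expect_equal(unname(res$distances[1:4]), rep(0, 4), tolerance = 1e-9)
  expect_true(all(res$distances >= -1e-12))

  # mirrored point clouds have identical mean dispersion
  cloud <- matrix(rnorm(10), 5, 2)
  both <- rbind(cloud, -cloud + 10)
  rownames(both) <- paste0("s", 1:10)
  g2 <- rep(c("a", "b"), each = 5)
  res2 <- betaDispersion(dist(both), g2, permutations = 99, seed = 1)
  expect_equal(unname(res2$groupMeans[["a"]]),
               unname(res2$groupMeans[["b"]]), tolerance = 1e-9)
})

test_that("PCoA embeddings reconstruct Euclidean inputs", {
  set.seed(89)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("p", 1:5), NULL))
  d <- dist(pts)
  res <- pcoaOrdination(d)
  expect_equal(as.matrix(dist(res$coordinates)), as.matrix(d),
               tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))

  two <- matrix(c(0, 3, 3, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  res2 <- pcoaOrdination(two)
  expect_equal(unname(sort(abs(res2$coordinates[, 1]))), c(1.5, 1.5),
               tolerance = 1e-9)

  asym <- matrix(c(0, 1, 2, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoaOrdination(asym), "symmetric")
})

test_that("the stochasticity-size mixed model estimates and degenerates", {
  # exact line, multiple compartments, no noise
  x <- rep(seq(0, 1, length.out = 10), 4)
  comp <- rep(c("leaf", "root", "soil", "rhizosphere"), each = 10)
  y <- 0.9 - 0.5 * x
  res <- suppressMessages(mixedStochasticityModel(y, x, comp))
  expect_equal(res$slope, -0.5, tolerance = 1e-6)
  expect_gt(res$conditionalR2, 0.99)

  # single compartment degenerates to OLS with a warning (the noiseless
  # line additionally triggers lm's perfect-fit warning)
  w <- capture_warnings(ols <- mixedStochasticityModel(y[1:10], x[1:10],
                                                       comp[1:10]))
  expect_true(any(grepl("ordinary", w)))
  expect_equal(ols$slope, -0.5, tolerance = 1e-9)
  expect_equal(ols$marginalR2, ols$conditionalR2)

  # simulate-and-refit with known slope -0.1 and compartment intercepts
  set.seed(11)
  xr <- rep(seq(1, 5, length.out = 10), 4)
  compr <- rep(c("leaf", "root", "soil", "rhizosphere"), each = 10)
  intercept <- rep(c(0.8, 0.6, 0.7, 0.9), each = 10)
  yr <- intercept - 0.1 * xr + rnorm(40, 0, 0.03)
  fit <- mixedStochasticityModel(yr, xr, compr)
  se <- stats::coef(summary(fit$model))["x", "Std. Error"]
  expect_true(abs(fit$slope - (-0.1)) < 1.96 * se + 1e-9)
  expect_lt(fit$p, 0.05)
  expect_gte(fit$conditionalR2, fit$marginalR2)
})

test_that("co-abundance clustering finds proportional blocks", {
  set.seed(13)
  n <- 30
  base1 <- rnorm(n); base2 <- rnorm(n)
  m <- cbind(sapply(1:4, function(i) base1 + rnorm(n, 0, 0.05)),
             sapply(1:4, function(i) base2 + rnorm(n, 0, 0.05)))
  m <- m - rowMeans(m) # rows must be clr-centred
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("t%d", 1:8))
  res <- cooccurrenceClusters(communityTable(m, "clr"))
  expect_equal(max(res$clusters$cluster), 2)
  blocks <- split(res$clusters$taxon_id, res$clusters$cluster)
  expect_setequal(vapply(blocks, length, 1L), c(4L, 4L))
  expect_true(all(res$edges$r > 0.8))
  expect_true(all(res$edges$phi < 0.1))
  expect_true(all(res$edges$pAdjusted < 0.001))

  # single taxon: no edges, one singleton cluster (a one-part composition
  # has clr identically zero, so the column is constant and warned about)
  single <- matrix(0, 9, 1, dimnames = list(paste0("s", 1:9), "t1"))
  res1 <- suppressWarnings(cooccurrenceClusters(communityTable(single,
                                                               "clr")))
  expect_equal(nrow(res1$edges), 0)
  expect_equal(res1$clusters$cluster, 1L)
})

test_that("the age-delay protocol recovers known developmental shifts", {
  fx <- successionFixture(weeks = 1:10, reps = 6, shift = 0, seed = 8)
  # drought samples drawn from the same-week profile: no discrepancy
  res0 <- ageDelayProtocol(fx$table, fx$metadata, numTrees = 300, seed = 2)
  expect_lt(abs(mean(res0$discrepancy$discrepancy)), 0.6)

  # determinism
  res0b <- ageDelayProtocol(fx$table, fx$metadata, numTrees = 300, seed = 2)
  expect_identical(res0$discrepancy, res0b$discrepancy)
  expect_identical(res0$topTaxa, res0b$topTaxa)

  # permuting training weeks destroys the signal
  fx2 <- successionFixture(weeks = 1:10, reps = 6, shift = 2, seed = 5)
  res2 <- ageDelayProtocol(fx2$table, fx2$metadata, numTrees = 300,
                           seed = 2)
  mdPerm <- fx2$metadata
  set.seed(4)
  ctl <- mdPerm$treatment == "control"
  mdPerm$week[ctl] <- sample(mdPerm$week[ctl])
  resPerm <- ageDelayProtocol(fx2$table, mdPerm, numTrees = 300, seed = 2)
  expect_gt(mean(res2$discrepancy$discrepancy),
            mean(resPerm$discrepancy$discrepancy) + 0.5)

  # contract errors
  few <- fx$metadata[fx$metadata$week <= 2 |
                       fx$metadata$treatment != "control", ]
  fewTab <- communityTable(
    abundanceMatrix(fx$table)[few$sample_id, , drop = FALSE])
  expect_error(ageDelayProtocol(fewTab, few, seed = 1), ">= 3 weeks")
})
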