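test_that("bMNTD matches its definition and picante", {
  tree <- taxonomyToCladogram(annotationFixture())
  D <- patristicDistances(tree)

  # single shared taxon
  m <- matrix(c(4, 0, 0, 0,
                7, 0, 0, 0), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), colnames(D)))
  expect_equal(as.numeric(betaMNTD(communityTable(m), tree)), 0)

  # one taxon per sample at patristic distance 4
  m2 <- matrix(c(1, 0, 0, 0,
                 0, 0, 1, 0), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), colnames(D)))
  expect_equal(as.numeric(betaMNTD(communityTable(m2), tree)), 4)

  # equal abundances: weighted equals unweighted
  m3 <- matrix(c(1, 1, 0, 1,
                 0, 1, 1, 1), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), colnames(D)))
  t3 <- communityTable(m3)
  expect_equal(as.matrix(betaMNTD(t3, tree, weighted = TRUE)),
               as.matrix(betaMNTD(t3, tree, weighted = FALSE)),
               tolerance = 1e-12)

  bad <- communityTable(matrix(1, 1, 1, dimnames = list("A", "zz")))
  expect_error(betaMNTD(bad, tree), "zz")

  # random tables against the reference loop and picante::comdistnt
  set.seed(31)
  meta <- sampleMetacommunity(40, seed = 31)
  tab <- simulateAssembly(meta, assemblyScenario("drift", N = 40,
                                                 generations = 5, m = 0.3,
                                                 seed = 2), 6)
  Dm <- patristicDistances(meta@tree)
  got <- as.matrix(betaMNTD(tab, meta@tree, weighted = TRUE))
  mm <- abundanceMatrix(tab)
  for (pr in list(c(1, 2), c(3, 5), c(4, 6))) {
    expect_equal(got[pr[1], pr[2]],
                 referenceBmntd(mm[pr[1], ], mm[pr[2], ], Dm),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("picante")
  pic <- as.matrix(picante::comdistnt(mm, Dm, abundance.weighted = TRUE))
  expect_equal(got, pic[rownames(got), colnames(got)], tolerance = 1e-8)
})

test_that("bNTI agrees with exhaustive tip-permutation enumeration", {
  tree <- taxonomyToCladogram(annotationFixture())
  D <- patristicDistances(tree)
  taxa <- colnames(D)
  m <- matrix(c(3, 1, 0, 0,
                0, 0, 2, 2), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), taxa))
  tab <- communityTable(m)

  perms <- allPermutations(4)
  nullVals <- apply(perms, 1, function(p) {
    Dp <- D[p, p]; dimnames(Dp) <- dimnames(D)
    referenceBmntd(m["A", ], m["B", ], Dp)
  })
  obs <- referenceBmntd(m["A", ], m["B", ], D)
  exact <- (obs - mean(nullVals)) /
    sqrt(mean((nullVals - mean(nullVals))^2))

  res <- bNTI(tab, tree, reps = 999, seed = 4)
  z <- pairScores(res)$score
  mcSe <- sqrt((1 + exact^2 / 2) / 999)
  expect_lt(abs(z - exact), 3 * mcSe)
})

test_that("star phylogenies give a degenerate bNTI null", {
  # all four OTUs in one genus: every tip pair is equidistant
  ann <- annotationFixture()
  ann[, c("phylum", "class", "order", "family", "genus")] <-
    list("p1", "c1", "o1", "f1", "g1")
  star <- taxonomyToCladogram(ann)
  m <- matrix(c(2, 1, 0, 0,
                0, 0, 1, 2), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), ann$taxon_id))
  res <- bNTI(communityTable(m), star, reps = 99, seed = 1)
  expect_true(all(pairScores(res)$degenerate))
  expect_true(all(is.na(pairScores(res)$score)))
})

test_that("bNTI is invariant to uniform branch-length scaling", {
  meta <- sampleMetacommunity(30, seed = 41)
  tab <- simulateAssembly(meta, assemblyScenario("drift", N = 30,
                                                 generations = 5, m = 0.2,
                                                 seed = 3), 5)
  scaled <- meta@tree
  scaled$edge.length <- scaled$edge.length * 5
  z1 <- pairScores(bNTI(tab, meta@tree, reps = 99, seed = 7))$score
  z2 <- pairScores(bNTI(tab, scaled, reps = 99, seed = 7))$score
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("Raup-Crick matches complete enumeration on a tiny pool", {
  m <- matrix(c(1, 1, 1, 0, 0, 0,
                0, 1, 0, 1, 1, 0,
                1, 0, 1, 0, 1, 1,
                0, 0, 1, 1, 0, 1), 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:6)))
  tab <- communityTable(m)
  exact <- exactRaupCrick(m, 1, 2)

  res <- raupCrick(tab, reps = 999, seed = 9)
  got <- pairScores(res)
  mc <- got$score[got$sampleA == "s1" & got$sampleB == "s2"]
  expect_lt(abs(mc - exact), 0.1)
})

test_that("Raup-Crick hits its quantile boundaries and invariances", {
  # two identical, rich samples in a wide low-occupancy pool: the observed
  # pair is more similar than every null assemblage
  set.seed(5)
  n <- 15; S <- 40
  m <- matrix(rbinom(n * S, 1, 0.2), n, S,
              dimnames = list(sprintf("x%02d", 1:n), sprintf("t%02d", 1:S)))
  m[rowSums(m) == 0, 1] <- 1
  m[1, ] <- 0; m[2, ] <- 0
  m[1, 1:5] <- 1; m[2, 1:5] <- 1
  res <- raupCrick(communityTable(m), reps = 999, seed = 2)
  got <- pairScores(res)
  expect_equal(got$score[got$sampleA == "x01" & got$sampleB == "x02"], -1)

  # disjoint pair while the null is forced through three ubiquitous taxa:
  # every null assemblage is more similar than the observation
  m2 <- matrix(0, 23, 12,
               dimnames = list(sprintf("y%02d", 1:23), sprintf("t%02d", 1:12)))
  m2[4:23, 1:3] <- 1                     # three taxa of occupancy 20
  m2[1, 4:8] <- 1
  m2[2, 9:12] <- 1
  m2[3, 1:4] <- 1
  res2 <- raupCrick(communityTable(m2), reps = 999, seed = 2)
  got2 <- pairScores(res2)
  expect_equal(got2$score[got2$sampleA == "y01" & got2$sampleB == "y02"], 1)

  # relabeling taxa leaves RCI unchanged up to Monte-Carlo error
  perm <- sample(ncol(m))
  s3 <- pairScores(raupCrick(communityTable(m[, perm]), reps = 999,
                             seed = 77))$score
  s4 <- pairScores(raupCrick(communityTable(m), reps = 999,
                             seed = 78))$score
  expect_lt(mean(abs(s3 - s4)), 0.06)

  expect_error(raupCrick(communityTable(
    matrix(c(1, 0, 0, 0), 2, 2,
           dimnames = list(c("a", "b"), c("t1", "t2")))), reps = 9),
    "zero richness")
})

test_that("process classification applies the joint threshold scheme", {
  mk <- function(b, r, deg = FALSE) {
    pairs <- data.frame(sampleA = "A", sampleB = "B", observed = 1,
                        nullMean = 1, nullSd = 1, score = b,
                        degenerate = deg, stringsAsFactors = FALSE)
    bn <- new("NullModelResult", pairs = pairs, statistic = "bNTI",
              reps = 99L, variant = "weighted")
    pairs$score <- r
    rc <- new("NullModelResult", pairs = pairs, statistic = "RCI",
              reps = 99L, variant = "presence_occupancy")
    as.character(classifyProcesses(bn, rc)$pairs$class)
  }
  expect_equal(mk(-3, -1), "homogeneous_selection")
  expect_equal(mk(0.5, 0.2), "stochastic_undominated")
  expect_equal(mk(1.0, -0.99), "selection_or_dispersal_ambiguous")
  expect_equal(mk(2.5, 0.2), "variable_selection")
  expect_equal(mk(1.0, 0.96), "dispersal_limitation")
  # degenerate bNTI: classified on RCI alone, with a message
  expect_message(cls <- mk(NA, 0.1, deg = TRUE), "degenerate")
  expect_equal(cls, "stochastic_undominated")
})

test_that("per-group process fractions count correctly", {
  pairs <- data.frame(
    sampleA = c("a1", "a1", "a2", "b1"),
    sampleB = c("a2", "a3", "a3", "b2"),
    bMNTD = 1, bNTI = 0, RCI = 0,
    class = factor(c("stochastic_undominated", "homogeneous_selection",
                     "stochastic_undominated", "stochastic_undominated"),
                   levels = mycoassembly:::PROCESS_CLASSES))
  md <- data.frame(sample_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
                   compartment = c(rep("leaf", 3), "root", "root", "soil"),
                   week = 1, treatment = "control")
  expect_warning(fr <- stochasticFraction(pairs, md, "compartment"),
                 "skipped")
  leaf <- fr[fr$compartment == "leaf", ]
  expect_equal(leaf$stochastic_undominated, 2 / 3)
  expect_equal(leaf$homogeneous_selection, 1 / 3)
  expect_equal(leaf$nPairs, 3)
  root <- fr[fr$compartment == "root", ]
  expect_equal(root$stochastic_undominated, 1)
  classCols <- mycoassembly:::PROCESS_CLASSES
  expect_true(all(abs(rowSums(fr[, classCols]) - 1) < 1e-9))
})

test_that("dispersal limitation elevates RCI relative to matched drift", {
  # matched N and generations; the dispersal-limited arm only ever sees a
  # 10% pool subset per replicate, the drift arm the whole pool
  meta <- sampleMetacommunity(200, seed = 7)
  lim <- simulateAssembly(meta,
                          assemblyScenario("dispersal_limitation", N = 200,
                                           generations = 5, m = 0,
                                           seed = 9), 10)
  dri <- simulateAssembly(meta,
                          assemblyScenario("drift", N = 200,
                                           generations = 5, m = 0.1,
                                           seed = 9), 10)
  rLim <- pairScores(raupCrick(lim, reps = 199, seed = 2))$score
  rDri <- pairScores(raupCrick(dri, reps = 199, seed = 2))$score
  expect_gt(mean(rLim), mean(rDri))
  expect_gte(mean(rLim >= 0.95), mean(rDri >= 0.95))
})
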