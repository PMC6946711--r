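#' Generate a synthetic ranked taxonomy
#'
#' Draws a nested six-rank lineage (one kingdom, random phyla and nested
#' lower ranks) plus a random functional guild for `S` taxa. Used to give
#' simulated metacommunities a cladogram with realistic topological
#' structure, so that Brownian traits are phylogenetically conserved and
#' selection scenarios produce phylogenetic signal.
#'
#' The number of groups shrinks going up the ranks (about `S/3` genera,
#' `S/6` families and so on, as in observed fungal OTU inventories), and
#' OTUs are spread over genera with lognormally skewed sizes, so a few
#' species-rich genera hold many OTUs while most hold one or two - the
#' feature that puts close relatives (congeners) in the pool.
#'
#' @param S number of taxa.
#' @param seed integer seed (`NULL` = use the current RNG stream).
#' @param nPhyla number of phyla to spread taxa over.
#' @param genusSizeSkew lognormal sd of the genus-size weights; 0 gives
#'   near-even genera, larger values concentrate OTUs in a few rich genera.
#' @return a taxon annotation data.frame (see [validateTaxonAnnotation()]).
#' @export
randomTaxonAnnotation <- function(S, seed = NULL, nPhyla = NULL,
                                  genusSizeSkew = 1) {
  if (S < 1) stop("S must be >= 1")
  if (is.null(nPhyla)) nPhyla <- max(2L, min(8L, ceiling(S / 40)))
  withSeed(seed, {
    nGen <- max(1L, round(S / 3))
    nFam <- max(1L, round(S / 6))
    nOrd <- max(1L, round(S / 12))
    nCls <- max(1L, round(S / 24))
    # parent links drawn uniformly; genus sizes lognormally skewed
    famOf <- sample.int(nFam, nGen, replace = TRUE)
    ordOf <- sample.int(nOrd, nFam, replace = TRUE)
    clsOf <- sample.int(nCls, nOrd, replace = TRUE)
    phyOf <- sample.int(nPhyla, nCls, replace = TRUE)
    w <- stats::rlnorm(nGen, 0, genusSizeSkew)
    genus <- sample.int(nGen, S, replace = TRUE, prob = w)
    fam <- famOf[genus]; ord <- ordOf[fam]; cls <- clsOf[ord]
    phy <- phyOf[cls]
    data.frame(taxon_id = sprintf("OTU%04d", seq_len(S)),
               kingdom = "Fungi",
               phylum = paste0("p", phy),
               class = paste0("c", cls),
               order = paste0("o", ord),
               family = paste0("f", fam),
               genus = paste0("g", genus),
               guild = sample(GUILDS[1:5], S, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# Brownian motion along tree edges, parent before child (handles singleton
# internal nodes, which taxonomy-derived cladograms contain). The per-edge
# rate decays geometrically with depth below the root (`tipRateDecay`) and
# drops by `conservedMult` below `conservedDepth` (edges at the genus level
# and below on a fully resolved six-rank cladogram): niches differentiate
# between higher clades and are conserved within families - phylogenetic
# niche conservatism, the regime in which phylogenetic turnover metrics
# carry information about selection.
brownianTraits <- function(tree, sigma = 1, tipRateDecay = 0.3,
                           conservedDepth = 5L, conservedMult = 0.01) {
  nTip <- length(tree$tip.label)
  tr <- if (nTip > 1L) ape::reorder.phylo(tree, "cladewise") else tree
  nNode <- nTip + tr$Nnode
  x <- numeric(nNode)
  depth <- integer(nNode)
  root <- nTip + 1L
  x[root] <- 0
  depth[root] <- 0L
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    depth[ch] <- depth[p] + 1L
    rate <- sigma * tipRateDecay^depth[p]
    if (depth[p] >= conservedDepth) rate <- rate * conservedMult
    x[ch] <- x[p] + stats::rnorm(1L, 0, rate * sqrt(tr$edge.length[i]))
  }
  stats::setNames(x[seq_len(nTip)], tr$tip.label)
}

#' Sample a metacommunity (regional species pool)
#'
#' Relative abundances are drawn from a lognormal species-abundance
#' distribution and normalised to the simplex. Traits are either Brownian on
#' the cladogram (phylogenetically conserved; required for selection
#' scenarios to leave a phylogenetic signal detectable by bNTI) or
#' independent normals. When no tree is supplied, a synthetic taxonomy is
#' drawn with [randomTaxonAnnotation()] and converted with
#' [taxonomyToCladogram()].
#'
#' @param S number of taxa (>= 1).
#' @param lognormalSigma log-scale standard deviation of the abundance
#'   distribution.
#' @param traitModel `"brownian_on_tree"` (default) or `"independent"`.
#' @param brownianRate Brownian diffusion sd per unit branch length at the
#'   root; the per-edge rate decays geometrically with depth
#'   (`tipRateDecay`) and is additionally suppressed a hundredfold below
#'   the family level, concentrating trait variance on deep edges. Close
#'   relatives then share near-identical niches (phylogenetic niche
#'   conservatism) while distant clades differ strongly - the regime in
#'   which phylogenetic null models can recognise selection.
#' @param tipRateDecay geometric decay of the Brownian rate per level of
#'   depth below the root.
#' @param tree optional `phylo` whose tips will be the taxa.
#' @param seed integer seed; the same seed reproduces the metacommunity
#'   exactly.
#' @return a [Metacommunity-class].
#' @export
sampleMetacommunity <- function(S, lognormalSigma = 1,
                                traitModel = c("brownian_on_tree",
                                               "independent"),
                                brownianRate = 30, tipRateDecay = 0.3,
                                tree = NULL, seed = NULL) {
  if (!is.numeric(S) || S < 1) stop("S must be >= 1")
  S <- as.integer(S)
  traitModel <- match.arg(traitModel)
  if (is.null(tree)) {
    ann <- randomTaxonAnnotation(S, seed = if (is.null(seed)) NULL else
      childSeed(seed, "taxonomy"))
    tree <- taxonomyToCladogram(ann)
  } else if (length(tree$tip.label) != S) {
    stop("tree tip count must equal S")
  }
  ids <- tree$tip.label
  withSeed(if (is.null(seed)) NULL else childSeed(seed, "abundance"), {
    ab <- stats::rlnorm(S, meanlog = 0, sdlog = lognormalSigma)
    ab <- stats::setNames(ab / sum(ab), ids)
    traits <- if (traitModel == "brownian_on_tree") {
      brownianTraits(tree, sigma = brownianRate,
                     tipRateDecay = tipRateDecay)
    } else {
      stats::setNames(stats::rnorm(S, sd = brownianRate), ids)
    }
    new("Metacommunity", taxonIds = ids, abundance = ab, traits = traits,
        tree = tree)
  })
}

#' Construct an assembly scenario
#'
#' @param process assembly process: `drift`, `homogeneous_selection`,
#'   `variable_selection`, `dispersal_limitation` or
#'   `homogenizing_dispersal`.
#' @param N local community size (individuals per sample).
#' @param generations resampling generations after the seeding draw.
#' @param m immigration rate from the metacommunity (drift/selection), or
#'   the migrant-exchange rate among replicates (homogenizing dispersal).
#'   Forced to 0 for dispersal limitation after seeding.
#' @param s selection strength of Gaussian stabilising selection
#'   `exp(-s * (trait - optimum)^2)`.
#' @param optima named numeric of per-plot trait optima (variable selection)
#'   or a single shared optimum (homogeneous selection). Empty = derived
#'   from the metacommunity traits.
#' @param seed integer seed.
#' @return an [AssemblyScenario-class].
#' @export
assemblyScenario <- function(process, N, generations = 50L, m = 0.1, s = 0,
                             optima = numeric(0), seed = 1L) {
  new("AssemblyScenario", process = process, N = as.integer(N),
      generations = as.integer(generations), m = as.numeric(m),
      s = as.numeric(s), optima = optima, seed = as.integer(seed))
}

#' Simulate community assembly under a known process
#'
#' A Wright-Fisher-style neutral core with process-specific modifications.
#' Each replicate is seeded by one multinomial draw of `N` individuals from
#' the metacommunity (or from a replicate-specific random 10% subset of the
#' pool under dispersal limitation), then updated for `generations`
#' resampling steps. Each step draws `N` individuals multinomially from
#' `(1 - m) * local frequencies + m * metacommunity` (drift, selection), or
#' with `m`-rate migrant exchange among replicates instead of the
#' metacommunity (homogenizing dispersal), or with `m = 0` (dispersal
#' limitation). Under selection the resampling weights are additionally
#' multiplied by `exp(-s * (trait - optimum)^2)`: a shared optimum across
#' replicates for homogeneous selection, per-plot optima for variable
#' selection.
#'
#' @param meta a [Metacommunity-class].
#' @param scenario an [AssemblyScenario-class].
#' @param nReplicates number of replicate local communities.
#' @param plots optional character vector of plot ids (one per replicate);
#'   defaults to `plot1..plotR`.
#' @return a counts-mode [CommunityTable-class]; every row sums to `N`.
#' @export
simulateAssembly <- function(meta, scenario, nReplicates, plots = NULL) {
  stopifnot(is(meta, "Metacommunity"), is(scenario, "AssemblyScenario"))
  validObject(scenario)
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  N <- scenario@N
  if (N < 1L) stop("N must be >= 1")
  proc <- scenario@process
  selective <- proc %in% c("homogeneous_selection", "variable_selection")
  if (selective && !length(meta@traits))
    stop("selection scenarios require metacommunity traits")
  if (is.null(plots)) plots <- paste0("plot", seq_len(nReplicates))
  if (length(plots) != nReplicates)
    stop("plots must have one entry per replicate")
  S <- length(meta@taxonIds)
  metaAb <- as.numeric(meta@abundance)

  withSeed(scenario@seed, {
    # per-plot optima for selection
    optima <- NULL
    if (selective) {
      tr <- meta@traits[meta@taxonIds]
      if (proc == "homogeneous_selection") {
        # default shared optimum: the trait of one abundance-weighted pool
        # taxon - selection favours a particular clade, not the pool mean
        opt <- if (length(scenario@optima)) scenario@optima[[1L]] else
          tr[sample.int(S, 1L, prob = metaAb)]
        optima <- stats::setNames(rep(opt, nReplicates), plots)
      } else {
        optima <- if (length(scenario@optima)) {
          miss <- setdiff(plots, names(scenario@optima))
          if (length(miss)) stop(sprintf("no optimum for plot(s): %s",
                                         paste(miss, collapse = ", ")))
          scenario@optima[plots]
        } else {
          # each plot selects toward the trait of a random (abundance-
          # weighted) pool taxon, giving divergent targets across plots
          stats::setNames(tr[sample.int(S, nReplicates, replace = TRUE,
                                        prob = metaAb)], plots)
        }
      }
    }

    m <- if (proc == "dispersal_limitation") 0 else scenario@m
    counts <- matrix(0, nReplicates, S)
    for (r in seq_len(nReplicates)) {
      p0 <- metaAb
      if (proc == "dispersal_limitation") {
        # each replicate only ever sees its own random 10% of the pool;
        # uniform draw, so replicate subsets are nearly disjoint
        k <- max(5L, ceiling(0.1 * S))
        sub <- sample.int(S, min(k, S))
        p0 <- numeric(S)
        p0[sub] <- metaAb[sub] / sum(metaAb[sub])
      }
      counts[r, ] <- stats::rmultinom(1L, N, p0)[, 1L]
    }

    selFactor <- function(plotIdx) {
      if (!selective) return(1)
      d <- meta@traits[meta@taxonIds] - optima[[plotIdx]]
      exp(-scenario@s * d * d)
    }

    if (scenario@generations > 0L) {
      for (g in seq_len(scenario@generations)) {
        freq <- counts / N
        poolFreq <- if (proc == "homogenizing_dispersal")
          colMeans(freq) else metaAb
        for (r in seq_len(nReplicates)) {
          w <- (1 - m) * freq[r, ] + m * poolFreq
          w <- w * selFactor(r)
          if (sum(w) <= 0) w <- freq[r, ] # selection wiped support; drift on
          counts[r, ] <- stats::rmultinom(1L, N, w)[, 1L]
        }
      }
    }

    dimnames(counts) <- list(sprintf("rep%02d", seq_len(nReplicates)),
                             meta@taxonIds)
    communityTable(counts, "counts")
  })
}

#' Construct a field design
#'
#' @param compartments,weeks,treatments design factor levels (subsets of the
#'   leaf/root/rhizosphere/soil, 0..17 and
#'   control/pre_flowering_drought/post_flowering_drought vocabularies).
#' @param replicates replicate samples per design cell.
#' @param scenario an [AssemblyScenario-class] template shared by every
#'   cell, or a function `(compartment, week, treatment)` returning one.
#' @param sizeSchedule optional function `week -> N` overriding the
#'   scenario's community size, producing a size gradient across weeks.
#' @param seed master seed; each cell's scenario seed is derived
#'   deterministically from it, so any subset of the grid reproduces without
#'   simulating the rest.
#' @return a [FieldDesign-class].
#' @export
fieldDesign <- function(compartments, weeks, treatments, replicates,
                        scenario, sizeSchedule = NULL, seed = 1L) {
  new("FieldDesign", compartments = compartments, weeks = as.integer(weeks),
      treatments = treatments, replicates = as.integer(replicates),
      scenario = scenario, sizeSchedule = sizeSchedule,
      seed = as.integer(seed))
}

.COMP_ABBREV <- c(leaf = "L", root = "R", rhizosphere = "Z", soil = "S")
.TREAT_ABBREV <- c(control = "C", pre_flowering_drought = "preD",
                   post_flowering_drought = "postD")

#' Simulate a full field design
#'
#' Runs [simulateAssembly()] once per design cell (compartment x week x
#' treatment) with a deterministic child seed per cell, and assembles the
#' combined counts table plus matching sample metadata. The metadata's
#' `community_size` column records the exact `N` used for each sample.
#'
#' @param design a [FieldDesign-class].
#' @param meta a [Metacommunity-class].
#' @return list with `table` (counts [CommunityTable-class]) and `metadata`
#'   (data.frame aligned to the table rows).
#' @export
simulateFieldDesign <- function(design, meta) {
  stopifnot(is(design, "FieldDesign"), is(meta, "Metacommunity"))
  validObject(design)
  tables <- list()
  mdRows <- list()
  for (comp in design@compartments) {
    for (wk in design@weeks) {
      for (trt in design@treatments) {
        scen <- if (is.function(design@scenario))
          design@scenario(comp, wk, trt) else design@scenario
        if (!is(scen, "AssemblyScenario"))
          stop("scenario function must return an AssemblyScenario")
        if (!is.null(design@sizeSchedule)) {
          N <- design@sizeSchedule(wk)
          if (!is.numeric(N) || N < 1)
            stop(sprintf("sizeSchedule returned invalid N for week %d", wk))
          scen@N <- as.integer(N)
        }
        scen@seed <- childSeed(design@seed, comp, wk, trt)
        tab <- simulateAssembly(meta, scen, design@replicates)
        ids <- sprintf("%s_w%02d_%s_r%02d", .COMP_ABBREV[[comp]], wk,
                       .TREAT_ABBREV[[trt]], seq_len(design@replicates))
        m <- abundanceMatrix(tab)
        rownames(m) <- ids
        tables[[length(tables) + 1L]] <- m
        mdRows[[length(mdRows) + 1L]] <- data.frame(
          sample_id = ids, compartment = comp, week = wk, treatment = trt,
          cultivar = NA_character_,
          plot = paste0("plot", seq_len(design@replicates)),
          x = NA_real_, y = NA_real_,
          community_size = as.numeric(scen@N),
          stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(rbind, tables)
  metadata <- do.call(rbind, mdRows)
  rownames(metadata) <- NULL
  table <- communityTable(values, "counts")
  list(table = table, metadata = validateSampleMetadata(metadata, table))
}
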