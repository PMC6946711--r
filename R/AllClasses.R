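#' @import methods
NULL

VALID_MODES <- c("counts", "relative", "clr")

COMPARTMENTS <- c("leaf", "root", "rhizosphere", "soil")
TREATMENTS <- c("control", "pre_flowering_drought", "post_flowering_drought")
CULTIVARS <- c("RTx430", "BTx642")
GUILDS <- c("saprotroph", "plant_pathogen", "amf", "endophyte", "yeast",
            "unknown")
LINEAGE_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
ASSEMBLY_PROCESSES <- c("drift", "homogeneous_selection", "variable_selection",
                        "dispersal_limitation", "homogenizing_dispersal")
PROCESS_CLASSES <- c("variable_selection", "homogeneous_selection",
                     "dispersal_limitation", "homogenizing_dispersal",
                     "stochastic_undominated", "selection_or_dispersal_ambiguous")

#' CommunityTable: samples-by-taxa abundance matrix with a mode flag
#'
#' The central data container: a numeric matrix with samples as rows and taxa
#' as columns, plus a `mode` flag recording what the cells mean. `counts` are
#' non-negative (typically integer) abundances, `relative` rows lie on the
#' unit simplex, and `clr` rows are centred log-ratio coordinates (they sum
#' to zero and may be negative). All downstream functions dispatch on the
#' mode and refuse mismatched inputs, so e.g. Aitchison distance cannot be
#' computed on raw counts by accident.
#'
#' @slot values numeric matrix, rows = samples, columns = taxa, with unique
#'   dimnames.
#' @slot mode one of `"counts"`, `"relative"`, `"clr"`.
#' @seealso [communityTable()], [abundanceMatrix()], [tableMode()]
#' @export
setClass("CommunityTable",
         representation(values = "matrix", mode = "character"),
         prototype(values = matrix(numeric(0), 0, 0,
                                   dimnames = list(character(0), character(0))),
                   mode = "counts"))

setValidity("CommunityTable", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate taxon ids")
  }
  if (length(object@mode) != 1L || !object@mode %in% VALID_MODES)
    msg <- c(msg, sprintf("mode must be one of %s",
                          paste(VALID_MODES, collapse = ", ")))
  else if (nrow(v) > 0 && is.numeric(v)) {
    if (object@mode %in% c("counts", "relative") && any(v < 0))
      msg <- c(msg, "negative abundances not allowed in counts/relative mode")
    if (object@mode == "relative" &&
        any(abs(rowSums(v) - 1) > 1e-9))
      msg <- c(msg, "relative rows must sum to 1 (tolerance 1e-9)")
    if (object@mode == "clr" && any(abs(rowSums(v)) > 1e-9))
      msg <- c(msg, "clr rows must sum to 0 (tolerance 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Metacommunity: regional species pool for assembly simulation
#'
#' Relative abundances of the regional pool on the simplex, optional
#' per-taxon trait values (used by selection scenarios) and the cladogram
#' the traits evolved on.
#'
#' @slot taxonIds character vector of taxon identifiers.
#' @slot abundance numeric simplex vector, named by taxon.
#' @slot traits numeric vector named by taxon, or length-0 when absent.
#' @slot tree the linked cladogram (`phylo`) or `NULL`.
#' @export
setClass("Metacommunity",
         representation(taxonIds = "character", abundance = "numeric",
                        traits = "numeric", tree = "ANY"),
         prototype(taxonIds = character(0), abundance = numeric(0),
                   traits = numeric(0), tree = NULL))

setValidity("Metacommunity", function(object) {
  msg <- character(0)
  if (length(object@abundance) != length(object@taxonIds))
    msg <- c(msg, "abundance and taxonIds lengths differ")
  if (length(object@abundance)) {
    if (any(object@abundance < 0)) msg <- c(msg, "abundances must be >= 0")
    if (abs(sum(object@abundance) - 1) > 1e-12)
      msg <- c(msg, "abundances must sum to 1 (tolerance 1e-12)")
  }
  if (length(object@traits) &&
      !setequal(names(object@traits), object@taxonIds))
    msg <- c(msg, "trait names must match taxonIds")
  if (!is.null(object@tree) && !inherits(object@tree, "phylo"))
    msg <- c(msg, "tree must be a phylo object or NULL")
  if (length(msg)) msg else TRUE
})

#' AssemblyScenario: parameters of one community-assembly regime
#'
#' @slot process one of `drift`, `homogeneous_selection`,
#'   `variable_selection`, `dispersal_limitation`, `homogenizing_dispersal`.
#' @slot N local community size (individuals per sample).
#' @slot generations number of resampling generations after seeding.
#' @slot m immigration (or migrant-exchange) rate in `[0, 1]`.
#' @slot s selection strength (Gaussian stabilising selection, >= 0).
#' @slot optima named numeric of per-plot trait optima (may be empty; a
#'   shared default optimum is derived from the metacommunity).
#' @slot seed integer seed.
#' @export
setClass("AssemblyScenario",
         representation(process = "character", N = "integer",
                        generations = "integer", m = "numeric", s = "numeric",
                        optima = "numeric", seed = "integer"),
         prototype(process = "drift", N = 100L, generations = 0L, m = 0,
                   s = 0, optima = numeric(0), seed = 1L))

setValidity("AssemblyScenario", function(object) {
  msg <- character(0)
  if (!object@process %in% ASSEMBLY_PROCESSES)
    msg <- c(msg, sprintf("unknown process '%s'", object@process))
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (object@generations < 0L) msg <- c(msg, "generations must be >= 0")
  if (object@m < 0 || object@m > 1) msg <- c(msg, "m must lie in [0, 1]")
  if (object@s < 0) msg <- c(msg, "s must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FieldDesign: compartment x week x treatment sampling grid
#'
#' Every design cell (compartment, week, treatment) maps to exactly one
#' assembly scenario; replicates within a cell share the scenario but get
#' independent child seeds. An optional per-week size schedule overrides the
#' scenario's `N`, producing a community-size gradient across weeks.
#'
#' @slot compartments character subset of leaf/root/rhizosphere/soil.
#' @slot weeks integer vector in 0..17.
#' @slot treatments character subset of the treatment vocabulary.
#' @slot replicates replicates per cell.
#' @slot scenario the template [AssemblyScenario-class], or a function
#'   `(compartment, week, treatment) -> AssemblyScenario`.
#' @slot sizeSchedule `NULL` or a function `week -> N`.
#' @slot seed integer master seed; all cell seeds derive from it.
#' @export
setClass("FieldDesign",
         representation(compartments = "character", weeks = "integer",
                        treatments = "character", replicates = "integer",
                        scenario = "ANY", sizeSchedule = "ANY",
                        seed = "integer"),
         prototype(compartments = "leaf", weeks = 1L, treatments = "control",
                   replicates = 3L, scenario = NULL, sizeSchedule = NULL,
                   seed = 1L))

setValidity("FieldDesign", function(object) {
  msg <- character(0)
  if (!length(object@compartments) || !length(object@weeks) ||
      !length(object@treatments) || object@replicates < 1L)
    msg <- c(msg, "design must have >= 1 compartment, week, treatment and replicate")
  if (!all(object@compartments %in% COMPARTMENTS))
    msg <- c(msg, "unknown compartment")
  if (!all(object@treatments %in% TREATMENTS))
    msg <- c(msg, "unknown treatment")
  if (any(object@weeks < 0L) || any(object@weeks > 17L))
    msg <- c(msg, "weeks must lie in 0..17")
  if (!(is(object@scenario, "AssemblyScenario") ||
        is.function(object@scenario)))
    msg <- c(msg, "scenario must be an AssemblyScenario or a function")
  if (!is.null(object@sizeSchedule) && !is.function(object@sizeSchedule))
    msg <- c(msg, "sizeSchedule must be NULL or a function of week")
  if (length(msg)) msg else TRUE
})

#' NullModelResult: per-pair observed statistic against its null
#'
#' Holds, for every sample pair, the observed statistic, the null mean and
#' standard deviation, and either a standardised z-score (bNTI) or a scaled
#' quantile score in `[-1, 1]` (RCI). Pairs whose null distribution is
#' (numerically) degenerate carry `degenerate = TRUE` and an `NA` score.
#'
#' @slot pairs data.frame with columns `sampleA`, `sampleB`, `observed`,
#'   `nullMean`, `nullSd`, `score`, `degenerate`.
#' @slot statistic `"bNTI"` or `"RCI"`.
#' @slot reps null replicate count.
#' @slot variant variant label (e.g. RCI null flavour), possibly `""`.
#' @export
setClass("NullModelResult",
         representation(pairs = "data.frame", statistic = "character",
                        reps = "integer", variant = "character"),
         prototype(pairs = data.frame(), statistic = "bNTI", reps = 999L,
                   variant = ""))

setValidity("NullModelResult", function(object) {
  msg <- character(0)
  need <- c("sampleA", "sampleB", "observed", "nullMean", "nullSd", "score",
            "degenerate")
  if (!all(need %in% names(object@pairs)))
    msg <- c(msg, "pairs must have columns sampleA/sampleB/observed/nullMean/nullSd/score/degenerate")
  if (object@reps < 1L) msg <- c(msg, "reps must be >= 1")
  if (object@statistic == "RCI" && nrow(object@pairs)) {
    sc <- object@pairs$score
    if (any(!is.na(sc) & (sc < -1 - 1e-12 | sc > 1 + 1e-12)))
      msg <- c(msg, "RCI scores must lie in [-1, 1]")
  }
  if (nrow(object@pairs)) {
    bad <- !is.na(object@pairs$nullSd) & object@pairs$nullSd < 1e-12 &
      !object@pairs$degenerate & object@statistic == "bNTI"
    if (any(bad)) msg <- c(msg, "degenerate flag must be set when null sd < 1e-12")
  }
  if (length(msg)) msg else TRUE
})

#' DOCResult: dissimilarity-overlap curve analysis
#'
#' @slot points data.frame of pair points (`overlap`, `rjsd`).
#' @slot curve data.frame of the smoothed curve (`overlap`, `fitted`).
#' @slot xmin overlap value where the terminal negative slope begins
#'   (median over bootstrap curves).
#' @slot fns fraction of real pairs with overlap beyond `xmin`.
#' @slot pvalue fraction of bootstrap curves lacking a negative terminal
#'   slope (after any Bonferroni scaling).
#' @slot significant logical; `TRUE` when >= 95% of bootstrap curves have a
#'   negative terminal slope (adjusted p <= 0.05).
#' @slot bootstrapReps bootstrap replicates used.
#' @slot excluded number of zero-overlap pairs excluded.
#' @export
setClass("DOCResult",
         representation(points = "data.frame", curve = "data.frame",
                        xmin = "numeric", fns = "numeric", pvalue = "numeric",
                        significant = "logical", bootstrapReps = "integer",
                        excluded = "integer"),
         prototype(points = data.frame(), curve = data.frame(),
                   xmin = NA_real_, fns = NA_real_, pvalue = NA_real_,
                   significant = NA, bootstrapReps = 0L, excluded = 0L))

setValidity("DOCResult", function(object) {
  msg <- character(0)
  if (!is.na(object@fns) && (object@fns < 0 || object@fns > 1))
    msg <- c(msg, "fns must lie in [0, 1]")
  if (nrow(object@points)) {
    if (any(object@points$overlap < 0 | object@points$overlap > 1))
      msg <- c(msg, "overlap must lie in [0, 1]")
    if (any(object@points$rjsd < -1e-12 |
            object@points$rjsd > sqrt(log(2)) + 1e-9))
      msg <- c(msg, "rJSD must lie in [0, sqrt(ln 2)]")
    if (!is.na(object@xmin) &&
        (object@xmin < min(object@points$overlap) - 1e-9 ||
         object@xmin > max(object@points$overlap) + 1e-9))
      msg <- c(msg, "xmin must lie within the observed overlap range")
  }
  if (length(msg)) msg else TRUE
})
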