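#' Accessors for CommunityTable and friends
#'
#' `abundanceMatrix` returns the samples-by-taxa matrix, `tableMode` the mode
#' flag, `sampleIds`/`taxonIds` the ordered identifiers.
#'
#' @param x a [CommunityTable-class] (or, for `taxonIds`, a
#'   [Metacommunity-class]).
#' @return `abundanceMatrix`: numeric matrix; the others: character / scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("tableMode", function(x) standardGeneric("tableMode"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))

#' @rdname accessors
setMethod("abundanceMatrix", "CommunityTable", function(x) x@values)

#' @rdname accessors
setMethod("tableMode", "CommunityTable", function(x) x@mode)

#' @rdname accessors
setMethod("sampleIds", "CommunityTable", function(x) rownames(x@values))

#' @rdname accessors
setMethod("taxonIds", "CommunityTable", function(x) colnames(x@values))

#' @rdname accessors
setMethod("taxonIds", "Metacommunity", function(x) x@taxonIds)

#' @describeIn accessors number of samples and taxa.
setMethod("dim", "CommunityTable", function(x) dim(x@values))

#' Null-model pair table accessor
#'
#' @param x a [NullModelResult-class].
#' @return data.frame with one row per sample pair.
#' @export
setGeneric("pairScores", function(x) standardGeneric("pairScores"))

#' @rdname pairScores
setMethod("pairScores", "NullModelResult", function(x) x@pairs)

setMethod("show", "CommunityTable", function(object) {
  cat(sprintf("CommunityTable: %d samples x %d taxa (mode: %s)\n",
              nrow(object@values), ncol(object@values), object@mode))
  if (nrow(object@values)) {
    tot <- rowSums(object@values)
    cat(sprintf("  row totals: min %.4g, median %.4g, max %.4g\n",
                min(tot), stats::median(tot), max(tot)))
  }
})

setMethod("show", "Metacommunity", function(object) {
  cat(sprintf("Metacommunity: %d taxa%s%s\n", length(object@taxonIds),
              if (length(object@traits)) ", with traits" else "",
              if (!is.null(object@tree)) ", with cladogram" else ""))
})

setMethod("show", "AssemblyScenario", function(object) {
  cat(sprintf("AssemblyScenario: %s (N=%d, generations=%d, m=%g, s=%g, seed=%d)\n",
              object@process, object@N, object@generations, object@m,
              object@s, object@seed))
})

setMethod("show", "FieldDesign", function(object) {
  cat(sprintf("FieldDesign: %d compartments x %d weeks x %d treatments x %d replicates (%d samples)\n",
              length(object@compartments), length(object@weeks),
              length(object@treatments), object@replicates,
              length(object@compartments) * length(object@weeks) *
                length(object@treatments) * object@replicates))
})

setMethod("show", "NullModelResult", function(object) {
  cat(sprintf("NullModelResult: %s over %d pairs (%d null replicates%s)\n",
              object@statistic, nrow(object@pairs), object@reps,
              if (nzchar(object@variant))
                paste0(", variant: ", object@variant) else ""))
  if (nrow(object@pairs)) {
    sc <- object@pairs$score
    cat(sprintf("  score: min %.3g, median %.3g, max %.3g; %d degenerate pair(s)\n",
                min(sc, na.rm = TRUE), stats::median(sc, na.rm = TRUE),
                max(sc, na.rm = TRUE), sum(object@pairs$degenerate)))
  }
})

setMethod("show", "DOCResult", function(object) {
  cat(sprintf("DOCResult: %d pairs (%d zero-overlap pairs excluded)\n",
              nrow(object@points), object@excluded))
  cat(sprintf("  xmin = %.4g, Fns = %.4g, p = %.4g (%ssignificant, %d bootstraps)\n",
              object@xmin, object@fns, object@pvalue,
              if (isTRUE(object@significant)) "" else "not ",
              object@bootstrapReps))
})
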