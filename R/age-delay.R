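#' Community-age delay protocol (drought effect on development)
#'
#' Quantifies how much a perturbation delays community development by
#' training a regression forest to predict sample age (week) from taxon
#' abundances of unperturbed (control) samples. Half the control samples
#' (a seeded, week-stratified split) train a full forest; features are
#' ranked by permutation importance; a sparse forest is refit on the top-k
#' taxa (k chosen by out-of-bag error over a small grid when
#' `topK = "cv_select"`); the sparse model then predicts the ages of the
#' held-out controls and of every treatment sample. The reported
#' discrepancy at a week is the mean predicted age of held-out controls
#' minus the mean predicted age of treatment samples: positive values mean
#' the treatment communities look younger than their true age, i.e.
#' development is delayed.
#'
#' @param x a [CommunityTable-class] (any mode; used as the feature
#'   matrix).
#' @param metadata sample metadata with `week` and `treatment`; control
#'   samples must span >= 3 weeks with >= 4 samples each.
#' @param topK `"cv_select"` (default) or an integer number of taxa for
#'   the sparse model.
#' @param numTrees trees per forest (default 500).
#' @param seed integer seed controlling the split and both forests.
#' @return list with `discrepancy` (data.frame `week`, `treatment`,
#'   `controlPredicted`, `treatmentPredicted`, `discrepancy`, `nControl`,
#'   `nTreatment`), `topTaxa` (features of the sparse model) and `k`.
#' @export
ageDelayProtocol <- function(x, metadata, topK = "cv_select",
                             numTrees = 500L, seed = NULL) {
  metadata <- validateSampleMetadata(metadata, x)
  m <- abundanceMatrix(x)
  isControl <- metadata$treatment == "control"
  ctlWeeks <- metadata$week[isControl]
  if (length(unique(ctlWeeks)) < 3L)
    stop("control samples must span >= 3 weeks")
  perWeek <- table(ctlWeeks)
  if (any(perWeek < 4L))
    stop(sprintf("fewer than 4 control samples in week(s): %s",
                 paste(names(perWeek)[perWeek < 4L], collapse = ", ")))

  withSeed(seed, {
    ctlIdx <- which(isControl)
    train <- unlist(lapply(split(ctlIdx, metadata$week[ctlIdx]),
                           function(ix) sample(ix, floor(length(ix) / 2))),
                    use.names = FALSE)
    holdout <- setdiff(ctlIdx, train)

    full <- randomForest::randomForest(x = m[train, , drop = FALSE],
                                       y = metadata$week[train],
                                       ntree = numTrees, importance = TRUE)
    imp <- randomForest::importance(full, type = 1L)[, 1L]
    ranked <- names(sort(imp, decreasing = TRUE))

    if (identical(topK, "cv_select")) {
      grid <- unique(pmin(c(5L, 10L, 20L, 40L, length(ranked)),
                          length(ranked)))
      oob <- vapply(grid, function(k) {
        f <- randomForest::randomForest(
          x = m[train, ranked[seq_len(k)], drop = FALSE],
          y = metadata$week[train], ntree = numTrees)
        f$mse[numTrees]
      }, numeric(1))
      k <- grid[which.min(oob)]
    } else {
      k <- as.integer(topK)
      if (is.na(k) || k < 1L || k > length(ranked))
        stop("topK must be 'cv_select' or an integer in 1..nTaxa")
    }
    topTaxa <- ranked[seq_len(k)]
    sparse <- randomForest::randomForest(
      x = m[train, topTaxa, drop = FALSE],
      y = metadata$week[train], ntree = numTrees)

    predictFor <- function(ix) stats::predict(
      sparse, m[ix, topTaxa, drop = FALSE])
    ctlPred <- predictFor(holdout)
    ctlWeek <- metadata$week[holdout]

    rows <- list()
    for (trt in setdiff(unique(metadata$treatment), "control")) {
      tIdx <- which(metadata$treatment == trt)
      tPred <- predictFor(tIdx)
      tWeek <- metadata$week[tIdx]
      for (w in sort(intersect(unique(tWeek), unique(ctlWeek)))) {
        cp <- mean(ctlPred[ctlWeek == w])
        tp <- mean(tPred[tWeek == w])
        rows[[length(rows) + 1L]] <- data.frame(
          week = w, treatment = trt, controlPredicted = cp,
          treatmentPredicted = tp, discrepancy = cp - tp,
          nControl = sum(ctlWeek == w), nTreatment = sum(tWeek == w),
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      stop("no week is shared between held-out controls and any treatment")
    disc <- do.call(rbind, rows)
    rownames(disc) <- NULL
    list(discrepancy = disc, topTaxa = topTaxa, k = k)
  })
}
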