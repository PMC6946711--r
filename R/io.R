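#' Construct a CommunityTable
#'
#' @param values numeric matrix (samples x taxa) with unique row and column
#'   names, or a data.frame coercible to one.
#' @param mode abundance mode: `"counts"` (default), `"relative"` or `"clr"`.
#' @return a validated [CommunityTable-class].
#' @examples
#' m <- matrix(c(5, 0, 3, 2, 1, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' communityTable(m)
#' @export
communityTable <- function(values, mode = c("counts", "relative", "clr")) {
  mode <- match.arg(mode)
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("CommunityTable", values = values, mode = mode)
}

#' Read / write a community abundance table
#'
#' Tab-separated text with a header row; first column `sample_id`, remaining
#' columns one per taxon. Round-trips at full double precision.
#'
#' @param path file path.
#' @param mode abundance mode of the stored table.
#' @return `readCommunityTable`: a [CommunityTable-class];
#'   `writeCommunityTable`: the path, invisibly.
#' @export
readCommunityTable <- function(path, mode = c("counts", "relative", "clr")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("first column of a community table must be 'sample_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  communityTable(m, mode)
}

#' @rdname readCommunityTable
#' @param x a [CommunityTable-class].
#' @export
writeCommunityTable <- function(x, path) {
  stopifnot(is(x, "CommunityTable"))
  df <- data.frame(sample_id = sampleIds(x), abundanceMatrix(x),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate (and read/write) sample metadata
#'
#' Metadata carries the design factors of each sample: compartment
#' (leaf/root/rhizosphere/soil), week (0-17), treatment, cultivar, plot,
#' optional field coordinates `x`,`y` and an optional `community_size` proxy
#' (qPCR abundance, fungal read fraction, or the simulator's exact N).
#'
#' @param metadata data.frame with at least `sample_id`, `compartment`,
#'   `week`, `treatment`.
#' @param table optional [CommunityTable-class]; when given, every table
#'   sample must appear exactly once in the metadata and rows are reordered
#'   to match the table.
#' @return the validated (possibly reordered) data.frame.
#' @export
validateSampleMetadata <- function(metadata, table = NULL) {
  need <- c("sample_id", "compartment", "week", "treatment")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop(sprintf("metadata is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(metadata$compartment), COMPARTMENTS)
  if (length(bad))
    stop(sprintf("unknown compartment(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(metadata$treatment), TREATMENTS)
  if (length(bad))
    stop(sprintf("unknown treatment(s): %s", paste(bad, collapse = ", ")))
  if ("cultivar" %in% names(metadata)) {
    bad <- setdiff(stats::na.omit(unique(metadata$cultivar)), CULTIVARS)
    if (length(bad))
      stop(sprintf("unknown cultivar(s): %s", paste(bad, collapse = ", ")))
  }
  wk <- metadata$week
  if (any(is.na(wk)) || any(wk != round(wk)) || any(wk < 0) || any(wk > 17))
    stop("week must be an integer in 0..17")
  if (!is.null(table)) {
    missing <- setdiff(sampleIds(table), metadata$sample_id)
    if (length(missing))
      stop(sprintf("metadata is missing table sample(s): %s",
                   paste(missing, collapse = ", ")))
    metadata <- metadata[match(sampleIds(table), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  metadata
}

#' @rdname validateSampleMetadata
#' @param path file path (TSV).
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  validateSampleMetadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname validateSampleMetadata
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate (and read/write) taxon annotations
#'
#' One row per taxon: the six-rank lineage (kingdom..genus) and a functional
#' guild. Unresolved ranks are marked with the literal string `"unknown"`,
#' never left empty.
#'
#' @param annotation data.frame with columns `taxon_id`, the six lineage
#'   ranks, and `guild`.
#' @return the validated data.frame (empty rank cells normalised to
#'   `"unknown"`).
#' @export
validateTaxonAnnotation <- function(annotation) {
  need <- c("taxon_id", LINEAGE_RANKS, "guild")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop(sprintf("annotation is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  annotation$taxon_id <- as.character(annotation$taxon_id)
  if (anyDuplicated(annotation$taxon_id))
    stop("duplicate taxon_id in annotation")
  for (r in LINEAGE_RANKS) {
    v <- as.character(annotation[[r]])
    v[is.na(v) | !nzchar(v)] <- "unknown"
    annotation[[r]] <- v
  }
  bad <- setdiff(unique(annotation$guild), GUILDS)
  if (length(bad))
    stop(sprintf("unknown guild(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(GUILDS, collapse = ", ")))
  annotation
}

#' @rdname validateTaxonAnnotation
#' @param path file path (TSV).
#' @export
readTaxonAnnotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  validateTaxonAnnotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname validateTaxonAnnotation
#' @export
writeTaxonAnnotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a complete dataset from disk
#'
#' Reads the OTU table, sample metadata and taxon annotation, cross-validates
#' them (every table sample present in the metadata; every table taxon
#' annotated) and aligns the metadata row order to the table.
#'
#' @param tablePath,metadataPath,taxonomyPath TSV file paths.
#' @param mode abundance mode of the table on disk.
#' @return list with elements `table` ([CommunityTable-class]), `metadata`
#'   (data.frame) and `annotation` (data.frame).
#' @export
loadDataset <- function(tablePath, metadataPath, taxonomyPath,
                        mode = "counts") {
  table <- readCommunityTable(tablePath, mode)
  metadata <- validateSampleMetadata(
    utils::read.delim(metadataPath, stringsAsFactors = FALSE), table)
  annotation <- readTaxonAnnotation(taxonomyPath)
  missing <- setdiff(taxonIds(table), annotation$taxon_id)
  if (length(missing))
    stop(sprintf("annotation is missing taxon/taxa: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  list(table = table, metadata = metadata, annotation = annotation)
}

#' Read / write a cladogram as newick
#'
#' @param path newick file path.
#' @return `readCladogram`: an `ape::phylo`; `writeCladogram`: the path,
#'   invisibly.
#' @export
readCladogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ape::read.tree(path)
}

#' @rdname readCladogram
#' @param tree a `phylo` object.
#' @export
writeCladogram <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
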