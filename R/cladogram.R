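#' Build a cladogram from ranked taxonomy
#'
#' Converts a ranked lineage table into a rooted tree usable as a stand-in
#' phylogeny for phylogenetic beta-diversity (bMNTD/bNTI). One internal node
#' is created per distinct rank path (kingdom, phylum, class, order, family,
#' genus); each tip hangs below the deepest rank resolved for that taxon, and
#' every edge gets the same configurable length. Because bNTI standardises
#' against a null, only relative patristic distances matter, so unit edge
#' lengths are the default.
#'
#' Unresolved ranks (the literal `"unknown"`) truncate the lineage: a taxon
#' with unknown genus attaches directly under its family node, avoiding
#' zero-length one-child chains. Ranks are read as a prefix - the lineage is
#' used down to the first unknown rank.
#'
#' @param annotation taxon annotation data.frame (see
#'   [validateTaxonAnnotation()]).
#' @param branchLengthPerRank positive edge length shared by every edge.
#' @return a rooted `ape::phylo` whose tip labels are the annotation's
#'   `taxon_id`s.
#' @examples
#' ann <- data.frame(taxon_id = c("t1", "t2"),
#'                   kingdom = "Fungi", phylum = "Ascomycota",
#'                   class = "Sordariomycetes", order = "Hypocreales",
#'                   family = "Nectriaceae", genus = "Fusarium",
#'                   guild = "plant_pathogen")
#' tr <- taxonomyToCladogram(ann)
#' patristicDistances(tr)["t1", "t2"] # 2: one unit tip edge each side
#' @export
taxonomyToCladogram <- function(annotation, branchLengthPerRank = 1) {
  annotation <- validateTaxonAnnotation(annotation)
  if (!nrow(annotation)) stop("annotation is empty")
  if (!is.numeric(branchLengthPerRank) || branchLengthPerRank <= 0)
    stop("branchLengthPerRank must be a positive number")
  bl <- branchLengthPerRank

  # resolved lineage prefix per taxon (stop at first unknown rank)
  paths <- lapply(seq_len(nrow(annotation)), function(i) {
    lin <- as.character(unlist(annotation[i, LINEAGE_RANKS]))
    k <- match("unknown", lin)
    if (!is.na(k)) lin <- lin[seq_len(k - 1L)]
    lin
  })
  names(paths) <- annotation$taxon_id

  build <- function(taxa, depth) {
    # taxa: names of taxa under this node; depth: next rank index to split on
    here <- taxa[vapply(paths[taxa], length, 1L) < depth]
    below <- setdiff(taxa, here)
    parts <- vapply(here, function(t) sprintf("%s:%g", t, bl), "")
    if (length(below)) {
      key <- vapply(paths[below], function(p) p[depth], "")
      for (grp in split(below, key)) {
        parts <- c(parts, sprintf("%s:%g", build(grp, depth + 1L), bl))
      }
    }
    if (length(parts) == 1L && length(here) == 0L) {
      sprintf("(%s)", parts)
    } else sprintf("(%s)", paste(parts, collapse = ","))
  }

  nw <- paste0(build(annotation$taxon_id, 1L), ";")
  tree <- ape::read.tree(text = nw)
  if (is.null(tree)) stop("internal error: failed to build cladogram")
  tree
}

#' Patristic distance matrix of a cladogram
#'
#' Sum of branch lengths along the path between every pair of tips; labels
#' follow the tip order given, symmetric with zero diagonal.
#'
#' @param tree an `ape::phylo`.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristicDistances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1L) {
    m <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  d <- ape::dist.nodes(tree)[seq_along(tree$tip.label),
                             seq_along(tree$tip.label)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}
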