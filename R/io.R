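#' @importFrom utils read.delim write.table
NULL

# Read a delimited text file, accepting tab- or comma-separated input.
.readDelim <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an accession taxonomy table
#'
#' Reads a tab- or comma-delimited file with header columns `accession_id`,
#' `species`, `section`, `genome`, `ploidy` (extra columns such as `country`
#' are carried along). Section names must belong to the closed vocabulary of
#' [arachisSections()]; genome tokens to A/B/AB/D/unassigned. Duplicate
#' accession ids, a species mapped to two sections, or an AB-genome accession
#' that is not tetraploid are rejected with an informative error.
#'
#' @param path Path to the delimited file.
#' @return A validated taxonomy `data.frame`.
#' @seealso [writeTaxonomy()], [generateTaxonomy()]
#' @export
readTaxonomy <- function(path) {
  tax <- .readDelim(path)
  validateTaxonomy(tax)
}

#' Validate a taxonomy data.frame
#'
#' @param tax data.frame as described in [readTaxonomy()].
#' @return The taxonomy, with `ploidy` coerced to integer, invisibly valid.
#' @export
validateTaxonomy <- function(tax) {
  tax <- as.data.frame(tax)
  if ("ploidy" %in% colnames(tax)) tax$ploidy <- as.integer(tax$ploidy)
  err <- .validateTaxonomyDF(tax)
  if (!is.null(err)) .stopf("invalid taxonomy: %s", err)
  tax
}

#' Read a marker panel table
#'
#' Delimited file with header `marker_id`, `source_class` (`genomic` or
#' `genic`), `size_min`, `size_max` — the permitted band-size window in bp.
#'
#' @param path Path to the delimited file.
#' @return A validated marker panel `data.frame`.
#' @seealso [generateMarkerPanel()]
#' @export
readMarkerPanel <- function(path) {
  panel <- .readDelim(path)
  validateMarkerPanel(panel)
}

#' Validate a marker panel data.frame
#'
#' @param panel data.frame as described in [readMarkerPanel()].
#' @return The panel with size columns coerced to integer.
#' @export
validateMarkerPanel <- function(panel) {
  panel <- as.data.frame(panel)
  for (col in c("size_min", "size_max"))
    if (col %in% colnames(panel)) panel[[col]] <- as.integer(panel[[col]])
  err <- .validateMarkerPanelDF(panel)
  if (!is.null(err)) .stopf("invalid marker panel: %s", err)
  panel
}

#' Read long-format band scores into an SSRSet
#'
#' Rows are `(accession_id, marker_id, size_bp, presence)` with presence in
#' \{0, 1\}. Accessions or markers not listed in the taxonomy/panel, and band
#' sizes outside the marker's window, are errors. Any (accession, marker)
#' combination without a row — or scored 0 — is absent: the dominant-marker
#' coding has no missing-data state. With `binTolerance > 0`, band sizes of
#' the same marker within the tolerance are merged into one allele labelled
#' by the smallest size in the bin (sizes are otherwise assumed pre-called
#' against a ladder).
#'
#' @param path Path to the delimited file.
#' @param panel Marker panel data.frame ([readMarkerPanel()]).
#' @param taxonomy Taxonomy data.frame ([readTaxonomy()]); its row order
#'   fixes the accession order.
#' @param cultivatedSpecies Marker-source species (see [SSRSet()]).
#' @param binTolerance Integer bp; 0 (default) disables binning.
#' @return An [SSRSet-class]. The companion amplification matrix is available
#'   via [amplificationMatrix()].
#' @export
readGenotypeLong <- function(path, panel, taxonomy,
                             cultivatedSpecies = "A. hypogaea",
                             binTolerance = 0L) {
  panel <- validateMarkerPanel(panel)
  taxonomy <- validateTaxonomy(taxonomy)
  gt <- .readDelim(path)
  required <- c("accession_id", "marker_id", "size_bp", "presence")
  missing <- setdiff(required, colnames(gt))
  if (length(missing))
    .stopf("genotype table lacks column(s): %s",
           paste(missing, collapse = ", "))
  unknown <- setdiff(unique(gt$accession_id), taxonomy$accession_id)
  if (length(unknown))
    .stopf("unknown accession id(s) in genotype table: %s",
           paste(unknown, collapse = ", "))
  unknown <- setdiff(unique(gt$marker_id), panel$marker_id)
  if (length(unknown))
    .stopf("unknown marker id(s) in genotype table: %s",
           paste(unknown, collapse = ", "))
  if (!all(gt$presence %in% c(0L, 1L)))
    .stopf("presence must be 0 or 1")
  gt$size_bp <- as.integer(gt$size_bp)
  idx <- match(gt$marker_id, panel$marker_id)
  out <- gt$size_bp < panel$size_min[idx] | gt$size_bp > panel$size_max[idx]
  if (any(out))
    .stopf("band size outside marker window: %s",
           paste(unique(paste0(gt$marker_id[out], ":", gt$size_bp[out])),
                 collapse = ", "))
  gt <- gt[gt$presence == 1L, , drop = FALSE]
  if (binTolerance > 0 && nrow(gt)) {
    gt$size_bp <- unsplit(lapply(split(gt$size_bp, gt$marker_id), function(s) {
      u <- sort(unique(s))
      bin <- u[1]
      lab <- setNames(u, u)
      for (v in u) {
        if (v - bin > binTolerance) bin <- v
        lab[as.character(v)] <- bin
      }
      lab[as.character(s)]
    }), gt$marker_id)
  }
  alleles <- unique(gt[, c("marker_id", "size_bp")])
  alleles <- alleles[order(alleles$marker_id, alleles$size_bp), , drop = FALSE]
  presence <- matrix(FALSE, nrow(alleles), nrow(taxonomy))
  if (nrow(gt)) {
    ri <- match(paste(gt$marker_id, gt$size_bp),
                paste(alleles$marker_id, alleles$size_bp))
    ci <- match(gt$accession_id, taxonomy$accession_id)
    presence[cbind(ri, ci)] <- TRUE
  }
  SSRSet(presence, alleles, taxonomy, panel, cultivatedSpecies)
}

#' Write SSRSet components back to delimited text
#'
#' `writeGenotypeLong()` emits the long-format band table (presence-1 rows
#' only, sorted by accession, marker, size); `writeTaxonomy()` and
#' `writeMarkerPanel()` emit their tables as TSV. Re-reading with the
#' corresponding readers reproduces the object exactly.
#'
#' @param x An [SSRSet-class] (or data.frame for the table writers).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeGenotypeLong <- function(x, path) {
  p <- presenceMatrix(x)
  al <- alleleTable(x)
  idx <- which(p, arr.ind = TRUE)
  gt <- data.frame(accession_id = colnames(x)[idx[, 2]],
                   marker_id = al$marker_id[idx[, 1]],
                   size_bp = al$size_bp[idx[, 1]],
                   presence = 1L)
  gt <- gt[order(gt$accession_id, gt$marker_id, gt$size_bp), , drop = FALSE]
  write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeLong
#' @export
writeTaxonomy <- function(x, path) {
  tax <- if (is(x, "SSRSet")) taxonomyTable(x) else as.data.frame(x)
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeLong
#' @export
writeMarkerPanel <- function(x, path) {
  panel <- if (is(x, "SSRSet")) markerPanel(x) else as.data.frame(x)
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a support-annotated tree as Newick
#'
#' Serializes an [ape::phylo] tree (as produced by [neighborJoining()] or
#' [bootstrapSupport()]) in standard Newick. Branch lengths are written with
#' 6 decimals; bootstrap supports, when present as `node.label`, appear as
#' integer-percent internal node labels. Re-parsing yields the same
#' bipartition set and branch lengths. Note the usual Newick convention:
#' spaces in tip labels are written as underscores.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @seealso [readNewick()]
#' @export
writeNewick <- function(tree, path) {
  if (!inherits(tree, "phylo")) .stopf("tree must be an ape 'phylo' object")
  tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path, digits = 8)
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that errors on unreadable input.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object (internal node labels are kept as written).
#' @export
readNewick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) .stopf("could not parse Newick file: %s", path)
  tree
}

#' Write a set of result tables plus a JSON summary
#'
#' Each named table is written as `<name>.tsv` with rows ordered by their key
#' columns (all columns, left to right) so output is deterministic; a
#' `summary.json` records table names, dimensions and column names. Running
#' twice on the same input produces byte-identical files.
#'
#' @param tables Named list of data.frames.
#' @param path Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
writeReport <- function(tables, path) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    .stopf("tables must be a named list")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) .stopf("cannot create directory: %s", path)
  files <- character()
  for (nm in sort(names(tables))) {
    tab <- as.data.frame(tables[[nm]])
    if (nrow(tab) > 1)
      tab <- tab[do.call(order, unname(as.list(tab))), , drop = FALSE]
    f <- file.path(path, paste0(nm, ".tsv"))
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  summ <- lapply(tables[sort(names(tables))], function(tab)
    list(n_rows = nrow(as.data.frame(tab)),
         columns = colnames(as.data.frame(tab))))
  jf <- file.path(path, "summary.json")
  jsonlite::write_json(summ, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, jf))
}
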