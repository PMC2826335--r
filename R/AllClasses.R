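#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' SSRSet: presence/absence SSR genotypes with taxonomy and marker metadata
#'
#' `SSRSet` extends [SummarizedExperiment::SummarizedExperiment] for dominant
#' (0/1 band-scored) SSR genotype data. Rows are alleles — unique
#' (marker, fragment size in bp) pairs — and columns are accessions. The
#' single assay, `"presence"`, is a logical matrix: `TRUE` where the allele
#' (band) was scored in the accession. There is no missing-data state: a band
#' not recorded is absent, matching the strict 0/1 coding of dominant SSR
#' scoring.
#'
#' Component metadata:
#' \describe{
#'   \item{`rowData`}{`marker_id` and integer `size_bp` per allele.}
#'   \item{`colData`}{accession taxonomy: `species`, `section` (one of
#'     [arachisSections()]), `genome` (A/B/AB/D/unassigned), `ploidy`
#'     (18, 20 or 40).}
#'   \item{`metadata(x)$panel`}{marker panel: `marker_id`,
#'     `source_class` (`"genomic"` = derived from the cultivated species'
#'     genomic library; `"genic"` = derived from conserved gene sequences of
#'     related genera), `size_min`, `size_max` (permitted band sizes, bp).}
#'   \item{`metadata(x)$cultivated_species`}{the marker-source species
#'     excluded when scoring genomic-class transferability
#'     (default `"A. hypogaea"`).}
#' }
#'
#' Validity requires: unique (marker, size) rows, every allele carried by at
#' least one accession, allele sizes inside their marker's window, every
#' allele's marker present in the panel, and a valid taxonomy (AB genome
#' implies ploidy 40; sections outside *Arachis* imply unassigned genome).
#'
#' @seealso [SSRSet()] for construction, [amplificationMatrix()],
#'   [readGenotypeLong()], [simulateDataset()].
#' @aliases SSRSet-class
#' @exportClass SSRSet
setClass("SSRSet", contains = "SummarizedExperiment")

.validateTaxonomyDF <- function(tax) {
  required <- c("accession_id", "species", "section", "genome", "ploidy")
  missing <- setdiff(required, colnames(tax))
  if (length(missing))
    return(sprintf("taxonomy lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  dup <- unique(tax$accession_id[duplicated(tax$accession_id)])
  if (length(dup))
    return(sprintf("duplicate accession_id: %s", paste(dup, collapse = ", ")))
  bad <- setdiff(unique(tax$section), arachisSections())
  if (length(bad))
    return(sprintf(
      "unknown section token(s): %s (allowed: %s)",
      paste(bad, collapse = ", "),
      paste(arachisSections(), collapse = ", ")))
  bad <- setdiff(unique(tax$genome), .GENOME_CLASSES)
  if (length(bad))
    return(sprintf("unknown genome token(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "),
                   paste(.GENOME_CLASSES, collapse = ", ")))
  if (!all(tax$ploidy %in% .PLOIDIES))
    return(sprintf("ploidy must be one of %s",
                   paste(.PLOIDIES, collapse = ", ")))
  off <- tax$genome == "AB" & tax$ploidy != 40L
  if (any(off))
    return(sprintf("genome AB implies ploidy 40; violated by: %s",
                   paste(tax$accession_id[off], collapse = ", ")))
  off <- tax$section != "Arachis" & tax$genome != "unassigned"
  if (any(off))
    return(sprintf(
      "sections outside Arachis carry genome 'unassigned'; violated by: %s",
      paste(tax$accession_id[off], collapse = ", ")))
  # each species maps to exactly one section
  map <- unique(tax[, c("species", "section")])
  dup <- unique(map$species[duplicated(map$species)])
  if (length(dup))
    return(sprintf("species mapped to more than one section: %s",
                   paste(dup, collapse = ", ")))
  NULL
}

.validSSRSet <- function(object) {
  msgs <- character()
  if (!"presence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'presence' is required")
  p <- assay(object, "presence")
  if (!is.logical(p))
    msgs <- c(msgs, "assay 'presence' must be a logical matrix")
  rd <- rowData(object)
  if (!all(c("marker_id", "size_bp") %in% colnames(rd)))
    return("rowData must contain marker_id and size_bp")
  key <- paste(rd$marker_id, rd$size_bp)
  if (anyDuplicated(key))
    msgs <- c(msgs, sprintf("duplicate allele row(s): %s",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  if (nrow(object) && any(rd$size_bp <= 0))
    msgs <- c(msgs, "allele size_bp must be positive")
  if (nrow(object) && any(rowSums(p) == 0))
    msgs <- c(msgs, sprintf(
      "allele(s) present in no accession: %s",
      paste(key[rowSums(p) == 0], collapse = ", ")))
  tax <- as.data.frame(colData(object))
  tax$accession_id <- colnames(object)
  err <- .validateTaxonomyDF(tax)
  if (!is.null(err)) msgs <- c(msgs, err)
  panel <- metadata(object)$panel
  if (is.null(panel)) {
    msgs <- c(msgs, "metadata(x)$panel is required")
  } else {
    perr <- .validateMarkerPanelDF(panel)
    if (!is.null(perr)) msgs <- c(msgs, perr)
    unknown <- setdiff(unique(rd$marker_id), panel$marker_id)
    if (length(unknown))
      msgs <- c(msgs, sprintf("allele marker(s) absent from panel: %s",
                              paste(unknown, collapse = ", ")))
    if (!length(msgs) && nrow(object)) {
      idx <- match(rd$marker_id, panel$marker_id)
      out <- rd$size_bp < panel$size_min[idx] | rd$size_bp > panel$size_max[idx]
      if (any(out))
        msgs <- c(msgs, sprintf("allele size outside marker window: %s",
                                paste(key[out], collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("SSRSet", .validSSRSet)

.validateMarkerPanelDF <- function(panel) {
  required <- c("marker_id", "source_class", "size_min", "size_max")
  missing <- setdiff(required, colnames(panel))
  if (length(missing))
    return(sprintf("marker panel lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  dup <- unique(panel$marker_id[duplicated(panel$marker_id)])
  if (length(dup))
    return(sprintf("duplicate marker_id: %s", paste(dup, collapse = ", ")))
  bad <- setdiff(unique(panel$source_class), .MARKER_CLASSES)
  if (length(bad))
    return(sprintf("unknown source_class token(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "),
                   paste(.MARKER_CLASSES, collapse = ", ")))
  if (any(panel$size_min <= 0) || any(panel$size_max <= panel$size_min))
    return("marker size windows need 0 < size_min < size_max")
  NULL
}

#' Construct an SSRSet
#'
#' @param presence Logical (or 0/1) matrix, alleles in rows, accessions in
#'   columns. Column names, if set, must match `taxonomy$accession_id`.
#' @param alleles data.frame with columns `marker_id`, `size_bp`, one row per
#'   presence-matrix row.
#' @param taxonomy data.frame with columns `accession_id`, `species`,
#'   `section`, `genome`, `ploidy` (see [readTaxonomy()]); row order fixes the
#'   accession order of the object.
#' @param panel data.frame with columns `marker_id`, `source_class`,
#'   `size_min`, `size_max` (see [readMarkerPanel()]).
#' @param cultivatedSpecies Marker-source species excluded when scoring
#'   genomic-class transferability.
#' @return A validated [SSRSet-class] object.
#' @examples
#' tax <- data.frame(accession_id = c("a1", "a2"),
#'                   species = "A. pintoi", section = "Caulorrhizae",
#'                   genome = "unassigned", ploidy = 20L)
#' panel <- data.frame(marker_id = "M1", source_class = "genomic",
#'                     size_min = 100L, size_max = 300L)
#' al <- data.frame(marker_id = "M1", size_bp = c(200L, 210L))
#' x <- SSRSet(matrix(c(TRUE, TRUE, FALSE, TRUE), 2), al, tax, panel)
#' x
#' @export
SSRSet <- function(presence, alleles, taxonomy, panel,
                   cultivatedSpecies = "A. hypogaea") {
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  alleles <- as.data.frame(alleles)
  taxonomy <- as.data.frame(taxonomy)
  panel <- as.data.frame(panel)
  if (nrow(presence) != nrow(alleles))
    .stopf("presence has %d rows but alleles has %d", nrow(presence),
           nrow(alleles))
  if (ncol(presence) != nrow(taxonomy))
    .stopf("presence has %d columns but taxonomy has %d accessions",
           ncol(presence), nrow(taxonomy))
  if (!is.null(colnames(presence)) &&
      !identical(colnames(presence), as.character(taxonomy$accession_id)))
    .stopf("presence column names do not match taxonomy accession order")
  alleles$size_bp <- as.integer(alleles$size_bp)
  rn <- paste(alleles$marker_id, alleles$size_bp, sep = ":")
  dimnames(presence) <- list(rn, taxonomy$accession_id)
  cd <- DataFrame(taxonomy[, setdiff(colnames(taxonomy), "accession_id"),
                           drop = FALSE],
                  row.names = taxonomy$accession_id)
  se <- SummarizedExperiment(
    assays = SimpleList(presence = presence),
    rowData = DataFrame(alleles, row.names = rn),
    colData = cd)
  metadata(se)$panel <- panel
  metadata(se)$cultivated_species <- cultivatedSpecies
  obj <- new("SSRSet", se)
  validObject(obj)
  obj
}

#' @describeIn SSRSet Compact display of dimensions, panel composition and
#'   taxonomy breadth.
#' @param object An `SSRSet`.
#' @export
setMethod("show", "SSRSet", function(object) {
  panel <- metadata(object)$panel
  cat(sprintf("SSRSet: %d alleles x %d accessions\n",
              nrow(object), ncol(object)))
  cat(sprintf("  markers: %d (%d genomic, %d genic)\n",
              nrow(panel), sum(panel$source_class == "genomic"),
              sum(panel$source_class == "genic")))
  tax <- colData(object)
  cat(sprintf("  taxa: %d species, %d sections; ploidy: %s\n",
              length(unique(tax$species)), length(unique(tax$section)),
              paste(sort(unique(tax$ploidy)), collapse = "/")))
  cat(sprintf("  cultivated (marker-source) species: %s\n",
              metadata(object)$cultivated_species))
})
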