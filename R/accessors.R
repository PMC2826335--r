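#' @include AllClasses.R
NULL

#' Accessors for SSRSet components
#'
#' Convenience accessors around the SummarizedExperiment internals:
#' `presenceMatrix()` returns the logical allele-by-accession matrix,
#' `alleleTable()` the allele identities (marker, size), `taxonomyTable()` the
#' accession taxonomy as a plain data.frame (with `accession_id` column),
#' `markerPanel()` the marker metadata, and `cultivatedSpecies()` the
#' marker-source species used by the transferability exclusion rule.
#'
#' @param x An [SSRSet-class].
#' @return See individual descriptions.
#' @name SSRSet-accessors
NULL

#' @rdname SSRSet-accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname SSRSet-accessors
#' @export
setMethod("presenceMatrix", "SSRSet", function(x) assay(x, "presence"))

#' @rdname SSRSet-accessors
#' @export
setGeneric("alleleTable", function(x) standardGeneric("alleleTable"))

#' @rdname SSRSet-accessors
#' @export
setMethod("alleleTable", "SSRSet", function(x) {
  df <- as.data.frame(rowData(x))
  rownames(df) <- NULL
  df[, c("marker_id", "size_bp")]
})

#' @rdname SSRSet-accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname SSRSet-accessors
#' @export
setMethod("taxonomyTable", "SSRSet", function(x) {
  df <- as.data.frame(colData(x))
  data.frame(accession_id = colnames(x), df, row.names = NULL,
             check.names = FALSE)
})

#' @rdname SSRSet-accessors
#' @export
setGeneric("markerPanel", function(x) standardGeneric("markerPanel"))

#' @rdname SSRSet-accessors
#' @export
setMethod("markerPanel", "SSRSet", function(x) metadata(x)$panel)

#' @rdname SSRSet-accessors
#' @export
setGeneric("cultivatedSpecies", function(x) standardGeneric("cultivatedSpecies"))

#' @rdname SSRSet-accessors
#' @export
setMethod("cultivatedSpecies", "SSRSet", function(x)
  metadata(x)$cultivated_species)

#' Marker-level amplification matrix
#'
#' Collapses the allele-level presence matrix to markers: a marker "amplifies"
#' in an accession when at least one of its alleles (sharp bands) is present.
#' Markers of the panel with no scored allele anywhere appear as all-`FALSE`
#' rows, so the matrix always covers the full panel. The amplification matrix
#' is by construction the allele-wise OR of the presence matrix.
#'
#' @param x An [SSRSet-class].
#' @return Logical matrix, panel markers in rows (panel order), accessions in
#'   columns.
#' @examples
#' x <- simulateDataset(config = simulationConfig(seed = 1))$ssr
#' dim(amplificationMatrix(x))
#' @export
setGeneric("amplificationMatrix", function(x)
  standardGeneric("amplificationMatrix"))

#' @rdname amplificationMatrix
#' @export
setMethod("amplificationMatrix", "SSRSet", function(x) {
  panel <- markerPanel(x)
  amp <- matrix(FALSE, nrow(panel), ncol(x),
                dimnames = list(panel$marker_id, colnames(x)))
  if (nrow(x)) {
    p <- presenceMatrix(x)
    agg <- rowsum(p + 0L, group = as.character(rowData(x)$marker_id))
    amp[rownames(agg), ] <- agg > 0L
  }
  amp
})

#' Subset an SSRSet to a set of accessions
#'
#' Returns the set restricted to `accessions`, dropping allele rows that no
#' longer have any carrier so that the result remains a valid `SSRSet`
#' (every allele must be present in at least one accession). Use this rather
#' than `[` when columns are removed.
#'
#' @param x An [SSRSet-class].
#' @param accessions Character vector of accession ids to keep (order kept as
#'   given).
#' @return A valid [SSRSet-class].
#' @export
subsetAccessions <- function(x, accessions) {
  missing <- setdiff(accessions, colnames(x))
  if (length(missing))
    .stopf("unknown accession id(s): %s", paste(missing, collapse = ", "))
  p <- presenceMatrix(x)[, accessions, drop = FALSE]
  keep <- rowSums(p) > 0
  SSRSet(p[keep, , drop = FALSE],
         alleleTable(x)[keep, , drop = FALSE],
         taxonomyTable(x)[match(accessions, colnames(x)), , drop = FALSE],
         markerPanel(x),
         cultivatedSpecies(x))
}
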