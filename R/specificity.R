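#' Alleles specific to a species or section
#'
#' An allele is taxon-specific at a level (species or section) when every
#' accession carrying it belongs to a single taxon at that level. Specificity
#' is defined over the accessions present in the input — an allele carried by
#' a single accession counts. When comparing against a simulation's planted
#' private alleles, first remove the tetraploid accessions with
#' [subsetAccessions()]: tetraploids carry their donors' alleles and would
#' otherwise break the donors' species-specificity.
#'
#' @param x An [SSRSet-class].
#' @param level `"species"` or `"section"`.
#' @return A list with:
#'   \describe{
#'     \item{`alleles`}{data.frame `marker_id`, `size_bp`, `level`, `taxon`,
#'       `carrier_accessions` (comma-separated ids).}
#'     \item{`summary`}{per-taxon counts sorted by descending count, with
#'       `pct` = share of all specific alleles at this level, rounded
#'       half-up.}
#'   }
#' @examples
#' sim <- simulateDataset(config = simulationConfig(seed = 3))
#' rep <- specificAlleles(sim$ssr, "species")
#' head(rep$summary)
#' @export
specificAlleles <- function(x, level = c("species", "section")) {
  level <- match.arg(level)
  p <- presenceMatrix(x)
  taxa <- taxonomyTable(x)[[level]]
  al <- alleleTable(x)
  rows <- list()
  for (i in seq_len(nrow(p))) {
    carriers <- which(p[i, ])
    tx <- unique(taxa[carriers])
    if (length(tx) == 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = al$marker_id[i], size_bp = al$size_bp[i],
        level = level, taxon = tx,
        carrier_accessions = paste(colnames(x)[carriers], collapse = ","))
  }
  alleles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_id = character(), size_bp = integer(),
               level = character(), taxon = character(),
               carrier_accessions = character())
  counts <- sort(table(alleles$taxon), decreasing = TRUE)
  summary <- data.frame(
    taxon = names(counts), level = rep(level, length(counts)),
    n_specific = as.integer(counts),
    pct = as.integer(roundHalfUp(100 * as.integer(counts) /
                                   max(1L, nrow(alleles)))))
  list(alleles = alleles, summary = summary)
}

#' Markers confined to a single section
#'
#' Markers whose amplification occurs in at least one accession of exactly
#' one section and nowhere else (e.g. primer pairs amplifying only in the
#' source section).
#'
#' @param amp Amplification matrix.
#' @param taxonomy Taxonomy data.frame.
#' @return Sorted character vector of marker ids.
#' @export
sectionSpecificMarkers <- function(amp, taxonomy) {
  taxonomy <- validateTaxonomy(taxonomy)
  .ampCheck(amp, taxonomy)
  sections <- unique(taxonomy$section)
  if (length(sections) < 2L) .stopf("need at least two sections")
  bySec <- vapply(sections, function(sec)
    rowSums(amp[, taxonomy$accession_id[taxonomy$section == sec],
                drop = FALSE]) > 0, logical(nrow(amp)))
  sort(rownames(amp)[rowSums(bySec) == 1L])
}

#' Markers amplifying only in tetraploids
#'
#' Markers amplified by at least one tetraploid (ploidy 40) accession and by
#' no diploid or aneuploid accession — the signature of an SSR locus created
#' after the polyploidization event.
#'
#' @param amp Amplification matrix.
#' @param taxonomy Taxonomy data.frame.
#' @return Sorted character vector of marker ids.
#' @export
polyploidOriginMarkers <- function(amp, taxonomy) {
  taxonomy <- validateTaxonomy(taxonomy)
  .ampCheck(amp, taxonomy)
  tet <- taxonomy$accession_id[taxonomy$ploidy == 40L]
  dip <- taxonomy$accession_id[taxonomy$ploidy < 40L]
  if (!length(tet)) .stopf("taxonomy contains no tetraploid accession")
  if (!length(dip)) .stopf("taxonomy contains no diploid accession")
  inTet <- rowSums(amp[, tet, drop = FALSE]) > 0
  inDip <- rowSums(amp[, dip, drop = FALSE]) > 0
  sort(rownames(amp)[inTet & !inDip])
}

#' Duplicated-locus signatures in tetraploids
#'
#' A marker shows a duplicated locus when some tetraploid accession carries,
#' at that marker, at least one allele from the A-donor's set, at least one
#' from the B-donor's set, and at least one allele absent from every diploid
#' accession (the tetraploid-only fragment).
#'
#' @param x An [SSRSet-class].
#' @param donorA,donorB Accession ids of the designated diploid donors.
#' @return data.frame `marker_id`, `extra_alleles` (comma-separated
#'   tetraploid-only sizes in bp), sorted by marker.
#' @export
duplicatedLocusMarkers <- function(x, donorA, donorB) {
  tax <- taxonomyTable(x)
  for (d in c(donorA, donorB)) {
    if (!d %in% tax$accession_id) .stopf("donor accession not found: %s", d)
    if (tax$ploidy[tax$accession_id == d] >= 40L)
      .stopf("donor %s is not diploid", d)
  }
  p <- presenceMatrix(x)
  al <- alleleTable(x)
  tet <- tax$accession_id[tax$ploidy == 40L]
  dip <- tax$accession_id[tax$ploidy < 40L]
  if (!length(tet)) .stopf("taxonomy contains no tetraploid accession")
  dipAbsent <- rowSums(p[, dip, drop = FALSE]) == 0
  out <- list()
  for (m in sort(unique(al$marker_id))) {
    idx <- which(al$marker_id == m)
    setA <- idx[p[idx, donorA]]
    setB <- idx[p[idx, donorB]]
    extra <- idx[dipAbsent[idx]]
    if (!length(setA) || !length(setB) || !length(extra)) next
    hit <- vapply(tet, function(t)
      any(p[setA, t]) && any(p[setB, t]) && any(p[extra, t]), logical(1))
    if (any(hit)) {
      carried <- extra[rowSums(p[extra, tet, drop = FALSE]) > 0]
      out[[length(out) + 1L]] <- data.frame(
        marker_id = m,
        extra_alleles = paste(sort(al$size_bp[carried]), collapse = ","))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(marker_id = character(), extra_alleles = character())
}

#' Classify markers by donor-allele amplification pattern
#'
#' For each marker, examines the two candidate diploid donors and the
#' tetraploid accessions: `both_donors` when the marker amplifies both
#' candidates and at least one allele of each candidate appears in some
#' tetraploid; `A_only` when it amplifies only candidate A and an A allele
#' appears in a tetraploid; `B_only` symmetrically; `neither` otherwise.
#'
#' @param x An [SSRSet-class].
#' @param candidateA,candidateB Diploid accession ids.
#' @param tetraploids Character vector of tetraploid accession ids.
#' @return Named character vector (marker_id to class) over all panel
#'   markers.
#' @export
classifyDonorAmplification <- function(x, candidateA, candidateB,
                                       tetraploids) {
  tax <- taxonomyTable(x)
  ids <- c(candidateA, candidateB, tetraploids)
  missing <- setdiff(ids, tax$accession_id)
  if (length(missing))
    .stopf("unknown accession id(s): %s", paste(missing, collapse = ", "))
  if (!length(tetraploids)) .stopf("tetraploids must be non-empty")
  for (d in c(candidateA, candidateB))
    if (tax$ploidy[tax$accession_id == d] >= 40L)
      .stopf("candidate %s is not diploid", d)
  p <- presenceMatrix(x)
  al <- alleleTable(x)
  panel <- markerPanel(x)
  out <- setNames(rep("neither", nrow(panel)), panel$marker_id)
  for (m in panel$marker_id) {
    idx <- which(al$marker_id == m)
    if (!length(idx)) next
    setA <- idx[p[idx, candidateA]]
    setB <- idx[p[idx, candidateB]]
    inTetA <- length(setA) &&
      any(rowSums(p[setA, tetraploids, drop = FALSE]) > 0)
    inTetB <- length(setB) &&
      any(rowSums(p[setB, tetraploids, drop = FALSE]) > 0)
    out[m] <- if (length(setA) && length(setB) && inTetA && inTetB)
      "both_donors"
    else if (length(setA) && !length(setB) && inTetA) "A_only"
    else if (length(setB) && !length(setA) && inTetB) "B_only"
    else "neither"
  }
  out
}
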