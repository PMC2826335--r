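#' @importFrom stats pnorm
NULL

# Accessions scorable for a marker class: for genomic-class markers the
# cultivated (marker-source) species is excluded, for genic-class markers it
# is included.
.scorableIds <- function(taxonomy, class, cultivated) {
  if (class == "genomic")
    taxonomy$accession_id[taxonomy$species != cultivated]
  else taxonomy$accession_id
}

.ampCheck <- function(amp, taxonomy, panel = NULL) {
  if (!setequal(colnames(amp), taxonomy$accession_id))
    .stopf("amplification matrix columns do not match taxonomy accessions")
  if (!is.null(panel) && !setequal(rownames(amp), panel$marker_id))
    .stopf("amplification matrix rows do not match marker panel")
}

#' Section-level marker transferability table
#'
#' A marker counts as transferable to a section when it amplifies in at least
#' one scorable accession of that section. Because genomic-class markers were
#' developed from the cultivated species, its accessions are excluded from
#' scoring for that class (they would trivially amplify); for genic-class
#' markers all accessions count. Percentages are rounded half-up to integers;
#' the per-class `Mean` row holds the rounded mean of the seven per-section
#' transferable counts and of their percentages.
#'
#' @param amp Amplification matrix from [amplificationMatrix()].
#' @param taxonomy Taxonomy data.frame.
#' @param panel Marker panel data.frame.
#' @param cultivated Marker-source species excluded for genomic markers.
#' @return data.frame with columns `section`, `source_class`,
#'   `n_transferable`, `n_total`, `pct`; sections in [arachisSections()]
#'   order followed by one `Mean` row per class.
#' @examples
#' sim <- simulateDataset(config = simulationConfig(seed = 1))
#' tab <- sectionTransferability(sim$amp, taxonomyTable(sim$ssr),
#'                               markerPanel(sim$ssr))
#' subset(tab, section == "Mean")
#' @export
sectionTransferability <- function(amp, taxonomy, panel,
                                   cultivated = "A. hypogaea") {
  taxonomy <- validateTaxonomy(taxonomy)
  panel <- validateMarkerPanel(panel)
  .ampCheck(amp, taxonomy, panel)
  sections <- intersect(arachisSections(), unique(taxonomy$section))
  rows <- list()
  for (cls in .MARKER_CLASSES) {
    markers <- panel$marker_id[panel$source_class == cls]
    if (!length(markers)) next
    scorable <- .scorableIds(taxonomy, cls, cultivated)
    counts <- integer(0)
    for (sec in sections) {
      ids <- intersect(scorable,
                       taxonomy$accession_id[taxonomy$section == sec])
      if (!length(ids))
        .stopf("section %s has no scorable accession for class %s",
               sec, cls)
      n_tr <- sum(rowSums(amp[markers, ids, drop = FALSE]) > 0)
      counts[sec] <- n_tr
      rows[[length(rows) + 1L]] <- data.frame(
        section = sec, source_class = cls, n_transferable = n_tr,
        n_total = length(markers),
        pct = as.integer(roundHalfUp(100 * n_tr / length(markers))))
    }
    pcts <- vapply(rows[seq(length(rows) - length(sections) + 1L,
                            length(rows))],
                   function(r) r$pct, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      section = "Mean", source_class = cls,
      n_transferable = as.integer(roundHalfUp(mean(counts))),
      n_total = length(markers),
      pct = as.integer(roundHalfUp(mean(pcts))))
  }
  do.call(rbind, rows)
}

#' Accession-level transferability rate
#'
#' For each marker, the fraction of scorable accessions (exclusion rule as in
#' [sectionTransferability()]) within the given sections that amplify;
#' returns the mean of those fractions over all markers, as a percentage.
#' This is the statistic behind headline rates such as "81% to the source
#' section, 59% to the other six".
#'
#' @inheritParams sectionTransferability
#' @param sections Character vector of sections to score.
#' @return A single numeric percentage (not rounded).
#' @export
accessionLevelRate <- function(amp, taxonomy, panel, sections,
                               cultivated = "A. hypogaea") {
  taxonomy <- validateTaxonomy(taxonomy)
  panel <- validateMarkerPanel(panel)
  .ampCheck(amp, taxonomy, panel)
  if (!length(sections)) .stopf("sections must be non-empty")
  fracs <- numeric(0)
  for (cls in .MARKER_CLASSES) {
    markers <- panel$marker_id[panel$source_class == cls]
    if (!length(markers)) next
    ids <- intersect(.scorableIds(taxonomy, cls, cultivated),
                     taxonomy$accession_id[taxonomy$section %in% sections])
    if (!length(ids))
      .stopf("no scorable accessions for class %s in the given sections", cls)
    fracs <- c(fracs, rowMeans(amp[markers, ids, drop = FALSE]))
  }
  100 * mean(fracs)
}

#' Markers transferable to every scorable accession
#'
#' Markers that amplify in 100% of scorable accessions (exclusion rule
#' applied per class), i.e. fully cross-species transferable primer pairs.
#'
#' @inheritParams sectionTransferability
#' @return Sorted character vector of marker ids.
#' @export
fullyTransferableMarkers <- function(amp, taxonomy, panel,
                                     cultivated = "A. hypogaea") {
  taxonomy <- validateTaxonomy(taxonomy)
  panel <- validateMarkerPanel(panel)
  .ampCheck(amp, taxonomy, panel)
  out <- character()
  for (cls in .MARKER_CLASSES) {
    markers <- panel$marker_id[panel$source_class == cls]
    ids <- .scorableIds(taxonomy, cls, cultivated)
    if (!length(markers) || !length(ids)) next
    full <- markers[rowSums(amp[markers, ids, drop = FALSE]) == length(ids)]
    out <- c(out, full)
  }
  sort(out)
}

#' Markers failing in exactly one section
#'
#' Markers that amplify in at least one accession of every section except
#' exactly one, where they amplify nowhere — the pattern of a
#' section-specific null (primer-site mutation or locus loss in that
#' section).
#'
#' @param amp Amplification matrix.
#' @param taxonomy Taxonomy data.frame.
#' @return Named character vector mapping marker_id to the null section;
#'   empty when no marker qualifies.
#' @export
singleSectionNullMarkers <- function(amp, taxonomy) {
  taxonomy <- validateTaxonomy(taxonomy)
  .ampCheck(amp, taxonomy)
  sections <- unique(taxonomy$section)
  if (length(sections) < 2L) .stopf("need at least two sections")
  bySec <- vapply(sections, function(sec)
    rowSums(amp[, taxonomy$accession_id[taxonomy$section == sec],
                drop = FALSE]) > 0, logical(nrow(amp)))
  nulls <- rowSums(!bySec)
  hit <- which(nulls == 1L)
  out <- vapply(hit, function(i) sections[which(!bySec[i, ])], character(1))
  names(out) <- rownames(amp)[hit]
  out
}

#' Compare transferability of the two marker classes
#'
#' Pooled two-proportion z-test contrasting the class mean transferable
#' counts against the class panel sizes, signed so that higher genic
#' transferability gives a positive z. The p-value is two-sided normal.
#'
#' @param table Output of [sectionTransferability()] (both class `Mean` rows
#'   must be present).
#' @return Named numeric vector `c(z = ..., p = ...)`.
#' @examples
#' tab <- data.frame(section = "Mean", source_class = c("genomic", "genic"),
#'                   n_transferable = c(62L, 17L), n_total = c(82L, 19L),
#'                   pct = c(76L, 88L))
#' compareMarkerClasses(tab)
#' @export
compareMarkerClasses <- function(table) {
  means <- table[table$section == "Mean", , drop = FALSE]
  if (!all(.MARKER_CLASSES %in% means$source_class))
    .stopf("table lacks a Mean row for one of the marker classes")
  x1 <- means$n_transferable[means$source_class == "genomic"]
  n1 <- means$n_total[means$source_class == "genomic"]
  x2 <- means$n_transferable[means$source_class == "genic"]
  n2 <- means$n_total[means$source_class == "genic"]
  if (n1 == 0 || n2 == 0) .stopf("zero class denominator")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p2 - p1) / se
  c(z = z, p = 2 * pnorm(-abs(z)))
}
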