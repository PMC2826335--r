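#' Reference tables from a published Arachis SSR survey
#'
#' Two small summary tables from a published genus-wide SSR survey of
#' *Arachis* (96 accessions, 36 species, 7 sections; 101 markers), bundled
#' for worked examples and for recomputing the survey's printed summary
#' statistics from its per-section counts:
#'
#' * `arachisTransferCounts()` — per-section counts of transferable markers
#'   for the 82 genomic-library and 19 genic markers of the panel.
#' * `arachisClusterMarkers()` — the 32-marker subset used for the survey's
#'   cluster analysis, with the number of alleles each marker amplified.
#'
#' From these, [sectionCountsToTable()] rebuilds the full transferability
#' table (percentages and class means) through the same rounding rules used
#' by [sectionTransferability()].
#'
#' @return A data.frame (see above).
#' @examples
#' tab <- sectionCountsToTable(arachisTransferCounts())
#' subset(tab, section == "Mean")         # genomic 76%, genic 88%
#' sum(arachisClusterMarkers()$n_alleles) # 454 alleles in the 32-marker set
#' @name survey-tables
NULL

#' @rdname survey-tables
#' @export
arachisTransferCounts <- function() {
  read.delim(system.file("extdata", "arachis_section_transfer_counts.tsv",
                         package = "SSRwild"))
}

#' @rdname survey-tables
#' @export
arachisClusterMarkers <- function() {
  read.delim(system.file("extdata", "arachis_cluster_markers.tsv",
                         package = "SSRwild"))
}

#' Rebuild a transferability table from per-section counts
#'
#' Converts a wide per-section count table (as returned by
#' [arachisTransferCounts()]) into the long [sectionTransferability()]
#' format, recomputing percentages and the per-class mean rows with half-up
#' rounding. Useful to verify that printed class means follow from the
#' printed per-section counts.
#'
#' @param counts data.frame with columns `section`,
#'   `n_genomic_transferable`, `n_genomic_total`, `n_genic_transferable`,
#'   `n_genic_total`.
#' @return data.frame in the [sectionTransferability()] layout.
#' @export
sectionCountsToTable <- function(counts) {
  rows <- list()
  for (cls in c("genomic", "genic")) {
    tr <- counts[[paste0("n_", cls, "_transferable")]]
    tot <- counts[[paste0("n_", cls, "_total")]]
    pct <- as.integer(roundHalfUp(100 * tr / tot))
    rows[[cls]] <- data.frame(
      section = c(counts$section, "Mean"), source_class = cls,
      n_transferable = c(tr, as.integer(roundHalfUp(mean(tr)))),
      n_total = c(tot, tot[1]),
      pct = c(pct, as.integer(roundHalfUp(mean(pct)))))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
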