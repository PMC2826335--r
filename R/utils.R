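#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all printed percentages so that
#' e.g. 87.5 becomes 88. `base::round()` rounds half to even, which does not
#' match the convention of published transferability tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.5))  # 1 2 3
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Taxonomic sections of genus Arachis covered by the analysis
#'
#' The seven sections of genus *Arachis* handled by this package, listed in
#' increasing order of divergence from section *Arachis* (the source section
#' of the cultivated-species genomic markers). The section vocabulary is
#' closed: taxonomies naming any other section are rejected, so that the
#' exclusion of unanalyzed sections is always explicit.
#'
#' @return Character vector of the seven section names, ordered by divergence
#'   rank (rank 0 = *Arachis*).
#' @examples
#' arachisSections()
#' @export
arachisSections <- function() {
  c("Arachis", "Erectoides", "Procumbentes", "Heteranthae",
    "Caulorrhizae", "Extranervosae", "Triseminatae")
}

.GENOME_CLASSES <- c("A", "B", "AB", "D", "unassigned")
.PLOIDIES <- c(18L, 20L, 40L)
.MARKER_CLASSES <- c("genomic", "genic")

# Deterministic substream seed for counter-based RNG derivation; kept < 2^31.
.substreamSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807 + 11) %%
               2147483629)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
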