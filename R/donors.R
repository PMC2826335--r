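#' Mean genetic distance of an accession to a group
#'
#' Arithmetic mean of the pairwise [neiLiDistance()] between `accession` and
#' each member of `group` — the "distance to the tetraploid group" statistic
#' used to nominate genome donors.
#'
#' @param x An [SSRSet-class].
#' @param accession Accession id.
#' @param group Character vector of accession ids; must be non-empty, free of
#'   duplicates, and must not contain `accession`.
#' @return Numeric mean distance.
#' @export
groupDistance <- function(x, accession, group) {
  if (!length(group)) .stopf("group must be non-empty")
  if (anyDuplicated(group))
    .stopf("group contains duplicate accession id(s): %s",
           paste(unique(group[duplicated(group)]), collapse = ", "))
  if (accession %in% group) .stopf("accession must not belong to the group")
  ids <- c(accession, group)
  missing <- setdiff(ids, colnames(x))
  if (length(missing))
    .stopf("unknown accession id(s): %s", paste(missing, collapse = ", "))
  P <- presenceMatrix(x)
  mean(vapply(group, function(g)
    neiLiDistance(P[, accession], P[, g]), numeric(1)))
}

#' Rank diploid donor candidates by distance to a tetraploid group
#'
#' For every diploid accession of genome class A and B within section
#' *Arachis*, computes [groupDistance()] to the accessions of
#' `targetSpecies` (the allotetraploid under study) and ranks candidates
#' ascending within each genome class. The top-ranked accession of each
#' class is the nominated genome donor.
#'
#' @param x An [SSRSet-class].
#' @param targetSpecies Species whose accessions form the group (default
#'   the cultivated species of `x`).
#' @return A list with elements `A` and `B` — data.frames
#'   (`accession_id`, `species`, `genome`, `group_distance`) sorted
#'   ascending — and `nominated`, a named character vector of the two
#'   top-ranked accession ids.
#' @examples
#' sim <- simulateDataset(config = simulationConfig(seed = 2))
#' rep <- rankDonorCandidates(sim$ssr)
#' rep$nominated
#' c(sim$truth$donor_A, sim$truth$donor_B)
#' @export
rankDonorCandidates <- function(x, targetSpecies = cultivatedSpecies(x)) {
  tax <- taxonomyTable(x)
  group <- tax$accession_id[tax$species == targetSpecies]
  if (!length(group))
    .stopf("target species %s has no accessions", targetSpecies)
  out <- list()
  for (g in c("A", "B")) {
    cand <- tax[tax$genome == g & tax$ploidy < 40L &
                  tax$section == "Arachis" &
                  tax$species != targetSpecies, , drop = FALSE]
    if (!nrow(cand))
      .stopf("no diploid %s-genome candidates in section Arachis", g)
    d <- vapply(cand$accession_id, function(a)
      groupDistance(x, a, group), numeric(1))
    df <- data.frame(accession_id = cand$accession_id,
                     species = cand$species, genome = g,
                     group_distance = unname(d))
    out[[g]] <- df[order(df$group_distance, df$accession_id), ,
                   drop = FALSE]
    rownames(out[[g]]) <- NULL
  }
  out$nominated <- c(A = out$A$accession_id[1], B = out$B$accession_id[1])
  out
}

#' Donor recovery experiment over simulated datasets
#'
#' Simulates `nSeeds` independent datasets and records, per genome class,
#' the fraction of runs in which [rankDonorCandidates()] nominates the
#' planted true donor.
#'
#' @param config A [simulationConfig()]; seeds `config$seed + 1 ... + nSeeds`
#'   are used.
#' @param nSeeds Number of independent simulations (>= 1).
#' @return Named numeric vector `c(A = ..., B = ...)` of recovery rates.
#' @export
donorRecoveryExperiment <- function(config = simulationConfig(),
                                    nSeeds = 100L) {
  if (nSeeds < 1L) .stopf("nSeeds must be >= 1")
  hitA <- hitB <- logical(nSeeds)
  for (k in seq_len(nSeeds)) {
    sim <- simulateDataset(config = config, seed = config$seed + k)
    rep <- rankDonorCandidates(sim$ssr)
    hitA[k] <- rep$nominated[["A"]] == sim$truth$donor_A
    hitB[k] <- rep$nominated[["B"]] == sim$truth$donor_B
  }
  c(A = mean(hitA), B = mean(hitB))
}
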