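#' @importFrom stats runif setNames
NULL

.sampleRange <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Simulation configuration
#'
#' Parameters of the synthetic genotype generator. Defaults emulate the
#' structure of a genus-wide SSR survey: 7 sections, roughly 36 species and
#' 96 accessions, a 101-marker panel (82 genomic + 19 genic), class-dependent
#' amplification (genic markers transfer better than genomic ones), species-
#' private alleles, a cultivated allotetraploid whose allele complement is the
#' union of two designated diploid donors, and tetraploid-only duplicated
#' loci.
#'
#' @param n_sections Number of sections simulated (first `n_sections` of
#'   [arachisSections()], so section *Arachis* is always present).
#' @param species_per_section Integer range `c(lo, hi)` of species per
#'   section. Section *Arachis* always receives at least its six mandatory
#'   species: the AB tetraploid plus two A-genome, two B-genome and one
#'   D-genome diploid.
#' @param accessions_per_species Integer range of accessions per species.
#' @param tetraploid_accessions Accessions of the cultivated tetraploid
#'   species (at least 2).
#' @param n_genomic_markers,n_genic_markers Panel composition
#'   (defaults 82 and 19).
#' @param base_transfer_prob Named probabilities of amplification in a
#'   source-section accession for each marker class (defaults: genomic 0.76,
#'   genic 0.88 — the class-mean transfer rates of the emulated survey).
#' @param section_divergence_penalty Non-negative decay rate: amplification
#'   probability in a section of divergence rank `r` is
#'   `base * exp(-penalty * r)`. 0 removes the section gradient.
#' @param p_private_allele Probability, per species x marker, that the
#'   species gains a globally unique private allele.
#' @param p_tetraploid_locus Probability that a genomic marker amplified by
#'   both donors gains a duplicated-locus fragment carried by all tetraploids
#'   and absent from every diploid.
#' @param donor_retention Probability that a tetraploid accession retains any
#'   given donor allele.
#' @param alleles_per_marker Integer range of the target allele count per
#'   marker (drives pool sizes; the emulated survey's per-marker counts span
#'   4 to 29).
#' @param seed Integer master seed; all taxonomy, panel and per-marker
#'   substreams derive from it by counter, so adding markers does not perturb
#'   earlier draws.
#' @param section_order Section divergence order (rank 0 first).
#' @return A validated list of class `ssr_sim_config`.
#' @seealso [generateTaxonomy()], [generateMarkerPanel()],
#'   [simulateDataset()]
#' @export
simulationConfig <- function(n_sections = 7L,
                             species_per_section = c(4L, 6L),
                             accessions_per_species = c(2L, 3L),
                             tetraploid_accessions = 4L,
                             n_genomic_markers = 82L,
                             n_genic_markers = 19L,
                             base_transfer_prob = c(genomic = 0.76,
                                                    genic = 0.88),
                             section_divergence_penalty = 0.08,
                             p_private_allele = 0.05,
                             p_tetraploid_locus = 0.1,
                             donor_retention = 0.95,
                             alleles_per_marker = c(4L, 29L),
                             seed = 1L,
                             section_order = arachisSections()) {
  cfg <- list(n_sections = as.integer(n_sections),
              species_per_section = as.integer(species_per_section),
              accessions_per_species = as.integer(accessions_per_species),
              tetraploid_accessions = as.integer(tetraploid_accessions),
              n_genomic_markers = as.integer(n_genomic_markers),
              n_genic_markers = as.integer(n_genic_markers),
              base_transfer_prob = base_transfer_prob,
              section_divergence_penalty = section_divergence_penalty,
              p_private_allele = p_private_allele,
              p_tetraploid_locus = p_tetraploid_locus,
              donor_retention = donor_retention,
              alleles_per_marker = as.integer(alleles_per_marker),
              seed = as.integer(seed),
              section_order = section_order)
  probs <- c(cfg$base_transfer_prob, cfg$p_private_allele,
             cfg$p_tetraploid_locus, cfg$donor_retention)
  if (any(probs < 0) || any(probs > 1))
    .stopf("all probabilities must lie in [0, 1]")
  if (!all(c("genomic", "genic") %in% names(cfg$base_transfer_prob)))
    .stopf("base_transfer_prob needs entries 'genomic' and 'genic'")
  if (cfg$section_divergence_penalty < 0)
    .stopf("section_divergence_penalty must be >= 0")
  for (nm in c("species_per_section", "accessions_per_species",
               "alleles_per_marker")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
      .stopf("%s must be a non-empty positive range c(lo, hi)", nm)
  }
  if (cfg$n_sections < 1L || cfg$n_sections > length(cfg$section_order))
    .stopf("n_sections must be between 1 and %d", length(cfg$section_order))
  if (cfg$n_genomic_markers < 0L || cfg$n_genic_markers < 0L ||
      cfg$n_genomic_markers + cfg$n_genic_markers < 1L)
    .stopf("panel must contain at least one marker")
  if (cfg$tetraploid_accessions < 2L)
    .stopf("tetraploid_accessions must be >= 2")
  class(cfg) <- "ssr_sim_config"
  cfg
}

#' Generate a synthetic accession taxonomy
#'
#' Section *Arachis* always contains the cultivated AB tetraploid species
#' (`"A. hypogaea"`, ploidy 40), two A-genome, two B-genome and one D-genome
#' diploid species; additional species alternate between the A and B classes.
#' Other sections hold diploid species of unassigned genome. Accession ids
#' are sequential `"ICG <n>"` tokens.
#'
#' @param config A [simulationConfig()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return A validated taxonomy `data.frame` ([readTaxonomy()] format).
#' @export
generateTaxonomy <- function(config = simulationConfig(),
                             seed = config$seed) {
  set.seed(.substreamSeed(seed, 1L))
  sections <- config$section_order[seq_len(config$n_sections)]
  rows <- list()
  counter <- 0L
  nextId <- function() {
    counter <<- counter + 1L
    sprintf("ICG-%d", 8000L + counter)
  }
  for (sec in sections) {
    n_sp <- .sampleRange(config$species_per_section)
    if (sec == "Arachis") {
      n_sp <- max(n_sp, 6L)
      mandatory <- data.frame(
        species = c("A. hypogaea", "A. duranensis", "A. cardenasii",
                    "A. ipaensis", "A. batizocoi", "A. glandulifera"),
        genome = c("AB", "A", "A", "B", "B", "D"),
        stringsAsFactors = FALSE)
      extra <- n_sp - 6L
      if (extra > 0L)
        mandatory <- rbind(mandatory, data.frame(
          species = sprintf("A. arachis-sp%d", seq_len(extra)),
          genome = rep(c("A", "B"), length.out = extra)))
      for (k in seq_len(nrow(mandatory))) {
        tetra <- mandatory$genome[k] == "AB"
        n_acc <- if (tetra) max(2L, config$tetraploid_accessions)
                 else .sampleRange(config$accessions_per_species)
        for (a in seq_len(n_acc))
          rows[[length(rows) + 1L]] <- data.frame(
            accession_id = nextId(), species = mandatory$species[k],
            section = sec, genome = mandatory$genome[k],
            ploidy = if (tetra) 40L else 20L)
      }
    } else {
      for (k in seq_len(n_sp)) {
        n_acc <- .sampleRange(config$accessions_per_species)
        sp <- sprintf("A. %s-sp%d", tolower(sec), k)
        for (a in seq_len(n_acc))
          rows[[length(rows) + 1L]] <- data.frame(
            accession_id = nextId(), species = sp, section = sec,
            genome = "unassigned", ploidy = 20L)
      }
    }
  }
  validateTaxonomy(do.call(rbind, rows))
}

#' Generate a synthetic marker panel
#'
#' Genomic markers are named `AhSSR<k>`, genic markers `CsSSR<k>`. Each
#' marker receives a 200-bp permitted size window at a random position, wide
#' enough that all of a marker's alleles can be drawn without replacement
#' (sizes are unique within markers by construction).
#'
#' @inheritParams generateTaxonomy
#' @return A validated marker panel `data.frame` ([readMarkerPanel()]
#'   format).
#' @export
generateMarkerPanel <- function(config = simulationConfig(),
                                seed = config$seed) {
  set.seed(.substreamSeed(seed, 2L))
  n <- config$n_genomic_markers + config$n_genic_markers
  ids <- c(sprintf("AhSSR%03d", seq_len(config$n_genomic_markers)),
           sprintf("CsSSR%03d", seq_len(config$n_genic_markers)))
  cls <- rep(c("genomic", "genic"),
             c(config$n_genomic_markers, config$n_genic_markers))
  lo <- sample(100:700, n, replace = TRUE)
  validateMarkerPanel(data.frame(marker_id = ids, source_class = cls,
                                 size_min = lo, size_max = lo + 199L))
}

#' Simulate a band-scored SSR dataset with planted ground truth
#'
#' Generates an allele presence/absence matrix whose statistical structure
#' mirrors a genus-wide cross-species SSR survey:
#'
#' * a marker amplifies in a diploid accession with probability
#'   `base_transfer_prob[class] * exp(-penalty * divergence_rank(section))`;
#' * every amplified accession carries the marker's genus-wide alleles plus
#'   its section's shared allele pool, A/B-genome accessions of section
#'   *Arachis* additionally carry their genome-class pool, so conspecific and
#'   consectional accessions cluster;
#' * with probability `p_private_allele` a (diploid species, marker) pair
#'   gains a globally unique private allele carried by all of that species'
#'   amplified accessions, recorded in the ground-truth ledger;
#' * each tetraploid accession carries the union of the two designated
#'   diploid donors' alleles, each retained with probability
#'   `donor_retention`;
#' * a genomic marker amplified by both donors gains, with probability
#'   `p_tetraploid_locus`, a duplicated-locus fragment carried by every
#'   tetraploid and absent from all diploids.
#'
#' Shared (genus/section/class) pools are only emitted when their scope spans
#' at least two diploid species, and a shared allele that amplification
#' chance leaves confined to a single diploid species is discarded; the set
#' of species-confined alleles among diploids therefore coincides exactly
#' with the private-allele ledger, which is what the recovery experiments
#' assert. All draws derive from per-marker substreams of `seed`, so results
#' are fully reproducible and earlier markers are unaffected by panel
#' extensions.
#'
#' @param taxonomy Taxonomy data.frame; generated from `config` when `NULL`.
#' @param panel Marker panel data.frame; generated from `config` when `NULL`.
#' @param config A [simulationConfig()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return A list with elements `ssr` (the [SSRSet-class]), `amp` (its
#'   marker-level amplification matrix) and `truth`, a ground-truth ledger:
#'   `donor_A`/`donor_B` accession ids, `private_alleles`
#'   (species, marker_id, size_bp), `section_specific_alleles`,
#'   `tetraploid_only_alleles`, and `duplicated_locus_markers`.
#' @examples
#' sim <- simulateDataset(config = simulationConfig(seed = 7))
#' sim$ssr
#' head(sim$truth$private_alleles)
#' @export
simulateDataset <- function(taxonomy = NULL, panel = NULL,
                            config = simulationConfig(),
                            seed = config$seed) {
  if (is.null(taxonomy)) taxonomy <- generateTaxonomy(config, seed)
  if (is.null(panel)) panel <- generateMarkerPanel(config, seed)
  taxonomy <- validateTaxonomy(taxonomy)
  panel <- validateMarkerPanel(panel)

  diploid <- taxonomy$ploidy < 40L
  if (!any(taxonomy$genome == "A" & diploid) ||
      !any(taxonomy$genome == "B" & diploid))
    .stopf("taxonomy must contain at least one A-genome and one B-genome diploid accession")
  donor_A <- taxonomy$accession_id[taxonomy$genome == "A" & diploid][1]
  donor_B <- taxonomy$accession_id[taxonomy$genome == "B" & diploid][1]
  tetra_ids <- taxonomy$accession_id[taxonomy$ploidy == 40L]

  rank <- match(taxonomy$section, config$section_order) - 1L
  if (anyNA(rank)) .stopf("taxonomy section outside config$section_order")
  dip_tax <- taxonomy[diploid, , drop = FALSE]
  dip_rank <- rank[diploid]
  # species scopes: counts of diploid species per section and per genome class
  spp <- unique(dip_tax[, c("species", "section", "genome")])
  n_spp_section <- table(spp$section)
  n_spp_class <- table(spp$genome[spp$section == "Arachis"])

  acc_ids <- taxonomy$accession_id
  n_acc <- nrow(taxonomy)
  entries <- list()   # per allele: marker, size, carriers (ids), type, scope
  truth_priv <- list(); truth_sect <- list(); truth_extra <- list()
  dup_markers <- character()

  for (j in seq_len(nrow(panel))) {
    set.seed(.substreamSeed(seed, 100L + j))
    m_id <- panel$marker_id[j]
    m_class <- panel$source_class[j]
    avail <- panel$size_min[j]:panel$size_max[j]
    take <- function(k) {
      if (length(avail) < k)
        .stopf("size window of marker %s too narrow for requested alleles",
               m_id)
      idx <- sample.int(length(avail), k)
      out <- avail[idx]
      avail <<- avail[-idx]
      out
    }
    target <- .sampleRange(config$alleles_per_marker)
    n_pools <- config$n_sections + 2L  # section pools + A/B class pools
    pool_size <- max(1L, as.integer(roundHalfUp((target - 2L) / n_pools)))

    genus_alleles <- take(2L)
    sect_pool <- list()
    for (sec in config$section_order[seq_len(config$n_sections)]) {
      sizes <- take(pool_size)
      # pools scoped to a single diploid species are not emitted
      if (!is.na(n_spp_section[sec]) && n_spp_section[sec] >= 2L)
        sect_pool[[sec]] <- sizes
    }
    class_pool <- list()
    for (g in c("A", "B")) {
      sizes <- take(pool_size)
      if (!is.na(n_spp_class[g]) && n_spp_class[g] >= 2L)
        class_pool[[g]] <- sizes
    }
    priv <- list()
    for (k in seq_len(nrow(spp))) {
      u <- runif(1)
      if (u < config$p_private_allele) priv[[spp$species[k]]] <- take(1L)
    }
    # amplification of diploid accessions
    p_amp <- config$base_transfer_prob[[m_class]] *
      exp(-config$section_divergence_penalty * dip_rank)
    amp_dip <- runif(nrow(dip_tax)) < p_amp
    # per-accession allele sets for diploids
    dip_sets <- vector("list", nrow(dip_tax))
    for (i in which(amp_dip)) {
      sizes <- c(genus_alleles,
                 sect_pool[[dip_tax$section[i]]],
                 if (dip_tax$section[i] == "Arachis")
                   class_pool[[dip_tax$genome[i]]],
                 priv[[dip_tax$species[i]]])
      dip_sets[[i]] <- sizes
    }
    # tetraploids: union of donor allele sets, each allele kept w.p. retention
    dA <- dip_sets[[match(donor_A, dip_tax$accession_id)]]
    dB <- dip_sets[[match(donor_B, dip_tax$accession_id)]]
    donor_union <- unique(c(dA, dB))
    tet_sets <- setNames(vector("list", length(tetra_ids)), tetra_ids)
    for (t in seq_along(tetra_ids)) {
      keep <- runif(length(donor_union)) < config$donor_retention
      tet_sets[[t]] <- donor_union[keep]
    }
    u_dup <- runif(1)
    if (m_class == "genomic" && length(dA) && length(dB) &&
        length(tetra_ids) && u_dup < config$p_tetraploid_locus) {
      extra <- take(1L)
      for (t in seq_along(tet_sets))
        tet_sets[[t]] <- c(tet_sets[[t]], extra)
      dup_markers <- c(dup_markers, m_id)
      truth_extra[[length(truth_extra) + 1L]] <-
        data.frame(marker_id = m_id, size_bp = extra)
    }
    # collect carriers per allele size
    all_sets <- c(setNames(dip_sets, dip_tax$accession_id), tet_sets)
    all_sets <- all_sets[lengths(all_sets) > 0]
    if (!length(all_sets)) next
    long <- data.frame(
      accession_id = rep(names(all_sets), lengths(all_sets)),
      size_bp = unlist(all_sets, use.names = FALSE))
    carriers <- split(long$accession_id, long$size_bp)
    sizes <- as.integer(names(carriers))
    # annotate allele provenance for the emission rules and the truth ledger
    type <- rep("shared", length(sizes))
    scope <- rep(NA_character_, length(sizes))
    for (sec in names(sect_pool)) {
      hit <- sizes %in% sect_pool[[sec]]
      type[hit] <- "section"; scope[hit] <- sec
    }
    for (g in names(class_pool)) {
      hit <- sizes %in% class_pool[[g]]
      type[hit] <- "class"; scope[hit] <- g
    }
    for (sp in names(priv)) {
      hit <- sizes %in% priv[[sp]]
      type[hit] <- "private"; scope[hit] <- sp
    }
    if (length(truth_extra) && m_id %in% dup_markers) {
      hit <- sizes %in% truth_extra[[length(truth_extra)]]$size_bp
      type[hit] <- "tetraploid_only"
    }
    entries[[j]] <- list(marker = m_id, sizes = sizes, carriers = carriers,
                         type = type, scope = scope)
  }

  # assemble the presence matrix
  rows_marker <- character(); rows_size <- integer()
  rows_type <- character(); rows_scope <- character()
  cells_r <- integer(); cells_c <- integer()
  r <- 0L
  for (e in entries) {
    if (is.null(e)) next
    for (k in seq_along(e$sizes)) {
      r <- r + 1L
      rows_marker[r] <- e$marker; rows_size[r] <- e$sizes[k]
      rows_type[r] <- e$type[k]; rows_scope[r] <- e$scope[k]
      ci <- match(e$carriers[[k]], acc_ids)
      cells_r <- c(cells_r, rep(r, length(ci))); cells_c <- c(cells_c, ci)
    }
  }
  presence <- matrix(FALSE, r, n_acc)
  presence[cbind(cells_r, cells_c)] <- TRUE

  # drop shared alleles left confined to a single diploid species
  dip_cols <- which(diploid)
  species_of <- taxonomy$species
  keep <- rep(TRUE, r)
  for (i in seq_len(r)) {
    if (rows_type[i] %in% c("private", "tetraploid_only")) next
    n_sp_carr <- length(unique(species_of[dip_cols[
      presence[i, dip_cols]]]))
    if (n_sp_carr <= 1L) keep[i] <- FALSE
  }
  keep <- keep & rowSums(presence) > 0L
  presence <- presence[keep, , drop = FALSE]
  rows_marker <- rows_marker[keep]; rows_size <- rows_size[keep]
  rows_type <- rows_type[keep]; rows_scope <- rows_scope[keep]

  ord <- order(rows_marker, rows_size)
  presence <- presence[ord, , drop = FALSE]
  rows_marker <- rows_marker[ord]; rows_size <- rows_size[ord]
  rows_type <- rows_type[ord]; rows_scope <- rows_scope[ord]

  ssr <- SSRSet(presence,
                data.frame(marker_id = rows_marker, size_bp = rows_size),
                taxonomy, panel)

  # ground truth (emitted alleles only)
  is_priv <- rows_type == "private"
  truth_private <- data.frame(species = rows_scope[is_priv],
                              marker_id = rows_marker[is_priv],
                              size_bp = rows_size[is_priv])
  sec_rows <- rows_type %in% c("section", "class", "tetraploid_only")
  sec_scope <- ifelse(rows_type[sec_rows] == "section",
                      rows_scope[sec_rows], "Arachis")
  truth_section <- data.frame(section = sec_scope,
                              marker_id = rows_marker[sec_rows],
                              size_bp = rows_size[sec_rows])
  is_extra <- rows_type == "tetraploid_only"
  truth_tetra <- data.frame(marker_id = rows_marker[is_extra],
                            size_bp = rows_size[is_extra])
  truth <- list(donor_A = donor_A, donor_B = donor_B,
                private_alleles = truth_private,
                section_specific_alleles = truth_section,
                tetraploid_only_alleles = truth_tetra,
                duplicated_locus_markers = sort(unique(truth_tetra$marker_id)))
  class(truth) <- "ssr_ground_truth"
  list(ssr = ssr, amp = amplificationMatrix(ssr), truth = truth)
}
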