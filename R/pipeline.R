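#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis so runs are auditable
#' and reproducible from a single seed. Either `simulation` is a
#' [simulationConfig()] (simulation mode) or `taxonomy_path`,
#' `marker_panel_path` and `genotype_path` point at input tables (real-data
#' mode).
#'
#' @param output_dir Directory to write results to.
#' @param seed Integer master seed.
#' @param simulation A [simulationConfig()] or `NULL`.
#' @param taxonomy_path,marker_panel_path,genotype_path Input paths for
#'   real-data mode; ignored in simulation mode.
#' @param bootstrap_reps Bootstrap replicates for both dendrograms
#'   (default 1000).
#' @param min_support_display Only splits with at least this percent support
#'   are listed in the rendered report (default 80, the conventional
#'   reporting cut-off).
#' @param bootstrap_unit `"allele"` or `"marker"` (see [bootstrapSupport()]).
#' @return A validated list of class `ssr_pipeline_config`.
#' @export
pipelineConfig <- function(output_dir, seed = 1L, simulation = NULL,
                           taxonomy_path = NULL, marker_panel_path = NULL,
                           genotype_path = NULL, bootstrap_reps = 1000L,
                           min_support_display = 80L,
                           bootstrap_unit = c("allele", "marker")) {
  bootstrap_unit <- match.arg(bootstrap_unit)
  if (bootstrap_reps < 1L) .stopf("bootstrap_reps must be >= 1")
  if (min_support_display < 0L || min_support_display > 100L)
    .stopf("min_support_display must lie in [0, 100]")
  if (is.null(simulation)) {
    for (p in c(taxonomy_path, marker_panel_path, genotype_path))
      if (is.null(p) || !file.exists(p))
        .stopf("real-data mode requires existing taxonomy, panel and genotype files (missing: %s)",
               if (is.null(p)) "unset path" else p)
  } else if (!inherits(simulation, "ssr_sim_config"))
    .stopf("simulation must be a simulationConfig()")
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 simulation = simulation, taxonomy_path = taxonomy_path,
                 marker_panel_path = marker_panel_path,
                 genotype_path = genotype_path,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 min_support_display = as.integer(min_support_display),
                 bootstrap_unit = bootstrap_unit),
            class = "ssr_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipelineConfig()] arguments; a `simulation:` block, when
#' present, is passed to [simulationConfig()].
#'
#' @param path YAML file path.
#' @return A `ssr_pipeline_config`.
#' @export
loadPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    if (!is.null(y$simulation$base_transfer_prob))
      y$simulation$base_transfer_prob <- unlist(y$simulation$base_transfer_prob)
    y$simulation <- do.call(simulationConfig, y$simulation)
  }
  do.call(pipelineConfig, y)
}

#' Run the full SSR analysis pipeline
#'
#' Executes (simulation ->) transferability -> allele specificity ->
#' distances, NJ trees and bootstrap (accession- and section-level) ->
#' donor ranking, writing all result tables, Newick trees, a JSON summary
#' and a log of every setting to `config$output_dir`. Any stage error aborts
#' with the stage name. Re-running with the same configuration reproduces
#' the outputs byte-for-byte.
#'
#' @param config A [pipelineConfig()].
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "ssr_pipeline_config"))
    .stopf("config must come from pipelineConfig()")
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate",
                 simulateDataset(config = config$simulation,
                                 seed = config$seed))
    x <- sim$ssr
    truth <- sim$truth
    writeTaxonomy(x, file.path(out, "taxonomy.tsv"))
    writeMarkerPanel(x, file.path(out, "marker_panel.tsv"))
    writeGenotypeLong(x, file.path(out, "genotype_long.tsv"))
    tr <- truth
    tr$duplicated_locus_markers <- as.list(tr$duplicated_locus_markers)
    jsonlite::write_json(unclass(tr), file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, dataframe = "rows",
                         pretty = TRUE)
  } else {
    x <- stage("load", {
      tax <- readTaxonomy(config$taxonomy_path)
      panel <- readMarkerPanel(config$marker_panel_path)
      readGenotypeLong(config$genotype_path, panel, tax)
    })
  }
  tax <- taxonomyTable(x)
  panel <- markerPanel(x)
  amp <- amplificationMatrix(x)

  ttab <- stage("transferability",
                sectionTransferability(amp, tax, panel, cultivatedSpecies(x)))
  ztest <- compareMarkerClasses(ttab)
  full <- fullyTransferableMarkers(amp, tax, panel, cultivatedSpecies(x))
  nulls <- singleSectionNullMarkers(amp, tax)
  spAll <- stage("alleles", specificAlleles(x, "species"))
  seAll <- specificAlleles(x, "section")
  writeReport(list(
    transferability = ttab,
    specific_alleles_species = spAll$alleles,
    specific_alleles_species_summary = spAll$summary,
    specific_alleles_section = seAll$alleles,
    specific_alleles_section_summary = seAll$summary,
    null_markers = data.frame(marker_id = names(nulls),
                              null_section = unname(nulls))), out)
  writeLines(full, file.path(out, "fully_transferable.txt"))

  accTree <- stage("tree", bootstrapSupport(
    x, nReps = config$bootstrap_reps, seed = config$seed,
    grouping = "accession", unit = config$bootstrap_unit))
  writeNewick(accTree, file.path(out, "accession_tree.nwk"))
  secTree <- stage("tree", bootstrapSupport(
    x, nReps = config$bootstrap_reps, seed = config$seed,
    grouping = "section", unit = config$bootstrap_unit))
  writeNewick(secTree, file.path(out, "section_tree.nwk"))
  writeReport(list(accession_tree_supports = attr(accTree, "supports"),
                   section_tree_supports = attr(secTree, "supports")),
              file.path(out, "supports"))

  donors <- stage("donors", rankDonorCandidates(x))
  writeReport(list(donor_ranking = rbind(donors$A, donors$B)), out)

  concord <- c(species = treeTaxonConcordance(accTree, tax, "species"),
               section = treeTaxonConcordance(accTree, tax, "section"),
               genome = treeTaxonConcordance(accTree, tax, "genome"))
  summary <- list(
    mode = if (is.null(config$simulation)) "real-data" else "simulation",
    seed = config$seed,
    n_accessions = ncol(x), n_alleles = nrow(x), n_markers = nrow(panel),
    bootstrap_reps = config$bootstrap_reps,
    bootstrap_unit = config$bootstrap_unit,
    class_comparison = list(z = unname(ztest["z"]), p = unname(ztest["p"])),
    fully_transferable_markers = as.list(full),
    tree_concordance = as.list(concord),
    nominated_donors = as.list(donors$nominated))
  if (!is.null(truth)) {
    summary$ground_truth_comparison <- list(
      donor_A_recovered = donors$nominated[["A"]] == truth$donor_A,
      donor_B_recovered = donors$nominated[["B"]] == truth$donor_B,
      true_donor_A = truth$donor_A, true_donor_B = truth$donor_B)
  }
  jsonlite::write_json(summary, file.path(out, "pipeline_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log <- c(sprintf("seed: %d", config$seed),
           sprintf("bootstrap_reps: %d", config$bootstrap_reps),
           sprintf("bootstrap_unit: %s", config$bootstrap_unit),
           sprintf("min_support_display: %d", config$min_support_display),
           "rounding: half-up (percentages)",
           "distance: Nei-Li as 1 - Dice similarity",
           "nj_tie_break: smallest label pair",
           "negative_branch_lengths: clamped to 0",
           sprintf("R: %s; SSRwild: %s", R.version.string,
                   as.character(utils::packageVersion("SSRwild"))))
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(out)
}

#' Render a human-readable pipeline report
#'
#' Summarizes a [runPipeline()] output directory as markdown: the
#' transferability table, the top specific-allele taxa, tree concordance,
#' high-support splits, and donor nominations (plus the ground-truth
#' comparison in simulation mode).
#'
#' @param dir Output directory of [runPipeline()].
#' @param minSupport Only splits with at least this support are listed
#'   (defaults to the value logged by the run).
#' @return The markdown report as a character scalar, invisibly; also
#'   written to `report.md` inside `dir`.
#' @export
renderReport <- function(dir, minSupport = NULL) {
  needed <- c("transferability.tsv", "specific_alleles_species_summary.tsv",
              "pipeline_summary.json", "accession_tree.nwk",
              "section_tree.nwk", "donor_ranking.tsv")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    .stopf("incomplete pipeline directory, missing: %s",
           paste(missing, collapse = ", "))
  summ <- jsonlite::read_json(file.path(dir, "pipeline_summary.json"))
  ttab <- read.delim(file.path(dir, "transferability.tsv"))
  spp <- read.delim(file.path(dir, "specific_alleles_species_summary.tsv"))
  donors <- read.delim(file.path(dir, "donor_ranking.tsv"))
  if (is.null(minSupport)) {
    lg <- readLines(file.path(dir, "run_log.txt"))
    minSupport <- as.integer(sub(".*: ", "",
                                 grep("min_support_display",
                                      lg, value = TRUE)[1]))
    if (is.na(minSupport)) minSupport <- 80L
  }
  sup <- read.delim(file.path(dir, "supports", "accession_tree_supports.tsv"))
  fmt <- function(df) {
    header <- paste(colnames(df), collapse = " | ")
    rule <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, function(r) paste(r, collapse = " | "))
    c(paste("|", header, "|"), paste("|", rule, "|"),
      paste("|", body, "|"))
  }
  means <- ttab[ttab$section == "Mean", , drop = FALSE]
  lines <- c(
    "# SSR analysis report", "",
    sprintf("Mode: %s; seed %s; %s accessions, %s alleles, %s markers.",
            summ$mode, summ$seed, summ$n_accessions, summ$n_alleles,
            summ$n_markers), "",
    "## Marker transferability by section", "", fmt(ttab), "",
    sprintf("Class means: genomic %s%%, genic %s%% (z = %.2f, p = %.3g).",
            means$pct[means$source_class == "genomic"],
            means$pct[means$source_class == "genic"],
            summ$class_comparison$z, summ$class_comparison$p), "",
    "## Species-specific alleles (top taxa)", "",
    fmt(utils::head(spp, 10)), "",
    "## Dendrogram concordance", "",
    sprintf("Fraction of taxa recovered as tree splits: species %.2f, section %.2f, genome %.2f.",
            as.numeric(summ$tree_concordance$species),
            as.numeric(summ$tree_concordance$section),
            as.numeric(summ$tree_concordance$genome)), "",
    sprintf("Splits with bootstrap support >= %d%%: %d of %d.",
            minSupport, sum(sup$support >= minSupport), nrow(sup)), "",
    "## Nominated genome donors", "",
    sprintf("A-genome: %s; B-genome: %s.", summ$nominated_donors$A,
            summ$nominated_donors$B), "",
    fmt(utils::head(donors[order(donors$group_distance), ], 6)))
  if (!is.null(summ$ground_truth_comparison)) {
    gt <- summ$ground_truth_comparison
    lines <- c(lines, "", "## Recovery vs simulated truth", "",
               sprintf("True donors %s / %s; recovered: A %s, B %s.",
                       gt$true_donor_A, gt$true_donor_B,
                       gt$donor_A_recovered, gt$donor_B_recovered))
  }
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(dir, "report.md"))
  invisible(txt)
}
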