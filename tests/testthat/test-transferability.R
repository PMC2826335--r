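# 5-accession fixture exercising the source-species exclusion rule:
# genomic markers ignore the cultivated accessions, genic markers count them.
exclusionFixture <- function() {
  tax <- data.frame(
    accession_id = c("hyp1", "hyp2", "dur1", "ipa1", "pin1"),
    species = c("A. hypogaea", "A. hypogaea", "A. duranensis",
                "A. ipaensis", "A. pintoi"),
    section = c("Arachis", "Arachis", "Arachis", "Arachis", "Caulorrhizae"),
    genome = c("AB", "AB", "A", "B", "unassigned"),
    ploidy = c(40L, 40L, 20L, 20L, 20L))
  panel <- data.frame(marker_id = c("G1", "G2", "C1"),
                      source_class = c("genomic", "genomic", "genic"),
                      size_min = 100L, size_max = 999L)
  amp <- rbind(
    G1 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    G2 = c(TRUE, TRUE, FALSE, FALSE, FALSE),  # only in excluded cultivated
    C1 = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  colnames(amp) <- tax$accession_id
  list(amp = amp, tax = tax, panel = panel)
}

test_that("section transferability applies the exclusion rule and half-up rounding", {
  f <- exclusionFixture()
  tab <- sectionTransferability(f$amp, f$tax, f$panel)
  g <- tab[tab$source_class == "genomic" & tab$section != "Mean", ]
  # G2 amplifies only the excluded cultivated accessions: not transferable
  expect_equal(g$n_transferable[g$section == "Arachis"], 1L)
  expect_equal(g$pct[g$section == "Arachis"], 50L)
  expect_equal(g$n_transferable[g$section == "Caulorrhizae"], 1L)
  cMean <- tab[tab$source_class == "genic" & tab$section == "Mean", ]
  expect_equal(cMean$pct, 50L)  # mean of 100 and 0, half-up
  # pct column is recomputable from its own counts
  body <- tab[tab$section != "Mean", ]
  expect_equal(body$pct,
               as.integer(roundHalfUp(100 * body$n_transferable /
                                        body$n_total)))
})

test_that("per-section counts reproduce the published class summary", {
  # the published genus-wide survey: per-section genomic percentages
  # {100,68,87,84,84,60,50} average to 76, genic to 88
  tab <- sectionCountsToTable(arachisTransferCounts())
  expect_equal(tab$pct[tab$source_class == "genomic"][1:7],
               c(100L, 68L, 87L, 84L, 84L, 60L, 50L))
  expect_equal(tab$n_transferable[tab$section == "Mean"], c(62L, 17L))
  expect_equal(tab$pct[tab$section == "Mean"], c(76L, 88L))
})

test_that("accession-level rates average per-marker fractions", {
  f <- exclusionFixture()
  # saturation and degenerate cases
  ampAll <- f$amp; ampAll[] <- TRUE
  expect_equal(accessionLevelRate(ampAll, f$tax, f$panel,
                                  arachisSections()), 100)
  ampNone <- f$amp; ampNone[] <- FALSE
  expect_equal(accessionLevelRate(ampNone, f$tax, f$panel,
                                  arachisSections()), 0)
  # two markers amplifying 3/4 and 1/4 scorable accessions -> 50%
  tax <- data.frame(accession_id = paste0("w", 1:4),
                    species = paste0("A. sp", c(1, 1, 2, 2)),
                    section = "Erectoides", genome = "unassigned",
                    ploidy = 20L)
  panel <- data.frame(marker_id = c("M1", "M2"), source_class = "genomic",
                      size_min = 100L, size_max = 999L)
  amp <- rbind(M1 = c(TRUE, TRUE, TRUE, FALSE),
               M2 = c(TRUE, FALSE, FALSE, FALSE))
  colnames(amp) <- tax$accession_id
  expect_equal(accessionLevelRate(amp, tax, panel, "Erectoides"), 50)
})

test_that("fully transferable markers respect the exclusion rule", {
  f <- exclusionFixture()
  # G1 amplifies everywhere; C1 misses pin1; G2 only cultivated
  expect_equal(fullyTransferableMarkers(f$amp, f$tax, f$panel), "G1")
  # genomic marker failing only in an excluded cultivated accession
  f$amp["G1", "hyp1"] <- FALSE
  expect_equal(fullyTransferableMarkers(f$amp, f$tax, f$panel), "G1")
  # but a miss in a scorable accession disqualifies
  f$amp["G1", "pin1"] <- FALSE
  expect_equal(fullyTransferableMarkers(f$amp, f$tax, f$panel), character(0))
})

test_that("adding cultivated accessions never changes genomic-class rows", {
  sim <- simulateDataset(config = simulationConfig(
    species_per_section = c(2, 2), accessions_per_species = c(2, 2),
    tetraploid_accessions = 2, seed = 21))
  tax <- taxonomyTable(sim$ssr)
  panel <- markerPanel(sim$ssr)
  wild <- tax$accession_id[tax$species != "A. hypogaea"]
  ampWild <- sim$amp[, wild, drop = FALSE]
  t1 <- sectionTransferability(ampWild, tax[tax$species != "A. hypogaea", ],
                               panel)
  t2 <- sectionTransferability(sim$amp, tax, panel)
  expect_equal(t1[t1$source_class == "genomic", ],
               t2[t2$source_class == "genomic", ])
})

test_that("single-section null markers require exactly one silent section", {
  f <- exclusionFixture()
  amp <- rbind(
    N1 = c(TRUE, TRUE, TRUE, TRUE, FALSE),   # silent only in Caulorrhizae
    N2 = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    N3 = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  colnames(amp) <- f$tax$accession_id
  out <- singleSectionNullMarkers(amp, f$tax)
  expect_equal(out, c(N1 = "Caulorrhizae"))
})

test_that("the class z-test matches the pooled two-proportion hand oracle", {
  tab <- data.frame(section = "Mean", source_class = c("genomic", "genic"),
                    n_transferable = c(62L, 17L), n_total = c(82L, 19L),
                    pct = c(76L, 88L))
  z <- compareMarkerClasses(tab)
  # hand computation: p1=62/82, p2=17/19, pooled 79/101
  expect_equal(unname(z["z"]), 1.3192, tolerance = 1e-4)
  expect_equal(unname(z["p"]), 2 * pnorm(-1.3192), tolerance = 1e-4)
  # identical proportions -> z = 0, p = 1
  tab0 <- tab; tab0$n_transferable <- c(41L, 19L); tab0$n_total <- c(82L, 38L)
  z0 <- compareMarkerClasses(tab0)
  expect_equal(unname(z0["z"]), 0)
  expect_equal(unname(z0["p"]), 1)
  # swapping the class labels negates z, p unchanged
  tabSwap <- tab
  tabSwap$source_class <- rev(tabSwap$source_class)
  zs <- compareMarkerClasses(tabSwap)
  expect_equal(unname(zs["z"]), -unname(z["z"]))
  expect_equal(unname(zs["p"]), unname(z["p"]))
})
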