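test_that("taxonomy generation satisfies the structural postconditions", {
  tax <- generateTaxonomy(simulationConfig(seed = 1))
  expect_equal(sort(unique(tax$section)), sort(arachisSections()))
  ara <- tax[tax$section == "Arachis", ]
  expect_true(any(ara$genome == "A" & ara$ploidy == 20))
  expect_true(any(ara$genome == "B" & ara$ploidy == 20))
  expect_true(any(ara$genome == "D" & ara$ploidy == 20))
  expect_gte(sum(ara$genome == "AB" & ara$ploidy == 40), 2)
  expect_true(all(tax$genome[tax$section != "Arachis"] == "unassigned"))

  # determinism
  expect_identical(tax, generateTaxonomy(simulationConfig(seed = 1)))
  expect_false(identical(tax, generateTaxonomy(simulationConfig(seed = 2))))

  # minimal ranges still yield a valid 7-section taxonomy
  mini <- generateTaxonomy(simulationConfig(
    species_per_section = c(1, 1), accessions_per_species = c(1, 1)))
  expect_equal(length(unique(mini$section)), 7L)
  expect_true(any(mini$genome == "AB"))
})

test_that("marker panel generation matches the configured composition", {
  panel <- generateMarkerPanel(simulationConfig(seed = 1))
  expect_equal(nrow(panel), 101L)
  expect_equal(sum(panel$source_class == "genomic"), 82L)
  expect_equal(sum(panel$source_class == "genic"), 19L)
  expect_identical(panel, generateMarkerPanel(simulationConfig(seed = 1)))
  allGenic <- generateMarkerPanel(simulationConfig(n_genomic_markers = 0))
  expect_true(all(allGenic$source_class == "genic"))
})

test_that("configuration validation rejects impossible parameters", {
  expect_error(simulationConfig(p_private_allele = 1.5), "\\[0, 1\\]")
  expect_error(simulationConfig(species_per_section = c(3, 2)), "range")
  expect_error(simulationConfig(tetraploid_accessions = 1), ">= 2")
  tax <- generateTaxonomy(simulationConfig(seed = 1))
  tax <- tax[tax$genome != "B", ]
  expect_error(simulateDataset(tax, config = simulationConfig(seed = 1)),
               "B-genome diploid")
})

test_that("simulated datasets are reproducible and structurally valid", {
  cfg <- simulationConfig(seed = 11)
  s1 <- simulateDataset(config = cfg)
  s2 <- simulateDataset(config = cfg)
  expect_equal(presenceMatrix(s1$ssr), presenceMatrix(s2$ssr))
  expect_identical(s1$truth, s2$truth)
  expect_true(validObject(s1$ssr))
  # amplification is the allele-wise OR of presence
  agg <- rowsum(presenceMatrix(s1$ssr) + 0L,
                alleleTable(s1$ssr)$marker_id) > 0
  expect_equal(s1$amp[rownames(agg), ], agg)
})

test_that("degenerate generator settings force the documented identities", {
  # no private alleles planted
  s <- simulateDataset(config = simulationConfig(p_private_allele = 0,
                                                 seed = 3))
  expect_equal(nrow(s$truth$private_alleles), 0L)

  # full retention, no duplicated loci: tetraploids carry exactly the
  # union of the two donors' alleles
  s <- simulateDataset(config = simulationConfig(
    donor_retention = 1, p_tetraploid_locus = 0, seed = 5))
  p <- presenceMatrix(s$ssr)
  donorUnion <- p[, s$truth$donor_A] | p[, s$truth$donor_B]
  tet <- taxonomyTable(s$ssr)$accession_id[taxonomyTable(s$ssr)$ploidy == 40]
  for (t in tet) expect_equal(unname(p[, t]), unname(donorUnion))
  expect_equal(length(s$truth$duplicated_locus_markers), 0L)
})

test_that("tetraploids retain donor alleles at the configured rate", {
  # fraction of donor-union alleles carried by a tetraploid accession
  # estimates donor_retention; averaged over seeds it must sit within
  # Monte-Carlo error of the configured value
  retained <- total <- 0
  for (k in 1:15) {
    s <- simulateDataset(config = simulationConfig(
      p_tetraploid_locus = 0, seed = 500 + k))
    p <- presenceMatrix(s$ssr)
    donorUnion <- p[, s$truth$donor_A] | p[, s$truth$donor_B]
    tet <- taxonomyTable(s$ssr)$accession_id[
      taxonomyTable(s$ssr)$ploidy == 40]
    for (t in tet) {
      retained <- retained + sum(p[donorUnion, t])
      total <- total + sum(donorUnion)
    }
  }
  phat <- retained / total
  expect_lt(abs(phat - 0.95), 3 * sqrt(0.95 * 0.05 / total) + 1e-3)
})

test_that("per-marker substreams keep earlier markers stable when the panel grows", {
  cfg1 <- simulationConfig(seed = 9)
  cfg2 <- simulationConfig(seed = 9, n_genic_markers = 25)
  tax <- generateTaxonomy(cfg1)
  p1 <- generateMarkerPanel(cfg1)
  s1 <- simulateDataset(tax, p1, cfg1)
  p2 <- rbind(p1, data.frame(marker_id = sprintf("XtraSSR%02d", 1:6),
                             source_class = "genic",
                             size_min = 100L, size_max = 299L))
  s2 <- simulateDataset(tax, p2, cfg1)
  shared <- alleleTable(s1$ssr)$marker_id %in% p1$marker_id
  k1 <- paste(alleleTable(s1$ssr)$marker_id, alleleTable(s1$ssr)$size_bp)
  k2 <- paste(alleleTable(s2$ssr)$marker_id, alleleTable(s2$ssr)$size_bp)
  keep2 <- alleleTable(s2$ssr)$marker_id %in% p1$marker_id
  expect_equal(k1[shared], k2[keep2])
  expect_equal(unname(presenceMatrix(s1$ssr)[shared, ]),
               unname(presenceMatrix(s2$ssr)[keep2, ]))
})
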