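test_that("taxonomy reading validates tokens and invariants", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeTaxonomy(tinyTaxonomy(), tf)
  tax <- readTaxonomy(tf)
  expect_equal(nrow(tax), 6L)
  expect_equal(sort(unique(tax$section)), c("Arachis", "Caulorrhizae"))

  bad <- tinyTaxonomy()
  bad$section[5:6] <- "Rhizomatosae"
  bad$genome[5:6] <- "unassigned"
  writeTaxonomy(bad, tf)
  expect_error(readTaxonomy(tf), "Rhizomatosae.*allowed")

  bad <- tinyTaxonomy()
  bad$ploidy[1] <- 20L
  writeTaxonomy(bad, tf)
  expect_error(readTaxonomy(tf), "AB implies ploidy 40")

  bad <- tinyTaxonomy()
  bad$accession_id[2] <- "hyp1"
  writeTaxonomy(bad, tf)
  expect_error(readTaxonomy(tf), "duplicate accession_id: hyp1")

  bad <- tinyTaxonomy()
  bad$section[6] <- "Arachis"
  bad$genome[6] <- "A"
  writeTaxonomy(bad, tf)
  expect_error(readTaxonomy(tf), "more than one section")
})

test_that("long-format genotypes build consistent allele and amplification matrices", {
  gt <- data.frame(
    accession_id = c("dur1", "ipa1", "dur1"),
    marker_id = c("M1", "M1", "M1"),
    size_bp = c(200L, 200L, 210L),
    presence = 1L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(gt, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  x <- readGenotypeLong(tf, tinyPanel(), tinyTaxonomy())
  expect_s4_class(x, "SSRSet")
  expect_equal(dim(x), c(2L, 6L))
  expect_true(presenceMatrix(x)["M1:200", "ipa1"])
  expect_false(presenceMatrix(x)["M1:210", "ipa1"])
  amp <- amplificationMatrix(x)
  # no row for M2 anywhere: amplification defaults to absent
  expect_false(any(amp["M2", ]))
  expect_true(amp["M1", "dur1"])
  # amplification is always the allele-wise OR of presence
  agg <- rowsum(presenceMatrix(x) + 0L, alleleTable(x)$marker_id) > 0
  expect_equal(amp[rownames(agg), , drop = FALSE], agg)
})

test_that("genotype reader rejects unknown ids and out-of-window sizes", {
  gt <- data.frame(accession_id = "dur1", marker_id = "M1",
                   size_bp = 5000L, presence = 1L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(gt, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGenotypeLong(tf, tinyPanel(), tinyTaxonomy()),
               "outside marker window")
  gt$size_bp <- 200L
  gt$accession_id <- "nope"
  write.table(gt, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGenotypeLong(tf, tinyPanel(), tinyTaxonomy()),
               "unknown accession")
})

test_that("a simulated dataset round-trips through the text formats exactly", {
  sim <- simulateDataset(config = simulationConfig(
    species_per_section = c(2, 2), accessions_per_species = c(2, 2),
    tetraploid_accessions = 2, seed = 4))
  d <- withr::local_tempdir()
  writeTaxonomy(sim$ssr, file.path(d, "tax.tsv"))
  writeMarkerPanel(sim$ssr, file.path(d, "panel.tsv"))
  writeGenotypeLong(sim$ssr, file.path(d, "gt.tsv"))
  x2 <- readGenotypeLong(file.path(d, "gt.tsv"),
                         readMarkerPanel(file.path(d, "panel.tsv")),
                         readTaxonomy(file.path(d, "tax.tsv")))
  expect_equal(presenceMatrix(x2), presenceMatrix(sim$ssr))
  expect_equal(alleleTable(x2), alleleTable(sim$ssr))
  expect_equal(amplificationMatrix(x2), amplificationMatrix(sim$ssr))
})

test_that("SSRSet validity catches duplicate and carrier-free alleles", {
  expect_error(
    buildSSRSet(list("M1:200" = "dur1", "M1:200" = "ipa1")),
    "duplicate")
  tax <- tinyTaxonomy()
  p <- matrix(FALSE, 1, nrow(tax))
  expect_error(
    SSRSet(p, data.frame(marker_id = "M1", size_bp = 200L), tax,
           tinyPanel()),
    "no accession")
})

test_that("newick serialization round-trips splits and branch lengths", {
  sim <- simulateDataset(config = simulationConfig(
    species_per_section = c(2, 2), accessions_per_species = c(2, 2),
    tetraploid_accessions = 2, seed = 6))
  tr <- bootstrapSupport(sim$ssr, nReps = 20, seed = 3)
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, tf)
  back <- readNewick(tf)
  expect_setequal(unname(treeBipartitions(back)),
                  unname(treeBipartitions(tr)))
  Da <- ape::cophenetic.phylo(tr)
  Db <- ape::cophenetic.phylo(back)[rownames(Da), colnames(Da)]
  expect_lt(max(abs(Da - Db)), 1e-5)
  # supports survive as integer internal-node labels
  expect_true(all(grepl("^[0-9]*$", back$node.label)))

  # smallest unrooted case
  t3 <- neighborJoining(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                               dimnames = list(LETTERS[1:3], LETTERS[1:3])))
  writeNewick(t3, tf)
  expect_match(readLines(tf), "^\\(A:[0-9.]+,B:[0-9.]+,C:[0-9.]+\\);$")
})

test_that("writeReport output is deterministic and complete", {
  tabs <- list(alpha = data.frame(k = c("b", "a"), v = 2:1),
               empty = data.frame(k = character(), v = integer()))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeReport(tabs, d1)
  writeReport(tabs, d2)
  for (f in c("alpha.tsv", "empty.tsv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(readLines(file.path(d1, "empty.tsv")), "k\tv")
  # rows sorted by key columns
  expect_equal(read.delim(file.path(d1, "alpha.tsv"))$k, c("a", "b"))
})
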