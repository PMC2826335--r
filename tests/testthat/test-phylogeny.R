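test_that("Nei-Li distance matches the Dice-complement formula", {
  expect_equal(neiLiDistance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(neiLiDistance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # a=3, b=1, c=2 -> 1 - 6/9
  expect_equal(neiLiDistance(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 1, 1)),
               1 / 3)
  expect_error(neiLiDistance(c(0, 0), c(0, 0)), "all-zero")
  expect_error(neiLiDistance(c(1, 0), c(1)), "equal positive length")
})

test_that("Nei-Li properties hold over random profiles", {
  set.seed(17)
  for (k in 1:50) {
    n <- sample(5:40, 1)
    x <- runif(n) < 0.4
    y <- runif(n) < 0.4
    if (!any(x)) x[1] <- TRUE
    if (!any(y)) y[2 %% n + 1] <- TRUE
    d <- neiLiDistance(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, neiLiDistance(y, x))
    # joint absences never contribute
    expect_equal(d, neiLiDistance(c(x, rep(FALSE, 7)),
                                  c(y, rep(FALSE, 7))))
    if (identical(x, y)) expect_equal(d, 0) else expect_gt(d, 0)
  }
})

test_that("distance matrices agree with pairwise calls and group means", {
  x <- buildSSRSet(list(
    "M1:200" = c("dur1", "ipa1", "pin1"),
    "M1:210" = c("dur1", "pin2"),
    "M2:300" = c("ipa1", "pin1", "pin2"),
    "M3:400" = c("dur1", "ipa1", "pin2")))
  ids <- c("dur1", "ipa1", "pin1", "pin2")
  xs <- subsetAccessions(x, ids)
  D <- neiLiDistanceMatrix(xs)
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D, t(D))
  P <- presenceMatrix(xs)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(D[i, j], neiLiDistance(P[, i], P[, j]))
  # section-level entry = brute-force mean over the 4 cross pairs
  G <- neiLiDistanceMatrix(xs, grouping = "section")
  cross <- c(D["dur1", "pin1"], D["dur1", "pin2"],
             D["ipa1", "pin1"], D["ipa1", "pin2"])
  expect_equal(G["Arachis", "Caulorrhizae"], mean(cross))
  expect_equal(G["Caulorrhizae", "Arachis"], mean(cross))
})

test_that("NJ solves the 3-taxon case in closed form", {
  D <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  expect_equal(tr$Nnode, 1L)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], (.3 + .5 - .6) / 2)
  expect_equal(len[["B"]], (.3 + .6 - .5) / 2)
  expect_equal(len[["C"]], (.5 + .6 - .3) / 2)
  expect_error(neighborJoining(D[1:2, 1:2]), "at least 3")
  Dasym <- D; Dasym[1, 2] <- 0.9
  expect_error(neighborJoining(Dasym), "not symmetric")
})

test_that("NJ recovers the generating quartet exactly from additive distances", {
  # tree ((A:1,B:2):1,(C:3,D:4))
  lab <- LETTERS[1:4]
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(lab, lab))
  tr <- neighborJoining(D)
  expect_setequal(unname(treeBipartitions(tr)), "C|D")
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], D)
  len <- setNames(tr$edge.length, c(tr$tip.label, "")[
    ifelse(tr$edge[, 2] <= 4, tr$edge[, 2], 5)])
  expect_equal(sort(unname(len[names(len) != ""])), c(1, 2, 3, 4))
  # internal edge length 1
  expect_equal(unname(len[names(len) == ""]), 1)
})

test_that("equidistant inputs resolve deterministically with zero internal edges", {
  lab <- LETTERS[1:4]
  D <- matrix(1, 4, 4, dimnames = list(lab, lab)); diag(D) <- 0
  t1 <- neighborJoining(D)
  t2 <- neighborJoining(D)
  expect_identical(t1$edge, t2$edge)
  internal <- t1$edge[, 2] > 4
  expect_equal(t1$edge.length[internal], 0)
  # tie-break joins the lexicographically smallest label pair first
  expect_setequal(unname(treeBipartitions(t1)), "C|D")
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(5)
  for (k in 1:10) {
    f <- randomAdditiveMatrix(sample(6:9, 1))
    D <- f$D + matrix(runif(length(f$D), 0, 0.02), nrow(f$D))
    D <- (D + t(D)) / 2; diag(D) <- 0
    mine <- neighborJoining(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("allele row order never affects the tree", {
  sim <- simulateDataset(config = simulationConfig(
    species_per_section = c(2, 2), accessions_per_species = c(2, 2),
    tetraploid_accessions = 2, seed = 8))
  x <- sim$ssr
  D1 <- neiLiDistanceMatrix(x)
  set.seed(1)
  perm <- sample(nrow(x))
  x2 <- SSRSet(presenceMatrix(x)[perm, ], alleleTable(x)[perm, ],
               taxonomyTable(x), markerPanel(x))
  expect_equal(neiLiDistanceMatrix(x2), D1)
  expect_equal(treeBipartitions(neighborJoining(neiLiDistanceMatrix(x2))),
               treeBipartitions(neighborJoining(D1)))
})

test_that("bootstrap supports are reproducible and saturate for identical twins", {
  tax <- rbind(tinyTaxonomy(),
               data.frame(accession_id = c("ere1", "ere2"),
                          species = "A. erect-sp1", section = "Erectoides",
                          genome = "unassigned", ploidy = 20L))
  # pin1/pin2 get identical profiles: their cherry must reach support 100
  x <- buildSSRSet(list(
    "M1:200" = c("pin1", "pin2"),
    "M1:210" = c("pin1", "pin2", "dur1"),
    "M2:300" = c("dur1", "ipa1"),
    "M2:310" = c("ere1", "ere2", "ipa1"),
    "M3:400" = c("hyp1", "hyp2", "ere1"),
    "M3:410" = c("hyp1", "hyp2", "dur1", "ere2")), taxonomy = tax)
  b1 <- bootstrapSupport(x, nReps = 60, seed = 7)
  b2 <- bootstrapSupport(x, nReps = 60, seed = 7)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
  sup <- attr(b1, "supports")
  cherry <- vapply(strsplit(sup$bipartition, "|", fixed = TRUE),
                   function(s) setequal(s, c("pin1", "pin2")), logical(1))
  expect_true(any(cherry))
  expect_equal(sup$support[cherry], 100L)
  expect_true(all(sup$support >= 0 & sup$support <= 100))
})

test_that("taxon concordance counts splits of the unrooted tree", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  tax <- data.frame(accession_id = c("a1", "a2", "b1", "b2"),
                    species = c("A. sp1", "A. sp1", "A. sp2", "A. sp2"),
                    section = "Erectoides", genome = "unassigned",
                    ploidy = 20L)
  expect_equal(treeTaxonConcordance(tr, tax, "species"), 1)
  swapped <- tax
  swapped$species <- c("A. sp1", "A. sp2", "A. sp1", "A. sp2")
  expect_equal(treeTaxonConcordance(tr, swapped, "species"), 0)
})
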