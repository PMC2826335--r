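# Hand-built fixtures and independent oracles shared across tests.

tinyTaxonomy <- function() {
  data.frame(
    accession_id = c("hyp1", "hyp2", "dur1", "ipa1", "pin1", "pin2"),
    species = c("A. hypogaea", "A. hypogaea", "A. duranensis",
                "A. ipaensis", "A. pintoi", "A. pintoi"),
    section = c("Arachis", "Arachis", "Arachis", "Arachis",
                "Caulorrhizae", "Caulorrhizae"),
    genome = c("AB", "AB", "A", "B", "unassigned", "unassigned"),
    ploidy = c(40L, 40L, 20L, 20L, 20L, 20L))
}

tinyPanel <- function() {
  data.frame(marker_id = c("M1", "M2", "M3"),
             source_class = c("genomic", "genomic", "genic"),
             size_min = 100L, size_max = 999L)
}

# presence rows given as named list: "marker:size" -> accession ids
buildSSRSet <- function(carriers, taxonomy = tinyTaxonomy(),
                        panel = tinyPanel()) {
  ids <- strsplit(names(carriers), ":", fixed = TRUE)
  alleles <- data.frame(marker_id = vapply(ids, `[`, "", 1),
                        size_bp = as.integer(vapply(ids, `[`, "", 2)))
  p <- matrix(FALSE, length(carriers), nrow(taxonomy))
  for (i in seq_along(carriers))
    p[i, match(carriers[[i]], taxonomy$accession_id)] <- TRUE
  SSRSet(p, alleles, taxonomy, panel)
}

# Brute-force least-squares resolution of a quartet: returns the pair joined
# with the first taxon under the best-fitting of the three topologies.
quartetLS <- function(D, q) {
  pairs <- list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3))
  rss <- vapply(pairs, function(p) {
    a <- q[1]; b <- q[p[1]]; c_ <- q[p[2]]; d <- q[p[3]]
    # topology ab|cd with branch lengths ea..ed and internal em
    X <- rbind(c(1, 1, 0, 0, 0),   # d(a,b)
               c(1, 0, 1, 0, 1),   # d(a,c)
               c(1, 0, 0, 1, 1),   # d(a,d)
               c(0, 1, 1, 0, 1),   # d(b,c)
               c(0, 1, 0, 1, 1),   # d(b,d)
               c(0, 0, 1, 1, 0))   # d(c,d)
    y <- c(D[a, b], D[a, c_], D[a, d], D[b, c_], D[b, d], D[c_, d])
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  q[pairs[[which.min(rss)]][1]]
}

# Quartet split induced by an unrooted tree: which taxon pairs with q[1].
treeQuartetMate <- function(tree, q) {
  D <- ape::cophenetic.phylo(tree)
  sums <- c(D[q[1], q[2]] + D[q[3], q[4]],
            D[q[1], q[3]] + D[q[2], q[4]],
            D[q[1], q[4]] + D[q[2], q[3]])
  q[c(2, 3, 4)[which.min(sums)]]
}

randomAdditiveMatrix <- function(nTips) {
  tr <- ape::unroot(ape::rtree(nTips, br = function(n) runif(n, 0.1, 2)))
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}
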