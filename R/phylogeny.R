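#' Nei-Li genetic distance between two binary allele profiles
#'
#' The Dice-complement reading of the Nei & Li restriction-data coefficient
#' for dominant markers: with `a` shared present bands, `b` bands present
#' only in `x` and `c` only in `y`,
#' `D = 1 - 2a / (2a + b + c)`. Jointly absent bands never contribute, so
#' padding profiles with all-zero alleles leaves every distance unchanged.
#' The coefficient is undefined when both profiles are all-zero.
#'
#' @param x,y Logical (or 0/1) vectors of equal length, one element per
#'   allele.
#' @return Distance in `[0, 1]`.
#' @examples
#' neiLiDistance(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 1, 1))  # a=3 b=1 c=2
#' @export
neiLiDistance <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y) || !length(x))
    .stopf("profiles must have equal positive length")
  a <- sum(x & y)
  b <- sum(x & !y)
  cc <- sum(!x & y)
  if (2 * a + b + cc == 0)
    .stopf("Nei-Li distance undefined: both profiles are all-zero")
  1 - 2 * a / (2 * a + b + cc)
}

# Pairwise Nei-Li distances from a presence matrix (alleles x accessions),
# optionally averaged over groups (mean of all inter-group accession pairs).
.neiLiFromPresence <- function(P, groups = NULL) {
  M <- P + 0
  cross <- crossprod(M)            # shared band counts a
  tot <- colSums(M)                # per-profile band counts a+b / a+c
  denom <- outer(tot, tot, "+")    # 2a + b + c
  bad <- which(denom == 0 & upper.tri(denom), arr.ind = TRUE)
  if (nrow(bad))
    .stopf("Nei-Li distance undefined for all-zero pair: %s vs %s",
           colnames(P)[bad[1, 1]], colnames(P)[bad[1, 2]])
  D <- 1 - 2 * cross / denom
  diag(D) <- 0
  dimnames(D) <- list(colnames(P), colnames(P))
  if (is.null(groups)) return(D)
  labs <- unique(groups)
  if (length(labs) < 2L) .stopf("need at least two groups")
  G <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i == j) next
    G[i, j] <- mean(D[groups == labs[i], groups == labs[j], drop = FALSE])
  }
  G
}

#' Pairwise Nei-Li distance matrix of an SSRSet
#'
#' Computes all pairwise [neiLiDistance()] values over the presence matrix.
#' With `grouping = "section"`, entries are the arithmetic mean of all
#' inter-section accession-pair distances (the unweighted average-linkage
#' construction used for section-level dendrograms); the diagonal is zero.
#'
#' @param x An [SSRSet-class].
#' @param grouping `"accession"` (default) or `"section"`.
#' @return Symmetric labelled numeric matrix with zero diagonal.
#' @export
neiLiDistanceMatrix <- function(x, grouping = c("accession", "section")) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "section") taxonomyTable(x)$section else NULL
  D <- .neiLiFromPresence(presenceMatrix(x), groups)
  if (nrow(D) < 2L) .stopf("need at least two labels")
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Studier-Keppler neighbor joining, implemented from scratch: repeatedly
#' join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch lengths
#' from the standard formulas. Ties in Q are broken by the lexicographically
#' smallest (label, label) pair, so the result is deterministic. Negative
#' branch lengths are clamped to zero (their count is kept in
#' `attr(tree, "n_negative_branches")`). On an additive matrix the generating
#' tree is recovered exactly.
#'
#' @param D Symmetric numeric matrix with zero diagonal and at least 3
#'   labelled rows.
#' @return An unrooted `ape::phylo` tree (internal nodes of degree 3),
#'   stored rooted at a trichotomy as usual for unrooted trees.
#' @examples
#' D <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' tr <- neighborJoining(D)
#' ape::cophenetic.phylo(tr)["A", "B"]  # 3
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) .stopf("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(n))
  if (anyNA(D)) .stopf("distance matrix contains NA")
  if (max(abs(D - t(D))) > 1e-9) .stopf("distance matrix is not symmetric")
  tips <- rownames(D)
  act <- seq_len(n)            # tmp node ids of active clusters
  actLab <- tips               # smallest member label, for tie-breaks
  W <- D
  nextTmp <- n
  par <- integer(); chd <- integer(); len <- numeric()
  nNeg <- 0L
  clamp <- function(v) {
    if (v < 0) nNeg <<- nNeg + 1L
    max(v, 0)
  }
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(W)
    Q <- (m - 2) * W - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    o <- order(pmin(actLab[cand[, 1]], actLab[cand[, 2]]),
               pmax(actLab[cand[, 1]], actLab[cand[, 2]]))
    i <- cand[o[1], 1]; j <- cand[o[1], 2]
    dij <- W[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    nextTmp <- nextTmp + 1L
    par <- c(par, nextTmp, nextTmp)
    chd <- c(chd, act[i], act[j])
    len <- c(len, clamp(bi), clamp(bj))
    dNew <- (W[i, ] + W[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    W <- rbind(cbind(W[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    act <- c(act[keep], nextTmp)
    actLab <- c(actLab[keep], min(actLab[c(i, j)]))
  }
  # final trichotomy
  d12 <- W[1, 2]; d13 <- W[1, 3]; d23 <- W[2, 3]
  nextTmp <- nextTmp + 1L
  par <- c(par, rep(nextTmp, 3L))
  chd <- c(chd, act[1], act[2], act[3])
  len <- c(len, clamp((d12 + d13 - d23) / 2),
           clamp((d12 + d23 - d13) / 2),
           clamp((d13 + d23 - d12) / 2))
  center <- nextTmp
  # renumber: tips 1..n, internal nodes in preorder from the center = n+1
  kids <- split(seq_along(par), par)
  newId <- integer(nextTmp)
  newId[seq_len(n)] <- seq_len(n)
  counter <- n + 1L
  newId[center] <- counter
  edge <- matrix(0L, length(par), 2L)
  elen <- numeric(length(par))
  row <- 0L
  visit <- function(tmp) {
    for (e in kids[[as.character(tmp)]]) {
      child <- chd[e]
      if (child > n) {
        counter <<- counter + 1L
        newId[child] <<- counter
      }
      row <<- row + 1L
      edge[row, ] <<- c(newId[tmp], newId[child])
      elen[row] <<- len[e]
      if (child > n) visit(child)
    }
  }
  visit(center)
  tree <- list(edge = edge, edge.length = elen, tip.label = tips,
               Nnode = n - 2L)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  attr(tree, "n_negative_branches") <- nNeg
  tree
}

# tip labels below each node, indexed by ape node number
.descTips <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

.canonicalSplit <- function(side, allTips) {
  if (min(allTips) %in% side) side <- setdiff(allTips, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Every internal edge of an unrooted tree splits the leaves in two; the
#' split is canonicalized as the sorted side not containing the
#' lexicographically smallest leaf. Trivial splits (one side a single leaf)
#' are excluded, as they are present in every tree.
#'
#' @param tree An `ape::phylo` tree.
#' @return Character vector of canonical split keys, named by the ape node
#'   number of the edge's child node.
#' @export
treeBipartitions <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  desc <- .descTips(tree)
  root <- n + 1L
  nodes <- setdiff(seq(n + 1L, n + tree$Nnode), root)
  keep <- vapply(nodes, function(v) {
    k <- length(desc[[v]])
    k >= 2L && (n - k) >= 2L
  }, logical(1))
  nodes <- nodes[keep]
  out <- vapply(nodes, function(v)
    .canonicalSplit(desc[[v]], tree$tip.label), character(1))
  names(out) <- nodes
  out
}

#' Neighbor-joining tree with bootstrap bipartition support
#'
#' Builds the full-data NJ tree, then resamples characters with replacement
#' (`unit = "allele"`: individual allele rows, mirroring character
#' resampling; `unit = "marker"`: whole markers as the independent loci),
#' rebuilds distance matrix and tree per replicate, and annotates each
#' non-trivial bipartition of the full-data tree with the percentage of
#' replicate trees containing it. A replicate leaving some accession with an
#' all-zero profile is redrawn (at most 100 redraws, then an error). Fully
#' reproducible from `seed`.
#'
#' @param x An [SSRSet-class].
#' @param nReps Number of bootstrap replicates (published SSR dendrograms
#'   typically use 1000).
#' @param seed Integer seed.
#' @param grouping `"accession"` or `"section"` (section-level dendrogram).
#' @param unit Resampling unit, `"allele"` (default) or `"marker"`.
#' @return The full-data `ape::phylo` tree with `node.label` holding integer
#'   percent supports ("" at the root); `attr(tree, "supports")` is a
#'   data.frame (node, bipartition, support) and
#'   `attr(tree, "n_redraws")` counts redrawn replicates.
#' @export
bootstrapSupport <- function(x, nReps = 1000L, seed = 1L,
                             grouping = c("accession", "section"),
                             unit = c("allele", "marker")) {
  grouping <- match.arg(grouping)
  unit <- match.arg(unit)
  if (nReps < 1L) .stopf("nReps must be >= 1")
  P <- presenceMatrix(x)
  groups <- if (grouping == "section") taxonomyTable(x)$section else NULL
  tree <- neighborJoining(.neiLiFromPresence(P, groups))
  splits <- treeBipartitions(tree)
  counts <- setNames(numeric(length(splits)), splits)
  markers <- as.character(rowData(x)$marker_id)
  byMarker <- split(seq_len(nrow(P)), markers)
  set.seed(.substreamSeed(seed, 9L))
  nRedraw <- 0L
  for (rep in seq_len(nReps)) {
    repeat {
      idx <- if (unit == "allele")
        sample.int(nrow(P), nrow(P), replace = TRUE)
      else unlist(byMarker[sample.int(length(byMarker), length(byMarker),
                                      replace = TRUE)], use.names = FALSE)
      Pb <- P[idx, , drop = FALSE]
      if (all(colSums(Pb) > 0L)) break
      nRedraw <- nRedraw + 1L
      if (nRedraw > 100L)
        .stopf("more than 100 bootstrap redraws due to all-zero profiles")
    }
    bt <- neighborJoining(.neiLiFromPresence(Pb, groups))
    hit <- intersect(names(counts), treeBipartitions(bt))
    counts[hit] <- counts[hit] + 1
  }
  support <- roundHalfUp(100 * counts / nReps)
  n <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  labs[as.integer(names(splits)) - n] <-
    sprintf("%d", as.integer(support[splits]))
  tree$node.label <- labs
  attr(tree, "supports") <- data.frame(
    node = as.integer(names(splits)), bipartition = unname(splits),
    support = as.integer(unname(support[splits])))
  attr(tree, "n_redraws") <- nRedraw
  tree
}

#' Taxon-tree concordance
#'
#' Fraction of taxa (with at least two leaves in the tree) whose leaf set
#' forms one side of a split of the unrooted tree — the unrooted analogue of
#' monophyly. Measures how well a dendrogram groups accessions by species,
#' section, or genome class.
#'
#' @param tree An `ape::phylo` tree whose tip labels are accession ids.
#' @param taxonomy Taxonomy data.frame covering all tips.
#' @param level `"species"`, `"section"` or `"genome"`.
#' @return Fraction in `[0, 1]` (NaN when no taxon has >= 2 leaves).
#' @export
treeTaxonConcordance <- function(tree,
                                 taxonomy,
                                 level = c("species", "section", "genome")) {
  level <- match.arg(level)
  taxonomy <- validateTaxonomy(taxonomy)
  tips <- tree$tip.label
  missing <- setdiff(tips, taxonomy$accession_id)
  if (length(missing))
    .stopf("tree tip(s) absent from taxonomy: %s",
           paste(missing, collapse = ", "))
  taxa <- taxonomy[[level]][match(tips, taxonomy$accession_id)]
  tree <- ape::reorder.phylo(tree, "cladewise")
  desc <- .descTips(tree)
  sides <- unique(unlist(lapply(
    tree$edge[, 2], function(v) {
      s <- desc[[v]]
      c(paste(sort(s), collapse = "|"),
        paste(sort(setdiff(tips, s)), collapse = "|"))
    })))
  groups <- split(tips, taxa)
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups)) return(NaN)
  ok <- vapply(groups, function(g)
    length(g) == length(tips) ||
      paste(sort(g), collapse = "|") %in% sides, logical(1))
  mean(ok)
}
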