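---
title: "Methods: dominant SSR analysis across wild Arachis germplasm"
author: "SSRwild authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant SSR analysis across wild Arachis germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SSRwild)
```

# Scope and data model

SSRwild analyses *dominant* SSR genotypes: each allele is a
(marker, fragment-size) pair scored 1 when a sharp band of that size was
observed in an accession and 0 otherwise. This coding has two consequences
that shape everything downstream. First, there is **no missing-data
state** — an unscored band is an absent band; heterozygote dosage is
invisible. Second, allele identity is purely electrophoretic: two bands of
equal size at the same marker are the same allele whether or not they are
identical by descent (size homoplasy is a known limitation of the marker
system, not of the implementation).

The container is `SSRSet`, a `SummarizedExperiment` whose rows are alleles,
columns are accessions, and single logical assay `presence` is the 0/1
matrix. Accession taxonomy (species, section, genome class A/B/AB/D,
chromosome number) lives in `colData`; the marker panel (genomic-library vs
genic origin, permitted size window) in `metadata`. Validity enforces the
closed seven-section vocabulary, genome/ploidy consistency (AB implies
2n = 40), uniqueness of (marker, size) rows, and that every allele has at
least one carrier. The marker-level *amplification* matrix is always
derived as the allele-wise OR of presence, never stored, so the two can
never drift apart.

Band sizes are assumed pre-called against a ladder; an optional binning
tolerance (default 0 bp) in `readGenotypeLong()` merges sizes within the
tolerance, labelling the bin with its smallest size.

# Transferability

A marker is *transferable to a section* when it amplifies in at least one
scored accession of that section; the *accession-level rate* is the mean,
over markers, of the fraction of scorable accessions amplifying. Both are
needed: the section-level reading saturates quickly (one success per
section suffices), which is exactly how published per-section tables reach
100% for the source section while the accession-level rate sits near 80%.

The **source-species exclusion rule**: genomic-library markers were
developed from the cultivated species, so its accessions are excluded from
their scoring; genic markers, developed from related genera, count
everyone. The rule is applied per marker class in every transferability
operation, and a property test asserts that adding cultivated accessions
can never change a genomic-class row.

Percentages are rounded **half-up** (`roundHalfUp()`), matching the
convention of printed marker tables; per-class mean rows average the seven
per-section integer percentages (and counts) and round half-up again, which
is how the bundled survey count table reproduces its printed class means of
76% and 88%.

The class comparison is a pooled two-proportion z-test on the class mean
transferable counts over the class panel sizes, signed so that higher genic
transferability is positive. The basis of such z-tests is often left
unstated in the literature and printed values are not always recoverable
from the printed tables; ours is documented, deterministic, and checked
against a hand computation (62/82 vs 17/19 gives z = 1.32).

# Specific alleles, duplicated loci, donor classes

An allele is *taxon-specific* at a level (species, section) when all of its
carriers belong to one taxon at that level; a single carrier counts.
Species-specificity implies section-specificity for the containing section,
and the report's per-taxon counts always sum to its total — both are
asserted as invariants. When comparing detections against simulated truth,
tetraploid accessions must be removed first (`subsetAccessions()`): they
carry their donors' alleles, and a donor's private allele shared with its
tetraploid descendant is still private in the biological sense but no
longer confined to one species in the matrix.

A *duplicated locus* is reported when some tetraploid accession carries, at
one marker, at least one allele from each designated donor's set plus at
least one allele absent from every diploid — the classic pattern of an
A-fragment, a B-fragment and a tetraploid-only fragment. *Polyploid-origin*
markers amplify in tetraploids only. Donor amplification classes
(`both_donors` / `A_only` / `B_only` / `neither`) follow from which
candidate amplifies and whose alleles reappear in the tetraploids.

# Distances, trees, bootstrap

The genetic distance is the Dice-complement reading of the Nei–Li
coefficient for restriction/dominant data: `D = 1 − 2a/(2a + b + c)`.
Jointly absent alleles never contribute, so the distance is invariant under
padding with all-zero rows (tested by property). The −ln(F) variant of the
coefficient is deliberately out of scope; the choice is isolated inside
`neiLiDistance()` so substituting it is a one-function change. The
coefficient is undefined for two all-zero profiles — an error, not an NA,
because an accession without a single scored band carries no information.

`neighborJoining()` is a from-scratch Studier–Keppler implementation.
Numerical choices:

* ties in the Q criterion are broken by the lexicographically smallest
  pair of cluster labels (a cluster inherits its smallest member label), so
  results are independent of everything except the label set;
* negative branch lengths are clamped to zero (dominant-marker distance
  matrices are noisy; dendrograms with negative edges are not
  interpretable); the raw count is kept in
  `attr(tree, "n_negative_branches")`;
* the unrooted tree is stored rooted at the final trichotomy, ape-style.

On additive matrices the implementation recovers the generating topology
and all path distances to machine precision (asserted over 50 random 6–10
leaf trees, against `ape::nj` as an independent oracle and against
brute-force least-squares resolution of sampled quartets).

Bootstrap support resamples **characters** — individual allele columns —
with replacement, the convention of classic tree software for 0/1 matrices;
`unit = "marker"` resamples whole markers instead, defensible because
markers are the independent loci. Both are exposed; allele resampling is
the default. A replicate that leaves an accession with an all-zero profile
is redrawn (at most 100 times), because the distance would be undefined.
Support is the percentage of replicate trees containing each non-trivial
bipartition of the full-data tree, written as integer internal-node labels
in Newick output.

Section-level dendrograms use the mean of all inter-section accession-pair
distances (unweighted average linkage) — published section trees rarely
state their construction, and the parameter-free mean is the conservative
choice. The same reasoning fixes `groupDistance()` (donor inference) as the
mean of pairwise distances to the group members rather than the distance to
a consensus profile.

# The synthetic generator and what passing tests mean

`simulateDataset()` emulates the structure a genus-wide survey assumes:

* **Amplification**: a marker amplifies in a diploid accession with
  probability `base × exp(−penalty × rank)`, where `base` is the class
  transfer probability (defaults 0.76 genomic / 0.88 genic — the class
  means of the emulated survey) and `rank` is the section's divergence
  order from the source section. The default penalty 0.08 reproduces the
  observed gradient: at rank 6 the genomic rate falls to about 0.47, close
  to the lowest published per-section rates.
* **Allele sharing** is hierarchical: every amplified accession carries the
  marker's two genus-wide alleles and its section's pool; A- and B-genome
  accessions of the source section additionally carry their genome-class
  pool. Shared pools are what make conspecific and consectional accessions
  cluster.
* **Private alleles**: with probability 0.05 per (diploid species, marker),
  a globally unique allele carried by all amplified conspecifics, recorded
  in the ground-truth ledger.
* **Tetraploids** carry the union of the two designated donors' allele
  sets, each allele retained with probability 0.95 per accession, plus —
  for 10% of genomic markers amplified by both donors — a duplicated-locus
  fragment present in every tetraploid and no diploid.
* **Determinism**: all draws come from per-marker substreams derived from
  one seed by counter, so extending the panel never perturbs earlier
  markers.

Two emission rules keep the ledger exact. A shared pool whose structural
scope covers a single species (a one-species section; the lone D-genome
species' class pool) is not emitted, and a shared allele that amplification
chance leaves confined to one diploid species is discarded. Together they
guarantee that the species-confined alleles among diploids are *exactly*
the planted private alleles — which is why the recovery experiments can
demand precision = recall = 1 rather than a fuzzy threshold.

Default sizes — 7 sections, 4–6 species per section (the source section
always carries its six mandatory species: the AB tetraploid, two A, two B
and one D diploid), 2–3 accessions per species, 4 tetraploid accessions —
yield about 33 species and 80 accessions, matching the scale of a real
genus survey (96 accessions, 36 species).

The **strong-structure condition** used for bootstrap recovery deserves a
note. Section cohesion in this generator comes from jointly amplified
section-pool alleles; a *large* divergence penalty therefore weakens
distant sections (their accessions share too few amplified markers) rather
than sharpening them. Real surveys sit in a mild-decay regime — even the
most divergent section keeps ~50% transferability — so the strong-structure
condition is defined as the default penalty (0.08) with an elevated
private-allele rate (0.3) and richer per-marker allele counts (10–29), two
species of two accessions per section. Under it, every true section
bipartition reaches 100% support at 200 replicates.

What passing tests do **not** show about real data: the generator has no
size homoplasy across sections (every shared allele is identical by
descent), no systematic whole-section amplification failures (nulls are
binomial, so `singleSectionNullMarkers()` is exercised on constructed
fixtures instead), no intraspecific allele variation beyond amplification
noise, and inter-section distances are roughly exchangeable rather than
graded — the generator validates the machinery, not the biology.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `base_transfer_prob` | 0.76 / 0.88 | probability | class mean transfer rates of the emulated survey |
| `section_divergence_penalty` | 0.08 | per divergence rank | reproduces the ~100%→50% per-section gradient |
| `p_private_allele` | 0.05 | per species × marker | yields ~100–150 private alleles per dataset, the scale of a real census |
| `donor_retention` | 0.95 | probability | allotetraploids retain most but not all parental fragments |
| `p_tetraploid_locus` | 0.1 | per genomic marker | ~10 of 82 genomic markers with duplicated loci, as observed |
| `alleles_per_marker` | 4–29 | count | span of published per-marker allele counts |
| `bootstrap_reps` | 1000 | replicates | convention of published SSR dendrograms |
| `min_support_display` | 80 | percent | conventional reporting cut-off |

# Problem sizes used by the test and acceptance suites

Recovery experiments run at the default study conditions: donor recovery
over 100 simulated datasets (and 3 retention settings × 50 paired seeds for
monotonicity), private-allele recovery over 20 datasets, amplification
calibration pooled over 50 datasets, NJ validation over 50 random additive
matrices, and bootstrap recovery at 200 replicates on the strong-structure
condition; the acceptance script uses the same conditions with 50/10/25
dataset batches. These sizes give Monte-Carlo error well inside the asserted
thresholds while keeping a full run in a few minutes.

# Known limitations

* Dominant 0/1 coding cannot separate allele dosage or heterozygosity; all
  statistics inherit this.
* Size homoplasy: equal-size bands are treated as identical alleles.
* The Nei–Li −ln(F) transform, distance-to-consensus donor aggregation and
  geographic plausibility weighting of donor candidates are documented
  extension points, not implemented.
* Section-level distances and trees depend on the average-linkage
  construction chosen here; other linkages would move weakly supported
  edges.
* The generator's sections are exchangeable in expectation apart from the
  amplification gradient; it cannot be used to test methods that rely on
  graded inter-section divergence.
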