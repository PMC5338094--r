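---
title: "Models and methods behind segdupr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind segdupr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segdupr)
```

segdupr bundles the four quantitative analyses that recur in studies of
segmentally duplicated gene families — the primate *SPATA31* core-duplicon
family being the motivating case: droplet-digital-PCR (ddPCR) copy-number
quantification, read-depth copy-number estimation over collapsed paralogous
loci, distance-based phylogenetics with a concerted-evolution statistic, and
CRISPR amplicon frameshift counting. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
several reasonable choices existed. Every empirical claim below is one the
package's own test suite or acceptance script computes.

## 1. ddPCR copy-number quantification

A ddPCR reaction partitions template molecules into roughly 20,000 droplets.
Under Poisson loading, a droplet is negative when it received zero template
molecules, so with mean occupancy $\lambda$ (molecules/droplet) the positive
fraction is $p = 1 - e^{-\lambda}$ and the observed fraction $\hat p$
inverts to

$$\hat\lambda = -\ln(1 - \hat p).$$

The copy number per diploid genome is the concentration ratio of the target
channel to a reference channel scaled by the reference's known copy number
(2 for a single-copy autosomal gene such as *EIF2C1*):

$$\widehat{\mathrm{cn}} = c_\mathrm{ref} \cdot
\hat\lambda_\mathrm{target} / \hat\lambda_\mathrm{reference}.$$

Droplet volume cancels in the ratio, so it is not a parameter; an absolute
concentration would need it, but the analyses here never do.

Design choices:

* **Confidence intervals.** A 95% Wilson score interval on $\hat p$,
  transformed through $-\ln(1-\cdot)$. Wilson rather than Wald because
  wells near $\hat p = 0$ are routine for low-concentration channels; the
  copy-number interval is the conservative ratio of channel bounds.
* **Saturation.** $\hat p = 1$ leaves $\hat\lambda$ undefined; the function
  raises an error rather than returning `Inf`, since a saturated well needs
  re-dilution, not a number.
* **Population summaries** use the sample ($n-1$) standard deviation — the
  natural choice for panels of dozens of individuals per population; the
  convention is stated because summaries of this kind are often printed
  without it.
* **Binning** for histograms uses half-open bins $[c - w/2, c + w/2)$
  centered on multiples of the width, default $w = 0.5$ copies. The width is
  configurable since display conventions vary.

The simulator (`simulate_droplets()`) draws positives as
$\mathrm{Binomial}(n_\mathrm{droplets}, 1 - e^{-\lambda})$ per channel with
$\lambda_\mathrm{target} = \lambda_\mathrm{ref} \cdot \mathrm{cn}/c_\mathrm{ref}$.
Default reference occupancy is $\lambda_\mathrm{ref} = 0.2$, a typical
working concentration well below saturation even at 11 target copies. The
acceptance script simulates a 322-individual panel across four populations
with per-population copy-number means of 7.24, 7.61, 7.62 and 7.62 and
standard deviations 1.24, 0.98, 0.71 and 0.85 — the study conditions for
human *SPATA31A* variation (322 is the genotyped-panel size behind the
published distribution; a larger figure appears elsewhere for the assayed
panel, and we use the number the distribution was computed from). With
$10^6$ droplets per channel the estimator's mean relative bias is below 1%
for true copy numbers 1–11 (acceptance suite).

## 2. Read-depth copy number over collapsed loci

When a gene family has more copies in a genome than in the reference
assembly, reads from the extra copies still map to the represented
paralog-homologous loci. Depth there is proportional to the *total* number
of copies in the sequenced genome. The estimator is

$$\widehat{\mathrm{cn}} = \rho \cdot
\frac{\sum_{r \in \mathrm{regions}} \overline{\mathrm{depth}}(r)}
     {\mathrm{depth}_\mathrm{background}},$$

with ploidy scaling $\rho = 2$ by default (overridable for haploid or
ancient-genome callsets), so a single-copy locus at background depth scores
exactly 2.

Design choices:

* **"Overall read depth"** is the mean over background regions — by default
  everything outside the paralog loci; a median option exists for genomes
  with skewed depth. The mean is the primary statistic because the estimator
  is a ratio of means.
* **Coordinates** are 0-based half-open everywhere inside the package;
  1-based conventions appear only at the `samtools depth` TSV boundary
  (positions) — a single convention prevents off-by-one errors in region
  sums. Positions missing from a depth TSV are depth 0, matching the tool's
  default of omitting zero-depth sites.
* **No GC or mappability correction** is applied: the estimator mirrors the
  simple normalize-and-sum pipeline it implements, and this is a stated
  limitation for real data (see §6).

The simulator draws depth at base $i$ as
$\mathrm{Poisson}(\mathrm{coverage} \cdot m_i / 2)$ with $m_i$ the haploid
copy multiplicity (2 in background). A 10 kb collapsed locus at coverage 30
is the test condition; mean absolute error stays below 0.3 copies for
multiplicities 2–14 (acceptance suite). The idealization that *all* family
reads stack on the represented locus (no mapping ambiguity or loss) is ours,
not a property of any particular mapper.

## 3. K2P distances, NJ trees, bootstrap, concerted evolution

Pairwise distances use the Kimura 2-parameter model: with transition
fraction $P$ and transversion fraction $Q$ over comparable sites,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

*Pairwise deletion* excludes, per pair, any site where either sequence has a
gap **or** any non-ACGT ambiguity code. The ambiguity rule is stricter than
the minimum the name implies; treating partial information as missing keeps
$P$ and $Q$ exact counts. If an argument of a logarithm is non-positive the
pair is reported as saturated and the matrix construction fails loudly,
listing the offending pairs. Protein alignments are accepted with a
p-distance fallback (`model = "p"`), since K2P is a nucleotide model;
whether a published protein tree used amino-acid or nucleotide distances is
often underdetermined, so both routes are provided and neither is asserted
as canonical.

Trees come from standard neighbor joining on the Q-criterion. Two
robustness rules make results platform-deterministic:

* ties in the Q-criterion are broken by the lexicographically smallest pair
  of cluster labels (each cluster represented by its smallest tip label);
* a negative branch-length estimate is clamped to zero and its length
  transferred to the sibling branch, preserving path lengths through the
  join.

On additive matrices NJ is exact: the acceptance suite verifies topology
recovery and path-length reproduction to $10^{-9}$ on 200 random additive
matrices up to 12 leaves, and for small cases checks the topology against an
exhaustive enumeration of all unrooted topologies (via non-negative
least-squares branch fitting). An all-zero matrix returns an unresolved star
rather than an arbitrary binary resolution.

Bootstrap supports resample alignment columns with replacement, rebuild the
NJ tree, and score each internal branch of the original tree by the
percentage of replicates containing the same bipartition (500 replicates is
the customary figure default). Replicates whose resampled matrix saturates
are skipped, warned about, and excluded from the denominator. Supports are
reproducible bit-for-bit under a fixed seed.

Concerted evolution — the homogenization of paralogs within a lineage,
typically by interlocus gene conversion — predicts that duplicated copies
are more similar within a species than between species. The package
formalizes this as

$$W/B, \qquad W = \text{mean within-species pairwise distance}, \quad
B = \text{mean between-species distance},$$

with $W/B < 1$ indicating within-species clustering, plus a per-species
monophyly flag read off the NJ tree's bipartitions. The gene-family
simulator evolves an ancestor through a duplication (default 3 time units
before present) and a later speciation (1 unit), under a two-rate
substitution process matching K2P assumptions (default rate 0.01
substitutions/site/unit, $\kappa = 2$), then applies
Poisson-distributed gene-conversion events per terminal lineage, each
overwriting a uniformly placed tract (default 20% of the alignment) with the
homologous tract of a random within-species paralog — the simplest mechanism
that produces the homogenization signature. With conversion off, $W/B > 1$
(orthologous clustering, since the duplication predates the speciation); at
5 expected events per lineage, $W/B < 1$. Both hold in at least 90% of 50
seeds (acceptance suite; in the runs shipped here, 100%).

## 4. CRISPR amplicon frameshift counting

Editing outcomes are read from amplicon sequencing as follows: each read is
globally aligned to the reference (Needleman–Wunsch with affine gaps,
Gotoh recursion; match +1, mismatch −1, a gap of length $L$ costs
$4 + L$; `N` never matches), the net indel length (insertions minus
deletions) is summed within a window of ±20 bp around the cut site, and the
read is classified by the reading-frame consequence: unedited (0), in-frame
(multiple of 3) or frameshift (otherwise). Judging the **net** length means
two indels that cancel are in-frame — the reading frame downstream is what
matters biologically. Traceback ties prefer match/mismatch over deletion
over insertion, making alignments deterministic.

Clone summaries count the classes and call a clone `high` when the
frameshift fraction reaches a threshold (default 0.5). The threshold is a
required, logged parameter because no universal cutoff exists for sorting
low- versus high-frameshift clones; it should be chosen per experiment.

Spacer-site scanning reports every position on both strands where a
19-nt window (the length of the guide this family of experiments used;
20 by flag) is followed by an NGG PAM. It is a plain exhaustive scan — no
off-target scoring is attempted.

The amplicon simulator writes one indel per edited read at the cut site with
a configurable signed-length spectrum, no sequencing errors by default (an
optional substitution-error rate exists), which isolates the counting logic:
at zero error the caller recovers the simulated class counts *exactly*
(acceptance suite).

## 5. Numerical and interface conventions

* All tabular inputs and outputs are tibbles; results chain with the pipe.
  Fitted objects (`depth_cn`, `concerted_stat`) have `tidy()`/`glance()`
  methods; histograms have `autoplot()`.
* Trees are `ape::phylo` objects; Newick I/O goes through ape, so branch
  lengths and integer node-label supports round-trip.
* Every simulator takes an integer `seed` and is bit-reproducible given one.
* Protein masses use average (not monoisotopic) residue masses plus one
  water, the convention matching gel-based and predicted molecular weights;
  unknown residues (including lowercase and selenocysteine) are an error
  naming the character and position, because a silently wrong mass is worse
  than no mass. For comparison with published figures, kD is Da/1000
  rounded to the nearest integer.
* Problem sizes in the shipped tests and acceptance script — $10^6$ droplets
  per channel, 10 kb loci at coverage 30, 1000-site alignments of 8–20
  sequences, 500 bootstrap replicates, 200-read clones on 120-bp
  amplicons — were chosen as the smallest sizes at which the statistical
  claims above are comfortably resolvable.

## 6. What the synthetic data does and does not show

The simulators reproduce the *statistical structure* each estimator assumes:
Poisson droplet loading, Poisson depth over a collapsed locus, K2P
substitution with tract-copy conversion, single-indel edits. Passing tests
therefore demonstrate correctness of the estimators under their own models.
Real data violate these models in known ways the package does not correct
for: ddPCR droplet volume variation and rain (partially positive droplets),
GC- and mappability-dependent depth bias, rate variation across sites and
lineages, selection on paralogs, multi-indel and substitution edits, PCR and
sequencing error. Results on real data should be read with those caveats;
the depth estimator in particular is comparative (between genomes processed
alike) rather than absolute.

Two source-data notes recorded as decisions: the RefSeq accession for the
C-type transcript is written in some sources without an underscore; the
resolvable identifier is `NM_001145124`. And where two panel sizes are in
circulation (366 assayed, 322 genotyped), the synthetic panel uses 322, the
basis of the published distribution.
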