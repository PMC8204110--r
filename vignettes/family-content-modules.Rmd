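---
title: "Detecting modules of co-occurring protein families in archaeal genome collections"
author: "fammod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting modules of co-occurring protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fammod)
```

## The analysis

Reduced-genome archaea such as the DPANN radiation are hard to place by
sequence phylogeny alone, but their *gene content* carries a strong signal:
blocks of protein families that are consistently present together in the
genomes of one lineage and absent elsewhere. `fammod` implements the
comparative protein-family-content analysis behind that observation as a
reusable, fully tested pipeline:

1. **Genome QC and dereplication** — completeness and contamination from a
   set of 38 single-copy marker genes, a draft-quality rule, percent-level
   filters, a ribosomal-protein alignment-coverage and single-scaffold
   check, and species-level dereplication at 95% average nucleotide
   identity (ANI) with representative selection.
2. **Presence/absence matrix** — homology hit tables (e.g. `hmmsearch`
   tabular output) are thresholded at E-value 0.001 and collapsed to a
   binary family x genome matrix.
3. **Module detection** — families are clustered by the Jaccard distance
   between their presence profiles (complete linkage); cutting the
   dendrogram at 0.95 yields flat clusters, and clusters with at least 20
   families become *modules*. Each module is assigned a taxonomic
   distribution by the median-genome rule and classified by its occurrence
   and enrichment in DPANN versus other archaea.
4. **Breadth** — a cross-domain screen: for each archaeal family, the
   percentage of bacterial phyla in which at least one third of
   representative genomes have an above-threshold hit. High-breadth small
   families are candidates for inter-domain lateral transfer.

A synthetic-data generator plants all of this structure with known ground
truth, so every stage is verifiable without downloading a single genome.

## Models and rules

### Quality control

Let $c_g \in \{0,1,2,\dots\}^{38}$ be the copy numbers of the 38 marker
genes in genome $g$. Then

* completeness $= 100 \cdot |\{i : c_{gi} \ge 1\}| / 38$,
* contamination $= 100 \cdot (\sum_i c_{gi} - |\{i : c_{gi} \ge 1\}|)/38$.

The published marker set has no published contamination formula; the extra-copy
proxy above is monotone in duplication and directly testable, which is why
the package adopts it. The draft-quality rule requires *more than* 22
markers present and *fewer than* 4 duplicated (both strict); the
results-level rule removes genomes with completeness < 70%, contamination
> 10%, fewer than 50% non-gap columns in the concatenated
14-ribosomal-protein alignment, or ribosomal proteins split across
scaffolds. Both rule families are applied; they are independent per-genome
predicates, so the surviving set does not depend on evaluation order (a
property the test suite asserts).

Dereplication treats the 95% ANI threshold *inclusively* and forms
single-linkage connected components — the contract is the threshold and the
representative rule ("most complete, then least contaminated, then
smallest id"), not any particular two-stage implementation. Single linkage
means a chain a–b–c at 96% merges all three even if ANI(a,c) is 80%.

### Jaccard distance and the dendrogram cut

For two families with presence sets $P(x), P(y)$ over genomes,

$$d(x,y) = 1 - \frac{|P(x) \cap P(y)|}{|P(x) \cup P(y)|}.$$

Two all-absent profiles are identical, so $d = 0$ by convention; such rows
are uninformative and excluded from clustering by default. The distance is
a true metric (symmetry, zero diagonal and the triangle inequality are
property-tested on random profiles and cross-checked against
`vegan::vegdist(binary = TRUE)`).

The family dendrogram is cut at cophenetic distance 0.95. The linkage for
the family side is not uniquely determined by the published description;
complete linkage is adopted to match the genome-side clustering that *is*
named, with average linkage available via `linkage = "average"`. Because
Jaccard distances are bounded by 1, the 0.95 cutoff is read on the Jaccard
cophenetic scale. The cut is inclusive: clusters merged at exactly 0.95
stay together. Labels are sorted lexicographically (byte order, locale
independent) before clustering, so results are invariant to input row
order.

### The median-genome taxonomy rule

For a module $M$ with families $f_1,\dots,f_k$, let $n_i$ be the number of
genomes carrying $f_i$. Then $m = \mathrm{median}(n_i)$, rounded *half-up*
to an integer when the median is fractional (retaining at least the
median-typical genome count). Genomes are ranked by how many of the
module's families they carry, ties broken by lexicographic genome id, and
the top $m$ are retained; their phylum tally is the module's taxonomic
assignment. A single lineage is assigned when all retained genomes share
one phylum — strict unanimity is the default, with
`singleLineageFraction` available because a survey may reasonably tolerate
a minority of off-lineage genomes; the table always reports the
`dominant_lineage` too. Under flip noise the median count $m$ typically
exceeds the number of true carriers (noise adds spurious carriers), so a
few off-lineage genomes in the retained set are expected and strict
unanimity rarely holds on noisy data — the dominant lineage is the robust
readout there.

### Occurrence and enrichment

A module *occurs* in the DPANN if at least one DPANN genome carries at
least one of its families (no minimum-carriage threshold is published; one
family is the weakest, most inclusive reading). Its DPANN prevalence is
the mean over families of the fraction of DPANN genomes carrying the
family; the non-DPANN prevalence is the analogue over the remaining
archaeal genomes; *enriched* means the former exceeds the latter. With
zero genomes in either group the prevalences are undefined and flagged
(`prevalence_defined = FALSE`). No significance testing is attached — the
comparison is descriptive, as in the survey this reproduces.

### Breadth

For family $f$ and bacterial phylum $p$ with $G_p$ representative genomes,
the incidence is $100 \cdot |\{g \in G_p: \text{hit at } E \le
0.001\}|/|G_p|$. For families with at least one bacterial hit, breadth is
the percentage of phyla whose incidence is at least one third —
*inclusive*, so 2 hits among 6 genomes count (the boundary is asserted at
exactly 2/6). The denominator is all phyla in the supplied metadata,
including phyla with no hits for that family; `minPhylumGenomes` can
exclude poorly sampled phyla but defaults to no exclusion. The supplied
bacterial metadata *is* the representative set: no internal re-selection
is performed.

## The synthetic-data generator

`simulateDataset()` emulates the statistical structure of a genome
collection, not its sequences:

* **Lineage-labelled genomes** — by default 6 lineages (4 DPANN, 2 other
  archaea) of 50 genomes each.
* **Planted modules** — each module's families share one carrier-genome
  set before noise. When several modules list the same carrier lineage,
  the generator allocates successive non-overlapping genome blocks of that
  lineage. This is deliberate: two modules whose carrier sets overlap
  heavily have cross-module Jaccard distances far below 0.95 and merge
  under any linkage — they are mathematically one block, not two. A
  ground-truth generator must plant structure that is distinguishable in
  principle.
* **Background families** — independent Bernoulli presence, default
  probability 0.1 per cell (sparse families dominate real collections; a
  range can be given to draw per-family prevalences).
* **Noise** — every cell is toggled independently with probability
  `flipNoise` (default 0.05), the simplest exchangeable corruption that
  degrades Jaccard distances smoothly.
* **Hit records** — present cells get E-values log-uniform in
  $[10^{-30}, 10^{-4}]$; a small fraction of absent cells (default 1%)
  emit decoys in $(0.001, 10]$ so threshold filtering is actually
  exercised.
* **Bacterial panel** — 8 phyla x 6 genomes; a configurable fraction of
  families (default 10%) is flagged bacterial-like and hit with
  probability 0.6 per bacterial genome versus 0.02 otherwise, giving the
  breadth screen a planted signal to find.
* **QC inputs** — 38-marker copy-number tables, pairwise ANI, an aligned
  FASTA and a scaffold table, with a configurable number of genomes
  planted to fail each rule (completeness, duplication, alignment
  coverage, scaffold split, ANI redundancy).

One pseudo-random stream per artifact, all derived from the single seed,
so adding an output never perturbs another; identical configurations are
byte-identical.

What the generator does **not** emulate: phylogenetic autocorrelation
within lineages, gene-order, family-size heterogeneity beyond a uniform
prevalence range, correlated (batch-like) noise, and contamination that
mimics biology rather than random flips. Passing the planted-recovery
tests therefore shows the pipeline implements its rules correctly and is
robust to exchangeable noise — it does not by itself validate biological
conclusions drawn from real collections.

## Numerical choices and degenerate inputs

* All threshold comparisons follow the published wording exactly: strict
  for ">22", "<4", "<70%", ">10%", "<50%"; inclusive for ANI $\ge$ 95,
  E-value $\le$ 0.001, coverage $\ge$ 0.5 and "at least one third".
  The breadth boundary uses a $10^{-9}$ epsilon on the percent scale so
  the floating-point representations of $100 \cdot 2/6$ and
  $100 \cdot 1/3$ compare as intended; incidences are quantized far more
  coarsely than the epsilon, so it can never admit a genuinely failing
  phylum.
* Ties are broken lexicographically everywhere (genome ranking, cluster
  numbering, representative choice), making every output independent of
  input row order; sorting uses byte order, not the locale.
* Empty-vs-empty profiles have distance 0 and are excluded from family
  clustering by default; all-absent genomes are kept as columns so the
  genome-side dendrogram reflects them.
* A single family forms a trivial cluster without building a dendrogram;
  genome clustering requires at least two genomes and errors otherwise.
* Modules whose median count $m$ is 0 (possible only for all-absent
  families, which the default path excludes) get an empty retained set and
  no assignment rather than an error.
* Outputs are written atomically (`.partial` then rename); the run
  manifest contains checksums and counts but no timestamps or absolute
  paths, so reruns on identical inputs are byte-identical.

## Problem sizes used by the test suite

The planted-recovery benchmark uses 300 genomes across 6 lineages, 1,500
background families and 12 planted modules of 20–60 families at 5% flip
noise — large enough that recovery is a meaningful statistic (the
expected family-set overlap is well above the 0.8 yardstick) and small
enough to run in seconds. The exactness fixture uses three 25-family
modules on distinct DPANN lineages with occupancy 1, no noise and no
background families: exactness is a contract about the planted blocks
themselves, and a random background family can legitimately sit within
Jaccard 0.95 of a block and be absorbed by complete linkage, which is a
property of the permissive cutoff, not a bug. Rule-equivalence checks run
the verbatim-rule oracles on hundreds of randomized instances of up to 30
genomes and 50 families.

## Worked example

```{r example, eval = FALSE}
cfg <- SimConfig(seed = 1)
sim <- simulateDataset(cfg)
pm  <- buildPresenceMatrix(sim$hits, sim$genomes)
ms  <- detectModules(pm)
summarizeModules(ms)
head(moduleTable(ms)[, c("module_id", "size", "m", "dominant_lineage",
                         "dpann_prevalence", "enriched")])
inc <- perPhylumIncidence(sim$bacterialHits, sim$bacterialMeta,
                          families = familyIDs(pm))
head(computeBreadth(inc))
```

## Known limitations

* Contamination is an extra-copy proxy, not a lineage-aware estimate;
  percentages are not comparable to CheckM's.
* Enrichment is a descriptive mean-prevalence comparison without a test
  statistic.
* The 0.95 cutoff is permissive by construction; near the cutoff,
  weakly-overlapping profiles can join a module. Module boundaries on
  real data should be read as blocks, not as sharp sets.
* Dereplication requires a precomputed ANI table; the package does not
  compute ANI from sequence.
* The breadth screen nominates candidates; confirming lateral transfer
  requires phylogenetics outside this package's scope.
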