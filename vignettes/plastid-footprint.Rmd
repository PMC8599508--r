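---
title: "Detecting a plastid footprint: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a plastid footprint: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egtscan)
```

## The model

A nuclear genome descended from a plastid-bearing ancestor carries genes of
cyanobacterial origin even after organelle loss. In a single-gene phylogeny
such a gene appears as a clade of plastid-bearing eukaryotes — including
the focal species — branching **sister to cyanobacteria**. Any species,
plastid-bearing or not, also shows clades sister to other bacteria
(ordinary horizontal transfer, contamination, or phylogenetic error). The
decision statistic is therefore a ratio of tree counts, EGT:HGT, computed
with one and the same sorting procedure; only the donor group differs.
Below 1, the cyanobacterial signal is within the bacterial background;
above 1, it is evidence of plastid ancestry. The procedure is a *screen*,
not a proof: individual sorted trees can still reflect contamination or
poor resolution, which is exactly why the ratio, and the comparison against
known plastid-lacking controls, carry the interpretation.

### Sisterhood without rooting

Published gene trees from maximum-likelihood programs are unrooted, and the
sorting rules never specify a root. `sister_pairs()` therefore enumerates,
at every internal node of degree $d$, all $\binom{d}{2}$ unordered pairs of
the adjacent subtrees. For binary trees this yields exactly $3(L-2)$ pairs,
and the set equals the union of rooted sister pairs over all possible
rootings of the tree — the test suite asserts this equivalence against an
exhaustive-rerooting oracle on hand-built and random trees. Working with
the full rooting-free superset is deterministic and cannot miss a
configuration that any particular rooting would have shown.

### Classification rules and their parameters

All parameters live in `scan_config()`:

| parameter | default | meaning |
|---|---|---|
| `contamination_max` | 0.10 (inclusive) | max fraction of sequences from groups with no plastid ancestry on the eukaryote side |
| `min_cyano` | 2 | minimum size of the pure cyanobacterial donor clade |
| `min_bacteria` | 2 | minimum size of the pure bacterial donor clade (HGT) |
| `min_other_plastid` | 1 | non-focal plastid-bearing sequences required on an EGT eukaryote side |
| `min_focal_assemblies` | 2 | distinct single-cell assemblies that must group monophyletically (multi-assembly focal species only) |
| `higher_group` | unset | label whose members may sit with the focal clade in the HGT rule without counting as contamination |

Decisions the source procedure left open, resolved here and frozen:

* **"Up to 10%" is inclusive** (`<=`), exposed as
  `contamination_inclusive`. The acceptance suite asserts the boundary both
  ways: a side at exactly 10% passes, one more contaminant fails.
* **Contamination denominator** is every sequence on the eukaryote side;
  focal sequences are exempt from the numerator. Without that exemption a
  plastid-lacking focal species could never pass its own screen. Whether
  contamination should be counted per sequence or per species was not
  specified; per sequence is used.
* **Donor purity**: "a clade of cyanobacteria" is read as *exclusively*
  cyanobacterial (and the HGT donor as exclusively non-cyanobacterial
  bacteria). A mixed donor is rejected with reason `cyano_impure` /
  `donor_impure`. Override with `donor_pure = FALSE`.
* **HGT donor minimum is 2**, for symmetry with the EGT rule; the source
  procedure says only "a bacterial clade".
* **Counting unit is the tree**: a tree with two disjoint qualifying
  configurations contributes one event (the detail report lists both).
* **`min_other_plastid` = 1**: "grouped with other plastid-bearing
  lineages" is read as at least one non-focal plastid-bearing sequence.
* **No support-value filter** is applied in sorting; whether the original
  screen used one is not stated, so none is invented. Branch lengths and
  support labels are parsed and preserved but never interpreted.
* Every rejection carries a machine-readable reason
  (`reject_reason()`), although the original procedure reported only
  totals — auditability is worth the small API surface.

The taxon annotation table has no separate species column; the focal
"species" is the set of records flagged `focal`, and multi-assembly status
is auto-detected from distinct `assembly_id` values (overridable).
`unknown`-group sequences count as contamination — conservative, since
groups of unknown ancestry cannot support a plastid claim.

## What the simulator states, and what it does not

`simulate_dataset()` emulates the statistical structure the scanner
consumes: collections of unrooted gene trees over taxa annotated with
plastid-ancestry groups, with planted sister-to-cyanobacteria and
sister-to-bacteria events, configurable contamination on the planted
eukaryote sides, and several focal single-cell assemblies. Defaults (one
focal species over 4 assemblies; 8 cyanobacteria, 8 other bacteria, 10
photosynthetic and 4 non-photosynthetic plastid-bearing, 8 plastid-lacking
taxa; 100 genes; 20% EGT, 20% HGT; trees of 12–24 leaves; donor clades of
2; contamination 0) are a desk-scale mirror of a genome-wide screen —
hundreds of clusters over hundreds of taxa — chosen once and kept.

Design choices worth knowing:

* **Certified background trees.** A pure-prokaryote clade of size ≥ 2 must
  contain a prokaryote–prokaryote cherry; the background builder never
  attaches a prokaryote leaf onto the pendant edge of another prokaryote
  (or focal) leaf and starts from a three-leaf star with at most one
  prokaryote, so no such cherry can ever form. Background trees are
  therefore event-free *by construction* for any configuration with donor
  minima ≥ 2, and false-positive assertions in the tests are exact counts,
  not statistics.
* **Branch lengths are decorative** (exponential draws, recorded and
  ignored): the detector is purely topological, and the simulator is
  honest about that. No sequence evolution along trees is simulated.
* **Contamination is planted by count**: the number of contaminant leaves
  is `round(level * n_clean / (1 - level))`, and the achieved fraction is
  recorded in the truth table, so threshold tests compare against what was
  actually planted.
* The generator refuses configurations that would plant events below the
  default scan minima unless `allow_substandard = TRUE` (negative-control
  mode), so recall = 1.0 assertions are meaningful.

A green recovery test therefore establishes that the scanner implements
the stated rules exactly on trees with known structure. It does **not**
establish robustness to gene-tree estimation error, paralogy, incomplete
lineage sorting, or misannotation — none of which the generator emulates.

`simulate_alignment()` provides the structure the site filters assume:
gamma-distributed site rates (a site's residues are resampled with
probability $1-e^{-r/2}$; the $1/2$ keeps the site bulk recognisably
conserved, as in curated marker alignments) and compositional bias
confined to a taxon and site subset. The shifted composition concentrates
on the two globally rarest residues (tryptophan and cysteine): a
compositional shift onto already-common residues is statistically
invisible at single-site resolution, and lineage-specific attraction to
rare residues is the textbook form of the artefact that χ² trimming
targets. At `bias_strength = 0.8` on 10% of sites the planted sites'
median χ² score rank falls in the top 15%; with the bias fully confined
(`bias_strength = 1`) the top slice recovers ≥ 90% of planted sites.

## Matrix utilities: numerical choices

* **χ² site score.** Total heterogeneity is
  $X^2 = \sum_t \sum_s (c_{ts} - n_t f_s)^2 / (n_t f_s)$ over taxa and
  amino-acid states, gaps and `X` excluded, zero-expectation terms
  contributing 0. The score of site $i$ is $X^2(\text{full}) -
  X^2(\text{without } i)$, computed incrementally from cached counts and
  verified against full recomputation to 1e-9. The exact χ² variant used
  by the original trimming tool is not published; this removal-based
  reading is oracle-checkable and matches the common interpretation.
  One caveat found during verification: because the score is nonlinear in
  the counts, duplicating every column preserves the site *ranking* only
  approximately (rank correlation > 0.95, not identity); the test suite
  asserts the property that actually holds.
* **Fast-site removal** sorts by rate descending with ties broken by site
  index ascending, and removes `k * step` sites at step `k`; removed sets
  are nested by construction. Rates come from an external whitespace table
  (`read_site_rates()`) or from the built-in `fitch_site_rates()` proxy —
  parsimony step counts on a guide topology, computed with Hartigan's
  counting rule so the basal trifurcation of an unrooted guide tree is
  scored exactly. The external-rate path is first-class because published
  fast-site analyses use model-based rate estimates whose settings are not
  reproduced here.
* **Ceiling rule everywhere**: trimming a fraction $f$ of $L$ sites
  removes $\lceil f L \rceil$ (so 25% of 317 sites removes 80), ties by
  site index. Partitions are re-spanned after any site removal and dropped
  when empty; 1-based inclusive coordinates match common partition files.
* **OTU merging** keeps, per gene, the member row with the fewest gap+`X`
  characters (ties: first listed member), which provably never decreases
  occupancy relative to the best member.

## QC rules

Contig flagging uses the inclusive 60% rule on all predicted proteins
(no-hit proteins count in the denominator — the conservative reading of an
unstated detail); zero-protein contigs are reported unflagged with a note,
since they carry no evidence either way. Ribotype clustering is
single-linkage over pairs strictly above 99% identity ("above 99%" read as
strict, exposed as `inclusive`); identities arrive as a precomputed table
because computing them is aligner work, not rule logic. Completeness
reports per-assembly and union fractions and lists assemblies under the
five-marker floor.

## Determinism and degenerate inputs

Every simulator artifact is byte-identical under a fixed seed; scans are
deterministic given their inputs (enumeration order is fixed by node and
neighbour indices). The run manifest records command, config hash and
seed, but carries timestamps and is excluded from the byte-identity
contract. Degenerate inputs fail loudly and early: trees under four
leaves, empty gene lists, all-gap matrices, site removals that would empty
a matrix, identities outside [0, 100], unknown group labels, duplicate
taxon or gene ids, and — in strict mode — any leaf that does not resolve
in the taxon map.

## Known limitations

* The scanner is topological only; it cannot weigh branch support, and a
  poorly resolved tree that happens to show the pattern counts.
* The EGT:HGT ratio has no attached significance test here; the original
  analysis interprets it comparatively against control taxa, and so should
  users of this package.
* The simulator's event trees place all focal sequences inside the planted
  clade; configurations with focal paralogs scattered through the tree are
  not generated.
* `fitch_site_rates()` is a proxy, not a substitute for model-based rate
  estimation; it is offered for self-contained pipelines and testing.
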