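---
title: "Dating gene duplications and detecting co-duplicated groups on a paralogon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating gene duplications and detecting co-duplicated groups on a paralogon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The question

Human chromosomes 1, 2, 8 and 20 carry a *paralogon*: a set of chromosomal
segments in which many unrelated gene families each have three- or four-fold
representation.  Under the 2R hypothesis these segments descend from two
rounds of whole-genome duplication (WGD) early in vertebrate history, so the
families should have duplicated *together*, twice, inside one narrow time
window.  Under the competing small-scale-duplication (SD) model the families
duplicated independently at scattered times.  `paralogon` implements the two
phylogenomic instruments that discriminate the hypotheses:

1. **Relative dating.**  Duplication nodes found in each family's gene tree
   are placed into ordinal epochs bounded by speciation events.  WGD predicts
   a concentration of events between the invertebrate–vertebrate and
   teleost–tetrapod splits; SD predicts a spread.
2. **Topology congruence.**  Each family's tree is collapsed to a small
   *schematic topology* whose leaves are human chromosome labels.  Families
   that duplicated as one physical block must show congruent schematics (up
   to a small number of assumed translocations) and fall into common
   *co-duplicated groups*; independent histories fragment the families into
   many groups.

## The reference species framework

Dating is ordinal, not absolute: an event is bracketed by named speciations
on the human root path (sponge, placozoan, cnidarian,
protostome–deuterostome, ambulacrarian, cephalochordate, tunicate,
invertebrate–vertebrate, teleost–tetrapod, amphibian splits).  The packaged
tree covers the 46 metazoans of the underlying survey — 25 tetrapods, 5
teleosts, 16 invertebrates — arranged on the conventional metazoan
phylogeny.  Because only the named splits enter the dating, the resolution
*within* tetrapods and teleosts follows a standard arrangement and is
otherwise inconsequential.  Two placements deserve mention:

* The sampled set contains no lamprey or coelacanth, so the
  invertebrate–vertebrate split coincides with the tunicate split (tunicates
  are the closest sampled invertebrate relatives of vertebrates), and the
  vertebrate crown is the teleost–tetrapod split.
* *Saccoglossus* and *Ptychodera* are placed as Hemichordata inside
  Ambulacraria.  Changing this requires editing the newick fixture; the
  epoch scale is unaffected as long as they stay invertebrate.

Branch lengths on the reference tree are relative depths chosen to be
order-consistent (root deepest); only their order matters for dating, and
the simulator reuses them as its time axis.

The four reporting epochs are: **B1** before the invertebrate–vertebrate
split (refined by the deeper named splits where the species span pins one
down), **B2** between the invertebrate–vertebrate and teleost–tetrapod
splits — the proposed 2R window, **B3** teleost-lineage specific, **B4**
tetrapod-lineage specific.  Duplications confined to an invertebrate
subclade fall outside the human-path scale and are reported as `other`.

## Tree inference

Alignments are consumed, not constructed: the input is aligned amino-acid
FASTA whose headers carry `species|gene|chromosome`.  Before distances are
computed, *complete deletion* removes every column containing a gap or a
missing/ambiguous residue, the most conservative of the standard treatments;
the package treats any non-standard letter as missing.

Distances are the uncorrected proportion of differing sites (*p*-distance),
with a Poisson correction $d = -\ln(1-p)$ available as the model-corrected
option.  Trees are built by neighbor joining (Saitou–Nei).  Three numerical
choices are pinned down for reproducibility:

* ties in the $Q$ criterion are broken by the lexicographically smallest
  active pair, so runs are bit-identical;
* negative branch lengths are clamped to zero with the deficit moved to the
  sibling branch, preserving the path length through the joined pair;
* bootstrap supports (column resampling, default $B = 1000$, seed
  mandatory) are keyed to *unrooted bipartitions* and re-attached after
  rooting, so a support value always describes the same split it was
  computed for.

Maximum-likelihood inference is deliberately out of scope; the dating and
congruence stages accept any rooted, support-annotated newick, so trees from
external ML tools can be slotted in.

Rooting follows the conventions of the underlying survey: invertebrate
sequences when present (the pipeline's default), one subfamily rooting the
other when a family splits into two ancient subfamilies (pass the subfamily
as `outgroup` to `root_tree()`).  A non-monophyletic outgroup roots the tree
at the edge of maximal outgroup-side purity, with a warning.

Sequences whose placement contradicts the conventional animal history (for
example one insect sequence nested inside a mammalian clade) fabricate
ancient duplications.  `flag_discordant_leaves()` quantifies this as the
number of species-overlap duplication nodes mapping at or above the
invertebrate–vertebrate split and greedily flags the leaf whose removal
reduces that count the most, repeating while single removals help.  Genuine
ancient duplications survive the screen because no single leaf removal
dissolves a duplication supported by whole clades on both sides.  Flagged
leaves are reported; dropping them is the caller's (or the pipeline
configuration's) decision.

## Duplication detection and dating

An internal node of a rooted gene tree is a **duplication** when the species
sets of two of its children intersect (species overlap): some species kept
both copies, so the node cannot be a speciation.  This is the deterministic
core of the survey's procedure; no gene losses are inferred and no
most-parsimonious reconciliation is attempted.

Each duplication is dated by two bounds.  The *younger* bound is the
speciation at the MRCA of the species under the node — the duplication must
predate it, because both copies crossed those speciations.  The *older*
bound is the MRCA of those species together with the species of the gene
tree's sister lineage above the node; the gene-tree root is unbounded above.
The epoch is assigned from the younger bound.  When the two bounds straddle
an epoch boundary the event is flagged `ambiguous`, matching the "at least
prior to" phrasing such intervals deserve; ambiguous events are counted in
their younger bin and remain identifiable in the event table.

Support filtering (`filter_by_support()`, default threshold 50%) is applied
before the congruence stage; events lacking a support value (the root) are
retained with a flag, and the unfiltered table is always reported alongside
because the survey's printed per-family counts do not state whether they
were filtered.

## Schematic topologies and congruence

For the congruence stage each family is collapsed to its **schematic
topology** for the focal window (default B2): only duplication nodes dated
to the window contribute branching; the tree is restricted to human
paralogs; leaves are relabelled with chromosome tokens.  Around the window
the structure is absorbed deliberately:

* duplications *younger* than the window fold their paralogs into one
  compound slot (`8/6` — the slot is a chromosome *set*, and two slots match
  when their sets intersect);
* same-chromosome paralogs under one node merge to a single leaf;
* for duplications *older* than the window, only the subtree carrying the
  most window duplications is kept — the family's analysed "section", the
  same choice a curator makes when an ancient subfamily split predates the
  question being asked.

Families with fewer than two window duplications carry no congruence signal
and are excluded (a condition of class `paralogon_exclusion`, logged by the
pipeline), mirroring how such families are set aside in the survey.

The **translocation distance** between two schematics is the minimum number
of leaf relabellings joining them under the best rooted-tree isomorphism,
found by exhaustive matching (schematics have at most about six leaves).
Non-isomorphic shapes are incongruent at any allowance (distance $\infty$).
An optional padding mode (`pad = TRUE`) instead charges one unit per
surplus leaf against wildcard padding; it is off by default because shape
disagreement is evidence against joint duplication, not a unit cost.

**Co-duplicated groups** are the connected components of the congruence
graph at a translocation allowance $k$.  The pairwise predicate is not
transitive; rather than force transitivity, intra-group pairs exceeding
their allowance are reported (`flagged_pairs`).  The allowance can be a
single number (default 3) or a per-pair table.  The per-pair form is the
faithful encoding of the published analysis, which posits a specific number
of independent translocations for each comparison set (3, 2, 5 and 4 for
its four panels) and none elsewhere; with translocation assumptions taken
as input — like the physical linkage they summarise — the packaged 16
family schematics yield exactly the four published groups from the
distances the package computes.  A single global allowance cannot reproduce
that grouping: three of the panels are three-leaf caterpillars whose
cross-panel distances (2) are smaller than the largest within-panel
distance (3), so any scalar $k$ either splits a panel or merges panels.
That observation is itself a finding about the method: with so few slots,
topology alone under a generous allowance cannot separate the groups, and
the published grouping leans on which translocations one is prepared to
assume.

## The simulator

`scenario_spec()` fixes the study conditions; `simulate_family_trees()` and
`evolve_sequences()` generate gene families with known histories.

* **two_round_WGD**: every family duplicates at the same two points on the
  vertebrate stem (1 → 2 → 4 copies).  Copies fill the target chromosomes
  {1, 2, 8, 20} in order, emulating linked blocks, so the true schematic is
  the symmetric `((1,8),(2,20))` and the true partition is one group.
* **independent_SD**: each family draws its own placements (default two
  events) uniformly from edges spanning all four epochs; the new copy of a
  single-locus event lands on a random free chromosome, because independent
  events land independently.  The true partition is all singletons.
* **mixed** alternates the two.

Losses are applied per copy and species (default 0.1); the focal human
lineage keeps everything by default because surveyed families are
*ascertained* for retained paralogs — a family that lost its copies would
never have entered the catalog.  Translocation moves an extant human copy
to a random other chromosome with probability 0.05.  Sequences evolve by an
i.i.d.-site exchangeable model (substitution probability $1-e^{-r b}$ per
site on a branch of length $b$, uniform among the other 19 residues),
with defaults of 1000 columns at rate 1 per unit depth.  No indels are
simulated — alignments are exact, and the trimming stage is exercised by
dedicated gap fixtures instead — and there is no rate heterogeneity across
sites or lineages.  Ground truth records one duplication node per surviving
application of an event (a genome-wide event crossing $k$ copies leaves up
to $k$ nodes), the chromosome of every extant human copy and the true
family partition.

What passing recovery tests shows, and what it does not: the simulator
emulates topology, ordinal depth, loss, translocation and sampling noise,
but real protein families additionally face alignment error, rate
heterogeneity, hidden paralogy from unsampled genomes and assembly
artifacts.  Recovery on these simulations validates the machinery, not the
biological conclusions.

## Problem sizes and numerical choices

The recovery experiments shipped with the package run both presets at 20
fixed seeds, 6 families per seed, 12 species, 1000 columns, 100 bootstrap
replicates, and compare (i) the fraction of true duplication nodes dated to
their true epoch (matched per family and bin, surplus inferences do not
help) and (ii) the adjusted Rand index between true and inferred
co-duplication partitions, with excluded families counted as singleton
groups.  Dating recovery is measured on unfiltered events: at these
problem sizes bootstrap uncertainty is a property of the replicate count,
not of the method under test, and support filtering is exercised separately.
The identical-partition guard returns 1 when both partitions are fully
singleton and equal, where the raw Rand formula is 0/0.

Other numerical choices: distances are exact fractions of column counts;
the NJ tie-break and negative-length policy are described above; bootstrap
replicates that saturate a Poisson distance are skipped (they carry no
signal); schematic consensus within a group is the modal canonical form
with lexicographic tie-break.

## Known limitations

* Ordinal dating cannot separate events within one epoch, by design.
* The species-overlap criterion under-counts duplications whose losses
  erased the overlap, and a badly rooted tree can shift events across
  epochs; the discordance screen and ambiguity flags mitigate but do not
  remove this.
* Congruence of three-leaf schematics is weakly discriminating at generous
  allowances (see above); conclusions about co-duplication should quote the
  allowances they assume.
* The previous-survey fixture carries only the four families named in the
  published comparison, with representative members reconstructed from
  public annotation; totals over "36 families" are therefore not asserted
  anywhere in the package.
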