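---
title: "Mapping a shared allosteric site from structures and mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a shared allosteric site from structures and mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosite)
```

## The problem

Class C G protein-coupled receptors (the metabotropic glutamate, GABA-B,
taste 1, calcium-sensing and a handful of orphan receptors) bind their
endogenous ligands in a large extracellular domain, while small-molecule
allosteric modulators — positive (PAM) and negative (NAM) — bind in the
seven-helix transmembrane domain (TMD). Two independent lines of evidence
locate that modulator site: co-crystallized receptor–modulator complexes,
and a large curated body of single-point mutagenesis measurements
expressed as fold changes of modulator potency or affinity. `allosite`
merges the two on a common cross-receptor coordinate system and asks
which positions constitute a site shared across receptor families, which
positions are family-spanning hotspots, and which mutational effects lie
outside the site and are better explained by indirect mechanisms.

## Generic residue numbering

Cross-receptor comparison needs position labels that survive sequence
divergence. Each segment (TM1–TM7, loops such as ECL2 = segment 45) is
anchored at its most conserved residue, which carries index 50; any other
residue's index is `50 + (sequence offset from the anchor)`. A position is
written `"<segment>x<index>"`, e.g. `6x50` or `45x52`. The package
consumes segment bounds and anchors from an annotation table rather than
recomputing them from structure: structure-aware renumbering of bulged or
constricted helices is a separate problem, and annotations externalize it
cleanly. Loop indices below 50 count backwards from the anchor with the
same arithmetic, so the residue before the conserved ECL2 cysteine
(`45x50`) is `45x49`. Mappings are strict inverses on the annotated
range: `genericToSeq(assignGeneric(i)) == i`, and an index that escapes
1–99 is treated as an annotation inconsistency, not clamped.

## The contact rule

A residue of a complex is a modulator contact when the minimum distance
between its tested atoms and **any** modulator atom is at most the cutoff
(default 5 Å, inclusive; distances on unrounded coordinates). Tested
atoms are the C-alpha plus all side-chain heavy atoms; backbone N, C, O
and OXT are never tested, and glycine is testable through its C-alpha
only. Hydrogens are dropped at parse time; alternate locations resolve to
the highest-occupancy copy (ties to altloc A); author residue numbering
is reconciled to sequence numbering by a per-chain constant offset, and
insertion codes are rejected rather than guessed at. When a structure
carries two protomers, contacts are computed per chain and unioned.
In-contact residues that have no generic position under the annotation
are reported in a dedicated slot with a warning — never silently dropped.
Unions across structures keep provenance (which structures and receptors
support each position) so either reading of a multi-structure union —
pooled or per receptor first — can be reconstructed.

## The effect rule

One mutation record is one mutant × one modulator measurement. The fold
effect is stored as a direction-agnostic magnitude (≥ 1): the inclusion
rule is about magnitude, not direction. A record passes when its fold
effect **strictly exceeds** the threshold (default 5; a fold of exactly
5.0 fails) or when the response was qualitatively abolished; `no_effect`
records never pass at any threshold. Binding and function assays are
interchangeable — any single passing measurement suffices. Per-position
summaries count distinct entities (receptors, families, ligands), so a
ligand measured in two assays counts once and the statistics are
invariant under record duplication. Conflicting duplicate reports for the
same mutant × ligand are kept and surfaced through `conflictReport()`
rather than reconciled by any precedence rule.

## Integration

The site profile is the union of structural contact positions and passing
mutational positions, one row per position with both provenances. On top
of it:

* **Venn partition** by evidence type (structure-only / mutation-only /
  both); a true partition by construction, satisfying the
  inclusion–exclusion identity on every input.
* **Hotspots**: positions whose passing *mutational* evidence spans at
  least `minFamilies` (default 3) distinct receptor families. Structural
  support is not required; requiring more families can only shrink the
  set.
* **Overlap statistics**: the share of positions recurring in ≥ 2
  families (structural evidence credits the structure's receptor family),
  and the share of mutation-supported positions with both PAM and NAM
  passing evidence. Allosteric agonists carry their own modality and are
  excluded from the PAM/NAM statistic. Because the natural denominator of
  the multi-family share is ambiguous (all profiled positions, or only
  mutation-testable ones), both variants are reported. Displayed
  percentages are rounded half-up; unrounded values are retained.
* **Outside-site classification**: every effect position absent from the
  site set is flagged when its evidence is confined to one ligand on one
  receptor, and when the mutated wild type is a glycine (backbone
  flexibility rather than a lost contact). Adjacency-to-site and
  membrane-facing flags are computed only when a neighbour list or an
  orientation annotation is supplied — the package does not invent
  orientations. Receptor-unique evidence (sub-pocket extensions) falls
  out of the profile as a selectivity column rather than as a separate
  construct.

## Distances and trees

Tree building replaces an external phylogeny package with an in-package
distance + UPGMA implementation. Distances are alignment-based: columns
gapped in either sequence are excluded, `p` is the mismatch proportion,
and the selectable models are the raw p-distance and the Poisson
correction `-ln(1 - p)` (capped at `p = 0.95` with a warning to avoid
infinities). This deviates from the maximum-likelihood substitution-model
distances of classic phylogeny suites; the deviation is deliberate — the
claim being tested at tree level is qualitative family coherence, which
is robust to the distance model, and branch lengths are not an output
anyone should consume for dating. UPGMA merges the closest cluster pair,
with size-weighted average linkage (equivalently: the mean over all
member pairs of the input matrix), node height = merge distance / 2, and
a deterministic tie rule (lexicographically smallest pair of cluster
labels, a cluster labelled by its alphabetically first taxon), so output
is independent of input order. Trees are rooted and ultrametric by
construction and are returned as `ape` `phylo` objects (Newick I/O via
`ape`). A family is *coherent* when some subtree's leaf set equals the
family exactly; singletons are trivially coherent.

## Conservation

Per-column physicochemical conservation across receptors uses a
configurable property scheme; the default maps each amino acid to one or
more of aromatic/aliphatic/polar/positive/negative/small/gly/pro, with
histidine counted as aromatic (a choice that matters for aromatic-column
statistics). The default denominator excludes receptors lacking the
position; an all-receptor variant (gap counts as non-matching) is emitted
alongside in `conservationReport()` because either convention is
defensible. Site similarity between two receptors is percentage identity
over site columns non-gap in both.

## The synthetic-data generator

The generator exists so that every stage is testable end to end without
external downloads, with known ground truth. Its defaults are the study
conditions emulated throughout: 22 receptors in five family blocks
(8/2/3/2/7), a 28-position planted site spanning TM2/3/5/6/7 and one
ECL2 position, four modulator complexes distributed 3 + 1 over the first
two receptors, a 70-modulator ligand pool with a 45/45/10 PAM/NAM/agonist
mix, passing folds log-normal with median 15 (bulk roughly 3–75,
matching the few-fold to > 55-fold span of reported effects) truncated
above the 5-fold threshold, and roughly 1100–1200 records overall, of
which 800 are sub-threshold background.

* **Sequences** follow a family-block process: random root, family
  ancestors substituted per column at the between-family rate (0.35),
  members at the within-family rate (0.08), so within-family distances
  sit below between-family ones by construction. The disulphide
  cysteines 3x29 and 45x50 are pinned to Cys everywhere.
* **Structures** are idealized: seven helices (3.6 residues/turn, 1.5 Å
  rise, 2.3 Å helical radius) on a 14 Å bundle circle plus an ECL2 arc,
  one C-alpha and one pseudo side-chain atom per residue. Planted
  residues point a 7 Å side chain into the core, all others point
  outward; ligand atoms are placed radially inward of each planted side
  chain at `cutoff - margin` (minus jitter). Because a ligand atom's
  cylindrical radius is then always at least `cutoff + margin` smaller
  than any non-planted atom's radius, the clearance constraint holds by
  geometry and is re-verified on the written coordinates; violation is a
  generation error. Every residue gets a pseudo side-chain atom — even
  glycine — since controllable distances, not rotamer realism, are the
  goal; glycine's C-alpha-only behaviour in real structures is exercised
  by hand-built fixtures instead. Coordinates are quantized to PDB
  precision (3 decimals) before any distance is verified, and placement
  sits half a grid step inside the target so the zero-margin,
  zero-jitter configuration lands at the cutoff *on the inclusive side*
  up to coordinate precision.
* **Mutation tables** guarantee at least one passing record per planted
  position (the guarantee can be switched off for calibration checks,
  where per-record passes are Bernoulli with the configured
  probability); background records never pass — folds at most the
  threshold, or `no_effect`. Wild-type letters are read from the actual
  generated sequences.
* All generators are pure functions of the spec seed and restore the
  caller's RNG state.

What the generator does *not* emulate: real rotamers and packing, loop
flexibility, assay noise and inter-laboratory disagreement, publication
bias in which mutants get made, and structure-specific numbering
corrections. Passing closed-loop tests therefore demonstrates the
correctness of the rules and their integration, not the field
reliability of curated data.

## Numerical choices and degenerate inputs

* Contact boundary inclusive at exactly the cutoff; distances on
  unrounded parsed coordinates.
* Fold boundary strict at exactly the threshold.
* Percentages rounded half away from zero for display only.
* Poisson distances capped at `p = 0.95`, with a warning per capped pair.
* UPGMA ties broken lexicographically; fully tied matrices resolve to a
  deterministic order-independent tree.
* Empty profiles make overlap statistics an error, not a `NaN`; all-gap
  columns make conservation an error; fewer than two taxa make UPGMA an
  error.

## Problem sizes

The validation suite runs entirely on generated data: 50 random studies
of 5–20 receptors and 5–30 planted positions for closed-loop recovery,
100 random 4–8 taxon matrices against a naive recomputed-average UPGMA
oracle, brute-force all-pair contact scans on every synthetic complex,
and 20 random rigid motions for invariance. The default study
(`syntheticSpec()`) at 22 receptors runs the full pipeline in a few
seconds.

## Worked example

```{r example, eval = FALSE}
spec <- syntheticSpec(seed = 1)
res <- simulateStudy(spec, outDir = "report")
res$profile            # merged site profile
res$hotspots           # family-spanning positions
res$statistics         # multi-family and PAM/NAM overlap percentages
res$coherence          # family monophyly on the TMD and site trees
```

## Known limitations

Annotation-driven numbering cannot represent helix bulges; insertion
codes and mmCIF input are unsupported; distance models are p/Poisson
only (no substitution matrices, no rate heterogeneity); conservation is
class-fraction based, not entropy- or matrix-weighted; and the Venn/
hotspot statistics inherit whatever curation biases the input mutation
table carries.
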