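---
title: "The ten-cysteine reference array: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ten-cysteine reference array: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## 1. The model

CS-αβ defensive peptides share a fold — an α-helix packed against two
antiparallel β-strands — stabilized by a conserved disulfide core, yet
their cysteine counts range from 4 to 10 and their inter-cysteine
spacings vary so much that position-by-position alignment across
families is meaningless. The package's central object is therefore not
an alignment but an *assignment*: an order-preserving, injective map
from a sequence's observed cysteines to ten conceptual reference slots
C1–C10.

Two landmarks pin the assignment down.

**The CSH motif.** Every member carries the cysteine-stabilized
α-helix: slots C3 and C4 separated by exactly 3 residues, slots C8 and
C9 by exactly 1, with disulfides C3–C8 and C4–C9. These two spacings
are the only spacings in the model treated as (near-)invariant.

**The γ-core.** A β-hairpin region of 8–16 residues containing a GXC or
CXG tripattern whose cysteine maps to slot C6 — except in mytilins,
where the homologous cysteine is C7 (the "mytilin exception", §3).

Given slot labels, everything else is derived data:

- a family is a *slot set* (nine built-in templates, from the
  four-cysteine CSH-only archetype to the ten-cysteine macins);
- disulfide bonds follow from slot pairs
  (C2–C6, C3–C8, C4–C9, plus C1–C10 / C1–C7 / C5–C10 in the larger
  templates);
- a compact notation such as `1[C2]8[C3]3[C4]4[-5][C6]3[-7][C8]1[C9]1`
  records filled slots, empty slots and inter-slot spacings;
- a superfamily-wide alignment exists whose only hard constraint is
  that each assigned slot occupies one shared column;
- indels between anchors become discrete phylogenetic characters.

## 2. Slot assignment: scoring and search

`map_to_reference()` enumerates *all* order-preserving assignments of
the k observed cysteines (2 ≤ k ≤ 12) to the ten slots, allowing up to
two unslotted "extra" cysteines, and maximizes

| term | value |
|---|---|
| γ-core cysteine at the anchor slot (C6, or C7 in the exception pass) | +8 |
| each intact CSH spacing (3 between C3/C4, 1 between C8/C9) | +4 each |
| occupied slot set equals a family template exactly | +3 |
| template deviation (slot-set mismatch ×2 + out-of-range region lengths) | −1 per unit |
| each extra (unslotted) cysteine | −2 |

Ties break by template match, then minimal deviation, then the
lexicographically smallest slot assignment, making the result fully
deterministic. The weights are ordinal, not fitted: the γ-core bonus
(+8) dominates one CSH spacing (+4) because a planted γ-core is rarer
by chance than a 1-in-19 spacing coincidence; the template bonus (+3)
is deliberately smaller than a CSH bonus so that a template can never
justify breaking the motif; extras cost −2 so that discarding a
cysteine must buy at least one scoring unit elsewhere.

The search is exhaustive but vectorized: for each choice of extras and
subset size, all `choose(10, m)` slot subsets are scored at once via a
membership matrix, so even the worst case (12 cysteines, 2 extras)
completes in tens of milliseconds. Exhaustiveness matters more than
speed here — the test suite checks the vectorized search against a
plain nested-loop oracle, which is only possible because both explore
the identical space.

Sequences with fewer than 2 or more than 12 cysteines are rejected
rather than guessed at: below 2 there is nothing to anchor; above 12
the enumeration is no longer the bottleneck, the biology is — such
sequences fall outside the modeled superfamily envelope.

## 3. The mytilin exception

Mytilins align their γ-core cysteine with C7, not C6. The package
always evaluates a second assignment pass anchored at slot 7 whenever a
γ-core exists, but accepts it only under strict conditions: the slot-7
reading must be an exact, deviation-free template fit with both CSH
spacings intact, must place a γ-core cysteine at C7, and must strictly
outscore the slot-6 reading. The strictness is deliberate. Random
GXC/CXG tripatterns occur frequently in synthetic and real sequences,
and a permissive exception would let any stray tripattern drag
assignments toward the mytilin template. Conversely, a trigger that
only fires when the slot-6 reading is visibly bad is insufficient:
a stray tripattern can hand the slot-6 pass a deviation-*free* decoy
(with the leftover cysteines written off as extras) that still scores
below the true slot-7 reading. Comparing full scores of both passes
resolves this without any new parameter.

The mytilin template's C5–C7 range (6–10 residues) was chosen disjoint
from the mollusk/nematode C5–C6 range (2–4) so that the two
eight-cysteine templates are separable on spacings alone; with
overlapping ranges the exception could not be made safe.

## 4. Anchored alignment and indel coding

`build_anchored_alignment()` creates one column per slot that *any*
record assigns, and distributes each record's inter-anchor segments
into the blocks between anchor columns: the N-terminal flank is
right-justified against its first anchor, and each following segment is
left-justified after its leading anchor. No substitution scoring is
involved — the alignment is a bookkeeping device for the assignment,
not an optimization, so it is reproducible and arguments about gap
penalties cannot arise. `gap_spaces()` counts gap columns strictly
between two bounding anchor columns, which is what the indel characters
need.

Indel characters are coded relative to the ancestral four-cysteine
reference (AdDLP, a bacterial defensin-like peptide), whose six area
lengths are fixed by `indel_code_scheme()`: flank 3, C2–C3 span 17,
C3–C4 3, C6–C8 span 11, C8–C9 1, tail 9. Each area codes `0` (shorter
than the reference), `1` (equal) or `2` (longer); areas bounded by an
unassigned slot code `-` (missing). Areas 1, 3, 5 and 6 use raw residue
counts; areas 2 and 4 use alignment gap columns, because those two
spans include interior slots that may or may not be occupied, and the
alignment already accounts for that. Two further characters code N- and
C-terminal propeptide presence (1/0/−).

## 5. NEXUS output

The coded matrix is written as a single NEXUS DATA block with
`DATATYPE=MIXED(PROTEIN:…,STANDARD:…)`, plus a `sets` block and a
MrBayes block (protein partition: `rates=invgamma`,
`aamodelpr=mixed`; standard partitions: `rates=gamma`; all:
`ratepr=variable`; an `mcmc` line is included as a comment rather than
executed). Two deliberate choices:

- **`-` doubles as the missing symbol in the standard spans.** MIXED
  matrices allow one FORMAT line; `?` remains the global missing
  symbol, but unknown indel/propeptide states are written as `-` and
  documented in a header comment, so a parser that treats `-` as "no
  data" in non-sequence characters reads the matrix correctly.
- **A hand-written reader (`read_nexus_matrix()`) provides the
  round-trip check.** No available R parser understands
  `DATATYPE=MIXED`; plain protein alignments exported by
  `export_alignment()` are round-tripped through `ape::read.nexus.data`
  as an independent oracle instead.

## 6. The synthetic generator, realism and limitations

`generate_family()` draws each inter-slot region length uniformly from
the family template's range, fills non-cysteine positions uniformly
from the 19 non-cysteine residues, and plants a G-x-C ending at the
template's γ-core slot (plus K…N for the channel-toxin motif on
request). All randomness is confined to `withr::with_seed`, so
generation is bit-for-bit reproducible. `perturb()` substitutes
non-anchor residues at a given rate, never touching cysteines or
planted motifs, which makes "template recovery under 10% mutation" a
well-posed property.

What the generator deliberately does *not* model:

- **Residue composition.** Real defensins are cationic and
  glycine/arginine-rich; uniform composition is used because the
  assignment algorithm only reads cysteines and the γ-core/KCXN
  letters, so composition realism would add parameters without adding
  test power. The flip side: spurious GXC tripatterns arise at roughly
  the natural random rate, which is exactly the decoy pressure the
  mytilin exception (§3) must survive.
- **Indel processes within regions.** Region lengths are drawn i.i.d.
  uniform per record, not evolved on a tree; the package codes indel
  characters but does not simulate their evolution.
- **True disulfide connectivity.** Bonds are inferred from templates by
  homology; `infer_bonds()` accepts experimentally `verified` pairs and
  reports everything else as inferred, in the
  `C3–C8, C4–C9, (C2–C6, …)` grammar.

Other known limitations: sequences with more than two supernumerary
cysteines (e.g. big defensins) are out of scope by construction;
family classification of non-template slot sets reports `unassigned`
with a nearest-template note rather than forcing a label; and the
long-chain-toxin versus drosomycin/plant split rests on a single
C9–C10 extension threshold (default 10 residues, configurable), which
is a coarse but honest proxy.

## 7. Problem sizes

The intended regime is interactive: hundreds of peptides of 30–150
residues. Assignment is the only super-linear step and is bounded by
`choose(12, 2) × Σ choose(10, m)` scored candidates per record (~65 ms
worst case observed); alignment, coding and NEXUS export are linear in
total sequence length. The full test suite (≈2,300 assertions,
including 1,800 mapping-classification runs for the recovery
properties) completes in about six minutes on one CPU.
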