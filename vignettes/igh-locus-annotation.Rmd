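---
title: "Annotating teleost IGH loci and tracing IGHZ evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating teleost IGH loci and tracing IGHZ evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The immunoglobulin heavy chain (IGH) locus of a teleost fish is a long
(hundreds of kb) genomic region holding three kinds of material: arrays of
VH, DH and JH gene segments that VDJ recombination assembles into the
antigen-binding part of the heavy chain; and constant-region (CH) exon
blocks — *IGHM*, *IGHD* and the teleost-specific mucosal isotype *IGHZ* —
that determine antibody class. Annotating such a locus from genomic
sequence alone means recognising each of these elements by homology to
previously characterized reference loci and by the short conserved motifs
that flank them: recombination signal sequences (RSS) around V/D/J
segments and splice motifs around CH exons. Once several loci are
annotated, the comparative questions follow: how similar are paralogous
constant regions, how many IGHZ copies does each locus carry, and how
often has IGHZ been deleted across the phylogeny?

`ighlocus` implements that workflow as composable, deterministic stages,
plus a synthetic-locus generator that makes every stage testable without
any genome download.

## Homology search and E-values

CH exons are found by local alignment of reference exon sequences against
the locus. The search is seed-and-extend: exact `word_size` = 11 nt seeds
(4 residues in translated amino-acid mode), grouped by diagonal, each
group extended by an affine-gap Smith–Waterman restricted to a window
around the seeds. Scoring defaults to match +2, mismatch −3, gap open 5,
gap extend 2 — the conventions under which the downstream E-value and
bitscore thresholds were stated. Significance uses the Karlin–Altschul
model, `E = K·m'·n'·exp(−λS)`, with the finite-size adjustment
`l = ln(K·m·n)/H`. λ is solved exactly from
`Σ p_i p_j exp(λ s_ij) = 1` under uniform base composition (0.634 for
+2/−3), and H follows in closed form from the implied target frequencies.
K defaults to 0.41, the standard tabulated value for this scheme; the
E-value filters below sit orders of magnitude apart, so the precise K is
immaterial to every decision the pipeline makes, and the test suite
checks the exponential tail shape against an empirical null with freely
fitted λ and K. The search reports permissively (E ≤ 10): the curation
filters, not the search, are meant to do the real discrimination.

A candidate-scaffold screen mirrors locus discovery in a fragmented
assembly: a scaffold is kept when it has hits to at least two distinct
segment types, or when hits of a single type cover at least 1% of its
length (interval union, so stacked hits never inflate coverage).

## Constant-region curation

Hits to reference exons of the same isotype and exon label whose
intervals overlap on one strand are collapsed into an *alignment group*;
the group records its best E-value, best bitscore, and how many distinct
reference exons (across all reference species) support it. Two filter
passes then apply the published thresholds behaviourally:

1. discard groups with best E-value above 0.001, and groups overlapped by
   a different-label group scoring at least 16.5 bits higher (both rules
   evaluated against the pre-filter set, so the result is independent of
   input order);
2. stringent pass: keep only groups with E ≤ 1e−8 *and* at least two
   aligned reference exons.

Surviving groups are refined on splice motifs as a deterministic stand-in
for manual curation: within a ±30 nt window of the best member's aligned
edge, the exon start snaps to the position immediately after the nearest
AG acceptor and the end to the position immediately before the nearest GT
donor (nearest motif wins; equidistant ties break to the 5' candidate).
Terminal secretory exons, which have no 3' splice site, instead run to
the first canonical polyadenylation hexamer (AATAAA only by default —
ATTAAA is not accepted unless configured) with the translation truncated
at the first stop. Missing motifs flag the exon `incomplete` rather than
guessing.

Refined exons chain into constant regions while consecutive gaps stay
within `max_intron_gap` (default 15 kb — teleost CH introns are short,
and spans beyond this are better treated as separate regions) and exon
ranks are non-decreasing, with the IGHD (Cδ2–Cδ3–Cδ4) block allowed to
repeat; a rank violation splits the region and flags both parts. A region
is a pseudogene when any exon translates with a premature stop in frame 0
or is frameshifted relative to its reference exon length; it is complete
when it has Cμ1–Cμ4 (IGHM), Cζ1–Cζ4 (IGHZ), or Cδ1 and Cδ7 (IGHD). TM2 is
deliberately excluded from completeness: its conserved coding stretch is
too short to find reliably, and requiring it would misclassify loci.
`classify_ighz_status()` reduces a locus to present (with a count),
pseudogene remnant, or absent.

## Variable-segment discovery

VH and JH candidates come from windowed position-specific scoring
profiles: per-column log2-odds against the background with pseudocount 1,
majority-gap columns dropped. Profiles are built per VH reference family
— a single profile over a mixed-family alignment averages itself into
uselessness, while per-family profiles retain discrimination and their
candidates merge downstream. Each profile's reporting threshold is
calibrated once, under a fixed seed, on i.i.d. sequence drawn from the
training composition: Gumbel-fitted block maxima give the score at which
the expected number of null hits per locus length (both strands) is at
most 0.01. Candidates extend ±40 nt to absorb boundary error and merge
within a strand keeping the best anchor.

Boundary refinement uses the RSS: a VH 3' end snaps to the nearest
downstream heptamer (CACAGTG, ≤ 1 mismatch, within +50 nt); a JH 5' end
snaps after the nearest upstream opposite-sense heptamer (read CACTGTG on
the coding strand) and its 3' end to the first GTA splice junction near
the anchor end (6 nt of upstream slack, +30 nt downstream). VH 5' ends
keep the profile extent and are flagged approximate — there is no local
motif that marks them.

DH segments are too short and variable for homology search; they are
found purely by their flanking signal: revcomp(nonamer) · 12-spacer ·
revcomp(heptamer) · core · heptamer · 12-spacer · nonamer, with canonical
heptamer CACAGTG and nonamer ACAAAAACC (the 12/23 spacer rule), core
length 10–40 nt, and at most 8 mismatches summed over the four signal
elements. The stringent second pass requires the most conserved heptamer
positions — CAC, and the complementary GTG on the opposite-sense copy —
to be exact in both flanks. The pattern is its own reverse complement
structurally, so a plus-strand scan finds all placements; orientation
comes from the nearest flanking VH/JH segment when available, else plus.
Overlapping placements resolve to fewest mismatches, then leftmost, then
shortest.

VH families are single-linkage clusters (equivalently, connected
components of the thresholded identity graph) at 80% global-alignment
identity. Identity uses a fixed published scheme — match +1, mismatch −1,
linear gap −2, denominator = aligned columns including gaps — documented
and constant so the 80% threshold is well-defined. Names are positional:
`VH<family>.<ordinal>` 5'→3' within family, `DH<n>`/`JH<n>` by position,
with coordinate ties broken by strand then input order so renaming is
stable under permutation.

## Comparative statistics and the IGHZ phylogeny

Exon identity matrices use the same fixed global-alignment identity;
"corresponding-exon" averages take pairs sharing an exon label. Subclass
votes rank labelled reference subclasses by maximum identity to same-label
reference exons, flagging a vote ambiguous when the top two subclasses
fall within 0.02 identity — a margin chosen to be comfortably above
alignment-noise resolution while still separating genuinely distinct
subclasses. IGHZ multiplicity is summarized as the geometric mean count
over IGHZ-bearing loci only.

For the subclass phylogeny, Cζ1–Cζ4 nucleotide sequences concatenate in
rank order (missing exons recorded in a presence mask; Cμ1–4 outgroups
built identically). Alignment is an in-package progressive aligner
(k-mer-distance guide tree, profile–profile Needleman–Wunsch merges) —
no multiple-alignment package ships with the supporting stack, and an
in-package aligner keeps the stage deterministic and seedable. Distances
are Jukes–Cantor on ungapped shared columns; trees come from neighbour
joining with negative branch lengths clamped to zero and the deficit
moved to the sibling, preserving path lengths. This distance+NJ stage is
a deliberate, documented substitution for maximum-likelihood inference:
it is desk-scale and dependency-free, and the downstream operations
(support collapsing, clade labelling, loss counting) consume any rooted
tree, so an externally computed ML tree in newick can be plugged in
unchanged.

Bootstrap support is nonparametric column resampling (seeded), each
replicate re-run through distances and NJ, with an internal edge's
support the percentage of replicates containing its bipartition. Nodes
with support strictly below 65 collapse into polytomies (64 collapses,
65 survives), with collapsed edge lengths pushed onto the children so tip
depths are preserved; collapsing is idempotent. After rooting on the
outgroup (falling back to the first outgroup tip if the outgroup is not
monophyletic in the gene tree), subclass labels go to maximal clades
strictly below the ingroup ancestor whose members come from at least two
species; single-species clades and leftover tips get `none`. One known
limitation deserves emphasis: on a true ancestral radiation the
nonparametric bootstrap can assign strong support to an arbitrary
backbone resolution (the star-tree paradox), in which case two radiating
lineages survive collapsing as one labelled clade. The analysis driver
demonstrates the intended behaviour on a realization whose backbone
correctly collapses; an ML tree with honest branch support is the remedy
on real data.

Loss counting is Dollo: with IGHZ present at the root and never regained,
the minimum number of deletions equals the number of maximal all-absent
tip subtrees, located by one postorder sweep; the function returns the
count and the loss lineages. The package ships a 14-tip atherinomorph
cladogram (assembled from published teleost phylogenies) with IGHZ
presence states for the studied species; on it the count is 3, and the
test suite verifies the sweep against exhaustive enumeration over loss
edge subsets on random 8-leaf trees.

## The synthetic-locus generator

`generate_locus()` emulates exactly the statistical structure the
annotation stages assume: i.i.d. intergenic background (default 42% GC,
mean spacer 600 nt) interleaved with planted features — VH copies
followed by heptamer/23-spacer/nonamer RSSs, DH cores inside
opposite-sense 12-spacer RSSs, JH copies with upstream RSS and downstream
GTA donor, CH exon blocks in blueprint order with AG..GT intron context
and AATAAA after the fourth C exon — optionally as multiple subloci on
opposite strands. Default counts (24 VH, 14 DH, 17 JH; six-exon IGHM and
twelve-exon IGHD blueprints) mirror a characterized killifish
architecture, and the default per-site divergence between a planted copy
and its reference is 0.10. Planted coding features use a codon-aware
mutation that rejects substitutions creating in-frame stops and conserves
3 nt at each exon edge — emulating purifying selection and the strong
constraint on splice-proximal bases. The synthetic reference library
derives three reference species from common ancestors at divergence 0.08
for CH/JH material (reference CH exon sets are conserved enough that true
exons attract multi-species evidence, the premise of the two-reference-
exon rule) and four VH family ancestors at 0.22 from a common VH ancestor
(families separate cleanly at the 80% threshold while remaining
profile-able).

What the generator does *not* emulate bounds what passing tests show:
there is no repeat structure or low-complexity sequence (no masking stage
exists, deliberately), no sequencing or assembly error, no pseudogenized
or truncated planted segments, and real cross-species divergence is
neither uniform per site nor free of selection. End-to-end recovery of
0.95+ precision and recall under these conditions demonstrates that the
algorithmic chain is correct and its thresholds behave as specified — not
that real-genome annotation will reach those numbers, where repeat
content and assembly quality dominate. One knock-on choice: truth
`family` labels record ancestry of the planted copy; at divergence 0.10,
two copies of one family sit near 72–80% pairwise identity, so the
operational 80% clustering legitimately splits ancestry families — family
correctness is therefore tested graph-theoretically against the identity
matrix, not against ancestry.

## Problem sizes and determinism

The test suite and acceptance script run everything at desk scale, chosen
so the full suite completes in minutes on one core: ~60 kb single-locus
simulations, 20-replicate end-to-end benchmarks, 50 kb DH-oracle
instances, 30-segment clustering instances, 6-leaf additivity checks
(100 replicates), 200-replicate bootstraps, and exhaustive Dollo
enumeration at 8 leaves. Every stochastic step takes an explicit seed:
simulation and mutation via per-call seeds, profile calibration via the
configuration seed, bootstraps via their own argument. Equal-score ties
everywhere break by fixed deterministic rules (leftmost coordinate, then
query id or input order), so identical inputs yield identical output
byte-for-byte.
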