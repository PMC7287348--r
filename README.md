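# ighlocus

Annotation and comparative evolution of teleost immunoglobulin heavy chain
(IGH) loci.

The IGH locus encodes the heavy chain of B-cell receptors and antibodies.
In teleost fishes it holds arrays of VH, DH and JH gene segments (joined
somatically by VDJ recombination) followed by constant-region (CH) exon
blocks that determine antibody class: *IGHM* and *IGHD*, universal in
teleosts, and the teleost-specific mucosal isotype *IGHZ* (also called
*IGHT*), which is repeatedly duplicated and lost across lineages.
`ighlocus` is for researchers who need to turn a locus-scale genomic
sequence plus reference gene-segment libraries into a curated annotation
(VH/DH/JH segments and CH exons assembled into constant regions) and to
carry that annotation into cross-locus statistics, an IGHZ subclass
phylogeny, and a minimum gene-loss reconstruction on a species tree.

## Methods at a glance

* **Homology search.** Seed-and-extend local alignment (exact word seeds,
  affine-gap Smith–Waterman extension in a window, both strands) with
  Karlin–Altschul statistics: `E = K·m'·n'·exp(−λS)` with the standard
  length adjustment `l = ln(K·m·n)/H`, and bitscore `(λS − ln K)/ln 2`.
  λ and H are solved exactly for the +2/−3 nucleotide scheme.
* **Constant regions.** Hits sharing isotype, exon label and overlapping
  coordinates are collapsed into alignment groups; groups are discarded
  when their best E-value exceeds 0.001 or an overlapping different-label
  group out-scores them by ≥ 16.5 bits; a stringent second pass requires
  E ≤ 1e−8 and at least two distinct aligned reference exons. Exon edges
  snap to AG acceptor / GT donor splice motifs (±30 nt window); terminal
  secretory exons run to the first AATAAA polyadenylation hexamer.
  Same-isotype exons chain into regions in exon-rank order, with the IGHD
  (Cδ2–Cδ3–Cδ4) block allowed to repeat; premature stops or frameshifts
  mark pseudogenes; TM2 never affects completeness.
* **Variable segments.** VH/JH candidates come from calibrated
  position-specific scoring profiles built per reference family; VH 3'
  ends snap to the RSS heptamer (CACAGTG), JH 5'/3' ends to the upstream
  heptamer and the GTA splice junction. DH segments are found by their
  opposite-sense 12-spacer RSS pattern with up to 8 mismatches across the
  signal elements and exact CAC/GTG heptamer anchors. VH families are
  single-linkage clusters at 80% Needleman–Wunsch identity.
* **Comparative/phylogenetics.** Exon identity matrices from global
  alignment; concatenated Cζ1–4 phylogeny via progressive alignment,
  Jukes–Cantor distances and neighbour joining with nonparametric
  bootstrap; nodes under 65% support collapse into polytomies; subclass
  clades require members from ≥ 2 species. IGHZ loss counting is Dollo:
  with the character present ancestrally and never regained, the minimum
  number of losses equals the number of maximal all-absent subtrees.
* **Synthetic loci.** A simulator plants divergence-controlled copies of
  reference segments with correct flanking context (RSS spacers, splice
  motifs, polyadenylation signals) in i.i.d. background, emitting exact
  ground truth so the whole pipeline is testable end to end.

## Worked example

Simulate a killifish-like locus (24 VH, 14 DH, 17 JH, IGHM + IGHD), then
annotate it blind and score against the planted truth:

```r
library(ighlocus)
refs <- make_reference_library(seed = 99)
gen  <- generate_locus(sim_config(seed = 5), refs)
ann  <- annotate_locus(gen$locus, refs)
ann
#> <igh_annotation> simlocus_s5 (60096 bp)
#>   segments: VH=24, DH=14, JH=17, CH-exon=18
#>   constant regions: IGHD=1, IGHM=1

score_recovery(gen$truth, ann$segments)
#>   segment_type n_truth n_pred precision recall exact_boundary_frac
#> 1      CH-exon      18     18         1      1               0.944
#> 2           DH      14     14         1      1               1.000
#> 3           JH      17     17         1      1               1.000
#> 4           VH      24     24         1      1               1.000
```

Every planted segment class is recovered with precision and recall 1.0 on
this locus; 94% of CH exons land on their exact planted splice boundaries
(the remainder are off by a few nucleotides where a chance splice-like
motif sits closer to the aligned edge). `write_annotations()` exports the
result as GFF3 (1-based), BED (0-based half-open) or TSV;
`write_locus_report()` emits per-type counts, per-isotype constant-region
counts and the locus span as JSON.

The scripted analyses under `analysis/` run the same machinery as a
narrative workflow: `01_simulate_locus.R` builds contrasting IGHZ-free and
two-IGHZ architectures, `02_annotate_locus.R` annotates and scores them,
`03_recovery_benchmark.R` repeats recovery over 20 seeded loci,
`04_comparative_identity.R` computes paralogue exon-identity matrices and
subclass votes, and `05_phylogeny_ighz_loss.R` builds the IGHZ subclass
tree (bootstrap, 65% collapse, clade labelling) and counts Dollo losses
on the shipped atherinomorph species tree. Outputs land in `results/`.

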