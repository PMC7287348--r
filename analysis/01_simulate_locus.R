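#!/usr/bin/env Rscript
# Simulate two contrasting IGH locus architectures with full ground truth:
# a killifish-like locus (24 VH, 14 DH, 17 JH; IGHM + IGHD only -- the
# IGHZ-free architecture) and a platyfish-like locus carrying two IGHZ
# constant regions. Writes FASTA and truth annotations under results/.

library(ighlocus)

dir.create("results", showWarnings = FALSE)
refs <- make_reference_library(seed = 1001)
write_sequences(refs, "results/reference_library.fa")

ighm6 <- c("Cm1", "Cm2", "Cm3", "Cm4", "TM1", "TM2")
ighd12 <- c("Cd1", "Cd2", "Cd3", "Cd4", "Cd2", "Cd3", "Cd4", "Cd5", "Cd6",
            "Cd7", "TM1", "TM2")
ighz6 <- c("Cz1", "Cz2", "Cz3", "Cz4", "TM1", "TM2")

# killifish-like: two subloci on opposite strands, no IGHZ
killi_cfg <- sim_config(n_vh = 12L, n_dh = 7L, n_jh = 9L,
                        ch_blueprints = list(IGHM = ighm6, IGHD = ighd12),
                        n_subloci = 2L, sublocus_strands = c("+", "-"),
                        seed = 2001)
killi <- generate_locus(killi_cfg, refs)

# platyfish-like: single configuration with two IGHZ constant regions
platy_cfg <- sim_config(n_vh = 24L, n_dh = 14L, n_jh = 15L,
                        ch_blueprints = list(IGHZ = ighz6, IGHM = ighm6,
                                             IGHD = ighd12, IGHZ = ighz6),
                        seed = 2002)
platy <- generate_locus(platy_cfg, refs)

for (nm in c("killi", "platy")) {
  gen <- get(nm)
  write_sequences(list(gen$locus), sprintf("results/%s_locus.fa", nm))
  write_annotations(gen$truth, sprintf("results/%s_truth.gff3", nm), "GFF3")
  write_annotations(gen$truth, sprintf("results/%s_truth.tsv", nm), "TSV")
  message(sprintf("%s locus: %d bp, %d planted features", nm,
                  nchar(gen$locus$residues), nrow(gen$truth)))
}
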