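#!/usr/bin/env Rscript
# Replicated end-to-end recovery benchmark: 20 seeded synthetic loci at
# per-site divergence 0.10, annotated blind and scored against truth.
# Writes the pooled per-class table under results/.

library(ighlocus)

bench <- recovery_benchmark(n_loci = 20L, base_seed = 301L)
pt <- as.data.frame(bench$per_type)
print(pt, digits = 4)
write.table(pt, "results/recovery_benchmark.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(bench$per_locus),
            "results/recovery_per_locus.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("CH exon boundaries exact in %.1f%% of recovered exons",
                100 * bench$ch_exact_frac))
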