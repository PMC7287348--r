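#!/usr/bin/env Rscript
# Cross-region exon identity statistics on the annotated platyfish-like
# locus: corresponding-exon identity between its two IGHZ constant regions
# (the paralogue comparison), and per-exon subclass votes of each region's
# Cz exons against labelled reference material. Writes TSV matrices.

library(ighlocus)

refs <- read_sequences("results/reference_library.fa", as_reference = TRUE)
refs$family <- ifelse(refs$segment_type == "VH",
                      sub(".*_(VH\\d+)$", "\\1", refs$id), NA)
locus <- read_sequences("results/platy_locus.fa")[[1]]
profiles <- build_segment_profiles(refs, seed = 11)
ann <- annotate_locus(locus, refs, profiles = profiles)

exons <- ann$segments[ann$segments$segment_type == "CH-exon", ]
z1 <- exons[exons$region == "IGHZ1", ]
z2 <- exons[exons$region == "IGHZ2", ]
m <- exon_identity_matrix(z1, z2)
write.table(round(m, 4), "results/ighz1_vs_ighz2_identity.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
message(sprintf(
  "mean corresponding-exon identity IGHZ1 vs IGHZ2: %.3f",
  attr(m, "corresponding_mean")))

# subclass votes against the synthetic reference species, treating each
# reference species' IGHZ exon set as a labelled subclass surrogate
zrefs <- refs[refs$segment_type == "CH" & refs$isotype == "IGHZ", ]
zrefs <- tibble::tibble(subclass = paste0("IGHZ_", toupper(zrefs$species)),
                        exon_label = zrefs$exon_label, seq = zrefs$residues)
for (rn in c("IGHZ1", "IGHZ2")) {
  zz <- exons[exons$region == rn & grepl("^Cz", exons$exon_label), ]
  if (!nrow(zz)) next
  votes <- per_exon_subclass_vote(zz, zrefs)
  write.table(as.data.frame(votes),
              sprintf("results/%s_subclass_votes.tsv", rn), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(rn, " votes: ", paste(votes$best, collapse = ", "))
}
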