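# Helpers to fabricate HSP and group rows without running a search.
mk_hit <- function(query_id, sstart, send, isotype = "IGHM",
                   exon_label = "Cm2", species = "sp1", strand = "+",
                   bitscore = 50, evalue = 1e-20) {
  tibble::tibble(query_id = query_id, species = species,
                 segment_type = "CH", isotype = isotype,
                 exon_label = exon_label, contig = "L", sstart = sstart,
                 send = send, strand = strand, qstart = 0L, qend = 10L,
                 score = bitscore, bitscore = bitscore, evalue = evalue,
                 identity = 0.9, matches = 9L, aln_len = 10L,
                 mismatches = 1L, gaps = 0L)
}

mk_group <- function(start, end, isotype = "IGHM", exon_label = "Cm2",
                     best_evalue = 1e-20, best_bitscore = 50,
                     n_ref_exons = 3L, strand = "+") {
  tibble::tibble(group_id = 1L, contig = "L", isotype = isotype,
                 exon_label = exon_label, strand = strand, start = start,
                 end = end, anchor_start = start, anchor_end = end,
                 best_evalue = best_evalue, best_bitscore = best_bitscore,
                 n_ref_exons = n_ref_exons, n_ref_species = 2L,
                 members = list(1L))
}

test_that("overlapping same-label hits collapse with member statistics", {
  hits <- dplyr::bind_rows(
    mk_hit("zf_Cm2", 100L, 400L, species = "zebrafish"),
    mk_hit("md_Cm2", 150L, 420L, species = "medaka"))
  g <- collapse_hsps(hits)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_ref_species, 2L)
  expect_identical(g$n_ref_exons, 2L)
  expect_identical(g$start, 100L)
  expect_identical(g$end, 420L)
  # an isolated hit forms a singleton group
  g2 <- collapse_hsps(mk_hit("zf_Cm3", 1000L, 1300L, exon_label = "Cm3"))
  expect_identical(nrow(g2), 1L)
  expect_length(g2$members[[1]], 1L)
})

test_that("collapsed groups equal brute-force overlap components", {
  skip_if_not_installed("igraph")
  set.seed(31)
  n <- 200L
  starts <- sample(0:5000, n, replace = TRUE)
  ends <- starts + sample(20:200, n, replace = TRUE)
  labs <- sample(c("IGHM.Cm1", "IGHM.Cm2", "IGHZ.Cz1"), n, replace = TRUE)
  iso <- sub("\\..*", "", labs); ex <- sub(".*\\.", "", labs)
  hits <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    mk_hit(paste0("q", i), starts[i], ends[i], isotype = iso[i],
           exon_label = ex[i])
  }))
  g <- collapse_hsps(hits)
  oracle <- overlap_components_oracle(starts, ends, labs)
  expect_identical(nrow(g), length(unique(oracle)))
  # membership partitions agree
  mine <- integer(n)
  for (k in seq_len(nrow(g))) mine[g$members[[k]]] <- k
  expect_identical(length(unique(paste(mine, oracle))),
                   length(unique(oracle)))
})

test_that("the primary filter applies the E-value and bitscore-gap rules", {
  cfg <- annotation_config()
  # E-value boundary: 1e-4 retained, 0.01 discarded
  g <- dplyr::bind_rows(mk_group(0L, 100L, best_evalue = 1e-4),
                        mk_group(500L, 600L, best_evalue = 0.01))
  kept <- filter_groups(g, cfg)
  expect_identical(kept$start, 0L)
  # bitscore gap 20 >= 16.5: the weaker different-label group is discarded
  g <- dplyr::bind_rows(
    mk_group(0L, 100L, exon_label = "Cm2", best_bitscore = 40),
    mk_group(50L, 150L, isotype = "IGHD", exon_label = "Cd1",
             best_bitscore = 60))
  kept <- filter_groups(g, cfg)
  expect_identical(kept$exon_label, "Cd1")
  # gap 10 < 16.5: both retained
  g$best_bitscore <- c(50, 60)
  expect_identical(nrow(filter_groups(g, cfg)), 2L)
  # same label groups never override each other
  g2 <- dplyr::bind_rows(mk_group(0L, 100L, best_bitscore = 40),
                         mk_group(50L, 150L, best_bitscore = 90))
  expect_identical(nrow(filter_groups(g2, cfg)), 2L)
})

test_that("the stringent pass requires E <= 1e-8 and >= 2 reference exons", {
  cfg <- annotation_config()
  g <- dplyr::bind_rows(
    mk_group(0L, 100L, best_evalue = 1e-9, n_ref_exons = 3L),
    mk_group(200L, 300L, best_evalue = 1e-7, n_ref_exons = 3L),
    mk_group(400L, 500L, best_evalue = 1e-12, n_ref_exons = 1L))
  kept <- filter_groups_stringent(g, cfg)
  expect_identical(kept$start, 0L)
})

test_that("filters are order-independent and monotone in the threshold", {
  set.seed(32)
  g <- dplyr::bind_rows(lapply(1:30, function(i) {
    mk_group(sample(0:2000, 1), sample(2100:4000, 1),
             isotype = sample(c("IGHM", "IGHD"), 1),
             exon_label = sample(c("Cm1", "Cd1"), 1),
             best_evalue = 10^sample(-12:0, 1),
             best_bitscore = runif(1, 20, 80),
             n_ref_exons = sample(1:3, 1))
  }))
  key <- function(x) sort(paste(x$start, x$end, x$isotype, x$exon_label))
  perm <- sample(nrow(g))
  expect_identical(key(filter_groups(g)), key(filter_groups(g[perm, ])))
  expect_identical(key(filter_groups_stringent(g)),
                   key(filter_groups_stringent(g[perm, ])))
  # raising the E-value ceiling never removes a previously retained group
  loose <- annotation_config(primary_evalue_max = 0.1)
  expect_true(all(key(filter_groups(g)) %in% key(filter_groups(g, loose))))
})

test_that("boundary refinement snaps to splice motifs", {
  set.seed(33)
  # build a locus with a planted exon in exact AG..GT context
  exon <- rand_seq(120)
  left <- paste0(rand_seq(200), "AG")
  locus <- locus_sequence("L", paste0(left, exon, "GT", rand_seq(200)))
  a <- nchar(left); b <- a + 120L
  # aligned boundary off by 3 nt on both sides still recovers exactly
  g <- mk_group(a - 3L, b + 3L)
  g$anchor_start <- a - 3L; g$anchor_end <- b + 3L
  seg <- refine_exon_boundaries(g, locus, mode = "internal")
  expect_identical(seg$start, a)
  expect_identical(seg$end, b)
  expect_identical(seg$seq, exon)
  # minus-strand group refines through the reverse complement
  rc_locus <- locus_sequence("L",
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(locus$residues))))
  Ltot <- nchar(locus$residues)
  gm <- g; gm$strand <- "-"
  gm$anchor_start <- Ltot - (b + 3L); gm$anchor_end <- Ltot - (a - 3L)
  segm <- refine_exon_boundaries(gm, rc_locus, mode = "internal")
  expect_identical(segm$start, Ltot - b)
  expect_identical(segm$end, Ltot - a)
  expect_identical(segm$seq, exon)
})

test_that("terminal secretory exons end at the polyadenylation signal", {
  set.seed(34)
  exon <- rand_seq(90)
  left <- paste0(rand_seq(150), "AG")
  tail40 <- gsub("AATAAA", "ACTAAA", rand_seq(40))
  locus <- locus_sequence("L", paste0(left, exon, tail40, "AATAAA",
                                      rand_seq(100)))
  a <- nchar(left); b <- a + 90L
  g <- mk_group(a, b)
  g$anchor_start <- a; g$anchor_end <- b
  seg <- refine_exon_boundaries(g, locus, mode = "terminal_secretory")
  # nucleotide sequence extends to and ends before the hexamer
  expect_identical(seg$end, b + 40L)
  expect_identical(substr(locus$residues, seg$end + 1L, seg$end + 6L),
                   "AATAAA")
  # no motif in range flags incomplete
  locus2 <- locus_sequence("L", paste0(left, exon,
                                       gsub("AATAAA", "ACTAAA",
                                            rand_seq(600))))
  seg2 <- refine_exon_boundaries(g, locus2, mode = "terminal_secretory")
  expect_true(ighlocus:::has_flag(seg2$flags, "incomplete"))
})

test_that("exons chain into regions per blueprint rules", {
  set.seed(35)
  mk_exons <- function(labels, isotype, start0 = 0L, gap = 300L,
                       len = 90L, seqs = NULL) {
    n <- length(labels)
    starts <- start0 + (seq_len(n) - 1L) * (len + gap)
    gene_segments(contig = "L", start = starts, end = starts + len,
                  strand = "+", segment_type = "CH-exon", isotype = isotype,
                  exon_label = labels,
                  seq = if (is.null(seqs)) rep(strrep("GCT", len / 3), n)
                        else seqs)
  }
  locus <- locus_sequence("L", rand_seq(20000))
  # six Cz exons in order -> one complete IGHZ region
  z <- mk_exons(c("Cz1", "Cz2", "Cz3", "Cz4", "TM1", "TM2"), "IGHZ")
  res <- assemble_constant_regions(z, locus)
  expect_identical(nrow(res$regions), 1L)
  expect_true(res$regions$complete)
  expect_false(res$regions$pseudogene)
  expect_identical(classify_ighz_status(res$regions)$status, "present")
  # a lone TM1 with an internal stop: incomplete pseudogene remnant
  tm <- mk_exons("TM1", "IGHZ", seqs = paste0("GCTTAA", strrep("GCT", 28)))
  res2 <- assemble_constant_regions(tm, locus)
  expect_false(res2$regions$complete)
  expect_true(res2$regions$pseudogene)
  expect_identical(classify_ighz_status(res2$regions)$status,
                   "pseudogene_remnant")
  # duplicated Cd2-Cd3-Cd4 block stays one 12-exon IGHD region
  d <- mk_exons(c("Cd1", "Cd2", "Cd3", "Cd4", "Cd2", "Cd3", "Cd4", "Cd5",
                  "Cd6", "Cd7", "TM1", "TM2"), "IGHD")
  res3 <- assemble_constant_regions(d, locus)
  expect_identical(nrow(res3$regions), 1L)
  expect_identical(res3$regions$n_exons, 12L)
  expect_true(res3$regions$complete)
  # an order violation splits the region and flags both parts
  bad <- mk_exons(c("Cm3", "Cm1"), "IGHM")
  res4 <- assemble_constant_regions(bad, locus)
  expect_identical(nrow(res4$regions), 2L)
  expect_true(all(ighlocus:::has_flag(res4$exons$flags, "manually_flagged")))
  # a gap beyond max_intron_gap starts a new region
  far <- mk_exons(c("Cm1", "Cm2"), "IGHM", gap = 20000L)
  locus_big <- locus_sequence("L", strrep("ACGT", 20000))
  res5 <- assemble_constant_regions(far, locus_big)
  expect_identical(nrow(res5$regions), 2L)
})

test_that("IGHZ status classification covers present, remnant and absent", {
  reg <- function(iso, complete, pseudo) {
    tibble::tibble(name = paste0(iso, "1"), contig = "L", isotype = iso,
                   strand = "+", start = 0L, end = 100L, n_exons = 6L,
                   complete = complete, pseudogene = pseudo)
  }
  two <- dplyr::bind_rows(reg("IGHZ", TRUE, FALSE), reg("IGHZ", TRUE, FALSE))
  st <- classify_ighz_status(two)
  expect_identical(st$status, "present")
  expect_identical(st$count, 2L)
  st2 <- classify_ighz_status(reg("IGHZ", FALSE, TRUE))
  expect_identical(st2$status, "pseudogene_remnant")
  st3 <- classify_ighz_status(reg("IGHM", TRUE, FALSE))
  expect_identical(st3$status, "absent")
})
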