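test_that("profile columns follow the log-odds closed form", {
  # two identical sequences, invariant columns: score for the observed base
  # is log2(((n + p) / (n + 4p)) / 0.25) with pseudocount p = 1
  aln <- c("AAAA", "AAAA")
  prof <- build_profile(aln, pseudocount = 1, null_bp = 1e4, seed = 1)
  expect_equal(unname(prof$pssm["A", 1]), log2(((2 + 1) / (2 + 4)) / 0.25))
  expect_equal(unname(prof$pssm["C", 1]), log2(((0 + 1) / (2 + 4)) / 0.25))
  # majority-gap columns are dropped
  aln2 <- c("A-CG", "A--G", "ATCG")
  prof2 <- build_profile(aln2, null_bp = 1e4, seed = 1)
  expect_identical(prof2$consensus_len, 3L)
  expect_error(build_profile(c("AC", "ACG")), "ragged")
})

test_that("a profile scores its consensus at least as high as mutants", {
  set.seed(41)
  ref <- rand_seq(120)
  prof <- build_profile(c(ref, ref, ref), null_bp = 1e4, seed = 1)
  score_of <- function(s) {
    ighlocus:::cpp_pssm_scan(prof$pssm, ighlocus:::dna_encode(s),
                             -1e9)$score[1]
  }
  s_ref <- score_of(ref)
  for (i in 1:5) {
    mut <- as.character(mutate_sequence(ref, 0.1, seed = i))
    if (nchar(mut) == nchar(ref)) expect_lte(score_of(mut), s_ref)
  }
})

test_that("the calibrated threshold keeps null hits near the budget", {
  set.seed(42)
  refs <- make_reference_library(seed = 7)
  jh <- refs[refs$segment_type == "JH", ]
  aln <- progressive_msa(setNames(jh$residues, jh$id))
  prof <- build_profile(aln, locus_len = 5e4, null_bp = 4e5, seed = 3)
  hits_per_rep <- vapply(1:20, function(i) {
    null_locus <- rand_seq(5e4)
    nrow(scan_profile(prof, locus_sequence("N", null_locus)))
  }, numeric(1))
  # budget is 0.01 expected hits per locus length; allow estimation slack
  expect_lte(mean(hits_per_rep), 0.1)
})

test_that("profile scan detects planted copies on both strands", {
  set.seed(43)
  refs <- make_reference_library(seed = 7)
  vh1 <- refs[refs$segment_type == "VH" & refs$family == "VH1", ]
  aln <- progressive_msa(setNames(vh1$residues, vh1$id))
  prof <- build_profile(aln, locus_len = 2e4, null_bp = 2e5, seed = 3)
  planted <- as.character(mutate_sequence(vh1$residues[1], 0.15, seed = 9))
  bg <- rand_seq(20000)
  at <- 8000L
  fwd <- paste0(substr(bg, 1, at), planted, substr(bg, at + 1, nchar(bg)))
  cand <- scan_profile(prof, locus_sequence("L", fwd))
  expect_gte(nrow(cand), 1L)
  best <- cand[which.max(cand$score), ]
  ov <- min(best$anchor_end, at + nchar(planted)) - max(best$anchor_start, at)
  expect_gte(ov / nchar(planted), 0.9)
  expect_identical(best$strand, "+")
  # reverse-complemented planting lands on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(planted)))
  rev <- paste0(substr(bg, 1, at), rc, substr(bg, at + 1, nchar(bg)))
  cand2 <- scan_profile(prof, locus_sequence("L", rev))
  expect_identical(cand2$strand[which.max(cand2$score)], "-")
})

test_that("VH and JH boundaries refine on RSS heptamer and GTA motifs", {
  set.seed(44)
  cfg <- annotation_config()
  # VH: exact heptamer 12 nt downstream of the anchor end
  body <- rand_seq(300)
  locus <- locus_sequence("L", paste0(rand_seq(100), body, rand_seq(12),
                                      "CACAGTG", rand_seq(100)))
  cand <- tibble::tibble(contig = "L", start = 60L, end = 440L,
                         anchor_start = 100L, anchor_end = 400L,
                         score = 50, strand = "+", segment_type = "VH")
  seg <- refine_segment_boundaries(cand, "VH", locus, cfg)
  expect_identical(seg$end, 412L)  # first base of the heptamer
  # JH: upstream opposite-sense heptamer and downstream GTA
  jh <- rand_seq(60)
  locus2 <- locus_sequence("L", paste0(rand_seq(80), "ACAAAAACC",
                                       rand_seq(23), "CACTGTG", jh,
                                       "GTAAGT", rand_seq(80)))
  a <- 80L + 9L + 23L + 7L
  cand2 <- tibble::tibble(contig = "L", start = a - 40L, end = a + 100L,
                          anchor_start = a + 2L, anchor_end = a + 60L,
                          score = 50, strand = "+", segment_type = "JH")
  seg2 <- refine_segment_boundaries(cand2, "JH", locus2, cfg)
  expect_identical(seg2$start, a)
  expect_identical(seg2$end, a + 60L)
  expect_identical(seg2$seq, jh)
})

test_that("refined VH 3' ends equal planted coding ends almost always", {
  refs <- make_reference_library(seed = 7)
  profiles <- build_segment_profiles(refs, locus_len = 1e5, seed = 2)
  hits <- 0L; total <- 0L
  for (s in 1:4) {
    gen <- generate_locus(sim_config(n_vh = 25L, n_dh = 0L, n_jh = 0L,
                                     ch_blueprints = list(), seed = 500 + s),
                          refs)
    ann <- annotate_locus(gen$locus, refs, profiles = profiles)
    vh <- ann$segments[ann$segments$segment_type == "VH", ]
    truth <- gen$truth[gen$truth$segment_type == "VH", ]
    for (i in seq_len(nrow(truth))) {
      j <- which(abs(vh$start - truth$start[i]) < 50)
      if (length(j)) {
        total <- total + 1L
        hits <- hits + (vh$end[j[1]] == truth$end[i])
      }
    }
  }
  expect_gte(total, 90L)
  expect_gte(hits / total, 0.95)
})

test_that("DH scanner reports exact plantings and honours the budget", {
  set.seed(45)
  cfg <- annotation_config()
  hept <- "CACAGTG"; nona <- "ACAAAAACC"
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  core <- rand_seq(15)
  pat <- paste0(rc(nona), rand_seq(12), rc(hept), core, hept,
                rand_seq(12), nona)
  locus <- locus_sequence("L", paste0(rand_seq(2000), pat, rand_seq(2000)))
  dh <- scan_dh_rss(locus, cfg)
  expect_identical(nrow(dh), 1L)
  expect_identical(dh$mismatches, 0L)
  expect_identical(dh$seq, core)
  expect_identical(dh$start, 2000L + 9L + 12L + 7L)
  # nine mismatches across the pattern: never reported
  mutate_k <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(v), k)
    for (i in idx) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  # distribute 9 mismatches over the two nonamers (anchors stay intact)
  pat9 <- paste0(mutate_k(rc(nona), 5), rand_seq(12), rc(hept), core, hept,
                 rand_seq(12), mutate_k(nona, 4))
  locus9 <- locus_sequence("L", paste0(rand_seq(500), pat9, rand_seq(500)))
  expect_identical(nrow(scan_dh_rss(locus9, cfg)), 0L)
  # eight mismatches: reported
  pat8 <- paste0(mutate_k(rc(nona), 4), rand_seq(12), rc(hept), core, hept,
                 rand_seq(12), mutate_k(nona, 4))
  locus8 <- locus_sequence("L", paste0(rand_seq(500), pat8, rand_seq(500)))
  expect_identical(nrow(scan_dh_rss(locus8, cfg)), 1L)
  # the stringent pass drops candidates lacking the CAC/GTG anchors
  pat_bad <- sub("^(.{28})CAC", "\\1AAC",
                 paste0(rc(nona), rand_seq(12), rc(hept), core,
                        sub("^CAC", "TAC", hept), rand_seq(12), nona))
  locus_bad <- locus_sequence("L", paste0(rand_seq(500),
                                          paste0(rc(nona), rand_seq(12),
                                                 rc(hept), core,
                                                 sub("^CAC", "TAC", hept),
                                                 rand_seq(12), nona),
                                          rand_seq(500)))
  expect_identical(nrow(scan_dh_rss(locus_bad, cfg, stringent = TRUE)), 0L)
  expect_gte(nrow(scan_dh_rss(locus_bad, cfg, stringent = FALSE)), 1L)
})

test_that("DH scanner equals the sliding-window Hamming oracle", {
  set.seed(46)
  cfg <- annotation_config(dh_core_min = 10L, dh_core_max = 20L)
  hept <- "CACAGTG"; nona <- "ACAAAAACC"
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  bg <- rand_seq(50000)
  pieces <- character(); pos <- 0L
  mutate_k <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in sample(seq_along(v), k)) {
      v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    }
    paste(v, collapse = "")
  }
  for (p in 1:5) {
    at <- 8000 * p
    core <- rand_seq(sample(10:20, 1))
    mm <- sample(0:8, 1)
    pat <- paste0(mutate_k(rc(nona), ceiling(mm / 2)), rand_seq(12),
                  rc(hept), core, hept, rand_seq(12),
                  mutate_k(nona, floor(mm / 2)))
    bg <- paste0(substr(bg, 1, at), pat, substr(bg, at + 1, nchar(bg)))
  }
  locus <- locus_sequence("L", bg)
  mine <- scan_dh_rss(locus, cfg, stringent = FALSE, resolve = FALSE)
  oracle <- dh_scan_oracle(bg, core_min = 10L, core_max = 20L)
  key <- function(s, e, m) sort(paste(s, e, m))
  expect_identical(key(mine$start, mine$end, mine$mismatches),
                   key(oracle$core_start, oracle$core_end,
                       oracle$mismatches))
})

test_that("single-linkage families equal thresholded graph components", {
  skip_if_not_installed("igraph")
  cfg <- annotation_config()
  # identities A-B 85%, B-C 82%, A-C 67%: one chained family
  base <- strrep("ACGTT", 20)
  mutate_at <- function(s, idx) {
    v <- strsplit(s, "")[[1]]
    for (i in idx) v[i] <- chartr("ACGT", "CAGT", v[i])
    # ensure an actual change at every position
    w <- strsplit(s, "")[[1]]
    for (i in idx) v[i] <- setdiff(c("A", "C", "G", "T"), w[i])[1]
    paste(v, collapse = "")
  }
  A <- base
  B <- mutate_at(A, 1:15)
  C <- mutate_at(B, 16:33)
  segs <- gene_segments(contig = "L", start = c(0L, 200L, 400L),
                        end = c(100L, 300L, 500L), segment_type = "VH",
                        name = c("a", "b", "c"), seq = c(A, B, C))
  fam <- cluster_vh_families(segs, cfg)
  expect_identical(fam$family, rep("1", 3))
  # all pairwise identities < 80%: four singleton families
  set.seed(47)
  segs2 <- gene_segments(contig = "L", start = (0:3) * 200L,
                         end = (0:3) * 200L + 100L, segment_type = "VH",
                         name = letters[1:4],
                         seq = vapply(1:4, function(i) rand_seq(100),
                                      character(1)))
  fam2 <- cluster_vh_families(segs2, cfg)
  expect_identical(sort(fam2$family), c("1", "2", "3", "4"))
  # 30 random segments: components match igraph on the identity graph
  set.seed(48)
  anc <- replicate(5, rand_seq(90))
  seqs <- vapply(1:30, function(i) {
    as.character(mutate_sequence(anc[1 + (i %% 5)], runif(1, 0, 0.25),
                                 seed = i))
  }, character(1))
  segs3 <- gene_segments(contig = "L", start = (0:29) * 200L,
                         end = (0:29) * 200L + 90L, segment_type = "VH",
                         name = paste0("v", 1:30), seq = seqs)
  fam3 <- cluster_vh_families(segs3, cfg)
  idm <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j) {
    pairwise_identity(seqs[i], seqs[j])
  }))
  g <- igraph::graph_from_adjacency_matrix(idm >= 0.80, mode = "undirected")
  oracle <- igraph::components(g)$membership
  expect_identical(length(unique(fam3$family)), length(unique(oracle)))
  expect_identical(length(unique(paste(fam3$family, oracle))),
                   length(unique(oracle)))
  # partition is invariant to input order
  perm <- sample(30)
  fam3p <- cluster_vh_families(segs3[perm, ], cfg)
  expect_identical(length(unique(paste(fam3p$family, oracle[perm]))),
                   length(unique(oracle)))
  # lowering the threshold only merges families
  fam_lo <- cluster_vh_families(segs3, annotation_config(
    vh_family_identity = 0.6))
  for (f in unique(fam3$family)) {
    members <- which(fam3$family == f)
    expect_identical(length(unique(fam_lo$family[members])), 1L)
  }
})

test_that("segment names are positional and stable under permutation", {
  segs <- gene_segments(contig = "L",
                        start = c(0L, 200L, 400L, 700L, 900L),
                        end = c(100L, 300L, 500L, 760L, 960L),
                        segment_type = c("VH", "VH", "VH", "JH", "JH"),
                        family = c("1", "1", "1", NA, NA),
                        name = NA, seq = NA)
  named <- assign_segment_names(segs)
  expect_identical(named$name[1:3], c("VH1.1", "VH1.2", "VH1.3"))
  expect_identical(named$name[4:5], c("JH1", "JH2"))
  perm <- c(3L, 5L, 1L, 4L, 2L)
  named2 <- assign_segment_names(segs[perm, ])
  expect_identical(named2$name[order(named2$start)],
                   named$name[order(named$start)])
})
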