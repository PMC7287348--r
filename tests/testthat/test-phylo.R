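test_that("Cz exons concatenate in rank order with a presence mask", {
  exons <- tibble::tibble(
    region = c(rep("Z1", 4), rep("Z2", 3)),
    exon_label = c("Cz4", "Cz1", "Cz3", "Cz2", "Cz1", "Cz3", "Cz4"),
    seq = c(strrep("T", 310), strrep("A", 300), strrep("G", 320),
            strrep("C", 330), strrep("A", 300), strrep("G", 320),
            strrep("T", 310)))
  cat1 <- concatenate_cz(exons)
  expect_identical(nchar(cat1[["Z1"]]), 300L + 330L + 320L + 310L)
  # shuffled input still yields Cz1 -> Cz4 order
  expect_identical(substr(cat1[["Z1"]], 1, 300), strrep("A", 300))
  expect_identical(substr(cat1[["Z1"]], 631, 950), strrep("G", 320))
  # missing exon contributes nothing and is recorded in the mask
  expect_identical(nchar(cat1[["Z2"]]), 930L)
  mask <- attr(cat1, "presence")
  expect_false(mask["Z2", "Cz2"])
  # a region with no requested exons is excluded with a warning
  exons2 <- dplyr::bind_rows(exons, tibble::tibble(
    region = "Z3", exon_label = "TM1", seq = "ACGT"))
  expect_warning(concatenate_cz(exons2), "excluded")
})

test_that("Jukes-Cantor distances follow the closed form", {
  expect_equal(jc_distance(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_equal(round(jc_distance(0.1), 4), 0.1073)
  set.seed(61)
  a <- rand_seq(1000)
  av <- strsplit(a, "")[[1]]
  idx <- sample(1000, 100)
  bv <- av
  for (i in idx) bv[i] <- setdiff(c("A", "C", "G", "T"), av[i])[1]
  res <- align_and_distance(setNames(
    c(a, paste(bv, collapse = ""), a), c("x", "y", "z")))
  expect_equal(res$distances["x", "z"], 0)
  # the aligner may trade a couple of mismatches for gaps; the distance
  # stays within a fraction of a percent of the ungapped closed form
  expect_equal(res$distances["x", "y"], jc_distance(0.1), tolerance = 0.05)
  expect_equal(res$distances, t(res$distances))
})

test_that("alignment distances track simulation down a known tree", {
  skip_if_not_installed("phangorn")
  set.seed(62)
  tree <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.15))
  dat <- as.character(phangorn::simSeq(tree, l = 2000))
  seqs <- setNames(apply(dat, 1, function(x) {
    paste(toupper(x), collapse = "")
  }), rownames(dat))
  res <- align_and_distance(seqs)
  true_d <- ape::cophenetic.phylo(tree)[rownames(res$distances),
                                        colnames(res$distances)]
  off <- upper.tri(true_d)
  expect_lt(max(abs(res$distances[off] - true_d[off])), 0.05)
})

test_that("neighbour joining solves three taxa exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  # three-point formulas: a = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ recovers additive trees and tolerates taxon permutation", {
  skip_if_not_installed("phangorn")
  set.seed(63)
  for (i in 1:10) {
    tree <- ape::rtree(6, br = function(n) runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(tree)
    est <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tree), est), 0)
    # no negative branch lengths after clamping
    expect_true(all(est$edge.length >= 0))
    perm <- sample(rownames(d))
    est2 <- nj_tree(d[perm, perm])
    expect_equal(phangorn::RF.dist(est, est2), 0)
  }
})

test_that("bootstrap supports behave at B = 1 and on conserved clades", {
  set.seed(64)
  # strongly structured alignment: two clean clades
  base1 <- rand_seq(400); base2 <- rand_seq(400)
  seqs <- c(a1 = base1,
            a2 = as.character(mutate_sequence(base1, 0.02, seed = 1)),
            a3 = as.character(mutate_sequence(base1, 0.02, seed = 2)),
            b1 = base2,
            b2 = as.character(mutate_sequence(base2, 0.02, seed = 3)))
  aln <- progressive_msa(seqs)
  t1 <- bootstrap_support(aln, B = 1L, seed = 5)
  sup1 <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
  t2 <- bootstrap_support(aln, B = 50L, seed = 5)
  sup2 <- suppressWarnings(as.numeric(t2$node.label))
  # the clade-defining split is fully supported
  expect_true(any(sup2 == 100, na.rm = TRUE))
  # same seed reproduces supports exactly
  t3 <- bootstrap_support(aln, B = 50L, seed = 5)
  expect_identical(t2$node.label, t3$node.label)
})

test_that("support collapsing respects the 65% boundary and is idempotent", {
  # caterpillar 5-taxon tree with supports written as node labels
  tr <- ape::read.tree(text = "((((a,b)90,c)65,d)64,e)root;")
  tr$edge.length <- rep(1, nrow(tr$edge))
  col <- collapse_low_support(tr, 65)
  # node at 64 collapses, 65 and 90 survive
  expect_identical(col$Nnode, tr$Nnode - 1L)
  remaining <- suppressWarnings(as.numeric(col$node.label))
  expect_false(any(remaining == 64, na.rm = TRUE))
  expect_true(all(c(65, 90) %in% remaining))
  # idempotent
  col2 <- collapse_low_support(col, 65)
  expect_identical(col2$Nnode, col$Nnode)
  expect_identical(ape::write.tree(col2), ape::write.tree(col))
  # all supports 100: unchanged; all 0: star tree
  tr2 <- tr
  tr2$node.label <- ifelse(is.na(suppressWarnings(
    as.numeric(tr$node.label))), tr$node.label, "100")
  expect_identical(collapse_low_support(tr2, 65)$Nnode, tr$Nnode)
  tr3 <- tr
  tr3$node.label <- ifelse(is.na(suppressWarnings(
    as.numeric(tr$node.label))), tr$node.label, "0")
  expect_identical(collapse_low_support(tr3, 65)$Nnode, 1L)
  # tip depths are preserved through collapsing
  d0 <- ape::node.depth.edgelength(tr)[1:5]
  d1 <- ape::node.depth.edgelength(collapse_low_support(tr, 65))[1:5]
  expect_equal(d0, d1)
})

test_that("subclass labelling finds multi-species clades below the root", {
  set.seed(1)
  # three subclass ancestors radiate star-like from a common ancestor
  # (zero-length deep edges), members within each subclass from 4 species;
  # two related outgroup sequences
  base <- rand_seq(600)
  anc <- lapply(1:3, function(k) {
    as.character(mutate_sequence(base, 0.15, seed = 100 + k))
  })
  seqs <- c(); species <- c()
  for (k in 1:3) {
    for (sp in 1:4) {
      nm <- paste0("sp", sp, "_Z", k)
      seqs[nm] <- as.character(mutate_sequence(anc[[k]], 0.04,
                                               seed = 10 + 4 * k + sp))
      species[nm] <- paste0("sp", sp)
    }
  }
  out_anc <- as.character(mutate_sequence(base, 0.3, seed = 7))
  for (o in 1:2) {
    nm <- paste0("out", o)
    seqs[nm] <- as.character(mutate_sequence(out_anc, 0.05, seed = 9 + o))
    species[nm] <- paste0("outsp", o)
  }
  aln <- progressive_msa(seqs)
  tr <- bootstrap_support(aln, B = 50L, seed = 3)
  col <- collapse_low_support(tr, 65)
  labels <- assign_subclasses(col, outgroup = c("out1", "out2"),
                              species = species)
  ing <- setdiff(names(seqs), c("out1", "out2"))
  expect_identical(length(unique(labels[ing])), 3L)
  for (k in 1:3) {
    members <- paste0("sp", 1:4, "_Z", k)
    expect_identical(length(unique(labels[members])), 1L)
  }
  # a single-species clade gets no label
  seqs2 <- seqs[c(paste0("sp1_Z", 1:3), "out1", "out2")]
  species2 <- species[names(seqs2)]
  aln2 <- progressive_msa(seqs2)
  tr2 <- bootstrap_support(aln2, B = 20L, seed = 3)
  lab2 <- assign_subclasses(tr2, outgroup = c("out1", "out2"),
                            species = species2)
  expect_true(all(lab2[paste0("sp1_Z", 1:3)] == "none"))
})

test_that("Dollo losses count maximal all-absent subtrees", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  all_p <- setNames(rep("present", 6), letters[1:6])
  expect_identical(dollo_min_losses(tr, all_p)$losses, 0L)
  all_a <- setNames(rep("absent", 6), letters[1:6])
  expect_identical(dollo_min_losses(tr, all_a)$losses, 1L)
  one_clade <- all_p; one_clade[c("a", "b")] <- "absent"
  res <- dollo_min_losses(tr, one_clade)
  expect_identical(res$losses, 1L)
  expect_error(dollo_min_losses(tr, all_p[-1]), "missing")
})

test_that("Dollo counts match exhaustive enumeration on random trees", {
  set.seed(66)
  for (i in 1:6) {
    tr <- ape::rtree(8)
    states <- setNames(sample(c("present", "absent"), 8, replace = TRUE,
                              prob = c(0.6, 0.4)), tr$tip.label)
    if (all(states == "present")) states[1] <- "absent"
    mine <- dollo_min_losses(tr, states)$losses
    expect_identical(mine, as.integer(dollo_oracle(tr, states)))
  }
})

test_that("the shipped atherinomorph cladogram implies three IGHZ losses", {
  tree <- ape::read.tree(system.file("extdata",
                                     "atherinomorph_species_tree.nwk",
                                     package = "ighlocus"))
  states <- read_presence_states(system.file(
    "extdata", "atherinomorph_ighz_status.tsv", package = "ighlocus"))
  res <- dollo_min_losses(tree, states)
  expect_identical(res$losses, 3L)
  # the three loss lineages: medaka, the N. furzeri clade, A. limnaeus
  expect_true("Oryzias_latipes" %in% res$loss_edges)
  expect_true("Austrofundulus_limnaeus" %in% res$loss_edges)
})
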