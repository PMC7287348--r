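# Seeded local alignment search: exact word seeds grouped by diagonal, each
# cluster extended by a windowed affine-gap Smith-Waterman. Both strands are
# searched; hits are deterministic given inputs (ties ordered by subject
# start, then query id).

#' Local alignment search of reference segments against a locus
#'
#' @param queries A reference-segment tibble (see [reference_segments()]) or
#'   a named character vector of query sequences.
#' @param subject A [locus_sequence()] (or plain nucleotide string).
#' @param scheme A [scoring_scheme()]. For amino-acid queries the search runs
#'   in translated three-frame mode with [scoring_scheme_aa()].
#' @param word_size Exact-match seed length (>= 4; default 11 nt, 4 aa).
#' @param report_evalue Reporting threshold: hits with E above this are not
#'   returned. The downstream filters do the real work, so this is
#'   deliberately permissive.
#' @return A tibble of HSPs with 0-based half-open plus-strand subject
#'   coordinates (`sstart`, `send`), query span, raw score, bitscore,
#'   E-value and identity fraction over aligned columns.
#' @export
local_search <- function(queries, subject, scheme = scoring_scheme(),
                         word_size = NULL, report_evalue = 10) {
  subject <- as_locus(subject)
  if (is.data.frame(queries)) {
    qtab <- queries
  } else {
    qtab <- tibble::tibble(id = names(queries), species = NA_character_,
                           segment_type = NA_character_, isotype = "none",
                           exon_label = "none",
                           residues = toupper(unname(queries)),
                           alphabet = "nt")
  }
  if (nrow(qtab) == 0L) return(empty_hsps())
  alph <- unique(qtab$alphabet)
  if (length(alph) != 1L) {
    stop("mixed query alphabets in one search", call. = FALSE)
  }
  if (alph == "aa") {
    if (is.null(word_size)) word_size <- 4L
    return(local_search_translated(qtab, subject, word_size, report_evalue))
  }
  if (is.null(word_size)) word_size <- 11L
  if (word_size < 4L) stop("word_size must be >= 4", call. = FALSE)
  n <- nchar(subject$residues)
  if (n < word_size) stop("subject shorter than word size", call. = FALSE)
  if (any(grepl("[^ACGTN]", qtab$residues))) {
    stop("nucleotide search requires nucleotide queries (alphabet mismatch)",
         call. = FALSE)
  }
  subj_enc <- dna_encode(subject$residues)
  out <- list()
  for (strand in c("+", "-")) {
    qres <- if (strand == "+") qtab$residues else revcomp(qtab$residues)
    qenc <- lapply(qres, dna_encode)
    raw <- cpp_seed_extend(qenc, subj_enc, scheme$submat,
                           scheme$gap_open, scheme$gap_extend,
                           as.integer(word_size), nletters = 4L,
                           min_score = 2 * word_size, diag_band = 12L,
                           max_window = 20000L)
    if (!nrow(raw)) next
    qlen <- nchar(qtab$residues)[raw$query]
    # map query span back to the original (plus) orientation of the query
    qs <- raw$qstart; qe <- raw$qend
    if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
    ev <- compute_evalue(raw$score, qlen, n, scheme)
    out[[strand]] <- tibble::tibble(
      query_id = qtab$id[raw$query],
      species = qtab$species[raw$query],
      segment_type = qtab$segment_type[raw$query],
      isotype = qtab$isotype[raw$query],
      exon_label = qtab$exon_label[raw$query],
      contig = subject$id,
      sstart = raw$sstart, send = raw$send, strand = strand,
      qstart = qs, qend = qe,
      score = raw$score, bitscore = bitscore(raw$score, scheme),
      evalue = ev,
      identity = raw$matches / raw$aln_len,
      matches = raw$matches, aln_len = raw$aln_len,
      mismatches = raw$aln_len - raw$matches - raw$gaps, gaps = raw$gaps)
  }
  hits <- dplyr::bind_rows(out)
  if (!nrow(hits)) return(empty_hsps())
  hits <- hits[hits$evalue <= report_evalue, , drop = FALSE]
  hits <- dedupe_hsps(hits)
  hits[order(hits$sstart, hits$query_id, hits$strand, method = "radix"), ]
}

empty_hsps <- function() {
  tibble::tibble(query_id = character(), species = character(),
                 segment_type = character(), isotype = character(),
                 exon_label = character(), contig = character(),
                 sstart = integer(), send = integer(), strand = character(),
                 qstart = integer(), qend = integer(), score = numeric(),
                 bitscore = numeric(), evalue = numeric(),
                 identity = numeric(), matches = integer(),
                 aln_len = integer(), mismatches = integer(),
                 gaps = integer())
}

# Collapse near-duplicate HSPs of the same query/strand (seed clusters split
# by indels can re-find the same local optimum): keep the best-scoring HSP
# among those sharing > 50% of the shorter interval.
dedupe_hsps <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  grp <- paste(hits$query_id, hits$strand)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    idx <- idx[order(-hits$score[idx])]
    for (i in seq_along(idx)[-1]) {
      a <- idx[i]
      for (j in idx[seq_len(i - 1L)]) {
        if (!keep[j]) next
        ov <- min(hits$send[a], hits$send[j]) -
          max(hits$sstart[a], hits$sstart[j])
        shorter <- min(hits$send[a] - hits$sstart[a],
                       hits$send[j] - hits$sstart[j])
        if (ov > 0.5 * shorter) { keep[a] <- FALSE; break }
      }
    }
  }
  hits[keep, , drop = FALSE]
}

# Translated three-frame search: amino-acid queries against the six
# translation frames of the subject, BLOSUM62 scoring, coordinates mapped
# back to nucleotides.
local_search_translated <- function(qtab, subject, word_size,
                                    report_evalue) {
  scheme <- scoring_scheme_aa()
  aa_letters <- rownames(scheme$submat)
  aa_encode <- function(s) {
    v <- match(strsplit(s, "")[[1]], aa_letters) - 1L
    v[is.na(v)] <- length(aa_letters) - 1L  # X row
    v
  }
  n <- nchar(subject$residues)
  qenc <- lapply(qtab$residues, aa_encode)
  out <- list()
  for (strand in c("+", "-")) {
    sres <- oriented_residues(subject, strand)
    for (frame in 0:2) {
      aa <- translate_nt(substr(sres, frame + 1L, nchar(sres)))
      if (nchar(aa) < word_size) next
      raw <- cpp_seed_extend(qenc, aa_encode(aa), scheme$submat,
                             scheme$gap_open, scheme$gap_extend,
                             as.integer(word_size),
                             nletters = length(aa_letters) - 1L,
                             min_score = 25, diag_band = 6L,
                             max_window = 10000L)
      if (!nrow(raw)) next
      # oriented nt coords of the aa hit
      os <- frame + 3L * raw$sstart
      oe <- frame + 3L * raw$send
      if (strand == "-") { tmp <- os; os <- n - oe; oe <- n - tmp }
      qlen <- nchar(qtab$residues)[raw$query]
      ev <- compute_evalue(raw$score, qlen, floor(n / 3), scheme)
      out[[paste(strand, frame)]] <- tibble::tibble(
        query_id = qtab$id[raw$query], species = qtab$species[raw$query],
        segment_type = qtab$segment_type[raw$query],
        isotype = qtab$isotype[raw$query],
        exon_label = qtab$exon_label[raw$query],
        contig = subject$id, sstart = os, send = oe, strand = strand,
        qstart = raw$qstart, qend = raw$qend, score = raw$score,
        bitscore = bitscore(raw$score, scheme), evalue = ev,
        identity = raw$matches / raw$aln_len, matches = raw$matches,
        aln_len = raw$aln_len,
        mismatches = raw$aln_len - raw$matches - raw$gaps, gaps = raw$gaps)
    }
  }
  hits <- dplyr::bind_rows(out)
  if (!nrow(hits)) return(empty_hsps())
  hits <- hits[hits$evalue <= report_evalue, , drop = FALSE]
  hits <- dedupe_hsps(hits)
  hits[order(hits$sstart, hits$query_id, hits$strand, method = "radix"), ]
}

#' Screen candidate scaffolds by their gene-segment hits
#'
#' A scaffold is retained if its hits cover at least
#' `scaffold_min_segment_types` distinct segment types, or if hits of a
#' single type jointly cover at least `scaffold_min_coverage_frac` of the
#' scaffold length (interval union, so overlapping hits never inflate
#' coverage). Scaffolds with no hits are discarded.
#'
#' @param scaffolds A list of [locus_sequence()] objects.
#' @param hits An HSP tibble from [local_search()] (column `contig` keys the
#'   scaffold).
#' @param config An [annotation_config()].
#' @return Character vector of retained scaffold ids.
#' @export
screen_scaffolds <- function(scaffolds, hits, config = annotation_config()) {
  keep <- character()
  for (sc in scaffolds) {
    h <- hits[hits$contig == sc$id, , drop = FALSE]
    if (!nrow(h)) next
    ntypes <- length(unique(h$segment_type))
    if (ntypes >= config$scaffold_min_segment_types) {
      keep <- c(keep, sc$id)
    } else {
      cov <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = h$sstart + 1L, end = h$send))))
      if (cov / nchar(sc$residues) >= config$scaffold_min_coverage_frac) {
        keep <- c(keep, sc$id)
      }
    }
  }
  keep
}
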