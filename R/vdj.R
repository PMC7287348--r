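# Variable-region discovery: boundary refinement of profile candidates on
# RSS and splice motifs, DH detection by the opposite-sense RSS pattern,
# single-linkage VH family clustering, and positional naming.

# Positions (0-based) of matches to `motif` in `s` with at most `max_mm`
# mismatches, within [lo, hi) (bounds on the match start).
fuzzy_positions <- function(s, motif, max_mm, lo, hi) {
  w <- nchar(motif)
  lo <- max(0L, lo); hi <- min(nchar(s) - w, hi)
  if (hi < lo) return(integer())
  mot <- strsplit(motif, "")[[1]]
  pos <- lo:hi
  keep <- vapply(pos, function(p) {
    sum(strsplit(substr(s, p + 1L, p + w), "")[[1]] != mot) <= max_mm
  }, logical(1))
  pos[keep]
}

#' Refine VH/JH candidate boundaries on RSS and splice motifs
#'
#' VH: the 3' end snaps to the first base of the nearest downstream RSS
#' heptamer (CACAGTG, at most 1 mismatch, within +50 nt of the anchor end);
#' the 5' end keeps the profile extent and is flagged approximate. JH: the
#' 5' end snaps immediately after the nearest upstream heptamer (the
#' opposite-sense copy, read CACTGTG on the coding strand, same tolerance,
#' within -50 nt), and the 3' end immediately before the first GTA
#' splice-junction trinucleotide near the anchor end (small upstream slack,
#' +30 nt downstream). Missing motifs leave the anchor coordinate and flag
#' the segment `incomplete`.
#'
#' @param candidate One row of the [scan_profile()] candidate tibble.
#' @param kind `"VH"` or `"JH"`.
#' @param locus The [locus_sequence()].
#' @param config An [annotation_config()].
#' @return A one-row gene-segment tibble with the refined oriented sequence.
#' @export
refine_segment_boundaries <- function(candidate, kind = c("VH", "JH"),
                                      locus, config = annotation_config()) {
  kind <- match.arg(kind)
  L <- nchar(locus$residues)
  strand <- candidate$strand
  s <- oriented_residues(locus, strand)
  if (strand == "+") {
    a <- candidate$anchor_start; b <- candidate$anchor_end
  } else {
    fl <- flip_interval(candidate$anchor_start, candidate$anchor_end, L)
    a <- fl$start; b <- fl$end
  }
  flags <- ""
  hept <- config$rss_heptamer
  if (kind == "VH") {
    flags <- add_flag(flags, "manually_flagged")  # 5' end is approximate
    cand <- fuzzy_positions(s, hept, 1L, b - 3L, b + 50L)
    if (length(cand)) {
      b <- nearest_pos(cand, b)
    } else {
      flags <- add_flag(flags, "incomplete")
    }
  } else {
    rc_hept <- revcomp(hept)  # upstream opposite-sense copy
    cand <- fuzzy_positions(s, rc_hept, 1L, a - 50L, a)
    if (length(cand)) {
      a <- nearest_pos(cand, a - nchar(hept)) + nchar(hept)
    } else {
      flags <- add_flag(flags, "incomplete")
    }
    gta <- fuzzy_positions(s, "GTA", 0L, b - 6L, b + 30L)
    if (length(gta)) {
      b <- gta[which.min(abs(gta - b))][1]
    } else {
      flags <- add_flag(flags, "incomplete")
    }
  }
  if (b <= a) { b <- max(a + 1L, b) }
  if (strand == "-") {
    fl <- flip_interval(a, b, L)
    out_a <- fl$start; out_b <- fl$end
  } else {
    out_a <- a; out_b <- b
  }
  gene_segments(contig = locus$id, start = out_a, end = out_b,
                strand = strand, segment_type = kind, flags = flags,
                seq = subseq_chr(s, a, b))
}

#' Locate DH segments by their opposite-sense flanking RSS pattern
#'
#' Scans for revcomp(nonamer) - 12nt spacer - revcomp(heptamer) - core -
#' heptamer - 12nt spacer - nonamer, counting mismatches over the four
#' signal elements only (the spacers and core are unconstrained), with core
#' length between `dh_core_min` and `dh_core_max`. Placements with more than
#' `dh_max_mismatches` mismatches are never reported. The stringent second
#' pass additionally requires the most conserved heptamer positions (CAC,
#' and the complementary GTG on the opposite-sense copy) to be exact in both
#' flanks. Overlapping candidates are resolved keeping the fewest
#' mismatches (ties: leftmost, then shortest). Candidates are oriented by
#' the strand of flanking VH/JH segments when provided, else plus.
#'
#' @param locus A [locus_sequence()].
#' @param config An [annotation_config()].
#' @param stringent Apply the conserved-position second pass?
#' @param context Optional gene-segment tibble of VH/JH segments used to
#'   orient candidates.
#' @param resolve Resolve overlapping candidates? Set `FALSE` to get every
#'   raw placement.
#' @return A gene-segment tibble of DH cores with a `mismatches` attribute
#'   column.
#' @export
scan_dh_rss <- function(locus, config = annotation_config(),
                        stringent = TRUE, context = NULL,
                        resolve = TRUE) {
  enc <- dna_encode(locus$residues)
  hept <- dna_encode(config$rss_heptamer)
  nona <- dna_encode(config$rss_nonamer)
  raw <- cpp_dh_scan(enc, hept, nona, config$dh_spacer, config$dh_core_min,
                     config$dh_core_max, config$dh_max_mismatches)
  raw <- tibble::as_tibble(raw)
  if (stringent && nrow(raw)) raw <- raw[raw$anchors_exact, , drop = FALSE]
  if (!nrow(raw)) {
    out <- gene_segments()
    out$mismatches <- integer()
    return(out)
  }
  if (resolve) {
    # resolve overlapping candidates: fewest mismatches, then leftmost,
    # then shortest
    raw <- raw[order(raw$mismatches, raw$core_start,
                     raw$core_end - raw$core_start), , drop = FALSE]
    keep <- logical(nrow(raw))
    taken_s <- integer(); taken_e <- integer()
    for (i in seq_len(nrow(raw))) {
      ov <- any(raw$core_start[i] < taken_e & raw$core_end[i] > taken_s)
      if (!ov) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, raw$core_start[i])
        taken_e <- c(taken_e, raw$core_end[i])
      }
    }
    raw <- raw[keep, , drop = FALSE]
  }
  raw <- raw[order(raw$core_start, raw$core_end), , drop = FALSE]
  strand <- rep("+", nrow(raw))
  if (!is.null(context) && nrow(context)) {
    ctx <- context[context$segment_type %in% c("VH", "JH"), , drop = FALSE]
    if (nrow(ctx)) {
      for (i in seq_len(nrow(raw))) {
        d <- pmax(ctx$start - raw$core_end[i], raw$core_start[i] - ctx$end)
        strand[i] <- ctx$strand[which.min(d)]
      }
    }
  }
  out <- gene_segments(contig = locus$id, start = raw$core_start,
                       end = raw$core_end, strand = strand,
                       segment_type = "DH",
                       seq = substr(locus$residues, raw$core_start + 1L,
                                    raw$core_end))
  out$mismatches <- raw$mismatches
  out
}

#' Pairwise global-alignment identity
#'
#' Needleman-Wunsch global alignment with the package's fixed scheme
#' (match +1, mismatch -1, linear gap -2); identity is matches over aligned
#' columns including gap columns.
#'
#' @param a,b Sequences (nucleotide or amino acid).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(NA_real_)
  alph <- unique(strsplit(paste0(a, b), "")[[1]])
  mat <- matrix(-1, length(alph), length(alph),
                dimnames = list(alph, alph))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  as.integer(Biostrings::nmatch(aln)) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

# Vectorized variant: identities of each element of `a_vec` against `b`
# (same scheme as pairwise_identity, one DP call per pair but one R call).
pairwise_identity_vec <- function(a_vec, b) {
  alph <- unique(strsplit(paste0(paste(a_vec, collapse = ""), b), "")[[1]])
  mat <- matrix(-1, length(alph), length(alph), dimnames = list(alph, alph))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(a_vec, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  total <- nm + nmm + Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  as.numeric(nm / total)
}

#' Cluster VH segments into families by single linkage
#'
#' Families are the connected components of the graph whose edges join
#' segment pairs with global-alignment identity at or above
#' `vh_family_identity`. Family labels are integers ordered by the genomic
#' position of each family's 5'-most member.
#'
#' @param segments A gene-segment tibble of VH segments with sequences in
#'   `seq`.
#' @param config An [annotation_config()].
#' @return `segments` with a `family` column (`"1"`, `"2"`, ...).
#' @export
cluster_vh_families <- function(segments, config = annotation_config()) {
  n <- nrow(segments)
  if (n == 0L) return(segments)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      ids <- pairwise_identity_vec(segments$seq[(i + 1L):n],
                                   segments$seq[i])
      for (j in which(!is.na(ids) & ids >= config$vh_family_identity)) {
        ri <- find(i); rj <- find(i + j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # order families by the genomic position of their first (5'-most) member
  first_pos <- tapply(segments$start, root, min)
  fam_order <- names(sort(first_pos))
  fam_id <- setNames(seq_along(fam_order), fam_order)
  segments$family <- as.character(fam_id[as.character(root)])
  segments
}

#' Assign positional names to annotated segments
#'
#' VH segments are named `VH<family>.<ordinal>` with ordinals by 5' to 3'
#' locus position within each family; DH and JH segments are named
#' `DH<ordinal>` / `JH<ordinal>` by position alone. Ties on coordinates
#' break deterministically by strand then input order, so names are stable
#' under re-running and input permutation.
#'
#' @param segments A gene-segment tibble (VH rows must carry families).
#' @return `segments` with names filled in.
#' @export
assign_segment_names <- function(segments) {
  if (!nrow(segments)) return(segments)
  ord <- order(segments$start, segments$end, segments$strand,
               method = "radix")
  for (type in c("DH", "JH")) {
    idx <- ord[segments$segment_type[ord] == type]
    if (length(idx)) segments$name[idx] <- paste0(type, seq_along(idx))
  }
  vh <- ord[segments$segment_type[ord] == "VH"]
  if (length(vh)) {
    for (fam in unique(segments$family[vh])) {
      idx <- vh[segments$family[vh] %in% fam]
      segments$name[idx] <- paste0("VH", fam, ".", seq_along(idx))
    }
  }
  segments
}
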