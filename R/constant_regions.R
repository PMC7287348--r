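# Constant-region (CH) curation: collapse raw hits into alignment groups,
# apply the two-stage filter, refine exon boundaries on splice motifs, chain
# exons into isotype regions, and classify IGHZ status.

# Exon rank tables per isotype. Greek exon labels are accepted and
# normalized to ASCII (Cμ2 -> Cm2 etc.).
normalize_exon_label <- function(label) {
  lab <- chartr("μδζ", "mdz", label)
  sub("^C([MDZmdz])", "C\\L\\1", lab, perl = TRUE)
}

exon_rank <- function(isotype, exon_label) {
  if (length(isotype) > 1L || length(exon_label) > 1L) {
    return(unlist(Map(exon_rank, isotype, exon_label, USE.NAMES = FALSE)))
  }
  lab <- normalize_exon_label(exon_label)
  tab <- switch(isotype,
    IGHM = c(Cm1 = 1, Cm2 = 2, Cm3 = 3, Cm4 = 4, TM1 = 5, TM2 = 6),
    IGHZ = c(Cz1 = 1, Cz2 = 2, Cz3 = 3, Cz4 = 4, TM1 = 5, TM2 = 6),
    IGHD = c(Cd1 = 1, Cd2 = 2, Cd3 = 3, Cd4 = 4, Cd5 = 5, Cd6 = 6, Cd7 = 7,
             TM1 = 8, TM2 = 9),
    NULL)
  if (is.null(tab)) return(rep(NA_real_, length(lab)))
  unname(tab[lab])
}

# Minimal exon sets for a region to count as complete. TM2 never affects
# completeness (its conserved coding sequence is too short to find reliably).
required_exons <- list(
  IGHM = c("Cm1", "Cm2", "Cm3", "Cm4"),
  IGHZ = c("Cz1", "Cz2", "Cz3", "Cz4"),
  IGHD = c("Cd1", "Cd7")
)

#' Collapse overlapping same-label HSPs into alignment groups
#'
#' Groups are the connected components of the relation "same isotype and
#' exon label, same strand, and genomic intervals overlap". Group statistics
#' are computed over members: best (minimum) E-value, best (maximum)
#' bitscore, the number of distinct reference exons aligned across all
#' reference species, and the number of distinct reference species.
#'
#' @param hits An HSP tibble from [local_search()] with isotype and exon
#'   label columns.
#' @return A tibble of alignment groups; column `members` holds the row
#'   indices of `hits` in each group.
#' @export
collapse_hsps <- function(hits) {
  if (!nrow(hits)) {
    return(tibble::tibble(group_id = integer(), contig = character(),
                          isotype = character(), exon_label = character(),
                          strand = character(), start = integer(),
                          end = integer(), anchor_start = integer(),
                          anchor_end = integer(), best_evalue = numeric(),
                          best_bitscore = numeric(), n_ref_exons = integer(),
                          n_ref_species = integer(), members = list()))
  }
  key <- paste(hits$contig, hits$isotype, normalize_exon_label(hits$exon_label),
               hits$strand, sep = "\r")
  out <- list()
  gid <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    ir <- IRanges::IRanges(start = hits$sstart[idx] + 1L, end = hits$send[idx])
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (g in seq_along(red)) {
      gid <- gid + 1L
      mem <- idx[revmap[[g]]]
      best <- mem[which.max(hits$bitscore[mem])]
      out[[gid]] <- tibble::tibble(
        group_id = gid, contig = hits$contig[mem[1]],
        isotype = hits$isotype[mem[1]],
        exon_label = normalize_exon_label(hits$exon_label[mem[1]]),
        strand = hits$strand[mem[1]],
        start = IRanges::start(red)[g] - 1L, end = IRanges::end(red)[g],
        anchor_start = hits$sstart[best], anchor_end = hits$send[best],
        best_evalue = min(hits$evalue[mem]),
        best_bitscore = max(hits$bitscore[mem]),
        n_ref_exons = length(unique(hits$query_id[mem])),
        n_ref_species = length(unique(hits$species[mem])),
        members = list(mem))
    }
  }
  grp <- dplyr::bind_rows(out)
  grp[order(grp$contig, grp$start, grp$end, method = "radix"), ]
}

#' First-stage filter of alignment groups
#'
#' A group is removed iff its best E-value exceeds `primary_evalue_max`, or
#' it overlaps (same contig and strand) a group with a different isotype or
#' exon label whose best bitscore exceeds its own by at least
#' `override_bitscore_diff`. Overlap removals are evaluated against the
#' pre-filter group set, so the result does not depend on input order.
#'
#' @param groups Output of [collapse_hsps()].
#' @param config An [annotation_config()].
#' @return The retained groups.
#' @export
filter_groups <- function(groups, config = annotation_config()) {
  if (!nrow(groups)) return(groups)
  drop <- groups$best_evalue > config$primary_evalue_max
  gr <- GenomicRanges::GRanges(
    groups$contig, IRanges::IRanges(groups$start + 1L, groups$end),
    strand = groups$strand)
  ov <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
  diff_label <- groups$isotype[qi] != groups$isotype[sj] |
    groups$exon_label[qi] != groups$exon_label[sj]
  beaten <- diff_label &
    (groups$best_bitscore[sj] - groups$best_bitscore[qi] >=
       config$override_bitscore_diff)
  drop[unique(qi[beaten])] <- TRUE
  groups[!drop, , drop = FALSE]
}

#' Stringent second-stage filter of alignment groups
#'
#' Retains a group iff its best E-value is at most `stringent_evalue_max`
#' and it aligned at least `stringent_min_ref_exons` distinct reference
#' exons over all reference species.
#'
#' @inheritParams filter_groups
#' @return The retained groups.
#' @export
filter_groups_stringent <- function(groups, config = annotation_config()) {
  if (!nrow(groups)) return(groups)
  keep <- groups$best_evalue <= config$stringent_evalue_max &
    groups$n_ref_exons >= config$stringent_min_ref_exons
  groups[keep, , drop = FALSE]
}

# Nearest-motif position search, shared by the boundary refiners. Returns
# the candidate in `cands` closest to `anchor` (ties toward the smaller
# coordinate), or NA when none.
nearest_pos <- function(cands, anchor) {
  if (!length(cands)) return(NA_integer_)
  d <- abs(cands - anchor)
  cands[order(d, cands)][1]
}

# All 0-based positions where `motif` occurs in `s` (fixed string).
motif_positions <- function(s, motif) {
  out <- integer(); from <- 1L
  repeat {
    p <- regexpr(motif, substr(s, from, nchar(s)), fixed = TRUE)
    if (p < 0L) break
    out <- c(out, from + p - 2L)
    from <- from + p
  }
  out
}

#' Refine the boundaries of a CH alignment group on splice motifs
#'
#' In `internal` mode the exon start snaps to the position immediately
#' following the nearest AG acceptor dinucleotide within a +/- window of the
#' aligned boundary, and the exon end to the position immediately preceding
#' the nearest GT donor. In `terminal_secretory` mode no 3' splice site is
#' expected: the nucleotide end extends to the first canonical
#' polyadenylation hexamer downstream (`AATAAA` by default) and the
#' translated end to the first stop codon. Missing motifs flag the exon
#' `incomplete`; windows truncated at the sequence edge flag it
#' `manually_flagged`. Minus-strand groups are refined on the reverse
#' complement and mapped back to plus-strand coordinates.
#'
#' @param group A single row of the group tibble (anchor coordinates are the
#'   best member's interval).
#' @param locus The [locus_sequence()].
#' @param mode `"internal"`, `"terminal_secretory"` or `"terminal_tm"`
#'   (terminal transmembrane exons refine like internal ones).
#' @param config An [annotation_config()].
#' @return A one-row gene-segment tibble (`segment_type` "CH-exon") with the
#'   refined oriented sequence in `seq`.
#' @export
refine_exon_boundaries <- function(group, locus,
                                   mode = c("internal", "terminal_secretory",
                                            "terminal_tm"),
                                   config = annotation_config()) {
  mode <- match.arg(mode)
  L <- nchar(locus$residues)
  w <- config$boundary_window
  strand <- group$strand
  # oriented coordinates: on "-" work on the reverse complement
  if (strand == "+") {
    a <- group$anchor_start; b <- group$anchor_end
  } else {
    fl <- flip_interval(group$anchor_start, group$anchor_end, L)
    a <- fl$start; b <- fl$end
  }
  s <- oriented_residues(locus, strand)
  flags <- ""
  if (a - w - 2L < 0L || b + w + 2L > L) flags <- add_flag(flags, "manually_flagged")

  # start: position immediately following an AG acceptor
  lo <- max(2L, a - w); hi <- min(L - 1L, a + w)
  cand <- (lo:hi)[vapply(lo:hi, function(p) {
    substr(s, p - 1L, p) == "AG"
  }, logical(1))]
  new_a <- nearest_pos(cand, a)
  if (is.na(new_a)) { new_a <- a; flags <- add_flag(flags, "incomplete") }

  if (mode == "terminal_secretory") {
    # nucleotide end at the first polyadenylation hexamer downstream
    tail_seq <- subseq_chr(s, b - w, min(L, b + 400L))
    pos <- motif_positions(tail_seq, config$polya_signal)
    if (length(pos)) {
      new_b <- (b - w) + pos[1]
    } else {
      new_b <- b; flags <- add_flag(flags, "incomplete")
    }
  } else {
    # end: position immediately preceding a GT donor
    lo <- max(new_a + 1L, b - w); hi <- min(L - 1L, b + w)
    cand <- (lo:hi)[vapply(lo:hi, function(p) {
      substr(s, p + 1L, p + 2L) == "GT"
    }, logical(1))]
    new_b <- nearest_pos(cand, b)
    if (is.na(new_b)) { new_b <- b; flags <- add_flag(flags, "incomplete") }
  }

  exon_seq <- subseq_chr(s, new_a, new_b)
  if (mode == "terminal_secretory") {
    aa <- translate_nt(exon_seq)
    stop_at <- regexpr("*", aa, fixed = TRUE)
    attr(exon_seq, "aa_to_stop") <- if (stop_at > 0L) {
      substr(aa, 1L, stop_at - 1L)
    } else aa
  }
  if (strand == "-") {
    fl <- flip_interval(new_a, new_b, L)
    out_a <- fl$start; out_b <- fl$end
  } else {
    out_a <- new_a; out_b <- new_b
  }
  seg <- gene_segments(contig = locus$id, start = out_a, end = out_b,
                       strand = strand, segment_type = "CH-exon",
                       isotype = group$isotype,
                       exon_label = group$exon_label,
                       flags = flags, seq = as.character(exon_seq))
  if (!is.null(attr(exon_seq, "aa_to_stop"))) {
    attr(seg, "aa_to_stop") <- attr(exon_seq, "aa_to_stop")
  }
  seg
}

# Pseudogene test for a refined exon: premature stop codon in the aligned
# frame, or a frameshift relative to the reference exon length.
exon_is_pseudo <- function(seq, ref_len = NA) {
  aa <- translate_nt(seq)
  n <- nchar(aa)
  if (n > 1L && grepl("*", substr(aa, 1L, n - 1L), fixed = TRUE)) return(TRUE)
  if (!is.na(ref_len) && (nchar(seq) - ref_len) %% 3L != 0L) return(TRUE)
  FALSE
}

#' Chain refined CH exons into constant regions
#'
#' Same-isotype exons on one contig and strand are chained into a region
#' while consecutive gaps stay within `max_intron_gap` and exon ranks are
#' non-decreasing (Cx1 < Cx2 < ... < TM1 < TM2), with the IGHD
#' (Cd2-Cd3-Cd4) block allowed to repeat. An order violation splits the
#' region at the violation and flags both parts. A region is a pseudogene
#' when any exon translates with a premature stop or is frameshifted
#' relative to its reference length; it is complete when it carries the
#' isotype's minimal exon set (Cm1-Cm4 for IGHM, Cz1-Cz4 for IGHZ, Cd1 and
#' Cd7 for IGHD; TM2 never affects completeness).
#'
#' @param exons A gene-segment tibble of refined CH exons.
#' @param locus The [locus_sequence()].
#' @param refs Optional reference-segment tibble used for reference exon
#'   lengths in the pseudogene test.
#' @param config An [annotation_config()].
#' @return A list with `regions` (one row per region) and `exons` (the input
#'   exons with `region` and `name` columns and updated flags).
#' @export
assemble_constant_regions <- function(exons, locus, refs = NULL,
                                      config = annotation_config()) {
  if (!nrow(exons)) {
    return(list(regions = tibble::tibble(
      name = character(), contig = character(), isotype = character(),
      strand = character(), start = integer(), end = integer(),
      n_exons = integer(), complete = logical(), pseudogene = logical()),
      exons = dplyr::mutate(exons, region = character(0))))
  }
  ref_len <- NULL
  if (!is.null(refs) && nrow(refs)) {
    ch <- refs[refs$segment_type == "CH", , drop = FALSE]
    key <- paste(ch$isotype, normalize_exon_label(ch$exon_label))
    ref_len <- tapply(nchar(ch$residues), key, function(x) round(mean(x)))
  }
  exons$rank <- exon_rank(exons$isotype, exons$exon_label)
  exons$region <- NA_character_
  exons$pseudo <- vapply(seq_len(nrow(exons)), function(i) {
    rl <- NA
    if (!is.null(ref_len)) {
      k <- paste(exons$isotype[i], normalize_exon_label(exons$exon_label[i]))
      if (k %in% names(ref_len)) rl <- ref_len[[k]]
    }
    exon_is_pseudo(exons$seq[i], rl)
  }, logical(1))
  exons$flags <- ifelse(exons$pseudo, add_flag(exons$flags, "pseudogene"),
                        exons$flags)

  key <- paste(exons$contig, exons$isotype, exons$strand, sep = "\r")
  chains <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    strand <- exons$strand[idx[1]]
    # strand-aware genomic order (5' -> 3' on the coding strand)
    ord <- if (strand == "+") idx[order(exons$start[idx])] else
      idx[order(-exons$end[idx])]
    cur <- ord[1]
    for (i in ord[-1]) {
      prev <- cur[length(cur)]
      gap <- if (strand == "+") exons$start[i] - exons$end[prev] else
        exons$start[prev] - exons$end[i]
      rank_prev <- exons$rank[prev]; rank_i <- exons$rank[i]
      ok_gap <- gap <= config$max_intron_gap
      ok_rank <- is.na(rank_prev) || is.na(rank_i) || rank_i >= rank_prev ||
        (exons$isotype[i] == "IGHD" && rank_i == 2 && rank_prev == 4)
      if (ok_gap && ok_rank) {
        cur <- c(cur, i)
      } else {
        chains[[length(chains) + 1L]] <- list(members = cur)
        if (!ok_rank && ok_gap) {
          # order violation within chaining distance: split, flag both sides
          exons$flags[c(cur, i)] <- add_flag(exons$flags[c(cur, i)],
                                             "manually_flagged")
        }
        cur <- i
      }
    }
    chains[[length(chains) + 1L]] <- list(members = cur)
  }

  regions <- list(); counters <- list()
  for (ci in seq_along(chains)) {
    mem <- chains[[ci]]$members
    iso <- exons$isotype[mem[1]]
    counters[[iso]] <- (counters[[iso]] %||% 0L) + 1L
    rname <- paste0(iso, "_tmp", counters[[iso]])
    labs <- normalize_exon_label(exons$exon_label[mem])
    req <- required_exons[[iso]]
    complete <- !is.null(req) && all(req %in% labs)
    pseudo <- any(exons$pseudo[mem])
    exons$region[mem] <- rname
    regions[[length(regions) + 1L]] <- tibble::tibble(
      name = rname, contig = exons$contig[mem[1]], isotype = iso,
      strand = exons$strand[mem[1]],
      start = min(exons$start[mem]), end = max(exons$end[mem]),
      n_exons = length(mem), complete = complete, pseudogene = pseudo)
  }
  exons$rank <- NULL; exons$pseudo <- NULL
  reg <- dplyr::bind_rows(regions)
  reg <- reg[order(reg$contig, reg$start, method = "radix"), ]
  # number region names by genomic position within isotype
  newname <- reg$name
  for (iso in unique(reg$isotype)) {
    i <- which(reg$isotype == iso)
    newname[i] <- paste0(iso, seq_along(i))
  }
  remap <- setNames(newname, reg$name)
  reg$name <- unname(remap[reg$name])
  exons$region <- unname(remap[exons$region])
  exons$name <- paste0(exons$contig, "_", exons$region, "_",
                       normalize_exon_label(exons$exon_label))
  list(regions = reg, exons = exons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify the IGHZ status of a locus
#'
#' `present` (with a count) when at least one complete, non-pseudogene IGHZ
#' region exists; `pseudogene_remnant` when only flagged or incomplete IGHZ
#' material exists; `absent` otherwise.
#'
#' @param regions The `regions` tibble from [assemble_constant_regions()].
#' @return A list with `status` and `count`.
#' @export
classify_ighz_status <- function(regions) {
  z <- regions[regions$isotype == "IGHZ", , drop = FALSE]
  good <- z$complete & !z$pseudogene
  if (any(good)) {
    list(status = "present", count = sum(good))
  } else if (nrow(z) > 0L) {
    list(status = "pseudogene_remnant", count = 0L)
  } else {
    list(status = "absent", count = 0L)
  }
}
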