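# Synthetic IGH loci with full ground truth. The generator plants
# divergence-controlled copies of reference segments in i.i.d. intergenic
# background with the flanking context each discovery stage keys on:
# heptamer/23-spacer/nonamer RSS after VH, opposite-sense 12-spacer RSSs
# around DH cores, upstream RSS and downstream GTA donor for JH, AG..GT
# intron context for CH exons and a polyadenylation signal after Cx4.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, gc = 0.42) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Stop-free random coding sequence (frame 0), used for reference ancestors.
rand_coding <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      c3 <- rand_dna(3L, gc = 0.5)
      if (!(c3 %in% stops)) break
    }
    codons[i] <- c3
  }
  paste(codons, collapse = "")
}

#' Mutate a sequence with per-site substitutions and indels
#'
#' Each site is substituted with probability `divergence` (uniform over the
#' three alternatives); indel events occur per site with probability
#' `indel_rate`, with geometric lengths. Fully reproducible by seed.
#'
#' @param seq Nucleotide string.
#' @param divergence Per-site substitution probability.
#' @param indel_rate Per-site indel event probability.
#' @param seed RNG seed.
#' @return The mutated sequence, with attribute `n_mut` (substitution +
#'   indel event count).
#' @export
mutate_sequence <- function(seq, divergence, indel_rate = 0, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.5, indel_rate >= 0)
  with_seed(seed, mutate_sequence_(seq, divergence, indel_rate))
}

mutate_sequence_ <- function(seq, divergence, indel_rate = 0) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  sub_at <- which(runif(n) < divergence & chars %in% bases)
  for (i in sub_at) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  n_mut <- length(sub_at)
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate)
    # apply right-to-left so earlier positions stay valid
    for (i in rev(ev)) {
      len <- 1L + stats::rgeom(1L, 0.5)
      if (runif(1) < 0.5) {
        ins <- strsplit(rand_dna(len, 0.5), "")[[1]]
        chars <- append(chars, ins, after = i)
      } else {
        chars <- chars[-(i:min(n, i + len - 1L))]
        n <- length(chars)
      }
      n_mut <- n_mut + 1L
    }
  }
  out <- paste(chars, collapse = "")
  attr(out, "n_mut") <- n_mut
  out
}

# Substitution-only mutation that preserves the reading frame's stop-free
# property and the terminal `conserve` bases of each end (splice-proximal
# bases are under strong constraint in real exons).
mutate_coding_ <- function(seq, divergence, conserve = 0L) {
  stops <- c("TAA", "TAG", "TGA")
  mut <- mutate_sequence_(seq, divergence, 0)
  chars <- strsplit(mut, "")[[1]]
  orig <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (conserve > 0L && n > 2L * conserve) {
    chars[1:conserve] <- orig[1:conserve]
    chars[(n - conserve + 1L):n] <- orig[(n - conserve + 1L):n]
  }
  # revert any codon that mutated into a stop
  for (cs in seq(1L, n - 2L, by = 3L)) {
    if (paste(chars[cs:(cs + 2L)], collapse = "") %in% stops) {
      chars[cs:(cs + 2L)] <- orig[cs:(cs + 2L)]
    }
  }
  out <- paste(chars, collapse = "")
  attr(out, "n_mut") <- sum(chars != orig)
  out
}

# Default CH blueprints: six-exon Cm1-Cm2-Cm3-Cm4-TM1-TM2 for IGHM, the
# 12-exon Cd1-(Cd2-Cd3-Cd4)x2-Cd5-Cd6-Cd7-TM1-TM2 configuration for IGHD,
# and six-exon Cz1-Cz4 + TM for IGHZ.
default_blueprints <- function() {
  list(
    IGHM = c("Cm1", "Cm2", "Cm3", "Cm4", "TM1", "TM2"),
    IGHD = c("Cd1", "Cd2", "Cd3", "Cd4", "Cd2", "Cd3", "Cd4", "Cd5", "Cd6",
             "Cd7", "TM1", "TM2")
  )
}

ch_exon_lengths <- function() {
  c(Cm1 = 318L, Cm2 = 324L, Cm3 = 321L, Cm4 = 330L,
    Cd1 = 306L, Cd2 = 300L, Cd3 = 312L, Cd4 = 297L, Cd5 = 309L,
    Cd6 = 303L, Cd7 = 315L,
    Cz1 = 321L, Cz2 = 330L, Cz3 = 324L, Cz4 = 312L,
    TM1 = 156L, TM2 = 90L)
}

#' Build a synthetic reference gene-segment library
#'
#' Emulates the reference libraries of previously characterized species:
#' `n_species` synthetic reference species, each carrying one copy of every
#' VH family, the JH segment, and every CH exon, diverged from common
#' ancestors. VH families descend from a single VH ancestor so a joint
#' profile can be built; family ancestors are mutually diverged enough to
#' fall below the 80% family threshold.
#'
#' @param seed RNG seed.
#' @param n_species Number of synthetic reference species.
#' @param n_vh_families Number of VH family ancestors.
#' @param species_divergence Per-site divergence of each species copy from
#'   the ancestor.
#' @param family_divergence Per-site divergence of each VH family ancestor
#'   from the VH ur-ancestor.
#' @param isotypes Isotypes to include CH exons for.
#' @return A reference-segment tibble; the ancestor sequences are attached
#'   as the `ancestors` attribute (used by the locus generator).
#' @export
make_reference_library <- function(seed = 42L, n_species = 3L,
                                   n_vh_families = 4L,
                                   species_divergence = 0.08,
                                   family_divergence = 0.22,
                                   isotypes = c("IGHM", "IGHD", "IGHZ")) {
  with_seed(seed, {
    anc <- list()
    vh_ur <- rand_coding(100L)  # 300 nt VH coding ancestor
    for (f in seq_len(n_vh_families)) {
      anc[[paste0("VH", f)]] <- mutate_coding_(vh_ur, family_divergence)
    }
    anc[["JH"]] <- rand_coding(20L)  # 60 nt
    lens <- ch_exon_lengths()
    for (iso in isotypes) {
      labs <- unique(c(grep(paste0("^C", tolower(substr(iso, 4, 4))),
                            names(lens), value = TRUE), "TM1", "TM2"))
      for (lab in labs) {
        anc[[paste(iso, lab)]] <- rand_coding(lens[[lab]] / 3L)
      }
    }
    rows <- list()
    for (sp in seq_len(n_species)) {
      spname <- paste0("ref_sp", sp)
      for (nm in names(anc)) {
        res <- mutate_coding_(anc[[nm]], species_divergence)
        if (startsWith(nm, "VH")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = paste0(spname, "_", nm), species = spname,
            segment_type = "VH", isotype = "none", exon_label = "none",
            residues = as.character(res), alphabet = "nt", family = nm)
        } else if (nm == "JH") {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = paste0(spname, "_JH"), species = spname,
            segment_type = "JH", isotype = "none", exon_label = "none",
            residues = as.character(res), alphabet = "nt", family = NA)
        } else {
          parts <- strsplit(nm, " ")[[1]]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = paste0(spname, "_", parts[1], "_", parts[2]),
            species = spname, segment_type = "CH", isotype = parts[1],
            exon_label = parts[2], residues = as.character(res),
            alphabet = "nt", family = NA)
        }
      }
    }
    lib <- dplyr::bind_rows(rows)
    attr(lib, "ancestors") <- anc
    lib
  })
}

#' Simulation configuration
#'
#' Defaults mirror the architecture of a characterized killifish sublocus:
#' 24 VH, 14 DH and 17 JH segments with IGHM and IGHD constant regions, a
#' per-site divergence of 0.10 from the reference copies, and i.i.d.
#' intergenic background at 42% GC.
#'
#' @param n_vh,n_dh,n_jh Segment counts per sublocus group.
#' @param ch_blueprints Named list isotype -> ordered exon labels.
#' @param divergence Per-site substitution probability vs the reference.
#' @param indel_rate Per-site indel probability in planted segments.
#' @param intergenic_len_mean Mean intergenic spacer length (bp).
#' @param gc Intergenic GC content.
#' @param n_subloci Number of subloci.
#' @param sublocus_strands Strand per sublocus.
#' @param seed RNG seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_vh = 24L, n_dh = 14L, n_jh = 17L,
                       ch_blueprints = default_blueprints(),
                       divergence = 0.10, indel_rate = 0,
                       intergenic_len_mean = 600L, gc = 0.42,
                       n_subloci = 1L, sublocus_strands = "+",
                       seed) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  stopifnot(n_vh >= 0, n_dh >= 0, n_jh >= 0, divergence >= 0,
            divergence < 0.5, indel_rate >= 0, gc > 0, gc < 1,
            length(sublocus_strands) == n_subloci)
  structure(list(n_vh = as.integer(n_vh), n_dh = as.integer(n_dh),
                 n_jh = as.integer(n_jh), ch_blueprints = ch_blueprints,
                 divergence = divergence, indel_rate = indel_rate,
                 intergenic_len_mean = as.integer(intergenic_len_mean),
                 gc = gc, n_subloci = as.integer(n_subloci),
                 sublocus_strands = sublocus_strands,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic IGH locus with ground truth
#'
#' Intergenic background is interleaved with planted features per the
#' configuration: VH copies followed by a heptamer/23-spacer/nonamer RSS,
#' DH cores flanked by opposite-sense 12-spacer RSSs, JH copies with an
#' upstream RSS and downstream GTA donor, and CH exons in blueprint order
#' with AG..GT intron context plus a polyadenylation hexamer after the
#' fourth C exon. A sublocus configured on the minus strand is
#' reverse-complemented wholesale. Re-running with the same seed yields
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @param references A library from [make_reference_library()].
#' @param annot_config An [annotation_config()] (motif strings and spacer
#'   lengths are taken from it).
#' @return List with `locus` (a [locus_sequence()]) and `truth` (a
#'   gene-segment tibble with `ref_id` and `n_mut` columns).
#' @export
generate_locus <- function(config, references,
                           annot_config = annotation_config()) {
  stopifnot(inherits(config, "sim_config"))
  hept <- annot_config$rss_heptamer
  nona <- annot_config$rss_nonamer
  vh_refs <- references[references$segment_type == "VH", , drop = FALSE]
  jh_refs <- references[references$segment_type == "JH", , drop = FALSE]
  ch_refs <- references[references$segment_type == "CH", , drop = FALSE]
  for (iso in names(config$ch_blueprints)) {
    need <- unique(config$ch_blueprints[[iso]])
    have <- unique(ch_refs$exon_label[ch_refs$isotype == iso])
    if (!all(need %in% have)) {
      stop("blueprint for ", iso, " needs exons missing from the reference ",
           "library: ", paste(setdiff(need, have), collapse = ", "),
           call. = FALSE)
    }
  }
  if (config$n_vh > 0L && nrow(vh_refs) == 0L) {
    stop("no VH references available", call. = FALSE)
  }
  if (config$n_jh > 0L && nrow(jh_refs) == 0L) {
    stop("no JH references available", call. = FALSE)
  }
  with_seed(config$seed, {
    contig <- paste0("simlocus_s", config$seed)
    subloci <- vector("list", config$n_subloci)
    for (si in seq_len(config$n_subloci)) {
      pieces <- character(); pos <- 0L
      truth <- list()
      emit <- function(s) {
        pieces[[length(pieces) + 1L]] <<- s
        pos <<- pos + nchar(s)
      }
      spacer <- function() {
        emit(rand_dna(60L + stats::rpois(1L, config$intergenic_len_mean),
                      config$gc))
      }
      record <- function(type, start, end, iso = "none", lab = "none",
                         ref_id = NA, n_mut = NA, fam = NA) {
        truth[[length(truth) + 1L]] <<- tibble::tibble(
          start = start, end = end, segment_type = type, isotype = iso,
          exon_label = lab, ref_id = ref_id, n_mut = n_mut, family = fam)
      }
      spacer()
      vh_fams <- unique(vh_refs$family)
      for (v in seq_len(config$n_vh)) {
        fam <- vh_fams[1L + (v - 1L) %% length(vh_fams)]
        cand <- which(vh_refs$family == fam)
        ri <- cand[sample.int(length(cand), 1L)]
        mut <- if (config$indel_rate > 0) {
          mutate_sequence_(vh_refs$residues[ri], config$divergence,
                           config$indel_rate)
        } else {
          mutate_coding_(vh_refs$residues[ri], config$divergence,
                         conserve = 3L)
        }
        record("VH", pos, pos + nchar(mut), ref_id = vh_refs$id[ri],
               n_mut = attr(mut, "n_mut"), fam = sub("VH", "", fam))
        emit(mut)
        emit(paste0(hept, rand_dna(23L, 0.5), nona))
        spacer()
      }
      for (d in seq_len(config$n_dh)) {
        core <- rand_dna(sample(12:28, 1L), 0.5)
        emit(paste0(revcomp(nona), rand_dna(annot_config$dh_spacer, 0.5),
                    revcomp(hept)))
        record("DH", pos, pos + nchar(core))
        emit(core)
        emit(paste0(hept, rand_dna(annot_config$dh_spacer, 0.5), nona))
        spacer()
      }
      for (j in seq_len(config$n_jh)) {
        ri <- sample.int(nrow(jh_refs), 1L)
        mut <- mutate_coding_(jh_refs$residues[ri], config$divergence,
                              conserve = 3L)
        emit(paste0(nona, rand_dna(23L, 0.5), revcomp(hept)))
        record("JH", pos, pos + nchar(mut), ref_id = jh_refs$id[ri],
               n_mut = attr(mut, "n_mut"))
        emit(mut)
        emit("GTAAGT")
        spacer()
      }
      for (iso in names(config$ch_blueprints)) {
        labs <- config$ch_blueprints[[iso]]
        # intron ending with the AG acceptor before the first exon
        emit(paste0(rand_dna(150L + stats::rpois(1L, 150L), config$gc), "AG"))
        for (k in seq_along(labs)) {
          lab <- labs[k]
          cand <- which(ch_refs$isotype == iso & ch_refs$exon_label == lab)
          ri <- cand[sample.int(length(cand), 1L)]
          mut <- mutate_coding_(ch_refs$residues[ri], config$divergence,
                                conserve = 3L)
          record("CH-exon", pos, pos + nchar(mut), iso = iso, lab = lab,
                 ref_id = ch_refs$id[ri], n_mut = attr(mut, "n_mut"))
          emit(mut)
          if (k < length(labs)) {
            ilen <- 120L + stats::rpois(1L, 200L)
            intron <- paste0("GT", rand_dna(ilen, config$gc), "AG")
            if (grepl("^C[a-z]4$", normalize_exon_label(lab))) {
              # polyadenylation signal downstream of the fourth C exon
              intron <- paste0("GT", rand_dna(30L, config$gc),
                               annot_config$polya_signal,
                               rand_dna(ilen - 36L, config$gc), "AG")
            }
            emit(intron)
          } else {
            emit(paste0("GT", rand_dna(80L, config$gc),
                        annot_config$polya_signal))
          }
        }
        spacer()
      }
      seq_str <- paste(pieces, collapse = "")
      truth <- dplyr::bind_rows(truth)
      strand <- config$sublocus_strands[si]
      if (strand == "-") {
        L <- nchar(seq_str)
        seq_str <- revcomp(seq_str)
        new_start <- L - truth$end
        truth$end <- L - truth$start
        truth$start <- new_start
      }
      truth$strand <- strand
      subloci[[si]] <- list(seq = seq_str, truth = truth)
    }
    # concatenate subloci with an intergenic joint
    offset <- 0L; all_seq <- character(); all_truth <- list()
    for (si in seq_len(config$n_subloci)) {
      sl <- subloci[[si]]
      all_seq[[si]] <- sl$seq
      sl$truth$start <- sl$truth$start + offset
      sl$truth$end <- sl$truth$end + offset
      all_truth[[si]] <- sl$truth
      offset <- offset + nchar(sl$seq)
    }
    res <- paste(unlist(all_seq), collapse = "")
    truth <- dplyr::bind_rows(all_truth)
    truth$contig <- contig
    truth$seq <- substr(rep(res, nrow(truth)), truth$start + 1L, truth$end)
    truth$seq <- ifelse(truth$strand == "-", revcomp(truth$seq), truth$seq)
    truth$name <- paste0("truth_", seq_len(nrow(truth)))
    truth$flags <- ""
    locus <- locus_sequence(contig, res, "synthetic IGH locus")
    list(locus = locus, truth = truth)
  })
}

#' Score predicted segments against planted truth
#'
#' A prediction matches a truth record when it has the same segment type and
#' strand and their reciprocal overlap is at least `overlap_frac`; matching
#' is one-to-one, greedy by best overlap. Precision with zero predictions is
#' reported as 1 by convention and flagged.
#'
#' @param truth Truth tibble from [generate_locus()].
#' @param predicted A gene-segment tibble of predictions.
#' @param overlap_frac Reciprocal overlap threshold.
#' @return A tibble with one row per segment type: counts, precision,
#'   recall, exact-boundary fraction and mean absolute boundary error.
#' @export
score_recovery <- function(truth, predicted, overlap_frac = 0.8) {
  types <- sort(unique(c(truth$segment_type, predicted$segment_type)))
  out <- list()
  for (type in types) {
    tt <- truth[truth$segment_type == type, , drop = FALSE]
    pp <- predicted[predicted$segment_type == type, , drop = FALSE]
    pairs <- list()
    if (nrow(tt) && nrow(pp)) {
      for (i in seq_len(nrow(tt))) {
        ov <- pmin(tt$end[i], pp$end) - pmax(tt$start[i], pp$start)
        rec <- pmin(ov / (tt$end[i] - tt$start[i]),
                    ov / (pp$end - pp$start))
        ok <- which(pp$strand == tt$strand[i] & rec >= overlap_frac)
        for (j in ok) {
          pairs[[length(pairs) + 1L]] <- c(i, j, rec[j])
        }
      }
    }
    matched_t <- integer(); matched_p <- integer()
    berr <- numeric(); exact <- logical()
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(-pm[, 3], pm[, 1], pm[, 2]), , drop = FALSE]
      for (r in seq_len(nrow(pm))) {
        i <- pm[r, 1]; j <- pm[r, 2]
        if (i %in% matched_t || j %in% matched_p) next
        matched_t <- c(matched_t, i); matched_p <- c(matched_p, j)
        berr <- c(berr, abs(tt$start[i] - pp$start[j]) +
                    abs(tt$end[i] - pp$end[j]))
        exact <- c(exact, tt$start[i] == pp$start[j] &&
                     tt$end[i] == pp$end[j])
      }
    }
    tp <- length(matched_t)
    out[[type]] <- tibble::tibble(
      segment_type = type, n_truth = nrow(tt), n_pred = nrow(pp), tp = tp,
      precision = if (nrow(pp) == 0L) 1.0 else tp / nrow(pp),
      precision_defined = nrow(pp) > 0L,
      recall = if (nrow(tt) == 0L) NA_real_ else tp / nrow(tt),
      exact_boundary_frac = if (tp) mean(exact) else NA_real_,
      mean_boundary_error = if (tp) mean(berr) else NA_real_)
  }
  dplyr::bind_rows(out)
}
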