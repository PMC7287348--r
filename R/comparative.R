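# Cross-region and cross-locus statistics: exon identity matrices,
# per-exon subclass votes, and the IGHZ multiplicity geometric mean.

#' Pairwise identity matrix between two exon sets
#'
#' Entry (i, j) is the global-alignment identity of exon i of set `a`
#' against exon j of set `b` (match +1, mismatch -1, linear gap -2;
#' identity over aligned columns including gaps). Empty sequences give
#' masked (`NA`) entries.
#'
#' @param exons_a,exons_b Tibbles with columns `name`, `exon_label`, `seq`
#'   (e.g. the `exons` element of [assemble_constant_regions()]).
#' @return A numeric matrix with exon names as dimnames and an attribute
#'   `corresponding_mean`, the mean identity over pairs sharing an exon
#'   label.
#' @export
exon_identity_matrix <- function(exons_a, exons_b) {
  m <- matrix(NA_real_, nrow(exons_a), nrow(exons_b),
              dimnames = list(exons_a$name, exons_b$name))
  for (i in seq_len(nrow(exons_a))) {
    for (j in seq_len(nrow(exons_b))) {
      ai <- exons_a$seq[i]; bj <- exons_b$seq[j]
      if (is.na(ai) || is.na(bj) || !nzchar(ai) || !nzchar(bj)) next
      m[i, j] <- pairwise_identity(ai, bj)
    }
  }
  same <- outer(normalize_exon_label(exons_a$exon_label),
                normalize_exon_label(exons_b$exon_label), "==")
  attr(m, "corresponding_mean") <- mean(m[same], na.rm = TRUE)
  m
}

#' Vote a subclass for each exon of a region
#'
#' For every exon, labelled reference subclasses are ranked by the maximum
#' identity to any same-label reference exon; the top subclass wins, and the
#' vote is flagged ambiguous when the top two subclasses are within
#' `margin` identity of one another.
#'
#' @param region_exons Tibble with `exon_label`, `seq` for the query region.
#' @param labelled_refs Tibble with `subclass`, `exon_label`, `seq` for
#'   reference exons of at least two subclasses.
#' @param margin Ambiguity margin on the identity scale.
#' @return A tibble with one row per query exon: `exon_label`, `best`,
#'   `best_identity`, `runner_up`, `runner_up_identity`, `ambiguous`.
#' @export
per_exon_subclass_vote <- function(region_exons, labelled_refs,
                                   margin = 0.02) {
  subclasses <- sort(unique(labelled_refs$subclass))
  if (length(subclasses) < 2L) {
    stop("need labelled reference exons from at least two subclasses",
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(region_exons))) {
    lab <- normalize_exon_label(region_exons$exon_label[i])
    best_id <- vapply(subclasses, function(sc) {
      refs <- labelled_refs[labelled_refs$subclass == sc &
          normalize_exon_label(labelled_refs$exon_label) == lab, ,
        drop = FALSE]
      if (!nrow(refs)) return(NA_real_)
      max(vapply(refs$seq, function(r) {
        pairwise_identity(region_exons$seq[i], r)
      }, numeric(1)))
    }, numeric(1))
    ord <- order(-best_id, subclasses)
    top <- ord[1]; second <- ord[2]
    amb <- !is.na(best_id[top]) && !is.na(best_id[second]) &&
      (best_id[top] - best_id[second]) < margin
    out[[i]] <- tibble::tibble(
      exon_label = lab, best = subclasses[top],
      best_identity = best_id[top], runner_up = subclasses[second],
      runner_up_identity = best_id[second], ambiguous = amb)
  }
  dplyr::bind_rows(out)
}

#' Geometric mean of IGHZ multiplicity over IGHZ-bearing loci
#'
#' Loci whose status is not `present` (absent or pseudogene remnant) are
#' excluded. Errors when no locus bears IGHZ.
#'
#' @param statuses A list of [classify_ighz_status()] outputs.
#' @return The geometric mean of the IGHZ region counts.
#' @export
ighz_geomean <- function(statuses) {
  counts <- vapply(statuses, function(s) {
    if (identical(s$status, "present")) as.numeric(s$count) else NA_real_
  }, numeric(1))
  counts <- counts[!is.na(counts)]
  if (!length(counts)) {
    stop("geometric mean undefined: no IGHZ-bearing locus", call. = FALSE)
  }
  exp(mean(log(counts)))
}
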