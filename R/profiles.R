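# Gap-free position-specific scoring matrix (PSSM) profiles built from a
# reference multiple alignment, with a null-calibrated score threshold.
# This is the windowed-profile stand-in for a profile-HMM search: columns
# with a gap majority are dropped, per-column scores are log2 odds against
# the background, and the reporting threshold is set so that the expected
# number of false hits on shuffled sequence of locus length is small.

#' Build a scoring profile from an aligned reference set
#'
#' Per-column scores are `log2(((count + p) / (total + 4p)) / background)`
#' with pseudocount `p`; columns with more than 50% gaps are dropped. The
#' score threshold is calibrated once, under a fixed seed, on sequence drawn
#' i.i.d. from the training composition: block maxima of the null score are
#' fitted with a Gumbel tail and the threshold set so that the expected
#' number of null hits per locus length (both strands) is at most
#' `fp_per_locus`.
#'
#' @param reference_msa Character vector of equal-length aligned sequences
#'   (gaps as `-`), e.g. from [progressive_msa()].
#' @param pseudocount Pseudocount added per symbol.
#' @param background Background base frequencies (A, C, G, T).
#' @param locus_len Locus length (bp) the false-positive budget refers to.
#' @param fp_per_locus Expected null hits per locus length, both strands.
#' @param null_bp Total null sequence used for calibration.
#' @param seed Calibration seed.
#' @return An object of class `igh_profile`.
#' @export
build_profile <- function(reference_msa, pseudocount = 1,
                          background = rep(0.25, 4), locus_len = 3e5,
                          fp_per_locus = 0.01, null_bp = 6e5, seed = 1L) {
  if (length(reference_msa) < 2L) {
    stop("profile construction needs at least 2 aligned sequences",
         call. = FALSE)
  }
  if (length(unique(nchar(reference_msa))) != 1L) {
    stop("ragged alignment: sequences must have equal aligned length",
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(reference_msa), ""))
  gap_frac <- colMeans(mat == "-")
  mat <- mat[, gap_frac <= 0.5, drop = FALSE]
  W <- ncol(mat)
  if (W == 0L) stop("no columns left after gap filtering", call. = FALSE)
  pssm <- matrix(0, nrow = 5, ncol = W,
                 dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (j in seq_len(W)) {
    counts <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    total <- sum(counts)
    freq <- (as.numeric(counts) + pseudocount) / (total + 4 * pseudocount)
    pssm[1:4, j] <- log2(freq / background)
  }
  # composition the null sequence is drawn from: the training residues
  res <- mat[mat %in% c("A", "C", "G", "T")]
  comp <- as.numeric(table(factor(res, levels = c("A", "C", "G", "T"))))
  comp <- comp / sum(comp)
  prof <- structure(list(pssm = pssm, consensus_len = W,
                         background = background, composition = comp,
                         score_threshold = NA_real_,
                         locus_len = locus_len, fp_per_locus = fp_per_locus),
                    class = "igh_profile")
  prof$score_threshold <- calibrate_threshold(prof, null_bp, seed)
  prof
}

#' @export
print.igh_profile <- function(x, ...) {
  cat("<igh_profile> ", x$consensus_len, " columns, threshold ",
      round(x$score_threshold, 2), " bits\n", sep = "")
  invisible(x)
}

calibrate_threshold <- function(profile, null_bp, seed) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  null_seq <- sample.int(4L, size = null_bp, replace = TRUE,
                         prob = profile$composition) - 1L
  block <- 10000L
  mx <- cpp_pssm_block_max(profile$pssm, null_seq, block)
  mx <- mx[is.finite(mx)]
  # Gumbel fit by moments on block maxima
  beta <- sd(mx) * sqrt(6) / pi
  mu <- mean(mx) - 0.5772156649 * beta
  # expected null exceedances per locus (both strands):
  # (2 * locus_len / block) * P(block max > t) <= fp_per_locus,
  # with the Gumbel upper tail P ~ exp(-(t - mu) / beta)
  nblocks <- 2 * profile$locus_len / block
  mu + beta * log(nblocks / profile$fp_per_locus)
}

#' Scan a locus with a profile
#'
#' Both strands are scanned; windows scoring at or above the calibrated
#' threshold become candidates. Each candidate keeps its best-scoring anchor
#' window and is extended by `extend` nt on either side to absorb boundary
#' error; overlapping same-strand candidates are merged, keeping the
#' best-scoring anchor.
#'
#' @param profile An `igh_profile`.
#' @param locus A [locus_sequence()].
#' @param segment_type Label recorded on the candidates (e.g. "VH").
#' @param extend Extension (nt) applied to each side of the anchor.
#' @return A tibble of candidates with plus-strand `start`/`end` (extended)
#'   and `anchor_start`/`anchor_end` (exact profile span), `score`, `strand`.
#' @export
scan_profile <- function(profile, locus, segment_type = "VH", extend = 40L) {
  L <- nchar(locus$residues)
  W <- profile$consensus_len
  out <- list()
  for (strand in c("+", "-")) {
    enc <- dna_encode(oriented_residues(locus, strand))
    hits <- cpp_pssm_scan(profile$pssm, enc, profile$score_threshold)
    if (!nrow(hits)) next
    os <- hits$pos; oe <- hits$pos + W
    if (strand == "-") {
      tmp <- os; os <- L - oe; oe <- L - tmp
    }
    out[[strand]] <- tibble::tibble(anchor_start = as.integer(os),
                                    anchor_end = as.integer(oe),
                                    score = hits$score, strand = strand)
  }
  cand <- dplyr::bind_rows(out)
  if (!nrow(cand)) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), anchor_start = integer(),
                          anchor_end = integer(), score = numeric(),
                          strand = character(), segment_type = character()))
  }
  # merge overlapping same-strand windows, keeping the best anchor
  merged <- list()
  for (strand in unique(cand$strand)) {
    cc <- cand[cand$strand == strand, , drop = FALSE]
    ir <- IRanges::IRanges(cc$anchor_start + 1L, cc$anchor_end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (g in seq_along(red)) {
      mem <- revmap[[g]]
      best <- mem[which.max(cc$score[mem])]
      merged[[length(merged) + 1L]] <- cc[best, , drop = FALSE]
    }
  }
  cand <- dplyr::bind_rows(merged)
  cand$contig <- locus$id
  cand$start <- pmax(0L, cand$anchor_start - as.integer(extend))
  cand$end <- pmin(L, cand$anchor_end + as.integer(extend))
  cand$segment_type <- segment_type
  cand <- cand[order(cand$start, cand$strand, method = "radix"), ]
  cand[, c("contig", "start", "end", "anchor_start", "anchor_end", "score",
           "strand", "segment_type")]
}
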