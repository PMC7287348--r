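# Alignment scoring and Karlin-Altschul search statistics.
#
# E-values use the classic extreme-value model for local alignment scores:
# E = K * m' * n' * exp(-lambda * S), with the finite-size length adjustment
# m' = max(1, m - l), n' = max(1, n - l), l = ln(K m n) / H. lambda and the
# relative entropy H are solved exactly for the score matrix under the
# background composition; K defaults to 0.41, the standard tabulated value
# for the +2/-3 nucleotide scheme.

#' Nucleotide scoring scheme with search statistics
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open Gap opening cost (positive; a gap of length g costs
#'   `gap_open + g * gap_extend`).
#' @param gap_extend Gap extension cost (positive).
#' @param lambda Karlin-Altschul lambda; solved from the score matrix when
#'   `NULL`.
#' @param K Karlin-Altschul K.
#' @param background Background base composition (length 4, sums to 1).
#' @return A list of class `scoring_scheme` with fields `match`, `mismatch`,
#'   `gap_open`, `gap_extend`, `lambda`, `K`, `H` and the 5x5 substitution
#'   matrix (row/col 5 is N, scored 0).
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, lambda = NULL, K = 0.41,
                           background = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0,
            length(background) == 4, abs(sum(background) - 1) < 1e-8)
  submat <- matrix(mismatch, 5, 5)
  diag(submat) <- match
  submat[5, ] <- 0; submat[, 5] <- 0  # N scores 0 against everything
  if (is.null(lambda)) {
    lambda <- solve_lambda(submat[1:4, 1:4], background)
  }
  if (lambda <= 0 || K <= 0) {
    stop("lambda and K must be positive", call. = FALSE)
  }
  H <- relative_entropy(submat[1:4, 1:4], background, lambda)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K, H = H,
                 background = background, submat = submat,
                 alphabet = "nt"),
            class = "scoring_scheme")
}

# Unique positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1.
solve_lambda <- function(s, p) {
  f <- function(l) sum(outer(p, p) * exp(l * s)) - 1
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

# H = lambda * sum_ij q_ij s_ij with target frequencies
# q_ij = p_i p_j exp(lambda s_ij) (in nats per aligned pair).
relative_entropy <- function(s, p, lambda) {
  q <- outer(p, p) * exp(lambda * s)
  lambda * sum(q * s)
}

#' Amino-acid scoring scheme (BLOSUM62)
#'
#' Used by the translated three-frame search mode. lambda and K are the
#' standard ungapped BLOSUM62 values.
#'
#' @inheritParams scoring_scheme
#' @return A `scoring_scheme` over the 20-letter amino-acid alphabet.
#' @export
scoring_scheme_aa <- function(gap_open = 11L, gap_extend = 1L,
                              lambda = 0.3176, K = 0.134) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  b62 <- data_env$BLOSUM62
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  submat <- rbind(cbind(b62[aa, aa], X = 0), X = 0)
  structure(list(match = NA, mismatch = NA, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 H = 0.4012, background = NULL, submat = submat,
                 alphabet = "aa"),
            class = "scoring_scheme")
}

#' Bitscore of a raw alignment score
#'
#' `(lambda * S - ln K) / ln 2`.
#'
#' @param raw_score Raw alignment score(s).
#' @param scheme A [scoring_scheme()].
#' @return Bitscore(s).
#' @export
bitscore <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `raw_score`
#' in a search of a query of length `query_len` against a subject of length
#' `subject_len`. Strictly decreasing in the score and (up to the length
#' adjustment) linear in the subject length.
#'
#' @param raw_score Raw alignment score(s).
#' @param query_len Query length (> 0).
#' @param subject_len Subject length (> 0).
#' @param scheme A [scoring_scheme()].
#' @param length_adjust Apply the finite-size length adjustment
#'   `l = ln(K m n) / H`?
#' @return E-value(s).
#' @export
compute_evalue <- function(raw_score, query_len, subject_len, scheme,
                           length_adjust = TRUE) {
  stopifnot(query_len > 0, subject_len > 0)
  if (scheme$lambda <= 0 || scheme$K <= 0) {
    stop("lambda and K must be positive", call. = FALSE)
  }
  m <- query_len; n <- subject_len
  if (length_adjust && is.finite(scheme$H) && scheme$H > 0) {
    l <- log(scheme$K * m * n) / scheme$H
    m <- pmax(1, m - l)
    n <- pmax(1, n - l)
  }
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}
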