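# Progressive multiple alignment: a k-mer-distance guide tree (average
# linkage) drives successive profile-profile Needleman-Wunsch merges.
# Deliberately small and deterministic; it serves profile construction and
# the distance phylogeny, not large-scale alignment.

kmer_counts <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(numeric(4^k))
  enc <- dna_encode(s)
  idx <- integer(n - k + 1L)
  valid <- rep(TRUE, n - k + 1L)
  for (j in 0:(k - 1L)) {
    v <- enc[(1L + j):(n - k + 1L + j)]
    valid <- valid & v < 4L
    idx <- idx * 4L + ifelse(v < 4L, v, 0L)
  }
  tabulate(idx[valid] + 1L, nbins = 4^k)
}

kmer_distance_matrix <- function(seqs, k = 4L) {
  counts <- lapply(seqs, kmer_counts, k = k)
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- sum(pmin(ci, cj))
      d[i, j] <- d[j, i] <- 1 - shared / max(1, min(sum(ci), sum(cj)))
    }
  }
  d
}

profile_of <- function(aln_mat) {
  # 4 x L frequency matrix over A,C,G,T; gap mass implicit
  L <- ncol(aln_mat)
  p <- matrix(0, 4, L)
  for (b in 1:4) {
    p[b, ] <- colMeans(aln_mat == c("A", "C", "G", "T")[b])
  }
  p
}

apply_path <- function(aln_mat, path, which_gap) {
  # expand an alignment matrix along the merge path; which_gap: the path
  # code that inserts a gap column into this alignment (1 = gap in B means
  # A advances, so code 2 gaps A; code 1 gaps B)
  out <- matrix("-", nrow(aln_mat), length(path),
                dimnames = list(rownames(aln_mat), NULL))
  j <- 0L
  for (i in seq_along(path)) {
    if (path[i] != which_gap) {
      j <- j + 1L
      out[, i] <- aln_mat[, j]
    }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' @param seqs Named character vector of nucleotide sequences (>= 2).
#' @param match,mismatch,gap Column scoring for the profile-profile merges.
#' @param k k-mer length for the guide-tree distance.
#' @return Named character vector of aligned sequences (equal length, gaps
#'   as `-`), in the input order.
#' @export
progressive_msa <- function(seqs, match = 1, mismatch = -1, gap = -2,
                            k = 4L) {
  n <- length(seqs)
  stopifnot(n >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 1L) return(seqs)
  d <- kmer_distance_matrix(seqs, k)
  hc <- hclust(as.dist(d), method = "average")
  # alignments indexed like hclust nodes: negatives are leaves
  get_aln <- function(node) {
    if (node < 0L) {
      matrix(strsplit(seqs[[-node]], "")[[1]], nrow = 1,
             dimnames = list(names(seqs)[-node], NULL))
    } else {
      merged[[node]]
    }
  }
  merged <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    a <- get_aln(hc$merge[m, 1])
    b <- get_aln(hc$merge[m, 2])
    path <- cpp_profile_nw(profile_of(a), profile_of(b), match, mismatch, gap)
    ea <- apply_path(a, path, which_gap = 2L)
    eb <- apply_path(b, path, which_gap = 1L)
    merged[[m]] <- rbind(ea, eb)
  }
  final <- merged[[nrow(hc$merge)]]
  out <- apply(final, 1, paste, collapse = "")
  out[names(seqs)]
}
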