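# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Random DNA of length n.
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive Needleman-Wunsch identity oracle: match +1, mismatch -1,
# linear gap -2; identity = matches / aligned columns (incl. gaps).
nw_identity_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  S <- matrix(0, m + 1, n + 1)
  S[, 1] <- seq(0, -2 * m, by = -2)
  S[1, ] <- seq(0, -2 * n, by = -2)
  for (i in 1:m) {
    for (j in 1:n) {
      S[i + 1, j + 1] <- max(S[i, j] + ifelse(av[i] == bv[j], 1, -1),
                             S[i, j + 1] - 2, S[i + 1, j] - 2)
    }
  }
  # traceback counting matches and columns
  i <- m; j <- n; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(av[i] == bv[j], 1, -1)) {
      matches <- matches + (av[i] == bv[j]); cols <- cols + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      cols <- cols + 1L; i <- i - 1
    } else {
      cols <- cols + 1L; j <- j - 1
    }
  }
  matches / cols
}

# Exhaustive local-alignment optimum via Biostrings Smith-Waterman with the
# package's nucleotide scheme (match +2, mismatch -3, gap 5/2).
sw_optimum_oracle <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(query, subject, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2,
                                scoreOnly = TRUE)
}

# Brute-force connected components of an overlap graph over labelled
# intervals (same label and overlapping => edge).
overlap_components_oracle <- function(start, end, label) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- label[i] == label[j] &&
        start[i] < end[j] && start[j] < end[i]
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Brute-force sliding-window Hamming oracle for the DH opposite-sense RSS
# pattern. Returns every placement with mismatches <= max_mm.
dh_scan_oracle <- function(seq, hept = "CACAGTG", nona = "ACAAAAACC",
                           spacer = 12L, core_min = 10L, core_max = 40L,
                           max_mm = 8L) {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  sv <- strsplit(seq, "")[[1]]
  hv <- strsplit(hept, "")[[1]]; nv <- strsplit(nona, "")[[1]]
  rhv <- strsplit(rc(hept), "")[[1]]; rnv <- strsplit(rc(nona), "")[[1]]
  H <- length(hv); N9 <- length(nv)
  out <- list()
  for (core in core_min:core_max) {
    plen <- 2L * (N9 + spacer + H) + core
    if (plen > length(sv)) next
    for (p in 0:(length(sv) - plen)) {
      lh <- p + N9 + spacer
      rh <- lh + H + core
      rn <- rh + H + spacer
      mm <- sum(sv[(p + 1):(p + N9)] != rnv) +
        sum(sv[(lh + 1):(lh + H)] != rhv) +
        sum(sv[(rh + 1):(rh + H)] != hv) +
        sum(sv[(rn + 1):(rn + N9)] != nv)
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          core_start = lh + H, core_end = rh, mismatches = mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(core_start = integer(), core_end = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# Exhaustive Dollo oracle: minimise the number of loss edges over all edge
# subsets that reproduce the tip states (present at root, no regain).
dollo_oracle <- function(tree, states) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  ne <- nrow(edges)
  # tips below each edge's child
  children_of <- split(edges[, 2], edges[, 1])
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(children_of[[as.character(v)]], tips_below))
  }
  below <- lapply(edges[, 2], tips_below)
  target_absent <- which(states[tree$tip.label] == "absent")
  best <- Inf
  for (mask in 0:(2^ne - 1)) {
    loss <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
    if (length(loss) >= best) next
    absent <- unique(unlist(below[loss]))
    if (setequal(absent, target_absent)) best <- length(loss)
  }
  best
}

# Brute-force optimal one-to-one matching size between truth and predicted
# intervals (same type/strand, reciprocal overlap >= frac), by recursion.
matching_oracle <- function(tt, pp, frac = 0.8) {
  if (!nrow(tt) || !nrow(pp)) return(0L)
  ok <- matrix(FALSE, nrow(tt), nrow(pp))
  for (i in seq_len(nrow(tt))) {
    for (j in seq_len(nrow(pp))) {
      ov <- min(tt$end[i], pp$end[j]) - max(tt$start[i], pp$start[j])
      rec <- min(ov / (tt$end[i] - tt$start[i]),
                 ov / (pp$end[j] - pp$start[j]))
      ok[i, j] <- tt$strand[i] == pp$strand[j] && rec >= frac
    }
  }
  rec_match <- function(i, used) {
    if (i > nrow(tt)) return(0L)
    best <- rec_match(i + 1L, used)
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec_match(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  rec_match(1L, rep(FALSE, nrow(pp)))
}
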