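# IGHZ subclass phylogeny at desk scale: Cz1-4 concatenation, progressive
# alignment, Jukes-Cantor distances, neighbour joining with nonparametric
# bootstrap, support-based polytomy collapsing, subclass clade labelling,
# and Dollo minimum-loss reconstruction on a species tree.

#' Concatenate constant-region exons in rank order
#'
#' Per region, the nucleotide sequences of the requested exons (Cz1-Cz4 by
#' default) are joined in rank order; missing exons contribute nothing and
#' are recorded in the presence mask. Outgroup sequences are built
#' identically from Cm1-Cm4. Regions with none of the requested exons are
#' excluded with a warning.
#'
#' @param exons Tibble with columns `region`, `exon_label`, `seq`.
#' @param labels Exon labels to concatenate, in rank order.
#' @return Named character vector of concatenated sequences, with a
#'   `presence` attribute (logical matrix regions x labels).
#' @export
concatenate_cz <- function(exons, labels = c("Cz1", "Cz2", "Cz3", "Cz4")) {
  labels <- normalize_exon_label(labels)
  exons$exon_label <- normalize_exon_label(exons$exon_label)
  regions <- unique(exons$region)
  out <- character(); mask <- NULL
  for (r in regions) {
    e <- exons[exons$region == r & exons$exon_label %in% labels, ,
               drop = FALSE]
    have <- labels %in% e$exon_label
    if (!any(have)) {
      warning("region '", r, "' has none of ",
              paste(labels, collapse = ", "), "; excluded", call. = FALSE)
      next
    }
    pieces <- vapply(labels[have], function(l) {
      e$seq[match(l, e$exon_label)]
    }, character(1))
    out[r] <- paste(pieces, collapse = "")
    mask <- rbind(mask, setNames(have, labels))
    rownames(mask)[nrow(mask)] <- r
  }
  attr(out, "presence") <- mask
  out
}

#' Jukes-Cantor distance from a mismatch fraction
#'
#' `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' @param p Mismatch fraction(s) in `[0, 0.75)`.
#' @return Corrected distance(s).
#' @export
jc_distance <- function(p) {
  ifelse(p >= 0.75, Inf, -0.75 * log(1 - (4 / 3) * p))
}

#' Align sequences and compute Jukes-Cantor distances
#'
#' Sequences are aligned with [progressive_msa()]; pairwise distances are
#' the Jukes-Cantor-corrected mismatch fraction over ungapped shared
#' columns. Two sequences sharing zero ungapped columns are an error.
#'
#' @param sequences Named character vector (>= 3 sequences).
#' @return List with `alignment` (named character vector) and `distances`
#'   (symmetric matrix, zero diagonal).
#' @export
align_and_distance <- function(sequences) {
  if (length(sequences) < 3L) {
    stop("need at least 3 sequences", call. = FALSE)
  }
  aln <- progressive_msa(sequences)
  list(alignment = aln, distances = alignment_jc_distances(aln))
}

alignment_jc_distances <- function(aln) {
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- mat[i, ] != "-" & mat[j, ] != "-"
      ns <- sum(shared)
      if (ns == 0L) {
        stop("sequences '", names(aln)[i], "' and '", names(aln)[j],
             "' share no ungapped columns; distance undefined",
             call. = FALSE)
      }
      p <- sum(mat[i, shared] != mat[j, shared]) / ns
      d[i, j] <- d[j, i] <- jc_distance(p)
    }
  }
  d
}

#' Neighbour-joining tree with non-negative branch lengths
#'
#' Standard neighbour joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch, preserving
#' path lengths through the parent.
#'
#' @param distances Symmetric distance matrix with taxon dimnames.
#' @return An \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(as.dist(distances))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  tree
}

#' Bootstrap support by column resampling
#'
#' Draws `B` seeded column-resampled replicates of the alignment, passes
#' each through Jukes-Cantor distances and neighbour joining, and scores
#' each internal edge of the full-alignment tree by the percentage of
#' replicates containing the same bipartition. Supports are stored in
#' `node.label`.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param B Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return The reference NJ tree with percentage supports in `node.label`.
#' @export
bootstrap_support <- function(alignment, B = 100L, seed = 1L) {
  stopifnot(B >= 1L)
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  ref <- nj_tree(alignment_jc_distances(alignment))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- ncol(mat)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    d <- alignment_jc_distances_safe(rep_aln)
    boots[[b]] <- nj_tree(d)
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- as.character(round(100 * counts / B, 1))
  ref
}

# As alignment_jc_distances, but saturated/degenerate pairs in a bootstrap
# replicate get a large finite distance instead of an error.
alignment_jc_distances_safe <- function(aln) {
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- mat[i, ] != "-" & mat[j, ] != "-"
      ns <- sum(shared)
      p <- if (ns == 0L) 0.74 else
        min(0.74, sum(mat[i, shared] != mat[j, shared]) / ns)
      d[i, j] <- d[j, i] <- jc_distance(p)
    }
  }
  d
}

#' Collapse weakly supported nodes into polytomies
#'
#' Every internal edge whose child-node support is strictly below
#' `threshold_pct` is contracted (the child's children reattach to its
#' parent, the collapsed edge length is added to the children's edges to
#' preserve tip depths). Tips are never touched; supports at or above the
#' threshold are kept. Idempotent.
#'
#' @param tree A `phylo` tree with numeric supports in `node.label` (root
#'   support may be empty/NA).
#' @param threshold_pct Support threshold in percent (default 65: a node at
#'   64 collapses, one at 65 survives).
#' @return The collapsed `phylo` tree.
#' @export
collapse_low_support <- function(tree, threshold_pct = 65) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  supports <- suppressWarnings(as.numeric(tree$node.label))
  drop_nodes <- which(!is.na(supports) & supports < threshold_pct) + ntip
  drop_nodes <- setdiff(drop_nodes, root)
  if (!length(drop_nodes)) return(tree)
  # contract deeper nodes first so chains of weak edges collapse onto the
  # surviving ancestor
  depth <- ape::node.depth.edgelength(
    structure(list(edge = tree$edge,
                   edge.length = rep(1, nrow(tree$edge)),
                   tip.label = tree$tip.label, Nnode = tree$Nnode),
              class = "phylo"))
  drop_nodes <- drop_nodes[order(-depth[drop_nodes])]
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(edge))
  # push each dropped node's extra length onto its children, reparent them
  parent_of <- function(v) edge[edge[, 2] == v, 1]
  for (v in drop_nodes) {
    in_e <- which(edge[, 2] == v)
    add <- elen[in_e]
    child_e <- which(edge[, 1] == v)
    edge[child_e, 1] <- edge[in_e, 1]
    elen[child_e] <- elen[child_e] + add
  }
  keep_e <- !(edge[, 2] %in% drop_nodes)
  edge <- edge[keep_e, , drop = FALSE]
  elen <- elen[keep_e]
  # renumber internal nodes
  kept_internal <- sort(unique(edge[, 1]))
  new_id <- setNames(seq_along(kept_internal) + ntip, kept_internal)
  edge[, 1] <- new_id[as.character(edge[, 1])]
  internal_child <- edge[, 2] > ntip
  edge[internal_child, 2] <- new_id[as.character(edge[internal_child, 2])]
  out <- tree
  out$edge <- edge
  out$edge.length <- elen
  out$Nnode <- length(kept_internal)
  if (!is.null(tree$node.label)) {
    out$node.label <- tree$node.label[kept_internal - ntip]
  }
  out
}

#' Label subclass clades on a rooted gene tree
#'
#' After rooting on the outgroup, the ingroup ancestor is treated as the
#' radiation point: maximal clades strictly below it whose tips come from
#' at least 2 distinct species are labelled IGHZA, IGHZB, ... in order of
#' first tip appearance; all other ingroup tips are labelled `"none"`.
#'
#' @param tree A `phylo` tree (rooted, or rootable on `outgroup`).
#' @param outgroup Tip labels of the outgroup.
#' @param species Named character vector mapping tip labels to species.
#' @return Named character vector: tip label -> subclass label or "none".
#' @export
assign_subclasses <- function(tree, outgroup, species) {
  if (!missing(outgroup) && length(outgroup)) {
    tree <- tryCatch(
      ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
      error = function(e) {
        # outgroup not monophyletic in the gene tree: root on its first tip
        ape::root(tree, outgroup = outgroup[1], resolve.root = TRUE)
      })
  } else if (!ape::is.rooted(tree)) {
    stop("tree must be rooted or an outgroup given", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  ingroup <- setdiff(tree$tip.label, outgroup)
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(children_of[[as.character(v)]], tips_below))
  }
  labels <- setNames(rep("none", length(ingroup)), ingroup)
  next_label <- 0L
  assign_rec <- function(v) {
    tips <- tips_below(v)
    all_in <- all(tips %in% ingroup)
    if (all_in && length(setdiff(ingroup, tips)) > 0L &&
        length(unique(species[tips])) >= 2L) {
      next_label <<- next_label + 1L
      labels[tips] <<- paste0("IGHZ", LETTERS[next_label])
      return(invisible())
    }
    if (v > ntip) {
      for (ch in children_of[[as.character(v)]]) assign_rec(ch)
    }
  }
  assign_rec(ntip + 1L)
  labels
}

#' Minimum Dollo loss count on a species tree
#'
#' Assuming the character (IGHZ) is present at the root and, once deleted,
#' can never be restored, the minimum number of loss events explaining the
#' tip states equals the number of maximal all-absent tip subtrees. Returns
#' the count and one optimal loss-edge set (named by the child node).
#'
#' @param species_tree A rooted `phylo` tree.
#' @param states Named character vector: tip label -> `"present"` or
#'   `"absent"`; every tip must have a state.
#' @return List with `losses` (integer) and `loss_edges` (character vector
#'   of child labels; internal nodes as `node_<k>` or their node label).
#' @export
dollo_min_losses <- function(species_tree, states) {
  tips <- species_tree$tip.label
  missing_states <- setdiff(tips, names(states))
  if (length(missing_states)) {
    stop("tips missing a presence state: ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(states[tips]), c("present", "absent"))
  if (length(bad)) {
    stop("states must be 'present' or 'absent'", call. = FALSE)
  }
  ntip <- length(tips)
  root <- ntip + 1L
  children_of <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  all_absent <- logical(ntip + species_tree$Nnode)
  postorder <- function(v) {
    if (v <= ntip) {
      all_absent[v] <<- states[tips[v]] == "absent"
    } else {
      ch <- children_of[[as.character(v)]]
      for (c in ch) postorder(c)
      all_absent[v] <<- all(all_absent[ch])
    }
  }
  postorder(root)
  node_name <- function(v) {
    if (v <= ntip) return(tips[v])
    if (!is.null(species_tree$node.label) &&
        nzchar(species_tree$node.label[v - ntip] %||% "")) {
      return(species_tree$node.label[v - ntip])
    }
    paste0("node_", v - ntip)
  }
  loss_edges <- character()
  walk <- function(v) {
    if (all_absent[v]) {
      loss_edges <<- c(loss_edges, node_name(v))
      return(invisible())
    }
    if (v > ntip) {
      for (c in children_of[[as.character(v)]]) walk(c)
    }
  }
  walk(root)
  list(losses = length(loss_edges), loss_edges = loss_edges)
}

#' Read IGHZ presence/absence states from a two-column TSV
#'
#' @param path TSV with columns `species` and `status` (present/absent).
#' @return Named character vector species -> status.
#' @export
read_presence_states <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(tab$status, tab$species)
}
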