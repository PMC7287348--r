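# FASTA input/output. Reference libraries use a pipe-delimited header
# grammar: id|species|segment_type|isotype|exon_label (documented in the
# README); plain headers yield locus sequences.

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @param as_reference If `TRUE`, every header must follow the reference
#'   grammar `id|species|segment_type|isotype|exon_label` and a reference
#'   segment table is returned. If `FALSE`, a list of [locus_sequence()]
#'   objects is returned. The default (`NA`) auto-detects from the first
#'   header.
#' @return A reference-segment tibble or a list of `locus_sequence` objects,
#'   in file order, residues uppercased.
#' @export
read_sequences <- function(path, alphabet = c("nt", "aa"),
                           as_reference = NA) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- parse_fasta(path)
  if (is.na(as_reference)) {
    as_reference <- length(recs$id) > 0L && grepl("|", recs$id[1], fixed = TRUE)
  }
  residues <- toupper(recs$seq)
  ok_re <- if (alphabet == "nt") "[^ACGTN]" else "[^ACDEFGHIKLMNPQRSTVWYX*]"
  for (i in seq_along(residues)) {
    bad <- regexpr(ok_re, residues[i])
    if (bad > 0L) {
      stop("illegal ", alphabet, " residue '", substr(residues[i], bad, bad),
           "' in record '", recs$id[i], "'", call. = FALSE)
    }
  }
  if (as_reference) {
    parts <- strsplit(recs$id, "|", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != 5L)) {
      bad <- which(nfield != 5L)[1]
      stop("reference header '", recs$id[bad], "' does not follow ",
           "id|species|segment_type|isotype|exon_label", call. = FALSE)
    }
    m <- do.call(rbind, parts)
    reference_segments(id = m[, 1], species = m[, 2], segment_type = m[, 3],
                       isotype = m[, 4], exon_label = m[, 5],
                       residues = residues, alphabet = alphabet)
  } else {
    mapply(function(id, seqs, desc) locus_sequence(id, seqs, desc),
           recs$id, residues, recs$desc, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
}

# Minimal strict FASTA parser that can report the offending line number;
# Biostrings is used for writing (and as a cross-check in the tests).
parse_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list(id = character(), desc = character(),
                                       seq = character()))
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) {
    stop("malformed FASTA at line 1 of ", path, ": expected '>'",
         call. = FALSE)
  }
  grp <- cumsum(hdr)
  ids <- character(max(grp)); desc <- character(max(grp))
  seqs <- character(max(grp))
  for (g in seq_len(max(grp))) {
    block <- lines[grp == g]
    h <- sub("^>", "", block[1])
    sp <- regexpr("[ \t]", h)
    if (sp > 0L) {
      ids[g] <- substr(h, 1L, sp - 1L)
      desc[g] <- sub("^[ \t]+", "", substr(h, sp, nchar(h)))
    } else {
      ids[g] <- h; desc[g] <- ""
    }
    body <- block[-1]
    if (any(grepl("[ \t]", body))) {
      bad_line <- which(grp == g)[-1][grep("[ \t]", body)[1]]
      stop("malformed FASTA at line ", bad_line, " of ", path,
           ": whitespace in sequence", call. = FALSE)
    }
    seqs[g] <- paste(body, collapse = "")
  }
  if (any(!nzchar(ids))) {
    stop("malformed FASTA in ", path, ": empty record id", call. = FALSE)
  }
  list(id = ids, desc = desc, seq = seqs)
}

#' Write sequences to FASTA
#'
#' Accepts a list of [locus_sequence()] objects, a reference-segment tibble
#' (headers are rebuilt from the pipe grammar), or a named character vector.
#'
#' @param x Sequences to write.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, width = 70L) {
  if (is.data.frame(x)) {
    nm <- paste(x$id, x$species, x$segment_type, x$isotype, x$exon_label,
                sep = "|")
    seqs <- x$residues
  } else if (is.list(x) && length(x) && inherits(x[[1]], "locus_sequence")) {
    nm <- vapply(x, function(s) {
      if (nzchar(s$description)) paste(s$id, s$description) else s$id
    }, character(1))
    seqs <- vapply(x, `[[`, character(1), "residues")
  } else {
    nm <- names(x)
    seqs <- unname(x)
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
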