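# Domain types and sequence utilities.
#
# Coordinate convention (used everywhere internally): 0-based, half-open
# intervals on the plus strand of the input sequence. Minus-strand features
# store plus-strand intervals with strand = "-". Conversions to 1-based
# (GFF3) happen only at I/O.

#' Create a locus sequence
#'
#' A named nucleotide sequence, the substrate of all scans. Residues are
#' uppercased on ingest and must be drawn from A, C, G, T, N; degenerate
#' IUPAC codes beyond N are rejected (they are accepted in motif definitions
#' only, not in genomic input).
#'
#' @param id Sequence identifier.
#' @param residues Nucleotide string.
#' @param description Optional free-text description.
#' @return An object of class `locus_sequence` with fields `id`, `residues`
#'   and `description`.
#' @export
locus_sequence <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (nchar(residues) < 1L) {
    stop("locus sequence '", id, "' is empty", call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", residues)
  if (bad > 0L) {
    stop("illegal residue '", substr(residues, bad, bad), "' at position ",
         bad, " in sequence '", id, "'", call. = FALSE)
  }
  structure(list(id = id, residues = residues, description = description),
            class = "locus_sequence")
}

#' @export
print.locus_sequence <- function(x, ...) {
  cat("<locus_sequence> ", x$id, " (", nchar(x$residues), " bp)\n", sep = "")
  invisible(x)
}

#' @export
length.locus_sequence <- function(x) nchar(x$residues)

as_locus <- function(x, id = "locus") {
  if (inherits(x, "locus_sequence")) x else locus_sequence(id, x)
}

#' Build a reference-segment table
#'
#' Reference gene-segment libraries carry, per record: an id, the source
#' species, the segment type (VH, JH or CH), and for CH entries the isotype
#' and exon label. VH/JH entries must have `isotype = "none"`.
#'
#' @param id,species,segment_type,isotype,exon_label,residues,alphabet
#'   Field vectors, recycled to a common length.
#' @return A tibble with one row per reference segment.
#' @export
reference_segments <- function(id, species, segment_type, isotype = "none",
                               exon_label = "none", residues,
                               alphabet = "nt") {
  out <- tibble::tibble(
    id = as.character(id), species = as.character(species),
    segment_type = as.character(segment_type),
    isotype = as.character(isotype), exon_label = as.character(exon_label),
    residues = toupper(as.character(residues)),
    alphabet = as.character(alphabet)
  )
  validate_reference_segments(out)
}

validate_reference_segments <- function(x) {
  stopifnot(all(c("id", "species", "segment_type", "isotype", "exon_label",
                  "residues", "alphabet") %in% names(x)))
  bad_type <- setdiff(unique(x$segment_type), c("VH", "JH", "CH"))
  if (length(bad_type)) {
    stop("unknown segment_type in reference library: ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  ch <- x$segment_type == "CH"
  if (any(ch & (x$isotype == "none" | x$exon_label == "none"))) {
    stop("CH reference entries must carry an isotype and an exon label",
         call. = FALSE)
  }
  if (any(!ch & x$isotype != "none")) {
    stop("VH/JH reference entries must have isotype 'none'", call. = FALSE)
  }
  x
}

#' Construct a gene-segment table
#'
#' The common currency of the annotation stages: one row per annotated
#' feature (VH, DH, JH segment or CH exon), with 0-based half-open
#' plus-strand coordinates, a strand, a name, optional family and a
#' comma-separated flag set drawn from `pseudogene`, `incomplete`,
#' `manually_flagged`.
#'
#' @param contig,start,end,strand,segment_type,isotype,exon_label,name,family,flags,seq
#'   Column vectors (recycled).
#' @return A tibble of gene segments.
#' @export
gene_segments <- function(contig = character(), start = integer(),
                          end = integer(), strand = "+",
                          segment_type = character(), isotype = "none",
                          exon_label = "none", name = NA_character_,
                          family = NA_character_, flags = "",
                          seq = NA_character_) {
  out <- tibble::tibble(
    contig = as.character(contig), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    segment_type = as.character(segment_type),
    isotype = as.character(isotype), exon_label = as.character(exon_label),
    name = as.character(name), family = as.character(family),
    flags = as.character(flags), seq = as.character(seq)
  )
  if (nrow(out)) {
    stopifnot(all(out$start >= 0L), all(out$end > out$start),
              all(out$strand %in% c("+", "-")))
  }
  out
}

add_flag <- function(flags, flag) {
  ifelse(flags == "" | is.na(flags), flag,
         ifelse(grepl(flag, flags, fixed = TRUE), flags,
                paste(flags, flag, sep = ",")))
}

has_flag <- function(flags, flag) {
  !is.na(flags) & grepl(flag, flags, fixed = TRUE)
}

# ---- sequence utilities ----------------------------------------------------

DNA_CODE <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[utf8ToInt("N") + 1L] <- 4L
  lut
})

dna_encode <- function(s) {
  DNA_CODE[as.integer(charToRaw(s)) + 1L]
}

dna_decode <- function(v) {
  rawToChar(as.raw(utf8ToInt("ACGTN")[v + 1L]))
}

revcomp <- function(s) {
  vapply(s, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}

subseq_chr <- function(s, start, end) {
  # 0-based half-open extraction
  substr(s, start + 1L, end)
}

translate_nt <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n)),
                          if.fuzzy.codon = "X")
  ))
}

# Map an interval between plus-strand coordinates and coordinates on the
# reverse-complemented sequence of total length L (both 0-based half-open).
flip_interval <- function(start, end, L) {
  list(start = L - end, end = L - start)
}

# Oriented view of a locus: residues as read 5'->3' on the given strand.
oriented_residues <- function(locus, strand) {
  if (strand == "+") locus$residues else revcomp(locus$residues)
}
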