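# Annotation output: GFF3 (1-based inclusive), BED (0-based half-open) and
# TSV. Writers are deterministic -- rows sorted by (contig, start, end, name)
# -- so write -> read -> write round trips are byte-identical.

sort_segments <- function(segments) {
  segments[order(segments$contig, segments$start, segments$end,
                 segments$name, method = "radix"), , drop = FALSE]
}

#' Write gene segments to GFF3, BED or TSV
#'
#' GFF3 is emitted 1-based inclusive, BED 0-based half-open. GFF3 and TSV
#' carry name, segment type, isotype, exon label and flags as attributes;
#' BED carries the feature name only (BED has no attribute column). Rows are
#' sorted by (contig, start, end, name).
#'
#' @param segments A gene-segment tibble (see [gene_segments()]).
#' @param path Output path.
#' @param format `"GFF3"`, `"BED"` or `"TSV"`.
#' @param contig_lengths Optional named vector of contig lengths; when given,
#'   intervals exceeding their contig are an error.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(segments, path,
                              format = c("GFF3", "BED", "TSV"),
                              contig_lengths = NULL) {
  format <- match.arg(format)
  segments <- sort_segments(segments)
  if (!is.null(contig_lengths) && nrow(segments)) {
    lim <- contig_lengths[segments$contig]
    if (any(is.na(lim)) || any(segments$end > lim)) {
      stop("segment interval exceeds contig length", call. = FALSE)
    }
  }
  con <- file(path, open = "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  if (format == "GFF3") {
    writeLines("##gff-version 3", con)
    if (nrow(segments)) {
      attrs <- sprintf(
        "ID=%s;segment_type=%s;isotype=%s;exon_label=%s;family=%s;flags=%s",
        segments$name, segments$segment_type, segments$isotype,
        segments$exon_label,
        ifelse(is.na(segments$family), "none", segments$family),
        ifelse(segments$flags == "", "none", segments$flags))
      writeLines(sprintf("%s\tighlocus\t%s\t%d\t%d\t.\t%s\t.\t%s",
                         segments$contig, segments$segment_type,
                         segments$start + 1L, segments$end, segments$strand,
                         attrs), con)
    }
  } else if (format == "BED") {
    writeLines("track name=ighlocus", con)
    if (nrow(segments)) {
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", segments$contig,
                         segments$start, segments$end, segments$name,
                         segments$strand), con)
    }
  } else {
    cols <- c("contig", "start", "end", "strand", "segment_type", "isotype",
              "exon_label", "name", "family", "flags")
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(segments)) {
      df <- segments[, cols]
      df$family <- ifelse(is.na(df$family), "none", df$family)
      df$flags <- ifelse(df$flags == "", "none", df$flags)
      writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
    }
  }
  invisible(path)
}

#' Read gene segments written by [write_annotations()]
#'
#' @param path Input path.
#' @param format `"GFF3"`, `"BED"` or `"TSV"`.
#' @return A gene-segment tibble with internal 0-based half-open coordinates.
#' @export
read_annotations <- function(path, format = c("GFF3", "BED", "TSV")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (!length(lines)) return(gene_segments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, f)
  if (format == "GFF3") {
    attr_get <- function(a, key) {
      v <- sub(paste0(".*", key, "="), "", a)
      sub(";.*", "", v)
    }
    fam <- attr_get(m[, 9], "family")
    flg <- attr_get(m[, 9], "flags")
    gene_segments(contig = m[, 1], start = as.integer(m[, 4]) - 1L,
                  end = as.integer(m[, 5]), strand = m[, 7],
                  segment_type = m[, 3],
                  isotype = attr_get(m[, 9], "isotype"),
                  exon_label = attr_get(m[, 9], "exon_label"),
                  name = attr_get(m[, 9], "ID"),
                  family = ifelse(fam == "none", NA_character_, fam),
                  flags = ifelse(flg == "none", "", flg))
  } else if (format == "BED") {
    gene_segments(contig = m[, 1], start = as.integer(m[, 2]),
                  end = as.integer(m[, 3]), strand = m[, 6],
                  segment_type = "none", name = m[, 4])
  } else {
    stopifnot(identical(f[[1]][1], "contig"))
    m <- m[-1, , drop = FALSE]
    if (!nrow(m)) return(gene_segments())
    gene_segments(contig = m[, 1], start = as.integer(m[, 2]),
                  end = as.integer(m[, 3]), strand = m[, 4],
                  segment_type = m[, 5], isotype = m[, 6],
                  exon_label = m[, 7], name = m[, 8],
                  family = ifelse(m[, 9] == "none", NA_character_, m[, 9]),
                  flags = ifelse(m[, 10] == "none", "", m[, 10]))
  }
}

#' Summarize a locus annotation
#'
#' Counts annotated segments per type, constant regions per isotype, reports
#' per-region completeness and the locus span (minimum start to maximum end
#' over annotated features).
#'
#' @param annotation An `igh_annotation` (see [annotate_locus()]), or a list
#'   with elements `segments` and (optionally) `regions`.
#' @return A list with elements `segment_counts`, `constant_regions`,
#'   `completeness` and `span`.
#' @export
locus_report <- function(annotation) {
  seg <- annotation$segments
  counts <- lapply(c(VH = "VH", DH = "DH", JH = "JH", `CH-exon` = "CH-exon"),
                   function(t) sum(seg$segment_type == t))
  regions <- annotation$regions
  reg_counts <- list(); completeness <- list()
  if (!is.null(regions) && nrow(regions)) {
    for (iso in sort(unique(regions$isotype))) {
      reg_counts[[iso]] <- sum(regions$isotype == iso)
    }
    completeness <- setNames(as.list(regions$complete), regions$name)
  }
  span <- if (nrow(seg)) {
    c(start = min(seg$start), end = max(seg$end))
  } else {
    c(start = NA_integer_, end = NA_integer_)
  }
  list(segment_counts = counts, constant_regions = reg_counts,
       completeness = completeness, span = as.list(span))
}

#' Write a locus report as JSON
#'
#' @inheritParams locus_report
#' @param path Output path.
#' @return The report list, invisibly.
#' @export
write_locus_report <- function(annotation, path) {
  rep <- locus_report(annotation)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(rep)
}
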