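#' Annotation configuration
#'
#' Houses every numeric threshold used by the annotation stages. Defaults
#' follow the published curation protocol for teleost IGH loci:
#' alignment groups with best E-value above `primary_evalue_max` (0.001) are
#' discarded, as are groups overlapped by a different-label group whose
#' bitscore exceeds theirs by at least `override_bitscore_diff` (16.5); the
#' stringent second pass requires E-value at most `stringent_evalue_max`
#' (1e-8) and at least `stringent_min_ref_exons` (2) distinct aligned
#' reference exons. Candidate scaffolds are retained with hits to at least
#' `scaffold_min_segment_types` (2) distinct segment types, or with a single
#' type covering at least `scaffold_min_coverage_frac` (1%) of the scaffold.
#' DH discovery tolerates up to `dh_max_mismatches` (8) mismatches across the
#' whole opposite-sense RSS pattern; VH families are single-linkage clusters
#' at `vh_family_identity` (80%) global-alignment identity; tree nodes below
#' `support_collapse_pct` (65) bootstrap support are collapsed.
#'
#' @param primary_evalue_max Maximum group E-value in the first CH filter.
#' @param override_bitscore_diff Bitscore gap at which an overlapping
#'   different-label group overrides this one.
#' @param stringent_evalue_max Maximum E-value in the stringent second pass.
#' @param stringent_min_ref_exons Minimum distinct aligned reference exons in
#'   the stringent second pass.
#' @param scaffold_min_coverage_frac Minimum hit coverage for single-type
#'   scaffolds.
#' @param scaffold_min_segment_types Distinct segment types that retain a
#'   scaffold outright.
#' @param dh_max_mismatches Mismatch budget across the whole DH RSS pattern.
#' @param vh_family_identity Single-linkage clustering threshold (fraction).
#' @param support_collapse_pct Bootstrap support (percent) below which nodes
#'   are collapsed into polytomies.
#' @param max_intron_gap Maximum intron gap (bp) when chaining CH exons into
#'   a constant region.
#' @param boundary_window Half-width (bp) of the splice-motif search window
#'   around an aligned exon edge.
#' @param polya_signal Canonical polyadenylation hexamer(s).
#' @param dh_core_min,dh_core_max Bounds on the DH core length (bp).
#' @param dh_spacer RSS spacer length flanking DH cores (bp).
#' @param rss_heptamer,rss_nonamer Canonical RSS motif strings.
#' @param rng_seed Seed forwarded to any stochastic step (profile
#'   calibration).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(primary_evalue_max = 0.001,
                              override_bitscore_diff = 16.5,
                              stringent_evalue_max = 1e-8,
                              stringent_min_ref_exons = 2L,
                              scaffold_min_coverage_frac = 0.01,
                              scaffold_min_segment_types = 2L,
                              dh_max_mismatches = 8L,
                              vh_family_identity = 0.80,
                              support_collapse_pct = 65,
                              max_intron_gap = 15000L,
                              boundary_window = 30L,
                              polya_signal = "AATAAA",
                              dh_core_min = 10L,
                              dh_core_max = 40L,
                              dh_spacer = 12L,
                              rss_heptamer = "CACAGTG",
                              rss_nonamer = "ACAAAAACC",
                              rng_seed = 1L) {
  cfg <- list(
    primary_evalue_max = primary_evalue_max,
    override_bitscore_diff = override_bitscore_diff,
    stringent_evalue_max = stringent_evalue_max,
    stringent_min_ref_exons = as.integer(stringent_min_ref_exons),
    scaffold_min_coverage_frac = scaffold_min_coverage_frac,
    scaffold_min_segment_types = as.integer(scaffold_min_segment_types),
    dh_max_mismatches = as.integer(dh_max_mismatches),
    vh_family_identity = vh_family_identity,
    support_collapse_pct = support_collapse_pct,
    max_intron_gap = as.integer(max_intron_gap),
    boundary_window = as.integer(boundary_window),
    polya_signal = toupper(polya_signal),
    dh_core_min = as.integer(dh_core_min),
    dh_core_max = as.integer(dh_core_max),
    dh_spacer = as.integer(dh_spacer),
    rss_heptamer = toupper(rss_heptamer),
    rss_nonamer = toupper(rss_nonamer),
    rng_seed = as.integer(rng_seed)
  )
  num <- unlist(cfg[c("primary_evalue_max", "override_bitscore_diff",
                      "stringent_evalue_max", "scaffold_min_coverage_frac",
                      "vh_family_identity", "support_collapse_pct")])
  if (!all(is.finite(num))) stop("all thresholds must be finite", call. = FALSE)
  if (cfg$vh_family_identity <= 0 || cfg$vh_family_identity >= 1) {
    stop("vh_family_identity must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "annotation_config")
}

#' Read an annotation configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a YAML file whose keys mirror [annotation_config()].
#' @return An `annotation_config`.
#' @export
read_annotation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(annotation_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(annotation_config, vals)
}
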