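#' Pipeline configuration
#'
#' Central container for the thresholds and bounds used across the pipeline:
#' variant filtering, database digestion, iBAQ peptide counting and
#' phosphosite localization filtering.
#'
#' @param min_supporting_reads Minimum total read depth (reference plus
#'   alternate) at a variant site; sites below this are removed. Default 2.
#' @param min_mapping_quality Minimum mapping quality for a variant call.
#'   Default 10.
#' @param read_filter_mode Whether `min_supporting_reads` applies to total
#'   site depth (`"site"`, default) or to the alternate allele count only
#'   (`"alt"`).
#' @param localization_threshold Minimum phosphosite localization
#'   probability retained (inclusive). Default 0.75.
#' @param homozygous_min_vaf Lowest variant allele frequency called
#'   homozygous. Default 1.0 (exact); real data typically warrants ~0.95.
#' @param peptide_length_bounds_db Length bounds (residues, inclusive) for
#'   peptides emitted into the variant search database. Default c(6, 45).
#' @param peptide_length_bounds_ibaq Length bounds for counting
#'   theoretically detectable peptides in iBAQ. Default c(7, 30), the
#'   MaxQuant convention.
#' @param max_missed_cleavages_per_side Missed cleavages allowed on each
#'   flank of the variant-containing tryptic segment. Default 1.
#' @param low_coverage_alt_count Alternate allele counts below this flag a
#'   homozygous conflict as low-coverage. Default 10.
#' @param seed Integer seed recorded for downstream simulation calls.
#'
#' @return An object of class `saavx_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_supporting_reads
#' @export
pipeline_config <- function(min_supporting_reads = 2L,
                            min_mapping_quality = 10,
                            read_filter_mode = c("site", "alt"),
                            localization_threshold = 0.75,
                            homozygous_min_vaf = 1.0,
                            peptide_length_bounds_db = c(6L, 45L),
                            peptide_length_bounds_ibaq = c(7L, 30L),
                            max_missed_cleavages_per_side = 1L,
                            low_coverage_alt_count = 10L,
                            seed = 1L) {
  read_filter_mode <- match.arg(read_filter_mode)
  cfg <- list(
    min_supporting_reads = as.integer(min_supporting_reads),
    min_mapping_quality = as.numeric(min_mapping_quality),
    read_filter_mode = read_filter_mode,
    localization_threshold = as.numeric(localization_threshold),
    homozygous_min_vaf = as.numeric(homozygous_min_vaf),
    peptide_length_bounds_db = as.integer(peptide_length_bounds_db),
    peptide_length_bounds_ibaq = as.integer(peptide_length_bounds_ibaq),
    max_missed_cleavages_per_side = as.integer(max_missed_cleavages_per_side),
    low_coverage_alt_count = as.integer(low_coverage_alt_count),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$min_supporting_reads >= 0L,
    cfg$min_mapping_quality >= 0,
    cfg$localization_threshold >= 0, cfg$localization_threshold <= 1,
    cfg$homozygous_min_vaf >= 0, cfg$homozygous_min_vaf <= 1,
    length(cfg$peptide_length_bounds_db) == 2L,
    cfg$peptide_length_bounds_db[1] <= cfg$peptide_length_bounds_db[2],
    length(cfg$peptide_length_bounds_ibaq) == 2L,
    cfg$peptide_length_bounds_ibaq[1] <= cfg$peptide_length_bounds_ibaq[2],
    cfg$max_missed_cleavages_per_side >= 0L
  )
  structure(cfg, class = "saavx_config")
}

#' @exportS3Method base::print
print.saavx_config <- function(x, ...) {
  cat("saavx pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-30s %s\n", nm, paste(x[[nm]], collapse = "-")))
  }
  invisible(x)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (inherits(cfg, "saavx_config")) return(cfg)
  if (is.list(cfg)) return(do.call(pipeline_config, cfg))
  stop("`cfg` must be NULL, a saavx_config, or a named list of overrides")
}
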