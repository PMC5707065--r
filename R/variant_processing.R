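#' Variant allele frequency
#'
#' VAF = alt_count / (ref_count + alt_count). Vectorised.
#'
#' @param ref_count,alt_count Non-negative read counts.
#' @return Fraction(s) in `[0, 1]`.
#' @examples
#' compute_vaf(26, 45) # 0.634 to 3 d.p.
#' @export
compute_vaf <- function(ref_count, alt_count) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0))
  total <- ref_count + alt_count
  if (any(total == 0)) {
    stop("undefined VAF: zero total read count at a site")
  }
  alt_count / total
}

#' Filter variants by read support and mapping quality
#'
#' Removes records with fewer supporting reads than
#' `cfg$min_supporting_reads` (total site depth by default, alternate
#' allele only when `cfg$read_filter_mode == "alt"`) or a mapping quality
#' below `cfg$min_mapping_quality`. Both thresholds keep records at the
#' threshold ("less than" semantics). Counts removed per criterion are
#' reported via `message()`.
#'
#' @param table A `saavx_variants` data frame.
#' @param cfg A [pipeline_config()] (or named list of overrides).
#' @return The filtered table; order preserved, attributes kept.
#' @export
filter_variants <- function(table, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (cfg$min_mapping_quality > 0 && all(is.na(table$mapping_quality))) {
    stop("mapping_quality column unpopulated but min_mapping_quality > 0")
  }
  support <- if (cfg$read_filter_mode == "alt") {
    table$alt_count
  } else {
    ifelse(is.na(table$ref_count), 0, table$ref_count) + table$alt_count
  }
  if (anyNA(support) && cfg$min_supporting_reads > 0L) {
    stop("allele counts unpopulated but min_supporting_reads > 0")
  }
  low_depth <- support < cfg$min_supporting_reads
  low_mq <- table$mapping_quality < cfg$min_mapping_quality
  keep <- !low_depth & !low_mq
  message(sprintf(
    "filter_variants: removed %d of %d (%d low depth, %d low mapping quality)",
    sum(!keep), nrow(table), sum(low_depth), sum(low_mq)))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict variants to exonic intervals
#'
#' Keeps variants whose 1-based position `p` falls inside at least one
#' BED interval, i.e. `start < p <= end` (BED 0-based half-open).
#' Overlap is computed with [GenomicRanges::findOverlaps()].
#'
#' @param table A `saavx_variants` data frame.
#' @param exons Intervals from [read_bed()] (columns `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @return The exon-overlapping subset, order preserved. A warning is
#'   issued for chromosomes carrying variants but no intervals.
#' @export
intersect_exons <- function(table, exons) {
  if (nrow(table) == 0L) return(table)
  missing_chrom <- setdiff(unique(table$chrom), unique(exons$chrom))
  if (length(missing_chrom) > 0L) {
    warning("no exon intervals on: ", paste(missing_chrom, collapse = ", "),
            "; variants there are dropped")
  }
  var_gr <- GenomicRanges::GRanges(
    table$chrom, IRanges::IRanges(start = table$pos, width = 1L))
  exon_gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(start = exons$start + 1L, end = exons$end))
  hits <- GenomicRanges::findOverlaps(var_gr, exon_gr)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify zygosity from the variant allele frequency
#'
#' A site is called homozygous when its VAF reaches
#' `cfg$homozygous_min_vaf` (default exactly 1.0, i.e. zero reference
#' reads), heterozygous otherwise.
#'
#' @param ref_count,alt_count Read counts (vectorised).
#' @param cfg A [pipeline_config()].
#' @return A data frame with columns `vaf` and `zygosity`
#'   (`"homozygous"`/`"heterozygous"`).
#' @examples
#' classify_zygosity(0, 3)   # homozygous, VAF 1
#' classify_zygosity(26, 45) # heterozygous, VAF 0.634
#' @export
classify_zygosity <- function(ref_count, alt_count, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  vaf <- compute_vaf(ref_count, alt_count)
  data.frame(
    vaf = vaf,
    zygosity = ifelse(vaf >= cfg$homozygous_min_vaf,
                      "homozygous", "heterozygous"),
    stringsAsFactors = FALSE
  )
}

#' Append VAF and zygosity columns to a variant table
#'
#' @param table A `saavx_variants` data frame with populated counts.
#' @param cfg A [pipeline_config()].
#' @return The table with `vaf` and `zygosity` columns appended.
#' @export
annotate_zygosity <- function(table, cfg = pipeline_config()) {
  z <- classify_zygosity(table$ref_count, table$alt_count, cfg)
  table$vaf <- z$vaf
  table$zygosity <- z$zygosity
  table
}
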