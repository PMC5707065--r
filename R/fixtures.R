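#' Bundled example: homozygous SAAV peptides with detected reference
#' counterparts
#'
#' Seven SAAV-containing peptides from a leukaemia cell-line
#' proteogenomic experiment whose SNVs were called homozygous from
#' whole-genome sequencing (WGS VAF = 1.0 at low depth), yet whose
#' reference-allele peptide was also detected by mass spectrometry — the
#' conflict pattern this package's pairing stage is designed to flag.
#' RNA-seq allele counts for the same sites reveal the calls to be
#' heterozygous. Reference read counts are back-solved from the reported
#' VAF/alternate-count pairs and round-trip to the reported VAFs at
#' 3 decimal places.
#'
#' @return Data frame with variant/reference peptide sequences, SAAV
#'   annotation (offset, ref/alt residue, protein position), RNA-seq and
#'   WGS allele counts, and peptide intensities.
#' @export
example_conflict_peptides <- function() {
  utils::read.delim(
    system.file("extdata", "homozygous_conflict_peptides.tsv",
                package = "saavx"),
    stringsAsFactors = FALSE)
}

#' Bundled example: SAAV phosphopeptides with site- or motif-creating
#' variants
#'
#' Twenty-four phosphopeptides from a leukaemia cell-line
#' phosphoproteomic experiment in which the single amino acid variant
#' either creates the phosphorylated residue itself or creates the
#' proline of an `[S/T]P` proline-directed kinase motif. Columns give
#' the peptide, the SAAV (reference/alternate residue and offset), the
#' phosphosite offset, genomic coordinates and dbSNP/population
#' frequency annotation (`NA` dbSNP id plus zero population frequency
#' marks putative somatic events).
#'
#' @return Data frame, one row per phosphopeptide.
#' @export
example_phospho_saavs <- function() {
  df <- utils::read.delim(
    system.file("extdata", "phosphogain_peptides.tsv", package = "saavx"),
    stringsAsFactors = FALSE, na.strings = "NA")
  df
}

#' Run the homozygous-conflict analysis on the bundled example
#'
#' Reconstructs identified-peptide records from
#' [example_conflict_peptides()], classifies zygosity from the WGS
#' allele counts, and applies [pair_and_flag()].
#'
#' @param cfg A [pipeline_config()].
#' @return The [pair_and_flag()] pair table (one row per variant
#'   peptide) with RNA-seq VAF appended as `rna_vaf`.
#' @export
example_conflict_pairs <- function(cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  fx <- example_conflict_peptides()
  key <- paste0(fx$protein_id, "|p.", fx$ref_aa, fx$protein_position,
                fx$alt_aa)
  matched <- rbind(
    data.frame(sequence = fx$variant_peptide,
               intensity = fx$variant_intensity,
               spectra_count = 1L, label = "variant", ambiguous = FALSE,
               variant_key = key, protein_id = fx$protein_id,
               saav_offset = fx$saav_offset, ref_aa = fx$ref_aa,
               alt_aa = fx$alt_aa, protein_position = fx$protein_position,
               effect = "missense", gene = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(sequence = fx$reference_peptide,
               intensity = fx$reference_intensity,
               spectra_count = 1L, label = "reference", ambiguous = FALSE,
               variant_key = NA_character_, protein_id = fx$protein_id,
               saav_offset = NA_integer_, ref_aa = NA_character_,
               alt_aa = NA_character_, protein_position = NA_integer_,
               effect = NA_character_, gene = NA_character_,
               stringsAsFactors = FALSE)
  )
  zyg <- classify_zygosity(fx$wgs_ref_count, fx$wgs_alt_count, cfg)
  zygosity <- data.frame(variant_key = key, vaf = zyg$vaf,
                         zygosity = zyg$zygosity,
                         alt_count = fx$wgs_alt_count,
                         stringsAsFactors = FALSE)
  pairs <- pair_and_flag(matched, zygosity, cfg)
  idx <- match(pairs$variant_key, key)
  pairs$rna_vaf <- compute_vaf(fx$rna_ref_count[idx], fx$rna_alt_count[idx])
  pairs
}
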