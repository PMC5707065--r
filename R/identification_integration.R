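#' Strip modification notation from peptide strings
#'
#' Removes bracketed/parenthesised modification tags (e.g. `(ph)`,
#' `[+79.97]`), terminal underscores and lowercase letters, leaving the
#' plain uppercase amino acid sequence used for matching.
#'
#' @param sequences Character vector of (possibly modified) peptide
#'   strings.
#' @return Plain amino acid strings.
#' @examples
#' strip_modifications("_KPGYH(ph)TPVALK_")
#' @export
strip_modifications <- function(sequences) {
  s <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", sequences)
  gsub("[^A-Z]", "", s)
}

isTRUE_v <- function(x) !is.na(x) & x

# TRUE for peptides occurring as a substring of any reference protein.
in_reference_proteome <- function(peptides, proteome) {
  haystack <- paste(proteome, collapse = "#")
  vapply(peptides, function(p) grepl(p, haystack, fixed = TRUE),
         logical(1), USE.NAMES = FALSE)
}

#' Match identified peptides against the variant database and proteome
#'
#' Identification here is exact sequence matching: each evidence row
#' (modifications stripped, intensities summed per unique sequence) is
#' labelled `variant` when it equals a SAAV database peptide and occurs
#' nowhere in the reference proteome, `reference` when it is a substring
#' of a reference protein, and `unassigned` otherwise. A sequence that
#' equals peptides of two different SAAVs is flagged ambiguous and
#' excluded from unique-SAAV counting downstream.
#'
#' @param evidence Data frame with columns `sequence` and `intensity`
#'   (optionally `spectra_count`).
#' @param saav_db A `saavx_peptides` table from [build_saav_database()].
#' @param reference_proteome Named character vector id -> sequence.
#' @return Data frame of identified peptides: `sequence`, `intensity`,
#'   `spectra_count`, `label`, `ambiguous`, `variant_key`, `protein_id`,
#'   `saav_offset`, `ref_aa`, `alt_aa`, `protein_position`, `effect`,
#'   `gene`.
#' @export
match_peptides <- function(evidence, saav_db, reference_proteome) {
  stopifnot(all(c("sequence", "intensity") %in% names(evidence)))
  if (any(evidence$intensity < 0, na.rm = TRUE)) {
    stop("negative intensities in evidence table")
  }
  seq_plain <- strip_modifications(evidence$sequence)
  if (any(nchar(seq_plain) == 0L)) stop("empty peptide sequence in evidence")
  spectra <- if ("spectra_count" %in% names(evidence)) {
    evidence$spectra_count
  } else rep(1L, nrow(evidence))
  agg <- stats::aggregate(
    cbind(intensity = evidence$intensity, spectra_count = spectra),
    by = list(sequence = seq_plain), FUN = sum)

  if (is.null(saav_db$variant_key)) saav_db$variant_key <- variant_key(saav_db)
  db_idx <- match(agg$sequence, saav_db$sequence)
  in_ref <- in_reference_proteome(agg$sequence, reference_proteome)

  n_keys <- vapply(agg$sequence, function(s) {
    length(unique(saav_db$variant_key[saav_db$sequence == s]))
  }, integer(1), USE.NAMES = FALSE)

  # a stop-gain truncation peptide is always a substring of the reference
  # protein (the truncated protein is a prefix); it is still a variant
  # identification when its C-terminus is non-tryptic, because the
  # reference digest can never produce that peptide
  trunc <- !is.na(db_idx) &
    isTRUE_v(saav_db$is_truncation_cterm[db_idx]) &
    !substr(agg$sequence, nchar(agg$sequence), nchar(agg$sequence)) %in%
      c("K", "R")
  label <- ifelse(!is.na(db_idx) & (!in_ref | trunc), "variant",
                  ifelse(in_ref, "reference", "unassigned"))
  out <- data.frame(
    sequence = agg$sequence,
    intensity = agg$intensity,
    spectra_count = agg$spectra_count,
    label = label,
    ambiguous = label == "variant" & n_keys > 1L,
    stringsAsFactors = FALSE
  )
  take <- function(col) {
    v <- saav_db[[col]][db_idx]
    v[out$label != "variant"] <- NA
    v
  }
  out$variant_key <- take("variant_key")
  out$protein_id <- take("protein_id")
  out$saav_offset <- take("saav_offset")
  out$ref_aa <- take("ref_aa")
  out$alt_aa <- take("alt_aa")
  out$protein_position <- take("protein_position")
  out$effect <- take("effect")
  out$gene <- take("gene")
  # reference-labelled rows: report a containing protein id
  ref_rows <- which(out$label == "reference")
  if (length(ref_rows)) {
    out$protein_id[ref_rows] <- vapply(out$sequence[ref_rows], function(p) {
      hit <- which(vapply(reference_proteome, grepl, logical(1),
                          pattern = p, fixed = TRUE))[1]
      names(reference_proteome)[hit]
    }, character(1), USE.NAMES = FALSE)
  }
  out[order(out$sequence), , drop = FALSE]
}

#' Reference counterpart of a variant peptide
#'
#' The variant peptide's sequence with the reference residue restored at
#' the SAAV offset. Truncation (stop-gain) peptides have no counterpart.
#'
#' @param sequence Variant peptide string(s).
#' @param saav_offset 1-based offset of the variant residue.
#' @param ref_aa Reference residue(s).
#' @param effect Effect class; `"stop_gain"` raises a no-counterpart
#'   error.
#' @return Counterpart sequence(s).
#' @examples
#' reference_counterpart("TYWK", 2, "C") # "TCWK"
#' @export
reference_counterpart <- function(sequence, saav_offset, ref_aa,
                                  effect = "missense") {
  if (any(effect == "stop_gain")) {
    stop("stop-gain truncation peptides have no reference counterpart")
  }
  stopifnot(all(saav_offset >= 1L),
            all(saav_offset <= nchar(sequence)))
  out <- sequence
  substr(out, saav_offset, saav_offset) <- ref_aa
  out
}

#' Pair variant peptides with reference counterparts and flag conflicts
#'
#' For every unambiguous missense variant peptide, looks up the exact
#' reference-counterpart sequence among the reference-labelled
#' identifications. A pair is a *conflict* when the SAAV was called
#' homozygous yet the reference peptide was detected (only one allele
#' should exist); conflicts with alternate allele count below
#' `cfg$low_coverage_alt_count` are additionally flagged low-coverage,
#' the usual explanation (the homozygous call itself is unreliable).
#'
#' @param matched Output of [match_peptides()].
#' @param zygosity Data frame keyed by `variant_key` with columns `vaf`,
#'   `zygosity` and optionally `alt_count` (the DNA-level alternate
#'   allele count used for the low-coverage flag).
#' @param cfg A [pipeline_config()].
#' @return Data frame of peptide pairs: `variant_sequence`,
#'   `reference_sequence`, `variant_intensity`, `reference_intensity`,
#'   `variant_key`, `vaf`, `zygosity`, `alt_count`,
#'   `reference_detected`, `conflict`, `low_coverage`.
#' @export
pair_and_flag <- function(matched, zygosity, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(all(c("variant_key", "zygosity") %in% names(zygosity)))
  vp <- matched[matched$label == "variant" & !matched$ambiguous &
                  matched$effect == "missense", , drop = FALSE]
  refs <- matched[matched$label == "reference", , drop = FALSE]
  if (nrow(vp) == 0L) {
    return(data.frame(
      variant_sequence = character(), reference_sequence = character(),
      variant_intensity = numeric(), reference_intensity = numeric(),
      variant_key = character(), vaf = numeric(), zygosity = character(),
      alt_count = numeric(), reference_detected = logical(),
      conflict = logical(), low_coverage = logical(),
      stringsAsFactors = FALSE))
  }
  counterpart <- reference_counterpart(vp$sequence, vp$saav_offset,
                                       vp$ref_aa)
  ridx <- match(counterpart, refs$sequence)
  zidx <- match(vp$variant_key, zygosity$variant_key)
  if (anyNA(zidx)) {
    stop("no zygosity call for SAAV(s): ",
         paste(unique(vp$variant_key[is.na(zidx)]), collapse = ", "))
  }
  alt_count <- if ("alt_count" %in% names(zygosity)) {
    zygosity$alt_count[zidx]
  } else rep(NA_real_, nrow(vp))
  vaf <- if ("vaf" %in% names(zygosity)) zygosity$vaf[zidx] else NA_real_
  reference_detected <- !is.na(ridx)
  zyg <- zygosity$zygosity[zidx]
  conflict <- zyg == "homozygous" & reference_detected
  out <- data.frame(
    variant_sequence = vp$sequence,
    reference_sequence = counterpart,
    variant_intensity = vp$intensity,
    reference_intensity = ifelse(reference_detected,
                                 refs$intensity[ridx], NA_real_),
    variant_key = vp$variant_key,
    vaf = vaf,
    zygosity = zyg,
    alt_count = alt_count,
    reference_detected = reference_detected,
    conflict = conflict,
    low_coverage = conflict & !is.na(alt_count) &
      alt_count < cfg$low_coverage_alt_count,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Allele-balance correlation of heterozygous peptide pairs
#'
#' Heterozygous SAAVs should express both alleles at similar levels, so
#' variant and reference peptide intensities should correlate. Computes
#' the Pearson correlation of log10 intensities over heterozygous pairs
#' where both members were detected with positive intensity.
#'
#' @param pairs Output of [pair_and_flag()].
#' @return List with elements `r` and `n`.
#' @export
allele_balance_correlation <- function(pairs) {
  use <- pairs$zygosity == "heterozygous" &
    pairs$reference_detected &
    pairs$variant_intensity > 0 &
    !is.na(pairs$reference_intensity) & pairs$reference_intensity > 0
  n <- sum(use)
  if (n < 3L) {
    stop("insufficient data: need >= 3 heterozygous pairs with both ",
         "intensities > 0, have ", n)
  }
  r <- stats::cor(log10(pairs$variant_intensity[use]),
                  log10(pairs$reference_intensity[use]))
  list(r = r, n = n)
}
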