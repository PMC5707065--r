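#' Filter phosphosites by localization probability
#'
#' Retains sites whose localization probability reaches
#' `cfg$localization_threshold` (inclusive; default 0.75).
#'
#' @param sites Data frame with a `localization_probability` column.
#' @param cfg A [pipeline_config()].
#' @return The retained subset.
#' @export
filter_localization <- function(sites, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot("localization_probability" %in% names(sites))
  p <- sites$localization_probability
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("localization probabilities must be in [0, 1]")
  }
  out <- sites[p >= cfg$localization_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify SAAV phosphopeptides by the variant's role
#'
#' Three exhaustive, mutually exclusive categories describe how a single
#' amino acid variant relates to a phosphosite observed on the same
#' peptide:
#'
#' * `SITE_CREATION` — the variant itself introduces the phosphorylated
#'   residue: the site sits at the SAAV offset, the alternate residue is
#'   S/T/Y and the reference residue is not (an S->T exchange keeps the
#'   site phosphorylatable and therefore does not qualify).
#' * `MOTIF_CREATION` — the variant creates the proline of a
#'   proline-directed kinase motif (`[S/T]P`): the alternate residue is
#'   P (reference is not), placed immediately C-terminal of a
#'   phosphorylated S or T.
#' * `DETECTION_ONLY` — neither rule fires; the variant merely put the
#'   peptide into the search space.
#'
#' `SITE_CREATION` takes precedence when a created S/T is itself
#' followed by a proline.
#'
#' @param peptides Data frame (vectorised) with columns
#'   `peptide_sequence`, `saav_offset`, `ref_aa`, `alt_aa`,
#'   `site_offset`.
#' @return The input with `site_residue` and `category` columns
#'   appended.
#' @export
classify_phosphopeptide <- function(peptides) {
  needed <- c("peptide_sequence", "saav_offset", "ref_aa", "alt_aa",
              "site_offset")
  stopifnot(all(needed %in% names(peptides)))
  n <- nrow(peptides)
  len <- nchar(peptides$peptide_sequence)
  if (any(peptides$site_offset < 1L | peptides$site_offset > len)) {
    stop("site_offset outside peptide")
  }
  if (any(peptides$saav_offset < 1L | peptides$saav_offset > len)) {
    stop("saav_offset outside peptide")
  }
  residue <- substr(peptides$peptide_sequence, peptides$site_offset,
                    peptides$site_offset)
  if (!all(residue %in% c("S", "T", "Y"))) {
    stop("phosphosite residue must be S, T or Y")
  }
  sty <- c("S", "T", "Y")
  site_creation <- peptides$site_offset == peptides$saav_offset &
    peptides$alt_aa %in% sty & !(peptides$ref_aa %in% sty)
  motif_creation <- !site_creation &
    peptides$alt_aa == "P" & peptides$ref_aa != "P" &
    peptides$saav_offset == peptides$site_offset + 1L &
    residue %in% c("S", "T")
  peptides$site_residue <- residue
  peptides$category <- ifelse(site_creation, "SITE_CREATION",
                              ifelse(motif_creation, "MOTIF_CREATION",
                                     "DETECTION_ONLY"))
  peptides
}

#' Annotate impacting classifications with population variant data
#'
#' Joins dbSNP identifiers and population allele frequencies (keyed by
#' genomic coordinate) onto site- and motif-creating classifications.
#' An impacting SAAV with no dbSNP id and zero (or absent) population
#' frequency is flagged putative-somatic. `DETECTION_ONLY` rows pass
#' through unannotated.
#'
#' @param classifications Output of [classify_phosphopeptide()] with a
#'   `genomic_coordinates` column (e.g. `"chr2:198285797"`).
#' @param dbsnp Named character vector, coordinate -> dbSNP id (may be
#'   partial or NULL).
#' @param popfreq Named numeric vector, coordinate -> population allele
#'   frequency (may be partial or NULL).
#' @return The input with `dbsnp_id`, `population_allele_freq` and
#'   `putative_somatic` columns appended.
#' @export
annotate_candidates <- function(classifications, dbsnp = NULL,
                                popfreq = NULL) {
  stopifnot(all(c("category", "genomic_coordinates") %in%
                  names(classifications)))
  coord <- classifications$genomic_coordinates
  id <- if (is.null(dbsnp)) rep(NA_character_, length(coord)) else {
    unname(dbsnp[coord])
  }
  freq <- if (is.null(popfreq)) rep(NA_real_, length(coord)) else {
    unname(popfreq[coord])
  }
  impacting <- classifications$category %in%
    c("SITE_CREATION", "MOTIF_CREATION")
  id[!impacting] <- NA_character_
  freq[!impacting] <- NA_real_
  classifications$dbsnp_id <- id
  classifications$population_allele_freq <- freq
  classifications$putative_somatic <- impacting &
    (is.na(id) | id == "") &
    (is.na(freq) | freq == 0)
  classifications
}

#' Summarise phosphopeptide categories
#'
#' @param classifications Output of [classify_phosphopeptide()].
#' @return List with `counts` (named integer vector over the three
#'   categories, summing to the number of inputs) and
#'   `impacting_fraction` (`(SITE_CREATION + MOTIF_CREATION) / total`;
#'   `NA` for empty input).
#' @export
summarize_categories <- function(classifications) {
  cats <- c("SITE_CREATION", "MOTIF_CREATION", "DETECTION_ONLY")
  counts <- vapply(cats, function(k) {
    sum(classifications$category == k)
  }, integer(1))
  total <- sum(counts)
  list(
    counts = counts,
    impacting_fraction = if (total == 0L) NA_real_ else {
      (counts[["SITE_CREATION"]] + counts[["MOTIF_CREATION"]]) / total
    }
  )
}
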