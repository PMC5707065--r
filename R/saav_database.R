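#' Translate a coding sequence to protein
#'
#' Standard genetic code via [Biostrings::translate()]. Translation stops
#' at (and excludes) the first stop codon; codons containing ambiguous
#' bases that do not resolve to a unique residue become `"X"`.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Protein string.
#' @examples
#' translate_cds("ATGAAA")    # "MK"
#' translate_cds("ATGTAAAAA") # "M"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length not divisible by 3 (", nchar(cds), " nt)")
  }
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve")))
  sub("\\*.*$", "", aa)
}

as_annotation <- function(ann) {
  if (is.data.frame(ann)) {
    stopifnot(nrow(ann) == 1L)
    ann <- as.list(ann)
  }
  stopifnot(is.list(ann))
  needed <- c("protein_position", "ref_aa", "alt_aa", "effect")
  missing <- setdiff(needed, names(ann))
  if (length(missing)) stop("annotation missing fields: ",
                            paste(missing, collapse = ", "))
  ann$protein_position <- as.integer(ann$protein_position)
  if (identical(ann$ref_aa, ann$alt_aa)) stop("ref_aa equals alt_aa")
  if (!ann$effect %in% c("missense", "stop_gain")) {
    stop("unknown effect class: ", ann$effect)
  }
  if ((ann$effect == "stop_gain") != (ann$alt_aa == "*")) {
    stop("stop_gain annotations must (and only they may) have alt_aa '*'")
  }
  for (field in c("protein_id", "transcript_id", "gene")) {
    if (is.null(ann[[field]])) ann[[field]] <- NA_character_
  }
  ann
}

#' Apply a missense substitution to a protein sequence
#'
#' @param protein Protein string.
#' @param ann Annotation (named list or one-row data frame) with
#'   `protein_position`, `ref_aa`, `alt_aa`, `effect = "missense"`.
#' @return The mutated sequence, differing at exactly one position.
#'   Errors with a reference-mismatch message when the sequence does not
#'   carry `ref_aa` at the stated position (annotation/proteome skew).
#' @export
apply_missense <- function(protein, ann) {
  ann <- as_annotation(ann)
  stopifnot(ann$effect == "missense")
  p <- ann$protein_position
  if (p < 1L || p > nchar(protein)) {
    stop("protein_position ", p, " outside sequence of length ",
         nchar(protein))
  }
  found <- substr(protein, p, p)
  if (found != ann$ref_aa) {
    stop(sprintf(
      "reference mismatch at position %d: annotation says %s, sequence has %s",
      p, ann$ref_aa, found))
  }
  substr(protein, p, p) <- ann$alt_aa
  protein
}

#' Truncate a protein at a stop-gain variant
#'
#' Returns residues 1 to `protein_position - 1`. The resulting C-terminus
#' is generally non-tryptic (unless the residue before the stop is K/R),
#' which is what makes truncation peptides distinguishable.
#'
#' @param protein Protein string.
#' @param ann Stop-gain annotation (`alt_aa = "*"`).
#' @return The truncated sequence.
#' @export
apply_stop_gain <- function(protein, ann) {
  ann <- as_annotation(ann)
  stopifnot(ann$effect == "stop_gain")
  p <- ann$protein_position
  if (p == 1L) stop("stop gain at position 1 yields an empty protein")
  if (p > nchar(protein)) {
    stop("protein_position ", p, " outside sequence of length ",
         nchar(protein))
  }
  found <- substr(protein, p, p)
  if (found != ann$ref_aa) {
    stop(sprintf(
      "reference mismatch at position %d: annotation says %s, sequence has %s",
      p, ann$ref_aa, found))
  }
  substr(protein, 1L, p - 1L)
}

#' Tryptic cleavage sites of a protein
#'
#' Trypsin cleaves C-terminally of K or R except when the next residue is
#' proline. Returns the 1-based positions after which cleavage occurs; a
#' terminal K/R is included (the C-terminus is always a peptide boundary,
#' whether or not it appears in this list).
#'
#' @param sequence Protein string.
#' @return Integer vector of cut positions (possibly empty).
#' @examples
#' tryptic_cleavage_sites("MKAVDRTCWKLPER") # 2 6 10 14
#' @export
tryptic_cleavage_sites <- function(sequence) {
  stopifnot(nchar(sequence) >= 1L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  kr <- which(res %in% c("K", "R"))
  kr[kr == n | res[pmin(kr + 1L, n)] != "P"]
}

#' In-silico tryptic digestion
#'
#' Enumerates all fully tryptic peptides (both boundaries at cleavage
#' sites or sequence termini) with at most `max_missed` internal missed
#' cleavage sites and length within `length_bounds`.
#'
#' @param sequence Protein string.
#' @param max_missed Maximum internal missed cleavages (>= 0).
#' @param length_bounds Inclusive `c(min, max)` residue length bounds.
#' @return Data frame with columns `sequence`, `start`, `end`, `missed`;
#'   unique by `(start, end)`.
#' @examples
#' digest("MKAVDRTCWKLPER", max_missed = 0, length_bounds = c(1, 50))
#' @export
digest <- function(sequence, max_missed = 0L, length_bounds = c(1L, .Machine$integer.max)) {
  stopifnot(max_missed >= 0L, length(length_bounds) == 2L)
  n <- nchar(sequence)
  bounds <- unique(c(0L, tryptic_cleavage_sites(sequence), n))
  bounds <- sort(bounds)
  m <- length(bounds)
  out <- vector("list", m - 1L)
  for (i in seq_len(m - 1L)) {
    jmax <- min(m, i + 1L + max_missed)
    js <- (i + 1L):jmax
    starts <- rep.int(bounds[i] + 1L, length(js))
    ends <- bounds[js]
    out[[i]] <- data.frame(start = starts, end = ends,
                           missed = js - i - 1L)
  }
  pep <- do.call(rbind, out)
  len <- pep$end - pep$start + 1L
  pep <- pep[len >= length_bounds[1] & len <= length_bounds[2], ,
             drop = FALSE]
  pep$sequence <- if (nrow(pep) == 0L) character(0) else
    substring(sequence, pep$start, pep$end)
  rownames(pep) <- NULL
  pep[, c("sequence", "start", "end", "missed")]
}

#' Enumerate SAAV-containing tryptic peptides
#'
#' Cleavage sites are computed on the *mutated* sequence (a substitution
#' that creates or destroys K, R or P changes the digest). The tryptic
#' segment containing the variant residue is extended independently by up
#' to `cfg$max_missed_cleavages_per_side` segments on the N side and on
#' the C side. For stop-gain variants the "variant segment" is the new
#' C-terminal segment of the truncated protein and only N-side extension
#' applies. Peptides outside `cfg$peptide_length_bounds_db` are dropped.
#'
#' @param mutated Protein string already carrying the substitution (or
#'   truncation), from [apply_missense()] / [apply_stop_gain()].
#' @param ann The variant annotation.
#' @param cfg A [pipeline_config()].
#' @return A `saavx_peptides` data frame: `sequence`, `start`, `end`
#'   (protein coordinates), `saav_offset` (position of the variant residue
#'   within the peptide; `NA` for truncations), `missed_n`, `missed_c`,
#'   `is_truncation_cterm`, plus the annotation columns.
#' @export
enumerate_saav_peptides <- function(mutated, ann, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  ann <- as_annotation(ann)
  n <- nchar(mutated)
  bounds <- sort(unique(c(0L, tryptic_cleavage_sites(mutated), n)))
  m <- length(bounds)
  if (ann$effect == "stop_gain") {
    seg <- m - 1L  # the new C-terminal segment
  } else {
    p <- ann$protein_position
    if (p > n) stop("variant position ", p, " beyond sequence end ", n)
    seg <- findInterval(p - 1L, bounds)  # b[seg] < p <= b[seg+1]
  }
  max_side <- cfg$max_missed_cleavages_per_side
  n_ext <- 0L:min(max_side, seg - 1L)
  c_ext <- if (ann$effect == "stop_gain") 0L else {
    0L:min(max_side, m - 1L - seg)
  }
  grid <- expand.grid(missed_n = n_ext, missed_c = c_ext)
  start <- bounds[seg - grid$missed_n] + 1L
  end <- bounds[seg + 1L + grid$missed_c]
  pep <- data.frame(
    sequence = substring(mutated, start, end),
    start = start, end = end,
    saav_offset = if (ann$effect == "stop_gain") NA_integer_ else
      ann$protein_position - start + 1L,
    missed_n = grid$missed_n, missed_c = grid$missed_c,
    is_truncation_cterm = ann$effect == "stop_gain",
    protein_id = ann$protein_id, transcript_id = ann$transcript_id,
    gene = ann$gene, protein_position = ann$protein_position,
    ref_aa = ann$ref_aa, alt_aa = ann$alt_aa, effect = ann$effect,
    stringsAsFactors = FALSE
  )
  len <- pep$end - pep$start + 1L
  lb <- cfg$peptide_length_bounds_db
  pep <- pep[len >= lb[1] & len <= lb[2], , drop = FALSE]
  rownames(pep) <- NULL
  class(pep) <- c("saavx_peptides", "data.frame")
  pep
}

#' Build a variant peptide database from a proteome and annotations
#'
#' Applies each annotation (missense or stop-gain) to its protein and
#' enumerates the SAAV-containing tryptic peptides.
#'
#' @param proteome Named character vector, protein id -> sequence (see
#'   [read_fasta()]).
#' @param annotations Data frame with columns `protein_id`,
#'   `protein_position`, `ref_aa`, `alt_aa`, `effect`, and optionally
#'   `transcript_id`, `gene`.
#' @param cfg A [pipeline_config()].
#' @return A `saavx_peptides` data frame over all annotations, with a
#'   `variant_key` column (`protein_id|p.<ref><pos><alt>`) identifying the
#'   SAAV each peptide derives from.
#' @export
build_saav_database <- function(proteome, annotations,
                                cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(is.data.frame(annotations), nrow(annotations) >= 1L)
  res <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    ann <- as_annotation(annotations[i, , drop = FALSE])
    if (is.na(ann$protein_id) || !ann$protein_id %in% names(proteome)) {
      stop("unknown protein_id in annotation row ", i, ": ", ann$protein_id)
    }
    prot <- proteome[[ann$protein_id]]
    mutated <- if (ann$effect == "stop_gain") {
      apply_stop_gain(prot, ann)
    } else {
      apply_missense(prot, ann)
    }
    res[[i]] <- enumerate_saav_peptides(mutated, ann, cfg)
  }
  db <- do.call(rbind, res)
  db$variant_key <- variant_key(db)
  rownames(db) <- NULL
  class(db) <- c("saavx_peptides", "data.frame")
  db
}

#' SAAV identifier string
#'
#' `protein_id|p.<ref><pos><alt>`, the key used to join peptides,
#' zygosity calls and ground truth.
#'
#' @param x A data frame with `protein_id`, `ref_aa`, `protein_position`,
#'   `alt_aa` columns (e.g. an annotation table or peptide table).
#' @return Character vector of keys.
#' @export
variant_key <- function(x) {
  paste0(x$protein_id, "|p.", x$ref_aa, x$protein_position, x$alt_aa)
}
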