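#' Theoretically detectable peptide count for iBAQ
#'
#' Number of fully tryptic, zero-missed-cleavage peptides whose length
#' falls within `cfg$peptide_length_bounds_ibaq` (default 7-30 residues,
#' the MaxQuant convention). Clamped below at 1 so the iBAQ denominator
#' is always defined.
#'
#' @param protein Protein string.
#' @param cfg A [pipeline_config()].
#' @return Positive integer count.
#' @export
theoretical_peptide_count <- function(protein, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  n <- nrow(digest(protein, max_missed = 0L,
                   length_bounds = cfg$peptide_length_bounds_ibaq))
  max(n, 1L)
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' @param total_intensity Summed peptide ion intensity of the protein.
#' @param theoretical_count Number of theoretically detectable peptides
#'   (>= 1), from [theoretical_peptide_count()].
#' @return `total_intensity / theoretical_count`.
#' @export
ibaq <- function(total_intensity, theoretical_count) {
  if (any(total_intensity < 0)) stop("negative total intensity")
  stopifnot(all(theoretical_count >= 1))
  total_intensity / theoretical_count
}

#' Updated iBAQ including variant peptide intensities
#'
#' Variant (SAAV-containing) peptide intensities are added to the
#' protein's total intensity; the denominator — the theoretical peptide
#' count of the reference sequence — is left unchanged.
#'
#' @param total_intensity Reference total intensity.
#' @param saav_intensities Numeric vector of SAAV peptide intensities for
#'   this protein (may be empty).
#' @param theoretical_count Theoretical peptide count (>= 1).
#' @return Updated iBAQ value; equals [ibaq()] when `saav_intensities`
#'   is empty or all zero.
#' @export
updated_ibaq <- function(total_intensity, saav_intensities,
                         theoretical_count) {
  if (any(saav_intensities < 0)) stop("negative SAAV peptide intensity")
  ibaq(total_intensity + sum(saav_intensities), theoretical_count)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param read_count Reads mapped to the transcript (>= 0).
#' @param transcript_length_bp Transcript length in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6) # 10
#' @export
rpkm <- function(read_count, transcript_length_bp, total_mapped_reads) {
  if (any(transcript_length_bp <= 0)) stop("transcript length must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be > 0")
  if (any(read_count < 0)) stop("negative read count")
  read_count / (transcript_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Williams' t-test for two dependent correlations sharing one variable
#'
#' Tests whether `cor(x1, x2)` differs from `cor(x1, x3)` given the
#' correlation `cor(x2, x3)`, for three variables measured on the same
#' `n` units (Williams 1959). Used here to compare the mRNA-vs-iBAQ and
#' mRNA-vs-updated-iBAQ correlations, which share the mRNA vector.
#'
#' The statistic is
#' \deqn{t = (r_{12} - r_{13})
#'   \sqrt{\frac{(n-1)(1 + r_{23})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1 - r_{23})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 +
#' 2 r_{12} r_{13} r_{23}} and \eqn{\bar r = (r_{12} + r_{13})/2},
#' referred to a t distribution on `n - 3` degrees of freedom.
#'
#' @param r12 Correlation of the shared variable with the first
#'   comparand.
#' @param r13 Correlation of the shared variable with the second
#'   comparand.
#' @param r23 Correlation between the two comparands.
#' @param n Sample size (> 3).
#' @return List with `r12`, `r13`, `r23`, `n`, `t`, `df` (`n - 3`) and
#'   two-sided `p`.
#' @export
williams_t <- function(r12, r13, r23, n) {
  stopifnot(length(r12) == 1L, length(r13) == 1L, length(r23) == 1L)
  if (n <= 3) stop("Williams' test requires n > 3")
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("degenerate input: correlations must lie strictly within (-1, 1)")
  }
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  list(r12 = r12, r13 = r13, r23 = r23, n = n,
       t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlation of log10-transformed values
#'
#' Pairs where either value is non-positive or missing are removed
#' before transformation.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient.
#' @export
correlate_log <- function(x, y) {
  stopifnot(length(x) == length(y))
  use <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  if (sum(use) < 3L) {
    stop("insufficient data: need >= 3 positive pairs, have ", sum(use))
  }
  stats::cor(log10(x[use]), log10(y[use]))
}

#' Per-protein quantification with and without variant peptides
#'
#' Builds the protein quantification table: iBAQ from the reference
#' total intensity, updated iBAQ after adding SAAV peptide intensities,
#' and RPKM when expression data are supplied.
#'
#' @param protein_intensities Data frame with `protein_id` and
#'   `total_intensity`.
#' @param proteome Named character vector id -> sequence (for the
#'   theoretical peptide counts).
#' @param saav_intensities Optional data frame with `protein_id` and
#'   `intensity` (one row per SAAV peptide); proteins absent from it get
#'   an unchanged iBAQ.
#' @param expression Optional data frame with `protein_id` and `rpkm`.
#' @param cfg A [pipeline_config()].
#' @return Data frame with columns `protein_id`, `total_intensity`,
#'   `saav_intensity`, `theoretical_peptide_count`, `ibaq`,
#'   `updated_ibaq` and (if supplied) `rpkm`.
#' @export
quantify_proteins <- function(protein_intensities, proteome,
                              saav_intensities = NULL, expression = NULL,
                              cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(all(c("protein_id", "total_intensity") %in%
                  names(protein_intensities)))
  ids <- protein_intensities$protein_id
  missing <- setdiff(ids, names(proteome))
  if (length(missing)) {
    stop("proteins missing from proteome: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  counts <- vapply(proteome[ids], theoretical_peptide_count, integer(1),
                   cfg = cfg)
  saav_sum <- rep(0, length(ids))
  if (!is.null(saav_intensities) && nrow(saav_intensities) > 0L) {
    agg <- stats::aggregate(intensity ~ protein_id,
                            data = saav_intensities, FUN = sum)
    idx <- match(ids, agg$protein_id)
    saav_sum <- ifelse(is.na(idx), 0, agg$intensity[idx])
  }
  out <- data.frame(
    protein_id = ids,
    total_intensity = protein_intensities$total_intensity,
    saav_intensity = saav_sum,
    theoretical_peptide_count = counts,
    stringsAsFactors = FALSE
  )
  out$ibaq <- ibaq(out$total_intensity, out$theoretical_peptide_count)
  out$updated_ibaq <- mapply(updated_ibaq, out$total_intensity,
                             saav_sum, out$theoretical_peptide_count)
  if (!is.null(expression)) {
    out$rpkm <- expression$rpkm[match(ids, expression$protein_id)]
  }
  rownames(out) <- NULL
  out
}

#' Compare mRNA-protein correlations before and after the iBAQ update
#'
#' Computes `r12 = cor(log RPKM, log iBAQ)`,
#' `r13 = cor(log RPKM, log updated iBAQ)` and the empirical
#' `r23 = cor(log iBAQ, log updated iBAQ)` over proteins with positive
#' values throughout, then applies [williams_t()].
#'
#' @param quant Output of [quantify_proteins()] including an `rpkm`
#'   column.
#' @return List with the three correlations, `n`, `t`, `df`, `p`.
#' @export
compare_quant_correlations <- function(quant) {
  stopifnot(all(c("rpkm", "ibaq", "updated_ibaq") %in% names(quant)))
  use <- !is.na(quant$rpkm) & quant$rpkm > 0 &
    quant$ibaq > 0 & quant$updated_ibaq > 0
  q <- quant[use, , drop = FALSE]
  n <- nrow(q)
  if (n <= 3L) stop("insufficient data: need > 3 complete proteins")
  r12 <- stats::cor(log10(q$rpkm), log10(q$ibaq))
  r13 <- stats::cor(log10(q$rpkm), log10(q$updated_ibaq))
  r23 <- stats::cor(log10(q$ibaq), log10(q$updated_ibaq))
  williams_t(r12, r13, r23, n)
}
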