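#' Parameters for the synthetic proteogenomic dataset
#'
#' Defaults emulate the study conditions the pipeline targets: a
#' deep-coverage cell-line experiment with mostly heterozygous exonic
#' SNVs (about two thirds, matching the observed heterozygous/homozygous
#' peptide split), a small stop-gain fraction (~3% of non-synonymous
#' calls), ~60x DNA read depth with negative-binomial dispersion,
#' log-normal protein abundance spanning several orders of magnitude,
#' peptide detectability increasing logistically with abundance, and
#' allele-balanced intensities for heterozygous SAAVs.
#'
#' @param n_proteins Number of proteins/transcripts. Default 200.
#' @param protein_length_mean,protein_length_sd Normal distribution of
#'   protein lengths (residues), truncated below at 60. Defaults 450/150.
#' @param n_variants Number of SNVs to plant. Default 300.
#' @param fraction_heterozygous Fraction of variants that are
#'   heterozygous. Default 0.65.
#' @param fraction_stop_gain Fraction of variants that are stop-gains.
#'   Default 0.03.
#' @param depth_mean,depth_dispersion Negative-binomial read depth at
#'   variant sites (mu and size). Defaults 60/5.
#' @param low_mq_fraction Fraction of variants given a mapping quality
#'   below 10 (to exercise filtering). Default 0.05.
#' @param abundance_mu_log10,abundance_sigma_log10 Log10-normal protein
#'   abundance (arbitrary intensity units). Defaults 7.5/1.2.
#' @param detection_slope,detection_midpoint Logistic detection model:
#'   `P(detect) = plogis(slope * (log10 abundance - midpoint))`.
#'   Defaults 1.5/7.0.
#' @param intensity_noise_sigma Log10-normal multiplicative noise on
#'   peptide intensities. Default 0.3.
#' @param rpkm_noise_sigma Log10-normal noise linking abundance to mRNA
#'   expression. Default 0.25.
#' @param total_mapped_reads RNA-seq library size for RPKM. Default 2e7.
#' @param n_phospho Number of planted SAAV phosphopeptides. Default 60.
#' @param category_mix Mix of planted categories (site creation, motif
#'   creation, detection only). Default c(0.4, 0.3, 0.3).
#' @param evidence_length_bounds Peptide lengths emitted into evidence
#'   tables. Default c(7, 30).
#' @param seed Integer seed; every generator call is deterministic given
#'   it.
#' @return A `saavx_simparams` list.
#' @export
simulation_params <- function(n_proteins = 200L,
                              protein_length_mean = 450,
                              protein_length_sd = 150,
                              n_variants = 300L,
                              fraction_heterozygous = 0.65,
                              fraction_stop_gain = 0.03,
                              depth_mean = 60,
                              depth_dispersion = 5,
                              low_mq_fraction = 0.05,
                              abundance_mu_log10 = 7.5,
                              abundance_sigma_log10 = 1.2,
                              detection_slope = 1.5,
                              detection_midpoint = 7.0,
                              intensity_noise_sigma = 0.3,
                              rpkm_noise_sigma = 0.25,
                              total_mapped_reads = 2e7,
                              n_phospho = 60L,
                              category_mix = c(site = 0.4, motif = 0.3,
                                               none = 0.3),
                              evidence_length_bounds = c(7L, 30L),
                              seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$n_proteins >= 1L, p$n_variants >= 0L,
    p$fraction_heterozygous >= 0, p$fraction_heterozygous <= 1,
    p$fraction_stop_gain >= 0, p$fraction_stop_gain <= 1,
    p$low_mq_fraction >= 0, p$low_mq_fraction <= 1,
    length(p$category_mix) == 3L, all(p$category_mix >= 0)
  )
  p$category_mix <- p$category_mix / sum(p$category_mix)
  structure(p, class = "saavx_simparams")
}

# codon table machinery -----------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# rough human amino-acid frequencies; K+R ~ 11% gives typical tryptic lengths
aa_frequencies <- function() {
  c(A = 7.0, R = 5.5, N = 3.6, D = 4.7, C = 2.3, E = 7.1, Q = 4.8,
    G = 6.6, H = 2.6, I = 4.3, L = 9.9, K = 5.7, M = 2.1, F = 3.6,
    P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)
}

# all single-nucleotide substitutions of a codon and the residues they encode
codon_neighbours <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (i in 1:3) {
    for (b in setdiff(bases, substr(codon, i, i))) {
      mut <- codon
      substr(mut, i, i) <- b
      out[[length(out) + 1L]] <- list(codon = mut, pos = i, base = b,
                                      aa = unname(gc[mut]))
    }
  }
  out
}

#' Generate a synthetic proteome with coding sequences
#'
#' Random protein sequences drawn from human-like amino acid
#' frequencies (so tryptic peptides have realistic lengths), each backed
#' by a coding sequence that translates exactly to it via
#' [translate_cds()]. Transcripts are laid out head-to-tail on a single
#' synthetic chromosome, giving every codon a genomic coordinate and
#' every CDS an exon interval.
#'
#' @param params A [simulation_params()].
#' @return List with `proteome` (named character vector),
#'   `cds` (named character vector), and `transcripts` (data frame:
#'   `protein_id`, `transcript_id`, `gene`, `length_aa`, `length_bp`,
#'   `chrom`, `cds_start` 1-based genomic start).
#' @export
generate_proteome <- function(params = simulation_params()) {
  stopifnot(inherits(params, "saavx_simparams"))
  set.seed(params$seed)
  n <- params$n_proteins
  freq <- aa_frequencies()
  codons <- codon_table()
  lengths <- pmax(60L, round(stats::rnorm(n, params$protein_length_mean,
                                          params$protein_length_sd)))
  proteome <- character(n)
  cds <- character(n)
  for (i in seq_len(n)) {
    aa <- c("M", sample(names(freq), lengths[i] - 1L, replace = TRUE,
                        prob = freq))
    cod <- vapply(aa, function(a) {
      opts <- codons[[a]]
      opts[sample.int(length(opts), 1L)]
    }, character(1), USE.NAMES = FALSE)
    proteome[i] <- paste(aa, collapse = "")
    cds[i] <- paste(cod, collapse = "")
  }
  ids <- sprintf("P%04d", seq_len(n))
  names(proteome) <- ids
  names(cds) <- ids
  gap <- 100L
  bp <- nchar(cds)
  cds_start <- cumsum(c(1L, utils::head(bp + gap, -1L)))
  transcripts <- data.frame(
    protein_id = ids,
    transcript_id = sprintf("T%04d", seq_len(n)),
    gene = sprintf("G%04d", seq_len(n)),
    length_aa = lengths,
    length_bp = bp,
    chrom = "chrS1",
    cds_start = cds_start,
    stringsAsFactors = FALSE
  )
  list(proteome = proteome, cds = cds, transcripts = transcripts)
}

#' Exon intervals of a synthetic proteome
#'
#' One BED interval (0-based half-open) per CDS.
#'
#' @param proteome_obj Output of [generate_proteome()].
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
synthetic_exons <- function(proteome_obj) {
  tr <- proteome_obj$transcripts
  data.frame(chrom = tr$chrom, start = tr$cds_start - 1L,
             end = tr$cds_start - 1L + tr$length_bp,
             stringsAsFactors = FALSE)
}

# pick a single-nucleotide codon substitution producing the wanted effect;
# returns NULL when the codon cannot reach it
pick_substitution <- function(codon, ref_aa, want) {
  nb <- codon_neighbours(codon)
  ok <- switch(
    want,
    missense = vapply(nb, function(x)
      x$aa != ref_aa && x$aa != "*", logical(1)),
    stop = vapply(nb, function(x) x$aa == "*", logical(1)),
    sty = vapply(nb, function(x)
      x$aa %in% c("S", "T", "Y"), logical(1)),
    pro = vapply(nb, function(x) x$aa == "P", logical(1)),
    neutral = vapply(nb, function(x)
      x$aa != ref_aa && !x$aa %in% c("S", "T", "Y", "P", "*"), logical(1))
  )
  hits <- nb[ok]
  if (length(hits) == 0L) return(NULL)
  hits[[sample.int(length(hits), 1L)]]
}

# 0-missed-cleavage tryptic peptide of `seq` containing position p
host_peptide <- function(seq, p) {
  bounds <- sort(unique(c(0L, tryptic_cleavage_sites(seq), nchar(seq))))
  seg <- findInterval(p - 1L, bounds)
  start <- bounds[seg] + 1L
  end <- bounds[seg + 1L]
  list(sequence = substr(seq, start, end), start = start, end = end,
       offset = p - start + 1L)
}

#' Generate synthetic SNVs with annotations and ground truth
#'
#' Plants `n_variants` single-nucleotide substitutions in the synthetic
#' CDS set. Zygosity is drawn per variant; read depth is negative
#' binomial and alternate counts are `Binomial(depth, 0.5)` for
#' heterozygous and `Binomial(depth, 1)` for homozygous sites. The
#' first `n_phospho` missense variants are planted with controlled
#' protein context so that their SAAV peptides carry a known
#' phosphosite category (site creation / motif creation / detection
#' only).
#'
#' @param proteome_obj Output of [generate_proteome()].
#' @param params A [simulation_params()].
#' @return List with `variants` (a `saavx_variants` table),
#'   `annotations` (protein-level consequences) and `truth` (per-variant
#'   ground truth: `variant_key`, `zygosity`, `true_vaf`, depth and
#'   quality, `phospho_category`).
#' @export
generate_variants <- function(proteome_obj, params = simulation_params()) {
  stopifnot(inherits(params, "saavx_simparams"))
  set.seed(params$seed + 1L)
  proteome <- proteome_obj$proteome
  cds <- proteome_obj$cds
  tr <- proteome_obj$transcripts
  n <- params$n_variants
  n_stop <- round(n * params$fraction_stop_gain)
  n_phos <- min(params$n_phospho, n - n_stop)
  n_cat <- stats::setNames(
    round(n_phos * params$category_mix),
    c("SITE_CREATION", "MOTIF_CREATION", "DETECTION_ONLY"))
  n_cat["DETECTION_ONLY"] <- n_phos - n_cat[1] - n_cat[2]
  wants <- c(rep("sty", n_cat[1]), rep("pro", n_cat[2]),
             rep("neutral", n_cat[3]),
             rep("stop", n_stop),
             rep("missense", n - n_stop - n_phos))
  categories <- c(rep(names(n_cat), n_cat),
                  rep(NA_character_, n - n_phos))
  used <- character(0)
  lb <- params$evidence_length_bounds
  rows <- vector("list", n)
  for (v in seq_len(n)) {
    want <- wants[v]
    hit <- NULL
    for (try in 1:500) {
      pi <- sample.int(length(proteome), 1L)
      prot <- proteome[[pi]]
      L <- nchar(prot)
      p <- sample(2:(L - 1L), 1L)
      if (want == "stop" && p < 10L) next
      key <- paste(pi, p)
      if (key %in% used) next
      ref_aa <- substr(prot, p, p)
      if (want == "sty" && ref_aa %in% c("S", "T", "Y")) next
      if (want == "pro" &&
          (ref_aa == "P" || !substr(prot, p - 1L, p - 1L) %in% c("S", "T")))
        next
      codon <- substr(cds[[pi]], 3L * p - 2L, 3L * p)
      sub <- pick_substitution(codon, ref_aa, want)
      if (is.null(sub)) next
      # planted phospho peptides must be emittable as evidence
      if (want %in% c("sty", "pro", "neutral")) {
        mutated <- prot
        substr(mutated, p, p) <- if (sub$aa == "*") "A" else sub$aa
        hp <- host_peptide(mutated, p)
        plen <- nchar(hp$sequence)
        if (plen < lb[1] || plen > lb[2]) next
        if (want == "neutral") {
          res <- strsplit(hp$sequence, "")[[1]]
          alt_sites <- which(res %in% c("S", "T", "Y"))
          alt_sites <- alt_sites[abs(alt_sites - hp$offset) >= 2L]
          if (length(alt_sites) == 0L) next
        }
      }
      hit <- list(pi = pi, p = p, codon = codon, sub = sub, ref_aa = ref_aa)
      used <- c(used, key)
      break
    }
    if (is.null(hit)) stop("could not place variant ", v,
                           " (want = ", want, ")")
    genomic_pos <- tr$cds_start[hit$pi] + 3L * (hit$p - 1L) +
      (hit$sub$pos - 1L)
    het <- stats::runif(1) < params$fraction_heterozygous
    depth <- max(1L, stats::rnbinom(1L, mu = params$depth_mean,
                                    size = params$depth_dispersion))
    alt <- stats::rbinom(1L, depth, if (het) 0.5 else 1)
    mq <- if (stats::runif(1) < params$low_mq_fraction) {
      stats::runif(1, 0, 9.5)
    } else stats::runif(1, 20, 60)
    rows[[v]] <- data.frame(
      chrom = tr$chrom[hit$pi],
      pos = genomic_pos,
      ref = substr(hit$codon, hit$sub$pos, hit$sub$pos),
      alt = hit$sub$base,
      ref_count = depth - alt,
      alt_count = alt,
      mapping_quality = round(mq, 1),
      protein_id = tr$protein_id[hit$pi],
      transcript_id = tr$transcript_id[hit$pi],
      gene = tr$gene[hit$pi],
      protein_position = hit$p,
      ref_aa = hit$ref_aa,
      alt_aa = hit$sub$aa,
      effect = if (hit$sub$aa == "*") "stop_gain" else "missense",
      true_zygosity = if (het) "heterozygous" else "homozygous",
      phospho_category = categories[v],
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, rows)
  variants <- new_variant_table(
    all[, c("chrom", "pos", "ref", "alt", "ref_count", "alt_count",
            "mapping_quality")])
  annotations <- all[, c("chrom", "pos", "ref", "alt",
                         "protein_id", "transcript_id",
                         "gene", "protein_position", "ref_aa", "alt_aa",
                         "effect")]
  truth <- data.frame(
    variant_key = variant_key(all),
    chrom = all$chrom, pos = all$pos,
    zygosity = all$true_zygosity,
    true_vaf = ifelse(all$true_zygosity == "heterozygous", 0.5, 1.0),
    observed_vaf = all$alt_count / (all$ref_count + all$alt_count),
    depth = all$ref_count + all$alt_count,
    alt_count = all$alt_count,
    mapping_quality = all$mapping_quality,
    effect = all$effect,
    phospho_category = all$phospho_category,
    stringsAsFactors = FALSE
  )
  list(variants = variants, annotations = annotations, truth = truth)
}

#' Simulate identification, phospho and expression tables
#'
#' Draws log-normal protein abundances, links mRNA expression to them
#' (RPKM proportional to abundance with log-normal noise), detects each
#' tryptic peptide with probability logistic in log10 abundance, and
#' assigns intensities `abundance x allele fraction x noise`.
#' Heterozygous SAAV peptides split intensity evenly with their
#' reference counterparts; homozygous SAAVs suppress the reference
#' peptide entirely. Planted phosphopeptides are emitted with true
#' sites localised at probability >= 0.75 and decoy sites below it.
#'
#' @param proteome_obj Output of [generate_proteome()].
#' @param variants_obj Output of [generate_variants()].
#' @param params A [simulation_params()].
#' @return List with `evidence` (sequence, intensity), `phospho_evidence`
#'   (sequence, site_offset, localization_probability, intensity),
#'   `expression` (transcript/protein ids, read_count, length_bp, rpkm),
#'   and `truth` (list: `protein` abundances, `peptide` per-SAAV
#'   detection record, `phospho` planted categories keyed by
#'   variant_key).
#' @export
simulate_identifications <- function(proteome_obj, variants_obj,
                                     params = simulation_params()) {
  stopifnot(inherits(params, "saavx_simparams"))
  set.seed(params$seed + 2L)
  proteome <- proteome_obj$proteome
  tr <- proteome_obj$transcripts
  ann <- variants_obj$annotations
  truth_v <- variants_obj$truth
  lb <- params$evidence_length_bounds
  n <- length(proteome)

  abundance <- 10^stats::rnorm(n, params$abundance_mu_log10,
                               params$abundance_sigma_log10)
  names(abundance) <- names(proteome)
  p_detect <- stats::plogis(params$detection_slope *
                              (log10(abundance) - params$detection_midpoint))

  rpkm_val <- abundance / 1e4 *
    10^stats::rnorm(n, 0, params$rpkm_noise_sigma)
  read_count <- pmax(0L, round(rpkm_val * (tr$length_bp / 1000) *
                                 (params$total_mapped_reads / 1e6)))
  expression <- data.frame(
    transcript_id = tr$transcript_id,
    protein_id = tr$protein_id,
    length_bp = tr$length_bp,
    read_count = read_count,
    total_mapped_reads = params$total_mapped_reads,
    rpkm = rpkm(read_count, tr$length_bp, params$total_mapped_reads),
    stringsAsFactors = FALSE
  )

  noise <- function(k) 10^stats::rnorm(k, 0, params$intensity_noise_sigma)
  ann$variant_key <- variant_key(ann)
  het <- truth_v$zygosity[match(ann$variant_key, truth_v$variant_key)] ==
    "heterozygous"

  # reference digest evidence; allele fraction 0.5 where a heterozygous
  # variant sits on the peptide, 0 (absent) where a homozygous one does
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- names(proteome)[i]
    pep <- digest(proteome[[i]], max_missed = 0L, length_bounds = lb)
    af <- rep(1, nrow(pep))
    vrows <- which(ann$protein_id == pid & ann$effect == "missense")
    for (v in vrows) {
      onpep <- pep$start <= ann$protein_position[v] &
        pep$end >= ann$protein_position[v]
      af[onpep] <- if (het[v]) pmin(af[onpep], 0.5) else 0
    }
    det <- stats::runif(nrow(pep)) < p_detect[i] & af > 0
    if (!any(det)) { ev[[i]] <- NULL; next }
    ev[[i]] <- data.frame(
      sequence = pep$sequence[det],
      intensity = abundance[i] * af[det] * noise(sum(det)),
      stringsAsFactors = FALSE
    )
  }

  # SAAV peptide evidence
  pep_truth <- vector("list", nrow(ann))
  saav_ev <- vector("list", nrow(ann))
  for (v in seq_len(nrow(ann))) {
    pid <- ann$protein_id[v]
    prot <- proteome[[pid]]
    if (ann$effect[v] == "stop_gain") {
      mutated <- substr(prot, 1L, ann$protein_position[v] - 1L)
      hp <- host_peptide(mutated, nchar(mutated))
    } else {
      mutated <- prot
      substr(mutated, ann$protein_position[v], ann$protein_position[v]) <-
        ann$alt_aa[v]
      hp <- host_peptide(mutated, ann$protein_position[v])
    }
    plen <- nchar(hp$sequence)
    eligible <- plen >= lb[1] && plen <= lb[2]
    af <- if (het[v]) 0.5 else 1
    detected <- eligible && stats::runif(1) < p_detect[pid]
    intensity <- if (detected) abundance[pid] * af * noise(1) else NA_real_
    pep_truth[[v]] <- data.frame(
      variant_key = ann$variant_key[v],
      protein_id = pid,
      saav_peptide = hp$sequence,
      saav_offset = hp$offset,
      peptide_length = plen,
      db_eligible = eligible,
      detected = detected,
      true_intensity = intensity,
      abundance = unname(abundance[pid]),
      stringsAsFactors = FALSE
    )
    if (detected) {
      saav_ev[[v]] <- data.frame(sequence = hp$sequence,
                                 intensity = intensity,
                                 stringsAsFactors = FALSE)
    }
  }
  evidence <- do.call(rbind, c(ev, saav_ev))
  rownames(evidence) <- NULL

  # planted phosphopeptides
  planted <- which(!is.na(truth_v$phospho_category[
    match(ann$variant_key, truth_v$variant_key)]))
  ph <- vector("list", length(planted))
  ph_truth <- vector("list", length(planted))
  for (k in seq_along(planted)) {
    v <- planted[k]
    cat_v <- truth_v$phospho_category[
      match(ann$variant_key[v], truth_v$variant_key)]
    pt <- pep_truth[[v]]
    res <- strsplit(pt$saav_peptide, "")[[1]]
    site <- switch(
      cat_v,
      SITE_CREATION = pt$saav_offset,
      MOTIF_CREATION = pt$saav_offset - 1L,
      DETECTION_ONLY = {
        cand <- which(res %in% c("S", "T", "Y"))
        cand <- cand[abs(cand - pt$saav_offset) >= 2L]
        cand[sample.int(length(cand), 1L)]
      })
    loc <- stats::runif(1, 0.75, 1)
    rowset <- data.frame(
      sequence = pt$saav_peptide,
      site_offset = site,
      localization_probability = round(loc, 3),
      intensity = pt$abundance * (if (het[v]) 0.5 else 1) * noise(1),
      stringsAsFactors = FALSE
    )
    decoys <- setdiff(which(res %in% c("S", "T", "Y")), site)
    if (length(decoys) > 0L) {
      d <- decoys[sample.int(length(decoys), 1L)]
      rowset <- rbind(rowset, data.frame(
        sequence = pt$saav_peptide, site_offset = d,
        localization_probability = round(stats::runif(1, 0.1, 0.74), 3),
        intensity = rowset$intensity[1] * 0.2,
        stringsAsFactors = FALSE))
    }
    ph[[k]] <- rowset
    ph_truth[[k]] <- data.frame(
      variant_key = ann$variant_key[v],
      peptide = pt$saav_peptide,
      site_offset = site,
      true_category = cat_v,
      stringsAsFactors = FALSE
    )
  }
  phospho_evidence <- if (length(ph)) do.call(rbind, ph) else
    data.frame(sequence = character(), site_offset = integer(),
               localization_probability = numeric(), intensity = numeric())
  rownames(phospho_evidence) <- NULL

  list(
    evidence = evidence,
    phospho_evidence = phospho_evidence,
    expression = expression,
    truth = list(
      protein = data.frame(protein_id = names(proteome),
                           abundance = unname(abundance),
                           detection_probability = unname(p_detect),
                           stringsAsFactors = FALSE),
      peptide = do.call(rbind, pep_truth),
      phospho = if (length(ph_truth)) do.call(rbind, ph_truth) else NULL
    )
  )
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_proteome()], [generate_variants()] and
#' [simulate_identifications()] and optionally writes every table to a
#' directory as plain-text files (FASTA/BED/TSV), the layout consumed by
#' the command-line interface.
#'
#' @param params A [simulation_params()].
#' @param dir Optional output directory.
#' @return List with `proteome_obj`, `variants_obj`, `identifications`,
#'   and `exons`.
#' @export
simulate_dataset <- function(params = simulation_params(), dir = NULL) {
  proteome_obj <- generate_proteome(params)
  variants_obj <- generate_variants(proteome_obj, params)
  idents <- simulate_identifications(proteome_obj, variants_obj, params)
  exons <- synthetic_exons(proteome_obj)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteome_obj$proteome, file.path(dir, "proteome.fasta"))
    write_variant_table(variants_obj$variants,
                        file.path(dir, "variants.tsv"))
    wt <- function(x, f) utils::write.table(
      x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(variants_obj$annotations, "annotations.tsv")
    utils::write.table(exons, file.path(dir, "exons.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    wt(idents$evidence, "evidence.tsv")
    wt(idents$phospho_evidence, "phospho_evidence.tsv")
    wt(idents$expression, "expression.tsv")
    wt(variants_obj$truth, "ground_truth.tsv")
  }
  list(proteome_obj = proteome_obj, variants_obj = variants_obj,
       identifications = idents, exons = exons)
}
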