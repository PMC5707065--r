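test_that("CDS translation follows the standard code with stop truncation", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("ATGTAAAAA"), "M")
  expect_equal(translate_cds("ATGNNN"), "MX")
  expect_error(translate_cds("ATGAA"), "divisible by 3")
})

test_that("missense application substitutes exactly one residue", {
  prot <- "MVWDSQASEHFF"
  ann <- list(protein_id = "P1", protein_position = 7, ref_aa = "A",
              alt_aa = "V", effect = "missense")
  mut <- apply_missense(prot, ann)
  expect_equal(mut, "MVWDSQVSEHFF")
  expect_equal(sum(strsplit(prot, "")[[1]] != strsplit(mut, "")[[1]]), 1L)
  # applying then reverting restores the input
  back <- apply_missense(mut, list(protein_id = "P1", protein_position = 7,
                                   ref_aa = "V", alt_aa = "A",
                                   effect = "missense"))
  expect_equal(back, prot)
  # annotation/proteome skew is surfaced, not silently absorbed
  ann$ref_aa <- "G"
  expect_error(apply_missense(prot, ann), "reference mismatch")
})

test_that("stop-gain truncation keeps residues before the stop", {
  ann <- list(protein_id = "P1", protein_position = 12, ref_aa = "P",
              alt_aa = "*", effect = "stop_gain")
  expect_equal(apply_stop_gain("MKAVDRTCWKLP", ann), "MKAVDRTCWKL")
  ann1 <- list(protein_id = "P1", protein_position = 1, ref_aa = "M",
               alt_aa = "*", effect = "stop_gain")
  expect_error(apply_stop_gain("MKAV", ann1), "empty protein")
})

test_that("cleavage sites follow trypsin K/R-not-P specificity", {
  expect_equal(tryptic_cleavage_sites("MKAVDRTCWKLPER"), c(2L, 6L, 10L, 14L))
  # K1 and R28 are each followed by P: no internal cuts
  expect_equal(tryptic_cleavage_sites("KPGYHTPVALLNDIPQSTEQYDPFAEHRPPK"),
               31L)
  expect_equal(tryptic_cleavage_sites("RRRR"), 1:4)
  expect_equal(digest("RRRR", 0, c(1, 50))$sequence, rep("R", 4))
})

test_that("digestion matches brute-force enumeration and partitions", {
  d0 <- digest("MKAVDRTCWKLPER", 0, c(1, 50))
  expect_equal(d0$sequence, c("MK", "AVDR", "TCWK", "LPER"))
  d1 <- digest("MKAVDRTCWKLPER", 1, c(1, 50))
  expect_setequal(setdiff(d1$sequence, d0$sequence),
                  c("MKAVDR", "AVDRTCWK", "TCWKLPER"))
  set.seed(101)
  for (i in 1:50) {
    seq <- random_protein(sample(20:70, 1))
    mm <- sample(0:2, 1)
    got <- digest(seq, mm, c(1, 1000))
    want <- brute_digest(seq, mm)
    expect_equal(got[order(got$start, got$end), ]$sequence, want$sequence)
    expect_equal(got[order(got$start, got$end), ]$missed, want$missed)
    # partition property: 0-missed peptides reconstruct the protein
    expect_equal(paste(digest(seq, 0, c(1, 1000))$sequence, collapse = ""),
                 seq)
    expect_false(anyDuplicated(paste(got$start, got$end)) > 0)
  }
})

test_that("SAAV peptide enumeration extends each flank independently", {
  cfg <- pipeline_config(peptide_length_bounds_db = c(1, 50))
  ann <- list(protein_id = "P1", protein_position = 8, ref_aa = "C",
              alt_aa = "Y", effect = "missense")
  pep <- enumerate_saav_peptides("MKAVDRTYWKLPER", ann, cfg)
  expect_setequal(pep$sequence,
                  c("TYWK", "AVDRTYWK", "TYWKLPER", "AVDRTYWKLPER"))
  expect_equal(pep$saav_offset[match(c("TYWK", "AVDRTYWK"), pep$sequence)],
               c(2L, 6L))
  # every missense variant peptide differs from the reference digest
  # peptide at exactly the variant residue
  for (i in seq_len(nrow(pep))) {
    refpep <- substr("MKAVDRTCWKLPER", pep$start[i], pep$end[i])
    diffs <- which(strsplit(pep$sequence[i], "")[[1]] !=
                     strsplit(refpep, "")[[1]])
    expect_equal(diffs, pep$saav_offset[i])
  }
})

test_that("a SAAV destroying a cleavage site merges the flanking peptides", {
  # K10 -> E removes the cut after position 10
  ann <- list(protein_id = "P1", protein_position = 10, ref_aa = "K",
              alt_aa = "E", effect = "missense")
  mut <- apply_missense("MKAVDRTCWKLPER", ann)
  cfg <- pipeline_config(peptide_length_bounds_db = c(1, 50),
                         max_missed_cleavages_per_side = 0)
  pep <- enumerate_saav_peptides(mut, ann, cfg)
  expect_equal(pep$sequence, "TCWELPER")  # merged segment only
})

test_that("truncation peptides are C-terminal with N-side extension only", {
  ann <- list(protein_id = "P1", protein_position = 12, ref_aa = "P",
              alt_aa = "*", effect = "stop_gain")
  mut <- apply_stop_gain("MKAVDRTCWKLP", ann)  # "MKAVDRTCWKL"
  cfg <- pipeline_config(peptide_length_bounds_db = c(1, 50))
  pep <- enumerate_saav_peptides(mut, ann, cfg)
  expect_setequal(pep$sequence, c("L", "TCWKL"))
  expect_true(all(pep$is_truncation_cterm))
  expect_true(all(pep$end == nchar(mut)))
  # non-tryptic C-terminus: last residue is not K/R
  expect_false(substr(mut, nchar(mut), nchar(mut)) %in% c("K", "R"))
})

test_that("enumeration equals the brute-force oracle on random SAAVs", {
  set.seed(202)
  cfg <- pipeline_config(peptide_length_bounds_db = c(1, 1000))
  for (i in 1:300) {
    L <- sample(25:70, 1)
    prot <- random_protein(L)
    p <- sample(2:(L - 1), 1)
    ref <- substr(prot, p, p)
    alt <- sample(setdiff(c("A", "K", "R", "P", "S", "G", "E"), ref), 1)
    ann <- list(protein_id = "PX", protein_position = p, ref_aa = ref,
                alt_aa = alt, effect = "missense")
    mut <- apply_missense(prot, ann)
    got <- enumerate_saav_peptides(mut, ann, cfg)
    got <- got[order(got$start, got$end), ]
    want <- brute_saav_peptides(mut, p, 1L, c(1, 1000))
    expect_equal(got$sequence, want$sequence)
    expect_equal(got$missed_n, want$missed_n)
    expect_equal(got$missed_c, want$missed_c)
  }
})

test_that("database builder keys peptides by SAAV and respects bounds", {
  proteome <- c(P1 = "MKAVDRTCWKLPER", P2 = "MSSSPHKTTTRGGGK")
  annotations <- data.frame(
    protein_id = c("P1", "P2"), protein_position = c(8L, 9L),
    ref_aa = c("C", "T"), alt_aa = c("Y", "S"),
    effect = "missense", gene = c("G1", "G2"))
  db <- build_saav_database(proteome, annotations,
                            pipeline_config(peptide_length_bounds_db = c(4, 45)))
  expect_true(all(nchar(db$sequence) >= 4))
  expect_setequal(unique(db$variant_key), c("P1|p.C8Y", "P2|p.T9S"))
  expect_error(
    build_saav_database(proteome, data.frame(
      protein_id = "P9", protein_position = 2L, ref_aa = "K",
      alt_aa = "E", effect = "missense")),
    "unknown protein_id")
})
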