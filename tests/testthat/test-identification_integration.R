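toy_db <- function() {
  proteome <- c(P1 = "MKAVDRTCWKLPER", P2 = "MSSSPHKTTTRGGGK")
  annotations <- data.frame(
    protein_id = "P1", protein_position = 8L, ref_aa = "C",
    alt_aa = "Y", effect = "missense", gene = "G1")
  list(proteome = proteome,
       db = build_saav_database(
         proteome, annotations,
         pipeline_config(peptide_length_bounds_db = c(4, 45))))
}

test_that("evidence rows are labelled variant / reference / unassigned", {
  t <- toy_db()
  evidence <- data.frame(
    sequence = c("TYWK", "TCWK", "QQQQQQ", "TYWK"),
    intensity = c(100, 50, 10, 20))
  m <- match_peptides(evidence, t$db, t$proteome)
  expect_equal(m$label[m$sequence == "TYWK"], "variant")
  expect_equal(m$label[m$sequence == "TCWK"], "reference")
  expect_equal(m$label[m$sequence == "QQQQQQ"], "unassigned")
  # repeated detections are summed per unique sequence
  expect_equal(m$intensity[m$sequence == "TYWK"], 120)
  expect_equal(m$variant_key[m$sequence == "TYWK"], "P1|p.C8Y")
  expect_equal(m$saav_offset[m$sequence == "TYWK"], 2L)
})

test_that("modification notation is stripped before matching", {
  expect_equal(strip_modifications("_TY(ph)WK_"), "TYWK")
  expect_equal(strip_modifications("TC[+57.02]WK"), "TCWK")
  t <- toy_db()
  m <- match_peptides(data.frame(sequence = "_TY(ph)WK_", intensity = 5),
                      t$db, t$proteome)
  expect_equal(m$label, "variant")
})

test_that("a SAAV peptide also present in the reference proteome is not a
          variant call, and two-SAAV collisions are flagged ambiguous", {
  proteome <- c(P1 = "MKAVDRTCWKLPER", P2 = "MTYWKGGGR")
  ann <- data.frame(protein_id = "P1", protein_position = 8L,
                    ref_aa = "C", alt_aa = "Y", effect = "missense")
  db <- build_saav_database(proteome, ann,
                            pipeline_config(peptide_length_bounds_db = c(4, 45)))
  # TYWK occurs in P2 verbatim -> reference, not variant
  m <- match_peptides(data.frame(sequence = "TYWK", intensity = 1),
                      db, proteome)
  expect_equal(m$label, "reference")

  # same peptide sequence generated by two different SAAVs -> ambiguous
  proteome2 <- c(P1 = "MKAVDRTCWKLPER", P3 = "MRAVDRTCWKGGGR")
  ann2 <- data.frame(protein_id = c("P1", "P3"),
                     protein_position = c(8L, 8L),
                     ref_aa = "C", alt_aa = "Y", effect = "missense")
  db2 <- build_saav_database(proteome2, ann2,
                             pipeline_config(peptide_length_bounds_db = c(4, 45)))
  m2 <- match_peptides(data.frame(sequence = "TYWK", intensity = 1),
                       db2, proteome2)
  expect_equal(m2$label, "variant")
  expect_true(m2$ambiguous)
  expect_equal(nrow(pair_and_flag(
    m2, data.frame(variant_key = c("P1|p.C8Y", "P3|p.C8Y"),
                   vaf = 1, zygosity = "homozygous", alt_count = 5))), 0L)
})

test_that("reference counterpart restores the reference residue", {
  expect_equal(reference_counterpart("TYWK", 2, "C"), "TCWK")
  expect_equal(reference_counterpart("SQLPDLSAPHSYSPGR", 8, "G"),
               "SQLPDLSGPHSYSPGR")
  expect_error(reference_counterpart("LTCWKL", 5, "K", effect = "stop_gain"),
               "no reference counterpart")
})

test_that("conflicts require homozygosity plus a detected reference", {
  t <- toy_db()
  evidence <- data.frame(sequence = c("TYWK", "TCWK"),
                         intensity = c(100, 80))
  m <- match_peptides(evidence, t$db, t$proteome)
  zyg_hom <- data.frame(variant_key = "P1|p.C8Y", vaf = 1,
                        zygosity = "homozygous", alt_count = 4)
  p <- pair_and_flag(m, zyg_hom)
  expect_true(p$conflict)
  expect_true(p$low_coverage)
  expect_equal(p$reference_intensity, 80)

  zyg_het <- transform(zyg_hom, vaf = 0.5, zygosity = "heterozygous",
                       alt_count = 40)
  p2 <- pair_and_flag(m, zyg_het)
  expect_true(p2$reference_detected)
  expect_false(p2$conflict)

  # homozygous without a detected reference peptide: no conflict
  m3 <- match_peptides(data.frame(sequence = "TYWK", intensity = 100),
                       t$db, t$proteome)
  p3 <- pair_and_flag(m3, zyg_hom)
  expect_false(p3$reference_detected)
  expect_false(p3$conflict)
})

test_that("matching is order-independent", {
  t <- toy_db()
  evidence <- data.frame(
    sequence = c("TYWK", "TCWK", "AVDR", "QQQQQQ", "LPER"),
    intensity = c(10, 20, 30, 40, 50))
  zyg <- data.frame(variant_key = "P1|p.C8Y", vaf = 1,
                    zygosity = "homozygous", alt_count = 3)
  base <- pair_and_flag(match_peptides(evidence, t$db, t$proteome), zyg)
  set.seed(5)
  for (i in 1:5) {
    shuf <- evidence[sample(nrow(evidence)), ]
    p <- pair_and_flag(match_peptides(shuf, t$db, t$proteome), zyg)
    expect_identical(p, base)
  }
})

test_that("allele-balance correlation recovers a planted correlation", {
  # identical intensities give r = 1
  pairs <- data.frame(
    variant_sequence = "X", reference_sequence = "Y",
    variant_intensity = c(10, 100, 1000),
    reference_intensity = c(10, 100, 1000),
    zygosity = "heterozygous", reference_detected = TRUE)
  expect_equal(allele_balance_correlation(pairs)$r, 1.0)
  expect_error(allele_balance_correlation(pairs[1:2, ]),
               "insufficient data")

  # log-normal shared abundance with independent noise: r ~ s2/(s2+n2)
  set.seed(9)
  n <- 800
  shared <- rnorm(n, 6, 1)
  eps_v <- rnorm(n, 0, 0.5)
  eps_r <- rnorm(n, 0, 0.5)
  pairs2 <- data.frame(
    variant_intensity = 10^(shared + eps_v),
    reference_intensity = 10^(shared + eps_r),
    zygosity = "heterozygous", reference_detected = TRUE)
  r_expected <- 1 / (1 + 0.25)  # var(shared) / (var(shared) + var(noise))
  got <- allele_balance_correlation(pairs2)
  expect_equal(got$n, n)
  expect_lt(abs(got$r - r_expected), 0.05)
})
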