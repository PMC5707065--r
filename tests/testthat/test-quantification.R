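test_that("theoretical peptide count honours bounds and the floor of 1", {
  expect_equal(theoretical_peptide_count(
    "MKAVDRTCWKLPER", pipeline_config(peptide_length_bounds_ibaq = c(1, 50))), 4L)
  expect_equal(theoretical_peptide_count(
    "MKAVDRTCWKLPER", pipeline_config(peptide_length_bounds_ibaq = c(7, 30))), 1L)
  # poly-K digests to single residues, all below the default lower bound
  expect_equal(theoretical_peptide_count("KKKKKKKK"), 1L)
})

test_that("iBAQ is intensity over theoretical count and scales linearly", {
  expect_equal(ibaq(900, 10), 90)
  expect_equal(ibaq(0, 5), 0)
  expect_equal(ibaq(2 * 900, 10), 2 * ibaq(900, 10))
  expect_error(ibaq(-1, 5), "negative")
})

test_that("updated iBAQ adds SAAV intensity without touching the
          denominator", {
  expect_equal(updated_ibaq(900, 100, 10), 100)
  expect_equal(updated_ibaq(900, numeric(0), 10), ibaq(900, 10))
  expect_equal(updated_ibaq(900, c(50, 50), 10), updated_ibaq(900, 100, 10))
  expect_error(updated_ibaq(900, -5, 10), "negative")
  # monotonicity: updated >= plain, strict when any SAAV intensity > 0
  set.seed(31)
  for (i in 1:100) {
    tot <- runif(1, 0, 1e9)
    cnt <- sample(1:60, 1)
    sv <- runif(sample(0:4, 1), 0, 1e8)
    u <- updated_ibaq(tot, sv, cnt)
    expect_gte(u, ibaq(tot, cnt))
    if (sum(sv) > 0) expect_gt(u, ibaq(tot, cnt))
  }
})

test_that("rpkm normalises by kilobase and library size", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
  expect_error(rpkm(10, 0, 1e6), "length")
})

test_that("Williams' t is zero under equality and antisymmetric", {
  expect_equal(williams_t(0.5, 0.5, 0.3, 100)$t, 0)
  expect_equal(williams_t(0.5, 0.5, 0.3, 100)$p, 1)
  a <- williams_t(0.6, 0.4, 0.5, 200)
  b <- williams_t(0.4, 0.6, 0.5, 200)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$df, 197)
  expect_error(williams_t(0.5, 0.4, 0.3, 3), "n > 3")
  expect_error(williams_t(1, 0.4, 0.3, 30), "degenerate")
})

test_that("a tiny correlation gain is significant when the comparands are
          near-identical, as for an iBAQ update", {
  res <- williams_t(0.6825, 0.6830, 0.9999, 6881)
  expect_lt(res$p, 0.01)
})

test_that("Williams' test is calibrated against a simulation oracle", {
  # under H0 (r12 == r13 by symmetry) the rejection rate at alpha = 0.05
  # must match alpha; this checks formula and df choice end to end
  set.seed(77)
  n <- 40
  nsim <- 1500
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    shared <- rnorm(n)
    x2 <- 0.5 * shared + rnorm(n, 0, sqrt(0.75))
    x3 <- 0.5 * shared + rnorm(n, 0, sqrt(0.75))
    r12 <- cor(shared, x2); r13 <- cor(shared, x3); r23 <- cor(x2, x3)
    rej[i] <- williams_t(r12, r13, r23, n)$p < 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("log-scale correlation excludes non-positive pairs", {
  x <- c(1, 10, 100, 1000)
  expect_equal(correlate_log(x, 2 * x), 1)
  expect_error(correlate_log(1:2, 1:2), "insufficient")
  set.seed(13)
  x <- 10^rnorm(2000); y <- 10^rnorm(2000)
  expect_lt(abs(correlate_log(x, y)), 0.06)
  # zeros are removed pairwise, not propagated
  expect_equal(correlate_log(c(x, 0), c(y, 5)), correlate_log(x, y))
})

test_that("protein quantification table links iBAQ, update and RPKM", {
  proteome <- c(P1 = "MKAVDRTCWKLPER", P2 = "MSSSPHKTTTRGGGK")
  cfg <- pipeline_config(peptide_length_bounds_ibaq = c(1, 50))
  q <- quantify_proteins(
    data.frame(protein_id = c("P1", "P2"), total_intensity = c(900, 500)),
    proteome,
    saav_intensities = data.frame(protein_id = "P1", intensity = 100),
    expression = data.frame(protein_id = c("P1", "P2"), rpkm = c(5, 2)),
    cfg = cfg)
  expect_equal(q$theoretical_peptide_count[1], 4L)
  expect_equal(q$ibaq[1], 225)
  expect_equal(q$updated_ibaq[1], 250)
  expect_equal(q$updated_ibaq[2], q$ibaq[2])  # no SAAV intensity
  expect_equal(q$rpkm, c(5, 2))
})

test_that("restoring withheld SAAV intensity improves the mRNA correlation
          on abundance-generated data", {
  # abundance drives both mRNA and intensity; for SAAV-carrying proteins
  # only half the true intensity is in the standard total
  set.seed(55)
  n <- 400
  abundance <- 10^rnorm(n, 6, 1)
  mrna <- abundance * 10^rnorm(n, 0, 0.2)
  has_saav <- seq_len(n) <= 150
  saav_part <- ifelse(has_saav, 0.5, 0) * abundance
  total <- (abundance - saav_part) * 10^rnorm(n, 0, 0.05)
  counts <- sample(5:40, n, TRUE)
  plain <- ibaq(total, counts)
  updated <- mapply(updated_ibaq, total, saav_part, counts)
  r_before <- correlate_log(mrna, plain)
  r_after <- correlate_log(mrna, updated)
  expect_gt(r_after, r_before)
  cmp <- compare_quant_correlations(data.frame(
    protein_id = as.character(seq_len(n)), rpkm = mrna, ibaq = plain,
    updated_ibaq = updated))
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$n, n)
})
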