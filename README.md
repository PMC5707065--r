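# saavx

Proteogenomic analysis of single amino acid variant (SAAV) peptides.

Massively parallel sequencing finds thousands of single nucleotide
variants (SNVs) in a cancer sample, but almost none of them are ever
checked at the protein level. `saavx` implements the downstream half of a
proteogenomic pipeline that does exactly that: it turns annotated
missense and stop-gain SNVs into a custom database of variant-containing
tryptic peptides, matches peptide identifications from a shotgun
proteomics experiment against it, and uses the results to (i) sanity-check
variant calls through zygosity, (ii) improve label-free protein
quantification, and (iii) find SNVs that create new phosphorylation
events. It is aimed at computational proteomics / cancer genomics
analysts who already have variant calls and search-engine output and
want the integration layer between them.

## What it computes

**Variant processing.** SNVs are filtered by site read depth (< 2 reads
removed), mapping quality (< 10 removed) and exon overlap; the variant
allele frequency VAF = alt / (ref + alt) classifies each site as
homozygous (VAF = 1.0) or heterozygous.

**SAAV peptide database.** Each missense SNV is applied to its protein
(`p.A86T` style); stop-gains truncate it. Tryptic peptides are
enumerated on the *mutated* sequence (a variant that creates or destroys
K/R/P changes the digest), with up to one missed cleavage independently
on each side of the variant residue, trypsin specificity
cleave-after-K/R-not-before-P, and configurable length bounds
(default 6–45 residues).

**Identification integration.** Evidence peptides are matched exactly
against the SAAV database and the reference proteome. Every variant
peptide is paired with its reference counterpart (same sequence with the
reference residue restored); a *homozygous conflict* is a homozygous SNV
whose reference peptide was nevertheless detected — with an alternate
allele count below 10 this usually exposes an unreliable zygosity call.
Heterozygous pairs should be allele-balanced; their log10-intensity
Pearson correlation quantifies that.

**Quantification.** iBAQ = total intensity / number of theoretically
detectable peptides (fully tryptic, 0 missed cleavages, 7–30 residues).
The updated iBAQ adds SAAV peptide intensities to the numerator while
keeping the denominator fixed. mRNA expression is RPKM, and the change
in cor(log10 RPKM, log10 iBAQ) after the update is tested with Williams'
(1959) t-test for two dependent correlations sharing one variable:

    t = (r12 − r13) · sqrt( (n−1)(1+r23) / (2·((n−1)/(n−3))·|R| + r̄²(1−r23)³) ),  df = n − 3

with |R| = 1 − r12² − r13² − r23² + 2·r12·r13·r23 and r̄ = (r12+r13)/2.

**Phosphopeptide classification.** SAAV phosphopeptides (localization
probability ≥ 0.75) are assigned one of three exhaustive categories:
`SITE_CREATION` (the variant introduces the phosphorylated S/T/Y),
`MOTIF_CREATION` (the variant introduces the proline of an [S/T]P
proline-directed kinase motif immediately C-terminal of the
phosphosite), or `DETECTION_ONLY`. Site creation takes precedence.
Impacting SAAVs absent from dbSNP with zero population allele frequency
are flagged putative-somatic.

**Synthetic data.** `simulate_dataset()` generates a complete input set
with known ground truth (binomial allele counts, log-normal abundance,
logistic detection, allele-balanced heterozygous intensities, planted
phosphosite categories), so the whole pipeline is testable offline.

## Worked example

```r
library(saavx)

proteome <- c(YTH1 = "MKAVDRTCWKLPEREFHNMGPPPPWQGSSK")
ann <- data.frame(protein_id = "YTH1", gene = "YTH1", protein_position = 8,
                  ref_aa = "C", alt_aa = "Y", effect = "missense")
db <- build_saav_database(proteome, ann,
                          pipeline_config(peptide_length_bounds_db = c(4, 45)))
db[, c("sequence", "saav_offset", "missed_n", "missed_c", "variant_key")]
#>       sequence saav_offset missed_n missed_c variant_key
#> 1         TYWK           2        0        0  YTH1|p.C8Y
#> 2     AVDRTYWK           6        1        0  YTH1|p.C8Y
#> 3     TYWKLPER           2        0        1  YTH1|p.C8Y
#> 4 AVDRTYWKLPER           6        1        1  YTH1|p.C8Y
```

Four database peptides: the variant-containing tryptic segment plus its
0/1 missed-cleavage extensions on each flank, each knowing where the
variant residue sits (`saav_offset`).

```r
evidence <- data.frame(sequence = c("TYWK", "TCWK", "AVDR"),
                       intensity = c(1.2e8, 0.9e8, 3e7))
matched <- match_peptides(evidence, db, proteome)
zyg <- data.frame(variant_key = "YTH1|p.C8Y", vaf = 1,
                  zygosity = "homozygous", alt_count = 3)
pair_and_flag(matched, zyg)[, c("variant_sequence", "reference_sequence",
                                "zygosity", "conflict", "low_coverage")]
#>   variant_sequence reference_sequence   zygosity conflict low_coverage
#> 1             TYWK               TCWK homozygous     TRUE         TRUE
```

The variant peptide TYWK and its reference counterpart TCWK were both
detected although the SNV was called homozygous — a conflict, flagged
low-coverage because only 3 reads supported the alternate allele.

```r
classify_phosphopeptide(data.frame(
  peptide_sequence = "KPGYHTPVALLNDIPQSTEQYDPFAEHRPPK",
  saav_offset = 6, ref_aa = "A", alt_aa = "T", site_offset = 6))$category
#> [1] "SITE_CREATION"
```

An A→T variant that is itself the phosphorylated threonine: the SNV
created the phosphosite (and the classification stays `SITE_CREATION`
despite the following proline, which would otherwise look like an
[S/T]P motif gain).

A command-line interface over the same functions is installed at
`system.file("cli", "saavx.R", package = "saavx")`, with subcommands
`filter-variants`, `build-db`, `match-peptides`, `quantify`,
`classify-phospho` and `simulate`.

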