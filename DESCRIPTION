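Package: saavx
Title: Proteogenomic Analysis of Single Amino Acid Variant Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating genomic variant calls with shotgun
    proteomics and phosphoproteomics identifications. Builds custom search
    databases of single amino acid variant (SAAV) tryptic peptides from
    annotated single nucleotide variants (missense and stop-gain), filters
    variants by read support, mapping quality and exon overlap, classifies
    zygosity from variant allele frequencies, pairs identified variant
    peptides with their reference counterparts and flags homozygous
    conflicts, recomputes intensity-based absolute quantification (iBAQ)
    with variant peptide intensities and compares mRNA-protein correlations
    with Williams' test for dependent correlations, and classifies
    SAAV-containing phosphopeptides by whether the variant creates a
    phosphorylation site or a proline-directed kinase motif. A synthetic
    data generator with known ground truth makes every stage testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
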