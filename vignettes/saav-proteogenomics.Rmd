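---
title: "SAAV proteogenomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAAV proteogenomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saavx)
```

# Overview

`saavx` implements the integration layer between genomic variant calls
and mass-spectrometry peptide identifications. This vignette documents
the underlying models and the design decisions taken where reasonable
alternatives existed, so that results can be interpreted — and
disagreed with — on an informed basis.

# Variant filtering and zygosity

Variants enter as single-nucleotide substitutions with reference and
alternate allele read counts and a mapping quality. Filtering removes
sites with fewer than `min_supporting_reads` (default 2) reads and
mapping quality below `min_mapping_quality` (default 10); both are
"less than" thresholds, so a site exactly at the threshold is kept.
The read-support filter applies to **total site depth** (ref + alt) by
default, matching the depth semantics of pileup-based callers; set
`read_filter_mode = "alt"` in `pipeline_config()` to count only
alternate-allele reads. Exon restriction uses the BED convention
throughout: a 1-based variant position $p$ overlaps a 0-based
half-open interval $(start, end]$ iff $start < p \le end$; both
boundaries are covered by tests.

Zygosity is a function of the variant allele frequency
$\mathrm{VAF} = a/(r+a)$. A site is homozygous when
$\mathrm{VAF} \ge$ `homozygous_min_vaf`, default exactly 1.0 — i.e.
zero reference reads. The exact-1.0 default reproduces the
classification used in the conflict analysis this package ships as an
example; for real data a floor such as 0.95 is more robust to
sequencing error and is a one-line configuration change. A VAF at a
zero-depth site is undefined and raises an error rather than returning
a sentinel.

# The SAAV peptide database

Missense variants substitute one residue
(`apply_missense`, which errors loudly on a reference-residue mismatch
— the signature of annotation/proteome version skew). Stop-gains
truncate the protein before the stop position; the resulting
C-terminus is generally non-tryptic, which is precisely what makes
truncation peptides identifiable (see below).

Digestion follows trypsin specificity: cleave after K or R unless the
next residue is proline. `enumerate_saav_peptides` computes cleavage
sites **on the mutated sequence**. The alternative (digesting the
reference and substituting afterwards) silently produces peptides that
cannot exist whenever a variant creates or destroys a K, R or P; the
proline rule in particular is required for a variant-created `[S/T]P`
motif peptide to come out as the 0-missed-cleavage identification it
really is.

"Up to one missed cleavage either side of the SAAV" is interpreted as
independent N-side and C-side extension of the variant-containing
tryptic segment, 0 or 1 skipped cleavage interval per flank (so up to
2 internal missed cleavages total, `max_missed_cleavages_per_side`).
A variant-centred peptide can legitimately retain one skipped site on
each flank, and the enumeration is verified in tests against a
brute-force oracle that simply scans all tryptic substrings containing
the variant (1,000 random instances per run). For stop-gains the
"variant segment" is the new C-terminal segment and only N-side
extension applies.

Database peptides are bounded at 6–45 residues
(`peptide_length_bounds_db`), standard search-engine practice; the
bounds are configurable because no single convention is universal.
Isoleucine and leucine are **not** collapsed: peptide identity is
exact string identity everywhere in the package.

# Matching and pairing

The package deliberately does not re-implement spectral search;
"identification" means exact sequence matching of (modification-
stripped) evidence peptides against the SAAV database and the
reference proteome. A peptide is a variant identification only if it
matches a database peptide *and* occurs nowhere in the reference
proteome; a peptide matching two different SAAVs is flagged ambiguous
and excluded from unique-SAAV counting. Repeated detections are summed
per unique sequence before pairing, the peptide-level convention of
MaxQuant-style outputs.

Truncation peptides need one exception: the truncated protein is a
prefix of the reference, so its peptides are always reference
substrings. A truncation peptide is therefore accepted as a variant
identification when its C-terminus is non-tryptic (last residue not
K/R), because no reference digest can produce it; a truncation peptide
that happens to end at a K/R is indistinguishable from the reference
peptide and is treated as such.

A *homozygous conflict* is a homozygous SNV whose reference-allele
peptide was detected anyway. Conflicts with alternate allele count
below `low_coverage_alt_count` (default 10) carry a low-coverage flag:
at such depths a heterozygous site easily presents all-alternate
reads, and the conflict indicts the zygosity call, not the peptide.
Allele balance of heterozygous pairs is summarised as the Pearson
correlation of log10 intensities; zero intensities are excluded
pairwise, and fewer than 3 usable pairs is an error, not a number.

# Quantification

iBAQ divides a protein's summed peptide intensity by its number of
theoretically detectable peptides: fully tryptic, zero missed
cleavages, length 7–30 (`peptide_length_bounds_ibaq`, the MaxQuant
convention), clamped below at 1 so the ratio is always defined. The
updated iBAQ adds SAAV peptide intensities to the numerator and leaves
the denominator unchanged — the update corrects intensity lost to the
variant search space, it does not redefine the protein's peptide
universe. Consequently `updated_ibaq >= ibaq` always, strictly when
any SAAV intensity is positive; this invariant is property-tested.

The change in mRNA–protein correlation is assessed with Williams'
(1959) t-test for two dependent correlations sharing one variable
(the mRNA vector), on $n-3$ degrees of freedom. The third correlation
$r_{23}$ (between the two iBAQ vectors) is computed empirically, never
assumed: because the update touches only the minority of proteins with
SAAV peptides, the two vectors are nearly identical and $r_{23}$ is
typically 0.999+, which is exactly what gives the test its power to
call a correlation difference in the third decimal place significant.
All abundance correlations use log10; the implementation is verified
by symmetry/antisymmetry properties and a Monte-Carlo type-I-error
calibration in the test suite.

# Phosphopeptide classification

Phosphosites below localization probability 0.75
(`localization_threshold`, inclusive) are discarded first. The
classifier then applies two rules in order:

1. **Site creation** — the phosphosite sits exactly at the variant
   offset, the alternate residue is S/T/Y and the reference residue is
   not. The reference-residue condition means an S→T exchange is *not*
   site creation: the position was phosphorylatable before, so nothing
   novel was created.
2. **Motif creation** — the alternate residue is a proline (reference
   is not) immediately C-terminal of a phosphorylated S or T, the
   `[S/T]P` substrate motif of proline-directed kinases (MAPK/CDK).
   The motif rule is deliberately restricted to S/T: `Y-P` is not a
   proline-directed motif. Other kinase motifs are out of scope
   because they lack an equally crisp sequence definition.

Everything else is detection-only. Site creation takes precedence when
a created S/T is itself followed by a proline — the variant made the
residue, which is the stronger claim. The categories are exhaustive
and mutually exclusive, and classification is invariant under flank
extension (tested). Loss-of-site and loss-of-motif events are out of
scope: only detected variant phosphopeptides are classified.

Impacting SAAVs with no dbSNP identifier and zero (or absent)
population allele frequency are flagged putative-somatic; in the
bundled 24-peptide example this flags five events, including the
splicing-factor SF3B1 T86 site.

# The synthetic data generator

`simulation_params()` fixes the study conditions the generator
emulates; the defaults are chosen once and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 200 | desk-scale proteome; keeps the full-pipeline test under a minute |
| `n_variants` | 300 | a few SAAVs per expressed protein region, comparable density to a deep cell-line experiment |
| `fraction_heterozygous` | 0.65 | matches the roughly 2:1 heterozygous:homozygous split seen in deep cell-line SAAV data |
| `fraction_stop_gain` | 0.03 | stop-gains are ~3% of non-synonymous calls |
| `depth_mean`, `depth_dispersion` | 60, 5 | 60x WGS-like negative-binomial depth |
| `abundance_mu_log10`, `abundance_sigma_log10` | 7.5, 1.2 | log-normal intensities spanning the usual 4–5 orders of magnitude |
| `detection_slope`, `detection_midpoint` | 1.5, 7.0 | logistic detection in log10 abundance — the simplest mechanism making highly expressed proteins more detectable |
| `intensity_noise_sigma` | 0.3 | log10 multiplicative peptide-level noise |
| `n_phospho`, `category_mix` | 60, 0.4/0.3/0.3 | enough planted sites per category for exact-recovery checks |

Heterozygous alternate counts are Binomial(depth, 0.5), homozygous
Binomial(depth, 1); heterozygous SAAV peptides split intensity evenly
with their reference counterparts, and homozygous variants suppress
the reference peptide entirely. Variants are planted at the nucleotide
level — a codon substitution whose translation gives the intended
amino acid change — so the CDS, protein, annotation and genomic
coordinate are mutually consistent by construction and the exon
intervals cover every variant. Planted phosphosites get localization
probabilities drawn from [0.75, 1) plus sub-threshold decoy sites, so
the localization filter is exercised in both directions. Every
generator call is deterministic given `seed`.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: spectra and search-engine
behaviour (no FDR, no chimeric spectra, no modification
misassignment), retention time and m/z, shared/degenerate peptides
between homologous proteins, RNA editing, multi-nucleotide or
phased variants, and allele-specific expression beyond the clean 50/50
split. Recovery rates near 100% on synthetic data are a correctness
check of the pipeline logic, not a sensitivity estimate for real
experiments.

# Numerical and degenerate-input policy

* VAF at zero depth, correlations on fewer than 3 positive pairs,
  Williams' test at $n \le 3$ or $|r| = 1$: errors, never NA or a
  sentinel value.
* Duplicate variant records (same chromosome, position, alternate
  allele) are collapsed keeping the deepest record.
* Zero-length digest results (every peptide outside the length
  bounds) yield a theoretical peptide count clamped to 1.
* The writer suffixes colliding FASTA headers with a numeric index;
  round-trips are exact and order-preserving.
* All genomic coordinates are 1-based internally (VCF convention);
  BED input is converted on read.

# Problem sizes

The shipped test suite runs the digestion oracle on 1,000 random
variant instances, the Williams calibration on 1,000–1,500 simulated
triples at $n = 35$–40, and the full synthetic pipeline at 200
proteins / 300 variants / 60 planted phosphosites (seed 1); the whole
suite completes in under a minute on one CPU. These sizes were chosen
as the smallest at which the property checks have real discriminating
power.

# Known limitations

* Exact-match identification cannot model peptides observable only
  through modification or miscleavage states absent from the database.
* Stop-gain peptides ending at K/R are systematically conceded to the
  reference (documented above); a retention-time or spectral model
  would be needed to rescue them.
* The updated-iBAQ denominator policy means proteins whose variant
  changes their theoretical peptide count are still normalised by the
  reference count.
* Williams' test assumes joint normality of the three variables on
  the correlation scale; with heavy-tailed abundance data the log10
  transform is load-bearing.
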