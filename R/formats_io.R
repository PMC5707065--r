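#' Read a protein FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' conventions used throughout the package: record ids are the header up to
#' the first whitespace, sequences are uppercased, insertion order is kept,
#' and empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, protein id -> sequence.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 test protein", "MKAV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- which(Biostrings::width(set) == 0L)[1]
    lines <- readLines(path)
    line_no <- grep("^>", lines)[bad]
    stop(sprintf("empty sequence for record '%s' (header at line %d) in %s",
                 names(set)[bad], line_no, path))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a protein FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

new_variant_table <- function(df, source_kind = "rna_seq") {
  needed <- c("chrom", "pos", "ref", "alt",
              "ref_count", "alt_count", "mapping_quality")
  for (col in setdiff(needed, names(df))) df[[col]] <- NA_real_
  df$pos <- as.integer(df$pos)
  df$chrom <- as.character(df$chrom)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  if (any(df$pos < 1L, na.rm = TRUE)) stop("variant positions must be >= 1")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  # collapse duplicate (chrom, pos, alt) keys keeping the deepest record
  key <- paste(df$chrom, df$pos, df$alt, sep = "\r")
  if (anyDuplicated(key)) {
    depth <- ifelse(is.na(df$ref_count), 0, df$ref_count) +
      ifelse(is.na(df$alt_count), 0, df$alt_count)
    df <- df[order(key, -depth), , drop = FALSE]
    df <- df[!duplicated(paste(df$chrom, df$pos, df$alt, sep = "\r")), ,
             drop = FALSE]
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("saavx_variants", "data.frame"),
            source_kind = source_kind)
}

#' Read a table of single nucleotide variants
#'
#' Two dialects are supported. The `tsv` dialect is the pipeline's
#' canonical interchange format: columns `chrom`, `pos` (1-based), `ref`,
#' `alt` and optionally `ref_count`, `alt_count`, `mapping_quality`,
#' `filter_status`; a headerless file is read positionally in that order.
#' The `vcf` dialect reads a VCF via [vcfR::read.vcfR()], keeps only
#' single-nucleotide ref/alt records and, when the FILTER column is
#' populated, only PASS rows; per-sample allele depths (`AD`) and the
#' `MQ`/`DP4` INFO keys supply allele counts and mapping quality when
#' present.
#'
#' Records are validated (1-based positions, ref != alt), duplicate
#' `(chrom, pos, alt)` keys are collapsed keeping the deepest record, and
#' the result is sorted by `(chrom, pos)`.
#'
#' @param path Path to the variant file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param source_kind Provenance label, `"rna_seq"` or `"wgs"`.
#' @return A `saavx_variants` data frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `ref_count`, `alt_count`, `mapping_quality`.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               source_kind = c("rna_seq", "wgs")) {
  dialect <- match.arg(dialect)
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (dialect == "tsv") {
    first <- readLines(path, n = 1L)
    has_header <- grepl("chrom", first, ignore.case = TRUE)
    df <- utils::read.table(path, header = has_header, sep = "",
                            stringsAsFactors = FALSE, fill = TRUE,
                            colClasses = "character")
    if (!has_header) {
      cols <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count",
                "mapping_quality", "filter_status")
      names(df) <- cols[seq_len(ncol(df))]
    }
    names(df) <- tolower(names(df))
    for (col in c("chrom", "pos", "ref", "alt")) {
      if (!col %in% names(df)) stop("missing required column: ", col)
    }
    pos <- suppressWarnings(as.numeric(df$pos))
    if (anyNA(pos)) {
      stop("non-numeric pos at data row ", which(is.na(pos))[1])
    }
    df$pos <- pos
    if (any(grepl(",", df$alt))) {
      stop("multi-allelic rows must be split into one row per alternate ",
           "allele (found ',' in alt)")
    }
    if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L)) {
      stop("tsv dialect accepts single-nucleotide ref/alt only")
    }
    for (col in c("ref_count", "alt_count", "mapping_quality")) {
      if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
    }
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    names(fix) <- tolower(names(fix))
    if (any(grepl(",", fix$alt))) {
      stop("multi-allelic VCF rows must be split before reading")
    }
    keep <- nchar(fix$ref) == 1L & nchar(fix$alt) == 1L
    if ("filter" %in% names(fix)) {
      filt <- fix$filter
      keep <- keep & (is.na(filt) | filt %in% c("PASS", "."))
    }
    df <- data.frame(chrom = fix$chrom, pos = as.numeric(fix$pos),
                     ref = fix$ref, alt = fix$alt,
                     stringsAsFactors = FALSE)
    df$mapping_quality <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = "MQ")))
    df$ref_count <- NA_real_
    df$alt_count <- NA_real_
    gt <- vcf@gt
    if (!is.null(gt) && ncol(gt) >= 2L) {
      ad <- suppressWarnings(vcfR::extract.gt(vcf, element = "AD"))
      if (!all(is.na(ad))) {
        parts <- strsplit(ad[, 1L], ",", fixed = TRUE)
        df$ref_count <- vapply(parts, function(p)
          suppressWarnings(as.numeric(p[1])), numeric(1))
        df$alt_count <- vapply(parts, function(p)
          suppressWarnings(as.numeric(p[2])), numeric(1))
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  new_variant_table(df, source_kind = source_kind)
}

#' Write a variant table in the canonical tab-separated dialect
#'
#' @param table A `saavx_variants` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read exon intervals from a BED file
#'
#' Imports a BED file via [rtracklayer::import()] and returns intervals in
#' the BED convention: 0-based half-open `(start, end]` when mapped to
#' 1-based positions, i.e. a 1-based position `p` overlaps an interval iff
#' `start < p <= end`.
#'
#' @param path Path to a BED file (3+ columns).
#' @return A data frame with columns `chrom`, `start` (0-based), `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop(sprintf("BED interval with start >= end at record %d (%s:%d-%d)",
                 bad, df$chrom[bad], df$start[bad], df$end[bad]))
  }
  df
}

saav_fasta_header <- function(peptides) {
  change <- ifelse(
    peptides$effect == "stop_gain",
    paste0("p.", peptides$ref_aa, peptides$protein_position, "*"),
    paste0("p.", peptides$ref_aa, peptides$protein_position,
           peptides$alt_aa)
  )
  sprintf("saav|%s|%s|%s|mc%d.%d|%s",
          peptides$protein_id,
          ifelse(is.na(peptides$gene) | peptides$gene == "",
                 "NA", peptides$gene),
          change, peptides$missed_n, peptides$missed_c, peptides$effect)
}

#' Write variant peptides as a FASTA search database
#'
#' One record per peptide. Headers follow a stable pipe-delimited scheme,
#' `saav|<protein>|<gene>|p.<ref><pos><alt>|mc<n>.<c>|<effect>`, with a
#' numeric suffix appended on collision so headers stay unique.
#'
#' @param peptides A variant peptide table from
#'   [enumerate_saav_peptides()] or [build_saav_database()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_saav_fasta <- function(peptides, path) {
  if (NROW(peptides) == 0L) stop("no peptides to write")
  headers <- saav_fasta_header(peptides)
  if (anyDuplicated(headers)) {
    headers <- make.unique(headers, sep = "|")
  }
  if (anyDuplicated(headers)) stop("internal error: duplicate FASTA headers")
  seqs <- peptides$sequence
  names(seqs) <- headers
  write_fasta(seqs, path)
}
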