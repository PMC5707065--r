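# Brute-force oracles, independent of the package's digestion code paths.

# all tryptic boundary positions of a sequence (0 and nchar included),
# by direct rule application
brute_boundaries <- function(seq) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(res)
  cuts <- integer(0)
  for (i in seq_len(n)) {
    if (res[i] %in% c("K", "R") && (i == n || res[i + 1] != "P")) {
      cuts <- c(cuts, i)
    }
  }
  sort(unique(c(0L, cuts, n)))
}

# every substring with tryptic boundaries and <= max_missed internal cuts
brute_digest <- function(seq, max_missed, bounds = c(1L, 10000L)) {
  b <- brute_boundaries(seq)
  out <- NULL
  for (i in seq_along(b)) {
    for (j in seq_along(b)) {
      if (j <= i) next
      missed <- j - i - 1L
      if (missed > max_missed) next
      len <- b[j] - b[i]
      if (len < bounds[1] || len > bounds[2]) next
      out <- rbind(out, data.frame(
        sequence = substr(seq, b[i] + 1L, b[j]),
        start = b[i] + 1L, end = b[j], missed = missed))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# every tryptic substring containing position p with <= max_side missed
# cleavages on each flank of p's segment (stop_gain: suffix peptides only)
brute_saav_peptides <- function(mutated, p, max_side, bounds,
                                truncation = FALSE) {
  b <- brute_boundaries(mutated)
  n <- nchar(mutated)
  if (truncation) p <- n
  out <- NULL
  for (i in seq_along(b)) {
    for (j in seq_along(b)) {
      if (j <= i) next
      start <- b[i] + 1L
      end <- b[j]
      if (p < start || p > end) next
      if (truncation && end != n) next
      internal <- b[b > b[i] & b < end]
      n_side <- sum(internal < p)
      c_side <- sum(internal >= p)
      if (n_side > max_side || c_side > max_side) next
      len <- end - start + 1L
      if (len < bounds[1] || len > bounds[2]) next
      out <- rbind(out, data.frame(
        sequence = substr(mutated, start, end),
        start = start, end = end,
        missed_n = n_side, missed_c = c_side))
    }
  }
  if (is.null(out)) return(out)
  out[order(out$start, out$end), , drop = FALSE]
}

# random protein-like sequence with cleavable residues
random_protein <- function(len, with_p = TRUE) {
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "Q", "R", "S", "T", "V", "W", "Y",
                if (with_p) "P")
  paste(sample(alphabet, len, replace = TRUE,
               prob = c(rep(1, 8), 2.2, rep(1, 4), 2.0, rep(1, 5),
                        if (with_p) 1.5)), collapse = "")
}

toy_cfg <- function(...) pipeline_config(...)
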