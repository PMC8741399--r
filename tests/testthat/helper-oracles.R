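# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own index code paths: rotation sorting, full suffix
# enumeration, and Biostrings pattern matching.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# BWT by materialising and sorting all cyclic rotations (C locale).
naive_bwt <- function(raw) {
  term <- paste0(raw, "$")
  n <- nchar(term)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(term, i, n), substr(term, 1, i - 1))
  }, "")
  rots <- sort(rots, method = "radix")
  paste(substr(rots, n, n), collapse = "")
}

# Suffix array by sorting the enumerated suffixes.
naive_suffix_array <- function(raw) {
  term <- paste0(raw, "$")
  n <- nchar(term)
  suf <- substring(term, seq_len(n), n)
  order(suf, method = "radix") - 1L
}

# All 0-based occurrence positions of a pattern, via Biostrings.
naive_positions <- function(text, pattern) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::BString(text))
  sort(BiocGenerics::start(hits)) - 1L
}

make_call <- function(pos, ref = "A", alt = "T", qual = 50, depth = 40,
                      chrom = "chr1", caller = "x") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             depth = depth, caller = caller, stringsAsFactors = FALSE)
}
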