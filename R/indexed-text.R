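# DNA alphabet used throughout; every ordering in the package is $ < A < C < G < T.
BASES <- c("A", "C", "G", "T")
ALPHABET <- c("$", BASES)

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Terminated DNA text
#'
#' Wraps an uppercase DNA string over \{A,C,G,T\} together with its
#' terminator-appended form. The terminator `$` sorts before every base; all
#' index structures in the package ([bwt_transform()], [build_suffix_array()],
#' [build_fm_index()], [build_suffix_tree()]) operate on the terminated text.
#'
#' @param x A single character string over \{A,C,G,T\}, optionally already
#'   ending in `$`. Lowercase input is uppercased. IUPAC ambiguity codes
#'   (including `N`) are rejected.
#'
#' @return An object of class `indexed_text`: a list with elements `raw`
#'   (the bases), `terminated` (`raw` plus `$`) and `n` (number of bases, so
#'   the terminated length is `n + 1`).
#'
#' @examples
#' tx <- indexed_text("ACGTACAAAT")
#' tx$terminated
#' @export
indexed_text <- function(x) {
  if (inherits(x, "indexed_text")) {
    return(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("'x' must be a single character string")
  }
  x <- toupper(x)
  if (endsWith(x, "$")) {
    x <- substr(x, 1L, nchar(x) - 1L)
  }
  if (nchar(x) == 0L) {
    stop("invalid alphabet: text must contain at least one base")
  }
  bad <- regmatches(x, regexpr("[^ACGT]", x))
  if (length(bad) > 0L) {
    stop("invalid alphabet: text may contain only A/C/G/T (found '", bad,
         "'); the terminator '$' is allowed only at the end")
  }
  structure(
    list(raw = x, terminated = paste0(x, "$"), n = nchar(x)),
    class = "indexed_text"
  )
}

#' @export
print.indexed_text <- function(x, ...) {
  s <- if (x$n > 60L) paste0(substr(x$raw, 1L, 57L), "...") else x$raw
  cat("<indexed_text> ", s, "$  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain named
#' character strings, the form the index builders and simulators consume.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences, or a
#'   [reference_genome][generate_reference()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "reference_genome")) {
    sequences <- stats::setNames(sequences$sequence, sequences$seq_id)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All simulators route their randomness through this so that every generator is
# a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
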