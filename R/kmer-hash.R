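# Base-4 k-mer hash index with 1-based positions.
#
# Encoding: the first character of a k-mer is the most significant base-4
# digit (A=0, C=1, G=2, T=3), so for k = 2: AA=0, AC=1, ..., TA=12, TT=15.
# Positions here are 1-based; the FM-index side of the package is 0-based, and
# conversions between the two are always explicit (+1 at the boundary).

#' Encode a k-mer as a base-4 integer
#'
#' Maps A, C, G, T to the digits 0-3 and reads the k-mer as a base-4 number
#' with the first character most significant.
#'
#' @param kmer String of length `k` over \{A,C,G,T\}.
#' @param k Expected k-mer length; defaults to `nchar(kmer)`.
#' @return Numeric code in `[0, 4^k)`. Exact for `k <= 26` (double precision).
#' @examples
#' encode_kmer("TA") # 12
#' encode_kmer("GT") # 11
#' @export
encode_kmer <- function(kmer, k = nchar(kmer)) {
  if (!is.character(kmer) || length(kmer) != 1L || is.na(kmer)) {
    stop("invalid k-mer: expected a single string")
  }
  kmer <- toupper(kmer)
  if (nchar(kmer) != k) {
    stop("invalid k-mer: length ", nchar(kmer), " does not match k = ", k)
  }
  d <- match(.chars(kmer), BASES) - 1L
  if (anyNA(d)) {
    stop("invalid k-mer: characters outside {A,C,G,T}")
  }
  sum(d * 4^((k - 1L):0L))
}

# Base-4 codes of all overlapping k-mers of a character string.
# Returns a numeric vector of length L - k + 1 (NA where the window contains a
# non-ACGT character). Uses a one-sided convolution so the whole sequence is
# encoded in one vectorised pass.
.kmer_codes <- function(seq, k) {
  d <- match(.chars(toupper(seq)), BASES) - 1L
  L <- length(d)
  filt <- stats::filter(d, 4^(0:(k - 1L)), method = "convolution", sides = 1L)
  as.numeric(filt[k:L])
}

#' Build a k-mer hash index of one or more sequences
#'
#' Enumerates every overlapping k-mer ("seed") of every input sequence and
#' records it in a postings table keyed by the seed's base-4 code, with
#' 1-based (sequence id, start position) entries. A sequence of length `L`
#' contributes exactly `L - k + 1` postings; seeds containing non-ACGT
#' characters are skipped with a warning rather than failing the build.
#'
#' @param sequences Character vector of sequences (a `DNAStringSet` is
#'   accepted), or a single string. Sequence ids are `1, 2, ...` in input
#'   order.
#' @param k Seed length (>= 1). The classical choices are 4 or 8; small
#'   values suit the worked examples, larger values real references.
#' @return An object of class `hash_index`: list with `k`, `postings` (named
#'   list, one data frame of `seq_id`/`pos` per seed code, ordered by seq_id
#'   then pos), `n_sequences`, `n_postings` and `min_count_applied` (`NULL`
#'   until [prune_low_frequency()] is applied).
#' @examples
#' idx <- build_hash_index("ACGTACAAAT", k = 2)
#' idx$postings[["12"]] # seed TA at (1, 4)
#' @export
build_hash_index <- function(sequences, k) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k != round(k)) {
    stop("'k' must be a positive integer")
  }
  k <- as.integer(k)
  parts <- vector("list", length(sequences))
  n_skipped <- 0L
  for (i in seq_along(sequences)) {
    L <- nchar(sequences[[i]])
    if (L < k) {
      stop("sequence ", i, " is shorter than k (length ", L, " < ", k, ")")
    }
    codes <- .kmer_codes(sequences[[i]], k)
    keep <- !is.na(codes)
    n_skipped <- n_skipped + sum(!keep)
    parts[[i]] <- data.frame(code = codes[keep], seq_id = i,
                             pos = which(keep))
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " seed(s) containing non-ACGT characters were skipped")
  }
  all <- do.call(rbind, parts)
  all <- all[order(all$seq_id, all$pos), , drop = FALSE]
  postings <- lapply(
    split(seq_len(nrow(all)), all$code),
    function(rows) {
      df <- all[rows, c("seq_id", "pos"), drop = FALSE]
      rownames(df) <- NULL
      df
    }
  )
  structure(
    list(k = k, postings = postings, n_sequences = length(sequences),
         n_postings = nrow(all), min_count_applied = NULL),
    class = "hash_index"
  )
}

#' @export
print.hash_index <- function(x, ...) {
  cat("<hash_index> k = ", x$k, ", ", length(x$postings),
      " distinct seed(s), ", x$n_postings, " posting(s) over ",
      x$n_sequences, " sequence(s)", sep = "")
  if (!is.null(x$min_count_applied)) {
    cat("  [pruned at min_count = ", x$min_count_applied, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Drop low-frequency seeds from a hash index
#'
#' Removes every seed whose posting list is shorter than `min_count`, the
#' standard pruning step that discards seeds too rare to anchor alignments.
#'
#' @param index A `hash_index`.
#' @param min_count Minimum posting-list length to retain (>= 1);
#'   `min_count = 1` is the identity.
#' @return The pruned `hash_index`, with `min_count_applied` recorded.
#' @export
prune_low_frequency <- function(index, min_count) {
  stopifnot(inherits(index, "hash_index"))
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 1L) {
    stop("'min_count' must be a single integer >= 1")
  }
  counts <- vapply(index$postings, nrow, integer(1))
  index$postings <- index$postings[counts >= min_count]
  index$n_postings <- sum(counts[counts >= min_count])
  index$min_count_applied <- as.integer(min_count)
  index
}

.postings_for <- function(index, code) {
  p <- index$postings[[as.character(code)]]
  if (is.null(p)) {
    data.frame(seq_id = integer(0), pos = integer(0))
  } else {
    p
  }
}

#' Query a pattern against a hash index by seed decomposition
#'
#' Decomposes the pattern into its `nchar(pattern) - k + 1` overlapping
#' seeds, looks each up in the postings table, and joins positions: a start
#' `p` in sequence `s` is reported iff for every seed offset `j` the posting
#' `(s, p + j)` exists for that seed's code. On an unpruned index this is an
#' exact-match query (equivalent to FM-index [locate()], shifted to 1-based
#' coordinates); on a pruned index hits anchored only by deleted seeds are
#' lost, which is the intended trade-off.
#'
#' @param index A `hash_index`.
#' @param pattern String over \{A,C,G,T\} of length >= `k`.
#' @return Data frame with columns `seq_id` and `pos` (1-based start),
#'   ordered by `(seq_id, pos)`; zero rows when the pattern does not occur.
#' @examples
#' idx <- build_hash_index("ACGTACAAAT", k = 2)
#' query_pattern(idx, "TAC") # seq_id 1, pos 4
#' @export
query_pattern <- function(index, pattern) {
  stopifnot(inherits(index, "hash_index"))
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("invalid query: expected a single string")
  }
  pattern <- toupper(pattern)
  k <- index$k
  L <- nchar(pattern)
  if (L < k) {
    stop("invalid query: pattern length ", L, " is shorter than k = ", k)
  }
  m <- L - k + 1L
  codes <- vapply(seq_len(m),
                  function(j) encode_kmer(substr(pattern, j, j + k - 1L), k),
                  numeric(1))
  cand <- .postings_for(index, codes[1L])
  cand <- data.frame(seq_id = cand$seq_id, start = cand$pos)
  for (j in seq_len(m)[-1L]) {
    if (nrow(cand) == 0L) {
      break
    }
    pj <- .postings_for(index, codes[j])
    pj <- data.frame(seq_id = pj$seq_id, start = pj$pos - (j - 1L))
    cand <- merge(cand, pj, by = c("seq_id", "start"))
  }
  out <- data.frame(seq_id = cand$seq_id, pos = cand$start)
  out <- out[order(out$seq_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
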