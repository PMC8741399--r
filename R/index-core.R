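# Burrows-Wheeler transform, suffix array/tree, FM-index and backward search.
#
# Conventions (used consistently across the package):
#   * ordering $ < A < C < G < T;
#   * suffix-array and FM-index positions are 0-based;
#   * occ(c, i) counts occurrences of c in bwt[0 .. i-1], i.e. in the length-i
#     prefix of the BWT string, so occ(c, 0) = 0 always.

#' Suffix array of a terminated DNA text
#'
#' Sorts all suffixes of the terminated text (the bases plus the final `$`)
#' lexicographically under `$ < A < C < G < T` and returns their 0-based start
#' positions. Construction is a direct suffix sort (radix order on the suffix
#' strings), adequate for desk-scale texts; the contract permits swapping in a
#' linear-time builder without API change.
#'
#' @param text An [indexed_text()] or a string coercible to one.
#' @return Integer vector of length `n + 1`, a permutation of `0:n`.
#' @examples
#' build_suffix_array("ACGTACAAAT")
#' @export
build_suffix_array <- function(text) {
  tx <- indexed_text(text)
  N <- tx$n + 1L
  suffixes <- substring(tx$terminated, seq_len(N), N)
  # method = "radix" sorts in the C locale, where "$" (0x24) < "A" < "C" < "G" < "T"
  order(suffixes, method = "radix") - 1L
}

#' Burrows-Wheeler transform
#'
#' Returns the last column of the lexicographically sorted cyclic-rotation
#' matrix of the terminated text. Computed through the suffix array
#' (`bwt[i] = terminated[(sa[i] - 1) mod (n + 1)]`); the rotation matrix is
#' never materialised.
#'
#' @param text An [indexed_text()] or a string coercible to one.
#' @return A single string of length `n + 1` over `{$,A,C,G,T}`, a permutation
#'   of the terminated text containing exactly one `$`.
#' @examples
#' bwt_transform("ACGTACAAAT") # "TCAT$AAACAG"
#' @seealso [bwt_inverse()]
#' @export
bwt_transform <- function(text) {
  tx <- indexed_text(text)
  sa <- build_suffix_array(tx)
  ch <- .chars(tx$terminated)
  paste(ch[((sa - 1L) %% (tx$n + 1L)) + 1L], collapse = "")
}

# Count array and occurrence table for a BWT character vector.
# Returns list(oc, occ) where oc[c] is the number of characters strictly
# smaller than c (equivalently the first row of c in the sorted first column)
# and occ is an (N+1) x 5 matrix with occ[i + 1, c] = count of c in ch[1..i],
# i.e. occ(c, i) in the 0-based prefix convention.
.bwt_tables <- function(ch) {
  N <- length(ch)
  ind <- vapply(ALPHABET, function(a) cumsum(ch == a), numeric(N))
  occ <- rbind(0, ind)
  dimnames(occ) <- list(NULL, ALPHABET)
  totals <- occ[N + 1L, ]
  oc <- stats::setNames(cumsum(c(0, totals[-length(totals)])), ALPHABET)
  list(oc = oc, occ = occ)
}

.check_bwt <- function(bwt) {
  if (!is.character(bwt) || length(bwt) != 1L || is.na(bwt) || nchar(bwt) == 0L) {
    stop("malformed BWT: expected a single non-empty string")
  }
  ch <- .chars(toupper(bwt))
  n_term <- sum(ch == "$")
  if (n_term != 1L) {
    stop("malformed BWT: expected exactly one '$' terminator, found ", n_term)
  }
  if (!all(ch %in% ALPHABET)) {
    stop("malformed BWT: characters outside {$,A,C,G,T}")
  }
  ch
}

#' Invert a Burrows-Wheeler transform
#'
#' Recovers the unique terminated text whose BWT equals the input, by the
#' standard last-to-first (LF) column walk: starting from the row of the sorted
#' rotation matrix that begins with `$`, each LF step yields the preceding
#' character of the text.
#'
#' @param bwt A BWT string containing exactly one `$`.
#' @return The terminated text as a single string ending in `$`.
#' @examples
#' bwt_inverse("TCAT$AAACAG") # "ACGTACAAAT$"
#' @export
bwt_inverse <- function(bwt) {
  ch <- .check_bwt(bwt)
  N <- length(ch)
  tabs <- .bwt_tables(ch)
  col <- match(ch, ALPHABET)
  # lf[r] (1-based row r = 0-based i + 1): oc(L[i]) + occ(L[i], i)
  lf <- tabs$oc[col] + tabs$occ[cbind(seq_len(N), col)]
  out <- character(N - 1L)
  i <- 0L
  for (k in seq_len(N - 1L)) {
    out[k] <- ch[i + 1L]
    i <- as.integer(lf[i + 1L])
  }
  paste0(paste(rev(out), collapse = ""), "$")
}

#' FM-index of a terminated DNA text
#'
#' Builds the full-text index consisting of the BWT, the smaller-symbol count
#' array `oc` (first row of each character in the sorted first column), the
#' occurrence table `occ(c, i)` = count of `c` in `bwt[0..i-1]`, and the suffix
#' array. Supports exact right-to-left pattern matching via
#' [backward_search()] and position recovery via [locate()].
#'
#' @param text An [indexed_text()] or a string coercible to one.
#' @return An object of class `fm_index` with elements `bwt` (string), `oc`
#'   (named numeric, `$`/A/C/G/T), `occ` (matrix, row `i + 1` holds
#'   `occ(., i)`), `sa` (0-based suffix array), `n` and `text`.
#' @examples
#' fm <- build_fm_index("ACGTACAAAT")
#' fm$oc # $=0 A=1 C=6 G=8 T=9
#' @export
build_fm_index <- function(text) {
  tx <- indexed_text(text)
  sa <- build_suffix_array(tx)
  ch <- .chars(tx$terminated)
  bwt_ch <- ch[((sa - 1L) %% (tx$n + 1L)) + 1L]
  tabs <- .bwt_tables(bwt_ch)
  structure(
    list(bwt = paste(bwt_ch, collapse = ""), oc = tabs$oc, occ = tabs$occ,
         sa = sa, n = tx$n, text = tx),
    class = "fm_index"
  )
}

#' @export
print.fm_index <- function(x, ...) {
  cat("<fm_index> text length", x$n, "+ terminator\n")
  cat("  bwt:", if (nchar(x$bwt) > 60L) paste0(substr(x$bwt, 1L, 57L), "...") else x$bwt, "\n")
  cat("  oc :", paste(names(x$oc), x$oc, sep = "=", collapse = " "), "\n")
  invisible(x)
}

.match_interval <- function(lo, hi) {
  structure(list(lo = as.integer(lo), hi = as.integer(hi), empty = FALSE),
            class = "match_interval")
}

.empty_interval <- function() {
  structure(list(lo = NA_integer_, hi = NA_integer_, empty = TRUE),
            class = "match_interval")
}

#' Size of a backward-search match interval
#'
#' @param interval A `match_interval` from [backward_search()].
#' @return `hi - lo + 1`, the exact occurrence count of the pattern; 0 for an
#'   empty interval.
#' @export
interval_size <- function(interval) {
  stopifnot(inherits(interval, "match_interval"))
  if (interval$empty) 0L else interval$hi - interval$lo + 1L
}

#' @export
print.match_interval <- function(x, ...) {
  if (x$empty) {
    cat("<match_interval> empty (0 occurrences)\n")
  } else {
    cat("<match_interval> rows [", x$lo, ", ", x$hi, "]  (",
        interval_size(x), " occurrence(s))\n", sep = "")
  }
  invisible(x)
}

#' FM-index backward search
#'
#' Matches a pattern right-to-left against the index. Starting from the full
#' row range `lo = 0, hi = n`, each character `c` updates
#' `lo' = oc(c) + occ(c, lo)` and `hi' = oc(c) + occ(c, hi + 1) - 1`; the
#' search stops with an empty interval as soon as `lo' > hi'`. The final
#' interval's size equals the exact number of occurrences of the pattern in
#' the text.
#'
#' @param fm An `fm_index` from [build_fm_index()].
#' @param pattern Non-empty string over \{A,C,G,T\}.
#' @return A `match_interval` with 0-based row bounds `lo`, `hi` (inclusive),
#'   or an empty interval.
#' @examples
#' fm <- build_fm_index("ACGTACAAAT")
#' backward_search(fm, "TAC") # rows [10, 10], one occurrence
#' @export
backward_search <- function(fm, pattern) {
  stopifnot(inherits(fm, "fm_index"))
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      nchar(pattern) == 0L) {
    stop("invalid pattern: expected a single non-empty string")
  }
  pattern <- toupper(pattern)
  pc <- .chars(pattern)
  if (!all(pc %in% BASES)) {
    stop("invalid pattern: characters outside {A,C,G,T}")
  }
  lo <- 0L
  hi <- fm$n
  for (c in rev(pc)) {
    lo2 <- fm$oc[[c]] + fm$occ[lo + 1L, c]
    hi2 <- fm$oc[[c]] + fm$occ[hi + 2L, c] - 1
    if (lo2 > hi2) {
      return(.empty_interval())
    }
    lo <- as.integer(lo2)
    hi <- as.integer(hi2)
  }
  .match_interval(lo, hi)
}

#' Locate pattern occurrences from a match interval
#'
#' Translates a [backward_search()] interval into text coordinates by reading
#' the suffix array over the interval's rows.
#'
#' @param fm The `fm_index` the interval came from.
#' @param interval A `match_interval`.
#' @return Sorted integer vector of 0-based start positions in the raw text;
#'   `integer(0)` for an empty interval.
#' @examples
#' fm <- build_fm_index("ACGTACAAAT")
#' locate(fm, backward_search(fm, "AC")) # 0 4
#' @export
locate <- function(fm, interval) {
  stopifnot(inherits(fm, "fm_index"), inherits(interval, "match_interval"))
  if (interval$empty) {
    return(integer(0))
  }
  if (interval$lo < 0L || interval$hi > fm$n || interval$lo > interval$hi) {
    stop("interval out of bounds: rows must lie in [0, ", fm$n, "]")
  }
  sort(fm$sa[(interval$lo:interval$hi) + 1L])
}

#' Count pattern occurrences with an FM-index
#'
#' Convenience wrapper: `interval_size(backward_search(fm, pattern))`.
#'
#' @inheritParams backward_search
#' @return Non-negative integer occurrence count.
#' @export
count_occurrences <- function(fm, pattern) {
  interval_size(backward_search(fm, pattern))
}
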