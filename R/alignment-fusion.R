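# Consensus fusion of alignment record sets from multiple aligners.
#
# The consensus key is exact equality of (read_id, seq_id, pos); MAPQ and
# CIGAR play no part in voting. With n sources the rule table is:
#   votes = n     -> ACCEPT_ALL      (every aligner agrees)
#   votes = n - 1 -> ACCEPT_MAJORITY (optionally gated on MAPQ)
#   votes = n - 2 -> ACCEPT_PANEL    if the read sequence occurs in a trusted
#                                    ("PCR") panel sequence, else REJECT
#   otherwise     -> REJECT

#' Read alignment records from SAM or TSV
#'
#' SAM files are converted with [Rsamtools::asBam()] and scanned for the
#' mandatory fields; the simplified tab-separated form has a header line with
#' columns `read_id`, `seq_id`, `pos`, `mapq` (and optionally `source`).
#'
#' @param path Path to a `.sam` file or a `.tsv`/`.txt` table.
#' @param source Aligner label to attach (overrides any `source` column).
#' @param format `"auto"` (by extension), `"sam"` or `"tsv"`.
#' @return Data frame with `read_id`, `seq_id`, `pos` (1-based leftmost),
#'   `mapq`, `source`; unmapped records are dropped.
#' @export
read_alignments <- function(path, source, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
    res <- Rsamtools::scanBam(
      bam,
      param = Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "mapq"))
    )[[1L]]
    out <- data.frame(read_id = res$qname,
                      seq_id = as.character(res$rname),
                      pos = res$pos, mapq = res$mapq,
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$pos), , drop = FALSE]
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "seq_id", "pos")
    if (!all(need %in% names(out))) {
      stop("TSV alignment table must have columns ",
           paste(need, collapse = ", "))
    }
    if (!"mapq" %in% names(out)) {
      out$mapq <- NA_integer_
    }
  }
  if (!missing(source)) {
    out$source <- source
  } else if (!"source" %in% names(out)) {
    stop("no 'source' column and no source label supplied")
  }
  rownames(out) <- NULL
  out[c("read_id", "seq_id", "pos", "mapq", "source")]
}

.bind_records <- function(records) {
  if (is.data.frame(records)) {
    return(records)
  }
  if (!is.null(names(records))) {
    records <- Map(function(df, nm) {
      if (!"source" %in% names(df)) df$source <- nm
      df
    }, records, names(records))
  }
  do.call(rbind, unname(records))
}

#' Per-placement vote table across aligners
#'
#' Counts, for every distinct placement `(read_id, seq_id, pos)`, how many
#' distinct sources reported it. Multi-mapping is allowed: each distinct
#' placement of a read is its own key. Duplicate reports of the same
#' placement by one source count once.
#'
#' @param records A data frame of alignment records with a `source` column,
#'   or a (named) list of per-source data frames.
#' @return Data frame with `read_id`, `seq_id`, `pos`, `votes`, `sources`
#'   (comma-joined, sorted) and `mapq_max`, ordered by votes descending then
#'   key.
#' @export
sort_and_count <- function(records) {
  rec <- .bind_records(records)
  if (length(unique(rec$source)) < 2L) {
    stop("at least two sources are required")
  }
  if (!"mapq" %in% names(rec)) {
    rec$mapq <- NA_integer_
  }
  rec <- rec[!duplicated(rec[c("read_id", "seq_id", "pos", "source")]), ,
             drop = FALSE]
  key <- paste(rec$read_id, rec$seq_id, rec$pos, sep = "\r")
  sp <- split(seq_len(nrow(rec)), key)
  first <- vapply(sp, `[[`, integer(1), 1L)
  out <- data.frame(
    read_id = rec$read_id[first],
    seq_id = rec$seq_id[first],
    pos = rec$pos[first],
    votes = vapply(sp, function(i) length(unique(rec$source[i])), integer(1)),
    sources = vapply(sp, function(i)
      paste(sort(unique(rec$source[i])), collapse = ","), character(1)),
    mapq_max = vapply(sp, function(i) {
      m <- rec$mapq[i]
      if (all(is.na(m))) NA_real_ else max(m, na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$votes, out$read_id, out$seq_id, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus verdicts from a vote table
#'
#' Applies the n / n-1 / n-2 voting rules. A placement supported by all
#' sources is `ACCEPT_ALL`; by all but one, `ACCEPT_MAJORITY` (optionally
#' requiring `mapq_max >= min_mapq` as the operationalisation of "frequency
#' of occurrence is quite high"); by all but two, `ACCEPT_PANEL` when the
#' read's sequence occurs as an exact substring of a trusted panel sequence,
#' otherwise `REJECT`; anything less is `REJECT`. Verdicts partition the
#' placements.
#'
#' @param vote_table Output of [sort_and_count()].
#' @param n_sources Number of aligners voting (default 4).
#' @param panel Character vector of trusted (e.g. PCR-validated) sequences,
#'   or a FASTA path. Required when any placement has `n_sources - 2` votes.
#' @param read_seqs Named character vector mapping `read_id` to the read
#'   sequence, needed for panel membership checks.
#' @param min_mapq Optional MAPQ gate on the `n - 1` rule; default off.
#' @return The vote table with a `verdict` column (one of `ACCEPT_ALL`,
#'   `ACCEPT_MAJORITY`, `ACCEPT_PANEL`, `REJECT`).
#' @export
consensus_vote <- function(vote_table, n_sources = 4L, panel = NULL,
                           read_seqs = NULL, min_mapq = NULL) {
  stopifnot(is.data.frame(vote_table), "votes" %in% names(vote_table))
  if (any(vote_table$votes > n_sources)) {
    stop("vote counts exceed 'n_sources'")
  }
  if (is.character(panel) && length(panel) == 1L && file.exists(panel)) {
    panel <- read_fasta(panel)
  }
  n_panel_rule <- sum(vote_table$votes == n_sources - 2L)
  if (n_panel_rule > 0L && is.null(panel)) {
    stop("configuration error: ", n_panel_rule, " placement(s) have ",
         n_sources - 2L, " votes but no reference panel was supplied")
  }
  verdict <- rep("REJECT", nrow(vote_table))
  verdict[vote_table$votes == n_sources] <- "ACCEPT_ALL"
  maj <- vote_table$votes == n_sources - 1L
  if (!is.null(min_mapq)) {
    maj <- maj & !is.na(vote_table$mapq_max) & vote_table$mapq_max >= min_mapq
  }
  verdict[maj] <- "ACCEPT_MAJORITY"
  for (i in which(vote_table$votes == n_sources - 2L)) {
    seq <- read_seqs[[vote_table$read_id[i]]]
    if (is.null(seq) || is.na(seq)) {
      next
    }
    in_panel <- any(vapply(panel, function(ps)
      grepl(seq, ps, fixed = TRUE), logical(1)))
    if (in_panel) {
      verdict[i] <- "ACCEPT_PANEL"
    }
  }
  vote_table$verdict <- verdict
  vote_table
}

# Counts of keys falling in each non-empty source subset (exact membership).
.subset_counts <- function(keysets) {
  sources <- names(keysets)
  keysets <- lapply(keysets, unique)
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  membership <- vapply(keysets, function(ks) all_keys %in% ks,
                       logical(length(all_keys)))
  if (length(all_keys) == 1L) {
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(NULL, sources))
  }
  pattern <- apply(membership, 1L, function(row)
    paste(sources[row], collapse = ","))
  subsets <- unlist(lapply(seq_along(sources), function(k)
    utils::combn(sources, k, paste, collapse = ",", simplify = FALSE)),
    use.names = FALSE)
  counts <- vapply(subsets, function(s) sum(pattern == s), integer(1))
  data.frame(
    sources = subsets,
    n_sources = lengths(strsplit(subsets, ",", fixed = TRUE)),
    count = counts,
    stringsAsFactors = FALSE
  )
}

#' Venn-style overlap counts across sources
#'
#' For every non-empty subset of sources, counts the placements present in
#' exactly that subset (so the counts over all subsets sum to the number of
#' distinct placements) - the per-tool "repeated quantity" comparison.
#'
#' @param records A data frame of alignment records with a `source` column,
#'   or a named list of per-source data frames.
#' @return Data frame with `sources` (comma-joined subset), `n_sources` and
#'   `count`.
#' @export
overlap_counts <- function(records) {
  rec <- .bind_records(records)
  srcs <- unique(rec$source)
  if (length(srcs) < 2L) {
    stop("at least two sources are required")
  }
  keysets <- lapply(stats::setNames(srcs, srcs), function(s) {
    sub <- rec[rec$source == s, , drop = FALSE]
    paste(sub$read_id, sub$seq_id, sub$pos, sep = "\r")
  })
  .subset_counts(keysets)
}

#' Venn-style overlap counts across variant call sets
#'
#' The call-set analogue of [overlap_counts()]: counts distinct variant keys
#' by the exact subset of callers reporting them.
#'
#' @param callsets Named list of call-set data frames (`chrom`, `pos`,
#'   `ref`, `alt`).
#' @return Data frame with `sources`, `n_sources`, `count`.
#' @export
callset_overlap <- function(callsets) {
  if (length(callsets) < 2L) {
    stop("at least two call sets are required")
  }
  if (is.null(names(callsets))) {
    names(callsets) <- paste0("caller", seq_along(callsets))
  }
  .subset_counts(lapply(callsets, .variant_keys))
}
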