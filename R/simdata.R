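# Synthetic-data generators: reference genomes, implanted SNP/indel truth
# sets, reads, read cleaning/QC, and simulated per-caller call sets. Every
# generator is a pure function of its parameters and an explicit integer seed.

#' Generate a random reference genome
#'
#' Draws i.i.d. bases with the G and C probabilities each set to
#' `gc_fraction / 2` and A and T sharing the remainder.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_fraction Target GC fraction, strictly in (0, 1). Default 0.49,
#'   typical of human tumour exome sequence.
#' @param seed Integer seed; the generator is deterministic given
#'   (`length`, `gc_fraction`, `seed`).
#' @param seq_id Sequence name, default `"chr1"`.
#' @return Object of class `reference_genome`: list with `seq_id`,
#'   `sequence`, `length`, `gc_fraction` (the target).
#' @export
generate_reference <- function(length, gc_fraction = 0.49, seed, seq_id = "chr1") {
  if (!is.numeric(length) || length < 1000L) {
    stop("'length' must be a single integer >= 1000")
  }
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stop("'gc_fraction' must lie strictly between 0 and 1")
  }
  length <- as.integer(length)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, paste(sample(BASES, length, replace = TRUE, prob = p),
                               collapse = ""))
  structure(
    list(seq_id = seq_id, sequence = seq, length = length,
         gc_fraction = gc_fraction),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  gc <- gc_content(x$sequence)
  cat("<reference_genome> ", x$seq_id, ": ", x$length, " bp, GC ",
      round(100 * gc, 2), "% (target ", round(100 * x$gc_fraction, 2),
      "%)\n", sep = "")
  invisible(x)
}

#' GC fraction of a sequence
#'
#' @param seq A DNA string, or a `reference_genome`.
#' @return Fraction of G + C bases.
#' @export
gc_content <- function(seq) {
  if (inherits(seq, "reference_genome")) {
    seq <- seq$sequence
  }
  ch <- .chars(toupper(seq))
  mean(ch %in% c("G", "C"))
}

.genome_sequence <- function(genome) {
  if (inherits(genome, "reference_genome")) genome$sequence else as.character(genome)
}

.genome_id <- function(genome) {
  if (inherits(genome, "reference_genome")) genome$seq_id else "chr1"
}

#' Implant SNPs and short indels into a reference
#'
#' Places `n_snp` single-nucleotide variants and `n_indel` indels (insertions
#' and deletions of 2-10 bp, split about 50/50) at non-overlapping positions
#' with a minimum spacing of `min_spacing` bp, and returns both the mutated
#' sequence and the truth set. All variants are represented VCF-style with a
#' 1-based anchored position: a deletion's `ref` spans the deleted bases plus
#' the anchor, an insertion's `alt` is the anchor plus the inserted bases.
#' Implanted variants are homozygous in the simulated sample (zygosity is not
#' modelled).
#'
#' @param ref A `reference_genome` or DNA string.
#' @param n_snp,n_indel Numbers of SNVs and indels to implant.
#' @param seed Integer seed.
#' @param min_spacing Minimum distance between consecutive variant anchors
#'   (default 12 bp, enough that a 10 bp deletion never reaches the next
#'   variant).
#' @return List with `sequence` (the mutated genome string), `truth` (data
#'   frame `chrom`, `pos`, `ref`, `alt`, `kind` in \{SNP, INS, DEL\}, sorted
#'   by position) and `ref` (the input genome string).
#' @seealso [apply_variants()] for the reference patcher used as the
#'   round-trip oracle.
#' @export
implant_variants <- function(ref, n_snp, n_indel, seed, min_spacing = 12L) {
  seq <- .genome_sequence(ref)
  chrom <- .genome_id(ref)
  L <- nchar(seq)
  n_tot <- as.integer(n_snp + n_indel)
  if (n_tot == 0L) {
    truth <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        kind = character(0))
    return(list(sequence = seq, truth = truth, ref = seq))
  }
  # positions start at 2 (so deletions keep a left anchor inside the sequence)
  # and end 11 bp before the end (room for the longest deletion)
  slack <- L - 12L - n_tot * min_spacing
  if (slack < n_tot) {
    stop("capacity error: cannot place ", n_tot, " variants with spacing ",
         min_spacing, " in a ", L, " bp sequence")
  }
  res <- with_seed(seed, {
    pos <- sort(sample.int(slack, n_tot)) +
      (seq_len(n_tot) - 1L) * as.integer(min_spacing) + 1L
    n_ins <- ceiling(n_indel / 2)
    n_del <- n_indel - n_ins
    kind <- sample(c(rep("SNP", n_snp), rep("INS", n_ins), rep("DEL", n_del)))
    ref_al <- character(n_tot)
    alt_al <- character(n_tot)
    for (i in seq_len(n_tot)) {
      base <- substr(seq, pos[i], pos[i])
      if (kind[i] == "SNP") {
        ref_al[i] <- base
        alt_al[i] <- sample(setdiff(BASES, base), 1L)
      } else if (kind[i] == "INS") {
        len <- sample(2:10, 1L)
        ref_al[i] <- base
        alt_al[i] <- paste0(base, paste(sample(BASES, len, replace = TRUE),
                                        collapse = ""))
      } else {
        len <- sample(2:10, 1L)
        ref_al[i] <- substr(seq, pos[i], pos[i] + len)
        alt_al[i] <- base
      }
    }
    data.frame(chrom = chrom, pos = pos, ref = ref_al, alt = alt_al,
               kind = kind, stringsAsFactors = FALSE)
  })
  list(sequence = apply_variants(seq, res), truth = res, ref = seq)
}

#' Apply a variant table to a reference sequence
#'
#' Patches a reference with a set of non-overlapping, position-sorted
#' VCF-style variants (each record's `ref` replaced by its `alt`). Serves as
#' the independent round-trip oracle for [implant_variants()].
#'
#' @param ref A `reference_genome` or DNA string.
#' @param truth Data frame with `pos`, `ref`, `alt` (1-based, sorted,
#'   non-overlapping).
#' @return The mutated sequence as a single string.
#' @export
apply_variants <- function(ref, truth) {
  seq <- .genome_sequence(ref)
  if (nrow(truth) == 0L) {
    return(seq)
  }
  truth <- truth[order(truth$pos), , drop = FALSE]
  ends <- truth$pos + nchar(truth$ref) - 1L
  if (any(truth$pos[-1L] <= ends[-nrow(truth)])) {
    stop("variants overlap; cannot apply")
  }
  mism <- substring(seq, truth$pos, ends) != truth$ref
  if (any(mism)) {
    stop("ref allele mismatch at position ", truth$pos[which(mism)[1L]])
  }
  gaps <- substring(seq, c(1L, ends + 1L), c(truth$pos - 1L, nchar(seq)))
  pieces <- character(2L * nrow(truth) + 1L)
  pieces[seq(1L, by = 2L, length.out = nrow(truth) + 1L)] <- gaps
  pieces[seq(2L, by = 2L, length.out = nrow(truth))] <- truth$alt
  paste(pieces, collapse = "")
}

#' Simulate a shotgun read set
#'
#' Draws single-end reads of fixed length with uniform start positions and
#' i.i.d. substitution errors. With `error_rate = 0` (the default, matching
#' an error-free simulation design) every read is an exact substring of the
#' genome. Per-base qualities are drawn around `base_quality` and clipped to
#' the Phred range [0, 41].
#'
#' @param genome A `reference_genome` or DNA string (typically the mutated
#'   sample sequence).
#' @param depth Target mean coverage; the read count is
#'   `round(depth * L / read_length)`.
#' @param read_length Read length in bp (default 75).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @param base_quality Mean Phred quality of emitted bases (default 35).
#' @return Object of class `read_set`: list with `reads` (data frame `id`,
#'   `sequence`, `quality` as a Phred+33 string), `read_length`, `depth`,
#'   `error_rate`.
#' @export
simulate_reads <- function(genome, depth, read_length = 75L, error_rate = 0,
                           seed, base_quality = 35L) {
  seq <- .genome_sequence(genome)
  L <- nchar(seq)
  if (!is.numeric(depth) || depth <= 0) {
    stop("'depth' must be positive")
  }
  if (read_length > L) {
    stop("'read_length' exceeds the genome length")
  }
  if (error_rate < 0 || error_rate > 1) {
    stop("'error_rate' must lie in [0, 1]")
  }
  read_length <- as.integer(read_length)
  n_reads <- as.integer(round(depth * L / read_length))
  reads <- with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    seqs <- substring(seq, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      n_bases <- n_reads * read_length
      err <- which(stats::runif(n_bases) < error_rate)
      if (length(err) > 0L) {
        mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      nrow = read_length)
        subs <- vapply(mat[err], function(b) sample(setdiff(BASES, b), 1L), "")
        mat[err] <- subs
        seqs <- apply(mat, 2L, paste, collapse = "")
      }
    }
    q <- matrix(pmin(41L, pmax(0L, round(stats::rnorm(n_reads * read_length,
                                                      base_quality, 2)))),
                nrow = read_length)
    quals <- vapply(seq_len(n_reads),
                    function(i) intToUtf8(q[, i] + 33L), "")
    data.frame(id = sprintf("read_%06d", seq_len(n_reads)),
               sequence = seqs, quality = quals, stringsAsFactors = FALSE)
  })
  structure(
    list(reads = reads, read_length = read_length, depth = depth,
         error_rate = error_rate),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", nrow(x$reads), " reads x ", x$read_length,
      " bp (target depth ", x$depth, "x, error rate ", x$error_rate, ")\n",
      sep = "")
  invisible(x)
}

.mean_qualities <- function(readset) {
  vapply(readset$reads$quality,
         function(q) mean(utf8ToInt(q) - 33L), numeric(1),
         USE.NAMES = FALSE)
}

#' Clean a read set by length and mean quality
#'
#' Drops reads shorter than `min_length` or with mean Phred quality below
#' `min_mean_quality` - the standard pre-alignment QC filter.
#'
#' @param readset A `read_set`.
#' @param min_length Minimum retained read length (default 20 bp).
#' @param min_mean_quality Minimum retained mean quality (default 20).
#' @return The filtered `read_set`, with attribute `retained_fraction`.
#' @export
clean_reads <- function(readset, min_length = 20L, min_mean_quality = 20) {
  stopifnot(inherits(readset, "read_set"))
  if (min_length < 0 || min_mean_quality < 0) {
    stop("thresholds must be non-negative")
  }
  lens <- nchar(readset$reads$sequence)
  mq <- .mean_qualities(readset)
  keep <- lens >= min_length & mq >= min_mean_quality
  out <- readset
  out$reads <- readset$reads[keep, , drop = FALSE]
  rownames(out$reads) <- NULL
  attr(out, "retained_fraction") <-
    if (nrow(readset$reads) == 0L) NA_real_ else mean(keep)
  out
}

#' Quality-control summary of a read set
#'
#' Tabulates read lengths, rounded mean qualities, per-read GC content and
#' the duplication-level distribution (the multiplicity of identical read
#' sequences).
#'
#' @param readset A non-empty `read_set`.
#' @return List of data frames: `length_dist` (`length`, `count`),
#'   `quality_dist` (`mean_quality`, `count`), `gc_dist` (`gc_percent`,
#'   `count`) plus scalar `gc_mean`, and `duplication` (`level`,
#'   `n_distinct` sequences at that multiplicity, `read_fraction` of all
#'   reads carried by that level).
#' @export
qc_summary <- function(readset) {
  stopifnot(inherits(readset, "read_set"))
  n <- nrow(readset$reads)
  if (n == 0L) {
    stop("empty read set: nothing to summarise")
  }
  lens <- nchar(readset$reads$sequence)
  mq <- round(.mean_qualities(readset))
  gc <- vapply(readset$reads$sequence, gc_content, numeric(1),
               USE.NAMES = FALSE)
  dup <- table(table(readset$reads$sequence))
  levels <- as.integer(names(dup))
  list(
    length_dist = data.frame(length = as.integer(names(table(lens))),
                             count = as.integer(table(lens))),
    quality_dist = data.frame(mean_quality = as.integer(names(table(mq))),
                              count = as.integer(table(mq))),
    gc_dist = data.frame(gc_percent = as.integer(names(table(round(100 * gc)))),
                         count = as.integer(table(round(100 * gc)))),
    gc_mean = mean(gc),
    duplication = data.frame(level = levels,
                             n_distinct = as.integer(dup),
                             read_fraction = levels * as.integer(dup) / n)
  )
}

#' Write a read set to FASTQ
#'
#' @param readset A `read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path) {
  stopifnot(inherits(readset, "read_set"))
  seqs <- Biostrings::DNAStringSet(readset$reads$sequence)
  names(seqs) <- readset$reads$id
  qs <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(readset$reads$quality)
  )
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A `read_set` (with `depth` and `error_rate` set to `NA`).
#' @export
read_fastq <- function(path) {
  # Biostrings warns that the quality metadata columns are dropped when it
  # re-binds them onto the QualityScaledDNAStringSet; the qualities are
  # extracted separately below, so the warning is noise here
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  reads <- data.frame(
    id = sub("\\s.*$", "", names(qs)),
    sequence = suppressWarnings(as.character(qs)),
    quality = as.character(Biostrings::quality(qs)),
    stringsAsFactors = FALSE
  )
  rownames(reads) <- NULL
  structure(
    list(reads = reads,
         read_length = if (nrow(reads)) max(nchar(reads$sequence)) else 0L,
         depth = NA_real_, error_rate = NA_real_),
    class = "read_set"
  )
}
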