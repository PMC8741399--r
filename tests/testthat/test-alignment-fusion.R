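# Consensus voting over multi-aligner placements and Venn overlap counts.

align_rec <- function(read_id, pos, source, seq_id = "chr1", mapq = 60L) {
  data.frame(read_id = read_id, seq_id = seq_id, pos = pos, mapq = mapq,
             source = source, stringsAsFactors = FALSE)
}

four_sources <- c("bowtie2", "bwa", "hisat2", "subread")

test_that("vote counting groups identical placements and splits multi-mappings", {
  recs <- do.call(rbind, lapply(four_sources, function(s)
    align_rec("r1", 100L, s)))
  vt <- sort_and_count(recs)
  expect_equal(nrow(vt), 1L)
  expect_equal(vt$votes, 4L)

  # two sources at pos 100, two at 101: two keys with 2 votes each
  recs2 <- rbind(align_rec("r2", 100L, "bowtie2"), align_rec("r2", 100L, "bwa"),
                 align_rec("r2", 101L, "hisat2"), align_rec("r2", 101L, "subread"))
  vt2 <- sort_and_count(recs2)
  expect_equal(vt2$votes, c(2L, 2L))
  expect_setequal(vt2$pos, c(100L, 101L))

  # duplicate report by one source counts once
  vt3 <- sort_and_count(rbind(recs2, align_rec("r2", 100L, "bwa")))
  expect_equal(vt3$votes, c(2L, 2L))
  expect_error(sort_and_count(align_rec("r1", 1L, "only")), "two sources")
})

test_that("vote totals equal a brute-force recount on random inputs", {
  set.seed(50)
  for (i in 1:10) {
    recs <- do.call(rbind, lapply(four_sources, function(s) {
      n <- sample(5:20, 1)
      align_rec(paste0("r", sample(1:8, n, replace = TRUE)),
                sample(1:5, n, replace = TRUE), s)
    }))
    vt <- sort_and_count(recs)
    for (r in seq_len(nrow(vt))) {
      brute <- length(unique(recs$source[
        recs$read_id == vt$read_id[r] & recs$pos == vt$pos[r]
      ]))
      expect_equal(vt$votes[r], brute)
    }
    expect_true(all(diff(vt$votes) <= 0)) # sorted by votes descending
  }
})

test_that("consensus verdicts follow the n / n-1 / n-2 rule table", {
  vt <- data.frame(
    read_id = c("a", "b", "c", "d", "e"),
    seq_id = "chr1", pos = 1:5,
    votes = c(4L, 3L, 2L, 2L, 1L),
    sources = "", mapq_max = 60,
    stringsAsFactors = FALSE
  )
  panel <- c(pcr1 = "AAACCCGGGTTT")
  read_seqs <- c(a = "AAA", b = "CCC", c = "CCGGG", d = "ACGACG", e = "TTT")
  out <- consensus_vote(vt, n_sources = 4, panel = panel,
                        read_seqs = read_seqs)
  expect_equal(out$verdict,
               c("ACCEPT_ALL", "ACCEPT_MAJORITY", "ACCEPT_PANEL",
                 "REJECT", "REJECT"))
  # verdicts partition the keys
  expect_true(all(out$verdict %in%
                    c("ACCEPT_ALL", "ACCEPT_MAJORITY", "ACCEPT_PANEL", "REJECT")))
  # missing panel while an n-2 key exists is a configuration error
  expect_error(consensus_vote(vt, n_sources = 4), "configuration error")
})

test_that("the optional MAPQ gate demotes low-quality majority placements", {
  vt <- data.frame(read_id = "a", seq_id = "chr1", pos = 1L, votes = 3L,
                   sources = "", mapq_max = 5, stringsAsFactors = FALSE)
  expect_equal(consensus_vote(vt, 4)$verdict, "ACCEPT_MAJORITY")
  expect_equal(consensus_vote(vt, 4, min_mapq = 30)$verdict, "REJECT")
})

test_that("adding agreement never downgrades a verdict", {
  panel <- c(p = "ACGTACGT")
  read_seqs <- c(r = "ACGT")
  rank <- c(REJECT = 0, ACCEPT_PANEL = 1, ACCEPT_MAJORITY = 2, ACCEPT_ALL = 3)
  prev <- -Inf
  for (v in 1:4) {
    vt <- data.frame(read_id = "r", seq_id = "chr1", pos = 1L, votes = v,
                     sources = "", mapq_max = 60, stringsAsFactors = FALSE)
    verdict <- consensus_vote(vt, 4, panel = panel, read_seqs = read_seqs)$verdict
    expect_gte(rank[[verdict]], prev)
    prev <- rank[[verdict]]
  }
})

test_that("overlap counts partition distinct keys over source subsets", {
  # identical inputs: only the full subset is non-zero
  same <- do.call(rbind, lapply(four_sources, function(s)
    align_rec(c("r1", "r2"), c(10L, 20L), s)))
  ov <- overlap_counts(same)
  expect_equal(sum(ov$count), 2L)
  expect_equal(ov$count[ov$n_sources == 4L], 2L)
  expect_true(all(ov$count[ov$n_sources < 4L] == 0L))

  # disjoint inputs: only singletons non-zero
  disj <- do.call(rbind, Map(function(s, i) align_rec(paste0("r", i), i, s),
                             four_sources, 1:4))
  ov2 <- overlap_counts(disj)
  expect_equal(sum(ov2$count[ov2$n_sources == 1L]), 4L)
  expect_true(all(ov2$count[ov2$n_sources > 1L] == 0L))
})

test_that("overlap counts match inclusion-exclusion brute force on random inputs", {
  set.seed(51)
  for (i in 1:8) {
    recs <- do.call(rbind, lapply(four_sources, function(s) {
      n <- sample(3:15, 1)
      align_rec(paste0("r", sample(1:6, n, replace = TRUE)),
                sample(1:4, n, replace = TRUE), s)
    }))
    ov <- overlap_counts(recs)
    keys <- unique(paste(recs$read_id, recs$pos))
    expect_equal(sum(ov$count), length(keys))
    # brute force: recompute each key's exact membership pattern
    brute <- table(vapply(keys, function(k) {
      members <- sort(unique(recs$source[paste(recs$read_id, recs$pos) == k]))
      paste(members, collapse = ",")
    }, ""))
    for (pat in names(brute)) {
      expect_equal(ov$count[ov$sources == pat], as.integer(brute[[pat]]),
                   info = pat)
    }
  }
})

test_that("SAM and TSV alignment readers agree on the mandatory fields", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t100\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r2\t0\tchr1\t250\t37\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"
  ), sam)
  recs <- read_alignments(sam, source = "bwa")
  expect_equal(nrow(recs), 2L) # the unmapped read is dropped
  expect_equal(recs$pos, c(100L, 250L))
  expect_equal(recs$mapq, c(60L, 37L))

  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(recs[c("read_id", "seq_id", "pos", "mapq")], tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  recs2 <- read_alignments(tsv, source = "bwa")
  expect_equal(recs2, recs)
})
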