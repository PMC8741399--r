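# Reference generation, variant implantation, read simulation, cleaning, QC
# and simulated caller call sets.

test_that("reference generation is deterministic and hits its GC target", {
  a <- generate_reference(10000, 0.49, seed = 1)
  b <- generate_reference(10000, 0.49, seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence,
                         generate_reference(10000, 0.49, seed = 2)$sequence))
  # binomial 99.99% band around the target for n = 1e4
  expect_gt(gc_content(a), 0.44)
  expect_lt(gc_content(a), 0.54)
  expect_error(generate_reference(10000, 1.0, seed = 1), "gc_fraction")
  expect_error(generate_reference(10, 0.5, seed = 1), "length")
})

test_that("implanted truth sets have the requested composition and round-trip", {
  ref <- generate_reference(50000, 0.49, seed = 3)
  imp <- implant_variants(ref, n_snp = 60, n_indel = 40, seed = 4)
  truth <- imp$truth
  expect_equal(sum(truth$kind == "SNP"), 60L)
  expect_equal(sum(truth$kind %in% c("INS", "DEL")), 40L)
  expect_equal(abs(sum(truth$kind == "INS") - sum(truth$kind == "DEL")) <= 1,
               TRUE)
  expect_false(is.unsorted(truth$pos))
  expect_true(all(diff(truth$pos) >= 12))
  # SNVs substitute, indels change length by 2-10
  snp <- truth[truth$kind == "SNP", ]
  expect_true(all(nchar(snp$ref) == 1 & nchar(snp$alt) == 1 &
                    snp$ref != snp$alt))
  ind <- truth[truth$kind != "SNP", ]
  expect_true(all(abs(nchar(ind$ref) - nchar(ind$alt)) %in% 2:10))
  # applying the truth set with the reference patcher reproduces the mutation
  expect_identical(apply_variants(imp$ref, truth), imp$sequence)
  # zero variants is the identity
  imp0 <- implant_variants(ref, 0, 0, seed = 5)
  expect_identical(imp0$sequence, ref$sequence)
  # infeasible density errors out
  expect_error(implant_variants(generate_reference(1200, 0.5, seed = 1),
                                500, 500, seed = 1),
               "capacity")
})

test_that("error-free reads are exact substrings at the expected count and coverage", {
  ref <- generate_reference(15000, 0.49, seed = 6)
  rs <- simulate_reads(ref, depth = 50, read_length = 75, error_rate = 0,
                       seed = 7)
  expect_equal(nrow(rs$reads), 10000L) # 50 * 15000 / 75
  idx <- sample(nrow(rs$reads), 200)
  expect_true(all(vapply(rs$reads$sequence[idx],
                         function(r) grepl(r, ref$sequence, fixed = TRUE),
                         logical(1))))
  cov <- nrow(rs$reads) * rs$read_length / ref$length
  expect_lt(abs(cov - 50) / 50, 0.05)
  # qualities stay in Phred range
  q <- utf8ToInt(rs$reads$quality[1]) - 33L
  expect_true(all(q >= 0 & q <= 41))
  expect_error(simulate_reads(ref, depth = 10, read_length = 20000, seed = 1),
               "read_length")
})

test_that("substitution errors appear at roughly the requested rate", {
  ref <- generate_reference(5000, 0.5, seed = 8)
  rs <- simulate_reads(ref, depth = 20, read_length = 50, error_rate = 0.05,
                       seed = 9)
  mism <- vapply(seq_len(nrow(rs$reads)), function(i) {
    r <- rs$reads$sequence[i]
    !grepl(r, ref$sequence, fixed = TRUE)
  }, logical(1))
  expect_gt(mean(mism), 0.5) # 50 bp at 5%: most reads carry >= 1 error
})

test_that("read cleaning drops exactly the reads failing the predicate", {
  ref <- generate_reference(5000, 0.5, seed = 10)
  rs <- simulate_reads(ref, depth = 10, read_length = 60, seed = 11)
  # high-quality full-length reads: everything retained
  clean <- clean_reads(rs, min_length = 20, min_mean_quality = 20)
  expect_equal(attr(clean, "retained_fraction"), 1)

  # mix in short reads and recount naively
  rs$reads$sequence[1:50] <- substr(rs$reads$sequence[1:50], 1, 10)
  rs$reads$quality[1:50] <- substr(rs$reads$quality[1:50], 1, 10)
  clean2 <- clean_reads(rs, min_length = 20, min_mean_quality = 20)
  lens <- nchar(rs$reads$sequence)
  mq <- vapply(rs$reads$quality, function(q) mean(utf8ToInt(q) - 33),
               numeric(1))
  expect_equal(nrow(clean2$reads), sum(lens >= 20 & mq >= 20))
  # impossible quality bar drops everything
  expect_equal(nrow(clean_reads(rs, min_mean_quality = 45)$reads), 0L)
})

test_that("QC summary histograms sum to the read count and track duplication", {
  ref <- generate_reference(3000, 0.5, seed = 12)
  rs <- simulate_reads(ref, depth = 5, read_length = 40, seed = 13)
  qc <- qc_summary(rs)
  n <- nrow(rs$reads)
  expect_equal(sum(qc$length_dist$count), n)
  expect_equal(sum(qc$quality_dist$count), n)
  expect_equal(sum(qc$gc_dist$count), n)
  gc_direct <- mean(vapply(rs$reads$sequence, gc_content, numeric(1)))
  expect_equal(qc$gc_mean, gc_direct)

  # force a triplicated read (marker sequence that cannot occur elsewhere)
  rs$reads$sequence[1:3] <- strrep("XY", 20)
  rs$reads$quality[2:3] <- rs$reads$quality[1]
  qc2 <- qc_summary(rs)
  expect_true(3L %in% qc2$duplication$level)
  expect_equal(qc2$duplication$n_distinct[qc2$duplication$level == 3L], 1L)

  # all-unique reads sit entirely at duplication level 1
  uniq <- rs
  uniq$reads <- rs$reads[4:20, ]
  qcu <- qc_summary(uniq)
  expect_equal(qcu$duplication$level, 1L)
  expect_equal(qcu$duplication$read_fraction, 1)
  empty <- rs
  empty$reads <- rs$reads[0, ]
  expect_error(qc_summary(empty), "empty")
})

test_that("FASTQ round-trip preserves sequences and qualities", {
  ref <- generate_reference(2000, 0.5, seed = 14)
  rs <- simulate_reads(ref, depth = 3, read_length = 30, seed = 15)
  path <- tempfile(fileext = ".fastq")
  write_fastq(rs, path)
  back <- read_fastq(path)
  expect_equal(back$reads$sequence, rs$reads$sequence)
  expect_equal(back$reads$quality, rs$reads$quality)
})

test_that("simulated call sets follow the caller profiles", {
  ref <- generate_reference(100000, 0.49, seed = 16)
  imp <- implant_variants(ref, 300, 0, seed = 17)

  perfect <- list(perfect = caller_profile("perfect", 1, 1, 1, 1, 0))
  cs <- simulate_caller_callsets(imp$truth, perfect, depth = 100, seed = 18,
                                 genome = ref)[[1]]
  expect_equal(paste(cs$pos, cs$ref, cs$alt),
               paste(imp$truth$pos, imp$truth$ref, imp$truth$alt))

  blind <- list(blind = caller_profile("blind", 0, 0, 0, 0, 0))
  cs0 <- simulate_caller_callsets(imp$truth, blind, depth = 100, seed = 18,
                                  genome = ref)[[1]]
  expect_equal(nrow(cs0), 0L)

  # sensitivity 0.8: detected count within 3 sigma of 240
  p80 <- list(p80 = caller_profile("p80", 0.8, 0.8, 0.8, 0.8, 0))
  cs80 <- simulate_caller_callsets(imp$truth, p80, depth = 100, seed = 19,
                                   genome = ref)[[1]]
  expect_lt(abs(nrow(cs80) - 240), 3 * sqrt(300 * 0.8 * 0.2))

  # determinism per seed
  again <- simulate_caller_callsets(imp$truth, p80, depth = 100, seed = 19,
                                    genome = ref)[[1]]
  expect_identical(cs80, again)
})

test_that("profile sensitivity is monotone in depth and clamped", {
  pr <- caller_profile("x", 0.6, 0.9, 0.5, 0.8, 10)
  d <- c(10, 50, 120, 300, 500)
  s <- profile_sensitivity(pr, d, "SNP")
  expect_true(all(diff(s) >= 0))
  expect_equal(s[1], 0.6) # clamped below 50x
  expect_equal(s[length(s)], 0.9) # clamped above 300x
  expect_error(caller_profile("bad", 0.9, 0.6, 0.5, 0.8, 10), "non-decreasing")
})
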