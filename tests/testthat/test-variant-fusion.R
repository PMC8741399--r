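# Call-set merging, hard filtering and Bayesian posterior fusion.

test_that("merging unions call sets on the normalised key with per-caller evidence", {
  snp <- make_call(100, "A", "G")
  four <- list(a = snp, b = snp, c = snp, d = snp)
  m <- merge_callsets(four)
  expect_equal(nrow(m$variants), 1L)
  expect_equal(sum(m$evidence), 4L)

  disjoint <- list(
    a = make_call(c(1, 5, 9) * 10, "A", "G"),
    b = make_call(c(2, 4, 6, 8, 12) * 10, "C", "T")
  )
  m2 <- merge_callsets(disjoint)
  expect_equal(nrow(m2$variants), 8L)
  expect_equal(unname(colSums(m2$evidence)), c(3L, 5L))
})

test_that("merged record count equals brute-force union size on random call sets", {
  set.seed(60)
  for (i in 1:15) {
    sets <- lapply(1:3, function(j) {
      pos <- sample(1:40, sample(3:12, 1))
      make_call(pos, "A", "G", caller = paste0("c", j))
    })
    names(sets) <- paste0("c", 1:3)
    m <- merge_callsets(sets)
    union_keys <- unique(unlist(lapply(sets, function(s)
      paste(s$chrom, s$pos, s$ref, s$alt))))
    expect_equal(nrow(m$variants), length(union_keys))
    # every merged record has at least one positive evidence entry
    expect_true(all(rowSums(m$evidence) >= 1L))
  }
})

test_that("indel normalisation aligns alternative representations to one key", {
  # same 2 bp deletion written three ways: padded, right-shifted, unpadded tail
  ref_seq <- "GGGCATATATGGG" # deleting one AT from the AT run
  a <- make_call(4, "CATAT", "CAT")  # suffix-trimmable padded form
  b <- make_call(6, "TAT", "T")      # right-shifted
  m <- merge_callsets(list(a = a, b = b), ref_seq = ref_seq)
  expect_equal(nrow(m$variants), 1L)
  expect_equal(sum(m$evidence), 2L)
  # left-aligned anchor
  expect_equal(m$variants$pos, 4L)
  expect_equal(nchar(m$variants$ref) - nchar(m$variants$alt), 2L)
})

test_that("hard filter keeps exactly depth > 10 and qual > 30, strictly", {
  calls <- make_call(1:4)
  calls$depth <- c(10, 11, 100, 100)
  calls$qual <- c(31, 31, 30, 30.001)
  out <- hard_filter(calls)
  expect_equal(out$pos, c(2L, 4L))
  # missing fields error unless explicitly allowed
  calls$qual[1] <- NA
  expect_error(hard_filter(calls), "missing")
  dropped <- hard_filter(calls, allow_missing = TRUE)
  expect_equal(attr(dropped, "n_dropped_missing"), 1L)
})

test_that("combined likelihood multiplies per-caller evidence terms", {
  m <- fusion_model(
    p_fire_variant = c(a = 0.5, b = 0.5, c = 0.5),
    p_fire_novariant = c(a = 0.1, b = 0.1, c = 0.1)
  )
  expect_equal(combined_likelihood(m, c(TRUE, TRUE, TRUE), "VARIANT"), 0.125)
  expect_equal(combined_likelihood(m, c(TRUE, FALSE, TRUE), "VARIANT"),
               0.5 * 0.5 * 0.5) # 1 - 0.5 = 0.5 for the miss
  m0 <- fusion_model(p_fire_variant = c(a = 0, b = 0.5),
                     p_fire_novariant = c(a = 0.1, b = 0.1))
  expect_equal(combined_likelihood(m0, c(TRUE, TRUE), "VARIANT"), 0)
  # log-domain oracle on random models
  set.seed(61)
  for (i in 1:30) {
    pv <- stats::setNames(runif(4, 0.01, 0.99), letters[1:4])
    pn <- stats::setNames(runif(4, 0.01, 0.99), letters[1:4])
    ev <- runif(4) < 0.5
    mm <- fusion_model(pv, pn)
    want <- exp(sum(log(ifelse(ev, pv, 1 - pv))))
    expect_equal(combined_likelihood(mm, ev, "VARIANT"), want,
                 tolerance = 1e-12)
  }
})

test_that("posterior fusion reproduces direct Bayes arithmetic", {
  # symmetric model: posterior is (0.5, 0.5), acceptance decided by Po
  sym <- fusion_model(p_fire_variant = c(a = 0.7, b = 0.7),
                      p_fire_novariant = c(a = 0.7, b = 0.7),
                      prior_variant = 0.5, po = 0.5)
  r <- fuse_posterior(sym, c(TRUE, TRUE))
  expect_equal(unname(r$posterior), c(0.5, 0.5))
  expect_true(r$accepted) # Po = 0.5 <= 0.5 posterior
  sym2 <- fusion_model(c(a = 0.7, b = 0.7), c(a = 0.7, b = 0.7),
                       prior_variant = 0.5, po = 0.6)
  expect_false(fuse_posterior(sym2, c(TRUE, TRUE))$accepted)

  # four concordant informative callers against a 1% prior
  m <- fusion_model(
    p_fire_variant = c(a = 0.9, b = 0.9, c = 0.9, d = 0.9),
    p_fire_novariant = c(a = 0.01, b = 0.01, c = 0.01, d = 0.01),
    prior_variant = 0.01
  )
  r4 <- fuse_posterior(m, rep(TRUE, 4))
  want <- (0.01 * 0.9^4) / (0.01 * 0.9^4 + 0.99 * 0.01^4)
  expect_equal(unname(r4$posterior[["VARIANT"]]), want, tolerance = 1e-12)
  expect_equal(r4$map_hypothesis, "VARIANT")
  expect_true(r4$accepted)

  # degenerate: zero joint under both hypotheses
  deg <- fusion_model(p_fire_variant = c(a = 1), p_fire_novariant = c(a = 1),
                      prior_variant = 0.5)
  expect_error(fuse_posterior(deg, FALSE), "degenerate")
})

test_that("posteriors normalise to one over random models", {
  set.seed(62)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    m <- fusion_model(
      p_fire_variant = stats::setNames(runif(k, 0.05, 0.95), letters[1:k]),
      p_fire_novariant = stats::setNames(runif(k, 0.05, 0.95), letters[1:k]),
      prior_variant = runif(1, 0.01, 0.99)
    )
    r <- fuse_posterior(m, runif(k) < 0.5)
    expect_lt(abs(sum(r$posterior) - 1), 1e-9)
    expect_equal(r$map_hypothesis, names(which.max(r$posterior)))
  }
})

test_that("more agreeing informative callers never decrease the variant posterior", {
  set.seed(63)
  for (i in 1:20) {
    k <- 4
    pv <- stats::setNames(runif(k, 0.5, 0.95), letters[1:k])
    pn <- stats::setNames(runif(k, 0.01, 0.4), letters[1:k]) # informative
    m <- fusion_model(pv, pn, prior_variant = runif(1, 0.05, 0.5))
    post <- vapply(0:k, function(v) {
      ev <- c(rep(TRUE, v), rep(FALSE, k - v))
      fuse_posterior(m, ev)$posterior[["VARIANT"]]
    }, numeric(1))
    expect_true(all(diff(post) > 0))
  }
})

test_that("single-caller fusion reduces to the likelihood-ratio decision", {
  m <- fusion_model(p_fire_variant = c(only = 0.8),
                    p_fire_novariant = c(only = 0.2),
                    prior_variant = 0.5, po = 0.5)
  r_fire <- fuse_posterior(m, TRUE)
  # uniform prior: posterior odds = likelihood ratio 0.8 / 0.2 = 4
  expect_equal(unname(r_fire$posterior[["VARIANT"]]), 0.8)
  expect_true(r_fire$accepted)
  r_miss <- fuse_posterior(m, FALSE)
  expect_equal(unname(r_miss$posterior[["VARIANT"]]), 0.2)
  expect_false(r_miss$accepted)
})

test_that("caller profile fitting matches brute-force confusion counts", {
  truth <- make_call(seq(10, 100, by = 10), "A", "G")
  exact <- truth
  half <- truth[1:5, ]
  noisy <- rbind(half, make_call(c(15, 25), "C", "T"))
  sets <- list(exact = exact, half = half, noisy = noisy)
  fit <- fit_caller_profiles(sets, truth)
  expect_equal(unname(fit$p_fire_variant), c(1, 0.5, 0.5))
  # universe: 10 truth + 2 false sites; noisy fires on both non-variant sites
  expect_equal(unname(fit$p_fire_novariant), c(0, 0, 1))
  expect_equal(fit$prior_variant, 10 / 12)
  expect_error(fit_caller_profiles(sets, truth[0, ]), "estimation error")
})

test_that("vectorised call-set fusion matches per-variant posterior fusion", {
  set.seed(64)
  sets <- lapply(1:4, function(j)
    make_call(sample(1:60, 25), "A", "G", caller = letters[j]))
  names(sets) <- letters[1:4]
  merged <- merge_callsets(sets)
  m <- fusion_model(
    p_fire_variant = stats::setNames(runif(4, 0.6, 0.95), letters[1:4]),
    p_fire_novariant = stats::setNames(runif(4, 0.02, 0.3), letters[1:4]),
    prior_variant = 0.4
  )
  fused <- fuse_callsets(merged, m)
  for (r in sample(nrow(fused), 10)) {
    single <- fuse_posterior(m, merged$evidence[r, ])
    expect_equal(fused$posterior_variant[r],
                 unname(single$posterior[["VARIANT"]]), tolerance = 1e-12)
    expect_equal(fused$accepted[r], single$accepted)
  }
})

test_that("VCF round-trip preserves call-set content", {
  calls <- make_call(c(5, 17, 23), c("A", "CAT", "G"), c("G", "C", "GTT"),
                     qual = c(55.5, 42, 61), depth = c(40L, 12L, 80L),
                     caller = "gatk")
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  back <- read_vcf_calls(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$qual, calls$qual, tolerance = 1e-3)
  expect_equal(unique(back$caller), "gatk")
})
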