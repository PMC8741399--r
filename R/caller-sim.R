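# Simulated variant callers. Each profile detects truth variants with a
# depth-dependent sensitivity and sprinkles Poisson false positives, emitting
# QUAL and DP so that downstream hard filtering is non-trivial.

#' Define a simulated caller profile
#'
#' Sensitivities are linear in depth between the 50x and 300x anchors and
#' clamped outside that range, so they are monotone non-decreasing in depth by
#' construction.
#'
#' @param name Caller label.
#' @param snp_sens_50,snp_sens_300 SNV sensitivity at 50x and 300x.
#' @param indel_sens_50,indel_sens_300 Indel sensitivity at 50x and 300x.
#' @param fp_rate_per_mb Expected false-positive calls per megabase at 50x
#'   depth. False calls are noise-driven, so the realised rate attenuates
#'   with coverage as `min(1, 50 / depth)`.
#' @return Object of class `caller_profile`.
#' @export
caller_profile <- function(name, snp_sens_50, snp_sens_300,
                           indel_sens_50, indel_sens_300, fp_rate_per_mb) {
  vals <- c(snp_sens_50, snp_sens_300, indel_sens_50, indel_sens_300)
  if (any(vals < 0 | vals > 1)) {
    stop("sensitivities must lie in [0, 1]")
  }
  if (snp_sens_300 < snp_sens_50 || indel_sens_300 < indel_sens_50) {
    stop("sensitivity must be non-decreasing in depth")
  }
  if (fp_rate_per_mb < 0) {
    stop("'fp_rate_per_mb' must be non-negative")
  }
  structure(
    list(name = name, snp_sens_50 = snp_sens_50, snp_sens_300 = snp_sens_300,
         indel_sens_50 = indel_sens_50, indel_sens_300 = indel_sens_300,
         fp_rate_per_mb = fp_rate_per_mb),
    class = "caller_profile"
  )
}

#' Sensitivity of a caller profile at a depth
#'
#' @param profile A `caller_profile`.
#' @param depth Sequencing depth.
#' @param class `"SNP"` or `"InDel"`.
#' @return Detection probability in [0, 1].
#' @export
profile_sensitivity <- function(profile, depth, class = c("SNP", "InDel")) {
  class <- match.arg(class)
  lo <- if (class == "SNP") profile$snp_sens_50 else profile$indel_sens_50
  hi <- if (class == "SNP") profile$snp_sens_300 else profile$indel_sens_300
  f <- (pmin(pmax(depth, 50), 300) - 50) / 250
  lo + f * (hi - lo)
}

#' Default panel of four simulated caller profiles
#'
#' Calibrated so that single-caller SNV sensitivity sits in 0.60-0.80 at 50x
#' and 0.80-0.95 at 300x, with the relative ordering
#' gatk > varscan2 > bcftools > freebayes, echoing the typical ranking of the
#' corresponding real tools without claiming their exact figures. Indel
#' sensitivities run ~6 points lower. The false-positive burden is heavily
#' concentrated in the most permissive caller (the usual pattern: permissive
#' callers inflate raw call counts), which is what gives the fused model
#' caller-identity information to exploit.
#'
#' @return Named list of four [caller_profile()] objects.
#' @export
default_caller_profiles <- function() {
  profiles <- list(
    caller_profile("gatk",      0.78, 0.94, 0.72, 0.88, fp_rate_per_mb = 20),
    caller_profile("varscan2",  0.74, 0.90, 0.68, 0.84, fp_rate_per_mb = 30),
    caller_profile("bcftools",  0.70, 0.87, 0.64, 0.81, fp_rate_per_mb = 40),
    caller_profile("freebayes", 0.66, 0.83, 0.60, 0.78, fp_rate_per_mb = 120)
  )
  stats::setNames(profiles, vapply(profiles, `[[`, "", "name"))
}

.variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "InDel")
}

# Random emission distributions. True calls gain quality with depth (so the
# quality>30 hard filter costs less at high depth); false calls sit lower and
# carry thinner coverage.
.emit_qual_tp <- function(n, depth) pmax(0, stats::rnorm(n, 45 + depth / 10, 10))
.emit_qual_fp <- function(n, depth) pmax(0, stats::rnorm(n, 38, 8))
.emit_dp_tp <- function(n, depth) stats::rpois(n, depth)
.emit_dp_fp <- function(n, depth) stats::rpois(n, 0.6 * depth)

#' Simulate per-caller variant call sets from a truth set
#'
#' Each caller detects each truth variant independently with its
#' depth-dependent sensitivity, and adds
#' `Poisson(fp_rate_per_mb * L / 1e6 * min(1, 50 / depth))` false-positive
#' calls at reference positions away from the truth (80% SNVs, 20% short
#' indels, reflecting the usual predominance of SNV false calls; the
#' `50 / depth` attenuation models the suppression of stochastic miscalls
#' as pileups deepen). Every call carries `qual` and `depth` fields drawn from the
#' caller's emission distributions. Deterministic given the seed.
#'
#' @param truth Truth data frame from [implant_variants()].
#' @param profiles Named list of [caller_profile()]s.
#' @param depth Sequencing depth of the sample being "called".
#' @param seed Integer seed.
#' @param genome The reference genome (`reference_genome` or string) used
#'   for false-positive ref alleles.
#' @return Named list of call-set data frames (`chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `depth`, `caller`), one per profile.
#' @export
simulate_caller_callsets <- function(truth, profiles, depth, seed, genome) {
  if (length(profiles) == 0L) {
    stop("'profiles' must name at least one caller")
  }
  seq <- .genome_sequence(genome)
  chrom <- .genome_id(genome)
  L <- nchar(seq)
  classes <- .variant_class(truth$ref, truth$alt)
  with_seed(seed, {
    out <- lapply(profiles, function(pr) {
      sens <- ifelse(classes == "SNP",
                     profile_sensitivity(pr, depth, "SNP"),
                     profile_sensitivity(pr, depth, "InDel"))
      hit <- stats::runif(nrow(truth)) < sens
      tp <- truth[hit, c("chrom", "pos", "ref", "alt"), drop = FALSE]
      n_tp <- nrow(tp)
      if (n_tp > 0L) {
        tp$qual <- .emit_qual_tp(n_tp, depth)
        tp$depth <- .emit_dp_tp(n_tp, depth)
      } else {
        tp$qual <- numeric(0)
        tp$depth <- integer(0)
      }
      n_fp <- stats::rpois(1L, pr$fp_rate_per_mb * (L / 1e6) * min(1, 50 / depth))
      fp <- NULL
      if (n_fp > 0L) {
        cand <- sample.int(L - 12L, 2L * n_fp + 8L) + 1L
        cand <- setdiff(cand, truth$pos)[seq_len(min(n_fp, length(cand)))]
        n_fp <- length(cand)
        ref_al <- substring(seq, cand, cand)
        alt_al <- vapply(ref_al, function(b) sample(setdiff(BASES, b), 1L), "")
        is_indel <- stats::runif(n_fp) < 0.2
        for (i in which(is_indel)) {
          len <- sample(2:10, 1L)
          if (stats::runif(1) < 0.5) { # spurious insertion
            alt_al[i] <- paste0(ref_al[i],
                                paste(sample(BASES, len, replace = TRUE),
                                      collapse = ""))
          } else {                     # spurious deletion
            ref_al[i] <- substring(seq, cand[i], cand[i] + len)
            alt_al[i] <- substring(seq, cand[i], cand[i])
          }
        }
        fp <- data.frame(chrom = chrom, pos = cand, ref = ref_al,
                         alt = alt_al,
                         qual = .emit_qual_fp(n_fp, depth),
                         depth = .emit_dp_fp(n_fp, depth),
                         stringsAsFactors = FALSE)
      }
      calls <- rbind(tp, fp)
      calls <- calls[order(calls$pos), , drop = FALSE]
      calls$caller <- rep(pr$name, nrow(calls))
      rownames(calls) <- NULL
      calls
    })
    stats::setNames(out, vapply(profiles, `[[`, "", "name"))
  })
}

#' Write a truth set to a TSV file
#'
#' @param truth Truth data frame from [implant_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth set from a TSV file
#'
#' @param path Path to a TSV written by [write_truth_tsv()].
#' @return Truth data frame.
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
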