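# Merging of multi-caller call sets, GATK-style hard filtering, and Bayesian
# evidence fusion over the hypothesis space {VARIANT, NO_VARIANT} per site.

.variant_keys <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
}

#' Normalise variant representations
#'
#' Trims shared suffix and prefix bases from ref/alt pairs (adjusting the
#' position for trimmed prefixes, always retaining at least one base of
#' each allele) and, when the reference sequence is supplied, left-aligns
#' pure indels by shifting them as far left as the sequence allows. Without
#' normalisation, representation differences between callers break
#' key-based deduplication.
#'
#' @param calls Data frame with `chrom`, `pos`, `ref`, `alt` (other columns
#'   pass through).
#' @param ref_seq Optional reference sequence (string or
#'   `reference_genome`) enabling left-alignment.
#' @return The data frame with normalised `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(calls, ref_seq = NULL) {
  if (!is.null(ref_seq)) {
    ref_seq <- .genome_sequence(ref_seq)
  }
  for (i in seq_len(nrow(calls))) {
    pos <- calls$pos[i]
    ref <- calls$ref[i]
    alt <- calls$alt[i]
    repeat {
      changed <- FALSE
      # shared suffix
      while (nchar(ref) > 1L && nchar(alt) > 1L &&
             substr(ref, nchar(ref), nchar(ref)) ==
             substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
        changed <- TRUE
      }
      # shared prefix
      while (nchar(ref) > 1L && nchar(alt) > 1L &&
             substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref))
        alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
        changed <- TRUE
      }
      # left-align a pure indel while its alleles end in the same base
      if (!is.null(ref_seq) && nchar(ref) != nchar(alt) &&
          (nchar(ref) == 1L || nchar(alt) == 1L) && pos > 1L &&
          substr(ref, nchar(ref), nchar(ref)) ==
          substr(alt, nchar(alt), nchar(alt))) {
        prev <- substr(ref_seq, pos - 1L, pos - 1L)
        ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
        pos <- pos - 1L
        changed <- TRUE
      }
      if (!changed) break
    }
    calls$pos[i] <- pos
    calls$ref[i] <- ref
    calls$alt[i] <- alt
  }
  calls
}

#' Merge variant call sets from multiple callers
#'
#' Unions the call sets on the normalised key `(chrom, pos, ref, alt)`,
#' removing duplicates, and records per-caller evidence: which callers
#' contain each merged key. Multi-allelic sites yield one merged record per
#' distinct alternate allele.
#'
#' @param callsets Named list (>= 2) of call-set data frames with columns
#'   `chrom`, `pos`, `ref`, `alt` (and optionally `qual`, `depth`).
#' @param normalize Normalise representations before merging (default TRUE).
#' @param ref_seq Optional reference for indel left-alignment.
#' @return Object of class `merged_callset`: list with `variants` (data
#'   frame `chrom`, `pos`, `ref`, `alt` ordered by key), `evidence` (logical
#'   matrix, variants x callers), `callers` and `n_callers`.
#' @export
merge_callsets <- function(callsets, normalize = TRUE, ref_seq = NULL) {
  if (!is.list(callsets) || length(callsets) < 2L) {
    stop("'callsets' must be a list of at least two call sets")
  }
  if (is.null(names(callsets)) || any(!nzchar(names(callsets)))) {
    names(callsets) <- paste0("caller", seq_along(callsets))
  }
  callers <- names(callsets)
  if (normalize) {
    callsets <- lapply(callsets, normalize_variants, ref_seq = ref_seq)
  }
  keysets <- lapply(callsets, .variant_keys)
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  variants <- data.frame(chrom = parts[, 1L],
                         pos = as.integer(parts[, 2L]),
                         ref = parts[, 3L], alt = parts[, 4L],
                         stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  keys <- .variant_keys(variants)
  evidence <- vapply(keysets, function(ks) keys %in% ks,
                     logical(length(keys)))
  if (length(keys) == 1L) {
    evidence <- matrix(evidence, nrow = 1L, dimnames = list(NULL, callers))
  }
  structure(
    list(variants = variants, evidence = evidence, callers = callers,
         n_callers = length(callers)),
    class = "merged_callset"
  )
}

#' @export
print.merged_callset <- function(x, ...) {
  cat("<merged_callset> ", nrow(x$variants), " distinct variant(s) from ",
      x$n_callers, " caller(s): ", paste(x$callers, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Hard-filter variant calls on depth and quality
#'
#' Keeps exactly the calls with `depth > min_depth` and `qual > min_qual`,
#' both strict inequalities (defaults 10 and 30, the usual post-calling
#' thresholds).
#'
#' @param calls Call-set data frame carrying `qual` and `depth` columns.
#' @param min_depth,min_qual Strict lower thresholds.
#' @param allow_missing If `FALSE` (default) a missing/NA `qual` or `depth`
#'   is an error; if `TRUE`, such calls are dropped and counted in the
#'   `n_dropped_missing` attribute.
#' @return The filtered data frame.
#' @export
hard_filter <- function(calls, min_depth = 10, min_qual = 30,
                        allow_missing = FALSE) {
  if (!all(c("qual", "depth") %in% names(calls))) {
    stop("calls must carry 'qual' and 'depth' columns")
  }
  missing <- is.na(calls$qual) | is.na(calls$depth)
  if (any(missing) && !allow_missing) {
    stop(sum(missing), " call(s) have missing qual/depth; ",
         "set allow_missing = TRUE to drop them")
  }
  keep <- !missing & calls$depth > min_depth & calls$qual > min_qual
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_missing") <- sum(missing)
  out
}

#' Specify a Bayesian fusion model
#'
#' The model carries the per-site hypothesis priors (default hypotheses
#' VARIANT / NO_VARIANT), one firing probability per caller under each
#' hypothesis, and the decision threshold `po`: a site is accepted when the
#' maximum-a-posteriori hypothesis is VARIANT and its posterior reaches
#' `po`.
#'
#' @param p_fire_variant Named numeric vector, per-caller probability of
#'   calling a site given a true variant.
#' @param p_fire_novariant Named numeric vector (same callers), probability
#'   of calling a site given no variant.
#' @param prior_variant Prior probability of the VARIANT hypothesis
#'   (default 0.001, the order of SNV density in a genome).
#' @param po Decision threshold in (0, 1) (default 0.5).
#' @return Object of class `fusion_model` with `priors` (VARIANT,
#'   NO_VARIANT), `likelihoods` (callers x hypotheses matrix of firing
#'   probabilities), `callers` and `po`.
#' @export
fusion_model <- function(p_fire_variant, p_fire_novariant,
                         prior_variant = 0.001, po = 0.5) {
  callers <- names(p_fire_variant)
  if (is.null(callers) || !identical(callers, names(p_fire_novariant))) {
    stop("'p_fire_variant' and 'p_fire_novariant' must be named identically")
  }
  probs <- c(p_fire_variant, p_fire_novariant, prior_variant)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (prior_variant <= 0 || prior_variant >= 1) {
    stop("'prior_variant' must lie strictly between 0 and 1")
  }
  if (po <= 0 || po >= 1) {
    stop("'po' must lie strictly between 0 and 1")
  }
  priors <- c(VARIANT = prior_variant, NO_VARIANT = 1 - prior_variant)
  stopifnot(abs(sum(priors) - 1) < 1e-12)
  lik <- cbind(VARIANT = as.numeric(p_fire_variant),
               NO_VARIANT = as.numeric(p_fire_novariant))
  rownames(lik) <- callers
  structure(
    list(priors = priors, likelihoods = lik, callers = callers, po = po),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model> P(VARIANT) = ", signif(x$priors[["VARIANT"]], 4),
      ", Po = ", x$po, "\n", sep = "")
  print(round(x$likelihoods, 4))
  invisible(x)
}

#' Combined likelihood of a caller evidence vector
#'
#' Product over callers of the per-caller evidence likelihood under the
#' hypothesis: `P(fire | hypothesis)` for a caller that fired,
#' `1 - P(fire | hypothesis)` for one that did not (the callers are modelled
#' as conditionally independent).
#'
#' @param model A `fusion_model`.
#' @param evidence Logical vector of length `n_callers` (fired / not fired),
#'   in the model's caller order.
#' @param hypothesis `"VARIANT"` or `"NO_VARIANT"`.
#' @return The joint likelihood in [0, 1].
#' @export
combined_likelihood <- function(model, evidence,
                                hypothesis = c("VARIANT", "NO_VARIANT")) {
  stopifnot(inherits(model, "fusion_model"))
  hypothesis <- match.arg(hypothesis)
  evidence <- as.logical(evidence)
  if (length(evidence) != length(model$callers)) {
    stop("evidence length must equal the number of callers")
  }
  p <- model$likelihoods[, hypothesis]
  prod(ifelse(evidence, p, 1 - p))
}

#' Posterior fusion of one evidence vector
#'
#' Bayes' rule over the two hypotheses: the posterior of each hypothesis is
#' proportional to its prior times the combined likelihood of the evidence,
#' normalised by the total probability of the evidence. The MAP hypothesis
#' is selected and the site accepted iff MAP = VARIANT and its posterior
#' reaches the threshold `po`.
#'
#' @param model A `fusion_model`.
#' @param evidence Logical caller-evidence vector.
#' @return Object of class `posterior_result`: list with `posterior` (named
#'   vector summing to 1), `map_hypothesis` and `accepted`.
#' @export
fuse_posterior <- function(model, evidence) {
  stopifnot(inherits(model, "fusion_model"))
  joint <- model$priors * c(
    VARIANT = combined_likelihood(model, evidence, "VARIANT"),
    NO_VARIANT = combined_likelihood(model, evidence, "NO_VARIANT")
  )
  total <- sum(joint)
  if (total == 0) {
    stop("degenerate evidence: joint probability is zero under every hypothesis")
  }
  posterior <- joint / total
  map <- names(posterior)[which.max(posterior)]
  structure(
    list(posterior = posterior, map_hypothesis = map,
         accepted = map == "VARIANT" && posterior[[map]] >= model$po),
    class = "posterior_result"
  )
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("<posterior_result> MAP = ", x$map_hypothesis,
      " (P = ", signif(max(x$posterior), 4), "), ",
      if (x$accepted) "accepted" else "rejected", "\n", sep = "")
  invisible(x)
}

#' Fuse a merged call set under a fusion model
#'
#' Applies [fuse_posterior()] to every merged variant (vectorised in the
#' log domain) and returns the per-variant decisions.
#'
#' @param merged A `merged_callset` whose callers match the model's.
#' @param model A `fusion_model`.
#' @return Data frame: the merged variants plus `n_callers` (votes),
#'   `posterior_variant`, `map_hypothesis`, `accepted`.
#' @export
fuse_callsets <- function(merged, model) {
  stopifnot(inherits(merged, "merged_callset"), inherits(model, "fusion_model"))
  if (!identical(merged$callers, model$callers)) {
    stop("merged call set and model disagree on the caller panel")
  }
  ev <- merged$evidence
  loglik <- function(hyp) {
    p <- model$likelihoods[, hyp]
    ev %*% log(p) + (!ev) %*% log(1 - p)
  }
  lv <- loglik("VARIANT") + log(model$priors[["VARIANT"]])
  ln <- loglik("NO_VARIANT") + log(model$priors[["NO_VARIANT"]])
  m <- pmax(lv, ln)
  pv <- as.numeric(exp(lv - m) / (exp(lv - m) + exp(ln - m)))
  if (any(!is.finite(pv))) {
    stop("degenerate evidence: joint probability is zero under every hypothesis")
  }
  out <- merged$variants
  out$n_callers <- as.integer(rowSums(ev))
  out$posterior_variant <- pv
  out$map_hypothesis <- ifelse(pv >= 0.5, "VARIANT", "NO_VARIANT")
  out$accepted <- out$map_hypothesis == "VARIANT" & pv >= model$po
  out
}

#' Estimate caller firing probabilities from a truth set
#'
#' Confusion-based estimation over the candidate-site universe (the union of
#' all calls plus the truth set): `P(fire | VARIANT)` is the fraction of
#' truth variants each caller detected; `P(fire | NO_VARIANT)` is that
#' caller's false calls over the candidate non-variant sites. The empirical
#' prior `P(VARIANT)` on the same universe is also returned, so that priors
#' and likelihoods live on one sample space.
#'
#' @param callsets Named list of call-set data frames.
#' @param truth Truth data frame (non-empty).
#' @return List with `p_fire_variant`, `p_fire_novariant` (named numeric)
#'   and `prior_variant`.
#' @export
fit_caller_profiles <- function(callsets, truth) {
  if (is.null(truth) || nrow(truth) == 0L) {
    stop("estimation error: truth set is empty")
  }
  truth_keys <- unique(.variant_keys(truth))
  keysets <- lapply(callsets, function(cs) unique(.variant_keys(cs)))
  universe <- union(unlist(keysets, use.names = FALSE), truth_keys)
  n_nonvar <- length(universe) - length(truth_keys)
  p_v <- vapply(keysets, function(ks) {
    mean(truth_keys %in% ks)
  }, numeric(1))
  p_nv <- vapply(keysets, function(ks) {
    if (n_nonvar == 0L) 0 else length(setdiff(ks, truth_keys)) / n_nonvar
  }, numeric(1))
  list(p_fire_variant = p_v, p_fire_novariant = p_nv,
       prior_variant = length(truth_keys) / length(universe))
}
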