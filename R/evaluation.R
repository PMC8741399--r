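# Truth matching, precision/recall, and the depth-series simulation driver
# reproducing the qualitative depth trend: with rising sequencing depth both
# precision and recall improve for every caller and for the fused method.

#' Match calls to a truth set
#'
#' A call is a true positive iff its normalised `(chrom, pos, ref, alt)` key
#' exactly equals a truth record; each truth record can be matched at most
#' once. Counts are reported separately for SNVs and indels.
#'
#' @param calls Call-set data frame (`chrom`, `pos`, `ref`, `alt`).
#' @param truth Truth data frame.
#' @return Data frame with one row per class (`SNP`, `InDel`): `TP`, `FP`,
#'   `FN`.
#' @export
match_calls_to_truth <- function(calls, truth) {
  call_keys <- unique(.variant_keys(calls))
  truth_keys <- unique(.variant_keys(truth))
  call_cls <- .variant_class(
    sub("^[^\r]*\r[^\r]*\r([^\r]*)\r.*$", "\\1", call_keys),
    sub("^.*\r", "", call_keys)
  )
  truth_cls <- .variant_class(
    sub("^[^\r]*\r[^\r]*\r([^\r]*)\r.*$", "\\1", truth_keys),
    sub("^.*\r", "", truth_keys)
  )
  out <- lapply(c("SNP", "InDel"), function(cl) {
    ck <- call_keys[call_cls == cl]
    tk <- truth_keys[truth_cls == cl]
    data.frame(class = cl,
               TP = length(intersect(ck, tk)),
               FP = length(setdiff(ck, tk)),
               FN = length(setdiff(tk, ck)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Precision and recall from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`. An undefined
#' ratio (0/0) is reported as `NA` with a warning, never as 0.
#'
#' @param counts Data frame with columns `TP`, `FP`, `FN` (e.g. from
#'   [match_calls_to_truth()]).
#' @return The data frame with `precision` and `recall` columns appended.
#' @export
precision_recall <- function(counts) {
  stopifnot(all(c("TP", "FP", "FN") %in% names(counts)))
  if (any(counts$TP < 0 | counts$FP < 0 | counts$FN < 0)) {
    stop("counts must be non-negative")
  }
  prec_den <- counts$TP + counts$FP
  rec_den <- counts$TP + counts$FN
  if (any(prec_den == 0) || any(rec_den == 0)) {
    warning("undefined ratio (0/0) reported as NA")
  }
  counts$precision <- ifelse(prec_den > 0, counts$TP / prec_den, NA_real_)
  counts$recall <- ifelse(rec_den > 0, counts$TP / rec_den, NA_real_)
  counts
}

.eval_method <- function(calls, truth, method, depth, seed) {
  pr <- precision_recall(match_calls_to_truth(calls, truth))
  cbind(data.frame(method = method, depth = depth, seed = seed,
                   stringsAsFactors = FALSE),
        pr)
}

#' Depth-series simulation experiment
#'
#' For each seed and depth: generates a reference, implants a truth set,
#' simulates the caller panel's call sets, hard-filters them, evaluates each
#' caller against the truth, then merges the filtered sets, fits the fusion
#' model on the candidate-site universe (per-caller firing probabilities and
#' the empirical variant prior) and evaluates the fused accepted set. Also
#' accumulates caller-overlap (Venn) counts per depth.
#'
#' Fitted firing probabilities are clamped to `[1e-6, 1 - 1e-6]` before
#' entering the model so that a caller that detects everything (or nothing)
#' cannot produce a zero joint probability.
#'
#' @param genome_length Simulated genome length in bp (default 200000).
#' @param n_snp,n_indel Implanted truth-set sizes (defaults 300 and 200,
#'   i.e. the classical 3:2 SNV:indel ratio at 1/10 scale).
#' @param depths Sequencing depths to sweep (default
#'   `c(50, 100, 150, 200, 250, 300)`).
#' @param n_seeds Number of replicate seeds (default 20). A single-seed run
#'   triggers a warning.
#' @param profiles Caller panel, default [default_caller_profiles()].
#' @param po Fusion decision threshold (default 0.5).
#' @param min_depth,min_qual Hard-filter thresholds (strict; defaults 10
#'   and 30).
#' @param gc_fraction Reference GC target (default 0.49).
#' @param seed Base seed from which per-replicate seeds are derived.
#' @return Object of class `depth_series`: list with `results` (long data
#'   frame: `method`, `depth`, `seed`, `class`, `TP`, `FP`, `FN`,
#'   `precision`, `recall`), `summary` (mean and sd over seeds per method x
#'   depth x class), `overlap` (Venn counts per depth, summed over seeds)
#'   and `config`.
#' @export
depth_series_experiment <- function(genome_length = 200000L,
                                    n_snp = 300L, n_indel = 200L,
                                    depths = c(50L, 100L, 150L, 200L, 250L, 300L),
                                    n_seeds = 20L,
                                    profiles = default_caller_profiles(),
                                    po = 0.5, min_depth = 10, min_qual = 30,
                                    gc_fraction = 0.49, seed = 1L) {
  if (length(profiles) == 0L) {
    stop("configuration error: no caller profiles supplied")
  }
  if (n_seeds < 2L) {
    warning("single-seed run: dispersion estimates will be unavailable")
  }
  rows <- list()
  overlap_acc <- NULL
  for (s in seq_len(n_seeds)) {
    seed_s <- (as.integer(seed) * 10007L + s * 131L) %% 2147483L
    ref <- generate_reference(genome_length, gc_fraction, seed = seed_s)
    imp <- implant_variants(ref, n_snp, n_indel, seed = seed_s + 1L)
    truth <- imp$truth
    for (d in depths) {
      callsets <- simulate_caller_callsets(truth, profiles, depth = d,
                                           seed = seed_s + as.integer(d),
                                           genome = ref)
      filtered <- lapply(callsets, hard_filter,
                         min_depth = min_depth, min_qual = min_qual)
      for (nm in names(filtered)) {
        rows[[length(rows) + 1L]] <-
          .eval_method(filtered[[nm]], truth, nm, d, s)
      }
      fit <- fit_caller_profiles(filtered, truth)
      clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
      model <- fusion_model(clamp(fit$p_fire_variant),
                            clamp(fit$p_fire_novariant),
                            prior_variant = clamp(fit$prior_variant),
                            po = po)
      merged <- merge_callsets(filtered, normalize = FALSE)
      fused <- fuse_callsets(merged, model)
      rows[[length(rows) + 1L]] <-
        .eval_method(fused[fused$accepted, , drop = FALSE], truth,
                     "fused", d, s)
      ov <- callset_overlap(filtered)
      ov$depth <- d
      overlap_acc <- rbind(overlap_acc, ov)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- stats::aggregate(
    cbind(TP, FP, FN, precision, recall) ~ method + depth + class,
    data = results,
    FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                        sd = stats::sd(v))
  )
  summary <- do.call(
    data.frame,
    c(summary[c("method", "depth", "class")],
      lapply(summary[c("TP", "FP", "FN", "precision", "recall")],
             function(m) m[, "mean"]),
      list(precision_sd = summary$precision[, "sd"],
           recall_sd = summary$recall[, "sd"]))
  )
  summary <- summary[order(summary$class, summary$method, summary$depth), ]
  rownames(summary) <- NULL
  overlap <- stats::aggregate(count ~ sources + n_sources + depth,
                              data = overlap_acc, FUN = sum)
  structure(
    list(results = results, summary = summary, overlap = overlap,
         config = list(genome_length = genome_length, n_snp = n_snp,
                       n_indel = n_indel, depths = depths,
                       n_seeds = n_seeds, po = po, min_depth = min_depth,
                       min_qual = min_qual, gc_fraction = gc_fraction,
                       seed = seed,
                       callers = names(profiles))),
    class = "depth_series"
  )
}

#' @export
print.depth_series <- function(x, ...) {
  cfg <- x$config
  cat("<depth_series> ", cfg$genome_length, " bp genome, ", cfg$n_snp,
      " SNV + ", cfg$n_indel, " indel truth, depths ",
      paste(cfg$depths, collapse = "/"), ", ", cfg$n_seeds, " seed(s)\n",
      sep = "")
  cat("Mean recall by method and depth (SNP):\n")
  snp <- x$summary[x$summary$class == "SNP", ]
  print(round(stats::xtabs(recall ~ method + depth, data = snp), 3))
  invisible(x)
}

#' Plot recall (or precision) against depth per method
#'
#' @param x A `depth_series` object.
#' @param metric `"recall"` or `"precision"`.
#' @param class `"SNP"` or `"InDel"`.
#' @param ... Passed to [graphics::matplot()].
#' @return The plotted matrix (depths x methods), invisibly.
#' @export
plot.depth_series <- function(x, metric = c("recall", "precision"),
                              class = c("SNP", "InDel"), ...) {
  metric <- match.arg(metric)
  class_ <- match.arg(class)
  sub <- x$summary[x$summary$class == class_, ]
  wide <- stats::xtabs(stats::as.formula(paste(metric, "~ depth + method")),
                       data = sub)
  graphics::matplot(as.numeric(rownames(wide)), wide, type = "b", pch = 19,
                    lty = 1, xlab = "depth (x)", ylab = metric,
                    main = paste(class_, metric, "vs depth"), ...)
  graphics::legend("bottomright", legend = colnames(wide),
                   col = seq_len(ncol(wide)), pch = 19, lty = 1, bty = "n")
  invisible(wide)
}

#' Spearman correlation between depth and a metric, per method
#'
#' Convenience check of the depth trend on a [depth_series_experiment()]
#' summary: positive values mean the metric improves with depth.
#'
#' @param series A `depth_series` object.
#' @param metric `"recall"` or `"precision"`.
#' @return Data frame with `method`, `class`, `spearman`.
#' @export
depth_trend <- function(series, metric = c("recall", "precision")) {
  metric <- match.arg(metric)
  sub <- series$summary
  out <- expand.grid(method = unique(sub$method),
                     class = unique(sub$class),
                     stringsAsFactors = FALSE)
  out$spearman <- mapply(function(m, cl) {
    rows <- sub[sub$method == m & sub$class == cl, ]
    stats::cor(rows$depth, rows[[metric]], method = "spearman")
  }, out$method, out$class)
  out
}
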