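# VCF 4.2 interchange for call sets. Reading goes through vcfR; writing is a
# minimal plain-text VCF 4.2 emitter (CHROM..INFO with DP and CALLER keys,
# plus NCALLERS/POSTERIOR/MAP for fused output).

#' Write a call set to a VCF 4.2 file
#'
#' Emits a sites-only plain-text VCF with `QUAL` filled from the `qual`
#' column and `DP` (and, when present, `CALLER`, `NCALLERS`, `POSTERIOR`,
#' `MAP`) in `INFO`.
#'
#' @param calls Call-set data frame (`chrom`, `pos`, `ref`, `alt`, optional
#'   `qual`, `depth`, `caller`, `n_callers`, `posterior_variant`,
#'   `map_hypothesis`).
#' @param path Output path.
#' @param source_tag Value for the `##source=` header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, source_tag = "varfuse") {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at the site">',
    '##INFO=<ID=CALLER,Number=1,Type=String,Description="Originating caller">',
    '##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description="Callers supporting the site">',
    '##INFO=<ID=POSTERIOR,Number=1,Type=Float,Description="Posterior probability of the VARIANT hypothesis">',
    '##INFO=<ID=MAP,Number=1,Type=String,Description="Maximum a posteriori hypothesis">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- rep("", nrow(calls))
  add <- function(info, key, val, fmt = "%s") {
    piece <- paste0(key, "=", sprintf(fmt, val))
    ifelse(nzchar(info), paste(info, piece, sep = ";"), piece)
  }
  if ("depth" %in% names(calls)) info <- add(info, "DP", calls$depth, "%d")
  if ("caller" %in% names(calls)) info <- add(info, "CALLER", calls$caller)
  if ("n_callers" %in% names(calls)) {
    info <- add(info, "NCALLERS", calls$n_callers, "%d")
  }
  if ("posterior_variant" %in% names(calls)) {
    info <- add(info, "POSTERIOR", calls$posterior_variant, "%.6g")
  }
  if ("map_hypothesis" %in% names(calls)) {
    info <- add(info, "MAP", calls$map_hypothesis)
  }
  info[!nzchar(info)] <- "."
  qual <- if ("qual" %in% names(calls)) {
    sprintf("%.4g", calls$qual)
  } else {
    rep(".", nrow(calls))
  }
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                qual, ".", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF file into a call-set data frame
#'
#' Parses a VCF 4.2 file with [vcfR::read.vcfR()] and extracts the fixed
#' columns plus `DP` from `INFO`. Multi-allelic `ALT` entries are split into
#' one row per alternate allele.
#'
#' @param path Path to a VCF file.
#' @param caller Caller label to attach; defaults to the `CALLER` INFO field
#'   when present, else the file name.
#' @return Call-set data frame (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `depth`, `caller`).
#' @export
read_vcf_calls <- function(path, caller = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  grab <- function(key) {
    pat <- paste0("(?:^|;)", key, "=[^;]*")
    vapply(regmatches(info, gregexpr(pat, info, perl = TRUE)),
           function(x) {
             if (length(x)) sub(paste0("^;?", key, "="), "", x[[1L]])
             else NA_character_
           },
           character(1))
  }
  dp <- suppressWarnings(as.integer(grab("DP")))
  src <- grab("CALLER")
  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    depth = dp,
    stringsAsFactors = FALSE
  )
  # split multi-allelic rows
  multi <- grepl(",", out$alt, fixed = TRUE)
  if (any(multi)) {
    expanded <- lapply(which(multi), function(i) {
      alts <- strsplit(out$alt[i], ",", fixed = TRUE)[[1L]]
      row <- out[rep(i, length(alts)), , drop = FALSE]
      row$alt <- alts
      row
    })
    out <- rbind(out[!multi, , drop = FALSE], do.call(rbind, expanded))
    out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  }
  out$caller <- if (!is.null(caller)) {
    caller
  } else if (!all(is.na(src))) {
    src
  } else {
    sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  rownames(out) <- NULL
  out
}
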