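#' Bin read coverage in non-overlapping windows
#'
#' Depth is base-resolution: the number of aligned reference bases (M and
#' D CIGAR operations) overlapping a window, divided by the window width.
#' Windows tile each chromosome (default 100 bp; the terminal window may
#' be shorter). Records flagged as PCR duplicates are skipped.
#'
#' @param alignments alignment table (see [read_sam()]).
#' @param genome named character vector of chromosome sequences.
#' @param config a [pipeline_config()].
#' @param accession accession label stored on the profile.
#' @return A `"coverage_profile"`: list with `accession`, `windows` (data
#'   frame: `chrom`, `start`, `end`, `gc_frac`, `raw_rc`, `corr_rc`) and
#'   `genome_median_rc`. Before GC correction `corr_rc == raw_rc`.
#' @export
bin_coverage <- function(alignments, genome, config = pipeline_config(),
                         accession = "acc") {
  aln <- alignments[alignments$mapped & !alignments$is_dup, , drop = FALSE]
  offenders <- setdiff(unique(aln$ref_name), names(genome))
  if (length(offenders)) {
    stop("alignment chromosome(s) absent from genome: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  reflen <- integer(nrow(aln))
  simple <- grepl("^[0-9]+M$", aln$cigar)
  reflen[simple] <- as.integer(sub("M$", "", aln$cigar[simple]))
  if (any(!simple)) {
    reflen[!simple] <- vapply(aln$cigar[!simple], cigar_ref_len, numeric(1))
  }
  win <- lapply(names(genome), function(ch) {
    L <- nchar(genome[[ch]])
    starts <- seq.int(0L, L - 1L, by = config$window_bp)
    ends <- pmin(starts + config$window_bp, L)
    a <- which(aln$ref_name == ch)
    cov <- IRanges::coverage(IRanges::IRanges(start = aln$pos[a] + 1L,
                                              width = reflen[a]),
                             width = L)
    sums <- IRanges::viewSums(IRanges::Views(cov, start = starts + 1L,
                                             end = ends))
    v <- Biostrings::Views(Biostrings::DNAString(genome[[ch]]),
                           start = starts + 1L, end = ends)
    gc <- as.numeric(Biostrings::letterFrequency(v, "GC")) / (ends - starts)
    data.frame(chrom = ch, start = starts, end = ends, gc_frac = gc,
               raw_rc = sums / (ends - starts), stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win)
  rownames(windows) <- NULL
  windows$corr_rc <- windows$raw_rc
  out <- list(accession = accession, windows = windows,
              genome_median_rc = stats::median(windows$raw_rc))
  class(out) <- "coverage_profile"
  out
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Coverage profile '", x$accession, "': ", nrow(x$windows),
      " windows on ", length(unique(x$windows$chrom)),
      " chromosome(s); genome median depth ",
      signif(x$genome_median_rc, 4), "\n", sep = "")
  invisible(x)
}

#' GC-correct a coverage profile
#'
#' Each window's depth is rescaled by the ratio of the genome-wide median
#' depth to the median depth of all windows sharing its integer GC
#' percentage: `corr_rc = raw_rc * m / m_GC`. GC bins holding fewer than
#' `min_bin_windows` windows fall back to the uncorrected value.
#'
#' @param profile a `"coverage_profile"`.
#' @param config a [pipeline_config()].
#' @param min_bin_windows minimum windows per integer-GC bin.
#' @return The profile with `corr_rc` and `genome_median_rc` updated.
#' @export
gc_correct <- function(profile, config = pipeline_config(),
                       min_bin_windows = 10L) {
  w <- profile$windows
  if (nrow(w) == 0) stop("empty profile", call. = FALSE)
  m <- stats::median(w$raw_rc)
  if (m == 0) stop("degenerate profile: genome-wide median depth is zero",
                   call. = FALSE)
  gc_pct <- as.integer(round(w$gc_frac * 100))
  med_by_bin <- tapply(w$raw_rc, gc_pct, stats::median)
  n_by_bin <- tapply(w$raw_rc, gc_pct, length)
  key <- as.character(gc_pct)
  m_gc <- as.numeric(med_by_bin[key])
  n_gc <- as.numeric(n_by_bin[key])
  corr <- w$raw_rc * m / m_gc
  fallback <- n_gc < min_bin_windows | m_gc == 0
  corr[fallback] <- w$raw_rc[fallback]
  profile$windows$corr_rc <- corr
  profile$genome_median_rc <- stats::median(corr)
  profile
}

unscaled_mad <- function(x) stats::median(abs(x - stats::median(x)))

#' Detect aberrant-coverage regions from two control profiles
#'
#' A window is flagged when its (GC-corrected) depth deviates from the
#' profile median by more than `mad_k` unscaled median absolute
#' deviations in either control. Runs of flagged windows, allowing a
#' single unflagged gap window, are merged into mask segments.
#'
#' @param profile_ctrl_a,profile_ctrl_b control `"coverage_profile"`s on
#'   the same windows (two reference re-sequencing runs).
#' @param config a [pipeline_config()].
#' @return Mask segments: data frame `chrom`, `start`, `end`, `reason`
#'   (`high_coverage` / `low_coverage`).
#' @export
detect_aberrant_regions <- function(profile_ctrl_a, profile_ctrl_b,
                                    config = pipeline_config()) {
  wa <- profile_ctrl_a$windows
  wb <- profile_ctrl_b$windows
  if (!identical(wa[c("chrom", "start", "end")],
                 wb[c("chrom", "start", "end")])) {
    stop("control profiles are not on the same windows", call. = FALSE)
  }
  flag_one <- function(x) {
    med <- stats::median(x)
    madv <- unscaled_mad(x)
    dev <- x - med
    list(flag = abs(dev) > config$mad_k * madv, high = dev > 0)
  }
  fa <- flag_one(wa$corr_rc)
  fb <- flag_one(wb$corr_rc)
  flagged <- fa$flag | fb$flag
  high <- ifelse(fa$flag, fa$high, fb$high)
  segs <- lapply(unique(wa$chrom), function(ch) {
    i <- which(wa$chrom == ch)
    f <- flagged[i]
    n <- length(f)
    if (!any(f)) return(NULL)
    # bridge single-window gaps between flagged neighbours
    bridged <- f
    if (n >= 3) {
      gap <- !f & c(FALSE, f[-n]) & c(f[-1], FALSE)
      bridged <- f | gap
    }
    r <- rle(bridged)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = ch,
               start = wa$start[i[starts_i[keep]]],
               end = wa$end[i[ends_i[keep]]],
               reason = vapply(keep, function(k) {
                 idx <- i[starts_i[k]:ends_i[k]]
                 if (mean(high[idx][flagged[idx]]) >= 0.5) "high_coverage"
                 else "low_coverage"
               }, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# indices of profile windows overlapping a family's pseudo-annotation
# (copies >= the length filter) and not overlapping masks
family_window_idx <- function(profile, annotations, family,
                              config = pipeline_config(), masks = NULL,
                              consensus_len = NULL) {
  ann <- annotations[annotations$family == family, , drop = FALSE]
  ann$copy_length <- ann$end - ann$start
  min_len <- if (config$gwas_mode_half_length) {
    if (is.null(consensus_len)) {
      stop("gwas_mode_half_length requires consensus_len", call. = FALSE)
    }
    consensus_len / 2
  } else config$min_te_len_cnv
  ann <- ann[ann$copy_length >= min_len, , drop = FALSE]
  if (nrow(ann) == 0) return(list(idx = integer(0), n_copies = 0L))
  w <- profile$windows
  idx <- which(overlaps_any(w, ann))
  if (!is.null(masks) && nrow(masks)) {
    idx <- idx[!overlaps_any(w[idx, , drop = FALSE], masks)]
  }
  list(idx = idx, n_copies = nrow(ann))
}

#' Aggregated per-family copy number from read depth
#'
#' Copy number is estimated over the family's joined pseudo-annotation
#' (annotated copies at least `min_te_len_cnv` bp, or at least half the
#' consensus length in GWAS mode) as
#' `n_ref_copies * [sum corr_rc(acc)/median(acc)] / [sum corr_rc(ref)/median(ref)]`
#' where medians are genome-wide. Windows overlapping `masks` are
#' excluded. Returns `NA` (untestable) when the pseudo-annotation is
#' empty after filtering.
#'
#' @param profile accession `"coverage_profile"` (GC-corrected).
#' @param annotations TE annotation data frame: `chrom`, `start`, `end`,
#'   `family`.
#' @param family family name.
#' @param reference_profile reference `"coverage_profile"`.
#' @param config a [pipeline_config()].
#' @param masks optional mask segments to exclude.
#' @param consensus_len family consensus length (GWAS mode only).
#' @return Estimated copy number (float), or `NA_real_` if untestable.
#' @export
family_copy_number <- function(profile, annotations, family,
                               reference_profile,
                               config = pipeline_config(), masks = NULL,
                               consensus_len = NULL) {
  sel <- family_window_idx(reference_profile, annotations, family, config,
                           masks, consensus_len)
  if (length(sel$idx) == 0) return(NA_real_)
  acc <- sum(profile$windows$corr_rc[sel$idx]) / profile$genome_median_rc
  ref <- sum(reference_profile$windows$corr_rc[sel$idx]) /
    reference_profile$genome_median_rc
  if (ref == 0) return(NA_real_)
  sel$n_copies * acc / ref
}

#' Per-window sign-flip permutation test for copy-number difference
#'
#' The statistic is the absolute difference of means between accession
#' and reference per-window normalized depths over the family's
#' pseudo-annotation. The null swaps accession/reference labels
#' independently per window (windows are paired, so the swap conditions
#' on locus effects). The test is run against each of the two reference
#' replicates and the maximum (most conservative) p-value is returned.
#' P-values carry the +1 correction and are never exactly zero.
#'
#' @param acc_values accession per-window normalized depths.
#' @param ref_values_a,ref_values_b matching reference depths.
#' @param n_perm number of label swaps.
#' @param seed integer seed.
#' @return p-value in (0, 1], or `NA` when fewer than 2 windows.
#' @export
cnv_permutation_test <- function(acc_values, ref_values_a, ref_values_b,
                                 n_perm = 999L, seed = 1L) {
  n <- length(acc_values)
  if (n < 2L) return(NA_real_)
  stopifnot(length(ref_values_a) == n, length(ref_values_b) == n)
  with_seed(seed, {
    one <- function(ref) {
      d <- acc_values - ref
      obs <- abs(mean(d))
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      null <- abs(as.numeric(signs %*% d) / n)
      (1 + sum(null >= obs)) / (1 + n_perm)
    }
    max(one(ref_values_a), one(ref_values_b))
  })
}

#' Empirical false discovery rate from a null p-value sample
#'
#' `fdr(p)` is the fraction of null p-values at or below `p`, the null
#' sample being built by randomizing TE-annotation labels over coverage
#' windows (see [cnv_null_pvalues()]).
#'
#' @param observed_p observed p-value(s).
#' @param null_p_sample numeric vector of null p-values.
#' @return Empirical FDR for each observed p-value.
#' @export
empirical_fdr <- function(observed_p, null_p_sample) {
  if (length(null_p_sample) == 0) stop("empty null p-value sample",
                                       call. = FALSE)
  vapply(observed_p, function(p) mean(null_p_sample <= p), numeric(1))
}

#' Null p-values by randomizing annotation labels over windows
#'
#' Draws random window sets of the same size as a family's
#' pseudo-annotation and recomputes the permutation test, yielding the
#' empirical null distribution used by [empirical_fdr()].
#'
#' @param profile,ref_profile_a,ref_profile_b `"coverage_profile"`s on
#'   identical windows.
#' @param n_windows size of each random window set.
#' @param n_draws number of null draws.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return Numeric vector of `n_draws` null p-values.
#' @export
cnv_null_pvalues <- function(profile, ref_profile_a, ref_profile_b,
                             n_windows, n_draws = 1000L, n_perm = 199L,
                             seed = 1L) {
  acc <- profile$windows$corr_rc / profile$genome_median_rc
  ra <- ref_profile_a$windows$corr_rc / ref_profile_a$genome_median_rc
  rb <- ref_profile_b$windows$corr_rc / ref_profile_b$genome_median_rc
  n <- length(acc)
  with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(n, n_windows)
      cnv_permutation_test(acc[idx], ra[idx], rb[idx], n_perm = n_perm,
                           seed = sample.int(.Machine$integer.max, 1))
    }, numeric(1))
  })
}

#' Family-level CNV scan of one accession against two references
#'
#' For each family: copy number via [family_copy_number()], a
#' permutation p-value (maximum over the two references), an empirical
#' FDR from annotation-label randomization, and a significance flag at
#' `config$cnv_fdr_threshold`.
#'
#' @param profile accession profile (GC-corrected).
#' @param ref_profile_a,ref_profile_b reference profiles (GC-corrected).
#' @param annotations TE annotations (`chrom`, `start`, `end`, `family`).
#' @param families character vector of family names to test.
#' @param config a [pipeline_config()].
#' @param masks optional mask segments.
#' @param n_null null draws for the empirical FDR.
#' @param seed integer seed.
#' @return Data frame of class `"cnv_calls"`: `accession`, `family`,
#'   `cn_est`, `p_value`, `fdr`, `significant`.
#' @export
cnv_scan <- function(profile, ref_profile_a, ref_profile_b, annotations,
                     families, config = pipeline_config(), masks = NULL,
                     n_null = 1000L, seed = 1L) {
  acc <- profile$windows$corr_rc / profile$genome_median_rc
  ra <- ref_profile_a$windows$corr_rc / ref_profile_a$genome_median_rc
  rb <- ref_profile_b$windows$corr_rc / ref_profile_b$genome_median_rc
  rows <- lapply(seq_along(families), function(k) {
    fam <- families[k]
    sel <- family_window_idx(ref_profile_a, annotations, fam, config, masks)
    cn <- family_copy_number(profile, annotations, fam, ref_profile_a,
                             config, masks)
    if (length(sel$idx) < 2L) {
      return(data.frame(accession = profile$accession, family = fam,
                        cn_est = cn, p_value = NA_real_, fdr = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    p <- cnv_permutation_test(acc[sel$idx], ra[sel$idx], rb[sel$idx],
                              n_perm = config$n_perm, seed = seed + k)
    null_p <- cnv_null_pvalues(profile, ref_profile_a, ref_profile_b,
                               n_windows = length(sel$idx),
                               n_draws = n_null,
                               n_perm = min(config$n_perm, 199L),
                               seed = seed + 1000L + k)
    fdr <- empirical_fdr(p, null_p)
    data.frame(accession = profile$accession, family = fam, cn_est = cn,
               p_value = p, fdr = fdr,
               significant = fdr < config$cnv_fdr_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cnv_calls", class(out))
  out
}
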