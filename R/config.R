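#' Pipeline configuration
#'
#' All tunable constants of the pipeline in a single validated list. The
#' defaults reproduce the published analysis settings; every value can be
#' overridden programmatically or from a flat `key=value` file (see
#' [read_config()]).
#'
#' @param window_bp coverage window width in bp (non-overlapping bins).
#' @param extremity_len length in bp of the 5'/3' TE extremities used as
#'   forced-mapping targets.
#' @param min_clip minimum soft-clip (and minimum anchor) length in nt; a
#'   split read must align to a TE extremity with exactly one terminal
#'   clip of at least this many nt, and recursive re-mapping stops when
#'   the clipped fragment would shrink below it.
#' @param min_reads_discovery minimum reads per clip cluster (each side)
#'   to call an insertion at discovery.
#' @param min_reads_genotype minimum spanning split reads to genotype an
#'   insertion as present in a further accession.
#' @param tsd_overlap_factor maximum allowed TSD interval width, as a
#'   multiple of the family TSD length.
#' @param mad_k number of (unscaled) median absolute deviations defining
#'   coverage outliers.
#' @param cohort_freq_filter carrier fraction at or above which a call is
#'   flagged as a likely artifact.
#' @param cnv_fdr_threshold empirical FDR below which a family CNV is
#'   declared significant.
#' @param enrich_tail upper tail probability of the randomization null
#'   declaring a 10-kb window enriched.
#' @param spread_short_bp,spread_long_bp distance landmarks (bp)
#'   separating short-, intermediate- and long-distance methylation
#'   spreading.
#' @param meth_window_bp width of the methylation windows flanking an
#'   insertion site.
#' @param meth_diff_threshold carrier minus non-carrier methylation
#'   difference below which spreading is considered to have ended.
#' @param min_te_len_cnv minimum annotated copy length (bp) entering the
#'   per-family pseudo-annotation for copy-number estimation.
#' @param short_family_bp families whose annotated copies are all shorter
#'   than this are excluded from copy-number analysis.
#' @param gwas_mode_half_length if `TRUE`, the pseudo-annotation instead
#'   keeps copies at least half the length of the family consensus.
#' @param te_annotation_superfamilies superfamilies for which calls
#'   overlapping annotated TE sequence are flagged.
#' @param genotype_tol_bp tolerance (bp) around the TSD interval when
#'   counting genotyping reads.
#' @param n_perm number of permutations / randomization iterations for
#'   the permutation-based statistics.
#' @param rng_seed integer seed used by operations that draw random
#'   numbers and are not passed an explicit seed.
#' @param ... ignored; reserved for forward compatibility.
#'
#' @return An object of class `"pipeline_config"`: a named list of
#'   validated settings.
#' @examples
#' cfg <- pipeline_config(min_reads_discovery = 3)
#' cfg$min_clip
#' @export
pipeline_config <- function(window_bp = 100,
                            extremity_len = 300,
                            min_clip = 20,
                            min_reads_discovery = 5,
                            min_reads_genotype = 2,
                            tsd_overlap_factor = 2,
                            mad_k = 3,
                            cohort_freq_filter = 0.5,
                            cnv_fdr_threshold = 1e-5,
                            enrich_tail = 5e-5,
                            spread_short_bp = 300,
                            spread_long_bp = 1000,
                            meth_window_bp = 50,
                            meth_diff_threshold = 0.2,
                            min_te_len_cnv = 300,
                            short_family_bp = 350,
                            gwas_mode_half_length = FALSE,
                            te_annotation_superfamilies = c("ATHILA", "GYPSY"),
                            genotype_tol_bp = 2,
                            n_perm = 999,
                            rng_seed = 1L,
                            ...) {
  cfg <- list(
    window_bp = as.integer(window_bp),
    extremity_len = as.integer(extremity_len),
    min_clip = as.integer(min_clip),
    min_reads_discovery = as.integer(min_reads_discovery),
    min_reads_genotype = as.integer(min_reads_genotype),
    tsd_overlap_factor = as.numeric(tsd_overlap_factor),
    mad_k = as.numeric(mad_k),
    cohort_freq_filter = as.numeric(cohort_freq_filter),
    cnv_fdr_threshold = as.numeric(cnv_fdr_threshold),
    enrich_tail = as.numeric(enrich_tail),
    spread_short_bp = as.integer(spread_short_bp),
    spread_long_bp = as.integer(spread_long_bp),
    meth_window_bp = as.integer(meth_window_bp),
    meth_diff_threshold = as.numeric(meth_diff_threshold),
    min_te_len_cnv = as.integer(min_te_len_cnv),
    short_family_bp = as.integer(short_family_bp),
    gwas_mode_half_length = isTRUE(gwas_mode_half_length),
    te_annotation_superfamilies = as.character(te_annotation_superfamilies),
    genotype_tol_bp = as.integer(genotype_tol_bp),
    n_perm = as.integer(n_perm),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("window_bp", "extremity_len", "min_clip", "min_reads_discovery",
           "min_reads_genotype", "tsd_overlap_factor", "mad_k",
           "cnv_fdr_threshold", "spread_short_bp", "spread_long_bp",
           "meth_window_bp", "min_te_len_cnv", "short_family_bp", "n_perm")
  for (k in pos) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("config: '", k, "' must be strictly positive", call. = FALSE)
    }
  }
  if (cfg$cohort_freq_filter <= 0 || cfg$cohort_freq_filter > 1) {
    stop("config: 'cohort_freq_filter' must lie in (0, 1]", call. = FALSE)
  }
  for (k in c("cnv_fdr_threshold", "enrich_tail")) {
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1) {
      stop("config: '", k, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$genotype_tol_bp < 0) stop("config: 'genotype_tol_bp' must be >= 0",
                                    call. = FALSE)
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (", length(x), " settings)\n", sep = "")
  for (k in names(x)) {
    cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = ",")))
  }
  invisible(x)
}

#' Read or write a configuration file
#'
#' Flat `key=value` dialect: one setting per line, `#` starts a comment,
#' blank lines ignored. Values are parsed as numeric where possible,
#' `TRUE`/`FALSE` as logical, and comma-separated values as vectors.
#' Unknown keys are rejected.
#'
#' @param path file path.
#' @param base configuration the file overrides; defaults to
#'   [pipeline_config()] defaults.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` writes `cfg` and returns `path` invisibly.
#' @export
read_config <- function(path, base = pipeline_config()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config: line is not key=value: '", ln, "'", call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(base)) {
      stop("config: unknown key '", key, "'", call. = FALSE)
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    suppressWarnings(num <- as.numeric(parts))
    if (!anyNA(num)) {
      overrides[[key]] <- num
    } else if (all(toupper(parts) %in% c("TRUE", "FALSE"))) {
      overrides[[key]] <- as.logical(toupper(parts))
    } else {
      overrides[[key]] <- parts
    }
  }
  args <- utils::modifyList(unclass(base), overrides)
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lines <- vapply(names(cfg), function(k) {
    paste0(k, "=", paste(cfg[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
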