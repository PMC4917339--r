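#' Randomize positions across a genome
#'
#' Places `n` items uniformly over the allowed bases of the genome
#' (total length minus exclusion zones), `n_iter` times. This is the
#' randomization null behind the positional enrichment statistics.
#'
#' @param n number of items per iteration.
#' @param genome named character vector of sequences, or a named integer
#'   vector of chromosome lengths.
#' @param exclusions interval data frame of excluded regions (aberrant
#'   coverage, inner pericentromeres, donor TE sequences), or `NULL`.
#' @param n_iter number of iterations (must be >= 1).
#' @param seed integer seed.
#' @return Object of class `"randomization_null"`: allowed space, and an
#'   `n_iter x n` matrix of placements encoded as global offsets into the
#'   allowed space. Use [null_positions()] to decode an iteration.
#' @export
randomize_positions <- function(n, genome, exclusions = NULL,
                                n_iter = 1000L, seed = 1L) {
  lens <- if (is.character(genome)) nchar(genome) else genome
  allowed <- complement_intervals(lens, exclusions)
  if (nrow(allowed) == 0) stop("allowed space is empty", call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be >= 1 (empty null)", call. = FALSE)
  w <- allowed$end - allowed$start
  total <- sum(as.numeric(w))
  offsets <- with_seed(seed, {
    matrix(floor(runif(n_iter * n) * total), nrow = n_iter)
  })
  out <- list(n = n, n_iter = n_iter, allowed = allowed,
              cum = cumsum(as.numeric(w)) - w, total = total,
              offsets = offsets, genome_lengths = lens)
  class(out) <- "randomization_null"
  out
}

#' Decode one iteration of a randomization null
#' @param null a `"randomization_null"`.
#' @param iter iteration index.
#' @return Data frame `chrom`, `pos` (0-based positions).
#' @export
null_positions <- function(null, iter = 1L) {
  off <- null$offsets[iter, ]
  idx <- findInterval(off, null$cum)
  data.frame(chrom = null$allowed$chrom[idx],
             pos = as.integer(null$allowed$start[idx] + (off - null$cum[idx])),
             stringsAsFactors = FALSE)
}

# fraction of points falling inside a region set, per null iteration
null_region_fractions <- function(null, regions) {
  vapply(seq_len(null$n_iter), function(it) {
    p <- null_positions(null, it)
    mean(points_in_regions(p$chrom, p$pos, regions))
  }, numeric(1))
}

points_in_regions <- function(chrom, pos, regions) {
  df <- data.frame(chrom = chrom, start = pos, end = pos + 1L,
                   stringsAsFactors = FALSE)
  overlaps_any(df, regions)
}

#' Pericentromeric enrichment by allele-count class
#'
#' Compares, per carrier-count stratum (private, shared by 2-10, shared
#' by more than 10), the observed fraction of insertions inside
#' pericentromeric regions with the randomization-null expectation;
#' reports the observed/expected ratio with null-quantile 95% confidence
#' bounds and a 1-df chi-square p-value on in/out counts.
#'
#' @param calls_by_class named list of call data frames (one per
#'   stratum; calls need `chrom` and `start`).
#' @param pericentromeres interval data frame.
#' @param null a [randomize_positions()] null.
#' @return Data frame: `class`, `n`, `observed`, `expected_mean`,
#'   `ci_low`, `ci_high`, `o_over_e`, `p_value`. Empty strata are
#'   dropped with a warning.
#' @export
pericentromere_test <- function(calls_by_class, pericentromeres, null) {
  fr <- null_region_fractions(null, pericentromeres)
  p0 <- mean(fr)
  ci <- stats::quantile(fr, c(0.025, 0.975), names = FALSE)
  rows <- lapply(names(calls_by_class), function(cl) {
    d <- calls_by_class[[cl]]
    if (is.null(d) || nrow(d) == 0) {
      warning("stratum '", cl, "' is empty; excluded", call. = FALSE)
      return(NULL)
    }
    inside <- sum(points_in_regions(d$chrom, d$start, pericentromeres))
    n <- nrow(d)
    obs <- inside / n
    expd <- c(p0, 1 - p0) * n
    chi <- sum((c(inside, n - inside) - expd)^2 / expd)
    data.frame(class = cl, n = n, observed = obs, expected_mean = p0,
               ci_low = ci[1], ci_high = ci[2],
               o_over_e = if (p0 > 0) obs / p0 else NA_real_,
               p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Insertion-cluster enrichment in fixed-width windows
#'
#' Divides the genome into non-overlapping windows (default 10 kb),
#' counts insertions per window, and declares a window enriched when its
#' count falls in the configured upper tail of the pooled per-window
#' null count distribution: the threshold is the smallest count `c` with
#' `P(null count >= c) <= enrich_tail`.
#'
#' @param calls call data frame (`chrom`, `start`).
#' @param genome genome sequences or named lengths.
#' @param null a [randomize_positions()] null built with matching `n`
#'   and exclusions.
#' @param window window width in bp.
#' @param config a [pipeline_config()].
#' @return List with `windows` (all windows with observed counts),
#'   `threshold`, `tail_prob` at the threshold, and `enriched` (the
#'   reported windows).
#' @export
window_enrichment <- function(calls, genome, null, window = 10000L,
                              config = pipeline_config()) {
  lens <- if (is.character(genome)) nchar(genome) else genome
  win <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq.int(0L, lens[[ch]] - 1L, by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, lens[[ch]]),
               stringsAsFactors = FALSE)
  }))
  win_index <- function(chrom, pos) {
    base <- stats::setNames(cumsum(c(0L, ceiling(lens / window)))[
      seq_along(lens)], names(lens))
    base[chrom] + pos %/% window + 1L
  }
  n_windows <- nrow(win)
  win$count <- tabulate(win_index(calls$chrom, calls$start), n_windows)
  # pooled null per-window count frequencies
  max_seen <- 0L
  freq <- numeric(0)
  for (it in seq_len(null$n_iter)) {
    p <- null_positions(null, it)
    cnt <- tabulate(win_index(p$chrom, p$pos), n_windows)
    t <- table(cnt)
    k <- as.integer(names(t))
    if (max(k) > max_seen) {
      freq <- c(freq, numeric(max(k) - max_seen))
      max_seen <- max(k)
    }
    for (j in seq_along(k)) {
      if (k[j] >= 1L) freq[k[j]] <- freq[k[j]] + t[[j]]
    }
  }
  total <- as.numeric(n_windows) * null$n_iter
  # P(count >= c) for c = 1..max_seen
  tail_ge <- rev(cumsum(rev(freq))) / total
  thr <- which(tail_ge <= config$enrich_tail)
  threshold <- if (length(thr)) min(thr) else max_seen + 1L
  enriched <- win[win$count >= threshold, , drop = FALSE]
  rownames(enriched) <- NULL
  list(windows = win, threshold = threshold,
       tail_prob = if (threshold <= max_seen) tail_ge[threshold] else 0,
       enriched = enriched)
}

#' Assign positions to metagene feature classes
#'
#' Each position receives exactly one class through the stepwise
#' hierarchy 5' UTR > 3' UTR > exon > intron > intergenic. Intergenic
#' positions get the distance to the closest gene, signed by the gene's
#' orientation (negative upstream of the gene's 5' end).
#'
#' @param positions data frame `chrom`, `pos` (0-based points).
#' @param gm a [gene_models()] object.
#' @return Data frame: `chrom`, `pos`, `class`, `gene_id`, `distance`
#'   (0 for genic classes).
#' @export
metagene_assign <- function(positions, gm) {
  hier <- c("five_prime_UTR", "three_prime_UTR", "exon", "intron")
  n <- nrow(positions)
  cls <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  dist <- rep(0L, n)
  for (kind in hier) {
    fe <- gm$features[gm$features$kind == kind, , drop = FALSE]
    if (nrow(fe) == 0) next
    todo <- which(is.na(cls))
    if (!length(todo)) break
    hit <- points_in_regions(positions$chrom[todo], positions$pos[todo], fe)
    for (i in todo[hit]) {
      cls[i] <- kind
      j <- which(fe$chrom == positions$chrom[i] &
                   fe$start <= positions$pos[i] &
                   fe$end > positions$pos[i])[1]
      gene[i] <- fe$gene_id[j]
    }
  }
  todo <- which(is.na(cls))
  g <- gm$genes
  for (i in todo) {
    cls[i] <- "intergenic"
    same <- which(g$chrom == positions$chrom[i])
    if (!length(same)) { dist[i] <- NA_integer_; next }
    pos <- positions$pos[i]
    d_left <- g$start[same] - pos   # positive when gene is to the right
    d_right <- pos - (g$end[same] - 1L) # positive when gene is to the left
    d <- pmax(pmax(d_left, d_right), 0L)
    j <- same[which.min(d)]
    gene[i] <- g$gene_id[j]
    side_right_of_gene <- pos >= g$end[j] # downstream in genome coords
    magnitude <- min(d)
    sign <- if (magnitude == 0) {
      0L # inside the gene but in no feature: distance 0
    } else if (g$strand[j] == "+") {
      if (side_right_of_gene) 1L else -1L
    } else {
      if (side_right_of_gene) -1L else 1L
    }
    dist[i] <- sign * magnitude
  }
  data.frame(chrom = positions$chrom, pos = positions$pos, class = cls,
             gene_id = gene, distance = dist, stringsAsFactors = FALSE)
}

#' Expression-ratio impact of TE insertions with a permutation null
#'
#' For every gene with an insertion call within `max_dist` (default
#' 1 kb), computes the ratio of the median expression in carrier
#' accessions to the median in non-carrier accessions. The null
#' distribution is built from `n_iter` random same-size gene sets with
#' carrier labels reassigned uniformly at random, preserving each
#' observed carrier count. Observed and null ratio distributions are
#' compared with a two-sample Kolmogorov-Smirnov test. Genes whose
#' non-carrier median is zero are excluded (and reported).
#'
#' @param expression genes x accessions numeric matrix.
#' @param gmat a [genotype_matrix()] (rows must carry the call ids used
#'   in `calls`' rownames pairing, see [detect_insertions()]).
#' @param calls insertion call data frame.
#' @param gm a [gene_models()] object.
#' @param n_iter null iterations.
#' @param seed integer seed.
#' @param max_dist gene-to-call distance defining "affected" genes (bp).
#' @return List with `impacts` (data frame: `gene_id`, `call`, `ratio`,
#'   `n_carriers`), `null_ratios`, `ks` (the `ks.test` result),
#'   `excluded` (genes dropped and why).
#' @export
expression_ratio_test <- function(expression, gmat, calls, gm,
                                  n_iter = 1000L, seed = 1L,
                                  max_dist = 1000L) {
  accs <- colnames(gmat$presence)
  accs <- intersect(accs, colnames(expression))
  if (length(accs) < 4) stop("too few accessions shared between expression ",
                             "matrix and genotypes", call. = FALSE)
  pres <- gmat$presence[, accs, drop = FALSE]
  # pair genes with calls within max_dist
  g <- gm$genes
  padded <- data.frame(chrom = g$chrom,
                       start = pmax(g$start - max_dist, 0L),
                       end = g$end + max_dist, stringsAsFactors = FALSE)
  pairs <- list()
  for (i in seq_len(nrow(calls))) {
    hit <- which(padded$chrom == calls$chrom[i] &
                   padded$start < calls$end[i] &
                   padded$end > calls$start[i])
    for (j in hit) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_id = g$gene_id[j], call = i, stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) stop("no gene has a call within ", max_dist, " bp",
                           call. = FALSE)
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[pairs$gene_id %in% rownames(expression), , drop = FALSE]
  impacts <- NULL
  excluded <- NULL
  for (r in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[r]
    carrier <- pres[pairs$call[r], ] == 1L
    if (!any(carrier) || all(carrier)) {
      excluded <- rbind(excluded, data.frame(gene_id = gid,
                                             reason = "no contrast",
                                             stringsAsFactors = FALSE))
      next
    }
    med_nc <- stats::median(expression[gid, accs[!carrier]])
    if (med_nc == 0) {
      excluded <- rbind(excluded, data.frame(gene_id = gid,
                                             reason = "non-carrier median 0",
                                             stringsAsFactors = FALSE))
      next
    }
    impacts <- rbind(impacts, data.frame(
      gene_id = gid, call = pairs$call[r],
      ratio = stats::median(expression[gid, accs[carrier]]) / med_nc,
      n_carriers = sum(carrier), stringsAsFactors = FALSE))
  }
  if (is.null(impacts) || nrow(impacts) == 0) {
    stop("no testable gene/call pair (all excluded)", call. = FALSE)
  }
  n_acc <- length(accs)
  all_genes <- rownames(expression)
  null_ratios <- with_seed(seed, {
    out <- numeric(0)
    for (it in seq_len(n_iter)) {
      gsel <- sample(all_genes, nrow(impacts), replace = TRUE)
      rr <- vapply(seq_along(gsel), function(q) {
        k <- impacts$n_carriers[q]
        idx <- sample.int(n_acc, k)
        med_nc <- stats::median(expression[gsel[q], accs[-idx]])
        if (med_nc == 0) return(NA_real_)
        stats::median(expression[gsel[q], accs[idx]]) / med_nc
      }, numeric(1))
      out <- c(out, rr[!is.na(rr)])
    }
    out
  })
  ks <- suppressWarnings(stats::ks.test(impacts$ratio, null_ratios))
  list(impacts = impacts, null_ratios = null_ratios, ks = ks,
       excluded = excluded)
}

#' Classify methylation spreading around an insertion site
#'
#' Given per-window (default 50 bp) average methylation moving outward
#' from the TSD for carrier and non-carrier cohorts, the spreading
#' extent is the distance to the first of two consecutive windows where
#' the carrier minus non-carrier difference drops below
#' `meth_diff_threshold`. Classes: `none` (no spreading at the first
#' window), `short` (up to `spread_short_bp`), `long` (beyond
#' `spread_long_bp`), `intermediate` otherwise.
#'
#' @param carrier,non_carrier numeric vectors of per-window methylation
#'   averages (window 1 adjacent to the TSD).
#' @param config a [pipeline_config()].
#' @param side label stored in the result (`"left"`/`"right"`).
#' @return Data frame: `side`, `extent_bp`, `klass`.
#' @export
methylation_spread_classify <- function(carrier, non_carrier,
                                        config = pipeline_config(),
                                        side = "right") {
  stopifnot(length(carrier) == length(non_carrier), length(carrier) >= 1)
  d <- carrier - non_carrier
  below <- d < config$meth_diff_threshold
  n <- length(d)
  stop_at <- NA_integer_
  for (i in seq_len(n - 1L)) {
    if (below[i] && below[i + 1L]) { stop_at <- i; break }
  }
  if (is.na(stop_at) && below[n]) stop_at <- n
  extent <- if (is.na(stop_at)) n * config$meth_window_bp
  else (stop_at - 1L) * config$meth_window_bp
  klass <- if (extent == 0) "none"
  else if (extent <= config$spread_short_bp) "short"
  else if (extent > config$spread_long_bp) "long"
  else "intermediate"
  data.frame(side = side, extent_bp = extent, klass = klass,
             stringsAsFactors = FALSE)
}

## Partial Mantel ------------------------------------------------------------

upper_tri_cor <- function(a, b) {
  u <- upper.tri(a)
  stats::cor(a[u], b[u])
}

partial_mantel_stat <- function(dx, dy, dz) {
  rxy <- upper_tri_cor(dx, dy)
  rxz <- upper_tri_cor(dx, dz)
  ryz <- upper_tri_cor(dy, dz)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Partial Mantel association between copy number and climate
#'
#' Distance matrices are built as absolute pairwise differences for copy
#' number and climate, and as `1 - kinship` for population structure.
#' The partial correlation of the CN and climate distances given kinship
#' distance is computed from Pearson correlations over upper triangles,
#' and its significance from permutations of the accession order of the
#' CN matrix (two-sided on `|r|`, with the +1 correction). With
#' `exact = TRUE` all `n!` permutations are enumerated instead
#' (small cohorts only).
#'
#' @param cn copy-number vector by accession.
#' @param climate climate-variable vector by accession.
#' @param kinship accessions x accessions kinship matrix.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exact enumerate all permutations (requires `n <= 8`).
#' @return Object of class `"mantel_result"`: list with `r_partial`,
#'   `p_value`, `n_perm`.
#' @export
partial_mantel <- function(cn, climate, kinship, n_perm = 999L, seed = 1L,
                           exact = FALSE) {
  n <- length(cn)
  stopifnot(length(climate) == n, all(dim(kinship) == n))
  if (!exact && n < 10) stop("need at least 10 accessions", call. = FALSE)
  if (anyNA(cn) || anyNA(climate) || anyNA(kinship)) {
    stop("missing values not allowed", call. = FALSE)
  }
  dx <- abs(outer(cn, cn, "-"))
  dy <- abs(outer(climate, climate, "-"))
  dz <- 1 - kinship
  r_obs <- partial_mantel_stat(dx, dy, dz)
  if (exact) {
    stopifnot(n <= 8)
    perms <- all_permutations(n)
    r_null <- vapply(perms, function(p) {
      partial_mantel_stat(dx[p, p], dy, dz)
    }, numeric(1))
    p <- mean(abs(r_null) >= abs(r_obs))
    n_eff <- length(perms)
  } else {
    r_null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        partial_mantel_stat(dx[p, p], dy, dz)
      }, numeric(1))
    })
    p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + n_perm)
    n_eff <- n_perm
  }
  out <- list(r_partial = r_obs, p_value = p, n_perm = n_eff)
  class(out) <- "mantel_result"
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Partial Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r_partial, x$p_value, x$n_perm))
  invisible(x)
}

#' Bonferroni-corrected per-test threshold
#' @param alpha family-wise significance level, in (0,1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.01, 12)
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Phenotypic variance explained by a single SNP
#'
#' `2 * MAF * (1 - MAF) * beta^2 / var_y` for a biallelic SNP with minor
#' allele frequency `MAF` and additive effect `beta` on a phenotype of
#' variance `var_y`.
#'
#' @param maf minor allele frequency, in (0, 0.5].
#' @param beta additive SNP effect.
#' @param var_y phenotype variance (> 0).
#' @return Fraction of variance explained.
#' @export
variance_explained <- function(maf, beta, var_y) {
  stopifnot(all(maf > 0), all(maf <= 0.5), all(var_y > 0))
  2 * maf * (1 - maf) * beta^2 / var_y
}

#' Probability of missing an insertion in all carriers screened
#'
#' The probability that a true insertion segregating at frequency `f` is
#' carried by the `n - k` screened accessions that lack a detection and
#' was missed in each by a pipeline with false negative rate `fn_rate`:
#' `fn_rate * choose(n, n - k) * f^(n - k) * (1 - f)^k`.
#'
#' @param f allele frequency, in `[0, 1]`.
#' @param fn_rate pipeline false negative rate, in `[0, 1]`.
#' @param n number of accessions screened.
#' @param k number of screened accessions without the insertion.
#' @return Probability.
#' @export
prob_missing <- function(f, fn_rate, n = 12L, k = 12L) {
  stopifnot(all(f >= 0), all(f <= 1), fn_rate >= 0, fn_rate <= 1,
            k >= 0, k <= n)
  fn_rate * choose(n, n - k) * f^(n - k) * (1 - f)^k
}

#' Benchmark calls against a truth set
#'
#' A call matches a truth record when it has the same family and its TSD
#' interval lies within `match_tolerance_bp` (both bounds). Matching is
#' 1-to-1, greedy by distance. Reports false-negative rate
#' (`fn / n_truth`) and false discovery rate (`fp / (fp + tp)`).
#'
#' @param truth_set,call_set data frames with `family`, `chrom`,
#'   `start`, `end`.
#' @param match_tolerance_bp maximum boundary displacement in bp.
#' @return Object of class `"benchmark_rates"`: `n_truth`, `n_calls`,
#'   `tp`, `fp`, `fn`, `fn_rate`, `fdr`, and `matches` (data frame with
#'   `truth_idx`, `call_idx`, `dist`).
#' @export
benchmark_rates <- function(truth_set, call_set, match_tolerance_bp = 100L) {
  n_truth <- nrow(truth_set)
  n_calls <- nrow(call_set)
  cand <- NULL
  for (i in seq_len(n_truth)) {
    j <- which(call_set$family == truth_set$family[i] &
                 call_set$chrom == truth_set$chrom[i])
    if (!length(j)) next
    d <- pmax(abs(call_set$start[j] - truth_set$start[i]),
              abs(call_set$end[j] - truth_set$end[i]))
    ok <- d <= match_tolerance_bp
    if (any(ok)) {
      cand <- rbind(cand, data.frame(truth_idx = i, call_idx = j[ok],
                                     dist = d[ok]))
    }
  }
  matches <- data.frame(truth_idx = integer(), call_idx = integer(),
                        dist = integer())
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), , drop = FALSE]
    used_t <- logical(n_truth)
    used_c <- logical(n_calls)
    for (r in seq_len(nrow(cand))) {
      ti <- cand$truth_idx[r]
      ci <- cand$call_idx[r]
      if (used_t[ti] || used_c[ci]) next
      used_t[ti] <- TRUE
      used_c[ci] <- TRUE
      matches <- rbind(matches, cand[r, , drop = FALSE])
    }
  }
  tp <- nrow(matches)
  fp <- n_calls - tp
  fn <- n_truth - tp
  out <- list(n_truth = n_truth, n_calls = n_calls, tp = tp, fp = fp,
              fn = fn, fn_rate = if (n_truth > 0) fn / n_truth else NA_real_,
              fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
              matches = matches)
  class(out) <- "benchmark_rates"
  out
}

#' @export
print.benchmark_rates <- function(x, ...) {
  cat(sprintf(paste0("Benchmark: %d truth, %d calls; TP=%d FP=%d FN=%d; ",
                     "FN rate %.1f%%, FDR %.1f%%\n"),
              x$n_truth, x$n_calls, x$tp, x$fp, x$fn, 100 * x$fn_rate,
              100 * x$fdr))
  invisible(x)
}
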