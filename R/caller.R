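#' Extract unmapped reads from whole-genome alignments
#'
#' Returns the query sequences of records that did not map to the
#' reference (SAM flag 4). Mate information is deliberately not used:
#' discovery rests on split reads alone.
#'
#' @param records alignment table (see [read_sam()]).
#' @return Named character vector of read sequences (names = read ids).
#' @export
extract_unmapped <- function(records) {
  u <- records[!records$mapped, , drop = FALSE]
  stats::setNames(u$query_seq, u$read_id)
}

#' Build the 5'/3' TE extremity library
#'
#' For each family sequence, the 5' extremity is its first
#' `extremity_len` bases and the 3' extremity its last `extremity_len`
#' bases. Sequences shorter than twice the extremity length contribute
#' overlapping ends, with a warning.
#'
#' @param te_sequences named character vector of full-length family
#'   sequences.
#' @param config a [pipeline_config()].
#' @return Named character vector of extremity targets; names follow
#'   `"<family>|5p"` / `"<family>|3p"`.
#' @export
build_extremity_library <- function(te_sequences,
                                    config = pipeline_config()) {
  if (any(!nzchar(te_sequences))) {
    stop("empty family sequence in extremity library input", call. = FALSE)
  }
  elen <- config$extremity_len
  n <- nchar(te_sequences)
  short <- n < 2L * elen
  if (any(short)) {
    warning(sum(short), " family sequence(s) shorter than 2*extremity_len: ",
            "5' and 3' extremities overlap", call. = FALSE)
  }
  e5 <- substr(te_sequences, 1L, pmin(elen, n))
  e3 <- substr(te_sequences, pmax(n - elen + 1L, 1L), n)
  stats::setNames(c(e5, e3),
                  c(paste0(names(te_sequences), "|5p"),
                    paste0(names(te_sequences), "|3p")))
}

split_target_name <- function(x) {
  fam <- sub("\\|[35]p$", "", x)
  side <- ifelse(endsWith(x, "|5p"), "5prime", "3prime")
  list(family = fam, te_side = side)
}

#' Force-map unmapped reads onto TE extremities
#'
#' Aligns each unmapped read against the extremity library with the
#' exact local aligner and keeps reads whose alignment has exactly one
#' terminal soft clip of at least `min_clip` nt (the anchor on the TE
#' extremity must also reach `min_clip`). Only junction-compatible
#' configurations are retained: a read-suffix anchored on a 5' extremity
#' (clip on the left) or a read-prefix anchored on a 3' extremity (clip
#' on the right). The clipped subsequence is kept for genomic remapping;
#' the junction is not yet set.
#'
#' @param unmapped_reads named character vector of read sequences.
#' @param library extremity library from [build_extremity_library()].
#' @param config a [pipeline_config()].
#' @param local_aligner optional custom aligner with the signature of
#'   [naive_local_align()]; by default an equivalent batch
#'   implementation of the same longest-terminal-block contract is used,
#'   with ambiguity assessed across the whole library.
#' @return Split-read evidence data frame: `read_id`, `family`,
#'   `te_side`, `te_match_len`, `clip_len`, `clip_seq`, `clip_end`
#'   (position of the clip in the aligned read), with unset `junction`,
#'   `genomic_side`, `orientation`, `trims` columns to be filled by
#'   [map_clipped_fragment()].
#' @export
map_to_extremities <- function(unmapped_reads, library,
                               config = pipeline_config(),
                               local_aligner = NULL) {
  empty <- data.frame(read_id = character(), family = character(),
                      te_side = character(), te_match_len = integer(),
                      clip_len = integer(), clip_seq = character(),
                      clip_end = character(), chrom = character(),
                      junction = integer(), genomic_side = character(),
                      orientation = character(), trims = integer(),
                      stringsAsFactors = FALSE)
  if (length(unmapped_reads) == 0) return(empty)
  ids <- names(unmapped_reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(unmapped_reads))
  if (is.null(local_aligner)) {
    res <- local_align_library(unname(unmapped_reads), library,
                               min_clip = config$min_clip)
  } else {
    res <- reduce_custom_local(unmapped_reads, library, config,
                               local_aligner)
  }
  keep <- which(res$mapped & res$clip_len >= config$min_clip &
                  res$block_len >= config$min_clip)
  if (!length(keep)) return(empty)
  res <- res[keep, , drop = FALSE]
  ids <- ids[keep]
  reads <- unmapped_reads[keep]
  tgt <- split_target_name(res$target)
  # junction-compatible configurations: block is a read'-suffix on a 5'
  # extremity (clip = prefix, genomic fragment left of the TE in the
  # aligned frame) or a read'-prefix on a 3' extremity (clip = suffix)
  ok <- (res$end == "suffix" & tgt$te_side == "5prime") |
    (res$end == "prefix" & tgt$te_side == "3prime")
  if (!any(ok)) return(empty)
  res <- res[ok, , drop = FALSE]
  ids <- ids[ok]
  reads <- reads[ok]
  fam <- tgt$family[ok]
  side <- tgt$te_side[ok]
  oriented <- ifelse(res$strand == "+", unname(reads), revcomp(unname(reads)))
  n <- nchar(oriented)
  clip_seq <- ifelse(res$end == "suffix",
                     substr(oriented, 1L, res$clip_len),
                     substr(oriented, n - res$clip_len + 1L, n))
  data.frame(read_id = ids, family = fam, te_side = side,
             te_match_len = res$block_len, clip_len = res$clip_len,
             clip_seq = clip_seq,
             clip_end = ifelse(res$end == "suffix", "prefix", "suffix"),
             chrom = NA_character_, junction = NA_integer_,
             genomic_side = NA_character_, orientation = NA_character_,
             trims = NA_integer_, stringsAsFactors = FALSE)
}

# reduce a per-target custom aligner over the library: keep a read iff a
# unique target attains the maximal anchor (M) length
reduce_custom_local <- function(reads, library, config, local_aligner) {
  rows <- lapply(seq_along(reads), function(i) {
    alns <- lapply(names(library), function(tn) {
      local_aligner(reads[[i]], library[[tn]], target_name = tn,
                    min_clip = config$min_clip,
                    read_id = names(reads)[i])
    })
    alns <- do.call(rbind, alns)
    alns <- alns[alns$mapped, , drop = FALSE]
    no <- data.frame(target = NA_character_, tpos = NA_integer_,
                     strand = NA_character_, end = NA_character_,
                     block_len = NA_integer_, clip_len = NA_integer_,
                     mapped = FALSE, stringsAsFactors = FALSE)
    if (nrow(alns) == 0) return(no)
    m <- cigar_parse(alns$cigar[1])
    mlen <- vapply(alns$cigar, function(cg) {
      mm <- cigar_parse(cg)
      sum(as.integer(mm[mm[, "op"] == "M", "len"]))
    }, numeric(1))
    best <- which(mlen == max(mlen))
    if (length(best) != 1L) return(no)
    a <- alns[best, , drop = FALSE]
    mm <- cigar_parse(a$cigar)
    first_op <- mm[1, "op"]
    rl <- nchar(reads[[i]])
    data.frame(target = a$ref_name, tpos = a$pos, strand = a$strand,
               end = if (first_op == "M") "prefix" else "suffix",
               block_len = as.integer(max(mlen)),
               clip_len = rl - as.integer(max(mlen)), mapped = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remap clipped fragments to the reference and set junctions
#'
#' Each clipped fragment is placed end-to-end on the reference genome
#' with the exact unique-match aligner. On failure the fragment is
#' recursively trimmed by 1 nt from its junction-proximal end (where TSD
#' or microhomology contamination accumulates) and retried, stopping
#' before the fragment would shrink below `min_clip`. The junction is
#' the fragment's reference coordinate adjacent to the TE, shifted by
#' the number of trimmed bases; `genomic_side` and `orientation` follow
#' from the TE side and the mapping strand.
#'
#' @param evidence output of [map_to_extremities()].
#' @param genome named character vector of chromosome sequences.
#' @param config a [pipeline_config()].
#' @param end_to_end_aligner a function with the contract of
#'   [naive_end_to_end_align()].
#' @return The evidence rows that could be placed, with `chrom`,
#'   `junction`, `genomic_side`, `orientation` and `trims` set.
#' @export
map_clipped_fragment <- function(evidence, genome,
                                 config = pipeline_config(),
                                 end_to_end_aligner = naive_end_to_end_align) {
  if (nrow(evidence) == 0) return(evidence)
  out <- evidence
  for (i in seq_len(nrow(evidence))) {
    frag <- evidence$clip_seq[i]
    # junction-proximal end of the fragment in the aligned read frame:
    # right end when the fragment sits left of the TE (5' side), left
    # end when it sits right of the TE (3' side)
    prox_right <- evidence$te_side[i] == "5prime"
    trims <- 0L
    hit <- NULL
    repeat {
      hit <- end_to_end_aligner(frag, genome)
      if (!is.null(hit)) break
      if (nchar(frag) - 1L < config$min_clip) break
      frag <- if (prox_right) substr(frag, 1L, nchar(frag) - 1L)
      else substr(frag, 2L, nchar(frag))
      trims <- trims + 1L
    }
    if (is.null(hit)) next
    flen <- nchar(frag)
    readframe_left <- prox_right # fragment left of TE in aligned frame
    side <- if (hit$strand == "+") {
      if (readframe_left) "left_of_TE" else "right_of_TE"
    } else {
      if (readframe_left) "right_of_TE" else "left_of_TE"
    }
    junction <- if (side == "left_of_TE") hit$pos + flen + trims
    else hit$pos - trims
    out$chrom[i] <- hit$chrom
    out$junction[i] <- junction
    out$genomic_side[i] <- side
    out$orientation[i] <- hit$strand
    out$trims[i] <- trims
  }
  out <- out[!is.na(out$junction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster split-read evidences by junction position
#'
#' Evidences of one family and one genomic side on the same chromosome
#' are grouped by single linkage with a gap of at most twice the family
#' TSD length between neighbouring junctions. The cluster boundary is
#' the modal junction position, ties broken toward the TE (larger
#' position for clusters left of the TE, smaller for clusters right of
#' it).
#'
#' @param evidence placed evidence (see [map_clipped_fragment()]).
#' @param family family name to cluster.
#' @param tsd_len the family's TSD length in bp.
#' @param config a [pipeline_config()].
#' @return Data frame of clip clusters: `family`, `chrom`,
#'   `genomic_side`, `boundary`, `n_reads`, `orientation` (modal),
#'   plus list columns `junctions` and `read_ids`.
#' @export
cluster_evidences <- function(evidence, family, tsd_len,
                              config = pipeline_config()) {
  ev <- evidence[evidence$family == family & !is.na(evidence$junction), ,
                 drop = FALSE]
  empty <- data.frame(family = character(), chrom = character(),
                      genomic_side = character(), boundary = integer(),
                      n_reads = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  empty$junctions <- list()
  empty$read_ids <- list()
  if (nrow(ev) == 0) return(empty)
  gap <- 2L * tsd_len
  rows <- list()
  for (key in unique(paste(ev$chrom, ev$genomic_side))) {
    d <- ev[paste(ev$chrom, ev$genomic_side) == key, , drop = FALSE]
    d <- d[order(d$junction), , drop = FALSE]
    brk <- c(0L, cumsum(diff(d$junction) > gap))
    for (g in unique(brk)) {
      dd <- d[brk == g, , drop = FALSE]
      tab <- table(dd$junction)
      modal <- as.integer(names(tab)[tab == max(tab)])
      boundary <- if (dd$genomic_side[1] == "left_of_TE") max(modal)
      else min(modal)
      otab <- table(dd$orientation)
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, chrom = dd$chrom[1],
        genomic_side = dd$genomic_side[1], boundary = boundary,
        n_reads = nrow(dd),
        orientation = names(otab)[which.max(otab)],
        junctions = I(list(dd$junction)), read_ids = I(list(dd$read_id)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call a TSD-validated insertion from a left/right cluster pair
#'
#' The overlap of the two flank mappings,
#' `[right boundary, left boundary)`, reconstructs the target site
#' duplication. A call is emitted only when both clusters reach
#' `min_reads_discovery` reads and the overlap width lies between 1 and
#' `tsd_overlap_factor` times the family TSD length.
#'
#' @param left_cluster,right_cluster single cluster rows from
#'   [cluster_evidences()] (genomic sides `left_of_TE` / `right_of_TE`).
#' @param family family name.
#' @param tsd_len family TSD length (bp).
#' @param genome reference genome (for the TSD sequence).
#' @param config a [pipeline_config()].
#' @param accession accession recorded as `discovered_in`.
#' @return One-row insertion call data frame, or `NULL`.
#' @export
call_insertion <- function(left_cluster, right_cluster, family, tsd_len,
                           genome, config = pipeline_config(),
                           accession = "acc") {
  if (is.na(tsd_len)) return(NULL)
  if (left_cluster$chrom != right_cluster$chrom) return(NULL)
  if (left_cluster$n_reads < config$min_reads_discovery ||
        right_cluster$n_reads < config$min_reads_discovery) return(NULL)
  width <- left_cluster$boundary - right_cluster$boundary
  if (width < 1L || width > config$tsd_overlap_factor * tsd_len) return(NULL)
  start <- right_cluster$boundary
  end <- left_cluster$boundary
  ori <- if (left_cluster$orientation == right_cluster$orientation) {
    left_cluster$orientation
  } else if (left_cluster$n_reads >= right_cluster$n_reads) {
    left_cluster$orientation
  } else right_cluster$orientation
  data.frame(family = family, chrom = left_cluster$chrom, start = start,
             end = end,
             tsd_seq = substr(genome[[left_cluster$chrom]], start + 1L, end),
             n_reads_left = left_cluster$n_reads,
             n_reads_right = right_cluster$n_reads, orientation = ori,
             discovered_in = accession, status = "PASS",
             stringsAsFactors = FALSE)
}

#' Detect non-reference TE insertions with TSDs in one accession
#'
#' Runs the four-step split-read pipeline: (i) unmapped-read extraction,
#' (ii) forced local mapping onto 5'/3' TE extremities with soft
#' clipping, (iii) recursive clipping and exact genomic remapping of the
#' clipped fragments, (iv) dual-cluster TSD reconstruction. Families
#' without a TSD length never yield calls.
#'
#' @param genome reference genome (named character vector).
#' @param te_library TE family library (see [simulate_te_families()]):
#'   list with `families` and `sequences`.
#' @param reads named character vector of reads (aligned internally with
#'   the naive exact aligner), or `NULL` when `alignments` are given.
#' @param alignments optional alignment table of a whole-genome
#'   alignment (e.g. from [read_sam()]).
#' @param config a [pipeline_config()].
#' @param accession accession label.
#' @return List of class `"insertion_calls"` with `calls` (one row per
#'   insertion: `family`, `chrom`, `start`, `end` — the TSD interval —
#'   `tsd_seq`, support counts, `orientation`, `discovered_in`,
#'   `status`), `evidence` (placed split-read evidence, reusable for
#'   genotyping) and `counts` (progress counts through the pipeline).
#' @export
detect_insertions <- function(genome, te_library, reads = NULL,
                              alignments = NULL,
                              config = pipeline_config(),
                              accession = "acc") {
  if (is.null(alignments)) {
    if (is.null(reads)) stop("provide reads or alignments", call. = FALSE)
    alignments <- naive_genome_align(reads, genome)
  }
  unmapped <- extract_unmapped(alignments)
  fam <- te_library$families
  with_tsd <- fam$name[!is.na(fam$tsd_len)]
  lib <- build_extremity_library(te_library$sequences[with_tsd], config)
  ev <- map_to_extremities(unmapped, lib, config)
  ev <- map_clipped_fragment(ev, genome, config)
  calls <- list()
  n_clusters <- 0L
  for (f in with_tsd) {
    tsd <- fam$tsd_len[fam$name == f]
    cl <- cluster_evidences(ev, f, tsd, config)
    cl <- cl[cl$n_reads >= config$min_reads_discovery, , drop = FALSE]
    n_clusters <- n_clusters + nrow(cl)
    if (nrow(cl) == 0) next
    left <- cl[cl$genomic_side == "left_of_TE", , drop = FALSE]
    right <- cl[cl$genomic_side == "right_of_TE", , drop = FALSE]
    for (i in seq_len(nrow(left))) for (j in seq_len(nrow(right))) {
      call <- call_insertion(left[i, , drop = FALSE],
                             right[j, , drop = FALSE], f, tsd, genome,
                             config, accession)
      if (!is.null(call)) calls[[length(calls) + 1L]] <- call
    }
  }
  calls <- if (length(calls)) {
    unique(do.call(rbind, calls))
  } else {
    data.frame(family = character(), chrom = character(), start = integer(),
               end = integer(), tsd_seq = character(),
               n_reads_left = integer(), n_reads_right = integer(),
               orientation = character(), discovered_in = character(),
               status = character(), stringsAsFactors = FALSE)
  }
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  out <- list(calls = calls, evidence = ev,
              counts = c(reads_in = nrow(alignments),
                         unmapped = length(unmapped),
                         evidences = nrow(ev), clusters = n_clusters,
                         calls = nrow(calls)))
  class(out) <- "insertion_calls"
  out
}

#' @export
print.insertion_calls <- function(x, ...) {
  cat("Non-reference TE insertion calls:", nrow(x$calls), "call(s)\n")
  cat("  pipeline counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Annotate insertion calls with filter flags
#'
#' Each call receives every triggered flag among: `in_mask` (overlaps an
#' aberrant-coverage mask), `inner_pericentromere`, `spans_donor` (TSD
#' interval within an annotated copy of the same family), `in_control`
#' (also called in a reference re-sequencing run), `coverage_outlier`
#' (total split-read support exceeds the genome coverage median by more
#' than `mad_k` MADs), `high_frequency` (carrier fraction at or above
#' `cohort_freq_filter`) and `in_te_annotation` (overlapping annotated
#' TE sequence of a flagged superfamily). Calls with no flag are `PASS`.
#'
#' @param calls insertion call data frame (see [detect_insertions()]).
#' @param masks aberrant-coverage mask segments.
#' @param inner_pericentromeres interval data frame.
#' @param te_annotations TE annotations (`chrom`, `start`, `end`,
#'   `family`, optionally `superfamily`).
#' @param control_calls calls made on the reference re-sequencing runs.
#' @param coverage_stats list with `median` and `mad` of whole-genome
#'   read coverage.
#' @param genotype_matrix presence/absence matrix (calls x accessions)
#'   from [genotype_matrix()], or `NULL` to skip the frequency filter
#'   only when no cohort exists (single-accession runs).
#' @param config a [pipeline_config()].
#' @return `calls` with the `status` column set (comma-joined flags, or
#'   `"PASS"`).
#' @export
apply_filters <- function(calls, masks, inner_pericentromeres,
                          te_annotations, control_calls, coverage_stats,
                          genotype_matrix = NULL,
                          config = pipeline_config()) {
  for (nm in c("masks", "inner_pericentromeres", "te_annotations",
               "control_calls", "coverage_stats")) {
    if (is.null(get(nm))) stop("missing filter resource: ", nm,
                               call. = FALSE)
  }
  if (nrow(calls) == 0) return(calls)
  flags <- vector("list", nrow(calls))
  add <- function(which, flag) {
    for (i in which(which)) flags[[i]] <<- c(flags[[i]], flag)
  }
  add(overlaps_any(calls, masks), "in_mask")
  add(overlaps_any(calls, inner_pericentromeres), "inner_pericentromere")
  # donor: TSD interval within an annotated copy of the same family
  spans <- rep(FALSE, nrow(calls))
  for (f in unique(calls$family)) {
    ann <- te_annotations[te_annotations$family == f, , drop = FALSE]
    ci <- which(calls$family == f)
    if (nrow(ann)) {
      spans[ci] <- within_any(calls[ci, , drop = FALSE], ann)
    }
  }
  add(spans, "spans_donor")
  in_ctrl <- rep(FALSE, nrow(calls))
  for (f in unique(calls$family)) {
    cc <- control_calls[control_calls$family == f, , drop = FALSE]
    ci <- which(calls$family == f)
    if (nrow(cc)) {
      pad <- calls[ci, , drop = FALSE]
      pad$start <- pmax(pad$start - config$genotype_tol_bp, 0L)
      pad$end <- pad$end + config$genotype_tol_bp
      in_ctrl[ci] <- overlaps_any(pad, cc)
    }
  }
  add(in_ctrl, "in_control")
  support <- calls$n_reads_left + calls$n_reads_right
  add(support > coverage_stats$median + config$mad_k * coverage_stats$mad,
      "coverage_outlier")
  if (!is.null(genotype_matrix)) {
    gm <- genotype_matrix$presence
    freq <- rowMeans(gm)
    add(freq >= config$cohort_freq_filter, "high_frequency")
  }
  flagged_sf <- config$te_annotation_superfamilies
  ann_sf <- te_annotations
  if (!is.null(ann_sf$superfamily)) {
    ann_sf <- ann_sf[ann_sf$superfamily %in% flagged_sf, , drop = FALSE]
  }
  if (nrow(ann_sf)) add(overlaps_any(calls, ann_sf), "in_te_annotation")
  calls$status <- vapply(flags, function(fl) {
    if (is.null(fl)) "PASS" else paste(sort(unique(fl)), collapse = ",")
  }, character(1))
  calls
}

#' Genotype a call in one accession from stored evidence
#'
#' An accession carries the insertion when at least `min_reads_genotype`
#' split reads of the call's family (either side, summed) have junctions
#' within the call's TSD interval padded by `genotype_tol_bp`.
#'
#' @param call one-row insertion call.
#' @param evidence placed evidence of one accession.
#' @param config a [pipeline_config()].
#' @return List with `present` (0/1) and `n_support`.
#' @export
genotype_call <- function(call, evidence, config = pipeline_config()) {
  tol <- config$genotype_tol_bp
  hit <- evidence$family == call$family &
    evidence$chrom == call$chrom &
    !is.na(evidence$junction) &
    evidence$junction >= call$start - tol &
    evidence$junction <= call$end + tol
  n <- sum(hit)
  list(present = as.integer(n >= config$min_reads_genotype), n_support = n)
}

#' Genotype all calls across a cohort
#'
#' Re-screens every call in every accession by reusing the stored
#' split-read evidence with the relaxed support threshold
#' (`min_reads_genotype`).
#'
#' @param calls insertion call data frame.
#' @param evidence_by_accession named list of placed evidence data
#'   frames, one per accession.
#' @param config a [pipeline_config()].
#' @return List of class `"genotype_matrix"` with `presence` (calls x
#'   accessions 0/1 matrix) and `support` (matching read counts).
#' @export
genotype_matrix <- function(calls, evidence_by_accession,
                            config = pipeline_config()) {
  accs <- names(evidence_by_accession)
  ids <- paste0(calls$family, ":", calls$chrom, ":", calls$start, "-",
                calls$end)
  pres <- matrix(0L, nrow(calls), length(accs), dimnames = list(ids, accs))
  supp <- pres
  for (a in accs) {
    ev <- evidence_by_accession[[a]]
    for (i in seq_len(nrow(calls))) {
      g <- genotype_call(calls[i, , drop = FALSE], ev, config)
      pres[i, a] <- g$present
      supp[i, a] <- g$n_support
    }
  }
  out <- list(presence = pres, support = supp)
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$presence), "call(s) x",
      ncol(x$presence), "accession(s);",
      sum(x$presence), "presence call(s)\n")
  invisible(x)
}

#' Allele frequency spectrum of insertion calls
#'
#' Histogram of carrier counts per call, with the carrier-count strata
#' used downstream: private (1 accession), shared by 2-10, shared by
#' more than 10.
#'
#' @param gmat a [genotype_matrix()].
#' @return List with `spectrum` (named table: carrier count ->
#'   number of calls) and `classes` (counts for `private`,
#'   `shared_2_10`, `shared_gt10`).
#' @export
allele_frequency_spectrum <- function(gmat) {
  counts <- rowSums(gmat$presence)
  spectrum <- table(factor(counts, levels = sort(unique(counts))))
  classes <- c(private = sum(counts == 1),
               shared_2_10 = sum(counts >= 2 & counts <= 10),
               shared_gt10 = sum(counts > 10))
  list(spectrum = spectrum, classes = classes, carrier_counts = counts)
}
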