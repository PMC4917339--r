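#' Reverse complement
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements (names preserved).
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  stats::setNames(out, names(x))
}

#' Exact end-to-end placement of a fragment on a genome
#'
#' Finds exact full-length matches of `fragment` on either strand of
#' `genome`. A unique placement is required: zero or two-or-more
#' placements (summed over strands and chromosomes; a palindromic
#' fragment therefore counts its site twice) yield `NULL` ("unmapped").
#'
#' @param fragment DNA string.
#' @param genome named character vector of chromosome sequences.
#' @return `list(chrom, pos, strand)` with 0-based `pos`, or `NULL`.
#' @export
naive_end_to_end_align <- function(fragment, genome) {
  hit <- NULL
  n_hits <- 0L
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") fragment else revcomp(fragment)
    for (ch in names(genome)) {
      p <- gregexpr(pat, genome[[ch]], fixed = TRUE)[[1]]
      if (p[1] == -1L) next
      n_hits <- n_hits + length(p)
      if (n_hits > 1L) return(NULL)
      hit <- list(chrom = ch, pos = as.integer(p[1]) - 1L, strand = strand)
    }
  }
  if (n_hits == 1L) hit else NULL
}

## Longest exact terminal block ------------------------------------------------

# Binary search for the longest terminal block (given end/strand) of
# `read_oriented` occurring in `subject`. Occurrence is monotone in block
# length, so bisection is exact.
longest_block <- function(read_oriented, subject, end) {
  n <- nchar(read_oriented)
  block_at <- function(L) {
    if (end == "prefix") substr(read_oriented, 1L, L)
    else substr(read_oriented, n - L + 1L, n)
  }
  if (regexpr(block_at(1L), subject, fixed = TRUE) == -1L) return(0L)
  lo <- 1L; hi <- n
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (regexpr(block_at(mid), subject, fixed = TRUE) != -1L) lo <- mid
    else hi <- mid - 1L
  }
  lo
}

block_positions <- function(read_oriented, subject, end, L) {
  n <- nchar(read_oriented)
  pat <- if (end == "prefix") substr(read_oriented, 1L, L)
  else substr(read_oriented, n - L + 1L, n)
  p <- gregexpr(pat, subject, fixed = TRUE)[[1]]
  if (p[1] == -1L) integer(0) else as.integer(p) - 1L
}

#' Exact local alignment of a read against a single target
#'
#' Finds the longest exact terminal block of the read (prefix or suffix,
#' on either strand) occurring in `target_seq`, and reports it as one `M`
#' block plus one `S` (soft clip) block for the remainder, in the aligned
#' orientation. If the longest block is shorter than `min_clip`, or is
#' ambiguous (two or more placements of maximal length, across ends,
#' strands and positions), the read is reported unmapped.
#'
#' @param read DNA string (length at least `min_clip`).
#' @param target_seq DNA string.
#' @param target_name identifier stored in `ref_name`.
#' @param min_clip minimum anchor length.
#' @param read_id identifier stored in `read_id`.
#' @return One-row alignment table (see [read_sam()] for columns); the
#'   `mapped` column is `FALSE` for unmapped reads. `query_seq` is stored
#'   in the aligned orientation.
#' @export
naive_local_align <- function(read, target_seq, target_name = "target",
                              min_clip = 20L, read_id = "read") {
  n <- nchar(read)
  stopifnot(n >= min_clip)
  rc <- revcomp(read)
  combos <- list(list("+", "prefix", read), list("+", "suffix", read),
                 list("-", "prefix", rc), list("-", "suffix", rc))
  lens <- vapply(combos, function(cb) longest_block(cb[[3]], target_seq,
                                                    cb[[2]]), integer(1))
  L <- max(lens)
  unmapped <- alignment_table(read_id = read_id, query_seq = read,
                              mapped = FALSE, ref_name = "*",
                              pos = NA_integer_, cigar = "*", strand = "+",
                              is_read1 = TRUE)
  if (L < min_clip) return(unmapped)
  plc <- do.call(rbind, lapply(which(lens == L), function(i) {
    cb <- combos[[i]]
    pos <- block_positions(cb[[3]], target_seq, cb[[2]], L)
    if (!length(pos)) return(NULL)
    data.frame(strand = cb[[1]], end = cb[[2]], pos = pos,
               seq = cb[[3]], stringsAsFactors = FALSE)
  }))
  # a full-length match is found under both "ends"; it is one placement
  if (L == n) plc <- plc[!duplicated(plc[c("strand", "pos")]), , drop = FALSE]
  if (nrow(plc) != 1L) return(unmapped)
  cig <- if (L == n) paste0(L, "M")
  else if (plc$end == "prefix") paste0(L, "M", n - L, "S")
  else paste0(n - L, "S", L, "M")
  alignment_table(read_id = read_id, query_seq = plc$seq, mapped = TRUE,
                  ref_name = target_name, pos = plc$pos, cigar = cig,
                  strand = plc$strand, is_read1 = TRUE)
}

## Batch machinery used by the caller -----------------------------------------

# Align many reads against a library of targets (named character vector)
# under the same longest-terminal-block contract as naive_local_align,
# with ambiguity assessed across the whole library. Returns a data frame
# with one row per read: target, tpos, strand, end, block_len, clip_len,
# mapped.
local_align_library <- function(reads, targets, min_clip = 20L) {
  stopifnot(length(targets) > 0)
  sep <- "#"
  concat <- paste(targets, collapse = sep)
  offs <- cumsum(c(0L, nchar(targets) + 1L))[seq_along(targets)]
  t_end <- offs + nchar(targets) # exclusive, 0-based within concat
  n_reads <- length(reads)
  res <- data.frame(target = rep(NA_character_, n_reads),
                    tpos = NA_integer_, strand = NA_character_,
                    end = NA_character_, block_len = NA_integer_,
                    clip_len = NA_integer_, mapped = FALSE,
                    stringsAsFactors = FALSE)
  rcs <- revcomp(reads)
  for (i in seq_len(n_reads)) {
    rd <- reads[[i]]
    n <- nchar(rd)
    combos <- list(c("+", "prefix"), c("+", "suffix"),
                   c("-", "prefix"), c("-", "suffix"))
    seqs <- c(rd, rd, rcs[[i]], rcs[[i]])
    lens <- integer(4)
    for (k in 1:4) lens[k] <- longest_block(seqs[k], concat, combos[[k]][2])
    L <- max(lens)
    if (L < min_clip) next
    plc <- NULL
    for (k in which(lens == L)) {
      pos <- block_positions(seqs[k], concat, combos[[k]][2], L)
      if (length(pos)) {
        plc <- rbind(plc, data.frame(strand = combos[[k]][1],
                                     end = combos[[k]][2], pos = pos,
                                     stringsAsFactors = FALSE))
      }
    }
    if (L == n) plc <- plc[!duplicated(plc[c("strand", "pos")]), , drop = FALSE]
    if (nrow(plc) != 1L) next
    ti <- findInterval(plc$pos, offs)
    # placements never span separators ('#' cannot occur in a read block)
    res$target[i] <- names(targets)[ti]
    res$tpos[i] <- plc$pos - offs[ti]
    res$strand[i] <- plc$strand
    res$end[i] <- plc$end
    res$block_len[i] <- L
    res$clip_len[i] <- n - L
    res$mapped[i] <- TRUE
  }
  res
}

# Exact-and-unique classification of constant-width reads against a
# genome via a k-mer dictionary of all read-length reference substrings.
# Identical in outcome to naive_end_to_end_align applied per read.
classify_reads_exact <- function(reads, genome) {
  w <- unique(nchar(reads))
  stopifnot(length(w) == 1L)
  km <- character(0)
  chrom_of <- integer(0)
  pos_of <- integer(0)
  for (ci in seq_along(genome)) {
    L <- nchar(genome[[ci]])
    if (L < w) next
    k <- substring(genome[[ci]], 1:(L - w + 1L), w:L)
    km <- c(km, k)
    chrom_of <- c(chrom_of, rep.int(ci, length(k)))
    pos_of <- c(pos_of, seq_along(k) - 1L)
  }
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  i_f <- match(reads, km)
  i_r <- match(revcomp(reads), km)
  n_f <- ifelse(is.na(i_f), 0L, ifelse(dup[pmax(i_f, 1L)], 2L, 1L))
  n_r <- ifelse(is.na(i_r), 0L, ifelse(dup[pmax(i_r, 1L)], 2L, 1L))
  total <- n_f + n_r
  mapped <- total == 1L
  strand <- ifelse(!mapped, NA_character_, ifelse(n_f == 1L, "+", "-"))
  idx <- ifelse(n_f == 1L, i_f, i_r)
  data.frame(mapped = mapped,
             chrom = ifelse(mapped, names(genome)[chrom_of[pmax(idx, 1L)]],
                            NA_character_),
             pos = ifelse(mapped, pos_of[pmax(idx, 1L)], NA_integer_),
             strand = strand, stringsAsFactors = FALSE)
}

#' Align reads to a genome with the naive exact aligner
#'
#' Applies the unique-exact-match contract of [naive_end_to_end_align()]
#' to a set of reads and returns SAM-like alignment records (mapped reads
#' get a full-`M` CIGAR; everything else is reported unmapped). Reads of
#' a single common width are classified through a reference k-mer
#' dictionary, which is fast enough for whole-genome use at desk scale;
#' mixed widths fall back to per-read search.
#'
#' @param reads named character vector of read sequences.
#' @param genome named character vector of chromosome sequences.
#' @return Alignment table (see [read_sam()]).
#' @export
naive_genome_align <- function(reads, genome) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  if (length(unique(nchar(reads))) == 1L && length(reads) > 1L) {
    cls <- classify_reads_exact(reads, genome)
  } else {
    cls <- do.call(rbind, lapply(reads, function(r) {
      h <- naive_end_to_end_align(r, genome)
      if (is.null(h)) {
        data.frame(mapped = FALSE, chrom = NA_character_, pos = NA_integer_,
                   strand = NA_character_, stringsAsFactors = FALSE)
      } else {
        data.frame(mapped = TRUE, chrom = h$chrom, pos = h$pos,
                   strand = h$strand, stringsAsFactors = FALSE)
      }
    }))
  }
  alignment_table(read_id = ids, query_seq = unname(reads),
                  mapped = cls$mapped,
                  ref_name = ifelse(cls$mapped, cls$chrom, "*"),
                  pos = ifelse(cls$mapped, cls$pos, NA_integer_),
                  cigar = ifelse(cls$mapped, paste0(nchar(reads), "M"), "*"),
                  strand = ifelse(cls$mapped, cls$strand, "+"),
                  is_read1 = TRUE)
}
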