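#' Read a FASTA file into a genome
#'
#' Sequences are uppercased and any character outside `A,C,G,T,N` is
#' mapped to `N`. A genome is represented throughout the package as a
#' named character vector of chromosome sequences.
#'
#' @param path FASTA file.
#' @return Named character vector (one element per chromosome).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) {
    stop("FASTA parse error at line 1: empty file '", path, "'",
         call. = FALSE)
  }
  if (!startsWith(first, ">")) {
    stop("FASTA parse error at line 1: expected '>' header, got '",
         substr(first, 1, 30), "'", call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("FASTA parse error: no records in ", path,
                            call. = FALSE)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("FASTA: duplicated sequence names in ", path, call. = FALSE)
  }
  if (any(nchar(seqs) < 1)) {
    stop("FASTA: zero-length sequence in ", path, call. = FALSE)
  }
  stats::setNames(seqs, nm)
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read FASTQ reads
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

write_fastq <- function(reads, path) {
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  out <- character(4L * n)
  out[seq(1, by = 4, length.out = n)] <- paste0("@", ids)
  out[seq(2, by = 4, length.out = n)] <- unname(reads)
  out[seq(3, by = 4, length.out = n)] <- "+"
  out[seq(4, by = 4, length.out = n)] <- strrep("I", nchar(reads))
  writeLines(out, path)
  invisible(path)
}

## CIGAR utilities ----------------------------------------------------------

#' Parse a CIGAR string
#' @param cigar a single CIGAR string (e.g. `"30S70M"`), or `"*"`.
#' @return Two-column matrix with columns `op` (character) and `len`
#'   (integer); zero rows for `"*"` or empty input.
#' @export
cigar_parse <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(cbind(op = character(0), len = character(0)))
  }
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) ||
      paste0(paste0(lens, ops), collapse = "") != cigar) {
    stop("malformed CIGAR: '", cigar, "'", call. = FALSE)
  }
  cbind(op = ops, len = lens)
}

cigar_len <- function(cigar, ops) {
  m <- cigar_parse(cigar)
  as.numeric(sum(as.integer(m[m[, "op"] %in% ops, "len"])))
}

#' Query-consuming length of a CIGAR (M, I, S ops)
#' @inheritParams cigar_parse
#' @export
cigar_query_len <- function(cigar) cigar_len(cigar, c("M", "I", "S"))

#' Reference-consuming length of a CIGAR (M, D ops)
#' @inheritParams cigar_parse
#' @export
cigar_ref_len <- function(cigar) cigar_len(cigar, c("M", "D"))

## SAM ----------------------------------------------------------------------

#' Read SAM text alignments
#'
#' Parses the 11 mandatory columns of SAM text (header lines ignored)
#' into an alignment table. The SAM 1-based `POS` is converted to the
#' package's 0-based convention. Records whose CIGAR contains an
#' unsupported operation (`H`, `P`, `N`, `X`, `=`) or whose
#' query-consuming CIGAR length disagrees with the sequence length are
#' rejected with a warning; the rejection count is attached as attribute
#' `"n_rejected"`.
#'
#' @param path SAM text file.
#' @return Data frame with columns `read_id`, `query_seq`, `mapped`,
#'   `ref_name`, `pos` (0-based; `NA` when unmapped), `cigar`, `strand`,
#'   `is_read1`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(alignment_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 11
  if (any(short)) {
    stop("SAM: record with fewer than 11 columns at data line ",
         which(short)[1], call. = FALSE)
  }
  flag <- as.integer(vapply(fields, `[[`, "", 2))
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- vapply(fields, `[[`, "", 6)
  cigar[!mapped] <- "*"
  seqs <- toupper(vapply(fields, `[[`, "", 10))
  rec <- data.frame(
    read_id = vapply(fields, `[[`, "", 1),
    query_seq = seqs,
    mapped = mapped,
    ref_name = vapply(fields, `[[`, "", 3),
    pos = ifelse(mapped, as.integer(vapply(fields, `[[`, "", 4)) - 1L,
                 NA_integer_),
    cigar = cigar,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    is_read1 = bitwAnd(flag, 64L) != 0L | bitwAnd(flag, 1L) == 0L,
    is_dup = bitwAnd(flag, 1024L) != 0L,
    stringsAsFactors = FALSE
  )
  bad_op <- mapped & grepl("[HPNX=]", cigar)
  bad_sum <- rep(FALSE, nrow(rec))
  chk <- which(mapped & !bad_op & cigar != "*")
  if (length(chk)) {
    qlen <- vapply(rec$cigar[chk], cigar_query_len, numeric(1))
    bad_sum[chk] <- qlen != nchar(rec$query_seq[chk]) & rec$query_seq[chk] != "*"
  }
  drop <- bad_op | bad_sum
  if (any(drop)) {
    warning(sum(drop), " SAM record(s) rejected (unsupported CIGAR op or ",
            "CIGAR/sequence length mismatch)", call. = FALSE)
    rec <- rec[!drop, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "n_rejected") <- sum(drop)
  rec
}

#' Construct an alignment table
#'
#' The in-memory alignment representation used throughout the package:
#' one row per read, the same columns [read_sam()] produces. Useful for
#' building alignments programmatically (e.g. from a custom mapper or in
#' tests) without going through a SAM file. Scalar arguments are
#' recycled to the length of `read_id`.
#'
#' @param read_id Read identifiers.
#' @param query_seq Read sequences (in the aligned orientation).
#' @param mapped Logical; is the read aligned.
#' @param ref_name Reference sequence name (`NA` when unmapped).
#' @param pos 0-based leftmost reference position (`NA` when unmapped).
#' @param cigar CIGAR string (`NA` when unmapped).
#' @param strand `"+"` or `"-"` (`NA` when unmapped).
#' @param is_read1 Logical; first mate of the pair.
#' @param is_dup Logical; PCR/optical duplicate flag.
#' @return Data frame with one row per read and the columns above.
#' @export
alignment_table <- function(read_id = character(), query_seq = character(),
                            mapped = logical(), ref_name = character(),
                            pos = integer(), cigar = character(),
                            strand = character(), is_read1 = logical(),
                            is_dup = FALSE) {
  data.frame(read_id = read_id, query_seq = query_seq, mapped = mapped,
             ref_name = ref_name, pos = as.integer(pos), cigar = cigar,
             strand = strand, is_read1 = is_read1,
             is_dup = rep_len(is_dup, length(read_id)),
             stringsAsFactors = FALSE)
}

## BED ----------------------------------------------------------------------

#' Read / write BED intervals
#'
#' BED is natively 0-based half-open, matching the internal convention.
#' 3- and 6-column BED are supported; `name` and `score` columns are kept
#' when present.
#'
#' @param path file path.
#' @return `read_bed` returns an interval data frame (columns `chrom`,
#'   `start`, `end`, and `name`, `score`, `strand` when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- as.character(mc$name)
  if (!is.null(mc$score)) df$score <- as.numeric(mc$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  validate_intervals(df, "BED")
  df
}

#' @rdname read_bed
#' @param intervals interval data frame.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals, "BED")
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name) || !is.null(intervals$score) ||
      !is.null(intervals$strand)) {
    nm <- if (is.null(intervals$name)) "." else intervals$name
    sc <- if (is.null(intervals$score)) 0 else intervals$score
    st <- if (is.null(intervals$strand)) "*" else intervals$strand
    st[st == "*"] <- "."
    cols <- c(cols, list(nm, sc, st))
  }
  df <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## GFF3 gene models -----------------------------------------------------------

#' Construct gene models
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open, stranded).
#' @param features data frame with columns `gene_id`, `kind` (one of
#'   `five_prime_UTR`, `three_prime_UTR`, `exon`, `intron`), `chrom`,
#'   `start`, `end`.
#' @param synthesize_introns add intron features as gaps between
#'   consecutive exons of each gene when no introns are present.
#' @return An object of class `"gene_models"`.
#' @export
gene_models <- function(genes, features, synthesize_introns = TRUE) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  stopifnot(all(c("gene_id", "kind", "chrom", "start", "end") %in%
                  names(features)))
  validate_intervals(genes, "gene")
  if (nrow(features)) validate_intervals(features, "feature")
  ok_kind <- c("five_prime_UTR", "three_prime_UTR", "exon", "intron")
  if (!all(features$kind %in% ok_kind)) {
    stop("gene_models: unknown feature kind(s): ",
         paste(setdiff(unique(features$kind), ok_kind), collapse = ", "),
         call. = FALSE)
  }
  # nesting invariant
  gidx <- match(features$gene_id, genes$gene_id)
  if (anyNA(gidx)) stop("gene_models: feature references unknown gene",
                        call. = FALSE)
  if (any(features$start < genes$start[gidx] |
            features$end > genes$end[gidx])) {
    stop("gene_models: feature not nested within its gene", call. = FALSE)
  }
  if (synthesize_introns && !any(features$kind == "intron")) {
    features <- rbind(features, synthesize_intron_features(features))
  }
  out <- list(genes = genes, features = features)
  class(out) <- "gene_models"
  out
}

synthesize_intron_features <- function(features) {
  ex <- features[features$kind == "exon", , drop = FALSE]
  if (nrow(ex) < 2) {
    return(ex[0, , drop = FALSE])
  }
  pieces <- lapply(split(ex, ex$gene_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    s <- d$end[-nrow(d)]
    e <- d$start[-1]
    keep <- s < e
    if (!any(keep)) return(NULL)
    data.frame(gene_id = d$gene_id[1], kind = "intron", chrom = d$chrom[1],
               start = s[keep], end = e[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(ex[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "genes,", nrow(x$features),
      "features\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. When a file carries no intron features, introns
#' are synthesized as the gaps between consecutive exons of each
#' transcript.
#'
#' @param path GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(S4Vectors::mcols(gr)$type),
                   id = as.character(S4Vectors::mcols(gr)$ID),
                   stringsAsFactors = FALSE)
  par <- S4Vectors::mcols(gr)$Parent
  df$parent <- vapply(as.list(par), function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  if (any(df$end < df$start)) {
    stop("GFF3: end < start after conversion at record ",
         which(df$end < df$start)[1], call. = FALSE)
  }
  g <- df[df$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) stop("GFF3: no gene records in ", path, call. = FALSE)
  genes <- data.frame(gene_id = g$id, chrom = g$chrom, start = g$start,
                      end = g$end, strand = g$strand,
                      stringsAsFactors = FALSE)
  # resolve each feature to its gene through (possibly) a transcript parent
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- stats::setNames(tx$parent, tx$id)
  kinds <- c(five_prime_UTR = "five_prime_UTR",
             three_prime_UTR = "three_prime_UTR", exon = "exon",
             intron = "intron")
  fe <- df[df$type %in% names(kinds), , drop = FALSE]
  if (nrow(fe)) {
    gene_of <- ifelse(fe$parent %in% names(tx2gene),
                      tx2gene[fe$parent], fe$parent)
    features <- data.frame(gene_id = unname(gene_of),
                           kind = unname(kinds[fe$type]),
                           chrom = fe$chrom, start = fe$start, end = fe$end,
                           stringsAsFactors = FALSE)
    features <- features[features$gene_id %in% genes$gene_id, , drop = FALSE]
    features <- unique(features)
    rownames(features) <- NULL
  } else {
    features <- data.frame(gene_id = character(), kind = character(),
                           chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  }
  gene_models(genes, features)
}

## TSV matrices ---------------------------------------------------------------

#' Read / write a TSV matrix
#'
#' Layout: header row with column identifiers, first column with row
#' identifiers, numeric body.
#'
#' @param path file path.
#' @return `read_tsv_matrix` returns a numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_tsv_matrix
#' @param mat numeric matrix with dimnames.
#' @param id_header name of the leading identifier column in the header.
#' @export
write_tsv_matrix <- function(mat, path, id_header = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
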