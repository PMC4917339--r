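#' Genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based, half-open) and optionally `strand` (`"+"`, `"-"` or `"*"`).
#' This constructor validates the invariants (`0 <= start < end`,
#' non-empty `chrom`).
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open bounds.
#' @param strand strand, recycled; defaults to `"*"` (unstranded).
#' @return A data frame of validated intervals.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) {
    stop(what, ": 'chrom' must be non-empty", call. = FALSE)
  }
  bad <- which(is.na(df$start) | is.na(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(what, ": need 0 <= start < end; violated at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if ("strand" %in% names(df) &&
      !all(df$strand %in% c("+", "-", "*"))) {
    stop(what, ": strand must be one of '+', '-', '*'", call. = FALSE)
  }
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

## IRanges bridge: per-chromosome overlap machinery ------------------------

intervals_to_grl <- function(df) {
  split(IRanges::IRanges(start = df$start + 1L, end = df$end), df$chrom)
}

#' Does each query interval overlap any subject interval?
#'
#' @param query,subject interval data frames (see [genomic_intervals()]).
#' @param min_overlap minimum overlapping bases.
#' @return Logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1L) {
  if (nrow(query) == 0) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  out <- rep(FALSE, nrow(query))
  subj <- intervals_to_grl(subject)
  for (ch in intersect(unique(query$chrom), names(subj))) {
    qi <- which(query$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    hits <- IRanges::overlapsAny(qr, subj[[ch]], minoverlap = min_overlap)
    out[qi] <- hits
  }
  out
}

#' Is each query interval fully contained within some subject interval?
#' @inheritParams overlaps_any
#' @return Logical vector along the rows of `query`.
#' @export
within_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  out <- rep(FALSE, nrow(query))
  subj <- intervals_to_grl(subject)
  for (ch in intersect(unique(query$chrom), names(subj))) {
    qi <- which(query$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    out[qi] <- IRanges::overlapsAny(qr, subj[[ch]], type = "within")
  }
  out
}

#' Merge overlapping or adjacent intervals
#' @param df intervals.
#' @return Reduced (non-overlapping, sorted) intervals.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(empty_intervals())
  pieces <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), strand = "*",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Subtract intervals from chromosome-wide space
#'
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param exclusions intervals to remove (may be `NULL`).
#' @return The complement as intervals ("allowed space").
#' @export
complement_intervals <- function(genome_lengths, exclusions = NULL) {
  out <- lapply(names(genome_lengths), function(ch) {
    full <- IRanges::IRanges(start = 1L, end = genome_lengths[[ch]])
    if (!is.null(exclusions) && nrow(exclusions)) {
      ex <- exclusions[exclusions$chrom == ch, , drop = FALSE]
      if (nrow(ex)) {
        exr <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
        full <- IRanges::setdiff(full, exr)
      }
    }
    if (length(full) == 0) return(empty_intervals())
    data.frame(chrom = ch, start = IRanges::start(full) - 1L,
               end = IRanges::end(full), strand = "*",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
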