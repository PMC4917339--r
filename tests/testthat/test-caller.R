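# one small synthetic cohort shared across the blocks in this file
cohort <- fix_cohort(seed = 7, len = 2e5, n_families = 5, n_ins = 8)
cfg <- pipeline_config()

test_that("unmapped-read extraction returns exactly the flag-4 subset", {
  rec <- alignment_table(read_id = c("a", "b", "c"),
                         query_seq = c("AAAA", "CCCC", "GGGG"),
                         mapped = c(TRUE, FALSE, FALSE),
                         ref_name = c("c1", "*", "*"),
                         pos = c(0L, NA, NA), cigar = c("4M", "*", "*"),
                         strand = "+", is_read1 = TRUE)
  u <- extract_unmapped(rec)
  expect_identical(u, c(b = "CCCC", c = "GGGG"))
  expect_length(extract_unmapped(rec[rec$mapped, ]), 0L)
})

test_that("extremity library takes 300-bp ends, warning on short sequences", {
  seqs <- c(long = paste(rep("ACGTT", 200), collapse = "")) # 1000 bp
  lib <- build_extremity_library(seqs, cfg)
  expect_length(lib, 2L)
  expect_identical(lib[["long|5p"]], unname(substr(seqs, 1, 300)))
  expect_identical(lib[["long|3p"]], unname(substr(seqs, 701, 1000)))
  short <- c(s = strrep("ACGT", 100)) # 400 bp
  expect_warning(lib2 <- build_extremity_library(short, cfg), "overlap")
  expect_identical(lib2[["s|5p"]], unname(substr(short, 1, 300)))
  expect_identical(lib2[["s|3p"]], unname(substr(short, 101, 400)))
  expect_error(build_extremity_library(c(x = "")), "empty")
})

# helper: construct a junction-spanning read for a truth record
junction_read <- function(fx, row, side = c("left", "right"),
                          n_genomic = 50, n_te = 50) {
  side <- match.arg(side)
  tr <- fx$acc$truth[row, ]
  te <- fx$lib$sequences[[tr$family]]
  if (tr$orientation == "-") te <- revcomp(te)
  ref <- fx$ref[[tr$chrom]]
  if (side == "left") {
    paste0(substr(ref, tr$end - n_genomic + 1L, tr$end),
           substr(te, 1L, n_te))
  } else {
    paste0(substr(te, nchar(te) - n_te + 1L, nchar(te)),
           substr(ref, tr$start + 1L, tr$start + n_genomic))
  }
}

test_that("extremity mapping keeps single terminal clips >= 20 nt with correct sides", {
  fx <- cohort
  lib <- build_extremity_library(fx$lib$sequences, cfg)
  plus <- which(fx$acc$truth$orientation == "+")[1]
  minus <- which(fx$acc$truth$orientation == "-")[1]
  reads <- c(L = junction_read(fx, plus, "left"),
             R = junction_read(fx, plus, "right"),
             Lm = junction_read(fx, minus, "left"),
             tiny = junction_read(fx, plus, "left", n_genomic = 19,
                                  n_te = 81))
  ev <- map_to_extremities(reads, lib, cfg)
  expect_false("tiny" %in% ev$read_id) # clip of 19 nt is discarded
  evL <- ev[ev$read_id == "L", ]
  expect_identical(evL$family, fx$acc$truth$family[plus])
  expect_identical(evL$te_side, "5prime")
  expect_identical(evL$clip_len, 50L)
  evR <- ev[ev$read_id == "R", ]
  expect_identical(evR$te_side, "3prime")
  # the minus-strand insertion read anchors on the 3' extremity
  evLm <- ev[ev$read_id == "Lm", ]
  expect_identical(evLm$family, fx$acc$truth$family[minus])
  expect_identical(evLm$te_side, "3prime")
})

test_that("clipped fragments place at the junction with the correct side and orientation", {
  fx <- cohort
  lib <- build_extremity_library(fx$lib$sequences, cfg)
  plus <- which(fx$acc$truth$orientation == "+")[1]
  minus <- which(fx$acc$truth$orientation == "-")[1]
  tr_p <- fx$acc$truth[plus, ]
  tr_m <- fx$acc$truth[minus, ]
  reads <- c(L = junction_read(fx, plus, "left"),
             R = junction_read(fx, plus, "right"),
             Lm = junction_read(fx, minus, "left"),
             Rm = junction_read(fx, minus, "right"))
  ev <- map_clipped_fragment(map_to_extremities(reads, lib, cfg), fx$ref,
                             cfg)
  expect_identical(nrow(ev), 4L)
  evL <- ev[ev$read_id == "L", ]
  expect_identical(evL$junction, tr_p$end)
  expect_identical(evL$genomic_side, "left_of_TE")
  expect_identical(evL$orientation, "+")
  expect_identical(evL$trims, 0L)
  evR <- ev[ev$read_id == "R", ]
  expect_identical(evR$junction, tr_p$start)
  expect_identical(evR$genomic_side, "right_of_TE")
  evLm <- ev[ev$read_id == "Lm", ]
  expect_identical(evLm$junction, tr_m$end)
  expect_identical(evLm$genomic_side, "left_of_TE")
  expect_identical(evLm$orientation, "-")
  evRm <- ev[ev$read_id == "Rm", ]
  expect_identical(evRm$junction, tr_m$start)
  expect_identical(evRm$genomic_side, "right_of_TE")
  expect_identical(evRm$orientation, "-")
})

test_that("recursive trimming shifts the junction by the trimmed bases", {
  fx <- cohort
  tr <- fx$acc$truth[fx$acc$truth$orientation == "+", ][1, ]
  ref <- fx$ref[[tr$chrom]]
  e <- tr$end
  # fragment = 30 genomic bases ending at the junction + 2 contaminating
  # bases that break the exact match (first one differs from the
  # continuing reference base)
  nxt <- substr(ref, e + 1L, e + 1L)
  junk1 <- setdiff(c("A", "C", "G", "T"), nxt)[1]
  frag <- paste0(substr(ref, e - 29L, e), junk1, "A")
  ev <- data.frame(read_id = "t", family = tr$family, te_side = "5prime",
                   te_match_len = 68L, clip_len = 32L, clip_seq = frag,
                   clip_end = "prefix", chrom = NA_character_,
                   junction = NA_integer_, genomic_side = NA_character_,
                   orientation = NA_character_, trims = NA_integer_,
                   stringsAsFactors = FALSE)
  placed <- map_clipped_fragment(ev, fx$ref, cfg)
  expect_identical(placed$trims, 2L)
  expect_identical(placed$junction, e + 2L) # shifted by the trims
  expect_identical(placed$genomic_side, "left_of_TE")
  # a 20-nt foreign fragment fails with no retries left
  ev$clip_seq <- strrep("AC", 10)
  ev$clip_len <- 20L
  expect_identical(nrow(map_clipped_fragment(ev, fx$ref, cfg)), 0L)
})

make_ev <- function(junctions, family = "F", side = "left_of_TE",
                    chrom = "c1", orientation = "+") {
  n <- length(junctions)
  data.frame(read_id = sprintf("r%d", seq_len(n)),
             family = rep_len(family, n),
             te_side = rep_len("5prime", n), te_match_len = rep_len(50L, n),
             clip_len = rep_len(50L, n), clip_seq = rep_len("N", n),
             clip_end = rep_len("prefix", n), chrom = rep_len(chrom, n),
             junction = as.integer(junctions),
             genomic_side = rep_len(side, n),
             orientation = rep_len(orientation, n), stringsAsFactors = FALSE,
             trims = rep_len(0L, n))
}

test_that("junction clustering is single-linkage with gap at most twice the TSD", {
  ev <- make_ev(c(100, 101, 130))
  cl <- cluster_evidences(ev, "F", tsd_len = 5)
  expect_identical(nrow(cl), 2L)
  expect_identical(sort(cl$n_reads), c(1L, 2L))
  ev6 <- make_ev(rep(250, 6))
  cl6 <- cluster_evidences(ev6, "F", tsd_len = 5)
  expect_identical(cl6$n_reads, 6L)
  expect_identical(cl6$boundary, 250L)
  expect_identical(nrow(cluster_evidences(make_ev(integer(0)), "F", 5)), 0L)
  # modal boundary with ties broken toward the TE
  tie_l <- cluster_evidences(make_ev(c(100, 100, 101, 101, 99)), "F", 5)
  expect_identical(tie_l$boundary, 101L) # TE lies right of a left cluster
  tie_r <- cluster_evidences(make_ev(c(100, 100, 101, 101, 99),
                                     side = "right_of_TE"), "F", 5)
  expect_identical(tie_r$boundary, 100L)
})

test_that("insertion calls require dual support and a TSD-compatible overlap", {
  g <- c(c1 = strrep("ACGTG", 100))
  mk_cluster <- function(boundary, side, n) {
    cluster_evidences(make_ev(rep(boundary, n), side = side), "F", 5)
  }
  left <- mk_cluster(105, "left_of_TE", 6)
  right <- mk_cluster(100, "right_of_TE", 7)
  call <- call_insertion(left, right, "F", 5, g, cfg)
  expect_identical(c(call$start, call$end), c(100L, 105L))
  expect_identical(nchar(call$tsd_seq), 5L)
  expect_identical(call$tsd_seq, substr(g[[1]], 101, 105))
  expect_identical(c(call$n_reads_left, call$n_reads_right), c(6L, 7L))
  # overlap of 11 exceeds twice the 5-bp TSD
  expect_null(call_insertion(mk_cluster(111, "left_of_TE", 6), right, "F",
                             5, g, cfg))
  # a 4-read cluster is below the discovery threshold
  expect_null(call_insertion(mk_cluster(105, "left_of_TE", 4), right, "F",
                             5, g, cfg))
  # no TSD length, no call
  expect_null(call_insertion(left, right, "F", NA_integer_, g, cfg))
  # zero-width or negative overlap is rejected
  expect_null(call_insertion(mk_cluster(100, "left_of_TE", 6), right, "F",
                             5, g, cfg))
})

test_that("the pipeline recovers planted insertions with exact TSDs on the small cohort", {
  fx <- cohort
  res <- detect_insertions(fx$ref, fx$lib, reads = fx$reads, config = cfg,
                           accession = "acc1")
  br <- benchmark_rates(fx$acc$truth, res$calls)
  expect_identical(br$fn, 0L)
  expect_identical(br$fp, 0L)
  expect_true(all(br$matches$dist == 0))
  expect_identical(res$calls$orientation,
                   fx$acc$truth$orientation[order(fx$acc$truth$chrom,
                                                  fx$acc$truth$start)])
  # monotonicity: a stricter discovery threshold never adds calls
  strict <- detect_insertions(fx$ref, fx$lib, reads = fx$reads,
                              config = pipeline_config(
                                min_reads_discovery = 12),
                              accession = "acc1")
  key <- function(d) paste(d$chrom, d$start, d$end, d$family)
  expect_true(all(key(strict$calls) %in% key(res$calls)))
})

test_that("reverse-complementing genome and reads mirrors the call set", {
  fx <- fix_cohort(seed = 31, len = 6e4, n_families = 3, n_ins = 4)
  res <- detect_insertions(fx$ref, fx$lib, reads = fx$reads,
                           accession = "a")
  ref_rc <- revcomp(fx$ref)
  reads_rc <- revcomp(fx$reads)
  res_rc <- detect_insertions(ref_rc, fx$lib, reads = reads_rc,
                              accession = "a")
  L <- nchar(fx$ref[res$calls$chrom])
  mirrored <- data.frame(chrom = res$calls$chrom,
                         start = L - res$calls$end,
                         end = L - res$calls$start,
                         family = res$calls$family)
  key <- function(d) sort(paste(d$chrom, d$start, d$end, d$family))
  expect_identical(key(res_rc$calls), key(mirrored))
})

test_that("genotyping marks presence from two spanning reads and builds the matrix", {
  fx <- cohort
  res <- detect_insertions(fx$ref, fx$lib, reads = fx$reads,
                           accession = "acc1")
  call1 <- res$calls[1, ]
  ev2 <- make_ev(rep(call1$start, 2), family = call1$family,
                 chrom = call1$chrom)
  expect_identical(genotype_call(call1, ev2, cfg)$present, 1L)
  ev1 <- make_ev(call1$start, family = call1$family, chrom = call1$chrom)
  expect_identical(genotype_call(call1, ev1, cfg)$present, 0L)
  # full matrix: discovery accession carries every call; an accession
  # without matching evidence carries none
  gm <- genotype_matrix(res$calls,
                        list(acc1 = res$evidence,
                             acc2 = make_ev(9e6, family = "none",
                                            chrom = "chr1")),
                        cfg)
  expect_true(all(gm$presence[, "acc1"] == 1L))
  expect_true(all(gm$presence[, "acc2"] == 0L))
  afs <- allele_frequency_spectrum(gm)
  expect_identical(unname(afs$classes["private"]), nrow(res$calls))
  expect_identical(sum(afs$spectrum), nrow(res$calls))
  # a call carried by 3 accessions lands in the shared 2-10 class
  gm3 <- list(presence = matrix(c(1L, 1L, 1L, 0L), 1, 4,
                                dimnames = list("c", paste0("a", 1:4))))
  class(gm3) <- "genotype_matrix"
  expect_identical(unname(allele_frequency_spectrum(gm3)$classes),
                   c(0L, 1L, 0L))
})
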