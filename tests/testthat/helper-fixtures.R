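# Shared fixture builders. Everything is generated in code; no files on
# disk beyond tempfiles created per test.

fix_genome <- function(seed = 1, len = 20000, n_chroms = 1) {
  simulate_reference(sim_config(rng_seed = seed, n_chroms = n_chroms,
                                chrom_len_bp = len))
}

# hand-built coverage profile for unit tests of the CNV machinery
fix_profile <- function(raw, gc = rep(0.5, length(raw)), chrom = "c1",
                        win = 100L, accession = "acc") {
  n <- length(raw)
  windows <- data.frame(chrom = chrom, start = seq(0L, by = win,
                                                   length.out = n),
                        end = seq(win, by = win, length.out = n),
                        gc_frac = gc, raw_rc = raw, corr_rc = raw,
                        stringsAsFactors = FALSE)
  out <- list(accession = accession, windows = windows,
              genome_median_rc = stats::median(raw))
  class(out) <- "coverage_profile"
  out
}

# small synthetic cohort shared by caller tests: one reference, one TE
# library, one accession with planted insertions, error-free reads
fix_cohort <- function(seed = 7, len = 2e5, n_families = 5, n_ins = 8,
                       coverage = 25) {
  sc <- sim_config(rng_seed = seed, n_chroms = 2, chrom_len_bp = len / 2,
                   n_families = n_families,
                   insertions_per_accession = n_ins,
                   mean_coverage = coverage)
  ref <- simulate_reference(sc)
  lib <- simulate_te_families(sc)
  acc <- plant_insertions(ref, lib, sc)
  rd <- simulate_reads(acc$genome, sc)
  reads <- c(rd$mate1, rd$mate2)
  names(reads) <- make.unique(names(reads))
  list(sc = sc, ref = ref, lib = lib, acc = acc, reads = reads)
}

# brute-force oracles (independent of the aligner implementation: plain
# substring-vector scans, no regex engine)

brute_positions <- function(pattern, subject) {
  L <- nchar(pattern)
  Tn <- nchar(subject)
  if (L > Tn) return(integer(0))
  subs <- substring(subject, 1:(Tn - L + 1L), L:Tn)
  which(subs == pattern) - 1L
}

brute_e2e <- function(fragment, genome) {
  hits <- NULL
  cnt <- 0L
  for (ch in names(genome)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fragment else revcomp(fragment)
      pos <- brute_positions(pat, genome[[ch]])
      cnt <- cnt + length(pos)
      if (length(pos)) {
        hits <- rbind(hits, data.frame(chrom = ch, pos = pos[1],
                                       strand = strand,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (cnt == 1L) as.list(hits[1, ]) else NULL
}

brute_local <- function(read, target, min_clip = 20L) {
  n <- nchar(read)
  combos <- list(c("+", "prefix"), c("+", "suffix"),
                 c("-", "prefix"), c("-", "suffix"))
  seqs <- c(read, read, revcomp(read), revcomp(read))
  best_len <- 0L
  plc <- NULL
  for (k in 1:4) {
    for (L in n:1) {
      pat <- if (combos[[k]][2] == "prefix") substr(seqs[k], 1, L)
      else substr(seqs[k], n - L + 1L, n)
      pos <- brute_positions(pat, target)
      if (length(pos)) {
        if (L > best_len) {
          best_len <- L
          plc <- data.frame(strand = combos[[k]][1], end = combos[[k]][2],
                            pos = pos, stringsAsFactors = FALSE)
        } else if (L == best_len) {
          plc <- rbind(plc, data.frame(strand = combos[[k]][1],
                                       end = combos[[k]][2], pos = pos,
                                       stringsAsFactors = FALSE))
        }
        break
      }
    }
  }
  if (best_len == n && !is.null(plc)) {
    plc <- plc[!duplicated(plc[c("strand", "pos")]), , drop = FALSE]
  }
  if (best_len < min_clip || is.null(plc) || nrow(plc) != 1L) {
    return(list(mapped = FALSE))
  }
  list(mapped = TRUE, strand = plc$strand, end = plc$end, pos = plc$pos,
       block_len = best_len)
}

# expression / genotype / gene-model bundle for the expression-ratio test
fix_expression_setup <- function(n_genes = 100, n_acc = 30, seed = 1,
                                 effect = NULL) {
  with_seed(seed, {
    accs <- paste0("a", seq_len(n_acc))
    genes <- paste0("g", seq_len(n_genes))
    expr <- matrix(rlnorm(n_genes * n_acc, 2, 0.3), n_genes, n_acc,
                   dimnames = list(genes, accs))
    gmod <- gene_models(
      data.frame(gene_id = genes, chrom = "c1",
                 start = seq(0L, by = 5000L, length.out = n_genes),
                 end = seq(2000L, by = 5000L, length.out = n_genes),
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(gene_id = character(), kind = character(),
                 chrom = character(), start = integer(), end = integer()))
    calls <- data.frame(chrom = "c1",
                        start = seq(2100L, by = 5000L,
                                    length.out = n_genes),
                        end = seq(2110L, by = 5000L, length.out = n_genes),
                        family = "F", stringsAsFactors = FALSE)
    pres <- t(vapply(seq_len(n_genes), function(i) {
      k <- sample(3:10, 1)
      as.integer(seq_len(n_acc) %in% sample(n_acc, k))
    }, integer(n_acc)))
    colnames(pres) <- accs
    if (!is.null(effect)) {
      for (i in seq_len(n_genes %/% 2)) {
        fold <- if (i %% 2 == 0) effect else 1 / effect
        expr[i, pres[i, ] == 1] <- expr[i, pres[i, ] == 1] * fold
      }
    }
    gmat <- list(presence = pres, support = pres)
    class(gmat) <- "genotype_matrix"
    list(expr = expr, gmat = gmat, calls = calls, gm = gmod)
  })
}
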