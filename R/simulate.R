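#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so every generator is a pure function of
#' (configuration, seed).
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Settings of the synthetic mobilome generator: the reference genome,
#' the TE family library, the planted insertions and the paired-end
#' reads. Defaults emulate the study conditions of a short-read mobilome
#' survey: 100-bp paired-end reads, 3-15 bp family-specific TSDs,
#' 20-30x coverage.
#'
#' @param rng_seed integer seed.
#' @param n_chroms number of chromosomes.
#' @param chrom_len_bp chromosome length (recycled across chromosomes).
#' @param gc_target target GC fraction of the simulated reference.
#' @param gc_domain_bp when positive, base composition varies between
#'   GC domains of this width (isochore-like heterogeneity); 0 gives a
#'   homogeneous genome.
#' @param gc_domain_sd standard deviation of per-domain GC around
#'   `gc_target`.
#' @param gc_domain_levels optional vector of discrete GC levels domains
#'   are sampled from (isochore classes); overrides the Gaussian draw.
#' @param n_families number of TE families (with TSDs).
#' @param n_families_no_tsd additional families lacking a TSD (excluded
#'   from split-read calling, as for HELITRON-like elements).
#' @param te_len_range full-length TE size range in bp (min must be at
#'   least twice the extremity length so 5'/3' extremities are disjoint).
#' @param tsd_range inclusive range of family TSD lengths in bp.
#' @param read_len read length in bp.
#' @param mean_coverage haploid sequencing depth.
#' @param fragment_mean,fragment_sd insert-size distribution in bp.
#' @param error_rate per-base substitution error rate.
#' @param gc_bias strength of a linear GC retention bias imposed on
#'   fragments (0 = none); used to stress GC correction.
#' @param insertions_per_accession planted insertions per accession.
#' @param min_insertion_spacing minimum distance between planted sites.
#' @param allow_short_fragments allow fragments shorter than two read
#'   lengths.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(rng_seed = 1L, n_chroms = 2L, chrom_len_bp = 1e6,
                       gc_target = 0.36, n_families = 10L,
                       n_families_no_tsd = 0L,
                       gc_domain_bp = 0L, gc_domain_sd = 0.08,
                       gc_domain_levels = NULL,
                       te_len_range = c(700L, 1500L),
                       tsd_range = c(3L, 15L), read_len = 100L,
                       mean_coverage = 25, fragment_mean = 300,
                       fragment_sd = 30, error_rate = 0, gc_bias = 0,
                       insertions_per_accession = 30L,
                       min_insertion_spacing = 1000L,
                       allow_short_fragments = FALSE) {
  sc <- list(rng_seed = as.integer(rng_seed), n_chroms = as.integer(n_chroms),
             chrom_len_bp = as.numeric(chrom_len_bp),
             gc_target = as.numeric(gc_target),
             gc_domain_bp = as.integer(gc_domain_bp),
             gc_domain_sd = as.numeric(gc_domain_sd),
             gc_domain_levels = if (is.null(gc_domain_levels)) NULL
             else as.numeric(gc_domain_levels),
             n_families = as.integer(n_families),
             n_families_no_tsd = as.integer(n_families_no_tsd),
             te_len_range = as.integer(te_len_range),
             tsd_range = as.integer(tsd_range),
             read_len = as.integer(read_len),
             mean_coverage = as.numeric(mean_coverage),
             fragment_mean = as.numeric(fragment_mean),
             fragment_sd = as.numeric(fragment_sd),
             error_rate = as.numeric(error_rate),
             gc_bias = as.numeric(gc_bias),
             insertions_per_accession = as.integer(insertions_per_accession),
             min_insertion_spacing = as.integer(min_insertion_spacing),
             allow_short_fragments = isTRUE(allow_short_fragments))
  if (sc$gc_target < 0 || sc$gc_target > 1) {
    stop("sim_config: gc_target must be in [0,1]", call. = FALSE)
  }
  if (sc$error_rate < 0 || sc$error_rate > 1) {
    stop("sim_config: error_rate must be in [0,1]", call. = FALSE)
  }
  for (k in c("n_chroms", "chrom_len_bp", "read_len", "fragment_mean")) {
    if (sc[[k]] <= 0) stop("sim_config: ", k, " must be positive",
                           call. = FALSE)
  }
  if (any(sc$tsd_range < 3L) || any(sc$tsd_range > 15L)) {
    stop("sim_config: TSD lengths must lie within 3..15 bp", call. = FALSE)
  }
  class(sc) <- "sim_config"
  sc
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a reference genome
#'
#' Bases are drawn with the configured GC content, either homogeneously
#' or in isochore-like GC domains (`sc$gc_domain_bp`); deterministic
#' given `sc$rng_seed`.
#'
#' @param sc a [sim_config()].
#' @return Named character vector of chromosome sequences
#'   (`chr1`, `chr2`, ...).
#' @export
simulate_reference <- function(sc = sim_config()) {
  with_seed(sc$rng_seed, {
    lens <- rep_len(as.integer(sc$chrom_len_bp), sc$n_chroms)
    one_chrom <- function(L) {
      if (sc$gc_domain_bp <= 0L) return(random_dna(L, sc$gc_target))
      starts <- seq.int(1L, L, by = sc$gc_domain_bp)
      widths <- pmin(sc$gc_domain_bp, L - starts + 1L)
      gcs <- if (!is.null(sc$gc_domain_levels)) {
        sample(sc$gc_domain_levels, length(starts), replace = TRUE)
      } else {
        pmin(pmax(rnorm(length(starts), sc$gc_target, sc$gc_domain_sd),
                  0.1), 0.9)
      }
      paste(vapply(seq_along(starts), function(i) {
        random_dna(widths[i], gcs[i])
      }, character(1)), collapse = "")
    }
    stats::setNames(vapply(lens, one_chrom, character(1)),
                    paste0("chr", seq_len(sc$n_chroms)))
  })
}

# global percent identity between two sequences
global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  Biostrings::pid(pa) / 100
}

#' Simulate a TE family library
#'
#' Each family gets a fixed TSD length drawn uniformly from
#' `sc$tsd_range` (3-15 bp), a full-length sequence of at least twice the
#' extremity length (so that 5' and 3' extremities are disjoint), and
#' extremities that are pairwise less than 80% identical across families
#' (rejection sampled).
#'
#' @param sc a [sim_config()].
#' @param config a [pipeline_config()] (for `extremity_len`).
#' @param max_tries rejection-sampling bound per family.
#' @return List with `families` (data frame: `name`, `te_class`,
#'   `superfamily`, `tsd_len`, `extremity_5`, `extremity_3`) and
#'   `sequences` (named character vector of full-length TE sequences).
#' @export
simulate_te_families <- function(sc = sim_config(),
                                 config = pipeline_config(),
                                 max_tries = 50L) {
  elen <- config$extremity_len
  if (sc$te_len_range[1] < 2L * elen) {
    stop("te_len_range minimum must be at least 2 * extremity_len",
         call. = FALSE)
  }
  n_total <- sc$n_families + sc$n_families_no_tsd
  supers <- c("COPIA", "GYPSY", "MUDR", "HAT", "LINE", "CACTA")
  with_seed(sc$rng_seed + 1L, {
    seqs <- character(0)
    for (i in seq_len(n_total)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- random_dna(sample(sc$te_len_range[1]:sc$te_len_range[2], 1),
                           gc = sc$gc_target)
        ends_c <- c(substr(cand, 1L, elen),
                    substr(cand, nchar(cand) - elen + 1L, nchar(cand)))
        clash <- FALSE
        for (s in seqs) {
          ends_s <- c(substr(s, 1L, elen),
                      substr(s, nchar(s) - elen + 1L, nchar(s)))
          for (a in ends_c) for (b in ends_s) {
            if (global_identity(a, b) >= 0.8) clash <- TRUE
          }
          if (clash) break
        }
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("could not generate a sufficiently dissimilar family ",
                    "after ", max_tries, " tries", call. = FALSE)
      seqs <- c(seqs, cand)
    }
    names(seqs) <- sprintf("TEFAM%02d", seq_len(n_total))
    tsd <- c(sample(sc$tsd_range[1]:sc$tsd_range[2], sc$n_families,
                    replace = TRUE),
             rep(NA_integer_, sc$n_families_no_tsd))
    fam <- data.frame(
      name = names(seqs),
      te_class = rep_len(c("I", "II"), n_total),
      superfamily = rep_len(supers, n_total),
      tsd_len = tsd,
      extremity_5 = substr(seqs, 1L, elen),
      extremity_3 = substr(seqs, nchar(seqs) - elen + 1L, nchar(seqs)),
      stringsAsFactors = FALSE
    )
    rownames(fam) <- NULL
    list(families = fam, sequences = seqs)
  })
}

#' Plant TSD-flanked TE insertions into a genome
#'
#' At each insertion site the accession genome carries
#' `left flank + TSD + TE + TSD + right flank`, where the TSD is the
#' reference's `tsd_len` bases at the site, so the duplication is exact
#' by construction. Sites are at least `sc$min_insertion_spacing` apart,
#' keep a margin from chromosome ends and never intersect `exclusions`.
#'
#' @param genome reference genome (named character vector).
#' @param te_library output of [simulate_te_families()].
#' @param sc a [sim_config()].
#' @param exclusions optional interval data frame of forbidden zones.
#' @param accession accession name recorded in the truth table.
#' @return List with `genome` (the accession genome) and `truth` (data
#'   frame: `accession`, `family`, `chrom`, `start`, `end` — the TSD
#'   interval on the reference — `orientation`, `tsd_seq`).
#' @export
plant_insertions <- function(genome, te_library, sc = sim_config(),
                             exclusions = NULL, accession = "acc1") {
  fam <- te_library$families
  fam <- fam[!is.na(fam$tsd_len), , drop = FALSE]
  if (nrow(fam) == 0) stop("no TSD-bearing families to plant", call. = FALSE)
  n_ins <- sc$insertions_per_accession
  margin <- 500L
  lens <- nchar(genome)
  with_seed(sc$rng_seed + 2L + sum(utf8ToInt(accession)), {
    sites <- data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    fam_pick <- character(0)
    ori_pick <- character(0)
    tries <- 0L
    while (nrow(sites) < n_ins) {
      tries <- tries + 1L
      if (tries > 200L * n_ins) {
        stop("genome too small to place ", n_ins, " insertions at ",
             sc$min_insertion_spacing, " bp spacing", call. = FALSE)
      }
      fi <- sample(nrow(fam), 1L)
      t <- fam$tsd_len[fi]
      ch <- sample(names(genome), 1L, prob = lens)
      s <- sample.int(lens[[ch]] - 2L * margin - t, 1L) + margin
      cand <- data.frame(chrom = ch, start = s, end = s + t,
                         stringsAsFactors = FALSE)
      near <- sites[sites$chrom == ch, , drop = FALSE]
      if (nrow(near) &&
          any(abs(near$start - s) < sc$min_insertion_spacing)) next
      if (!is.null(exclusions) && nrow(exclusions) &&
          overlaps_any(cand, exclusions)) next
      sites <- rbind(sites, cand)
      fam_pick <- c(fam_pick, fam$name[fi])
      ori_pick <- c(ori_pick, sample(c("+", "-"), 1L))
    }
    truth <- data.frame(accession = accession, family = fam_pick,
                        chrom = sites$chrom, start = sites$start,
                        end = sites$end, orientation = ori_pick,
                        stringsAsFactors = FALSE)
    truth$tsd_seq <- substring(genome[truth$chrom], truth$start + 1L,
                               truth$end)
    acc <- genome
    for (ch in unique(truth$chrom)) {
      d <- truth[truth$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      ref <- genome[[ch]]
      pieces <- character(0)
      prev0 <- 0L # 0-based start of the next reference chunk
      for (i in seq_len(nrow(d))) {
        te <- te_library$sequences[[d$family[i]]]
        if (d$orientation[i] == "-") te <- revcomp(te)
        pieces <- c(pieces, substr(ref, prev0 + 1L, d$end[i]), te)
        prev0 <- d$start[i] # re-emit the TSD after the TE
      }
      pieces <- c(pieces, substr(ref, prev0 + 1L, nchar(ref)))
      acc[[ch]] <- paste(pieces, collapse = "")
    }
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = acc, truth = truth)
  })
}

#' Simulate paired-end reads
#'
#' Fragments are drawn with density proportional to chromosome length,
#' normal insert sizes, FR orientation, and substitution-only sequencing
#' errors. The expected pair count is
#' `coverage * genome_length / (2 * read_length)`. A linear GC retention
#' bias can be imposed on fragments (`sc$gc_bias`) to stress the GC
#' correction of coverage profiles.
#'
#' @param genome named character vector of sequences (reference or
#'   accession genome).
#' @param sc a [sim_config()].
#' @param out_prefix if non-`NULL`, write `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return List with `mate1`, `mate2` (named character vectors) and
#'   `truth` (data frame: `read_id`, `chrom`, `frag_start`, `frag_end`).
#' @export
simulate_reads <- function(genome, sc = sim_config(), out_prefix = NULL) {
  rl <- sc$read_len
  lens <- nchar(genome)
  glen <- sum(as.numeric(lens))
  n_pairs <- round(sc$mean_coverage * glen / (2 * rl))
  min_frag <- if (sc$allow_short_fragments) rl else 2L * rl
  with_seed(sc$rng_seed + 17L, {
    draw_batch <- function(m) {
      ch <- sample(names(genome), m, replace = TRUE, prob = lens)
      fl <- pmin(pmax(round(rnorm(m, sc$fragment_mean, sc$fragment_sd)),
                      min_frag), lens[ch])
      st <- floor(runif(m) * (lens[ch] - fl)) # 0-based fragment start
      keep <- rep(TRUE, m)
      if (sc$gc_bias != 0) {
        frags <- substring(genome[ch], st + 1L, st + fl)
        gc <- gc_fraction(frags)
        p <- pmin(pmax(1 + sc$gc_bias * (gc - 0.5), 0.05), 1)
        keep <- runif(m) < p
      }
      data.frame(chrom = ch, start = st, flen = fl,
                 stringsAsFactors = FALSE)[keep, , drop = FALSE]
    }
    acc <- draw_batch(n_pairs)
    while (nrow(acc) < n_pairs) {
      acc <- rbind(acc, draw_batch(n_pairs - nrow(acc) + 100L))
    }
    acc <- acc[seq_len(n_pairs), , drop = FALSE]
    m1 <- substring(genome[acc$chrom], acc$start + 1L, acc$start + rl)
    m2 <- revcomp(substring(genome[acc$chrom], acc$start + acc$flen - rl + 1L,
                            acc$start + acc$flen))
    if (sc$error_rate > 0) {
      m1 <- add_substitution_errors(m1, sc$error_rate)
      m2 <- add_substitution_errors(m2, sc$error_rate)
    }
    ids <- sprintf("frag%07d", seq_len(n_pairs))
    names(m1) <- ids
    names(m2) <- ids
    truth <- data.frame(read_id = ids, chrom = acc$chrom,
                        frag_start = acc$start,
                        frag_end = acc$start + acc$flen,
                        stringsAsFactors = FALSE)
    if (!is.null(out_prefix)) {
      write_fastq(m1, paste0(out_prefix, "_1.fastq"))
      write_fastq(m2, paste0(out_prefix, "_2.fastq"))
    }
    list(mate1 = m1, mate2 = m2, truth = truth)
  })
}

gc_fraction <- function(seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(ss, "GC")
  as.numeric(f) / Biostrings::width(ss)
}

add_substitution_errors <- function(reads, rate) {
  rl <- nchar(reads)
  n_err <- rbinom(1L, sum(rl), rate)
  if (n_err == 0) return(reads)
  ri <- sample(length(reads), n_err, replace = TRUE, prob = rl)
  pos <- 1L + floor(runif(n_err) * rl[ri])
  alt <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
  for (k in seq_len(n_err)) {
    cur <- substr(reads[ri[k]], pos[k], pos[k])
    if (alt[k] == cur) alt[k] <- setdiff(c("A", "C", "G", "T"), cur)[1]
    substr(reads[ri[k]], pos[k], pos[k]) <- alt[k]
  }
  reads
}

#' Simulate structured copy-number, climate and kinship matrices
#'
#' A two-population cohort: kinship is high within and low between
#' populations, climate carries a population offset plus independent
#' noise, and per-family copy number is a baseline plus
#' `effect_size * climate` plus noise of which a fixed share is
#' population-structured. With `effect_size = 0` the climate-CN
#' association is null (up to shared population structure, which the
#' partial Mantel test conditions away through kinship).
#'
#' @param n_accessions cohort size (at least 10).
#' @param n_families number of TE families (rows of the CN matrix).
#' @param effect_size linear effect of climate on copy number.
#' @param sc a [sim_config()] (only `rng_seed` is used).
#' @param structured_share share of CN noise variance tied to population.
#'   The default is deliberately modest: the permutation scheme of the
#'   partial Mantel test assumes approximate exchangeability, and under
#'   strong shared structure in both variables its size is inflated (a
#'   known limitation of the test), which would make `effect_size = 0`
#'   fail to be a genuine null.
#' @param climate_pop_offset mean climate difference between the two
#'   populations.
#' @return List with `cn` (families x accessions matrix), `climate`
#'   (named vector) and `kinship` (accessions x accessions matrix,
#'   unit diagonal).
#' @export
simulate_structured_matrices <- function(n_accessions, n_families,
                                         effect_size = 0,
                                         sc = sim_config(),
                                         structured_share = 0.1,
                                         climate_pop_offset = 0.5) {
  stopifnot(n_accessions >= 10)
  with_seed(sc$rng_seed + 23L, {
    accs <- sprintf("acc%03d", seq_len(n_accessions))
    fams <- sprintf("FAM%03d", seq_len(n_families))
    pop <- rep_len(1:2, n_accessions)
    kin <- matrix(0.2, n_accessions, n_accessions, dimnames = list(accs, accs))
    kin[outer(pop, pop, "==")] <- 0.6
    diag(kin) <- 1
    climate <- stats::setNames(climate_pop_offset * (pop == 2) +
                                 rnorm(n_accessions), accs)
    h <- structured_share
    cn <- matrix(NA_real_, n_families, n_accessions,
                 dimnames = list(fams, accs))
    for (f in seq_len(n_families)) {
      zpop <- rnorm(2)
      noise <- sqrt(h) * zpop[pop] + sqrt(1 - h) * rnorm(n_accessions)
      cn[f, ] <- 10 + effect_size * climate + noise
    }
    list(cn = cn, climate = climate, kinship = kin)
  })
}
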