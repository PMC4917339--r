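test_that("randomized positions stay in the allowed space with uniform density", {
  lens <- c(a = 30000L, b = 70000L)
  # everything outside one 1-kb region excluded
  excl <- rbind(genomic_intervals("a", 0, 30000),
                genomic_intervals("b", 0, 60000),
                genomic_intervals("b", 61000, 70000))
  null <- randomize_positions(50, lens, excl, n_iter = 20, seed = 1)
  for (it in c(1, 10, 20)) {
    p <- null_positions(null, it)
    expect_true(all(p$chrom == "b" & p$pos >= 60000 & p$pos < 61000))
  }
  # 30/70 split across chromosomes, within 2 points at 1e5 draws
  null2 <- randomize_positions(100, lens, NULL, n_iter = 1000, seed = 2)
  all_p <- do.call(rbind, lapply(1:1000, null_positions, null = null2))
  fr <- mean(all_p$chrom == "a")
  expect_lt(abs(fr - 0.3), 0.02)
  # chi-square goodness of fit over 20 equal bins of one chromosome
  nullu <- randomize_positions(100, c(c1 = 20000L), NULL, n_iter = 1000,
                               seed = 3)
  pu <- do.call(rbind, lapply(1:1000, null_positions, null = nullu))
  counts <- tabulate(pu$pos %/% 1000 + 1L, 20)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  # degenerate inputs
  expect_error(randomize_positions(10, lens, NULL, n_iter = 0), "empty")
  expect_error(randomize_positions(10, c(a = 100L),
                                   genomic_intervals("a", 0, 100)),
               "allowed space")
})

test_that("pericentromeric enrichment detects total clustering and stays calibrated", {
  lens <- c(c1 = 100000L)
  peri <- genomic_intervals("c1", 0, 10000)
  null <- randomize_positions(100, lens, NULL, n_iter = 400, seed = 4)
  # all calls pericentromeric vs ~10% expectation
  calls_in <- data.frame(chrom = "c1", start = seq(0, 9900, length.out = 100))
  res <- pericentromere_test(list(private = calls_in), peri, null)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$o_over_e, 5)
  # calls drawn from the null itself: O/E within the 95% CI in most reps
  null_draws <- randomize_positions(100, lens, NULL, n_iter = 50, seed = 5)
  cover <- vapply(1:50, function(it) {
    d <- null_positions(null_draws, it)
    r <- pericentromere_test(list(x = data.frame(chrom = d$chrom,
                                                 start = d$pos)),
                             peri, null)
    r$observed >= r$ci_low && r$observed <= r$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.86)
  # empty stratum is dropped with a warning
  expect_warning(
    res2 <- pericentromere_test(list(private = calls_in,
                                     shared = calls_in[0, ]), peri, null),
    "empty")
  expect_identical(nrow(res2), 1L)
})

test_that("window enrichment reports stacked insertions and controls false positives", {
  lens <- c(c1 = 1000000L)
  set.seed(6)
  spread <- data.frame(chrom = "c1",
                       start = sort(sample(999999L, 20)))
  stacked <- data.frame(chrom = "c1", start = 500000L + seq(0, 6000, 1000))
  calls <- rbind(spread, stacked)
  null <- randomize_positions(nrow(calls), lens, NULL, n_iter = 400,
                              seed = 7)
  res <- window_enrichment(calls, lens, null, window = 10000)
  expect_true(any(res$enriched$start == 500000L))
  expect_true(all(res$enriched$count >= res$threshold))
  # uniform calls at a looser tail: false positives within Poisson bounds
  cfg_loose <- pipeline_config(enrich_tail = 0.005)
  res_u <- window_enrichment(spread, lens, null =
                               randomize_positions(20, lens, NULL,
                                                   n_iter = 400, seed = 8),
                             window = 10000, config = cfg_loose)
  expect_lte(nrow(res_u$enriched), 3L)
  # zero calls, zero windows
  res0 <- window_enrichment(spread[0, ], lens, null, window = 10000)
  expect_identical(nrow(res0$enriched), 0L)
})

fix_gene_models <- function() {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(1000L, 5000L), end = c(2000L, 6000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = c("g1", "g1", "g1", "g1"),
    kind = c("five_prime_UTR", "exon", "exon", "three_prime_UTR"),
    chrom = "c1",
    start = c(1000L, 1000L, 1600L, 1900L),
    end = c(1100L, 1500L, 2000L, 2000L), stringsAsFactors = FALSE)
  gene_models(genes, features)
}

test_that("metagene assignment follows the UTR > exon > intron hierarchy with signed distances", {
  gm <- fix_gene_models()
  res <- metagene_assign(data.frame(chrom = "c1",
                                    pos = c(1050L, 1950L, 1550L, 1200L,
                                            6499L, 500L)), gm)
  # 1050 is in both an exon and the 5' UTR: the UTR wins
  expect_identical(res$class,
                   c("five_prime_UTR", "three_prime_UTR", "intron", "exon",
                     "intergenic", "intergenic"))
  # 500 bp 5' of the minus-strand gene g2 (downstream in genome coords)
  expect_identical(res$distance[5], -500L)
  expect_identical(res$gene_id[5], "g2")
  # upstream of the plus-strand gene g1
  expect_identical(res$distance[6], -500L)
  expect_identical(res$gene_id[6], "g1")
  # totality: every position receives exactly one class
  grid <- data.frame(chrom = "c1", pos = seq(0L, 7000L, by = 37L))
  all_cls <- metagene_assign(grid, gm)
  expect_false(anyNA(all_cls$class))
})

test_that("expression-ratio test: trivial ratio, planted effects detected", {
  fx <- fix_expression_setup(n_genes = 4, n_acc = 12, seed = 2)
  # force equal carrier and non-carrier medians for one gene
  fx$expr[1, ] <- 5
  res <- expression_ratio_test(fx$expr, fx$gmat, fx$calls[1, , drop = FALSE],
                               fx$gm, n_iter = 20, seed = 1)
  expect_equal(res$impacts$ratio[res$impacts$gene_id == "g1"], 1.0)
  # planted two-fold up/down regulation in carriers for half the genes
  fx2 <- fix_expression_setup(n_genes = 100, n_acc = 30, seed = 3,
                              effect = 2)
  res2 <- expression_ratio_test(fx2$expr, fx2$gmat, fx2$calls, fx2$gm,
                                n_iter = 300, seed = 2)
  expect_lt(res2$ks$p.value, 1e-3)
  expect_identical(nrow(res2$impacts), 100L)
})

test_that("methylation spreading classes follow the 300 bp / 1 kb landmarks", {
  # identical cohort profiles: no spreading
  flat <- methylation_spread_classify(rep(0.5, 30), rep(0.5, 30))
  expect_identical(flat$extent_bp, 0L)
  expect_identical(flat$klass, "none")
  # difference of 0.8 over 6 windows then none: 300 bp, short
  c6 <- c(rep(0.9, 6), rep(0.1, 24))
  s <- methylation_spread_classify(c6, rep(0.1, 30))
  expect_identical(s$extent_bp, 300L)
  expect_identical(s$klass, "short")
  # 25 spreading windows: 1250 bp, long
  c25 <- c(rep(0.9, 25), rep(0.1, 5))
  l <- methylation_spread_classify(c25, rep(0.1, 30))
  expect_identical(l$extent_bp, 1250L)
  expect_identical(l$klass, "long")
  # 12 windows = 600 bp: intermediate
  c12 <- c(rep(0.9, 12), rep(0.1, 18))
  m <- methylation_spread_classify(c12, rep(0.1, 30))
  expect_identical(m$klass, "intermediate")
  # a single low window does not stop the scan (two consecutive needed)
  gap <- c(0.9, 0.1, 0.9, 0.9, rep(0.1, 26))
  g <- methylation_spread_classify(gap, rep(0.1, 30))
  expect_identical(g$extent_bp, 200L)
  expect_identical(g$klass, "short")
})

test_that("partial Mantel: perfect association, exact enumeration, vegan agreement", {
  set.seed(9)
  n <- 12
  cn <- rnorm(n)
  kin <- matrix(runif(n * n, 0.2, 0.4), n, n)
  kin <- (kin + t(kin)) / 2
  diag(kin) <- 1
  pm <- partial_mantel(cn, cn, kin, n_perm = 199, seed = 1)
  expect_equal(pm$r_partial, 1, tolerance = 1e-9)
  expect_equal(pm$p_value, 1 / 200)
  # exhaustive enumeration at n = 6, checked against an independent
  # brute-force oracle written here from the partial-correlation formula
  n6 <- 6
  cn6 <- rnorm(n6)
  cl6 <- cn6 + rnorm(n6, 0, 0.5)
  kin6 <- matrix(runif(n6 * n6, 0.2, 0.4), n6, n6)
  kin6 <- (kin6 + t(kin6)) / 2
  diag(kin6) <- 1
  ex <- partial_mantel(cn6, cl6, kin6, exact = TRUE)
  expect_identical(ex$n_perm, 720L)
  oracle_stat <- function(perm) {
    dx <- abs(outer(cn6[perm], cn6[perm], "-"))
    dy <- abs(outer(cl6, cl6, "-"))
    dz <- 1 - kin6
    v <- function(m) m[upper.tri(m)]
    rxy <- cor(v(dx), v(dy)); rxz <- cor(v(dx), v(dz))
    ryz <- cor(v(dy), v(dz))
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  r_all <- apply(perms, 1, oracle_stat)
  r_obs <- oracle_stat(1:6)
  expect_equal(ex$r_partial, r_obs, tolerance = 1e-12)
  expect_equal(ex$p_value, mean(abs(r_all) >= abs(r_obs)),
               tolerance = 1e-12)
  # input validation
  expect_error(partial_mantel(c(cn, NA), c(cn, 1),
                              matrix(1, n + 1, n + 1)), "missing")
})

test_that("partial Mantel statistic matches the vegan implementation", {
  skip_if_not_installed("vegan")
  m <- simulate_structured_matrices(25, 1, effect_size = 0.8,
                                    sc = sim_config(rng_seed = 3))
  pm <- partial_mantel(m$cn[1, ], m$climate, m$kinship, n_perm = 99,
                       seed = 1)
  vm <- vegan::mantel.partial(
    stats::as.dist(abs(outer(m$cn[1, ], m$cn[1, ], "-"))),
    stats::as.dist(abs(outer(m$climate, m$climate, "-"))),
    stats::as.dist(1 - m$kinship), permutations = 49)
  expect_equal(pm$r_partial, unname(vm$statistic), tolerance = 1e-10)
})

test_that("closed forms: Bonferroni identity and variance recovery by simulation", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  # least-squares recovery of the variance-explained formula
  set.seed(10)
  n <- 10000
  maf <- 0.3
  beta <- 0.8
  x <- rbinom(n, 2, maf)
  y <- beta * x + rnorm(n)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  expect_lt(abs(variance_explained(maf, beta, stats::var(y)) - r2), 0.01)
})

test_that("detection-miss probability matches the binomial mass and is monotone", {
  expect_equal(prob_missing(1, 0.56, 12, 0), 0.56)
  expect_equal(prob_missing(0.3, 0, 12, 6), 0)
  expect_equal(prob_missing(0.05, 0.56, 12, 12), 0.56 * 0.95^12)
  # binomial-mass cross-check
  f <- 0.2
  for (k in c(0, 3, 12)) {
    expect_equal(prob_missing(f, 0.56, 12, k),
                 0.56 * stats::dbinom(12 - k, 12, f))
  }
  fgrid <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(prob_missing(fgrid, 0.5, 12, 12)) < 0))
  expect_lt(prob_missing(0.3, 0.2, 12, 12), prob_missing(0.3, 0.9, 12, 12))
})

test_that("benchmarking matches greedily one-to-one within tolerance", {
  truth <- data.frame(family = "F", chrom = "c1",
                      start = seq(1000L, 30000L, 1000L))
  truth$end <- truth$start + 5L
  # calls identical to truth
  br <- benchmark_rates(truth, truth)
  expect_identical(c(br$tp, br$fp, br$fn), c(30L, 0L, 0L))
  expect_equal(br$fn_rate, 0)
  expect_equal(br$fdr, 0)
  # three decoys on top of a fully recovered truth set
  decoys <- data.frame(family = "F", chrom = "c1",
                       start = c(500000L, 600000L, 700000L))
  decoys$end <- decoys$start + 5L
  br3 <- benchmark_rates(truth, rbind(truth, decoys))
  expect_equal(br3$fdr, 3 / 33)
  expect_identical(br3$fn, 0L)
  # two calls near one truth record: only the closer one matches
  two <- data.frame(family = "F", chrom = "c1", start = c(1003L, 1050L),
                    end = c(1008L, 1055L))
  br2 <- benchmark_rates(truth[1, ], two)
  expect_identical(c(br2$tp, br2$fp, br2$fn), c(1L, 1L, 0L))
  expect_identical(br2$matches$call_idx, 1L)
  # family mismatch prevents matching
  wrong <- truth[1, ]
  wrong$family <- "G"
  expect_identical(benchmark_rates(truth[1, ], wrong)$tp, 0L)
})
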