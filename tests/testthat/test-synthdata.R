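test_that("make_genome produces the requested SNP density and structure", {
  g <- make_genome(n_contigs = 10, contig_length = 1e5, snp_per_kb = 1,
                   repeat_fraction = 0, low_freq_site_fraction = 0,
                   seed = 1)
  lambda <- 10 * 1e5 * 1 / 1000
  expect_lt(abs(nrow(g$sites) - lambda), 3 * sqrt(lambda))
  expect_true(all(g$sites$alt_carrier %in% c("MAT-1", "MAT-2")))
  expect_false(any(g$sites$in_repeat))
  expect_true(all(g$sites$ref != g$sites$alt))
  expect_true(all(g$sites$pos >= 1 & g$sites$pos <= 1e5))
  # positions strictly increasing within contigs
  expect_true(all(tapply(g$sites$pos, g$sites$contig,
                         function(p) all(diff(p) > 0))))
  # determinism
  g2 <- make_genome(n_contigs = 10, contig_length = 1e5, snp_per_kb = 1,
                    repeat_fraction = 0, low_freq_site_fraction = 0,
                    seed = 1)
  expect_identical(g, g2)
  expect_error(make_genome(0, 1e5, 1), "n_contigs")
  expect_error(make_genome(10, 1e5, -1), "snp_per_kb")
})

test_that("repeat intervals cover about the requested genome fraction", {
  g <- make_genome(n_contigs = 20, contig_length = 1e5, snp_per_kb = 0.5,
                   repeat_fraction = 0.4, seed = 7)
  covered <- sum(g$repeats$end - g$repeats$start) / (20 * 1e5)
  expect_lt(abs(covered - 0.4), 0.05)
  # in_repeat flags agree with direct interval lookup
  expect_identical(g$sites$in_repeat, sites_in_repeats(g$sites, g$repeats))
  s <- genome_summary(g)
  expect_equal(s$repeat_percent, 100 * covered)
  expect_equal(s$n_snps, nrow(g$sites))
})

test_that("low-frequency sites carry a positive sub-fraction, others zero", {
  g <- make_genome(5, 5e4, 2, low_freq_site_fraction = 0.2, seed = 3)
  lf <- g$sites$alt_carrier == "low_frequency"
  expect_gt(sum(lf), 0)
  expect_true(all(g$sites$low_freq_fraction[lf] > 0))
  expect_true(all(g$sites$low_freq_fraction[!lf] == 0))
})

test_that("nucleus population follows the MAT ratio and consensus", {
  d <- demo_population(ratio_r = 0.6, n_nuclei = 10, seed = 5)
  pop <- d$pop
  expect_equal(sum(pop$nuclei$mat == "MAT-1"), 6)
  expect_equal(nrow(pop$tracts), 0)
  # without tracts or low-frequency sites, every nucleus matches its
  # nucleotype consensus: alt exactly where alt_carrier == its MAT
  sites <- d$genome$sites
  for (j in seq_len(10)) {
    expected <- as.integer(sites$alt_carrier == pop$nuclei$mat[j])
    expect_identical(unname(pop$alleles[, j]), expected)
  }
  # boundary: ratio 1 makes every nucleus MAT-1
  m1 <- nucleotype_model(1)
  p1 <- make_nucleus_population(d$genome, m1, 6, seed = 1)
  expect_true(all(p1$nuclei$mat == "MAT-1"))
})

test_that("implanted tracts are recorded and swap to the opposite consensus", {
  d <- demo_population(ratio_r = 0.5, n_nuclei = 8, n_tracts = 3,
                       tract_len = 6, seed = 11)
  pop <- d$pop
  expect_equal(nrow(pop$tracts), 3)
  expect_true(all(pop$tracts$last_index - pop$tracts$first_index + 1 == 6))
  sites <- d$genome$sites
  for (k in seq_len(3)) {
    tr <- pop$tracts[k, ]
    j <- match(tr$nucleus_id, pop$nuclei$nucleus_id)
    global <- which(sites$contig == tr$contig)[tr$first_index:tr$last_index]
    opp_mat <- setdiff(c("MAT-1", "MAT-2"), pop$nuclei$mat[j])
    expect_identical(unname(pop$alleles[global, j]),
                     as.integer(sites$alt_carrier[global] == opp_mat))
  }
  expect_error(
    make_nucleus_population(d$genome, d$model, 8, n_recomb_tracts = 1,
                            tract_len_snps = 10000, seed = 1),
    "tract_len_snps")
})

test_that("pool counts respect the count law and the expected frequencies", {
  d <- demo_population(ratio_r = 0.5, n_nuclei = 10, n_contigs = 10,
                       contig_length = 2e5, mean_depth = 100, seed = 21)
  vt <- simulate_pool_counts(d$pop, d$model, seed = 1)
  expect_s3_class(vt, "variant_table")
  # error-free: RO + AO == DP everywhere
  expect_true(all(vt$ro + vt$ao == vt$dp))
  f <- af_spectrum(vt, "pool")$frequencies
  expect_lt(abs(mean(f) - 0.5), 0.01)
  # determinism
  vt2 <- simulate_pool_counts(d$pop, d$model, seed = 1)
  expect_identical(vt, vt2)
  # with sequencing error, some reads fall off the allele pair
  m_err <- nucleotype_model(0.5, error_rate = 0.05, mean_depth = 100)
  vte <- simulate_pool_counts(d$pop, m_err, seed = 2)
  expect_true(all(vte$ro + vte$ao <= vte$dp))
  expect_gt(sum(vte$dp - vte$ro - vte$ao), 0)
})

test_that("a 2:1 pool shows mirrored 33/67 modes and MAT-2 sites track 1 - r", {
  d <- demo_population(ratio_r = 2 / 3, n_nuclei = 30, n_contigs = 25,
                       contig_length = 2e5, mean_depth = 110, seed = 31)
  vt <- simulate_pool_counts(d$pop, d$model, seed = 3)
  modes <- detect_modes(af_spectrum(vt, "pool"))
  expect_length(modes, 2)
  expect_lt(abs(modes[1] - 100 / 3), 2)
  expect_lt(abs(modes[2] - 200 / 3), 2)
  # marginal alt frequency at MAT-2-carrier sites is 1 - ratio_r
  is2 <- d$genome$sites$alt_carrier == "MAT-2"
  f <- vt$ao[, 1] / (vt$ro[, 1] + vt$ao[, 1])
  expect_lt(abs(mean(f[is2]) - (1 - mean(d$pop$nuclei$mat == "MAT-1"))),
            0.01)
})

test_that("low-frequency sites appear at fraction x MAT-share read frequency", {
  g <- make_genome(4, 5e4, 1, low_freq_site_fraction = 0, seed = 8)
  # plant one low-frequency site by hand: fraction 0.2 within one MAT
  g$sites$alt_carrier[1] <- "low_frequency"
  g$sites$low_freq_fraction[1] <- 0.2
  m <- nucleotype_model(0.5, error_rate = 0, mean_depth = 100)
  # 10 nuclei -> 5 per MAT; 0.2 * 5 = 1 carrier nucleus -> freq 0.1
  freqs <- vapply(1:200, function(k) {
    p <- make_nucleus_population(g, m, 10, seed = k)
    vt <- simulate_pool_counts(p, m, seed = 1000 + k)
    vt$ao[1, 1] / (vt$ro[1, 1] + vt$ao[1, 1])
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 0.1), 0.02)
})

test_that("single-nucleus counts reflect dropout, purity and contamination", {
  d <- demo_population(ratio_r = 0.5, n_nuclei = 6, n_contigs = 4,
                       contig_length = 5e4, mean_depth = 40, seed = 41)
  clean <- simulate_nucleus_counts(d$pop, d$model, 0, 0, seed = 1)
  # no contamination/error: every covered site homozygous for the allele
  for (j in seq_len(6)) {
    cov <- !is.na(clean$dp[, j])
    a <- d$pop$alleles[cov, j]
    expect_true(all(clean$ao[cov, j][a == 1] == clean$dp[cov, j][a == 1]))
    expect_true(all(clean$ro[cov, j][a == 0] == clean$dp[cov, j][a == 0]))
  }
  # dropout = 1 removes all coverage
  dead <- simulate_nucleus_counts(d$pop, d$model, 0, 1, seed = 1)
  expect_true(all(is.na(dead$dp)))
  # heterozygous-looking sites increase with contamination
  het_rate <- vapply(c(0, 0.15, 0.3), function(cr) {
    vt <- simulate_nucleus_counts(d$pop, d$model, cr, 0, seed = 9)
    minor <- pmin(vt$ro, vt$ao) / vt$dp
    mean(minor >= 0.1, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(het_rate) > 0))
})

test_that("RNA counts follow the closed-form host mixing weights", {
  d <- demo_population(ratio_r = 2 / 3, n_nuclei = 30, n_contigs = 20,
                       contig_length = 2e5, mean_depth = 80, seed = 51)
  rna <- simulate_rna_counts(d$pop, d$model,
                             host_weights = list(even = c(1, 1),
                                                 equalizing = c(1, 2)),
                             expressed_fraction = 0.8, n_replicates = 2,
                             seed = 5)
  expect_named(rna, c("even", "equalizing"))
  expect_length(rna$even, 2)
  # same expressed subset across replicates of a host
  expect_identical(unname(is.na(rna$even[[1]]$dp)),
                   unname(is.na(rna$even[[2]]$dp)))
  # w = (1,1) keeps the genomic 2:1 mixture: modes near 33 and 67
  modes_even <- detect_modes(af_spectrum(rna$even[[1]], "even_rep1"))
  expect_length(modes_even, 2)
  expect_lt(abs(modes_even[1] - 100 / 3), 2)
  expect_lt(abs(modes_even[2] - 200 / 3), 2)
  # w = (1,2) at r = 2/3 equalizes expression: single mode near 50
  modes_eq <- detect_modes(af_spectrum(rna$equalizing[[1]],
                                       "equalizing_rep1"))
  expect_length(modes_eq, 1)
  expect_lt(abs(modes_eq - 50), 2)
  # w = (1,0): only MAT-1 transcripts, every expressed site monoallelic
  rna1 <- simulate_rna_counts(d$pop, d$model,
                              host_weights = list(only1 = c(1, 0)),
                              expressed_fraction = 0.5, n_replicates = 1,
                              seed = 6)
  vt <- rna1$only1[[1]]
  cov <- !is.na(vt$dp[, 1])
  expect_true(all(vt$ro[cov, 1] == 0 | vt$ao[cov, 1] == 0))
})

test_that("repeat sites are never expressed", {
  d <- demo_population(ratio_r = 0.5, n_nuclei = 10, repeat_fraction = 0.3,
                       seed = 61)
  rna <- simulate_rna_counts(d$pop, d$model,
                             host_weights = list(h = c(1, 1)),
                             expressed_fraction = 1, n_replicates = 1,
                             seed = 1)
  vt <- rna$h[[1]]
  expect_true(all(is.na(vt$dp[d$genome$sites$in_repeat, 1])))
  expect_true(all(!is.na(vt$dp[!d$genome$sites$in_repeat, 1])))
})
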