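test_that("call_nucleus applies depth, heterozygosity and majority rules", {
  # AO/DP exactly at the threshold is NOT heterozygous (strict >)
  vt <- toy_table(dp = c(20, 20, 9, 20, NA),
                  ro = c(18, 12, 9, 2, NA),
                  ao = c(2, 8, 0, 18, NA))
  cs <- call_nucleus(vt, "s1", het_filter_params(0.1, 500, 10))
  expect_equal(cs$calls, c("ref", NA, NA, "alt", NA))
  expect_equal(cs$het, c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("heterozygous neighbourhoods are excised at inclusive distance", {
  sites <- data.frame(contig = c("A", "A", "A", "A", "B"),
                      pos = c(600, 1000, 1400, 1501, 1000))
  keep <- exclude_heterozygous_neighborhoods(sites, het_index = 2,
                                             proximity_bp = 500)
  # het site at A:1000 removes itself, 600 and 1400; 1501 is 501 bp away;
  # contig B is untouched
  expect_equal(keep, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # boundary: exactly proximity_bp away is removed
  keep2 <- exclude_heterozygous_neighborhoods(
    data.frame(contig = "A", pos = c(500, 1000, 1500)), 2, 500)
  expect_equal(keep2, c(FALSE, FALSE, FALSE))
  expect_true(all(exclude_heterozygous_neighborhoods(sites, integer(0),
                                                     500)))
})

test_that("discordance flags follow the within-MAT both-alleles rule", {
  mats <- c("MAT-1", "MAT-1", "MAT-2", "MAT-2")
  calls <- rbind(c("ref", "alt", "alt", "alt"),   # MAT-1 group split
                 c("ref", "ref", "alt", "alt"),   # canonical dikaryon
                 c("ref", NA, "alt", "alt"))      # missing excluded
  cs <- callsets_from_matrix(t(t(calls)), mats)
  res <- find_discordant_snps(cs)
  expect_equal(res$discordant, c(TRUE, FALSE, FALSE))
  expect_equal(res$n_total, 3)
  expect_equal(res$n_discordant, 1)
  expect_error(find_discordant_snps(
    callsets_from_matrix(calls[, 1:2, drop = FALSE],
                         c("MAT-1", "MAT-2"))),
    "sharing a MAT")
})

test_that("discordance percentage arithmetic", {
  expect_equal(round(discordance_percentage(503, 9947)), 5)
  expect_equal(discordance_percentage(0, 10), 0)
  expect_equal(discordance_percentage(10, 10), 100)
  expect_error(discordance_percentage(1, 0), "n_total")
})

test_that("block calling: runs, maximality and contig skipping", {
  f <- function(x) x == "D"
  sites7 <- toy_sites(7)
  b <- find_recombination_blocks(sites7,
                                 f(c("C", "D", "D", "D", "D", "D", "C")))
  expect_equal(nrow(b), 1)
  expect_equal(b$first_index, 2)
  expect_equal(b$last_index, 6)
  expect_equal(b$n_snps, 5)
  # two runs of 4 interrupted by one concordant site: no block
  b2 <- find_recombination_blocks(
    toy_sites(9), f(c("D", "D", "D", "D", "C", "D", "D", "D", "D")))
  expect_equal(nrow(b2), 0)
  # a single-SNP contig is skipped even if discordant
  b3 <- find_recombination_blocks(toy_sites(1), TRUE, min_run = 1)
  expect_equal(nrow(b3), 0)
  # blocks never span contigs
  sites2 <- rbind(toy_sites(5, contig = "c1"), toy_sites(5, contig = "c2"))
  b4 <- find_recombination_blocks(sites2, rep(TRUE, 10), min_run = 5)
  expect_equal(b4$contig, c("c1", "c2"))
  expect_equal(b4$n_snps, c(5, 5))
})

test_that("discordance and block calling match brute-force enumeration", {
  set.seed(123)
  for (case in 1:200) {
    n_nuc <- sample(2:8, 1)
    n_sites <- sample(5:50, 1)
    mats <- sample(c("MAT-1", "MAT-2"), n_nuc, replace = TRUE)
    if (!any(duplicated(mats))) mats[2] <- mats[1]
    calls <- matrix(sample(c("ref", "alt", NA), n_nuc * n_sites,
                           replace = TRUE, prob = c(0.45, 0.45, 0.1)),
                    n_sites, n_nuc)
    n_contigs <- sample(1:3, 1)
    contigs <- sort(sample(n_contigs, n_sites, replace = TRUE))
    sites <- data.frame(contig = paste0("c", contigs),
                        pos = unlist(lapply(table(contigs), function(k)
                          seq_len(k) * 100)),
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
    cs <- callsets_from_matrix(calls, mats, sites)
    got <- find_discordant_snps(cs)
    expect_identical(got$discordant, oracle_discordant(calls, mats))
    min_run <- sample(2:5, 1)
    got_b <- find_recombination_blocks(sites, got$discordant,
                                       min_run = min_run)
    want_b <- oracle_blocks(sites, got$discordant, min_run = min_run)
    expect_equal(got_b[, c("contig", "first_index", "last_index",
                           "n_snps")],
                 want_b, ignore_attr = TRUE)
  }
})

test_that("increasing min_run never increases the number of blocks", {
  set.seed(5)
  sites <- toy_sites(80)
  flags <- runif(80) < 0.5
  counts <- vapply(1:8, function(mr)
    nrow(find_recombination_blocks(sites, flags, min_run = mr)),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("similarity matrix counts agreement over co-called sites", {
  calls <- cbind(a = c("ref", "ref", "alt", "alt"),
                 b = c("ref", "ref", "alt", "ref"),
                 c = c(NA, NA, NA, NA))
  cs <- callsets_from_matrix(calls, c("MAT-1", "MAT-1", "MAT-2"))
  s <- similarity_matrix(cs)
  expect_equal(s["a", "b"], 0.75)
  expect_equal(s["a", "a"], 1)
  expect_true(is.na(s["a", "c"]))  # zero co-called sites
  expect_equal(s, t(s))
  # identical callsets are fully similar
  s2 <- similarity_matrix(callsets_from_matrix(calls[, c(1, 1)],
                                               c("MAT-1", "MAT-1")))
  expect_equal(s2[1, 2], 1)
})

test_that("within-MAT similarity exceeds between-MAT on clean dikaryon data", {
  d <- demo_population(ratio_r = 0.5, n_nuclei = 8, n_contigs = 5,
                       contig_length = 5e4, mean_depth = 50, seed = 201)
  nuc <- simulate_nucleus_counts(d$pop, d$model, 0, 0, seed = 202)
  cs <- lapply(seq_len(8), function(j)
    call_nucleus(nuc, d$pop$nuclei$nucleus_id[j],
                 mat = d$pop$nuclei$mat[j]))
  s <- similarity_matrix(cs)
  mats <- d$pop$nuclei$mat
  same <- outer(mats, mats, "==") & upper.tri(s)
  diff_mat <- outer(mats, mats, "!=") & upper.tri(s)
  expect_gt(mean(s[same]), mean(s[diff_mat]))
  expect_gt(mean(s[same]), 0.99)
  expect_lt(mean(s[diff_mat]), 0.01)
})

test_that("implanted tracts are recovered exactly; short tracts are not called", {
  for (seed in 1:50) {
    tract_len <- if (seed <= 35) 5 + seed %% 3 else seed %% 4 + 1
    d <- demo_population(ratio_r = 0.5, n_nuclei = 8, n_contigs = 4,
                         contig_length = 6e4, n_tracts = 2,
                         tract_len = tract_len, mean_depth = 50,
                         seed = 300 + seed)
    nuc <- simulate_nucleus_counts(d$pop, d$model, 0, 0,
                                   seed = 400 + seed)
    pool <- simulate_pool_counts(d$pop,
                                 nucleotype_model(0.5, 0, 1000),
                                 seed = 500 + seed)
    res <- analyze_nuclei(pool, nuc, d$pop$nuclei,
                          params = het_filter_params(min_depth = 1))
    blocks <- res$blocks
    if (tract_len >= 5) {
      truth <- d$pop$tracts[order(d$pop$tracts$contig,
                                  d$pop$tracts$first_index), ]
      got <- blocks[order(blocks$contig, blocks$first_index), ]
      expect_equal(nrow(got), 2)
      expect_equal(got$contig, truth$contig)
      expect_equal(got$first_index, truth$first_index)
      expect_equal(got$last_index, truth$last_index)
      # the recombinant nucleus is identified as the minority carrier
      expect_equal(got$nuclei, truth$nucleus_id)
    } else {
      expect_equal(nrow(blocks), 0)
    }
  }
})

test_that("clean tract-free data yields zero discordant SNPs end to end", {
  d <- demo_population(ratio_r = 0.5, n_nuclei = 10, n_contigs = 5,
                       contig_length = 5e4, n_tracts = 0,
                       mean_depth = 50, seed = 601)
  nuc <- simulate_nucleus_counts(d$pop, d$model, 0, 0, seed = 602)
  pool <- simulate_pool_counts(d$pop, nucleotype_model(0.5, 0, 1000),
                               seed = 603)
  res <- analyze_nuclei(pool, nuc, d$pop$nuclei,
                        params = het_filter_params(min_depth = 1))
  expect_equal(res$discordance$n_discordant, 0)
  expect_equal(nrow(res$blocks), 0)
})

test_that("contamination produces het flags that excise neighbourhoods", {
  d <- demo_population(ratio_r = 0.5, n_nuclei = 6, n_contigs = 3,
                       contig_length = 3e4, mean_depth = 60, seed = 701)
  nuc <- simulate_nucleus_counts(d$pop, d$model, contamination_rate = 0.4,
                                 dropout_rate = 0, seed = 702)
  pool <- simulate_pool_counts(d$pop, nucleotype_model(0.5, 0, 1000),
                               seed = 703)
  res <- analyze_nuclei(pool, nuc, d$pop$nuclei)
  expect_gt(res$n_het_excluded, 0)
})
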