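#' Pooled-DNA SNP filter parameters
#'
#' Thresholds used to retain trustworthy biallelic SNPs in a pooled
#' (meta-genome) DNA sample: read depth within a window around the mean
#' mapping depth, and a minimum number of observations of *both* alleles.
#' Defaults follow the depth window 85-135x around a mean of 110x with at
#' least 10 observations per allele.
#'
#' @param cov_lo,cov_hi inclusive depth bounds (reads), `0 < cov_lo <=
#'   cov_hi`.
#' @param min_allele_obs minimum observations required of each allele.
#' @param exclude_repeats drop sites inside repeat-annotated intervals.
#' @return An object of class `pool_filter_params`.
#' @export
pool_filter_params <- function(cov_lo = 85, cov_hi = 135,
                               min_allele_obs = 10, exclude_repeats = TRUE) {
  if (!(cov_lo > 0 && cov_lo <= cov_hi))
    stop_hk("need 0 < cov_lo <= cov_hi")
  check_count(min_allele_obs, "min_allele_obs", min = 0L)
  structure(list(cov_lo = cov_lo, cov_hi = cov_hi,
                 min_allele_obs = min_allele_obs,
                 exclude_repeats = isTRUE(exclude_repeats)),
            class = "pool_filter_params")
}

#' RNA SNP filter parameters
#'
#' @param min_depth minimum (replicate-summed) depth per host.
#' @param min_allele_obs minimum observations of each allele per host.
#' @param require_all_hosts a site must pass in every host to be retained.
#' @return An object of class `rna_filter_params`.
#' @export
rna_filter_params <- function(min_depth = 20, min_allele_obs = 10,
                              require_all_hosts = TRUE) {
  check_count(min_depth, "min_depth", min = 0L)
  check_count(min_allele_obs, "min_allele_obs", min = 0L)
  if (min_depth < min_allele_obs)
    stop_hk("min_depth must be >= min_allele_obs")
  structure(list(min_depth = min_depth, min_allele_obs = min_allele_obs,
                 require_all_hosts = isTRUE(require_all_hosts)),
            class = "rna_filter_params")
}

#' Symmetric coverage window around a mean depth
#'
#' @param mean_depth mean mapping depth (reads).
#' @param half_width half-width of the window; `0 < half_width <
#'   mean_depth`.
#' @return Numeric pair `(cov_lo, cov_hi) = mean_depth -/+ half_width`.
#' @examples
#' coverage_window(110, 25)  # 85 135
#' @export
coverage_window <- function(mean_depth, half_width) {
  if (!(half_width > 0 && half_width < mean_depth))
    stop_hk("need 0 < half_width < mean_depth")
  c(cov_lo = mean_depth - half_width, cov_hi = mean_depth + half_width)
}

#' Filter pooled-DNA SNPs on depth, allele support and repeat status
#'
#' A site survives iff `cov_lo <= DP <= cov_hi`, `RO >= min_allele_obs`,
#' `AO >= min_allele_obs`, and (when `exclude_repeats`) the site lies
#' outside every repeat interval. Sites with missing counts are removed.
#' Order is preserved; filtering is idempotent.
#'
#' @param table a [variant_table()].
#' @param sample sample name whose counts drive the filter.
#' @param params a [pool_filter_params()].
#' @param repeats optional `repeat_intervals` data.frame (see
#'   [read_repeat_bed()]); required when `params$exclude_repeats`.
#' @return The filtered [variant_table()] (all samples retained).
#' @export
filter_pool_snps <- function(table, sample, params = pool_filter_params(),
                             repeats = NULL) {
  stopifnot(inherits(table, "variant_table"),
            inherits(params, "pool_filter_params"))
  j <- match(sample, table$samples)
  if (is.na(j)) stop_hk("sample '%s' not in table", sample)
  dp <- table$dp[, j]; ro <- table$ro[, j]; ao <- table$ao[, j]
  keep <- !is.na(dp) & !is.na(ro) & !is.na(ao) &
    dp >= params$cov_lo & dp <= params$cov_hi &
    ro >= params$min_allele_obs & ao >= params$min_allele_obs
  if (params$exclude_repeats) {
    if (is.null(repeats))
      repeats <- repeat_intervals(NULL)
    keep <- keep & !sites_in_repeats(table$sites, repeats)
  }
  subset_table(table, which(keep))
}

#' Filter expressed SNPs across hosts and compute per-host frequencies
#'
#' Counts are summed over a host's replicates (or, with
#' `pool_replicates = FALSE`, thresholds must hold in every replicate
#' separately). With `require_all_hosts`, a site survives iff in every host
#' the summed depth is at least `min_depth` and both allele counts are at
#' least `min_allele_obs`; otherwise a site survives if it passes in at
#' least one host.
#'
#' @param tables named list: host name -> list of [variant_table()]
#'   replicates (a bare `variant_table` is accepted as a single replicate).
#'   All tables must share the same site set.
#' @param params an [rna_filter_params()].
#' @param pool_replicates sum counts over replicates within a host before
#'   thresholding (default) rather than thresholding each replicate.
#' @return List with `sites` (data.frame of surviving sites), `keep`
#'   (logical over the input site order), and `frequencies` (matrix sites x
#'   hosts of alternate-allele frequencies `AO / (RO + AO)` from
#'   replicate-summed counts, rows restricted to surviving sites).
#' @export
filter_rna_snps <- function(tables, params = rna_filter_params(),
                            pool_replicates = TRUE) {
  stopifnot(inherits(params, "rna_filter_params"))
  if (length(tables) < 1L) stop_hk("need at least one host")
  tables <- lapply(tables, function(x)
    if (inherits(x, "variant_table")) list(x) else x)
  for (h in names(tables))
    if (length(tables[[h]]) == 0L)
      stop_hk("host '%s' has zero replicates", h)
  hosts <- names(tables)
  ref_sites <- tables[[1]][[1]]$sites
  key0 <- site_keys(ref_sites)
  n <- nrow(ref_sites)
  sum_counts <- function(reps, field) {
    acc <- matrix(0, n, 1)
    for (vt in reps) {
      if (!identical(site_keys(vt$sites), key0))
        stop_hk("replicate tables must share an identical site set")
      x <- rowSums(vt[[field]], na.rm = TRUE)
      acc <- acc + x
    }
    acc[, 1]
  }
  pass <- matrix(FALSE, n, length(hosts), dimnames = list(NULL, hosts))
  freqs <- matrix(NA_real_, n, length(hosts), dimnames = list(NULL, hosts))
  for (h in hosts) {
    ro_h <- sum_counts(tables[[h]], "ro")
    ao_h <- sum_counts(tables[[h]], "ao")
    dp_h <- sum_counts(tables[[h]], "dp")
    if (pool_replicates) {
      pass[, h] <- dp_h >= params$min_depth &
        ro_h >= params$min_allele_obs & ao_h >= params$min_allele_obs
    } else {
      ok <- rep(TRUE, n)
      for (vt in tables[[h]]) {
        dp1 <- vt$dp[, 1]; ro1 <- vt$ro[, 1]; ao1 <- vt$ao[, 1]
        ok <- ok & !is.na(dp1) & dp1 >= params$min_depth &
          !is.na(ro1) & ro1 >= params$min_allele_obs &
          !is.na(ao1) & ao1 >= params$min_allele_obs
      }
      pass[, h] <- ok
    }
    denom <- ro_h + ao_h
    freqs[denom > 0, h] <- (ao_h / denom)[denom > 0]
  }
  keep <- if (params$require_all_hosts) apply(pass, 1, all)
          else apply(pass, 1, any)
  list(sites = ref_sites[keep, , drop = FALSE], keep = keep,
       frequencies = freqs[keep, , drop = FALSE])
}

#' SNP density in SNPs per kilobase
#'
#' @param n_snps number of SNPs.
#' @param genome_length genome length in bp (> 0).
#' @return `1000 * n_snps / genome_length`.
#' @examples
#' snp_density(121109, 155051422)  # ~0.78 SNPs/kb
#' @export
snp_density <- function(n_snps, genome_length) {
  if (genome_length <= 0) stop_hk("genome_length must be > 0")
  1000 * n_snps / genome_length
}

#' Repeat content as a percentage of genome length
#'
#' @param total_repeat_length summed repeat length in bp.
#' @param genome_length genome length in bp.
#' @return `100 * total_repeat_length / genome_length`.
#' @examples
#' repeat_fraction(71617038, 155051422)  # ~46.19
#' @export
repeat_fraction <- function(total_repeat_length, genome_length) {
  if (genome_length <= 0) stop_hk("genome_length must be > 0")
  if (total_repeat_length < 0 || total_repeat_length > genome_length)
    stop_hk("total_repeat_length must be in [0, genome_length]")
  100 * total_repeat_length / genome_length
}

#' Mean contig length of an assembly
#'
#' @param total_length total assembly length in bp.
#' @param n_contigs number of contigs (> 0).
#' @return `total_length / n_contigs`.
#' @export
mean_contig_length <- function(total_length, n_contigs) {
  if (n_contigs <= 0) stop_hk("n_contigs must be > 0")
  total_length / n_contigs
}

#' Pairwise differences among aligned rDNA copies
#'
#' Counts, for every pair of pre-aligned equal-length sequences, the
#' positions where both carry an unambiguous base (`A`, `C`, `G`, `T`) and
#' the bases differ; positions where either sequence has a gap (`-`) or `N`
#' are skipped for that pair. Also reports the number of polymorphic
#' columns (>= 2 distinct unambiguous residues) and whether all copies are
#' mutually distinct.
#'
#' @param copies character vector (or `Biostrings::DNAStringSet`) of
#'   aligned sequences of equal length; at least 2.
#' @return List with `differences` (symmetric integer matrix),
#'   `n_polymorphic` (count of polymorphic columns) and `all_distinct`
#'   (TRUE iff every off-diagonal difference count is > 0).
#' @export
rdna_pairwise_differences <- function(copies) {
  if (inherits(copies, "XStringSet")) copies <- as.character(copies)
  if (length(copies) < 2L) stop_hk("need at least 2 sequences")
  lens <- nchar(copies)
  if (length(unique(lens)) != 1L)
    stop_hk("sequences must be pre-aligned to equal length")
  chars <- do.call(rbind, strsplit(toupper(copies), ""))
  ok_chars <- chars %in% c("A", "C", "G", "T", "-", "N")
  if (!all(ok_chars))
    stop_hk("alphabet must be {A,C,G,T,-,N}; found '%s'",
            chars[!ok_chars][1])
  valid <- matrix(chars %in% c("A", "C", "G", "T"), nrow(chars))
  k <- length(copies)
  d <- matrix(0L, k, k, dimnames = list(names(copies), names(copies)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    use <- valid[i, ] & valid[j, ]
    d[i, j] <- d[j, i] <- sum(chars[i, use] != chars[j, use])
  }
  n_poly <- sum(apply(chars, 2, function(col) {
    res <- unique(col[col %in% c("A", "C", "G", "T")])
    length(res) >= 2L
  }))
  list(differences = d, n_polymorphic = n_poly,
       all_distinct = all(d[upper.tri(d)] > 0))
}
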