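#' Alternate-allele frequency spectrum of one sample
#'
#' Computes `AO / (RO + AO)` at every site where the sample has at least
#' one allele observation. The shape of this spectrum is the primary
#' karyotype readout for a coenocytic mycelium: a homokaryon shows no
#' intermediate-frequency mass, a balanced dikaryon a single peak at 50%,
#' and an unbalanced dikaryon mirrored peaks at `1 - r` and `r` (e.g. 33%
#' and 67% at a 2:1 nucleotype ratio).
#'
#' @param table a [variant_table()].
#' @param sample sample name.
#' @return An object of class `af_spectrum`: list with `frequencies`
#'   (numeric in `[0, 1]`) and `sample`.
#' @export
af_spectrum <- function(table, sample) {
  stopifnot(inherits(table, "variant_table"))
  j <- match(sample, table$samples)
  if (is.na(j)) stop_hk("sample '%s' not in table", sample)
  ro <- table$ro[, j]; ao <- table$ao[, j]
  denom <- ro + ao
  use <- !is.na(denom) & denom > 0
  structure(list(frequencies = (ao / denom)[use], sample = sample),
            class = "af_spectrum")
}

#' @export
print.af_spectrum <- function(x, ...) {
  cat(sprintf("af_spectrum: %d sites (sample %s), mean freq %.3f\n",
              length(x$frequencies), x$sample, mean(x$frequencies)))
  invisible(x)
}

as_frequencies <- function(x) {
  f <- if (inherits(x, "af_spectrum")) x$frequencies else as.numeric(x)
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop_hk("frequencies must lie in [0, 1]")
  f[!is.na(f)]
}

#' Detect modes of an allele-frequency spectrum
#'
#' Smooths the spectrum with a Gaussian kernel density estimate on
#' `[0, 1]` and reports the positions of local maxima whose density exceeds
#' `min_prominence` times the global maximum, in percent, sorted
#' ascending. The returned vector carries a `"density"` attribute with the
#' kernel density height at each mode.
#'
#' @param spectrum an [af_spectrum()] or bare numeric vector of
#'   frequencies in `[0, 1]`; at least 2 values (>= 100 recommended for a
#'   meaningful density).
#' @param smoothing_bandwidth Gaussian kernel bandwidth on the frequency
#'   scale.
#' @param min_prominence minimum mode height as a fraction of the maximum
#'   density.
#' @return Numeric vector of mode positions in percent.
#' @export
detect_modes <- function(spectrum, smoothing_bandwidth = 0.02,
                         min_prominence = 0.1) {
  f <- as_frequencies(spectrum)
  if (length(f) < 2L) stop_hk("need at least 2 frequencies")
  check_proportion(min_prominence, "min_prominence")
  d <- stats::density(f, bw = smoothing_bandwidth, from = 0, to = 1,
                      n = 1024)
  y <- d$y
  n <- length(y)
  is_max <- c(y[1] > y[2],
              y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  keep <- is_max & y >= min_prominence * max(y)
  modes <- 100 * d$x[keep]
  o <- order(modes)
  structure(modes[o], density = y[keep][o])
}

#' Maximum-likelihood nucleotype ratio from pooled allele counts
#'
#' Models each biallelic site's alternate-allele count as a two-component
#' binomial mixture: the alternate allele is carried either by the major
#' nucleotype (read frequency `r`) or by the minor one (frequency
#' `1 - r`), with equal prior probability. The log-likelihood
#' \deqn{\sum_i \log\left[\tfrac12 B(a_i; n_i, r) + \tfrac12 B(a_i; n_i, 1-r)\right]}
#' is maximised over `r` in `[0.5, 1]` by a grid search at resolution
#' 0.001 followed by local refinement. A maximising `r` of at least
#' `mono_threshold` classifies the sample as a monokaryon (residual
#' low-frequency variants keep real monokaryons just below `r = 1`),
#' otherwise as a dikaryon.
#'
#' @param table a [variant_table()].
#' @param sample sample name.
#' @param mono_threshold monokaryon classification threshold on `r`.
#' @param min_sites minimum number of usable sites.
#' @return List of class `ratio_estimate`: `ratio_r` (major nucleotype
#'   share in `[0.5, 1]`), `log_likelihood`, `karyotype` (`"monokaryon"` or
#'   `"dikaryon"`), `modes` (detected spectrum modes in percent, when >=
#'   100 sites), `n_sites`.
#' @export
estimate_ratio_mle <- function(table, sample, mono_threshold = 0.95,
                               min_sites = 50) {
  stopifnot(inherits(table, "variant_table"))
  j <- match(sample, table$samples)
  if (is.na(j)) stop_hk("sample '%s' not in table", sample)
  ro <- table$ro[, j]; ao <- table$ao[, j]
  use <- !is.na(ro) & !is.na(ao) & (ro + ao) > 0
  ro <- ro[use]; ao <- ao[use]
  n <- ro + ao
  if (all(ao == 0 | ro == 0)) {
    # no site shows both alleles: a single nucleotype explains everything
    return(structure(list(ratio_r = 1, log_likelihood = mixture_ll(1, ao, n),
                          karyotype = "monokaryon", modes = numeric(0),
                          n_sites = length(n)),
                     class = "ratio_estimate"))
  }
  if (length(n) < min_sites)
    stop_hk("need at least %d sites with allele observations, have %d",
            min_sites, length(n))
  grid <- seq(0.5, 1, by = 0.001)
  ll <- vapply(grid, mixture_ll, numeric(1), ao = ao, n = n)
  best <- grid[which.max(ll)]
  lo <- max(0.5, best - 0.002); hi <- min(1, best + 0.002)
  opt <- stats::optimize(mixture_ll, c(lo, hi), ao = ao, n = n,
                         maximum = TRUE, tol = 1e-6)
  r_hat <- opt$maximum
  modes <- if (length(n) >= 100) {
    denom <- n
    detect_modes(ao / denom)
  } else numeric(0)
  structure(list(ratio_r = r_hat, log_likelihood = opt$objective,
                 karyotype = if (r_hat >= mono_threshold) "monokaryon"
                             else "dikaryon",
                 modes = modes, n_sites = length(n)),
            class = "ratio_estimate")
}

mixture_ll <- function(r, ao, n) {
  sum(log(0.5 * stats::dbinom(ao, n, r) +
            0.5 * stats::dbinom(ao, n, 1 - r)))
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "ratio_estimate: %s, major share r = %.3f (logL %.1f, %d sites)\n",
    x$karyotype, x$ratio_r, x$log_likelihood, x$n_sites))
  if (length(x$modes))
    cat(sprintf("  spectrum modes at %s%%\n",
                paste(sprintf("%.1f", x$modes), collapse = ", ")))
  invisible(x)
}

#' Nucleotype proportions from MAT-locus coverage
#'
#' The two MAT loci are each carried by one nucleotype only, so their mean
#' per-base read depths are proportional to the nucleotype abundances.
#'
#' @param depth_mat1,depth_mat2 mean per-base depth over the MAT-1 and
#'   MAT-2 locus; non-negative, not both zero.
#' @return Numeric pair of proportions summing to 1.
#' @examples
#' mat_coverage_ratio(200, 100)  # 2/3 1/3
#' @export
mat_coverage_ratio <- function(depth_mat1, depth_mat2) {
  if (depth_mat1 < 0 || depth_mat2 < 0)
    stop_hk("depths must be non-negative")
  tot <- depth_mat1 + depth_mat2
  if (tot == 0) stop_hk("both MAT-locus depths are zero")
  c(mat1 = depth_mat1 / tot, mat2 = depth_mat2 / tot)
}

#' PCA of samples on shared-SNP allele frequencies
#'
#' Restricts to sites with allele observations in every sample, builds the
#' samples x sites matrix of alternate-allele frequencies, drops
#' zero-variance site columns, centres and scales the remainder, and
#' returns the principal component coordinates.
#'
#' @param tables either a single multi-sample [variant_table()] or a named
#'   list of single-sample tables (names become sample names); at least 3
#'   samples.
#' @param k number of components to return.
#' @return List with `scores` (samples x components), `var_explained`
#'   (fraction of variance per component) and `n_sites` (shared,
#'   non-constant sites used).
#' @export
pca_shared_snps <- function(tables, k = 2) {
  if (inherits(tables, "variant_table")) {
    vt <- tables
  } else {
    if (length(tables) < 2L) stop_hk("need multiple samples")
    vt <- Reduce(intersect_tables, tables)
  }
  if (length(vt$samples) < 3L) stop_hk("need at least 3 samples for PCA")
  denom <- vt$ro + vt$ao
  covered <- !is.na(denom) & denom > 0
  shared <- rowSums(covered) == length(vt$samples)
  if (!any(shared)) stop_hk("no sites covered in all samples")
  freq <- t((vt$ao / denom)[shared, , drop = FALSE])
  rownames(freq) <- vt$samples
  sds <- apply(freq, 2, stats::sd)
  freq <- freq[, sds > 0, drop = FALSE]
  if (ncol(freq) < 2L)
    stop_hk("fewer than 2 variable shared sites; PCA is not meaningful")
  k <- min(k, nrow(freq) - 1L, ncol(freq))
  p <- stats::prcomp(freq, center = TRUE, scale. = TRUE)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       var_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
       n_sites = ncol(freq))
}
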