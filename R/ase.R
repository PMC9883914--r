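#' Allele-frequency spectra of expressed SNPs per host
#'
#' Applies the RNA expression filter (replicate-summed depth and allele
#' support, required in every host) and returns the per-host
#' alternate-allele frequency spectra over the shared expressed site set.
#' A host whose peak sits at 50% expresses both nucleotypes equally; hosts
#' with mirrored peaks off 50% weight the two nucleotypes' transcripts
#' unequally.
#'
#' @param tables named list: host -> list of [variant_table()] replicates
#'   over a common site set.
#' @param params an [rna_filter_params()].
#' @param keep_replicates also retain per-replicate spectra (needed by
#'   [replicate_consistency()]).
#' @return Object of class `host_spectra`: `hosts`, `sites`, `spectra`
#'   (named list of frequency vectors over the shared sites) and
#'   optionally `replicate_spectra` (host -> list of frequency vectors).
#' @export
host_spectra <- function(tables, params = rna_filter_params(),
                         keep_replicates = TRUE) {
  if (length(tables) < 2L) stop_hk("need at least 2 hosts")
  flt <- filter_rna_snps(tables, params)
  if (!nrow(flt$sites))
    stop_hk("no site passed the expression filter in all hosts (hosts: %s)",
            paste(names(tables), collapse = ", "))
  spectra <- lapply(seq_len(ncol(flt$frequencies)), function(j)
    flt$frequencies[, j])
  names(spectra) <- colnames(flt$frequencies)
  rep_spectra <- NULL
  if (keep_replicates) {
    rep_spectra <- lapply(tables, function(reps) {
      reps <- if (inherits(reps, "variant_table")) list(reps) else reps
      lapply(reps, function(vt) {
        ro <- vt$ro[flt$keep, 1]; ao <- vt$ao[flt$keep, 1]
        denom <- ro + ao
        f <- rep(NA_real_, sum(flt$keep))
        f[!is.na(denom) & denom > 0] <-
          (ao / denom)[!is.na(denom) & denom > 0]
        f
      })
    })
  }
  structure(list(hosts = names(spectra), sites = flt$sites,
                 spectra = spectra, replicate_spectra = rep_spectra),
            class = "host_spectra")
}

#' @export
print.host_spectra <- function(x, ...) {
  cat(sprintf("host_spectra: %d hosts (%s), %d shared expressed sites\n",
              length(x$hosts), paste(x$hosts, collapse = ", "),
              nrow(x$sites)))
  invisible(x)
}

ks_distance <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  unname(suppressWarnings(stats::ks.test(x, y)$statistic))
}

#' Quantify host-dependent shifts in allele-specific expression
#'
#' Two summary statistics over a [host_spectra()] object: `central_mass`,
#' the per-host fraction of shared sites with allele frequency within
#' `window_w` of 0.5 (high when the two nucleotypes contribute equally to
#' the mRNA pool), and the two-sample Kolmogorov-Smirnov statistic between
#' every pair of host frequency vectors.
#'
#' @param spectra a [host_spectra()] object (or named list of frequency
#'   vectors).
#' @param window_w half-width of the central window around 0.5.
#' @return Object of class `ase_shift`: `central_mass` (named vector),
#'   `pairwise_distance` (symmetric matrix of KS statistics), `window_w`.
#' @export
ase_shift <- function(spectra, window_w = 0.07) {
  sp <- if (inherits(spectra, "host_spectra")) spectra$spectra else spectra
  if (length(sp) < 2L) stop_hk("need at least 2 hosts")
  check_proportion(window_w, "window_w", allow_one = FALSE)
  central <- vapply(sp, function(f)
    mean(abs(f - 0.5) <= window_w, na.rm = TRUE), numeric(1))
  k <- length(sp)
  d <- matrix(0, k, k, dimnames = list(names(sp), names(sp)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- ks_distance(sp[[i]], sp[[j]])
  structure(list(central_mass = central, pairwise_distance = d,
                 window_w = window_w),
            class = "ase_shift")
}

#' @export
print.ase_shift <- function(x, ...) {
  cat("ase_shift: central mass near 50% per host\n")
  print(round(x$central_mass, 3))
  cat("pairwise KS distance\n")
  print(round(x$pairwise_distance, 3))
  invisible(x)
}

#' Across-replicate consistency of host spectra
#'
#' Mean pairwise Kolmogorov-Smirnov distance among the replicate spectra
#' of each host; hosts whose replicates disagree more than `threshold`
#' are flagged. Reproducible per-host spectra across biological
#' replicates are what licenses reading the host contrast as a host
#' effect rather than a batch effect.
#'
#' @param spectra a [host_spectra()] object built with
#'   `keep_replicates = TRUE`, or a named list host -> list of frequency
#'   vectors; every host needs at least 2 replicates.
#' @param threshold flag hosts with mean within-host distance above this.
#' @return data.frame: `host`, `n_replicates`, `mean_ks`, `flagged`.
#' @export
replicate_consistency <- function(spectra, threshold = 0.2) {
  reps <- if (inherits(spectra, "host_spectra")) spectra$replicate_spectra
          else spectra
  if (is.null(reps)) stop_hk("no replicate spectra available")
  rows <- lapply(names(reps), function(h) {
    r <- reps[[h]]
    if (length(r) < 2L)
      stop_hk("host '%s' has fewer than 2 replicates", h)
    pairs <- utils::combn(length(r), 2)
    ks <- mean(apply(pairs, 2, function(p)
      ks_distance(r[[p[1]]], r[[p[2]]])), na.rm = TRUE)
    data.frame(host = h, n_replicates = length(r), mean_ks = ks,
               flagged = ks > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
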