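#' Variant table: per-site, per-sample allele observation counts
#'
#' The central container of the package. A `variant_table` holds an ordered
#' set of biallelic SNP sites together with, for each sample, the freebayes
#' style observation triple at every site: total read depth (`DP`),
#' reference-allele observations (`RO`) and alternate-allele observations
#' (`AO`). Missing data (a sample not genotyped at a site) is `NA`, never
#' zero, and is excluded from all downstream denominators.
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`. Sites must be unique on (contig, pos, ref, alt) and sorted by
#'   position within each contig.
#' @param dp,ro,ao numeric matrices of dimension `nrow(sites)` x n_samples;
#'   `NA` marks missing observations. Column names are the sample names.
#' @return An object of class `variant_table` with elements `sites`,
#'   `samples`, `dp`, `ro`, `ao`.
#' @examples
#' sites <- data.frame(contig = "c1", pos = c(10, 20),
#'                     ref = c("A", "C"), alt = c("G", "T"))
#' m <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "s1"))
#' vt <- variant_table(sites, dp = m(c(100, 90)), ro = m(c(60, 45)),
#'                     ao = m(c(40, 45)))
#' vt
#' @export
variant_table <- function(sites, dp, ro, ao) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  sites <- data.frame(contig = as.character(sites$contig),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  dp <- as.matrix(dp); ro <- as.matrix(ro); ao <- as.matrix(ao)
  n <- nrow(sites)
  if (!all(dim(dp) == dim(ro)) || !all(dim(dp) == dim(ao)) ||
      nrow(dp) != n)
    stop_hk("count matrices must all be %d x n_samples", n)
  samples <- colnames(dp)
  if (is.null(samples) && ncol(dp) > 0)
    stop_hk("count matrices must carry sample names as column names")
  keys <- site_keys(sites)
  if (anyDuplicated(keys))
    stop_hk("duplicate site keys (contig:pos:ref:alt) are not allowed")
  if (any(unlist(tapply(sites$pos, sites$contig, function(p) diff(p) < 0))))
    stop_hk("sites must be sorted by position within each contig")
  bad <- which(!is.na(ro) & !is.na(ao) & !is.na(dp) & (ro + ao > dp))
  if (length(bad))
    stop_hk("RO + AO exceeds DP at %d entries", length(bad))
  structure(list(sites = sites, samples = as.character(samples),
                 dp = dp, ro = ro, ao = ao),
            class = "variant_table")
}

site_keys <- function(sites) {
  paste(sites$contig, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              if (length(x$samples)) paste(utils::head(x$samples, 5),
                                           collapse = ", ") else "none"))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a variant table by site index and/or sample name
#'
#' @param table a [variant_table()].
#' @param i integer or logical index over sites (optional).
#' @param samples character vector of sample names to keep (optional).
#' @return A `variant_table` restricted to the requested sites and samples.
#' @export
subset_table <- function(table, i = NULL, samples = NULL) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(i)) i <- seq_len(nrow(table$sites))
  j <- if (is.null(samples)) seq_along(table$samples)
       else match(samples, table$samples)
  if (anyNA(j)) stop_hk("unknown sample(s): %s",
                        paste(samples[is.na(j)], collapse = ", "))
  variant_table(table$sites[i, , drop = FALSE],
                dp = table$dp[i, j, drop = FALSE],
                ro = table$ro[i, j, drop = FALSE],
                ao = table$ao[i, j, drop = FALSE])
}

#' Intersect two variant tables on shared site keys
#'
#' Restricts both inputs to the site keys (contig, pos, ref, alt) present in
#' each, and concatenates their sample columns. This mirrors intersecting a
#' single-nucleus VCF with the filtered pooled-DNA VCF so that only sites
#' validated in the pool are carried into per-nucleus analyses.
#'
#' @param a,b [variant_table()] objects. Sample names must not collide.
#' @return A `variant_table` over the shared sites, in `a`'s site order,
#'   with `a`'s samples followed by `b`'s.
#' @export
intersect_tables <- function(a, b) {
  stopifnot(inherits(a, "variant_table"), inherits(b, "variant_table"))
  dup <- intersect(a$samples, b$samples)
  if (length(dup))
    stop_hk("duplicate sample names across tables: %s",
            paste(dup, collapse = ", "))
  ka <- site_keys(a$sites); kb <- site_keys(b$sites)
  ia <- which(ka %in% kb)
  ib <- match(ka[ia], kb)
  variant_table(a$sites[ia, , drop = FALSE],
                dp = cbind(a$dp[ia, , drop = FALSE], b$dp[ib, , drop = FALSE]),
                ro = cbind(a$ro[ia, , drop = FALSE], b$ro[ib, , drop = FALSE]),
                ao = cbind(a$ao[ia, , drop = FALSE], b$ao[ib, , drop = FALSE]))
}
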