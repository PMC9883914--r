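#' Heterozygosity / proximity filter parameters for single-nucleus calls
#'
#' A haploid nucleus should show only one allele at any site; apparent
#' heterozygosity signals contamination, amplification chimerism or mapping
#' artefacts. A site is flagged heterozygous in a nucleus when *both*
#' alleles exceed the `het_fraction` read share (strictly), and all SNPs
#' within `proximity_bp` of any such site (in any nucleus) are excluded as
#' collateral.
#'
#' @param het_fraction strict read-share threshold for calling both
#'   alleles present, in `(0, 0.5)`.
#' @param proximity_bp exclusion distance around heterozygous loci
#'   (inclusive at exactly this distance).
#' @param min_depth minimum depth for a call; below it the site is missing.
#' @return Object of class `het_filter_params`.
#' @export
het_filter_params <- function(het_fraction = 0.1, proximity_bp = 500,
                              min_depth = 10) {
  if (!(het_fraction > 0 && het_fraction < 0.5))
    stop_hk("het_fraction must be in (0, 0.5)")
  check_count(proximity_bp, "proximity_bp", min = 0L)
  check_count(min_depth, "min_depth", min = 0L)
  structure(list(het_fraction = het_fraction, proximity_bp = proximity_bp,
                 min_depth = min_depth),
            class = "het_filter_params")
}

#' Call per-site alleles for a single nucleus
#'
#' Per site: depth below `min_depth` (or missing counts, or zero allele
#' observations) gives a missing call; both alleles strictly above the
#' `het_fraction` read share flags the site heterozygous (call missing);
#' otherwise the call is the majority allele. After the heterozygosity rule
#' a tie `RO == AO > 0` cannot occur (both shares would exceed any
#' `het_fraction < 0.5`), which is asserted rather than handled.
#'
#' @param table a [variant_table()] containing the nucleus sample.
#' @param nucleus sample name of the nucleus.
#' @param params a [het_filter_params()].
#' @param mat optional MAT identity (`"MAT-1"`/`"MAT-2"`) to attach.
#' @return List of class `nucleus_callset`: `nucleus_id`, `mat`, `calls`
#'   (character `"ref"`/`"alt"`/`NA` along sites), `het` (logical:
#'   heterozygous-flagged sites), `sites`.
#' @export
call_nucleus <- function(table, nucleus, params = het_filter_params(),
                         mat = NA_character_) {
  stopifnot(inherits(table, "variant_table"),
            inherits(params, "het_filter_params"))
  j <- match(nucleus, table$samples)
  if (is.na(j)) stop_hk("nucleus '%s' not in table", nucleus)
  dp <- table$dp[, j]; ro <- table$ro[, j]; ao <- table$ao[, j]
  n <- nrow(table$sites)
  calls <- rep(NA_character_, n)
  het <- rep(FALSE, n)
  usable <- !is.na(dp) & !is.na(ro) & !is.na(ao) & dp >= params$min_depth &
    (ro + ao) > 0
  fr <- ro / dp; fa <- ao / dp
  het[usable] <- fr[usable] > params$het_fraction &
    fa[usable] > params$het_fraction
  callable <- usable & !het
  tie <- callable & ro == ao
  stopifnot("unexpected RO == AO tie after heterozygosity rule" =
              !any(tie))
  calls[callable] <- ifelse(ro[callable] > ao[callable], "ref", "alt")
  structure(list(nucleus_id = nucleus, mat = mat, calls = calls,
                 het = het, sites = table$sites),
            class = "nucleus_callset")
}

#' @export
print.nucleus_callset <- function(x, ...) {
  cat(sprintf(
    "nucleus_callset %s (%s): %d called / %d het-flagged / %d missing\n",
    x$nucleus_id, x$mat, sum(!is.na(x$calls)), sum(x$het),
    sum(is.na(x$calls) & !x$het)))
  invisible(x)
}

#' Exclude SNPs near heterozygous loci
#'
#' A site is removed iff it is itself heterozygous in any nucleus, or lies
#' within `proximity_bp` (inclusive) of such a site on the same contig.
#'
#' @param sites data.frame with `contig`, `pos` (sorted within contigs).
#' @param het_index integer or logical index of heterozygous sites (pooled
#'   across all nuclei) into `sites`.
#' @param proximity_bp exclusion distance in bp.
#' @return Logical vector: `TRUE` for retained sites.
#' @export
exclude_heterozygous_neighborhoods <- function(sites, het_index,
                                               proximity_bp = 500) {
  if (is.logical(het_index)) het_index <- which(het_index)
  keep <- rep(TRUE, nrow(sites))
  if (!length(het_index)) return(keep)
  for (ctg in unique(sites$contig[het_index])) {
    hp <- sites$pos[het_index[sites$contig[het_index] == ctg]]
    si <- which(sites$contig == ctg)
    near <- vapply(sites$pos[si],
                   function(p) min(abs(p - hp)) <= proximity_bp,
                   logical(1))
    keep[si[near]] <- FALSE
  }
  keep
}

call_matrix <- function(callsets) {
  stopifnot(length(callsets) >= 2L)
  calls <- vapply(callsets, `[[`, character(nrow(callsets[[1]]$sites)),
                  "calls")
  colnames(calls) <- vapply(callsets, `[[`, "", "nucleus_id")
  calls
}

#' Find MAT-discordant SNPs across nuclei
#'
#' In a strict dikaryon every SNP allele tracks the MAT identity of its
#' nucleotype, so all nuclei sharing a MAT locus should agree. A site is
#' discordant iff, within the MAT-1 group or within the MAT-2 group, both
#' reference and alternate calls occur (missing calls are excluded from
#' the test). Discordant sites are candidate inter-nucleus recombination
#' (or somatic mutation) signals.
#'
#' @param callsets list of [call_nucleus()] results over a shared site
#'   list, each with a `mat` identity; at least two nuclei must share a
#'   MAT identity.
#' @return List: `discordant` (logical per site), `n_total` (sites),
#'   `n_discordant`, `percent` (see [discordance_percentage()]).
#' @export
find_discordant_snps <- function(callsets) {
  calls <- call_matrix(callsets)
  mats <- vapply(callsets, `[[`, "", "mat")
  if (!any(table(mats[mats %in% c("MAT-1", "MAT-2")]) >= 2))
    stop_hk("need at least two nuclei sharing a MAT identity")
  disc <- rep(FALSE, nrow(calls))
  for (m in c("MAT-1", "MAT-2")) {
    cols <- which(mats == m)
    if (length(cols) < 2L) next
    g <- calls[, cols, drop = FALSE]
    has_ref <- rowSums(g == "ref", na.rm = TRUE) > 0
    has_alt <- rowSums(g == "alt", na.rm = TRUE) > 0
    disc <- disc | (has_ref & has_alt)
  }
  list(discordant = disc, n_total = nrow(calls),
       n_discordant = sum(disc),
       percent = if (nrow(calls)) discordance_percentage(sum(disc),
                                                         nrow(calls))
                 else NA_real_)
}

#' Discordance percentage
#'
#' @param n_discordant,n_total discordant and total SNP counts
#'   (`n_total > 0`).
#' @return `100 * n_discordant / n_total`.
#' @examples
#' discordance_percentage(503, 9947)  # ~5
#' @export
discordance_percentage <- function(n_discordant, n_total) {
  if (n_total <= 0) stop_hk("n_total must be > 0")
  100 * n_discordant / n_total
}

#' Find recombination blocks of consecutive discordant SNPs
#'
#' Contigs carrying fewer than `min_snps_per_contig` SNPs are skipped
#' entirely. On the remaining contigs, a block is a maximal run of at
#' least `min_run` consecutive discordant SNPs (in the ordered, retained
#' SNP list — an ordinal notion, not a bp distance). Blocks never span
#' contigs. When callsets are supplied, each block also reports the nuclei
#' carrying the minority allele across its sites.
#'
#' @param sites data.frame with `contig`, `pos`, ordered by position
#'   within contigs.
#' @param discordant logical per site (as from [find_discordant_snps()]).
#' @param min_run minimum block length in consecutive discordant SNPs.
#' @param min_snps_per_contig contigs with fewer total SNPs are ignored.
#' @param callsets optional list of [call_nucleus()] results used to
#'   report carrier nuclei.
#' @return data.frame of class `recombination_blocks`: `contig`,
#'   `first_index`, `last_index` (contig-local indices into the ordered
#'   SNP list), `first_pos`, `last_pos` (bp), `n_snps`, `nuclei`
#'   (comma-separated carrier ids, or `NA`).
#' @export
find_recombination_blocks <- function(sites, discordant, min_run = 5,
                                      min_snps_per_contig = 2,
                                      callsets = NULL) {
  stopifnot(nrow(sites) == length(discordant))
  check_count(min_run, "min_run", min = 1L)
  check_count(min_snps_per_contig, "min_snps_per_contig", min = 1L)
  mats <- if (!is.null(callsets)) vapply(callsets, `[[`, "", "mat")
  calls <- if (!is.null(callsets)) call_matrix(callsets)
  out <- list()
  for (ctg in unique(sites$contig)) {
    si <- which(sites$contig == ctg)
    if (length(si) < min_snps_per_contig) next
    flags <- discordant[si]
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_run)
    for (h in hit) {
      idx <- starts[h]:ends[h]          # contig-local
      global <- si[idx]
      nuclei <- NA_character_
      if (!is.null(callsets)) {
        carriers <- character(0)
        for (m in c("MAT-1", "MAT-2")) {
          cols <- which(mats == m)
          if (length(cols) < 2L) next
          g <- calls[global, cols, drop = FALSE]
          for (k in seq_len(nrow(g))) {
            row <- g[k, ]
            n_ref <- sum(row == "ref", na.rm = TRUE)
            n_alt <- sum(row == "alt", na.rm = TRUE)
            if (n_ref == 0 || n_alt == 0) next
            minority <- if (n_alt < n_ref) "alt"
                        else if (n_ref < n_alt) "ref"
                        else c("ref", "alt")
            carriers <- c(carriers,
                          colnames(g)[!is.na(row) & row %in% minority])
          }
        }
        nuclei <- paste(sort(unique(carriers)), collapse = ",")
      }
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, first_index = idx[1], last_index = idx[length(idx)],
        first_pos = sites$pos[global[1]],
        last_pos = sites$pos[global[length(global)]],
        n_snps = length(idx), nuclei = nuclei, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(contig = character(0), first_index = integer(0),
                         last_index = integer(0), first_pos = integer(0),
                         last_pos = integer(0), n_snps = integer(0),
                         nuclei = character(0), stringsAsFactors = FALSE)
  class(res) <- c("recombination_blocks", "data.frame")
  res
}

#' Pairwise similarity among nucleus callsets
#'
#' Entry `(i, j)` is the fraction of sites called (non-missing) in both
#' nuclei where the calls agree; pairs with zero co-called sites are `NA`.
#' The diagonal is 1 and the matrix symmetric. Within-MAT pairs of a true
#' dikaryon approach 1 while between-MAT pairs approach 0, giving the
#' block structure seen in nucleus relatedness heatmaps.
#'
#' @param callsets list of at least two [call_nucleus()] results over a
#'   shared site list.
#' @return Symmetric numeric matrix with nucleus ids as dimnames.
#' @export
similarity_matrix <- function(callsets) {
  calls <- call_matrix(callsets)
  k <- ncol(calls)
  s <- matrix(NA_real_, k, k, dimnames = list(colnames(calls),
                                              colnames(calls)))
  diag(s) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    co <- !is.na(calls[, i]) & !is.na(calls[, j])
    s[i, j] <- s[j, i] <- if (any(co))
      mean(calls[co, i] == calls[co, j]) else NA_real_
  }
  s
}

#' Full single-nucleus concordance pipeline
#'
#' Chains the per-nucleus analysis end to end: intersect the nucleus table
#' with the filtered pooled-DNA table (only pool-validated SNPs are
#' considered), drop repeat sites, call every nucleus, pool heterozygous
#' loci across nuclei and excise their `proximity_bp` neighbourhoods,
#' then compute discordance flags, recombination blocks and the
#' similarity matrix.
#'
#' @param pool_table filtered pooled-DNA [variant_table()].
#' @param nuclei_table per-nucleus [variant_table()] (one sample per
#'   nucleus).
#' @param mat data.frame `nucleus_id`, `mat` (see [read_mat_table()]).
#' @param params a [het_filter_params()].
#' @param min_run,min_snps_per_contig block-calling thresholds, see
#'   [find_recombination_blocks()].
#' @param repeats optional `repeat_intervals`; sites inside them are
#'   dropped.
#' @param site_mask optional logical over `nuclei_table` sites; `FALSE`
#'   drops a site (e.g. a user-supplied paired-read mask). Default keeps
#'   all.
#' @return List: `callsets`, `sites` (retained sites), `discordance`
#'   (from [find_discordant_snps()]), `blocks`, `similarity`,
#'   `n_het_excluded` (sites removed by the heterozygosity neighbourhood
#'   rule).
#' @export
analyze_nuclei <- function(pool_table, nuclei_table, mat,
                           params = het_filter_params(), min_run = 5,
                           min_snps_per_contig = 2, repeats = NULL,
                           site_mask = NULL) {
  vt <- intersect_tables(pool_table, nuclei_table)
  # intersection keeps the pool's sample columns; keep only the nuclei
  vt <- subset_table(vt, samples = nuclei_table$samples)
  if (!is.null(site_mask)) {
    stopifnot(length(site_mask) == nrow(nuclei_table$sites))
    masked_keys <- site_keys(nuclei_table$sites)[site_mask]
    vt <- subset_table(vt, site_keys(vt$sites) %in% masked_keys)
  }
  if (!is.null(repeats))
    vt <- subset_table(vt, !sites_in_repeats(vt$sites, repeats))
  ids <- mat$nucleus_id
  missing_ids <- setdiff(ids, vt$samples)
  if (length(missing_ids))
    stop_hk("MAT table lists unknown nuclei: %s",
            paste(missing_ids, collapse = ", "))
  callsets <- lapply(seq_along(ids), function(i)
    call_nucleus(vt, ids[i], params, mat = mat$mat[i]))
  het_any <- Reduce(`|`, lapply(callsets, `[[`, "het"))
  keep <- exclude_heterozygous_neighborhoods(vt$sites, het_any,
                                             params$proximity_bp)
  vt2 <- subset_table(vt, keep)
  callsets <- lapply(callsets, function(cs) {
    cs$calls <- cs$calls[keep]; cs$het <- cs$het[keep]
    cs$sites <- vt2$sites; cs
  })
  disc <- find_discordant_snps(callsets)
  blocks <- find_recombination_blocks(vt2$sites, disc$discordant,
                                      min_run = min_run,
                                      min_snps_per_contig =
                                        min_snps_per_contig,
                                      callsets = callsets)
  list(callsets = callsets, sites = vt2$sites, discordance = disc,
       blocks = blocks, similarity = similarity_matrix(callsets),
       n_het_excluded = sum(!keep))
}
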