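#' Two-nucleotype mixture model parameters
#'
#' Describes the nuclear population and sequencing model used both to
#' simulate data and to interpret it: a dikaryote-like mycelium contains
#' haploid nuclei of two nucleotypes (distinguished by their MAT-locus
#' allele), mixed at ratio `ratio_r`.
#'
#' @param ratio_r proportion of MAT-1 nuclei, in `[0, 1]`.
#' @param error_rate per-read base error probability, in `[0, 0.5)`.
#' @param mean_depth expected reads per site.
#' @param depth_dispersion negative-binomial overdispersion of per-site
#'   depth; 0 gives pure Poisson depth. Variance is
#'   `mean + dispersion * mean^2`.
#' @return An object of class `nucleotype_model`.
#' @export
nucleotype_model <- function(ratio_r, error_rate = 0.001, mean_depth = 110,
                             depth_dispersion = 0) {
  check_proportion(ratio_r, "ratio_r")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5)
    stop_hk("'error_rate' must be in [0, 0.5)")
  if (mean_depth <= 0) stop_hk("'mean_depth' must be positive")
  if (depth_dispersion < 0) stop_hk("'depth_dispersion' must be >= 0")
  structure(list(ratio_r = ratio_r, error_rate = error_rate,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion),
            class = "nucleotype_model")
}

#' Generate a synthetic dikaryon genome model
#'
#' Builds the genomic scaffold the simulators operate on: a set of contigs,
#' repeat-annotated intervals, biallelic SNP sites each carried by exactly
#' one nucleotype (or, for a configurable minority, by a sub-fraction of one
#' nucleotype's nuclei — "low-frequency" variants), and a family of
#' non-tandemly organised 45S rDNA copies that differ from one another by
#' point substitutions.
#'
#' SNP counts per contig are Poisson with mean `contig_length * snp_per_kb /
#' 1000`. Repeat intervals are laid down by marking 1-kb windows
#' independently with probability `repeat_fraction` and merging adjacent
#' marked windows, so they cover approximately `repeat_fraction` of the
#' genome at realistic interval sizes. Each non-low-frequency site's
#' alternate allele is assigned to MAT-1 with probability `p_alt_mat1`
#' (default 0.5) and otherwise to MAT-2.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param snp_per_kb expected SNP density (SNPs per kilobase); must be > 0.
#' @param repeat_fraction approximate fraction of the genome annotated as
#'   repeat, in `[0, 1)`.
#' @param low_freq_site_fraction fraction of sites whose alternate allele is
#'   carried by only a sub-fraction of one nucleotype's nuclei, in `[0, 1)`.
#'   The carried sub-fraction is drawn uniformly from `[0.2, 0.5]`, which at
#'   a balanced nucleotype ratio yields pooled read frequencies of 10-25%.
#' @param p_alt_mat1 probability that a non-low-frequency site's alternate
#'   allele is carried by MAT-1 (the remainder go to MAT-2).
#' @param n_rdna_copies,rdna_length,rdna_divergence number, length (bp) and
#'   per-base divergence of the 45S rDNA copies.
#' @param seed integer seed; identical arguments and seed give a
#'   bit-identical genome.
#' @return An object of class `genome_model` with elements `contigs`
#'   (data.frame `name`, `length`), `repeats` (0-based half-open intervals),
#'   `sites` (data.frame `contig`, `pos`, `ref`, `alt`, `in_repeat`,
#'   `alt_carrier`, `low_freq_fraction`) and `rdna_copies` (named character
#'   vector).
#' @examples
#' g <- make_genome(n_contigs = 5, contig_length = 1e5, snp_per_kb = 1,
#'                  seed = 1)
#' nrow(g$sites)
#' @export
make_genome <- function(n_contigs, contig_length, snp_per_kb,
                        repeat_fraction = 0, low_freq_site_fraction = 0,
                        p_alt_mat1 = 0.5, n_rdna_copies = 8,
                        rdna_length = 600, rdna_divergence = 0.01,
                        seed = NULL) {
  check_count(n_contigs, "n_contigs", min = 1L)
  check_count(contig_length, "contig_length", min = 1L)
  if (!is.numeric(snp_per_kb) || snp_per_kb <= 0)
    stop_hk("'snp_per_kb' must be > 0")
  check_proportion(repeat_fraction, "repeat_fraction", allow_one = FALSE)
  check_proportion(low_freq_site_fraction, "low_freq_site_fraction",
                   allow_one = FALSE)
  check_proportion(p_alt_mat1, "p_alt_mat1")
  run_seeded(seed, {
    contigs <- data.frame(
      name = sprintf("contig_%03d", seq_len(n_contigs)),
      length = rep(as.integer(contig_length), n_contigs),
      stringsAsFactors = FALSE)
    bases <- c("A", "C", "G", "T")
    site_list <- vector("list", n_contigs)
    rep_list <- vector("list", n_contigs)
    for (i in seq_len(n_contigs)) {
      n_snp <- stats::rpois(1, contig_length * snp_per_kb / 1000)
      n_snp <- min(n_snp, contig_length)
      pos <- sort(sample.int(contig_length, n_snp))
      ref <- sample(bases, n_snp, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      site_list[[i]] <- data.frame(contig = rep(contigs$name[i], n_snp),
                                   pos = pos,
                                   ref = ref, alt = unname(alt),
                                   stringsAsFactors = FALSE)
      if (repeat_fraction > 0) {
        n_win <- ceiling(contig_length / 1000)
        marked <- stats::runif(n_win) < repeat_fraction
        if (any(marked)) {
          r <- rle(marked)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          keep <- r$values
          rep_list[[i]] <- data.frame(
            contig = contigs$name[i],
            start = (starts[keep] - 1) * 1000,
            end = pmin(ends[keep] * 1000, contig_length),
            stringsAsFactors = FALSE)
        }
      }
    }
    sites <- do.call(rbind, site_list)
    rownames(sites) <- NULL
    repeats <- repeat_intervals(do.call(rbind, rep_list))
    n <- nrow(sites)
    sites$in_repeat <- sites_in_repeats(sites, repeats)
    is_lf <- stats::runif(n) < low_freq_site_fraction
    carrier <- ifelse(stats::runif(n) < p_alt_mat1, "MAT-1", "MAT-2")
    carrier[is_lf] <- "low_frequency"
    sites$alt_carrier <- carrier
    sites$low_freq_fraction <- ifelse(is_lf, stats::runif(n, 0.2, 0.5), 0)
    ancestor <- sample(bases, rdna_length, replace = TRUE)
    rdna <- vapply(seq_len(n_rdna_copies), function(k) {
      s <- ancestor
      mut <- which(stats::runif(rdna_length) < rdna_divergence)
      if (length(mut))
        s[mut] <- vapply(s[mut],
                         function(b) sample(setdiff(bases, b), 1), "")
      paste(s, collapse = "")
    }, "")
    names(rdna) <- sprintf("rdna_copy_%d", seq_len(n_rdna_copies))
    structure(list(contigs = contigs, repeats = repeats, sites = sites,
                   rdna_copies = rdna),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model: %d contigs (%.1f Mbp), %d SNP sites, %d rDNA copies\n",
    nrow(x$contigs), sum(x$contigs$length) / 1e6, nrow(x$sites),
    length(x$rdna_copies)))
  invisible(x)
}

#' Summary statistics of a genome model
#'
#' @param genome a [make_genome()] result.
#' @return List with total length, contig count, mean contig length, SNP
#'   count, SNP density per kb (see [snp_density()]) and repeat percentage.
#' @export
genome_summary <- function(genome) {
  total <- sum(genome$contigs$length)
  rep_len <- sum(genome$repeats$end - genome$repeats$start)
  list(total_length = total,
       n_contigs = nrow(genome$contigs),
       mean_contig_length = mean_contig_length(total, nrow(genome$contigs)),
       n_snps = nrow(genome$sites),
       snp_per_kb = snp_density(nrow(genome$sites), total),
       repeat_percent = repeat_fraction(rep_len, total))
}

#' Generate a population of haploid nuclei from a genome model
#'
#' `floor(ratio_r * n_nuclei)` nuclei are labelled MAT-1, the rest MAT-2.
#' Each nucleus carries, at every ordinary site, the allele dictated by its
#' nucleotype: the alternate allele where `alt_carrier` equals its MAT,
#' the reference allele otherwise (so the two nucleotype consensuses differ
#' at every non-low-frequency site). At low-frequency sites the alternate
#' allele is planted in a random sub-fraction of one randomly chosen
#' nucleotype's nuclei. Optionally, contiguous recombination tracts are
#' implanted: within a tract, one randomly chosen nucleus carries the
#' opposite nucleotype's consensus alleles. Tracts are placed in site-index
#' space (consecutive SNPs on one contig), never overlap or abut, and are
#' returned as ground truth for benchmarking the block caller.
#'
#' @param genome a [make_genome()] result.
#' @param model a [nucleotype_model()]; `ratio_r` sets the MAT-1 share.
#' @param n_nuclei number of nuclei (>= 2).
#' @param n_recomb_tracts number of recombination tracts to implant.
#' @param tract_len_snps tract length in consecutive SNPs (>= 1).
#' @param seed integer seed.
#' @return An object of class `nucleus_population`: `genome`, `nuclei`
#'   (data.frame `nucleus_id`, `mat`), `alleles` (sites x nuclei 0/1 matrix;
#'   1 = alternate), `tracts` (data.frame `nucleus_id`, `contig`,
#'   `first_index`, `last_index` with contig-local site indices).
#' @export
make_nucleus_population <- function(genome, model, n_nuclei,
                                    n_recomb_tracts = 0, tract_len_snps = 5,
                                    seed = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(model, "nucleotype_model"))
  check_count(n_nuclei, "n_nuclei", min = 2L)
  check_count(n_recomb_tracts, "n_recomb_tracts", min = 0L)
  check_count(tract_len_snps, "tract_len_snps", min = 1L)
  sites <- genome$sites
  n_sites <- nrow(sites)
  contig_sizes <- table(factor(sites$contig, unique(sites$contig)))
  if (n_recomb_tracts > 0 && tract_len_snps > max(contig_sizes))
    stop_hk("tract_len_snps (%d) exceeds the largest contig's SNP count (%d)",
            tract_len_snps, max(contig_sizes))
  run_seeded(seed, {
    n1 <- floor(model$ratio_r * n_nuclei)
    mat <- rep(c("MAT-1", "MAT-2"), c(n1, n_nuclei - n1))
    ids <- sprintf("nucleus_%02d", seq_len(n_nuclei))
    alleles <- matrix(0L, n_sites, n_nuclei, dimnames = list(NULL, ids))
    for (m in c("MAT-1", "MAT-2")) {
      cols <- which(mat == m)
      rows <- which(sites$alt_carrier == m)
      if (length(cols) && length(rows)) alleles[rows, cols] <- 1L
    }
    lf <- which(sites$alt_carrier == "low_frequency")
    for (i in lf) {
      m <- sample(c("MAT-1", "MAT-2"), 1)
      cols <- which(mat == m)
      if (!length(cols)) cols <- seq_len(n_nuclei)
      k <- max(1L, round(sites$low_freq_fraction[i] * length(cols)))
      carriers <- sample(cols, min(k, length(cols)))
      alleles[i, carriers] <- 1L
    }
    # nucleotype consensus = majority allele within each MAT group
    consensus <- function(m) {
      cols <- which(mat == m)
      if (!length(cols)) return(integer(n_sites))
      as.integer(rowMeans(alleles[, cols, drop = FALSE]) >= 0.5)
    }
    cons1 <- consensus("MAT-1"); cons2 <- consensus("MAT-2")
    tracts <- data.frame(nucleus_id = character(0), contig = character(0),
                         first_index = integer(0), last_index = integer(0),
                         stringsAsFactors = FALSE)
    if (n_recomb_tracts > 0) {
      eligible <- names(contig_sizes)[contig_sizes >= tract_len_snps]
      taken <- list()  # per contig, occupied (padded) index ranges
      placed <- 0L; attempts <- 0L
      while (placed < n_recomb_tracts) {
        attempts <- attempts + 1L
        if (attempts > 1000L * n_recomb_tracts)
          stop_hk("could not place %d non-overlapping tracts", n_recomb_tracts)
        ctg <- sample(eligible, 1)
        sz <- as.integer(contig_sizes[[ctg]])
        first <- sample.int(sz - tract_len_snps + 1L, 1)
        last <- first + tract_len_snps - 1L
        occ <- taken[[ctg]]
        clash <- !is.null(occ) &&
          any(first <= occ[, 2] + 1L & last >= occ[, 1] - 1L)
        if (clash) next
        taken[[ctg]] <- rbind(occ, c(first, last))
        nuc <- sample.int(n_nuclei, 1)
        global <- which(sites$contig == ctg)[first:last]
        opp <- if (mat[nuc] == "MAT-1") cons2 else cons1
        alleles[global, nuc] <- opp[global]
        tracts <- rbind(tracts, data.frame(
          nucleus_id = ids[nuc], contig = ctg, first_index = first,
          last_index = last, stringsAsFactors = FALSE))
        placed <- placed + 1L
      }
    }
    structure(list(genome = genome,
                   nuclei = data.frame(nucleus_id = ids, mat = mat,
                                       stringsAsFactors = FALSE),
                   alleles = alleles, tracts = tracts),
              class = "nucleus_population")
  })
}

#' @export
print.nucleus_population <- function(x, ...) {
  cat(sprintf(
    "nucleus_population: %d nuclei (%d MAT-1 / %d MAT-2), %d sites, %d implanted tracts\n",
    nrow(x$nuclei), sum(x$nuclei$mat == "MAT-1"),
    sum(x$nuclei$mat == "MAT-2"), nrow(x$alleles), nrow(x$tracts)))
  invisible(x)
}

#' Write a synthetic population's ground truth as a JSON sidecar
#'
#' Records the nucleotype ratio, MAT assignments, implanted tract
#' coordinates and (optionally) host expression weights, for test harnesses.
#'
#' @param population a [make_nucleus_population()] result.
#' @param path output path.
#' @param host_weights optional named list of per-host `(w_MAT1, w_MAT2)`
#'   weights to record.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(population, path, host_weights = NULL) {
  truth <- list(
    n_nuclei = nrow(population$nuclei),
    ratio_mat1 = mean(population$nuclei$mat == "MAT-1"),
    mat = stats::setNames(as.list(population$nuclei$mat),
                          population$nuclei$nucleus_id),
    tracts = population$tracts,
    host_weights = host_weights)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
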