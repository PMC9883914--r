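# Read-count simulators. Counts are generated directly at the site level
# (no read-level FASTQ simulation): per-site depth follows a negative
# binomial law (Poisson at dispersion 0), each read reports the allele of a
# source nucleus, and sequencing error converts a read to one of the three
# other bases uniformly, so an erroneous read hits the opposite allele of
# the pair with probability 1/3 and an off-pair base otherwise (hence
# RO + AO <= DP, with equality when error_rate = 0).

draw_depth <- function(n, model) {
  if (model$depth_dispersion > 0)
    stats::rnbinom(n, size = 1 / model$depth_dispersion,
                   mu = model$mean_depth)
  else
    stats::rpois(n, model$mean_depth)
}

# allele counts from per-site depth and per-site alt-source probability
draw_counts <- function(depth, p_alt_source, error_rate) {
  n <- length(depth)
  k_alt <- stats::rbinom(n, depth, p_alt_source)
  k_ref <- depth - k_alt
  ao_true <- stats::rbinom(n, k_alt, 1 - error_rate)
  ro_flip <- stats::rbinom(n, k_alt - ao_true, 1 / 3)
  ro_true <- stats::rbinom(n, k_ref, 1 - error_rate)
  ao_flip <- stats::rbinom(n, k_ref - ro_true, 1 / 3)
  list(dp = depth, ro = ro_true + ro_flip, ao = ao_true + ao_flip)
}

#' Simulate pooled-DNA (meta-genome) allele counts
#'
#' Emulates sequencing DNA pooled from the whole mycelium: at each site the
#' depth is drawn from the model's depth law and each read originates from a
#' nucleus chosen uniformly at random, so the expected alternate-allele
#' frequency equals the fraction of nuclei carrying the alternate allele
#' (e.g. `1 - ratio_r` at a MAT-1-carrier site).
#'
#' @param population a [make_nucleus_population()] result.
#' @param model a [nucleotype_model()] supplying the depth law and error
#'   rate.
#' @param sample_name name of the single sample column.
#' @param seed integer seed.
#' @return A [variant_table()] with one sample.
#' @export
simulate_pool_counts <- function(population, model, sample_name = "pool",
                                 seed = NULL) {
  stopifnot(inherits(population, "nucleus_population"),
            inherits(model, "nucleotype_model"))
  if (nrow(population$nuclei) == 0L) stop_hk("empty population")
  run_seeded(seed, {
    f_alt <- rowMeans(population$alleles)
    depth <- draw_depth(length(f_alt), model)
    cnt <- draw_counts(depth, f_alt, model$error_rate)
    m <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, sample_name))
    variant_table(population$genome$sites[, c("contig", "pos", "ref", "alt")],
                  dp = m(cnt$dp), ro = m(cnt$ro), ao = m(cnt$ao))
  })
}

#' Simulate single-nucleus allele counts with WGA artefacts
#'
#' Emulates whole-genome-amplified single-nucleus sequencing. Per nucleus
#' and site, depth follows the model's depth law; a `dropout_rate` fraction
#' of sites receives zero depth (amplification dropout, recorded as
#' missing); each read reports the focal nucleus's allele except that with
#' probability `contamination_rate` it reports the allele of a uniformly
#' chosen other nucleus; per-read error applies on top.
#'
#' @param population a [make_nucleus_population()] result.
#' @param model a [nucleotype_model()].
#' @param contamination_rate probability a read originates from another
#'   nucleus, in `[0, 1)`.
#' @param dropout_rate per-site dropout probability, in `[0, 1]`.
#' @param seed integer seed.
#' @return A [variant_table()] with one sample per nucleus (named by
#'   `nucleus_id`); dropped-out sites are `NA`.
#' @export
simulate_nucleus_counts <- function(population, model,
                                    contamination_rate = 0,
                                    dropout_rate = 0, seed = NULL) {
  stopifnot(inherits(population, "nucleus_population"),
            inherits(model, "nucleotype_model"))
  check_proportion(contamination_rate, "contamination_rate",
                   allow_one = FALSE)
  check_proportion(dropout_rate, "dropout_rate")
  run_seeded(seed, {
    a <- population$alleles
    n_sites <- nrow(a); n_nuc <- ncol(a)
    dp <- ro <- ao <- matrix(NA_real_, n_sites, n_nuc,
                             dimnames = list(NULL, colnames(a)))
    f_all <- rowMeans(a)
    for (j in seq_len(n_nuc)) {
      # mean allele over the *other* nuclei, as contamination source
      f_other <- if (n_nuc > 1) (f_all * n_nuc - a[, j]) / (n_nuc - 1)
                 else a[, j]
      p_alt <- (1 - contamination_rate) * a[, j] +
        contamination_rate * f_other
      depth <- draw_depth(n_sites, model)
      drop <- stats::runif(n_sites) < dropout_rate
      depth[drop] <- 0L
      cnt <- draw_counts(depth, p_alt, model$error_rate)
      covered <- cnt$dp > 0
      dp[covered, j] <- cnt$dp[covered]
      ro[covered, j] <- cnt$ro[covered]
      ao[covered, j] <- cnt$ao[covered]
    }
    variant_table(population$genome$sites[, c("contig", "pos", "ref", "alt")],
                  dp = dp, ro = ro, ao = ao)
  })
}

#' Simulate per-host RNA-seq allele counts
#'
#' Emulates allele-specific expression of the two nucleotypes in different
#' host plants. For each host, a random `expressed_fraction` subset of
#' non-repeat sites is expressed (the same subset across that host's
#' replicates). Each read's source nucleotype is drawn with probability
#' proportional to (number of nuclei of that MAT) x (the host's expression
#' weight for that MAT); within the chosen nucleotype the source nucleus is
#' uniform. With weights `(w1, w2)` and MAT-1 share `r`, the effective
#' MAT-1 share of the mRNA pool is `r * w1 / (r * w1 + (1 - r) * w2)`.
#'
#' @param population a [make_nucleus_population()] result.
#' @param model a [nucleotype_model()].
#' @param host_weights named list mapping host name to a numeric pair
#'   `(w_MAT1, w_MAT2)`; non-negative, not both zero.
#' @param expressed_fraction fraction of non-repeat sites expressed per
#'   host.
#' @param n_replicates biological replicates per host.
#' @param seed integer seed.
#' @return Named list (one element per host) of lists of [variant_table()]
#'   objects, one per replicate; unexpressed sites are `NA`.
#' @export
simulate_rna_counts <- function(population, model, host_weights,
                                expressed_fraction = 0.5, n_replicates = 3,
                                seed = NULL) {
  stopifnot(inherits(population, "nucleus_population"),
            inherits(model, "nucleotype_model"))
  if (is.null(names(host_weights)) || any(!nzchar(names(host_weights))))
    stop_hk("'host_weights' must be a named list of (w_MAT1, w_MAT2) pairs")
  for (h in names(host_weights)) {
    w <- host_weights[[h]]
    if (length(w) != 2L || any(w < 0) || sum(w) == 0)
      stop_hk("host '%s': weights must be two non-negative values, not both zero", h)
  }
  check_proportion(expressed_fraction, "expressed_fraction")
  check_count(n_replicates, "n_replicates", min = 1L)
  run_seeded(seed, {
    a <- population$alleles
    mat <- population$nuclei$mat
    sites <- population$genome$sites
    is1 <- mat == "MAT-1"
    n1 <- sum(is1); n2 <- sum(!is1)
    f1 <- if (n1) rowMeans(a[, is1, drop = FALSE]) else rep(0, nrow(a))
    f2 <- if (n2) rowMeans(a[, !is1, drop = FALSE]) else rep(0, nrow(a))
    candidates <- which(!sites$in_repeat)
    out <- list()
    for (h in names(host_weights)) {
      w <- host_weights[[h]]
      p1 <- n1 * w[1] / (n1 * w[1] + n2 * w[2])
      expressed <- sort(sample(candidates,
                               round(expressed_fraction *
                                       length(candidates))))
      p_alt <- p1 * f1 + (1 - p1) * f2
      reps <- lapply(seq_len(n_replicates), function(k) {
        dp <- ro <- ao <- matrix(NA_real_, nrow(a), 1,
                                 dimnames = list(NULL,
                                                 sprintf("%s_rep%d", h, k)))
        depth <- draw_depth(length(expressed), model)
        cnt <- draw_counts(depth, p_alt[expressed], model$error_rate)
        dp[expressed, 1] <- cnt$dp
        ro[expressed, 1] <- cnt$ro
        ao[expressed, 1] <- cnt$ao
        variant_table(sites[, c("contig", "pos", "ref", "alt")],
                      dp = dp, ro = ro, ao = ao)
      })
      out[[h]] <- reps
    }
    out
  })
}

#' Simulate nucleotype-ratio drift across spore bottlenecks
#'
#' Spore formation samples a finite number of nuclei from the parental
#' mycelium, so the nucleotype ratio drifts between generations like a
#' Wright-Fisher population: each generation, each lineage's new ratio is
#' `Binomial(n_nuclei_per_spore, current ratio) / n_nuclei_per_spore`.
#' Hyphal fusion (anastomosis) re-mixes nuclei between lineages; with
#' mixing rate `m` the post-sampling ratio is
#' `(1 - m) * sampled + m * mean(sampled across lineages)`. Without mixing
#' the ratio is a bounded martingale, so lineages eventually fix at 0 or 1
#' and the probability of fixing at 1 equals the starting ratio.
#'
#' @param ratio_r starting MAT-1 ratio, in `[0, 1]`.
#' @param n_nuclei_per_spore nuclei sampled into each new spore (>= 1).
#' @param n_generations number of spore generations.
#' @param n_lineages number of independent lineages.
#' @param mixing_rate anastomosis mixing rate `m`, in `[0, 1]`.
#' @param seed integer seed.
#' @return Matrix of ratios, `n_lineages` x `n_generations + 1`; column 1
#'   is the starting ratio (generation 0).
#' @examples
#' traj <- spore_bottleneck(0.5, n_nuclei_per_spore = 200,
#'                          n_generations = 1, n_lineages = 1000, seed = 1)
#' var(traj[, 2])          # ~ 0.5 * 0.5 / 200
#' @export
spore_bottleneck <- function(ratio_r, n_nuclei_per_spore, n_generations,
                             n_lineages, mixing_rate = 0, seed = NULL) {
  check_proportion(ratio_r, "ratio_r")
  check_count(n_nuclei_per_spore, "n_nuclei_per_spore", min = 1L)
  check_count(n_generations, "n_generations", min = 1L)
  check_count(n_lineages, "n_lineages", min = 1L)
  check_proportion(mixing_rate, "mixing_rate")
  run_seeded(seed, {
    traj <- matrix(NA_real_, n_lineages, n_generations + 1L,
                   dimnames = list(NULL,
                                   paste0("gen", 0:n_generations)))
    cur <- rep(ratio_r, n_lineages)
    traj[, 1] <- cur
    for (g in seq_len(n_generations)) {
      sampled <- stats::rbinom(n_lineages, n_nuclei_per_spore, cur) /
        n_nuclei_per_spore
      cur <- (1 - mixing_rate) * sampled + mixing_rate * mean(sampled)
      traj[, g + 1L] <- cur
    }
    traj
  })
}
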