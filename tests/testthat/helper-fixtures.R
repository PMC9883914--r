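# shared fixture builders and independent brute-force oracles

toy_sites <- function(n, contig = "c1", start = 100, step = 100) {
  data.frame(contig = rep(contig, n),
             pos = seq(start, by = step, length.out = n),
             ref = rep("A", n), alt = rep("G", n),
             stringsAsFactors = FALSE)
}

toy_table <- function(dp, ro, ao, sample = "s1", sites = NULL) {
  n <- length(dp)
  if (is.null(sites)) sites <- toy_sites(n)
  m <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, sample))
  variant_table(sites, dp = m(dp), ro = m(ro), ao = m(ao))
}

# build callsets directly from a character matrix of calls ("ref"/"alt"/NA)
callsets_from_matrix <- function(calls, mats, sites = NULL) {
  if (is.null(sites)) sites <- toy_sites(nrow(calls))
  ids <- if (!is.null(colnames(calls))) colnames(calls)
         else paste0("nuc", seq_len(ncol(calls)))
  lapply(seq_len(ncol(calls)), function(j) {
    structure(list(nucleus_id = ids[j], mat = mats[j],
                   calls = calls[, j], het = rep(FALSE, nrow(calls)),
                   sites = sites),
              class = "nucleus_callset")
  })
}

# brute-force oracle: a site is discordant iff some MAT group holds both
# non-missing call values — enumerated pair by pair, independent of the
# vectorised implementation
oracle_discordant <- function(calls, mats) {
  vapply(seq_len(nrow(calls)), function(i) {
    for (m in c("MAT-1", "MAT-2")) {
      g <- calls[i, mats == m]
      g <- g[!is.na(g)]
      if (length(g) >= 2) {
        for (a in seq_along(g)) for (b in seq_along(g))
          if (g[a] == "ref" && g[b] == "alt") return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

# brute-force oracle for maximal runs: checks every candidate window
oracle_blocks <- function(sites, flags, min_run = 5,
                          min_snps_per_contig = 2) {
  out <- list()
  for (ctg in unique(sites$contig)) {
    si <- which(sites$contig == ctg)
    if (length(si) < min_snps_per_contig) next
    f <- flags[si]
    n <- length(f)
    for (first in seq_len(n)) for (last in first:n) {
      len <- last - first + 1
      if (len < min_run) next
      all_disc <- all(f[first:last])
      maximal <- all_disc &&
        (first == 1 || !f[first - 1]) && (last == n || !f[last + 1])
      if (maximal)
        out[[length(out) + 1]] <- data.frame(
          contig = ctg, first_index = first, last_index = last,
          n_snps = len, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(contig = character(0), first_index = integer(0),
                  last_index = integer(0), n_snps = integer(0))
}

# a small end-to-end synthetic scenario reused across tests
demo_population <- function(ratio_r = 0.5, n_nuclei = 10, n_sites_kb = 1,
                            n_contigs = 5, contig_length = 2e4,
                            n_tracts = 0, tract_len = 6, seed = 42,
                            low_freq = 0, repeat_fraction = 0,
                            mean_depth = 60, error_rate = 0,
                            depth_dispersion = 0) {
  g <- make_genome(n_contigs, contig_length, snp_per_kb = n_sites_kb,
                   repeat_fraction = repeat_fraction,
                   low_freq_site_fraction = low_freq, seed = seed)
  m <- nucleotype_model(ratio_r, error_rate = error_rate,
                        mean_depth = mean_depth,
                        depth_dispersion = depth_dispersion)
  p <- make_nucleus_population(g, m, n_nuclei, n_recomb_tracts = n_tracts,
                               tract_len_snps = tract_len, seed = seed + 1)
  list(genome = g, model = m, pop = p)
}
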