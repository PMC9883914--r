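---
title: "Inferring nucleotype structure in coenocytic fungi from read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nucleotype structure in coenocytic fungi from read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterokaryon)
```

## The biological problem

Arbuscular mycorrhizal (AM) fungi such as *Rhizophagus irregularis* grow as
coenocytic mycelia: one shared cytoplasm containing up to millions of
haploid nuclei, with no known single-nucleus stage. Some isolates are
dikaryote-like — they harbour two genetically distinct classes of nuclei
("nucleotypes"), distinguishable by the allele each carries at the putative
mating-type (MAT) locus. Because every sequencing sample is a pool over
nuclei, the genetic organisation of such an individual has to be read out
indirectly, from allele frequencies:

* **Pooled DNA.** At a biallelic SNP whose alternate allele is carried by
  one nucleotype only, the expected alternate-read frequency equals that
  nucleotype's share of nuclei. A balanced dikaryon therefore shows a
  single spectrum peak at 50%; a 2:1 mixture shows mirrored peaks at ~33%
  and ~67% (whether a peak sits low or high depends on which nucleotype
  happens to carry the alternate allele at that site); a homokaryon shows
  no intermediate-frequency mass at all.
* **Single nuclei.** A haploid nucleus carries exactly one allele per
  site, and in a strict dikaryon all nuclei sharing a MAT allele should
  agree at every site. Sites where both alleles occur *within* one MAT
  group ("discordant" sites), especially in runs of consecutive SNPs on
  one contig, are the signature of inter-nucleus recombination.
* **RNA across hosts.** The two nucleotypes need not contribute equally
  to the mRNA pool. Comparing allele-frequency spectra of the same SNPs
  expressed in different host plants quantifies host-dependent
  allele-specific expression.

This package implements these read-outs as testable functions, together
with a synthetic-data generator that produces inputs with known ground
truth, so that every inference step can be benchmarked end to end.

## The generative model

The generator (`make_genome()`, `make_nucleus_population()`,
`simulate_*_counts()`) encodes the assumptions the analysis relies on:

* **Sites.** Biallelic SNPs are placed along contigs as a Poisson process
  with the requested density (default scale: ~1 SNP/kb, the order observed
  in dikaryote-like isolates). Each ordinary site's alternate allele is
  carried by exactly one nucleotype, assigned to either with equal
  probability (`p_alt_mat1 = 0.5`); this symmetry is what produces the
  mirrored spectrum peaks. A configurable minority of "low-frequency"
  sites is instead carried by a random sub-fraction of one nucleotype's
  nuclei, drawn uniformly from 0.2–0.5 of the group so that, at a balanced
  ratio, their pooled read frequencies land in the 10–25% range reported
  for real low-frequency polymorphisms. How such variants are really
  distributed across nuclei is unknown; the sub-fraction model is one
  plausible choice and is confined to the generator.
* **Repeats.** 1-kb windows are marked independently with the requested
  probability and merged, giving repeat intervals that cover approximately
  the requested genome fraction with realistic sizes. Repeat intervals are
  written as 0-based half-open BED; all SNP positions are 1-based, and a
  position *p* lies in interval [s, e) iff s ≤ p − 1 < e.
* **Depth.** Per-site depth is negative binomial with mean `mean_depth`
  and dispersion `depth_dispersion` (variance μ + φμ²), reducing to pure
  Poisson at φ = 0. Real coverage is only reported as empirical windows
  (e.g. 85–135x around a 110x mean), which a mild dispersion reproduces.
* **Error.** Each read reports its source allele, but with probability
  `error_rate` it is replaced by one of the three other bases uniformly —
  so an erroneous read hits the opposite allele of the pair with
  probability 1/3 and otherwise falls off the pair, which is why
  RO + AO ≤ DP with equality only at zero error.
* **Single-nucleus artefacts.** Whole-genome amplification is modelled
  only as per-site dropout (depth 0, recorded as missing) plus per-read
  contamination from a uniformly chosen other nucleus. No attempt is made
  to model MDA amplification bias beyond this.
* **Recombination tracts.** Ground-truth tracts swap a run of
  `tract_len_snps` *consecutive SNPs* (an ordinal, site-index notion, not
  a bp distance — matching how the block caller defines consecutiveness)
  in one nucleus to the opposite nucleotype's consensus. Tracts never
  overlap or abut, so implanted and recovered block boundaries are
  comparable one-to-one.
* **MAT labels** are error-free in synthesis: upstream PCR genotyping of
  sorted nuclei is assumed correct, and `floor(ratio_r * n_nuclei)` nuclei
  are labelled MAT-1. Note that with few nuclei the *realized* ratio can
  differ from `ratio_r` (10 nuclei at 2/3 gives 6/10 = 0.6); all recovery
  tests compare against the realized ratio.

What the generator does **not** emulate: mapping artefacts, indels and
multiallelic sites, linkage between neighbouring SNPs beyond tract
structure, GC- or repeat-dependent coverage bias, and real MDA chimeras.
Passing tests therefore demonstrate correctness of the inference
machinery under the stated model, not robustness to every artefact of
real libraries.

## Filters

`filter_pool_snps()` retains a site iff its depth lies inside an inclusive
window (default 85–135, i.e. `coverage_window(110, 25)`; inclusivity
matches the "between … and" phrasing of typical filter descriptions),
both alleles were observed at least `min_allele_obs = 10` times, and the
site lies outside annotated repeats. Filtering is idempotent and
monotone: loosening any single threshold can only grow the surviving set
— both are property-tested.

`call_nucleus()` encodes the haploidy logic: depth below `min_depth = 10`
gives a missing call; both alleles *strictly* above a 10% read share flag
the site heterozygous (contamination/chimerism, call withheld); otherwise
the majority allele is called. A tie RO = AO > 0 cannot survive the
heterozygosity rule (both shares would be 0.5), which the code asserts
rather than handles. Heterozygous loci are pooled across **all** nuclei
— the conservative scoping — and every SNP within 500 bp (inclusive at
exactly 500) on the same contig is excised before concordance analysis.
A per-site boolean mask is accepted for filters that need information
absent from count data (e.g. the paired-read status of supporting
reads); it defaults to a no-op.

`filter_rna_snps()` sums counts over a host's replicates before applying
the depth (≥ 20) and allele-support (≥ 10) thresholds in every host; a
stricter per-replicate mode (`pool_replicates = FALSE`) is available
since published per-replicate spectra suggest both conventions are in
use.

## Ratio inference

The spectrum read-out is made quantitative in two independent ways, and
their agreement is itself a tested property:

1. `detect_modes()` smooths the frequency spectrum with a Gaussian kernel
   (bandwidth 0.02 on the frequency scale; 1%-bin histograms remain
   available for plotting) and reports local maxima above 10% of the peak
   density, in percent. **Resolution limit:** mirrored peaks at r and
   1 − r are only resolvable when their separation exceeds the binomial
   read noise, roughly `|2r − 1| > 2·sqrt(r(1−r)/depth) + bandwidth`; at
   110x depth, ratios inside ~0.45–0.55 merge into one central mode. The
   estimator-agreement property is therefore tested at a depth where
   both estimators are in their validity regime.
2. `estimate_ratio_mle()` maximises, over the major-nucleotype share
   r ∈ [0.5, 1], the two-component binomial mixture log-likelihood
   Σᵢ log[½·B(aᵢ; nᵢ, r) + ½·B(aᵢ; nᵢ, 1 − r)], reflecting that each
   site's alternate allele sits on the major or minor nucleotype with
   equal prior. A grid search at 0.001 resolution (fine enough that the
   likelihood is unimodal within a cell at realistic site counts) is
   refined locally with `optimize()`. The estimate is invariant under
   ref/alt relabelling by the symmetry of the mixture. Samples with
   r ≥ 0.95 are classified monokaryon — residual low-frequency variants
   keep a real monokaryon just below r = 1, so the threshold is
   configurable rather than exact; degenerate all-monoallelic input
   short-circuits to r = 1.

`mat_coverage_ratio()` provides the orthogonal DNA read-out: the two MAT
loci are nucleotype-private, so their mean per-base depths normalise
directly to nucleotype proportions (per-base mean depth is used; read
counts over the locus would differ only by edge effects).
`pca_shared_snps()` reproduces the standard sample-level view: alternate
frequencies at sites covered in all samples, columns centred and scaled
(zero-variance columns dropped), `prcomp()`.

## Concordance, blocks and similarity

`find_discordant_snps()` flags a site when both alleles occur within a
MAT group, with missing calls excluded from the test; the denominator of
the discordance percentage counts sites, not site×nucleus observations.
`find_recombination_blocks()` first skips contigs with fewer than 2
SNPs, then reports maximal runs of ≥ 5 consecutive discordant SNPs per
contig, with the carrier set defined as the nuclei holding the minority
allele within their group across the block. Both functions are verified
against brute-force enumerators on hundreds of random genotype matrices,
and against implanted ground-truth tracts, which must be recovered with
exact site-index boundaries. `similarity_matrix()` is the fraction of
co-called sites in agreement per nucleus pair (pairs with no co-called
sites are missing, not zero).

## Drift at spore bottlenecks

`spore_bottleneck()` is a Wright–Fisher binomial sampler: each
generation, each lineage's ratio is resampled as
Binomial(n, r)/n over the `n_nuclei_per_spore` nuclei entering the new
spore, optionally pulled toward the across-lineage mean by a mixing rate
m that stands in for anastomosis. One-generation variance r(1−r)/n, the
martingale fixation probability (fraction of lineages fixed at 1 → r),
monotone variance growth without mixing, and variance collapse at m = 1
are all asserted against closed forms. The default study-scale scenario
uses a few hundred nuclei per spore, the order reported for AM fungal
spores.

## Host-dependent allele-specific expression

`simulate_rna_counts()` draws each read's source nucleotype with
probability proportional to (nuclei of that MAT) × (host weight), so a
host weighting the minority nucleotype's transcription twofold at a 2:1
DNA ratio equalises expression exactly: the effective MAT-1 share is
(2/3·1)/((2/3·1) + (1/3·2)) = 1/2, collapsing the mirrored 33/67 peaks
into one 50% peak. `ase_shift()` quantifies the visual contrast between
such spectra with two statistics: the *central mass* (fraction of shared
sites within ±0.07 of 0.5 — wide enough to absorb read noise at 20x,
narrow enough to separate 50% from 33/67 peaks) and the pairwise
two-sample Kolmogorov–Smirnov statistic. `replicate_consistency()`
supplies the matching null: between-host distances are only meaningful
when they exceed within-host replicate distances. Because count-level
RNA data cannot distinguish expression modulation from an underlying
shift in nucleotype ratio, the module reports expression-level shifts
only and makes no claim about DNA-level ratios.

## Numerical and design choices

* Missing data is explicit (`NA`) and excluded from denominators, never
  imputed as zero.
* Depth bounds, proximity distances and the heterozygosity threshold are
  inclusive/strict exactly as stated above; boundary behaviour is pinned
  by tests (e.g. AO/DP = 0.1 is *not* heterozygous; a site exactly 500 bp
  from a heterozygous locus *is* excluded; pos 100 is the last position
  inside BED interval [0, 100)).
* The printed heterozygosity rule in the source methods ("RO/DP > 0.1 ||
  AO/DP > 0.1") would be almost always true as written; the verbal
  definition — *both* alleles above 10% — dictates a conjunction, which
  is what is implemented.
* All generators are bit-reproducible given a seed (`withr::with_seed`),
  and a `NULL` seed draws from the session RNG.
* Test and acceptance problem sizes — ~5000 sites for spectrum checks,
  2000-site ratio recovery, 8×50 oracle matrices, 2000-lineage drift
  runs — were chosen as the smallest scales at which the Monte-Carlo
  error is comfortably below the assertion tolerances.

## Known limitations

* The binomial-mixture MLE assumes two nucleotypes; aneuploidy or three
  or more nucleotypes are out of scope (the spectrum of a 2:1 dikaryon is
  deliberately *analogous* to a triploid's, and the model cannot tell
  them apart from counts alone).
* Block calling operates in post-filter site-index space; a block's bp
  extent is reported but plays no role in calling.
* The KS statistic treats sites as independent; linkage between
  neighbouring expressed SNPs makes its nominal p-values optimistic,
  which is why only the statistic (never a p-value) is reported and the
  replicate null is used for calibration.
* `read_vcf()` handles the freebayes count dialect (DP/RO/AO) only; it
  is not a general VCF feature parser.
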