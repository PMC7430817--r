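#' Genome model for the synthetic XX/XY population
#'
#' Describes the reference genome the simulator emulates: a set of
#' linkage groups, one planted non-recombining sex-determining region
#' (SDR) on a single linkage group, and per-base rates for shared
#' background polymorphism and Y-specific divergent sites inside the SDR.
#' All coordinates are 1-based closed intervals.
#'
#' The default is a desk-scale genome of five 40 Mb linkage groups with a
#' 12 Mb SDR planted on "LG22", echoing the scale of a large
#' non-recombining sex locus on a cyprinid linkage group. Rates are
#' reduced relative to a real genome so that a whole-genome scan stays
#' fast: one shared SNP per 10 kb of background and one Y-divergent site
#' per kb inside the SDR.
#'
#' @param linkage_groups Data frame with columns `lg` (name) and
#'   `length` (bp).
#' @param sdr List with `lg`, `start`, `end` (1-based closed interval)
#'   locating the planted non-recombining region.
#' @param background_snp_rate Expected shared-polymorphism sites per bp.
#' @param y_divergent_rate Expected Y-specific divergent sites per bp
#'   inside the SDR.
#' @return An object of class `genome_model`.
#' @examples
#' genome_model()
#' @export
genome_model <- function(linkage_groups = tibble(
                           lg = paste0("LG", 20:24),
                           length = rep(40e6, 5)
                         ),
                         sdr = list(lg = "LG22", start = 14e6 + 1, end = 26e6),
                         background_snp_rate = 1e-4,
                         y_divergent_rate = 1e-3) {
  linkage_groups <- as_tibble(linkage_groups)
  if (!all(c("lg", "length") %in% names(linkage_groups)) ||
      nrow(linkage_groups) == 0) {
    abort("`linkage_groups` needs columns `lg` and `length` and >= 1 row.")
  }
  if (anyDuplicated(linkage_groups$lg)) abort("Linkage group names must be unique.")
  if (any(linkage_groups$length < 1)) abort("Linkage group lengths must be >= 1 bp.")
  check_prob(background_snp_rate, "background_snp_rate")
  check_prob(y_divergent_rate, "y_divergent_rate")
  if (!all(c("lg", "start", "end") %in% names(sdr))) {
    abort("`sdr` must be a list with `lg`, `start`, `end`.")
  }
  hit <- match(sdr$lg, linkage_groups$lg)
  if (is.na(hit)) abort("SDR linkage group is not part of the genome.")
  if (sdr$start < 1 || sdr$end > linkage_groups$length[hit] ||
      sdr$start > sdr$end) {
    abort("SDR interval must lie within its linkage group.")
  }
  structure(
    list(
      linkage_groups = linkage_groups,
      sdr = sdr,
      background_snp_rate = background_snp_rate,
      y_divergent_rate = y_divergent_rate
    ),
    class = "genome_model"
  )
}

#' Population and noise parameters for the simulator
#'
#' Collects every tunable rate of the synthetic population: cohort sizes,
#' the neomale rate (probability that a phenotypic male is genetically
#' XX, i.e. a temperature sex-reversed female), the undifferentiated-gonad
#' rate, marker-call discordance, pooled sequencing depth, and RAD-tag
#' dropout.
#'
#' Defaults mirror the study conditions the package emulates: 30
#' phenotypic males and 30 phenotypic females, a neomale rate of 0.5 as
#' observed in outdoor-reared animals, mean pool depth 50x, and 10% tag
#' dropout so a Y tag present in all 15 XY males is typically seen in
#' 12--15 of them. The discordance default 0.015 matches roughly one
#' contradictory marker call in 65.
#'
#' @param n_pheno_males,n_pheno_females Cohort sizes by phenotype.
#' @param neomale_rate Probability a phenotypic male is genetically XX.
#' @param undiff_rate Probability an offspring's gonad is histologically
#'   undifferentiated (overrides the phenotype label).
#' @param discordance Probability a marker call contradicts the genotype.
#' @param pool_depth Mean per-site sequencing depth of each pool.
#' @param tag_dropout Probability a truly present RAD tag has zero depth
#'   in an individual.
#' @param tag_depth_mean Mean depth of a present RAD tag (shifted
#'   Poisson, minimum 1).
#' @param seed Optional integer seed; when set, every generator called
#'   with these parameters is reproducible.
#' @return An object of class `population_params`.
#' @examples
#' population_params(neomale_rate = 0.078, seed = 1)
#' @export
population_params <- function(n_pheno_males = 30,
                              n_pheno_females = 30,
                              neomale_rate = 0.5,
                              undiff_rate = 0.2,
                              discordance = 0.015,
                              pool_depth = 50,
                              tag_dropout = 0.1,
                              tag_depth_mean = 20,
                              seed = NULL) {
  n_pheno_males <- check_count(n_pheno_males, "n_pheno_males")
  n_pheno_females <- check_count(n_pheno_females, "n_pheno_females")
  check_prob(neomale_rate, "neomale_rate")
  check_prob(undiff_rate, "undiff_rate")
  check_prob(discordance, "discordance")
  check_prob(tag_dropout, "tag_dropout")
  if (pool_depth <= 0) abort("`pool_depth` must be > 0.")
  if (tag_depth_mean < 1) abort("`tag_depth_mean` must be >= 1.")
  if (!is.null(seed)) seed <- check_count(seed, "seed")
  structure(
    list(
      n_pheno_males = n_pheno_males,
      n_pheno_females = n_pheno_females,
      neomale_rate = neomale_rate,
      undiff_rate = undiff_rate,
      discordance = discordance,
      pool_depth = pool_depth,
      tag_dropout = tag_dropout,
      tag_depth_mean = tag_depth_mean,
      seed = seed
    ),
    class = "population_params"
  )
}

#' Parameters of the RAD-tag presence/absence analysis
#'
#' @param min_depth Minimum read depth for a tag to count as present in
#'   an individual (default 1: any read).
#' @param min_males Minimum number of carrier males for a male-specific
#'   marker call (inclusive bound, default 12).
#' @param max_females Maximum number of carrier females tolerated
#'   (default 0: completely absent from females).
#' @param alpha Significance level of the sex-bias test after correction.
#' @param correction Multiple-testing correction; only `"bonferroni"`
#'   over the number of distinct carried tags is supported.
#' @return An object of class `rad_params`.
#' @export
rad_params <- function(min_depth = 1, min_males = 12, max_females = 0,
                          alpha = 0.05, correction = "bonferroni") {
  if (min_depth < 1) abort("`min_depth` must be >= 1.")
  min_males <- check_count(min_males, "min_males")
  max_females <- check_count(max_females, "max_females")
  check_prob(alpha, "alpha")
  correction <- match.arg(correction, "bonferroni")
  structure(
    list(min_depth = min_depth, min_males = min_males,
         max_females = max_females, alpha = alpha, correction = correction),
    class = "rad_params"
  )
}

#' Parameters of the two-pool site classification and window scan
#'
#' Numeric criteria of the pooled scan. A site is sex-specific when one
#' pool is heterozygous (exactly two alleles, each at frequency
#' `freq_het` +/- `range_het`) while the other pool is fixed (major
#' allele frequency at least `freq_hom - range_hom`) for an allele
#' different from the heterozygous pool's variant allele. Defaults are
#' the published scan settings: minimum depth 10, heterozygous band
#' 0.5 +/- 0.2, homozygous threshold 1 - 0.02 = 0.98, 100 kb sliding
#' windows with an output point every 500 bp.
#'
#' @param min_depth Minimum per-pool nucleotide depth; sites below it in
#'   either pool are classed `low_depth`.
#' @param freq_het,range_het Center and half-width of the heterozygous
#'   allele-frequency band.
#' @param freq_hom,range_hom Homozygous major-allele frequency target and
#'   tolerated departure.
#' @param window_size Sliding window width in bp (window centered on each
#'   output point, clipped at chromosome ends).
#' @param output_resolution Distance between output points in bp.
#' @return An object of class `poolscan_params`.
#' @export
poolscan_params <- function(min_depth = 10, freq_het = 0.5, range_het = 0.2,
                            freq_hom = 1.0, range_hom = 0.02,
                            window_size = 100e3, output_resolution = 500) {
  if (min_depth < 1) abort("`min_depth` must be >= 1.")
  if (freq_het - range_het <= 0 || freq_het + range_het >= 1) {
    abort("The heterozygous band `freq_het` +/- `range_het` must lie inside (0, 1).")
  }
  if (freq_hom - range_hom <= 0.5) {
    abort("`freq_hom - range_hom` must exceed 0.5.")
  }
  if (window_size < output_resolution) {
    abort("`window_size` must be >= `output_resolution`.")
  }
  structure(
    list(min_depth = min_depth, freq_het = freq_het, range_het = range_het,
         freq_hom = freq_hom, range_hom = range_hom,
         window_size = window_size, output_resolution = output_resolution),
    class = "poolscan_params"
  )
}

#' Policy for calling contiguous SDR intervals from the window scan
#'
#' Windows whose male-specific SNP count exceeds the genome-wide mean by
#' more than `z_threshold` standard deviations are flagged; flagged
#' windows on the same chromosome within `merge_gap` bp of each other are
#' merged, and merged spans of at least `min_span` bp are reported.
#'
#' @param z_threshold Number of genome-wide standard deviations above the
#'   mean a window must reach to be flagged (default 3).
#' @param merge_gap Maximum gap (bp) bridged when merging flagged
#'   windows (default 500 kb).
#' @param min_span Minimum reported span (bp, default 1 Mb).
#' @return An object of class `sdr_policy`.
#' @export
sdr_policy <- function(z_threshold = 3, merge_gap = 500e3, min_span = 1e6) {
  if (z_threshold < 0) abort("`z_threshold` must be >= 0.")
  if (merge_gap < 0) abort("`merge_gap` must be >= 0.")
  if (min_span < 0) abort("`min_span` must be >= 0.")
  structure(
    list(z_threshold = z_threshold, merge_gap = merge_gap, min_span = min_span),
    class = "sdr_policy"
  )
}
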