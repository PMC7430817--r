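#' Run the end-to-end synthetic sex-locus workflow
#'
#' Wires the package's stages into the full study design: simulate an
#' XX/XY population with sex reversal, discover male-specific RAD tags
#' and classify males into XY carriers and XX neomales, purify the male
#' pool down to marker-verified Y carriers, run the pooled window scan
#' and SDR caller, and simulate the two validation crosses (XX neomale
#' sire and XY sire) with their linkage and sex-ratio statistics.
#'
#' Purification is the load-bearing step: with a neomale rate near 0.5
#' an unpurified male pool carries the Y allele at frequency near 0.25,
#' outside the heterozygous detection band, which degrades the pooled
#' signal -- the reason the individual-based marker step precedes the
#' pooled scan.
#'
#' Each stage draws from its own seeded RNG stream derived from `seed`,
#' so a rerun with the same configuration is byte-identical.
#'
#' @param params A [population_params()]; its `seed` field is ignored in
#'   favour of `seed`.
#' @param genome A [genome_model()].
#' @param rad A [rad_params()].
#' @param pool A [poolscan_params()].
#' @param policy An [sdr_policy()].
#' @param seed Integer master seed.
#' @param purify_male_pool When `TRUE`, only phenotypic males classified
#'   Y-carrier enter the male pool of the pooled scan; when `FALSE` all
#'   phenotypic males do.
#' @param n_autosomal_tags,n_y_tags Tag counts for the simulated RAD
#'   matrix.
#' @param cross_sizes Named vector with offspring counts for the `xx`
#'   and `xy` sired crosses.
#' @param cross_params Optional [population_params()] used for the
#'   crosses. The default copies `params` but lowers the neomale rate to
#'   0.078, emulating indoor low-temperature rearing of the validation
#'   crosses as opposed to the outdoor-reared discovery population.
#' @param out_dir Optional directory; when given, every stage output is
#'   written there (tag matrix TSV, registry CSV, sync file, window
#'   table TSV, SDR BED + JSON, cross tables CSV, truth JSON) and the
#'   manifest records each file's md5 checksum.
#' @return An `sdr_pipeline` list: `truth`, `registry`, `tags`,
#'   `tag_truth`, `significant`, `male_tags`, `ind_calls`, `male_pool`,
#'   `sync`, `site_truth`, `sites`, `windows`, `sdr`, `crosses`,
#'   `cross_summary`, `linkage`, `sex_reversal`, `manifest`.
#' @export
run_pipeline <- function(params = population_params(),
                         genome = genome_model(),
                         rad = rad_params(),
                         pool = poolscan_params(),
                         policy = sdr_policy(),
                         seed = 42,
                         purify_male_pool = TRUE,
                         n_autosomal_tags = 2000,
                         n_y_tags = 32,
                         cross_sizes = c(xx = 131, xy = 127),
                         cross_params = NULL,
                         out_dir = NULL) {
  seed <- check_count(seed, "seed")
  params$seed <- NULL
  if (is.null(cross_params)) {
    cross_params <- params
    cross_params$neomale_rate <- 0.078
  }
  cross_params$seed <- NULL

  # stage 1: individuals
  ind <- withr::with_seed(seed + 1L, simulate_individuals(params))

  # stage 2: RAD tags + marker discovery + classification
  tagsim <- withr::with_seed(
    seed + 2L,
    simulate_tag_matrix(ind$truth, genome, params,
                        n_autosomal_tags = n_autosomal_tags,
                        n_y_tags = n_y_tags)
  )
  presence <- build_presence(tagsim$tags, rad$min_depth)
  sig <- significant_tags(presence, ind$registry, rad)
  mtags <- male_specific_tags(presence, ind$registry, rad)
  calls <- if (nrow(mtags) > 0) {
    classify_individuals(presence, ind$registry, mtags)
  } else NULL

  # stage 3: male-pool purification
  all_males <- ind$registry$id[ind$registry$phenotype == "male"]
  male_pool <- all_males
  if (purify_male_pool) {
    if (is.null(calls)) {
      warn("No male-specific tags found; pooling all phenotypic males.")
    } else {
      carriers <- calls$id[calls$phenotype == "male" & calls$call == "Y-carrier"]
      if (length(carriers) > 0) male_pool <- carriers
    }
  }

  # stage 4: pooled scan
  syncsim <- withr::with_seed(
    seed + 3L,
    simulate_sync(ind$truth, genome, params, male_pool = male_pool)
  )
  sites <- classify_sites(syncsim$sync, pool)
  chrom_lengths <- genome$linkage_groups |> rename(chrom = "lg")
  windows <- window_scan(sites, pool, chrom_lengths)
  sdr <- call_sdr(windows, policy)

  # stage 5: crosses
  cross_xx <- withr::with_seed(
    seed + 4L,
    simulate_cross("XX", cross_params, n_offspring = cross_sizes[["xx"]],
                   cross_id = "P(XX)")
  )
  cross_xy <- withr::with_seed(
    seed + 5L,
    simulate_cross("XY", cross_params, n_offspring = cross_sizes[["xy"]],
                   cross_id = "P(XY)")
  )
  cross_records <- bind_rows(cross_xx$records, cross_xy$records)
  cross_summary <- summarize_cross(cross_records)
  primers <- grep("^primer", names(cross_records), value = TRUE)
  linkage <- map(c("P(XX)", "P(XY)"), function(cr) {
    rec <- cross_records[cross_records$cross == cr, ]
    map(primers, function(p) {
      tidy(sex_linkage_test(rec, p)) |> mutate(cross = cr, .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()
  sex_rev <- estimate_sex_reversal(cross_xx$records)

  result <- list(
    seed = seed,
    params = params, genome = genome, rad = rad, pool = pool,
    policy = policy, purify_male_pool = purify_male_pool,
    truth = ind$truth, registry = ind$registry,
    tags = tagsim$tags, tag_truth = tagsim$tag_truth,
    significant = sig, male_tags = mtags, ind_calls = calls,
    male_pool = male_pool,
    sync = syncsim$sync, site_truth = syncsim$site_truth,
    sites = sites, windows = windows, sdr = sdr,
    crosses = list(xx = cross_xx, xy = cross_xy),
    cross_summary = cross_summary, linkage = linkage,
    sex_reversal = sex_rev
  )
  result$manifest <- build_manifest(result, out_dir)
  structure(result, class = "sdr_pipeline")
}

# write stage outputs (when out_dir is set) and collect checksums
build_manifest <- function(res, out_dir) {
  stages <- tibble(
    stage = c("simulate", "radtags", "purify", "poolscan", "cross"),
    n_out = c(nrow(res$truth), nrow(res$male_tags), length(res$male_pool),
              nrow(res$sdr), nrow(res$cross_summary))
  )
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_tag_matrix(res$tags, p("tag_matrix.tsv"))
    write_sex_registry(res$registry, p("sex_registry.csv"))
    write_sync(res$sync, p("pools.sync"))
    write_windows(as_tibble(res$windows), p("windows.tsv"))
    write_sdr_bed(res$sdr, p("sdr_calls.bed"))
    write_sdr_summary(res$sdr, p("sdr_summary.json"))
    write_cross_table(bind_rows(res$crosses$xx$records,
                                res$crosses$xy$records), p("crosses.csv"))
    write_truth_json(
      list(
        genotypes = res$truth,
        y_tags = res$tag_truth[res$tag_truth$is_y, ],
        sdr = res$genome$sdr,
        seed = res$seed
      ),
      p("truth.json")
    )
    paths <- c("tag_matrix.tsv", "sex_registry.csv", "pools.sync",
               "windows.tsv", "sdr_calls.bed", "sdr_summary.json",
               "crosses.csv", "truth.json")
    files <- tibble(
      file = paths,
      md5 = unname(tools::md5sum(file.path(out_dir, paths)))
    )
  }
  list(seed = res$seed, stages = stages, files = files)
}

#' @export
print.sdr_pipeline <- function(x, ...) {
  cat("Synthetic sex-locus pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  individuals: %d males / %d females; %d XY\n",
              sum(x$registry$phenotype == "male"),
              sum(x$registry$phenotype == "female"),
              sum(x$truth$genotype == "XY")))
  cat(sprintf("  male-specific tags: %d; male pool (purified=%s): %d\n",
              nrow(x$male_tags), x$purify_male_pool, length(x$male_pool)))
  cat(sprintf("  SDR calls: %d\n", nrow(x$sdr)))
  if (nrow(x$sdr)) {
    for (i in seq_len(nrow(x$sdr))) {
      cat(sprintf("    %s:%d-%d (%.1f Mb)\n", x$sdr$chrom[i],
                  x$sdr$start[i], x$sdr$end[i],
                  (x$sdr$end[i] - x$sdr$start[i] + 1) / 1e6))
    }
  }
  cat(sprintf("  sex reversal in P(XX): %.1f%% [%.3f, %.3f]\n",
              x$sex_reversal$pct, x$sex_reversal$conf.low,
              x$sex_reversal$conf.high))
  invisible(x)
}
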