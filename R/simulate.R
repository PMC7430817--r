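#' Simulate individuals of an XX/XY population with sex reversal
#'
#' Draws genotypes for a cohort of phenotypic males and females under
#' male heterogamety with environmental female-to-male sex reversal:
#' every phenotypic female is XX, and each phenotypic male is XY with
#' probability `1 - neomale_rate` and a sex-reversed XX neomale
#' otherwise.
#'
#' @param params A [population_params()] object.
#' @return A list with `registry`, a tibble of `id` and `phenotype`
#'   (what a field biologist would record), and `truth`, the same tibble
#'   with the latent `genotype` ("XX" or "XY") added.
#' @examples
#' sim <- simulate_individuals(population_params(seed = 1))
#' table(sim$truth$phenotype, sim$truth$genotype)
#' @export
simulate_individuals <- function(params = population_params()) {
  stopifnot(inherits(params, "population_params"))
  if (params$n_pheno_males < 1 || params$n_pheno_females < 1) {
    abort("Both pools need at least one individual.")
  }
  with_seed_if(params$seed, {
    male_ids <- sprintf("M%03d", seq_len(params$n_pheno_males))
    female_ids <- sprintf("F%03d", seq_len(params$n_pheno_females))
    male_geno <- if_else(runif(params$n_pheno_males) < params$neomale_rate,
                         "XX", "XY")
    truth <- tibble(
      id = c(male_ids, female_ids),
      phenotype = rep(c("male", "female"),
                      c(params$n_pheno_males, params$n_pheno_females)),
      genotype = c(male_geno, rep("XX", params$n_pheno_females))
    )
    list(registry = truth[c("id", "phenotype")], truth = truth)
  })
}

#' Simulate a per-individual RAD-tag depth matrix
#'
#' Generates the tag-by-individual depth matrix that individual-based
#' reduced-representation sequencing produces. Planted Y-linked tags sit
#' at random positions inside the SDR and have nonzero depth only in XY
#' individuals; autosomal tags are present in everyone. Presence is
#' thinned by the dropout probability `tag_dropout`, and depths of
#' present tags follow a shifted Poisson (minimum 1 read).
#'
#' @param truth Tibble with `id` and `genotype` columns (see
#'   [simulate_individuals()]).
#' @param genome A [genome_model()].
#' @param params A [population_params()].
#' @param n_autosomal_tags,n_y_tags Numbers of tags to plant.
#' @return A list with `tags` (wide tibble: `tag_id`, `sequence`, one
#'   integer depth column per individual) and `tag_truth` (tibble:
#'   `tag_id`, `lg`, `pos`, `is_y`). Every planted Y tag maps to a
#'   position inside the SDR.
#' @export
simulate_tag_matrix <- function(truth, genome = genome_model(),
                                params = population_params(),
                                n_autosomal_tags = 2000, n_y_tags = 32) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "population_params"))
  n_autosomal_tags <- check_count(n_autosomal_tags, "n_autosomal_tags")
  n_y_tags <- check_count(n_y_tags, "n_y_tags")
  if (!all(c("id", "genotype") %in% names(truth))) {
    abort("`truth` needs `id` and `genotype` columns.")
  }
  with_seed_if(params$seed, {
    n_ind <- nrow(truth)
    is_xy <- truth$genotype == "XY"
    n_tags <- n_autosomal_tags + n_y_tags
    tag_id <- sprintf("tag%06d", seq_len(n_tags))
    is_y <- rep(c(FALSE, TRUE), c(n_autosomal_tags, n_y_tags))

    # positions: Y tags inside the SDR, autosomal tags uniform elsewhere
    lgs <- genome$linkage_groups
    sdr <- genome$sdr
    a_lg <- sample(lgs$lg, n_autosomal_tags, replace = TRUE,
                   prob = lgs$length / sum(lgs$length))
    a_pos <- floor(runif(n_autosomal_tags) * lgs$length[match(a_lg, lgs$lg)]) + 1
    in_sdr <- a_lg == sdr$lg & a_pos >= sdr$start & a_pos <= sdr$end
    while (any(in_sdr)) { # push autosomal tags out of the SDR
      a_pos[in_sdr] <- floor(runif(sum(in_sdr)) *
                               lgs$length[match(a_lg[in_sdr], lgs$lg)]) + 1
      in_sdr <- a_lg == sdr$lg & a_pos >= sdr$start & a_pos <= sdr$end
    }
    y_pos <- if (n_y_tags > 0) {
      sdr$start + floor(runif(n_y_tags) * (sdr$end - sdr$start + 1))
    } else integer(0)
    tag_truth <- tibble(
      tag_id = tag_id,
      lg = c(a_lg, rep(sdr$lg, n_y_tags)),
      pos = c(a_pos, y_pos),
      is_y = is_y
    )

    # true presence: Y tags only on Y-bearing chromosomes, then dropout
    present_true <- matrix(TRUE, n_tags, n_ind)
    present_true[is_y, ] <- matrix(rep(is_xy, each = n_y_tags), n_y_tags, n_ind)
    kept <- present_true & matrix(runif(n_tags * n_ind) >= params$tag_dropout,
                                  n_tags, n_ind)
    depth <- matrix(0L, n_tags, n_ind, dimnames = list(NULL, truth$id))
    depth[kept] <- 1L + rpois(sum(kept), params$tag_depth_mean - 1)

    tags <- bind_cols(
      tibble(tag_id = tag_id, sequence = random_sequences(n_tags)),
      as_tibble(depth)
    )
    list(tags = tags, tag_truth = tag_truth)
  })
}

#' Simulate a two-pool sync table over the synthetic genome
#'
#' Emulates pooled sequencing of one male and one female pool mapped to
#' the reference: at each polymorphic position, per-pool nucleotide
#' counts are drawn with Poisson(`pool_depth`) total depth and binomial
#' allele sampling from the pool's allele frequency. Y-divergent sites
#' (inside the SDR only) carry the Y allele at frequency
#' `n_XY_in_pool / (2 * pool size)` in the male pool and are fixed for
#' the reference allele in the female pool; background sites share one
#' allele frequency (drawn uniform on \[0.1, 0.9\]) in both pools.
#'
#' Only polymorphic positions are emitted, so the table is sparse
#' relative to the genome.
#'
#' @param truth Tibble with `id`, `phenotype`, `genotype` (see
#'   [simulate_individuals()]).
#' @param genome A [genome_model()].
#' @param params A [population_params()].
#' @param male_pool,female_pool Character vectors of individual ids
#'   making up each pool; defaults are all phenotypic males and all
#'   phenotypic females. Passing a marker-purified subset of males
#'   mirrors the Y-carrier purification step of the workflow.
#' @return A list with `sync`, a tibble of `chrom`, `pos`, `ref` and the
#'   twelve count columns `m_A` ... `m_del`, `f_A` ... `f_del`, and
#'   `site_truth`, a tibble of `chrom`, `pos`, `class`
#'   ("y_divergent"/"background") and the latent allele frequencies.
#' @export
simulate_sync <- function(truth, genome = genome_model(),
                          params = population_params(),
                          male_pool = NULL, female_pool = NULL) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "population_params"))
  if (nrow(genome$linkage_groups) == 0) abort("Empty genome.")
  male_pool <- male_pool %||% truth$id[truth$phenotype == "male"]
  female_pool <- female_pool %||% truth$id[truth$phenotype == "female"]
  if (length(male_pool) == 0 || length(female_pool) == 0) {
    abort("Both pools need at least one individual.")
  }
  if (!all(c(male_pool, female_pool) %in% truth$id)) {
    abort("Pool ids must be present in `truth`.")
  }
  geno <- setNames(truth$genotype, truth$id)
  f_y_male <- sum(geno[male_pool] == "XY") / (2 * length(male_pool))
  f_y_female <- sum(geno[female_pool] == "XY") / (2 * length(female_pool))

  with_seed_if(params$seed, {
    lgs <- genome$linkage_groups
    sdr <- genome$sdr
    sites <- map(seq_len(nrow(lgs)), function(i) {
      len <- lgs$length[i]
      n_bg <- rpois(1, len * genome$background_snp_rate)
      pos_bg <- sample.int(len, min(n_bg, len))
      out <- tibble(chrom = lgs$lg[i], pos = pos_bg, class = "background")
      if (lgs$lg[i] == sdr$lg) {
        span <- sdr$end - sdr$start + 1
        n_y <- rpois(1, span * genome$y_divergent_rate)
        pos_y <- sdr$start - 1 + sample.int(span, min(n_y, span))
        out <- bind_rows(
          out[!(out$pos %in% pos_y), ],
          tibble(chrom = lgs$lg[i], pos = pos_y, class = "y_divergent")
        )
      }
      arrange(out, .data$pos)
    }) |> list_rbind()

    n <- nrow(sites)
    bases <- c("A", "T", "C", "G")
    ref_i <- sample.int(4, n, replace = TRUE)
    alt_i <- ((ref_i - 1 + sample.int(3, n, replace = TRUE)) %% 4) + 1
    shared_f <- runif(n, 0.1, 0.9)
    is_y <- sites$class == "y_divergent"
    f_m <- if_else(is_y, f_y_male, shared_f)   # variant-allele freq, male pool
    f_f <- if_else(is_y, f_y_female, shared_f) # female pool

    dm <- rpois(n, params$pool_depth)
    df <- rpois(n, params$pool_depth)
    alt_m <- rbinom(n, dm, f_m)
    alt_f <- rbinom(n, df, f_f)

    mk_counts <- function(depth, alt, prefix) {
      m <- matrix(0L, n, 6,
                  dimnames = list(NULL, paste0(prefix, c(bases, "N", "del"))))
      m[cbind(seq_len(n), ref_i)] <- as.integer(depth - alt)
      m[cbind(seq_len(n), alt_i)] <- m[cbind(seq_len(n), alt_i)] + as.integer(alt)
      as_tibble(m)
    }
    sync <- bind_cols(
      tibble(chrom = sites$chrom, pos = sites$pos, ref = bases[ref_i]),
      mk_counts(dm, alt_m, "m_"),
      mk_counts(df, alt_f, "f_")
    )
    site_truth <- tibble(
      chrom = sites$chrom, pos = sites$pos, class = sites$class,
      ref = bases[ref_i], alt = bases[alt_i],
      true_freq_male = f_m, true_freq_female = f_f
    )
    ord <- order(match(sync$chrom, lgs$lg), sync$pos)
    list(sync = sync[ord, ], site_truth = site_truth[ord, ])
  })
}

#' Simulate a cross between an XX dam and an XX or XY sire
#'
#' Offspring genotypes follow Mendelian segregation (an XY sire
#' transmits Y to half the offspring; an XX sire only X). Phenotype is
#' male for XY offspring; XX offspring become phenotypic males with
#' probability `neomale_rate` (environmental sex reversal). With
#' probability `undiff_rate` the gonad is scored undifferentiated,
#' overriding the phenotype label. Each Y-marker call equals the
#' genotype, flipped with probability `discordance`.
#'
#' @param sire_genotype "XY" or "XX".
#' @param params A [population_params()].
#' @param n_offspring Cohort size.
#' @param n_primers Number of Y-allele marker assays scored per
#'   offspring.
#' @param cross_id Label stored in the `cross` column.
#' @param dam_genotype Must be "XX"; other dams are not modelled.
#' @return A list with `records` (tibble: `id`, `cross`, `phenotype`,
#'   one `primer_*` column per assay with values "positive"/"negative")
#'   and `truth` (tibble: `id`, `genotype`).
#' @examples
#' cr <- simulate_cross("XX", population_params(neomale_rate = 0.078, seed = 1),
#'                      n_offspring = 90)
#' table(cr$records$phenotype)
#' @export
simulate_cross <- function(sire_genotype = c("XY", "XX"),
                           params = population_params(),
                           n_offspring = 100, n_primers = 3,
                           cross_id = NULL, dam_genotype = "XX") {
  sire_genotype <- match.arg(sire_genotype)
  stopifnot(inherits(params, "population_params"))
  if (!identical(dam_genotype, "XX")) {
    abort("Only XX dams are supported.")
  }
  n_offspring <- check_count(n_offspring, "n_offspring", min = 1)
  n_primers <- check_count(n_primers, "n_primers", min = 1)
  cross_id <- cross_id %||% paste0("P(", sire_genotype, ")")
  with_seed_if(params$seed, {
    genotype <- if (sire_genotype == "XY") {
      if_else(runif(n_offspring) < 0.5, "XY", "XX")
    } else {
      rep("XX", n_offspring)
    }
    phenotype <- if_else(
      genotype == "XY", "male",
      if_else(runif(n_offspring) < params$neomale_rate, "male", "female")
    )
    phenotype[runif(n_offspring) < params$undiff_rate] <- "undifferentiated"
    calls <- matrix(
      xor(rep(genotype == "XY", n_primers),
          runif(n_offspring * n_primers) < params$discordance),
      n_offspring, n_primers
    )
    records <- bind_cols(
      tibble(
        id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", cross_id),
                     seq_len(n_offspring)),
        cross = cross_id,
        phenotype = phenotype
      ),
      as_tibble(matrix(ifelse(calls, "positive", "negative"),
                       n_offspring, n_primers,
                       dimnames = list(NULL, paste0("primer_", seq_len(n_primers)))))
    )
    list(records = records, truth = tibble(id = records$id, genotype = genotype))
  })
}
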