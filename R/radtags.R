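#' Threshold a tag depth matrix into presence/absence
#'
#' A tag counts as present in an individual when its depth reaches
#' `min_depth`; the default (1, any read) matches the default behaviour
#' of individual-based RAD sex-marker software.
#'
#' @param tags Tag matrix tibble: `tag_id`, optional `sequence`, one
#'   depth column per individual.
#' @param min_depth Minimum depth for presence; must be >= 1.
#' @return A tibble with `tag_id` and one logical column per individual.
#' @export
build_presence <- function(tags, min_depth = 1) {
  if (min_depth < 1) abort("`min_depth` must be >= 1.")
  cols <- individual_cols(tags)
  if (length(cols) == 0) abort("Tag matrix has no individual columns.")
  bind_cols(
    tags["tag_id"],
    as_tibble(as.matrix(tags[cols]) >= min_depth)
  )
}

# split presence columns into male and female ids, checking labels
split_by_sex <- function(presence, sexes) {
  ids <- individual_cols(presence)
  hit <- match(ids, sexes$id)
  if (anyNA(hit)) {
    abort(sprintf("Individual '%s' has no sex label.", ids[which(is.na(hit))[1]]))
  }
  phen <- sexes$phenotype[hit]
  list(males = ids[phen == "male"], females = ids[phen == "female"])
}

# per-tag carrier counts among males (x) and females (y)
carrier_counts <- function(presence, sexes) {
  sx <- split_by_sex(presence, sexes)
  pm <- as.matrix(presence[sx$males])
  pf <- as.matrix(presence[sx$females])
  tibble(
    tag_id = presence$tag_id,
    n_males = as.integer(rowSums(pm)),
    n_females = as.integer(rowSums(pf)),
    total_males = length(sx$males),
    total_females = length(sx$females)
  )
}

#' Tag distribution grid over male and female carrier counts
#'
#' Counts, for every pair (x, y), the number of distinct tags present in
#' exactly x males and y females -- the heatmap used to spot sex-linked
#' tags: Y-linked tags accumulate in cells with many male and zero
#' female carriers. Tags carried by nobody are not counted, so the grid
#' total equals the number of tags with at least one carrier.
#'
#' @param presence Presence table from [build_presence()].
#' @param sexes Sex registry tibble (`id`, `phenotype`).
#' @return A `tag_distribution` tibble with columns `n_males`,
#'   `n_females`, `n_tags` covering the full (0..total males) x
#'   (0..total females) grid; attributes `total_males`/`total_females`
#'   hold the cohort sizes.
#' @export
tag_distribution <- function(presence, sexes) {
  if (nrow(presence) == 0) abort("Presence table is empty.")
  cc <- carrier_counts(presence, sexes)
  grid <- cc |>
    filter(.data$n_males + .data$n_females > 0) |>
    count(.data$n_males, .data$n_females, name = "n_tags") |>
    complete(
      n_males = 0:cc$total_males[1],
      n_females = 0:cc$total_females[1],
      fill = list(n_tags = 0L)
    )
  structure(grid,
            class = c("tag_distribution", class(grid)),
            total_males = cc$total_males[1],
            total_females = cc$total_females[1])
}

#' Chi-square test for sex-biased tag presence
#'
#' Pearson chi-square p-value (1 df, no continuity correction) for the
#' 2x2 table of carrier/non-carrier counts in males and females,
#' vectorised over tags. Degenerate tables -- no carriers, all carriers,
#' or an empty sex -- return p = 1.
#'
#' @param x_males,y_females Carrier counts per tag.
#' @param n_males,n_females Cohort sizes.
#' @return Numeric vector of p-values.
#' @examples
#' sex_bias_test(15, 0, 30, 30) # chi-square statistic 20
#' @export
sex_bias_test <- function(x_males, y_females, n_males, n_females) {
  if (any(x_males < 0) || any(y_females < 0)) abort("Counts must be >= 0.")
  if (any(x_males > n_males) || any(y_females > n_females)) {
    abort("Carrier counts cannot exceed cohort sizes.")
  }
  a <- x_males; b <- n_males - x_males
  c_ <- y_females; d <- n_females - y_females
  nn <- n_males + n_females
  stat <- nn * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[!is.finite(stat)] <- 1
  p
}

#' Tags significantly associated with sex
#'
#' Runs the sex-bias chi-square test on every tag and applies a
#' Bonferroni correction over the number of distinct carried tags (tags
#' with at least one carrier); uncarried tags are dropped.
#'
#' @param presence Presence table from [build_presence()].
#' @param sexes Sex registry tibble (`id`, `phenotype`).
#' @param params A [rad_params()] object (uses `alpha`).
#' @return A tibble of carried tags: `tag_id`, `n_males`, `n_females`,
#'   `p_value`, `p_adjusted`, `significant`, ordered by `p_value`.
#' @export
significant_tags <- function(presence, sexes, params = rad_params()) {
  stopifnot(inherits(params, "rad_params"))
  cc <- carrier_counts(presence, sexes) |>
    filter(.data$n_males + .data$n_females > 0)
  p <- sex_bias_test(cc$n_males, cc$n_females,
                     cc$total_males, cc$total_females)
  cc |>
    mutate(
      p_value = p,
      p_adjusted = stats::p.adjust(p, method = params$correction),
      significant = .data$p_adjusted < params$alpha
    ) |>
    select(-"total_males", -"total_females") |>
    arrange(.data$p_value, .data$tag_id)
}

#' Extract male-specific marker tags
#'
#' Tags present in at least `min_males` males and at most `max_females`
#' females -- with the defaults, present in 12 or more of the phenotypic
#' males and completely absent from all females, the operational
#' definition of a Y-linked marker in a population where roughly half
#' the phenotypic males are sex-reversed XX neomales.
#'
#' @inheritParams significant_tags
#' @param params A [rad_params()] (uses `min_males`, `max_females`).
#' @return Tibble `tag_id`, `n_males`, `n_females`, sorted by `tag_id`.
#' @export
male_specific_tags <- function(presence, sexes, params = rad_params()) {
  stopifnot(inherits(params, "rad_params"))
  carrier_counts(presence, sexes) |>
    filter(.data$n_males >= params$min_males,
           .data$n_females <= params$max_females) |>
    select("tag_id", "n_males", "n_females") |>
    arrange(.data$tag_id)
}

#' Classify individuals as Y-carriers from male-specific tags
#'
#' Scores every individual by the fraction of male-specific marker tags
#' it carries and calls it a Y-carrier when that fraction reaches
#' `min_carry_fraction` (default 0.5, tolerant of tag dropout while
#' rejecting sporadic false presence). Among phenotypic males this
#' separates XY genetic males from XX neomales; [glance()] on the result
#' returns the neomale summary.
#'
#' @inheritParams significant_tags
#' @param male_tags Character vector of tag ids, or the tibble returned
#'   by [male_specific_tags()]; must be nonempty.
#' @param min_carry_fraction Carried fraction required for a Y-carrier
#'   call.
#' @return An `sdr_ind_calls` tibble: `id`, `phenotype`, `n_carried`,
#'   `carry_fraction`, `call` ("Y-carrier"/"non-carrier").
#' @export
classify_individuals <- function(presence, sexes, male_tags,
                                 min_carry_fraction = 0.5) {
  if (is.data.frame(male_tags)) male_tags <- male_tags$tag_id
  if (length(male_tags) == 0) abort("`male_tags` must be nonempty.")
  check_prob(min_carry_fraction, "min_carry_fraction")
  rows <- match(male_tags, presence$tag_id)
  if (anyNA(rows)) abort("Some `male_tags` are missing from the presence table.")
  ids <- individual_cols(presence)
  sub <- as.matrix(presence[rows, ids, drop = FALSE])
  n_carried <- as.integer(colSums(sub))
  frac <- n_carried / length(male_tags)
  out <- tibble(
    id = ids,
    phenotype = sexes$phenotype[match(ids, sexes$id)],
    n_carried = n_carried,
    carry_fraction = frac,
    call = if_else(frac >= min_carry_fraction, "Y-carrier", "non-carrier")
  )
  structure(out,
            class = c("sdr_ind_calls", class(out)),
            n_male_tags = length(male_tags),
            min_carry_fraction = min_carry_fraction)
}

#' @method glance sdr_ind_calls
#' @export
glance.sdr_ind_calls <- function(x, ...) {
  males <- x[x$phenotype == "male", ]
  if (nrow(males) == 0) abort("No phenotypic males to summarise.")
  carriers <- sum(males$call == "Y-carrier")
  tibble(
    n_pheno_males = nrow(males),
    n_y_carrier_males = carriers,
    neomale_fraction = 1 - carriers / nrow(males)
  )
}
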