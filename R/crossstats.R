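#' Summarise a cross by phenotype and marker calls
#'
#' Per-cross counts of phenotypic males, females and undifferentiated
#' offspring, with the derived statistics used to characterise a cross:
#' the female:male ratio (one decimal, truncated toward zero, so 83:7
#' prints 11.8 and 65:48 prints 1.3) and the percentage of males among
#' sexed offspring (one decimal, half-up). Marker-positive counts per
#' phenotype class and primer are nested in the `markers` list column.
#'
#' @param records Cross table: `id`, optional `cross`, `phenotype`
#'   ("male"/"female"/"undifferentiated"), and zero or more `primer_*`
#'   columns with "positive"/"negative" calls.
#' @return One row per cross: `cross`, `n_male`, `n_female`, `n_undiff`,
#'   `n_total`, `fm_ratio` (NA when there are no males), `pct_males`,
#'   `markers` (nested tibble: `primer`, `phenotype`, `n_positive`,
#'   `n_total`).
#' @examples
#' x <- tibble::tibble(
#'   cross = "P(XX)",
#'   phenotype = rep(c("male", "female", "undifferentiated"), c(7, 83, 41))
#' )
#' summarize_cross(x)[, c("fm_ratio", "pct_males")]
#' @export
summarize_cross <- function(records) {
  if (nrow(records) == 0) abort("Cross table is empty.")
  if (!"cross" %in% names(records)) records$cross <- "cross"
  primers <- grep("^primer", names(records), value = TRUE)
  records |>
    group_by(.data$cross) |>
    summarise(
      n_male = sum(.data$phenotype == "male"),
      n_female = sum(.data$phenotype == "female"),
      n_undiff = sum(.data$phenotype == "undifferentiated"),
      n_total = n(),
      fm_ratio = if_else(.data$n_male > 0,
                         trunc_dec(.data$n_female / .data$n_male, 1),
                         NA_real_),
      pct_males = if_else(.data$n_male + .data$n_female > 0,
                          round_half_up(100 * .data$n_male /
                                          (.data$n_male + .data$n_female), 1),
                          NA_real_),
      markers = list({
        df <- pick(all_of(c("phenotype", primers)))
        if (length(primers) == 0) {
          tibble(primer = character(), phenotype = character(),
                 n_positive = integer(), n_total = integer())
        } else {
          df |>
            pivot_longer(all_of(primers), names_to = "primer",
                         values_to = "call") |>
            group_by(.data$primer, .data$phenotype) |>
            summarise(n_positive = sum(.data$call == "positive"),
                      n_total = n(), .groups = "drop")
        }
      }),
      .groups = "drop"
    )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing all hypergeometric
#' probabilities not exceeding that of the observed table (the
#' definition used by R's standard implementation, including its
#' `1 + 1e-7` tie tolerance). Implemented directly on the
#' hypergeometric mass so that very large batches of tables are cheap.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)) # 2/choose(10,5)
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("`tab` must be 2x2.")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Table entries must be non-negative integers.")
  }
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[1, 2] # row 1 total
  n <- tab[2, 1] + tab[2, 2] # row 2 total
  k <- tab[1, 1] + tab[2, 1] # column 1 total
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  min(1, max(p, .Machine$double.xmin))
}

#' Sex-linkage test of a marker against phenotypic sex
#'
#' Fisher's exact test on the 2x2 table of phenotype (male/female) by
#' marker call (positive/negative); undifferentiated offspring are
#' excluded from the table and reported separately. The marker is
#' declared linked when p < 0.05, otherwise "NS".
#'
#' @param records Cross table (see [summarize_cross()]).
#' @param primer Name of the marker column to test.
#' @param alpha Significance level for the linked/NS call.
#' @return A `sex_linkage` object; use [tidy()] or [glance()] for a
#'   tibble view.
#' @examples
#' pxy <- tibble::tibble(
#'   phenotype = rep(c("male", "female"), c(48, 65)),
#'   primer_1 = rep(c("positive", "positive", "negative"), c(48, 1, 64))
#' )
#' glance(sex_linkage_test(pxy, "primer_1"))
#' @export
sex_linkage_test <- function(records, primer, alpha = 0.05) {
  if (!primer %in% names(records)) {
    abort(sprintf("Column '%s' not found.", primer))
  }
  sexed <- records[records$phenotype %in% c("male", "female"), ]
  if (nrow(sexed) == 0) abort("No differentiated offspring to test.")
  pos <- sexed[[primer]] == "positive"
  tab <- matrix(
    c(sum(sexed$phenotype == "male" & pos),
      sum(sexed$phenotype == "male" & !pos),
      sum(sexed$phenotype == "female" & pos),
      sum(sexed$phenotype == "female" & !pos)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("male", "female"), c("positive", "negative"))
  )
  p <- fisher_exact_2x2(tab)
  structure(
    list(
      primer = primer, table = tab, p_value = p,
      linkage = if (p < alpha) "linked" else "NS",
      alpha = alpha,
      n_excluded = nrow(records) - nrow(sexed)
    ),
    class = "sex_linkage"
  )
}

#' @export
print.sex_linkage <- function(x, ...) {
  cat(sprintf("Sex linkage of %s: %s (Fisher exact p = %.3g)\n",
              x$primer, x$linkage, x$p_value))
  print(x$table)
  invisible(x)
}

#' @method tidy sex_linkage
#' @export
tidy.sex_linkage <- function(x, ...) {
  tibble(
    primer = x$primer,
    males_positive = x$table["male", "positive"],
    males_total = sum(x$table["male", ]),
    females_positive = x$table["female", "positive"],
    females_total = sum(x$table["female", ]),
    p.value = x$p_value,
    linkage = x$linkage
  )
}

#' @method glance sex_linkage
#' @export
glance.sex_linkage <- function(x, ...) {
  tibble(p.value = x$p_value, linkage = x$linkage,
         n_tested = sum(x$table), n_excluded = x$n_excluded)
}

#' Chi-square test of a sex ratio against 1:1
#'
#' One-degree-of-freedom goodness-of-fit test of observed male/female
#' counts against equal proportions, without continuity correction.
#'
#' @param n_males,n_females Observed counts; their sum must be positive.
#' @return One-row tibble: `n_males`, `n_females`, `statistic`, `df`,
#'   `p.value`.
#' @examples
#' sex_ratio_test(48, 65) # chi-square about 2.56, not significant
#' @export
sex_ratio_test <- function(n_males, n_females) {
  if (n_males + n_females <= 0) abort("Need at least one sexed offspring.")
  ht <- chisq.test(c(n_males, n_females), p = c(0.5, 0.5), correct = FALSE)
  tibble(
    n_males = n_males, n_females = n_females,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = ht$p.value
  )
}

#' Estimate the female-to-male sex-reversal rate of an XX-sired cross
#'
#' In a cross between an XX neomale sire and an XX dam every offspring
#' is genetically female, so phenotypic males measure environmental
#' sex reversal directly: the rate is males / (males + females) with an
#' exact Clopper-Pearson 95% confidence interval; undifferentiated
#' offspring are excluded.
#'
#' @param records Cross table (see [summarize_cross()]).
#' @param conf_level Confidence level of the interval.
#' @return One-row tibble: `n_males`, `n_females`, `rate`, `pct`
#'   (half-up, one decimal), `conf.low`, `conf.high`.
#' @examples
#' x <- tibble::tibble(phenotype = rep(c("male", "female"), c(7, 83)))
#' estimate_sex_reversal(x)
#' @export
estimate_sex_reversal <- function(records, conf_level = 0.95) {
  m <- sum(records$phenotype == "male")
  f <- sum(records$phenotype == "female")
  if (m + f == 0) abort("No sexed offspring.")
  bt <- binom.test(m, m + f, conf.level = conf_level)
  tibble(
    n_males = m, n_females = f,
    rate = m / (m + f),
    pct = round_half_up(100 * m / (m + f), 1),
    conf.low = bt$conf.int[1],
    conf.high = bt$conf.int[2]
  )
}
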