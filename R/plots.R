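#' Heatmap of the tag distribution grid
#'
#' Tiles the (males carried, females carried) grid with a log10 colour
#' scale, the standard view for spotting Y-linked tags: they cluster at
#' high male counts and zero female counts, away from the diagonal mass
#' of shared tags.
#'
#' @param object A `tag_distribution` from [tag_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tag_distribution
#' @export
autoplot.tag_distribution <- function(object, ...) {
  d <- as_tibble(object) |> mutate(n = if_else(.data$n_tags > 0,
                                               log10(.data$n_tags), NA_real_))
  ggplot(d, aes(x = .data$n_males, y = .data$n_females, fill = .data$n)) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10(tags)", na.value = "grey95") +
    labs(x = "Number of carrier males", y = "Number of carrier females",
         title = "Tag sharing between phenotypic males and females") +
    theme_minimal()
}

#' Genome tracks of the window scan
#'
#' Plots, per chromosome, the male- and female-specific SNP counts and
#' the normalised log2 depth ratio along the genome; SDR calls, when
#' supplied, are shaded.
#'
#' @param object A `window_scan` from [window_scan()].
#' @param sdr Optional `sdr_calls` tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, sdr = NULL, ...) {
  d <- as_tibble(object) |>
    select("chrom", "pos", "male_snp", "female_snp", "log2_ratio") |>
    pivot_longer(c("male_snp", "female_snp", "log2_ratio"),
                 names_to = "track", values_to = "value") |>
    mutate(track = factor(.data$track,
                          levels = c("male_snp", "female_snp", "log2_ratio")))
  p <- ggplot(d, aes(x = .data$pos / 1e6, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_grid(vars(.data$track), vars(.data$chrom), scales = "free") +
    labs(x = "Position (Mb)", y = NULL,
         title = "Two-pool window scan") +
    theme_minimal()
  if (!is.null(sdr) && nrow(sdr) > 0) {
    p <- p + geom_rect(
      data = as_tibble(sdr) |> select("chrom", "start", "end"),
      aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p
}

#' Carrier-fraction plot of individual Y-carrier calls
#'
#' Shows, for every individual, the fraction of male-specific marker
#' tags carried, split by phenotype; phenotypic males separate into an
#' XY carrier group near 1 and an XX neomale group near 0.
#'
#' @param object An `sdr_ind_calls` from [classify_individuals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdr_ind_calls
#' @export
autoplot.sdr_ind_calls <- function(object, ...) {
  d <- as_tibble(object) |> arrange(.data$phenotype, desc(.data$carry_fraction))
  d$id <- factor(d$id, levels = d$id)
  ggplot(d, aes(x = .data$id, y = .data$carry_fraction, fill = .data$call)) +
    geom_col() +
    geom_hline(yintercept = attr(object, "min_carry_fraction"),
               linetype = "dashed") +
    facet_grid(cols = vars(.data$phenotype), scales = "free_x",
               space = "free_x") +
    labs(x = NULL, y = "Fraction of male-specific tags carried") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
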