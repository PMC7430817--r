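#' Classify sync sites as male- or female-specific SNPs
#'
#' Applies the pooled-scan site criteria to every record of a two-pool
#' sync table. Per-pool depth is the sum of the four nucleotide counts
#' (N and deletion columns are ignored); a site with depth below
#' `min_depth` in either pool is `low_depth`. A site is `male_specific`
#' when the male pool is heterozygous -- exactly two alleles, each with
#' frequency inside `freq_het` +/- `range_het`, any further allele below
#' `1 - freq_het - range_het` -- while the female pool's major allele
#' has frequency at least `freq_hom - range_hom` and differs from at
#' least one of the male pool's two band alleles. `female_specific` is
#' the mirror image; everything else is `none`.
#'
#' @param sync Sync tibble from [read_sync()] or [simulate_sync()].
#' @param params A [poolscan_params()] object.
#' @return The input with added columns `depth_m`, `depth_f` and `class`
#'   (factor: `male_specific`, `female_specific`, `none`, `low_depth`).
#' @examples
#' rec <- tibble::tibble(chrom = "LG22", pos = 100L, ref = "A",
#'   m_A = 12L, m_T = 13L, m_C = 0L, m_G = 0L, m_N = 0L, m_del = 0L,
#'   f_A = 30L, f_T = 0L, f_C = 0L, f_G = 0L, f_N = 0L, f_del = 0L)
#' classify_sites(rec)$class
#' @export
classify_sites <- function(sync, params = poolscan_params()) {
  stopifnot(inherits(params, "poolscan_params"))
  nuc <- c("A", "T", "C", "G")
  M <- as.matrix(sync[paste0("m_", nuc)])
  F_ <- as.matrix(sync[paste0("f_", nuc)])
  if (any(M < 0) || any(F_ < 0)) abort("Counts must be >= 0.")
  dm <- rowSums(M)
  df <- rowSums(F_)
  eps <- 1e-9
  lo <- params$freq_het - params$range_het - eps
  hi <- params$freq_het + params$range_het + eps
  third_max <- 1 - params$freq_het - params$range_het + eps
  hom_thr <- params$freq_hom - params$range_hom - eps

  pool_state <- function(cnt, depth) {
    fr <- cnt / ifelse(depth > 0, depth, NA_real_)
    in_band <- !is.na(fr) & fr >= lo & fr <= hi
    out_freq <- ifelse(in_band, 0, fr)
    het <- rowSums(in_band) == 2 &
      pmax(out_freq[, 1], out_freq[, 2], out_freq[, 3], out_freq[, 4],
           na.rm = TRUE) <= third_max
    major <- max.col(cnt, ties.method = "first")
    hom <- !is.na(fr[cbind(seq_len(nrow(cnt)), major)]) &
      fr[cbind(seq_len(nrow(cnt)), major)] >= hom_thr
    list(in_band = in_band, het = het, major = major, hom = hom)
  }
  sm <- pool_state(M, dm)
  sf <- pool_state(F_, df)
  n <- nrow(sync)
  idx <- seq_len(n)
  # at least one band allele of the het pool differs from the other
  # pool's major allele
  diff_m <- rowSums(sm$in_band) - sm$in_band[cbind(idx, sf$major)] >= 1
  diff_f <- rowSums(sf$in_band) - sf$in_band[cbind(idx, sm$major)] >= 1

  low <- dm < params$min_depth | df < params$min_depth
  male_spec <- !low & sm$het & sf$hom & diff_m
  female_spec <- !low & sf$het & sm$hom & diff_f
  cls <- rep("none", n)
  cls[male_spec] <- "male_specific"
  cls[female_spec] <- "female_specific"
  cls[low] <- "low_depth"
  sync |>
    mutate(
      depth_m = as.integer(dm),
      depth_f = as.integer(df),
      class = factor(cls, levels = c("male_specific", "female_specific",
                                     "none", "low_depth"))
    )
}

#' Normalised log2 depth ratio between pools
#'
#' `log2(((depth_m + c) / lib_m) / ((depth_f + c) / lib_f))` with
#' pseudocount `c = 1`; equal normalised depths give 0, a doubled male
#' depth gives about +1.
#'
#' @param depth_m,depth_f Mean window depths per pool.
#' @param lib_m,lib_f Library sizes (total depth per pool); must be > 0.
#' @param pseudocount Added to both depths before the ratio.
#' @return Numeric vector of log2 ratios.
#' @examples
#' depth_ratio(9, 4) # log2(10/5) = 1
#' @export
depth_ratio <- function(depth_m, depth_f, lib_m = 1, lib_f = 1,
                        pseudocount = 1) {
  if (any(lib_m <= 0) || any(lib_f <= 0)) abort("Library sizes must be > 0.")
  log2(((depth_m + pseudocount) / lib_m) / ((depth_f + pseudocount) / lib_f))
}

#' Sliding-window scan of classified sites
#'
#' Produces one output point every `output_resolution` bp along each
#' chromosome; at each point a window of `window_size` bp centred on the
#' point (closed interval, clipped at the chromosome ends) is summarised:
#' counts of male- and female-specific SNPs, mean per-pool depths over
#' all sync sites in the window, and the normalised log2 depth ratio.
#'
#' @param sites Classified site tibble from [classify_sites()], sorted
#'   by chromosome and position.
#' @param params A [poolscan_params()].
#' @param chrom_lengths Tibble with `chrom` and `length` (bp); every
#'   chromosome listed gets output points, with or without sites.
#' @return A `window_scan` tibble: `chrom`, `pos`, `male_snp`,
#'   `female_snp`, `depth_m`, `depth_f`, `log2_ratio`.
#' @export
window_scan <- function(sites, params = poolscan_params(), chrom_lengths) {
  stopifnot(inherits(params, "poolscan_params"))
  if (!all(c("chrom", "length") %in% names(chrom_lengths))) {
    abort("`chrom_lengths` needs `chrom` and `length` columns.")
  }
  unknown <- setdiff(unique(sites$chrom), chrom_lengths$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("Sites on undeclared chromosome '%s'.", unknown[1]))
  }
  too_far <- sites$pos > chrom_lengths$length[match(sites$chrom,
                                                    chrom_lengths$chrom)]
  if (any(too_far)) {
    abort(sprintf("Site at %s:%d lies beyond the declared chromosome length.",
                  sites$chrom[which(too_far)[1]], sites$pos[which(too_far)[1]]))
  }
  half <- floor(params$window_size / 2)
  res <- params$output_resolution
  lib_m <- max(sum(as.numeric(sites$depth_m)), 1)
  lib_f <- max(sum(as.numeric(sites$depth_f)), 1)

  per_chrom <- function(chrom, len) {
    s <- sites[sites$chrom == chrom, ]
    s <- s[order(s$pos), ]
    pts <- seq(res, len, by = res)
    lo <- pmax(1, pts - half)
    hi <- pmin(len, pts + half)
    count_in <- function(p) {
      findInterval(hi, p) - findInterval(lo - 1, p)
    }
    pos_all <- s$pos
    n_in <- count_in(pos_all)
    cum_m <- c(0, cumsum(as.numeric(s$depth_m)))
    cum_f <- c(0, cumsum(as.numeric(s$depth_f)))
    ih <- findInterval(hi, pos_all) + 1
    il <- findInterval(lo - 1, pos_all) + 1
    sum_m <- cum_m[ih] - cum_m[il]
    sum_f <- cum_f[ih] - cum_f[il]
    mean_m <- ifelse(n_in > 0, sum_m / n_in, 0)
    mean_f <- ifelse(n_in > 0, sum_f / n_in, 0)
    tibble(
      chrom = chrom,
      pos = as.integer(pts),
      male_snp = count_in(pos_all[s$class == "male_specific"]),
      female_snp = count_in(pos_all[s$class == "female_specific"]),
      depth_m = mean_m,
      depth_f = mean_f,
      log2_ratio = depth_ratio(mean_m, mean_f, lib_m, lib_f)
    )
  }
  out <- map2(chrom_lengths$chrom, chrom_lengths$length, per_chrom) |>
    list_rbind()
  structure(out,
            class = c("window_scan", class(out)),
            params = params, chrom_lengths = chrom_lengths,
            lib_m = lib_m, lib_f = lib_f)
}

#' Call contiguous sex-determining regions from a window scan
#'
#' Flags windows whose male-specific SNP count exceeds the genome-wide
#' mean by more than `z_threshold` standard deviations, merges flagged
#' windows on the same chromosome separated by at most `merge_gap` bp,
#' and reports merged spans of at least `min_span` bp with their window
#' count and mean/peak male-specific densities. Deterministic; an
#' all-zero genome yields an empty call set.
#'
#' @param windows A `window_scan` tibble.
#' @param policy An [sdr_policy()] object.
#' @return An `sdr_calls` tibble: `chrom`, `start`, `end` (1-based
#'   closed), `n_windows`, `mean_density`, `peak_density`; attributes
#'   `threshold`, `genome_mean`, `genome_sd` record the flagging rule.
#' @export
call_sdr <- function(windows, policy = sdr_policy()) {
  stopifnot(inherits(policy, "sdr_policy"))
  if (nrow(windows) == 0) abort("Need at least one window.")
  x <- windows$male_snp
  mu <- mean(x)
  s <- sd(x)
  if (is.na(s)) s <- 0
  thr <- mu + policy$z_threshold * s
  flagged <- windows[x > thr, c("chrom", "pos", "male_snp")]
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), mean_density = double(),
                  peak_density = double())
  calls <- if (nrow(flagged) == 0) empty else {
    flagged |>
      arrange(.data$chrom, .data$pos) |>
      group_by(.data$chrom) |>
      mutate(block = cumsum(c(1, diff(.data$pos) > policy$merge_gap))) |>
      group_by(.data$chrom, .data$block) |>
      summarise(
        start = as.integer(min(.data$pos)),
        end = as.integer(max(.data$pos)),
        n_windows = n(),
        mean_density = mean(.data$male_snp),
        peak_density = max(.data$male_snp),
        .groups = "drop"
      ) |>
      filter(.data$end - .data$start + 1 >= policy$min_span) |>
      select(-"block") |>
      arrange(.data$chrom, .data$start)
  }
  structure(calls,
            class = c("sdr_calls", class(empty)),
            threshold = thr, genome_mean = mu, genome_sd = s,
            policy = policy)
}

#' @method glance sdr_calls
#' @export
glance.sdr_calls <- function(x, ...) {
  tibble(
    n_calls = nrow(x),
    total_span = if (nrow(x)) sum(x$end - x$start + 1) else 0,
    threshold = attr(x, "threshold"),
    genome_mean = attr(x, "genome_mean"),
    genome_sd = attr(x, "genome_sd")
  )
}

#' Write a JSON summary of SDR calls
#'
#' @param calls An `sdr_calls` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sdr_summary <- function(calls, path) {
  jsonlite::write_json(
    list(
      threshold = attr(calls, "threshold"),
      genome_mean = attr(calls, "genome_mean"),
      genome_sd = attr(calls, "genome_sd"),
      calls = as.data.frame(calls)
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
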