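test_that("sync parsing is lossless and strict", {
  f <- withr::local_tempfile()
  writeLines(c("LG22\t100\tA\t12:13:0:0:0:0\t30:0:0:0:0:0",
               "LG22\t250\tC\t0:0:20:5:1:0\t0:0:25:0:0:1"), f)
  s <- read_sync(f)
  expect_equal(nrow(s), 2)
  expect_equal(s$pos, c(100L, 250L))
  expect_equal(s$m_A[1], 12L)
  expect_equal(s$m_T[1], 13L)
  expect_equal(s$f_A[1], 30L)
  expect_equal(s$f_del[2], 1L)

  # round trip through the writer
  f2 <- withr::local_tempfile()
  write_sync(s, f2)
  expect_identical(readLines(f), readLines(f2))

  # empty file -> empty tibble
  f3 <- withr::local_tempfile()
  writeLines(character(0), f3)
  expect_equal(nrow(read_sync(f3)), 0)

  # three pools, malformed sextets, decreasing positions: all refused
  writeLines("LG1\t1\tA\t1:0:0:0:0:0\t1:0:0:0:0:0\t1:0:0:0:0:0", f3)
  expect_error(read_sync(f3), "Line 1.*5 tab-separated")
  writeLines("LG1\t1\tA\t1:0:0:0:0\t1:0:0:0:0:0", f3)
  expect_error(read_sync(f3), "Line 1.*malformed")
  writeLines(c("LG1\t500\tA\t1:0:0:0:0:0\t1:0:0:0:0:0",
               "LG1\t400\tA\t1:0:0:0:0:0\t1:0:0:0:0:0"), f3)
  expect_error(read_sync(f3), "Line 2.*decrease")
})

test_that("site classification applies the published frequency criteria", {
  # male 12A/13T (0.48/0.52 het), female fixed 30A -> male-specific
  r1 <- sync_row(m = c(A = 12, T = 13, C = 0, G = 0, N = 0, del = 0),
                 f = c(A = 30, T = 0, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r1)$class), "male_specific")

  # male depth 9 < 10 -> low_depth regardless of the female pool
  r2 <- sync_row(m = c(A = 4, T = 5, C = 0, G = 0, N = 0, del = 0),
                 f = c(A = 30, T = 0, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r2)$class), "low_depth")

  # both pools fixed -> none
  r3 <- sync_row(m = c(A = 30, T = 0, C = 0, G = 0, N = 0, del = 0),
                 f = c(A = 30, T = 0, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r3)$class), "none")

  # N and del columns do not count toward depth
  r4 <- sync_row(m = c(A = 4, T = 5, C = 0, G = 0, N = 20, del = 0),
                 f = c(A = 30, T = 0, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r4)$class), "low_depth")

  # female pool het, male fixed -> female-specific
  r5 <- sync_row(m = c(A = 30, T = 0, C = 0, G = 0, N = 0, del = 0),
                 f = c(A = 12, T = 13, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r5)$class), "female_specific")

  # female major below 0.98 -> not male-specific
  r6 <- sync_row(m = c(A = 12, T = 13, C = 0, G = 0, N = 0, del = 0),
                 f = c(A = 29, T = 1, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r6)$class), "none")
  # 49/50 = 0.98 passes the boundary
  r7 <- sync_row(m = c(A = 24, T = 26, C = 0, G = 0, N = 0, del = 0),
                 f = c(A = 49, T = 1, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r7)$class), "male_specific")

  # triallelic male pool is disqualified
  r8 <- sync_row(m = c(A = 10, T = 10, C = 10, G = 0, N = 0, del = 0),
                 f = c(A = 30, T = 0, C = 0, G = 0, N = 0, del = 0))
  expect_equal(as.character(classify_sites(r8)$class), "none")
})

test_that("classification is invariant to consistent base relabelling", {
  withr::with_seed(41, {
    truth <- make_truth(15, 0, 30)
    ss <- simulate_sync(truth, small_genome(), population_params(seed = 41))
    base <- classify_sites(ss$sync)$class
    # permute A->C, C->G, G->T, T->A consistently in both pools
    perm <- ss$sync
    for (pool in c("m_", "f_")) {
      old <- perm[paste0(pool, c("A", "T", "C", "G"))]
      perm[paste0(pool, "C")] <- old[[paste0(pool, "A")]]
      perm[paste0(pool, "A")] <- old[[paste0(pool, "T")]]
      perm[paste0(pool, "T")] <- old[[paste0(pool, "G")]]
      perm[paste0(pool, "G")] <- old[[paste0(pool, "C")]]
    }
    expect_identical(classify_sites(perm)$class, base)
  })
})

test_that("swapping the pools mirrors male- and female-specific calls", {
  truth <- make_truth(15, 0, 30)
  ss <- simulate_sync(truth, small_genome(), population_params(seed = 43))
  swapped <- ss$sync
  nuc <- c("A", "T", "C", "G", "N", "del")
  names(swapped)[match(paste0("m_", nuc), names(swapped))] <- paste0("x_", nuc)
  names(swapped)[match(paste0("f_", nuc), names(swapped))] <- paste0("m_", nuc)
  names(swapped)[match(paste0("x_", nuc), names(swapped))] <- paste0("f_", nuc)
  a <- classify_sites(ss$sync)$class
  b <- classify_sites(swapped)$class
  expect_identical(a == "male_specific", b == "female_specific")
  expect_identical(a == "female_specific", b == "male_specific")
  expect_identical(a %in% c("none", "low_depth"), b %in% c("none", "low_depth"))
})

test_that("window counts equal brute-force recounts on random sites", {
  withr::with_seed(47, {
    n <- 2000
    len <- 2e6
    pos <- sort(sample.int(len, n))
    cls <- sample(c("male_specific", "female_specific", "none"), n,
                  replace = TRUE, prob = c(0.3, 0.2, 0.5))
    sites <- tibble::tibble(
      chrom = "LG1", pos = pos, depth_m = 50L, depth_f = 50L,
      class = factor(cls, levels = c("male_specific", "female_specific",
                                     "none", "low_depth"))
    )
    w <- window_scan(sites, poolscan_params(),
                     tibble::tibble(chrom = "LG1", length = len))
    expect_equal(w$male_snp,
                 brute_window_counts(pos, cls == "male_specific", len))
    expect_equal(w$female_snp,
                 brute_window_counts(pos, cls == "female_specific", len))
  })
})

test_that("a clipped window keeps sites by closed-interval membership", {
  sites <- tibble::tibble(
    chrom = "LG1", pos = c(1000L, 50000L), depth_m = 50L, depth_f = 50L,
    class = factor("male_specific", levels = c("male_specific",
                                               "female_specific", "none",
                                               "low_depth"))
  )
  w <- window_scan(sites, poolscan_params(),
                   tibble::tibble(chrom = "LG1", length = 75000))
  # at output point 25,000 the centred 100 kb window clips to [1, 75000]
  expect_equal(w$male_snp[w$pos == 25000], 2)
  # no classified sites at all -> all-zero windows
  w0 <- window_scan(sites[0, ], poolscan_params(),
                    tibble::tibble(chrom = "LG1", length = 75000))
  expect_true(all(w0$male_snp == 0) && all(w0$female_snp == 0))
})

test_that("sites beyond the declared chromosome length are refused", {
  sites <- tibble::tibble(chrom = "LG1", pos = 1000L, depth_m = 50L,
                          depth_f = 50L,
                          class = factor("none", levels = c("male_specific",
                                                            "female_specific",
                                                            "none", "low_depth")))
  expect_error(window_scan(sites, poolscan_params(),
                           tibble::tibble(chrom = "LG1", length = 500)),
               "beyond the declared")
  expect_error(window_scan(sites, poolscan_params(),
                           tibble::tibble(chrom = "LG2", length = 5000)),
               "undeclared")
})

test_that("the depth ratio follows its closed form", {
  expect_equal(depth_ratio(50, 50), 0)
  expect_equal(depth_ratio(9, 4), 1)
  expect_equal(depth_ratio(999, 499), 1, tolerance = 1e-3)
  expect_equal(depth_ratio(10, 10, lib_m = 2, lib_f = 1), -1)
  expect_error(depth_ratio(1, 1, lib_m = 0), "> 0")
})

test_that("detection of planted sites rises with pool depth", {
  truth <- make_truth(15, 0, 30)
  g <- small_genome()
  frac <- vapply(c(12, 25, 50), function(lambda) {
    ss <- simulate_sync(truth, g, population_params(pool_depth = lambda,
                                                    seed = 53))
    cl <- classify_sites(ss$sync)
    y <- ss$site_truth$class == "y_divergent"
    mean(cl$class[y] == "male_specific")
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
  expect_gt(frac[3], 0.95)
})

test_that("50% neomale contamination pushes planted sites out of the het band", {
  g <- small_genome()
  pure <- simulate_sync(make_truth(15, 0, 30), g, population_params(seed = 59))
  mixed <- simulate_sync(make_truth(15, 15, 30), g, population_params(seed = 59))
  frac_of <- function(ss) {
    cl <- classify_sites(ss$sync)
    mean(cl$class[ss$site_truth$class == "y_divergent"] == "male_specific")
  }
  # pure XY pool: Y frequency 0.5, nearly every planted site detected;
  # half-XX pool: Y frequency 0.25, only binomial sampling into the band
  # keeps a minority of sites (P about 0.21 at depth ~50)
  expect_gt(frac_of(pure), 0.95)
  expect_lt(frac_of(mixed), 0.35)
  expect_gt(frac_of(mixed), 0.05)
})

test_that("SDR calling flags, merges and filters deterministically", {
  mk_windows <- function(counts, pos) {
    structure(tibble::tibble(chrom = "LG1", pos = pos, male_snp = counts,
                             female_snp = 0L, depth_m = 50, depth_f = 50,
                             log2_ratio = 0),
              class = c("window_scan", class(tibble::tibble())))
  }
  pos <- seq(500, 40e6, by = 500)
  counts <- integer(length(pos))
  # two dense regions separated by more than the 500 kb merge gap
  counts[pos >= 1e6 & pos <= 2.2e6] <- 50L
  counts[pos >= 4e6 & pos <= 5.2e6] <- 50L
  calls <- call_sdr(mk_windows(counts, pos))
  expect_equal(nrow(calls), 2)
  expect_equal(calls$start, c(1e6, 4e6))
  expect_equal(calls$end, c(2.2e6, 5.2e6))

  # all-zero genome -> no calls
  expect_equal(nrow(call_sdr(mk_windows(integer(length(pos)), pos))), 0)

  # a sub-minimum span is dropped
  counts2 <- integer(length(pos))
  counts2[pos >= 1e6 & pos <= 1.5e6] <- 50L
  expect_equal(nrow(call_sdr(mk_windows(counts2, pos))), 0)

  # two regions within the merge gap fuse into one call
  counts3 <- integer(length(pos))
  counts3[pos >= 1e6 & pos <= 2e6] <- 50L
  counts3[pos >= 2.3e6 & pos <= 3.3e6] <- 50L
  expect_equal(nrow(call_sdr(mk_windows(counts3, pos))), 1)
})

test_that("background-only genomes stay call-free", {
  # no planted region: background sites are shared polymorphisms, which
  # essentially never satisfy het-in-one/fixed-in-other at depth 50
  g <- genome_model(
    linkage_groups = tibble::tibble(lg = c("LG1", "LG2"), length = c(4e6, 4e6)),
    sdr = list(lg = "LG2", start = 1, end = 2),
    y_divergent_rate = 0
  )
  fp <- 0L
  for (s in 1:20) {
    ss <- simulate_sync(make_truth(15, 0, 30), g, population_params(seed = s))
    cl <- classify_sites(ss$sync)
    w <- window_scan(cl, poolscan_params(), chrom_lengths_of(g))
    fp <- fp + (nrow(call_sdr(w)) > 0)
  }
  expect_lte(fp, 1) # at most 1 of 20 seeds may produce a spurious call
})
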