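# shared fixtures and independent oracles, all built in code

# a truth tibble with fixed genotype composition (no randomness)
make_truth <- function(n_xy = 15, n_xx_males = 15, n_females = 30) {
  n_males <- n_xy + n_xx_males
  tibble::tibble(
    id = c(sprintf("M%03d", seq_len(n_males)),
           sprintf("F%03d", seq_len(n_females))),
    phenotype = rep(c("male", "female"), c(n_males, n_females)),
    genotype = c(rep("XY", n_xy), rep("XX", n_xx_males + n_females))
  )
}

registry_of <- function(truth) truth[c("id", "phenotype")]

# presence table built directly from a logical matrix (tags x individuals)
make_presence <- function(mat, ids) {
  tibble::as_tibble(`colnames<-`(mat, ids)) |>
    dplyr::mutate(tag_id = sprintf("tag%03d", dplyr::row_number()),
                  .before = 1)
}

# one sync row from simple allele specs, male pool first
sync_row <- function(chrom = "LG22", pos = 100L, ref = "A",
                     m = c(A = 0, T = 0, C = 0, G = 0, N = 0, del = 0),
                     f = c(A = 0, T = 0, C = 0, G = 0, N = 0, del = 0)) {
  nuc <- c("A", "T", "C", "G", "N", "del")
  tibble::as_tibble(c(
    list(chrom = chrom, pos = as.integer(pos), ref = ref),
    stats::setNames(as.list(as.integer(m[nuc])), paste0("m_", nuc)),
    stats::setNames(as.list(as.integer(f[nuc])), paste0("f_", nuc))
  ))
}

# brute-force O(points x sites) window recount, independent of window_scan
brute_window_counts <- function(pos, flag, len, window_size = 100e3,
                                resolution = 500) {
  pts <- seq(resolution, len, by = resolution)
  half <- floor(window_size / 2)
  vapply(pts, function(p) {
    lo <- max(1, p - half); hi <- min(len, p + half)
    sum(flag & pos >= lo & pos <= hi)
  }, integer(1))
}

# exact two-sided Fisher p by direct enumeration with choose(), for one
# table; independent code path from the dhyper implementation
fisher_enum_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# reciprocal overlap of two 1-based closed intervals
reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  min(inter / (e1 - s1 + 1), inter / (e2 - s2 + 1))
}

# small test genome: 2 x 4 Mb linkage groups, 1.2 Mb SDR
small_genome <- function() {
  genome_model(
    linkage_groups = tibble::tibble(lg = c("LG1", "LG2"), length = c(4e6, 4e6)),
    sdr = list(lg = "LG2", start = 1.4e6 + 1, end = 2.6e6)
  )
}

chrom_lengths_of <- function(genome) {
  dplyr::rename(genome$linkage_groups, chrom = "lg")
}
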