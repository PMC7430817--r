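#' Read and write the tabular interchange formats
#'
#' Plain-text readers/writers for the pipeline's inputs and outputs:
#' tag depth matrices (TSV with one depth column per individual), sex
#' registries (CSV: `id`, `phenotype`, optional `genotype`), cross
#' tables (CSV: `id`, `cross`, `phenotype`, one `primer_*` column per
#' assay), and window tables (TSV).
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name sdrscan_io
NULL

#' @rdname sdrscan_io
#' @export
write_tag_matrix <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname sdrscan_io
#' @export
read_tag_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"tag_id" %in% names(x)) abort("Tag matrix needs a `tag_id` column.")
  if (anyDuplicated(x$tag_id)) abort("Tag ids must be unique.")
  depth <- as.matrix(x[individual_cols(x)])
  if (any(depth < 0)) abort("Tag depths must be >= 0.")
  x
}

#' @rdname sdrscan_io
#' @export
write_sex_registry <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname sdrscan_io
#' @export
read_sex_registry <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "phenotype") %in% names(x))) {
    abort("Sex registry needs `id` and `phenotype` columns.")
  }
  x
}

#' @rdname sdrscan_io
#' @export
write_cross_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname sdrscan_io
#' @export
read_cross_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"phenotype" %in% names(x)) abort("Cross table needs a `phenotype` column.")
  x
}

#' @rdname sdrscan_io
#' @export
write_windows <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write a two-pool sync file
#'
#' Serialises a sync tibble (as produced by [simulate_sync()] or
#' [read_sync()]) to the popoolation sync dialect: tab-separated
#' `chrom`, `pos`, `ref`, then one `A:T:C:G:N:del` count sextet per pool
#' (male pool first).
#'
#' @param sync Tibble with `chrom`, `pos`, `ref` and count columns
#'   `m_A` ... `m_del`, `f_A` ... `f_del`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  fmt <- function(prefix) {
    do.call(paste, c(unname(as.list(
      sync[paste0(prefix, c("A", "T", "C", "G", "N", "del"))]
    )), sep = ":"))
  }
  lines <- paste(sync$chrom, sync$pos, sync$ref, fmt("m_"), fmt("f_"),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a two-pool sync file
#'
#' Parses the popoolation sync format: tab-separated `chrom`, 1-based
#' `pos`, reference base, then exactly two `A:T:C:G:N:del` count sextets
#' (male pool, female pool). Malformed count fields, lines without
#' exactly two pools, and positions that decrease within a chromosome
#' are rejected with the offending line number.
#'
#' @param path Path to a sync file.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `m_A` ... `m_del`,
#'   `f_A` ... `f_del`.
#' @export
read_sync <- function(path) {
  lines <- readr::read_lines(path)
  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    m_A = integer(), m_T = integer(), m_C = integer(), m_G = integer(),
    m_N = integer(), m_del = integer(),
    f_A = integer(), f_T = integer(), f_C = integer(), f_G = integer(),
    f_N = integer(), f_del = integer()
  )
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1]
    abort(sprintf(
      "Line %d: expected 5 tab-separated fields (chrom, pos, ref, 2 pools), found %d.",
      bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 5, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1)) {
    abort(sprintf("Line %d: position is not a positive integer.",
                  which(is.na(pos) | pos < 1)[1]))
  }
  parse_pool <- function(col, label) {
    ok <- grepl("^[0-9]+(:[0-9]+){5}$", col)
    if (!all(ok)) {
      abort(sprintf("Line %d: malformed %s count sextet '%s'.",
                    which(!ok)[1], label, col[which(!ok)[1]]))
    }
    cnt <- matrix(as.integer(unlist(strsplit(col, ":", fixed = TRUE))),
                  ncol = 6, byrow = TRUE)
    cnt
  }
  mc <- parse_pool(m[, 4], "male-pool")
  fc <- parse_pool(m[, 5], "female-pool")
  # positions must be non-decreasing within each chromosome block
  same_chrom <- m[-1, 1] == m[-nrow(m), 1]
  decreasing <- same_chrom & (pos[-1] < pos[-length(pos)])
  if (any(decreasing)) {
    abort(sprintf("Line %d: positions decrease within chromosome '%s'.",
                  which(decreasing)[1] + 1L, m[which(decreasing)[1] + 1L, 1]))
  }
  nuc <- c("A", "T", "C", "G", "N", "del")
  out <- bind_cols(
    tibble(chrom = m[, 1], pos = pos, ref = m[, 3]),
    as_tibble(`colnames<-`(mc, paste0("m_", nuc))),
    as_tibble(`colnames<-`(fc, paste0("f_", nuc)))
  )
  out
}

#' Write SDR calls as BED
#'
#' Converts 1-based closed SDR intervals to the 0-based half-open BED
#' convention.
#'
#' @param calls An `sdr_calls` tibble from [call_sdr()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sdr_bed <- function(calls, path) {
  lines <- if (nrow(calls) == 0) character(0) else {
    sprintf("%s\t%d\t%d\tSDR_%d\t%d", calls$chrom,
            as.integer(calls$start - 1), as.integer(calls$end),
            seq_len(nrow(calls)), as.integer(round(calls$mean_density)))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write ground-truth metadata as JSON
#'
#' @param truth A list of ground-truth components (individual genotypes,
#'   planted tag positions, SDR coordinates, ...).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
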