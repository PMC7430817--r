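# shared internal helpers

# half-up decimal rounding (round() in R is banker's rounding)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# truncation toward zero at a fixed number of decimals
trunc_dec <- function(x, digits = 1) {
  trunc(x * 10^digits) / 10^digits
}

# run code under a fixed seed when one is supplied, otherwise use the
# current RNG stream
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# column names of a tag matrix / presence table that hold individuals
individual_cols <- function(tags) {
  setdiff(names(tags), c("tag_id", "sequence"))
}

random_sequences <- function(n, width = 60L) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste(sample(bases, width, replace = TRUE), collapse = "")
  }, character(1))
}
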