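DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  .revcomp_cpp(x)
}

#' Generate random DNA sequences
#'
#' @param n Number of sequences.
#' @param length Length of each sequence in bp.
#' @return Character vector of `n` sequences.
#' @keywords internal
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste0(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Mutate a DNA sequence by random substitutions
#'
#' Applies substitutions at i.i.d. per-base rate `rate`; every substituted
#' base is replaced by a different base, so `rate` is the realized divergence
#' in expectation.
#'
#' @param x Single DNA string.
#' @param rate Per-base substitution probability in \[0, 1).
#' @return Mutated DNA string.
#' @keywords internal
mutate_sequence <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste0(chars, collapse = "")
}

# Validate that a data frame carries the given columns; abort naming offenders.
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Deterministic per-purpose sub-seed derived from a master seed, kept in
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587) + 1L
}
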