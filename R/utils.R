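# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going up (0.5 -> 1), matching how the
#' per-library summary tables are conventionally printed. Base `round()`
#' rounds half to even, which prints 99.95 as 99.9 rather than 100.0.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(100 * 2015 / 2016, 1) # 100.0
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * trunc(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

# Upper-case and convert T -> U so DNA- and RNA-alphabet inputs compare.
normalize_rna <- function(x) chartr("Tt", "UU", toupper(x))

# Upper-case and convert U -> T (genome/k-mer side works in DNA alphabet).
normalize_dna <- function(x) chartr("Uu", "TT", toupper(x))

# Reverse complement in the DNA alphabet.
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
  }, character(1), USE.NAMES = FALSE)
}

assert_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside A/C/G/U (after T->U normalization): %s",
      what, paste(head(x[bad], 3), collapse = ", ")
    ))
  }
  invisible(x)
}

# Collapse a character set to a stable comma-separated key (NA when empty).
collapse_set <- function(x) {
  x <- sort(unique(x))
  if (length(x) == 0) NA_character_ else paste(x, collapse = ",")
}

`%na%` <- function(a, b) if (is.na(a)) b else a
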