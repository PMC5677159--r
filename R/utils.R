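#' Round half away from zero
#'
#' Fixed-point rounding where ties go up (0.005 -> 0.01), the convention used
#' in the report tables, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with report rounding
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimal places (default 2, the table convention).
#' @return `100 * num / den`, rounded half-up.
#' @export
percent_of <- function(num, den, digits = 2) {
  round_half_up(100 * num / den, digits)
}

## internal: stop with a field-naming configuration error
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

## internal: check proportion in [0,1]
check_prop <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    config_error(field, "must be a proportion in [0, 1]")
  invisible(x)
}

## internal: reverse-complement of character sequences (vectorised)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## internal: complement of single-character vectors
comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

## internal: split a sequence string into a character vector of bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
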