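#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero toward
#' positive infinity (the "schoolbook" convention), unlike [base::round()]
#' which rounds half to even. All printed percentages in this package use
#' this single convention: one decimal for relative abundances, integers for
#' percent changes.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.5)        # 3, not 2
#' round_half_up(11.25, 1)   # 11.3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# split a "|"-delimited list field into a character vector; NA/"" -> empty
split_list_field <- function(x, sep = "|") {
  if (length(x) != 1 || is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- strsplit(x, sep, fixed = TRUE)[[1]]
  out <- trimws(out)
  out[nzchar(out)]
}

collapse_list_field <- function(x, sep = "|") {
  paste(x, collapse = sep)
}

# stable 32-bit substream seed from a master seed and an integer label,
# so adding decades never perturbs the streams of earlier ones
substream_seed <- function(seed, label) {
  as.integer((as.double(seed) * 1000003 + as.double(label) * 7919) %% 2147483647)
}
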