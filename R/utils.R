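DNA_BASES <- c("A", "C", "G", "T")

# fast char -> code lookup table (A=1, C=2, G=3, T=4, everything else 0)
.code_lut <- local({
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

#' Encode a DNA string as integer codes
#'
#' A=1, C=2, G=3, T=4; any other character (including N) becomes 0 and
#' invalidates every scanning window that covers it.
#'
#' @param x a single DNA string.
#' @return integer vector of codes, one per base.
#' @keywords internal
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .code_lut[as.integer(charToRaw(x))]
}

decode_dna <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes) & codes >= 1L & codes <= 4L
  out[ok] <- DNA_BASES[codes[ok]]
  paste(out, collapse = "")
}

revcomp_codes <- function(codes) {
  out <- rev(codes)
  ok <- out >= 1L & out <= 4L
  out[ok] <- 5L - out[ok]
  out
}

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b character vectors of equal-length strings (recycled pairwise).
#' @return integer vector of mismatch counts.
#' @export
#' @examples
#' hamming_distance("AGTACTAATGTTCT", "AGTACTAATGTACT")
hamming_distance <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) {
    sum(as.integer(charToRaw(x)) != as.integer(charToRaw(y)))
  }, a, b, USE.NAMES = FALSE)
}
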