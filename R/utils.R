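#' Nucleotide alphabet used throughout
#'
#' All sequence machinery works over A, C, G, T with N as the single
#' ambiguity code. Internally sequences are encoded as integers 1..4
#' (A, C, G, T) with 5 for N and any other character.
#' @noRd
DNA_BASES4 <- c("A", "C", "G", "T")

#' Encode a nucleotide string as integers 1..5
#' @noRd
encode_seq <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- match(x, DNA_BASES4)
  m[is.na(m)] <- 5L
  m
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`; preserves case-insensitivity by uppercasing first.
#' `N` maps to `N`.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("CACAGTG")
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", toupper(x)))
}

#' Sample random sequences from a base composition
#' @noRd
sample_bases <- function(n, background) {
  sample(DNA_BASES4, n, replace = TRUE, prob = background)
}

#' Default 0-order background: A/T 0.3, C/G 0.2
#' @noRd
default_background <- function() {
  c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
}

#' Stop with a classed ragscan error
#' @noRd
rs_abort <- function(msg, class = "ragscan_error") {
  rlang::abort(msg, class = class)
}

#' Derive a bounded child seed from a base seed (keeps below 2^31)
#' @noRd
child_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483629L
}
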