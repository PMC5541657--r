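# Internal 5+1 letter alphabet: $ (sentinel) < A < C < G < T < N.
# The sentinel ranks lexicographically smallest; N is a real fifth symbol in
# the reference that exact search never matches.

SENTINEL <- 0L
SYM_N <- 5L

.enc_table <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("$") + 1L] <- 0L
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab[utf8ToInt("N") + 1L] <- 5L
  tab
})

.dec_table <- c("$", "A", "C", "G", "T", "N")

#' Encode a DNA string to integer codes
#'
#' Maps `$ A C G T N` to `0..5`.  Characters outside the alphabet map to N;
#' inputs are expected to be uppercased already (the parsers guarantee this).
#'
#' @param s a single character string.
#' @return an integer vector of codes, one per character.
#' @keywords internal
encode_dna <- function(s) {
  v <- .enc_table[utf8ToInt(s) + 1L]
  v[is.na(v)] <- SYM_N
  v
}

#' @rdname encode_dna
#' @param codes integer codes as produced by [encode_dna()].
#' @keywords internal
decode_dna <- function(codes) {
  paste(.dec_table[codes + 1L], collapse = "")
}

# complement in code space: A<->T, C<->G, N->N (sentinel never complemented)
.comp_table <- c(0L, 4L, 3L, 2L, 1L, 5L)

revcomp_codes <- function(codes) rev(.comp_table[codes + 1L])

#' Reverse-complement a DNA string
#'
#' @param s a character string over `A C G T N`.
#' @return the reverse complement, same alphabet.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

reverse_string <- function(s) intToUtf8(rev(utf8ToInt(s)))

# Cheap deterministic rolling hash (FNV-flavoured, 31-bit) used to tie hits
# files and indexes to the reference they were built from.
text_checksum <- function(codes) {
  h <- 0
  m <- 2147483647
  # process in blocks to keep the R loop short
  block <- 4096L
  n <- length(codes)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + block - 1L)
    seg <- codes[i:j]
    for (x in seg) h <- (h * 33 + x + 1) %% m
    i <- j + 1L
  }
  sprintf("%08x", as.integer(h))
}

new_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$lf <- 0
  e$expansions <- 0
  e
}

counters_total <- function(counters) {
  if (is.null(counters)) return(0)
  counters$lf + counters$expansions
}
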