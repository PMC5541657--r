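# Burrows-Wheeler/FM index over the concatenated reference, held fully in
# memory.  Coordinates are 0-based half-open internally; conversion to SAM's
# 1-based convention happens only at SAM emission.

#' Build an FM index over a set of reference sequences
#'
#' The references are concatenated (boundaries recorded for coordinate
#' mapping) and terminated by a single sentinel that ranks smallest.  The
#' suffix array is built by prefix doubling; the BWT, cumulative symbol
#' counts (`count`), checkpointed occurrence table (`cp`, stride
#' `occ_stride`) and a sampled suffix array (stride `sa_stride`) are derived
#' from it.  `N` in the reference is a genuine fifth symbol that exact search
#' never extends into, so runs of `N` cannot anchor spurious matches.
#'
#' @param refs list of references (`list(name=, seq=)`) as from [read_fasta()].
#' @param sa_stride suffix-array sampling stride (rows whose suffix position
#'   is a multiple of `sa_stride` are stored; the rest are recovered by
#'   LF-walking).
#' @param occ_stride checkpoint stride of the occurrence table.
#' @return an object of class `FmIndex`.
#' @export
build_index <- function(refs, sa_stride = 4L, occ_stride = 64L) {
  if (length(refs) == 0L) stop("build_index: empty reference set", call. = FALSE)
  sa_stride <- as.integer(sa_stride)
  occ_stride <- as.integer(occ_stride)
  stopifnot(sa_stride >= 1L, occ_stride >= 1L)
  names <- vapply(refs, function(r) r$name, character(1))
  lens <- vapply(refs, function(r) nchar(r$seq), integer(1))
  if (any(lens == 0L)) stop("build_index: empty reference sequence", call. = FALSE)
  if (anyDuplicated(names)) stop("build_index: duplicate reference names", call. = FALSE)
  codes <- unlist(lapply(refs, function(r) encode_dna(r$seq)), use.names = FALSE)
  text <- c(codes, SENTINEL)
  n <- length(text)
  sa <- suffix_array(text)
  bwt <- text[ifelse(sa == 0L, n, sa)]            # text[(sa-1) mod n], 1-based
  cnt <- tabulate(bwt + 1L, nbins = 6L)
  count <- c(0L, cumsum(cnt)[-6L])                # symbols strictly smaller
  ncp <- n %/% occ_stride + 1L
  cp <- matrix(0L, nrow = 6L, ncol = ncp)
  if (ncp > 1L) {
    rows <- seq_len(ncp - 1L) * occ_stride
    for (s in 0:5) {
      cs <- cumsum(bwt == s)
      cp[s + 1L, 2:ncp] <- cs[rows]
    }
  }
  ssa <- rep(NA_integer_, n)
  keep <- sa %% sa_stride == 0L
  ssa[keep] <- sa[keep]
  boundaries <- data.frame(name = names,
                           start = cumsum(c(0L, lens))[seq_along(lens)],
                           len = lens,
                           stringsAsFactors = FALSE)
  structure(list(n = n,
                 bwt = bwt,
                 count = count,
                 cp = cp,
                 ssa = ssa,
                 sa_stride = sa_stride,
                 occ_stride = occ_stride,
                 boundaries = boundaries,
                 checksum = text_checksum(text)),
            class = "FmIndex")
}

#' @export
print.FmIndex <- function(x, ...) {
  cat("FmIndex:", x$n - 1L, "bases +1 sentinel;",
      nrow(x$boundaries), "reference(s);",
      "strides sa =", x$sa_stride, ", occ =", x$occ_stride,
      "; checksum", x$checksum, "\n")
  invisible(x)
}

# Suffix array by prefix doubling (order() with radix sort on integer ranks).
# Returns 0-based positions; the sentinel guarantees all suffixes distinct.
suffix_array <- function(text) {
  n <- length(text)
  if (n == 1L) return(0L)
  rank <- text + 1L                               # ranks >= 1; 0 reserved
  k <- 1L
  repeat {
    key2 <- c(rank[-seq_len(min(k, n))], rep(0L, min(k, n)))
    ord <- order(rank, key2, method = "radix")
    r1 <- rank[ord]
    r2 <- key2[ord]
    changed <- c(TRUE, r1[-1L] != r1[-n] | r2[-1L] != r2[-n])
    newrank <- integer(n)
    newrank[ord] <- cumsum(changed)
    rank <- newrank
    if (rank[ord[n]] == n) break
    k <- k * 2L
  }
  ord - 1L
}

# Occurrence count of symbol `sym` (code) in bwt[1..i]  (i in 0..n).
occ_one <- function(idx, sym, i) {
  if (i <= 0L) return(0L)
  j <- i %/% idx$occ_stride
  base <- idx$cp[sym + 1L, j + 1L]
  lo <- j * idx$occ_stride
  if (i > lo) base + sum(idx$bwt[(lo + 1L):i] == sym) else base
}

# Occurrence counts of codes 1..4 (A,C,G,T) in bwt[1..i], as a length-4 vector.
occ_acgt <- function(idx, i) {
  if (i <= 0L) return(c(0L, 0L, 0L, 0L))
  j <- i %/% idx$occ_stride
  base <- idx$cp[2:5, j + 1L]
  lo <- j * idx$occ_stride
  if (i > lo) base + tabulate(idx$bwt[(lo + 1L):i] + 1L, nbins = 6L)[2:5] else base
}

lf_row <- function(idx, r) {
  sym <- idx$bwt[r]
  idx$count[sym + 1L] + occ_one(idx, sym, r)
}

#' Exact backward search
#'
#' Extends a suffix-array interval one query symbol at a time from the end of
#' the query; the number of extension steps equals the query length unless
#' the interval empties early, i.e. runtime is linear in the query.  `N`
#' anywhere in the query yields the empty interval (N matches nothing in
#' exact mode).
#'
#' @param index an [build_index()] object.
#' @param query character string over `A C G T N`, or an integer code vector.
#' @param counters optional instrumentation environment (LF steps are added
#'   to `counters$lf`).
#' @return a suffix-array interval `list(low=, high=)`, 0-based half-open
#'   over suffix-array rows; empty iff `low == high`.
#' @export
backward_search_exact <- function(index, query, counters = NULL) {
  q <- if (is.character(query)) encode_dna(query) else as.integer(query)
  if (length(q) == 0L) stop("backward_search_exact: empty query", call. = FALSE)
  if (any(q == SYM_N | q == SENTINEL)) {
    return(list(low = 0L, high = 0L))
  }
  l <- 1L
  u <- index$n
  steps <- 0L
  for (i in rev(seq_along(q))) {
    sym <- q[i]
    l <- index$count[sym + 1L] + occ_one(index, sym, l - 1L) + 1L
    u <- index$count[sym + 1L] + occ_one(index, sym, u)
    steps <- steps + 1L
    if (l > u) break
  }
  if (!is.null(counters)) counters$lf <- counters$lf + steps
  if (l > u) list(low = 0L, high = 0L) else list(low = l - 1L, high = u)
}

#' Resolve a suffix-array interval to text positions
#'
#' Each row is resolved through the sampled suffix array by LF-walking;
#' results are identical to an unsampled lookup for any stride.
#'
#' @param index an `FmIndex`.
#' @param interval interval from [backward_search_exact()].
#' @param counters optional instrumentation environment.
#' @return sorted integer vector of 0-based global text positions.
#' @export
locate <- function(index, interval, counters = NULL) {
  low <- interval$low
  high <- interval$high
  if (low < 0L || high > index$n || low > high) {
    stop("locate: interval out of range", call. = FALSE)
  }
  if (low == high) return(integer(0))
  rows <- (low + 1L):high
  steps_total <- 0L
  pos <- vapply(rows, function(r) {
    steps <- 0L
    while (is.na(index$ssa[r])) {
      r <- lf_row(index, r)
      steps <- steps + 1L
    }
    steps_total <<- steps_total + steps
    index$ssa[r] + steps
  }, integer(1))
  if (!is.null(counters)) counters$lf <- counters$lf + steps_total
  sort(pos)
}

#' Invert a Burrows-Wheeler transform
#'
#' Test-oracle quality reconstruction of the text whose BWT is the input;
#' requires exactly one sentinel.
#'
#' @param bwt character string (with `$`) or integer code vector.
#' @return the original sentinel-terminated text, same representation.
#' @export
inverse_bwt <- function(bwt) {
  chr <- is.character(bwt)
  b <- if (chr) encode_dna(bwt) else as.integer(bwt)
  if (sum(b == SENTINEL) != 1L) {
    stop("inverse_bwt: input must contain exactly one sentinel", call. = FALSE)
  }
  n <- length(b)
  cnt <- tabulate(b + 1L, nbins = 6L)
  count <- c(0L, cumsum(cnt)[-6L])
  # per-row occurrence rank of its own symbol
  rnk <- integer(n)
  for (s in 0:5) {
    idx <- which(b == s)
    rnk[idx] <- seq_along(idx)
  }
  lf <- count[b + 1L] + rnk
  out <- integer(n)
  row <- 1L                                       # row of the "$" suffix
  for (k in seq_len(n)) {
    out[k] <- b[row]
    row <- lf[row]
  }
  # out holds text[n-1], text[n-2], ..., text[0] wrapped: last element is "$"
  text <- c(rev(out[seq_len(n - 1L)]), SENTINEL)
  if (chr) decode_dna(text) else text
}

# Map 0-based global text positions to per-reference coordinates.  Alignments
# spanning `span` reference bases starting at `pos` that straddle a reference
# boundary (or the sentinel) are flagged `ok = FALSE` and dropped by callers.
global_to_ref <- function(index, pos, span) {
  b <- index$boundaries
  i <- pmax(findInterval(pos, b$start), 1L)
  ok <- (pos + span) <= (b$start[i] + b$len[i])
  list(ok = ok, refname = b$name[i], refpos = pos - b$start[i])
}
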