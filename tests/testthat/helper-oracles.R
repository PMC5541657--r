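# Independent oracles, deliberately implemented with none of the package's
# index machinery: naive suffix sorting, sliding-window occurrence scans,
# and a banded dynamic-programming edit aligner mirroring the kernel's
# scoring model (mismatch / affine gap penalties, differences = mismatches
# + gap opens + gap extensions).

# naive suffix array by sorting suffix strings; symbol order $ < A < C < G
# < T < N is enforced by remapping N to a byte above T
naive_suffix_array <- function(text_string) {
  s <- chartr("$N", "!Z", text_string)
  n <- nchar(s)
  suf <- substring(s, seq_len(n), n)
  order(suf, method = "radix") - 1L
}

naive_bwt <- function(text_string) {
  codes <- gibarra:::encode_dna(text_string)
  sa <- naive_suffix_array(text_string)
  n <- length(codes)
  gibarra:::decode_dna(codes[ifelse(sa == 0L, n, sa)])
}

# all (overlapping) occurrence start positions of q in g, 0-based
naive_occurrences <- function(g, q) {
  L <- nchar(q)
  n <- nchar(g)
  if (L > n) return(integer(0))
  starts <- seq_len(n - L + 1L)
  which(substring(g, starts, starts + L - 1L) == q) - 1L
}

# ---------------------------------------------------------------------------
# Banded semi-global DP over the whole genome, vectorised over all start
# positions.  A placement starts at the reference base consumed by its first
# M operation (leading/trailing deletions are excluded, matching the
# kernel); leading/trailing insertions are allowed.  Cost model: mismatch
# `mm`; a gap run costs `go` + (len-1) * `ge`; differences = mismatches +
# gap opens + gap extensions, capped at `maxd` -- so total gap bases never
# exceed `maxd` and a band half-width B > maxd is exact.
# ---------------------------------------------------------------------------
oracle_scores_one_strand <- function(gcodes, qcodes, maxd, mm, go, ge, B) {
  L <- length(qcodes)
  Gn <- length(gcodes)
  nP <- Gn
  W <- 2L * B + 1L
  bvec <- (-B):B
  INF <- Inf
  infm <- matrix(INF, W, nP)
  layer <- function() lapply(seq_len(maxd + 1L), function(d) infm)
  # GM[o + 1, p] = gcodes[p + o] (-1 outside the genome), offsets 0..L+B-1
  off_max <- L + B
  GM <- matrix(-1L, nrow = off_max, ncol = nP)
  for (o in 0:(off_max - 1L)) {
    pr <- seq_len(nP) + o
    ok <- pr <= Gn
    GM[o + 1L, ok] <- gcodes[pr[ok]]
  }
  shift_up <- function(X) rbind(X[-1L, , drop = FALSE], rep(INF, nP))
  Mp <- layer(); Dp <- layer(); Ip <- layer()
  Mp[[1L]][B + 1L, ] <- 0                        # virtual start: b = 0, d = 0
  for (i in seq_len(L)) {
    jrow <- i + bvec                             # ref consumed per band row
    valid_r <- jrow >= 1L & jrow <= off_max
    Gsym <- matrix(-1L, W, nP)
    Gsym[valid_r, ] <- GM[jrow[valid_r], ]       # symbol consumed by M at row
    hit <- Gsym == qcodes[i] & Gsym >= 1L
    sub_ok <- !hit & Gsym >= 1L
    M <- layer(); D <- layer(); I <- layer()
    for (d in seq_len(maxd + 1L)) {
      # M-step: same band row as source
      src <- pmin(Mp[[d]], Dp[[d]], Ip[[d]])
      val <- infm
      val[hit] <- src[hit]
      if (d >= 2L) {
        srcm <- pmin(Mp[[d - 1L]], Dp[[d - 1L]], Ip[[d - 1L]]) + mm
        val[sub_ok] <- pmin(val[sub_ok], srcm[sub_ok])
      }
      val[!valid_r, ] <- INF
      M[[d]] <- val
      # I-step: source one band row up (b + 1); opens and extensions both
      # consume one unit of the difference budget
      ext <- if (d >= 2L) shift_up(Ip[[d - 1L]]) + ge else infm
      opn <- if (d >= 2L) shift_up(pmin(Mp[[d - 1L]], Dp[[d - 1L]])) + go
             else infm
      I[[d]] <- pmin(ext, opn)
    }
    # D-sweep within the layer, ascending band rows; extensions draw on the
    # next-lower difference level of the same sweep
    for (d in seq_len(maxd + 1L)) {
      Dd <- infm
      for (r in 2:W) {
        j <- jrow[r]
        if (j < 1L) next
        opn <- if (d >= 2L) pmin(M[[d - 1L]][r - 1L, ], I[[d - 1L]][r - 1L, ]) + go
               else rep(INF, nP)
        ext <- if (d >= 2L) D[[d - 1L]][r - 1L, ] + ge else rep(INF, nP)
        v <- pmin(ext, opn)
        v[seq_len(nP) + j - 1L > Gn] <- INF
        Dd[r, ] <- v
      }
      D[[d]] <- Dd
    }
    Mp <- M; Dp <- D; Ip <- I
  }
  colmin <- function(X) do.call(pmin, lapply(seq_len(nrow(X)),
                                             function(r) X[r, ]))
  S <- rep(INF, nP)
  for (d in seq_len(maxd + 1L)) {
    S <- pmin(S, colmin(Mp[[d]]), colmin(Ip[[d]]))
  }
  S
}

# minimum-score placements of `read` in `genome` on both strands:
# data.frame(pos [0-based], strand) plus the best score
oracle_hits <- function(genome, read, maxd = 2L, mm = 3L, go = 11L,
                        ge = 4L, B = 4L) {
  gcodes <- gibarra:::encode_dna(genome)
  hits <- list()
  best <- Inf
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    S <- oracle_scores_one_strand(gcodes, gibarra:::encode_dna(q),
                                  maxd, mm, go, ge, B)
    hits[[strand]] <- S
    best <- min(best, S)
  }
  if (!is.finite(best)) {
    return(list(best = Inf,
                hits = data.frame(pos = integer(0), strand = character(0))))
  }
  out <- do.call(rbind, lapply(c("+", "-"), function(st) {
    p <- which(hits[[st]] == best) - 1L
    if (length(p) == 0L) return(NULL)
    data.frame(pos = p, strand = st, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$pos, out$strand != "+"), , drop = FALSE]
  row.names(out) <- NULL
  list(best = best, hits = out)
}

# kernel parameters that make the oracle's model exact (no seed, caps
# non-binding beyond the difference budget, unbounded reporting)
oracle_params <- function(maxd = 2L) {
  search_params(max_diff = maxd, max_gap_opens = maxd, max_gap_extends = 16L,
                seed_len = 0L, max_queue = 10000000L,
                max_hits_reported = 1000000L)
}
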