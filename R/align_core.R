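# Single-end alignment kernel: 150 bp truncation, the non-divergent exact
# pre-pass, and the k-difference backtracking fallback it hands hard reads to.
# Every tunable below is a registered genetic-improvement site; the kernel is
# instrumented with deterministic work-unit counters (LF steps + search-state
# expansions) that stand in for wall-clock time in the GI fitness.

READ_LENGTH_LIMIT <- 150L

#' Search kernel parameters
#'
#' "Differences" are substitutions plus gap events (opens and extensions),
#' charged against `max_diff`; gap opens and extensions additionally have
#' their own caps.  Charging extensions keeps the per-prefix lower bound of
#' [compute_diff_bound()] valid: every difference occupies at most one read
#' position, so each exactly-unmatchable read segment costs at least one
#' unit of budget.
#' Scoring is by accumulated penalty (lower is better).  `max_diff = "auto"`
#' picks the budget from the read length: 2 up to 63 bp, 4 for 64-122 bp,
#' 5 for 123-150 bp.
#'
#' @param max_diff total difference budget, or `"auto"`.
#' @param max_gap_opens,max_gap_extends caps on gap opens / extensions.
#' @param gap_open_pen,gap_ext_pen,mismatch_pen positive integer penalties.
#' @param seed_len length of the seed (the first `seed_len` read bases);
#'   0 disables the seed constraint.
#' @param max_seed_diff differences allowed inside the seed.
#' @param max_queue cap on explored search states per read.
#' @param max_hits_reported cap on reported co-optimal hits.
#' @return a validated `SearchParams` list.
#' @export
search_params <- function(max_diff = "auto",
                          max_gap_opens = 1L,
                          max_gap_extends = 6L,
                          gap_open_pen = 11L,
                          gap_ext_pen = 4L,
                          mismatch_pen = 3L,
                          seed_len = 32L,
                          max_seed_diff = 2L,
                          max_queue = 100000L,
                          max_hits_reported = 32L) {
  p <- list(max_diff = max_diff,
            max_gap_opens = as.integer(max_gap_opens),
            max_gap_extends = as.integer(max_gap_extends),
            gap_open_pen = as.integer(gap_open_pen),
            gap_ext_pen = as.integer(gap_ext_pen),
            mismatch_pen = as.integer(mismatch_pen),
            seed_len = as.integer(seed_len),
            max_seed_diff = as.integer(max_seed_diff),
            max_queue = as.integer(max_queue),
            max_hits_reported = as.integer(max_hits_reported))
  if (!identical(p$max_diff, "auto")) {
    p$max_diff <- as.integer(p$max_diff)
    stopifnot(p$max_diff >= 0L)
  }
  stopifnot(p$gap_open_pen > 0L, p$gap_ext_pen > 0L, p$mismatch_pen > 0L,
            p$seed_len >= 0L, p$seed_len <= READ_LENGTH_LIMIT,
            p$max_queue >= 1L, p$max_hits_reported >= 1L,
            p$max_gap_opens >= 0L, p$max_gap_extends >= 0L)
  class(p) <- "SearchParams"
  p
}

#' Resolve an "auto" difference budget for a read length
#' @param params a [search_params()] object.
#' @param read_len read length in bases (after truncation).
#' @return integer budget.
#' @export
resolve_max_diff <- function(params, read_len) {
  if (!identical(params$max_diff, "auto")) return(params$max_diff)
  if (read_len <= 63L) 2L else if (read_len <= 122L) 4L else 5L
}

#' Kernel code-variant toggles
#'
#' The named code variants of the kernel, each a genetic-improvement site:
#' `prepass` gates the exact pre-pass, `use_diff_bound` gates the
#' lower-bound pruning of the backtracking search.  Defaults reproduce the
#' reference kernel.
#' @param prepass run the exact pre-pass before falling back.
#' @param use_diff_bound prune backtracking with the per-prefix difference
#'   lower bound.
#' @export
kernel_variants <- function(prepass = TRUE, use_diff_bound = TRUE) {
  list(prepass = isTRUE(prepass), use_diff_bound = isTRUE(use_diff_bound))
}

#' Truncate a read to the kernel's length limit
#'
#' Reads over 150 bp keep their first 150 bases and qualities; the remainder
#' is ignored with one warning per read.
#'
#' @param read a record `list(id=, bases=, quals=)`.
#' @return `list(record=, truncated=)`.
#' @export
truncate_read <- function(read) {
  n <- nchar(read$bases)
  if (n <= READ_LENGTH_LIMIT) {
    return(list(record = read, truncated = FALSE))
  }
  warning("read '", read$id, "' is ", n, " bp; ignoring bases beyond ",
          READ_LENGTH_LIMIT, call. = FALSE)
  read$bases <- substr(read$bases, 1L, READ_LENGTH_LIMIT)
  if (!is.null(read$quals)) read$quals <- substr(read$quals, 1L, READ_LENGTH_LIMIT)
  list(record = read, truncated = TRUE)
}

#' Lower bound on differences needed per read prefix
#'
#' One backward pass of the read against the reversed-reference index: every
#' time the exact interval empties, at least one more difference is forced
#' and the interval restarts.  `d[i]` is a valid lower bound on the
#' differences needed to align `read[1..i]` anywhere, and is non-decreasing.
#'
#' @param rindex `FmIndex` built over the reversed reference text.
#' @param read character string or integer codes (already truncated).
#' @param counters optional instrumentation environment.
#' @return integer vector `d`, one entry per read position.
#' @export
compute_diff_bound <- function(rindex, read, counters = NULL) {
  q <- if (is.character(read)) encode_dna(read) else as.integer(read)
  n <- length(q)
  d <- integer(n)
  z <- 0L
  l <- 1L
  u <- rindex$n
  steps <- 0L
  for (i in seq_len(n)) {
    sym <- q[i]
    empty <- TRUE
    if (sym >= 1L && sym <= 4L) {
      l2 <- rindex$count[sym + 1L] + occ_one(rindex, sym, l - 1L) + 1L
      u2 <- rindex$count[sym + 1L] + occ_one(rindex, sym, u)
      steps <- steps + 1L
      if (l2 <= u2) {
        empty <- FALSE
        l <- l2
        u <- u2
      }
    }
    if (empty) {
      z <- z + 1L
      l <- 1L
      u <- rindex$n
    }
    d[i] <- z
  }
  if (!is.null(counters)) counters$lf <- counters$lf + steps
  d
}

empty_hits <- function() {
  data.frame(refname = character(0), pos = integer(0), strand = character(0),
             score = integer(0), n_mismatch = integer(0),
             n_gap_open = integer(0), n_gap_ext = integer(0),
             cigar = character(0), interval_size = integer(0),
             stringsAsFactors = FALSE)
}

# run-length encode an op-code vector (1 = M, 2 = I, 3 = D) into a CIGAR
ops_to_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, c("M", "I", "D")[r$values], collapse = "")
}

cigar_ref_span <- function(ops) sum(ops != 2L)

# Assemble a hits data.frame from located placements, then impose the
# deterministic report order: ascending reference position, forward strand
# first, first-recorded completion first; duplicates by (pos, strand) drop.
finalize_hits <- function(index, cand, max_hits) {
  if (nrow(cand) == 0L) return(empty_hits())
  m <- global_to_ref(index, cand$gpos, cand$span)
  cand$refname <- m$refname
  cand$pos <- m$refpos
  cand <- cand[m$ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_hits())
  ord <- order(cand$gpos, cand$strand != "+", cand$comp)
  cand <- cand[ord, , drop = FALSE]
  dup <- duplicated(paste(cand$gpos, cand$strand))
  cand <- cand[!dup, , drop = FALSE]
  if (nrow(cand) > max_hits) cand <- cand[seq_len(max_hits), , drop = FALSE]
  data.frame(refname = cand$refname, pos = cand$pos, strand = cand$strand,
             score = cand$score, n_mismatch = cand$nmm,
             n_gap_open = cand$ngo, n_gap_ext = cand$nge,
             cigar = cand$cigar, interval_size = cand$isize,
             stringsAsFactors = FALSE)
}

#' Non-divergent exact pre-pass
#'
#' Tries the read and its reverse complement with plain exact backward
#' search (no backtracking; a fixed number of LF steps per strand).  Exact
#' hits short-circuit the expensive fallback; anything else is deferred.
#'
#' @param index a [index_reference()] object (or a bare forward `FmIndex`).
#' @param read record or bases string (already truncated).
#' @param params a [search_params()] object.
#' @param counters optional instrumentation environment.
#' @return `list(hits=, needs_fallback=)`.
#' @export
exact_prepass <- function(index, read, params = search_params(),
                          counters = NULL) {
  fwd <- if (inherits(index, "FmIndex")) index else index$fwd
  bases <- if (is.list(read)) read$bases else read
  q <- encode_dna(bases)
  len <- length(q)
  cand <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") q else revcomp_codes(q)
    if (any(qs == SYM_N)) next
    iv <- backward_search_exact(fwd, qs, counters)
    if (iv$high > iv$low) {
      pos <- locate(fwd, iv, counters)
      cand[[length(cand) + 1L]] <-
        data.frame(gpos = pos, strand = strand, score = 0L, nmm = 0L,
                   ngo = 0L, nge = 0L, cigar = sprintf("%dM", len),
                   span = len, isize = iv$high - iv$low,
                   comp = seq_along(pos), stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(gpos = integer(0), strand = character(0), score = integer(0),
               nmm = integer(0), ngo = integer(0), nge = integer(0),
               cigar = character(0), span = integer(0), isize = integer(0),
               comp = integer(0), stringsAsFactors = FALSE)
  hits <- finalize_hits(fwd, cand, params$max_hits_reported)
  list(hits = hits, needs_fallback = nrow(hits) == 0L)
}

# ---------------------------------------------------------------------------
# k-difference backtracking search (one strand).
#
# Best-first by penalty level: states are expanded level-synchronously in
# ascending score; within a level, in creation order.  Children are created
# match first, then substitutions in symbol order, then deletions in symbol
# order, then insertion -- fixing the deterministic expansion order.  States
# are pruned by the difference budget, the per-prefix lower bound `d`, the
# seed constraint, the gap caps, and the current best score (plus one
# mismatch-penalty window used for mapping-quality competitor detection).
# Returns completed states; op chains are recovered via parent links.
# ---------------------------------------------------------------------------
ksearch_strand <- function(fmi, q, params, dbound, maxd, best_in = Inf,
                           counters = NULL) {
  n <- length(q)
  mm <- params$mismatch_pen
  go <- params$gap_open_pen
  ge <- params$gap_ext_pen
  seed_from <- params$seed_len           # positions 1..seed_len are the seed
  smax <- maxd * mm + min(maxd, params$max_gap_opens) * go +
    params$max_gap_extends * ge + mm
  cap <- 256L
  st_l <- integer(cap); st_u <- integer(cap); st_i <- integer(cap)
  st_nmm <- integer(cap); st_ngo <- integer(cap); st_nge <- integer(cap)
  st_gap <- integer(cap)                 # 0 none, 1 deletion run, 2 insertion run
  st_sc <- integer(cap); st_seed <- integer(cap)
  st_par <- integer(cap); st_op <- integer(cap)  # 1 M, 2 I, 3 D, 0 root
  nst <- 0L
  push <- function(l, u, i, nmm_, ngo_, nge_, gap_, sc_, seed_, par_, op_) {
    if (nst == cap) {
      cap <<- cap * 2L
      length(st_l) <<- cap; length(st_u) <<- cap; length(st_i) <<- cap
      length(st_nmm) <<- cap; length(st_ngo) <<- cap; length(st_nge) <<- cap
      length(st_gap) <<- cap; length(st_sc) <<- cap; length(st_seed) <<- cap
      length(st_par) <<- cap; length(st_op) <<- cap
    }
    nst <<- nst + 1L
    st_l[nst] <<- l; st_u[nst] <<- u; st_i[nst] <<- i
    st_nmm[nst] <<- nmm_; st_ngo[nst] <<- ngo_; st_nge[nst] <<- nge_
    st_gap[nst] <<- gap_; st_sc[nst] <<- sc_; st_seed[nst] <<- seed_
    st_par[nst] <<- par_; st_op[nst] <<- op_
    invisible(NULL)
  }
  d_at <- function(i) if (i >= 1L) dbound[i] else 0L
  best <- best_in
  comp <- integer(0)
  expansions <- 0L
  lf <- 0L
  capped <- FALSE
  push(1L, fmi$n, n, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  process_one <- function(id) {
    i <- st_i[id]
    if (i == 0L) {
      comp <<- c(comp, id)
      if (st_sc[id] < best) best <<- st_sc[id]
      return(invisible(NULL))
    }
    if (expansions >= params$max_queue) {
      capped <<- TRUE
      return(invisible(NULL))
    }
    expansions <<- expansions + 1L
    l <- st_l[id]; u <- st_u[id]
    nmm_ <- st_nmm[id]; ngo_ <- st_ngo[id]; nge_ <- st_nge[id]
    gap_ <- st_gap[id]; sc_ <- st_sc[id]; seed_ <- st_seed[id]
    ndiff <- nmm_ + ngo_ + nge_
    allow <- maxd - ndiff
    occl <- occ_acgt(fmi, l - 1L)
    occu <- occ_acgt(fmi, u)
    lf <<- lf + 4L
    nl <- fmi$count[2:5] + occl + 1L
    nu <- fmi$count[2:5] + occu
    qc <- q[i]
    in_seed <- i <= seed_from
    # match
    if (qc >= 1L && qc <= 4L && nl[qc] <= nu[qc] &&
        ndiff + d_at(i - 1L) <= maxd) {
      push(nl[qc], nu[qc], i - 1L, nmm_, ngo_, nge_, 0L, sc_, seed_, id, 1L)
    }
    # substitutions, in symbol order A < C < G < T
    if (allow >= 1L && ndiff + 1L + d_at(i - 1L) <= maxd &&
        (!in_seed || seed_ + 1L <= params$max_seed_diff)) {
      sseed <- seed_ + (in_seed)
      for (b in 1:4) {
        if (b != qc && nl[b] <= nu[b]) {
          push(nl[b], nu[b], i - 1L, nmm_ + 1L, ngo_, nge_, 0L,
               sc_ + mm, sseed, id, 1L)
        }
      }
    }
    # deletions (reference base consumed, read position kept); never before
    # the first read base has been consumed (no trailing deletions)
    if (i < n) {
      if (gap_ == 1L) {
        if (allow >= 1L && nge_ + 1L <= params$max_gap_extends &&
            ndiff + 1L + d_at(i) <= maxd &&
            (!in_seed || seed_ + 1L <= params$max_seed_diff)) {
          sseed <- seed_ + (in_seed)
          for (b in 1:4) {
            if (nl[b] <= nu[b]) {
              push(nl[b], nu[b], i, nmm_, ngo_, nge_ + 1L, 1L,
                   sc_ + ge, sseed, id, 3L)
            }
          }
        }
      } else if (allow >= 1L && ngo_ + 1L <= params$max_gap_opens &&
                 ndiff + 1L + d_at(i) <= maxd &&
                 (!in_seed || seed_ + 1L <= params$max_seed_diff)) {
        sseed <- seed_ + (in_seed)
        for (b in 1:4) {
          if (nl[b] <= nu[b]) {
            push(nl[b], nu[b], i, nmm_, ngo_ + 1L, nge_, 1L,
                 sc_ + go, sseed, id, 3L)
          }
        }
      }
    }
    # insertion (read base consumed, interval unchanged)
    if (gap_ == 2L) {
      if (allow >= 1L && nge_ + 1L <= params$max_gap_extends &&
          ndiff + 1L + d_at(i - 1L) <= maxd &&
          (!in_seed || seed_ + 1L <= params$max_seed_diff)) {
        push(l, u, i - 1L, nmm_, ngo_, nge_ + 1L, 2L, sc_ + ge,
             seed_ + (in_seed), id, 2L)
      }
    } else if (allow >= 1L && ngo_ + 1L <= params$max_gap_opens &&
               ndiff + 1L + d_at(i - 1L) <= maxd &&
               (!in_seed || seed_ + 1L <= params$max_seed_diff)) {
      push(l, u, i - 1L, nmm_, ngo_ + 1L, nge_, 2L, sc_ + go,
           seed_ + (in_seed), id, 2L)
    }
    invisible(NULL)
  }
  # level-synchronous sweep: child scores never undercut their parent's, so
  # ascending score levels realise best-first order
  level <- 0L
  repeat {
    thr <- if (!is.finite(best)) smax else if (best == 0L) 0L else best + mm
    if (level > min(thr, smax) || capped) break
    from <- 1L
    repeat {
      hi <- nst
      if (from > hi) break
      ids <- from - 1L + which(st_sc[from:hi] == level)
      for (id in ids) process_one(id)
      from <- hi + 1L
      if (capped) break
    }
    level <- level + 1L
  }
  if (!is.null(counters)) {
    counters$lf <- counters$lf + lf
    counters$expansions <- counters$expansions + expansions
  }
  ops_of <- function(id) {
    ops <- integer(0)
    while (id != 1L) {              # stop at root (state 1)
      ops <- c(ops, st_op[id])
      id <- st_par[id]
    }
    ops                             # leaf-to-root == read left-to-right
  }
  list(comp = comp, best = best,
       score = st_sc, l = st_l, u = st_u,
       nmm = st_nmm, ngo = st_ngo, nge = st_nge,
       ops_of = ops_of)
}

#' k-difference inexact search
#'
#' Backtracking extension of backward search over both strands, pruned by
#' the per-prefix difference lower bound, the difference budget, the seed
#' constraint and the explored-state cap.  Returns all minimum-score hits
#' (up to `max_hits_reported`), deterministically ordered (ascending
#' reference position, forward strand first).  An exhausted budget or state
#' cap yields an empty hit set, not an error.
#'
#' @param index a [index_reference()] object.
#' @param read record or bases string (already truncated).
#' @param params a [search_params()] object.
#' @param bound optional list with per-strand difference lower bounds
#'   (`fwd`, `rev`); when `NULL` they are computed from the
#'   reversed-reference index.  Zero vectors disable the pruning.
#' @param counters optional instrumentation environment.
#' @return a hits `data.frame`; attributes `best_score` (penalty of the
#'   reported hits, `Inf` when unmapped) and `competitor` (whether a
#'   completed alignment exists within one mismatch penalty above the best).
#' @export
inexact_search <- function(index, read, params = search_params(),
                           bound = NULL, counters = NULL) {
  fwd <- index$fwd
  bases <- if (is.list(read)) read$bases else read
  q <- encode_dna(bases)
  n <- length(q)
  maxd <- resolve_max_diff(params, n)
  qr <- revcomp_codes(q)
  if (is.null(bound)) {
    bound <- list(fwd = compute_diff_bound(index$rev, q, counters),
                  rev = compute_diff_bound(index$rev, qr, counters))
  }
  res_f <- ksearch_strand(fwd, q, params, bound$fwd, maxd,
                          best_in = Inf, counters = counters)
  res_r <- ksearch_strand(fwd, qr, params, bound$rev, maxd,
                          best_in = res_f$best, counters = counters)
  best <- min(res_f$best, res_r$best)
  if (!is.finite(best)) {
    h <- empty_hits()
    attr(h, "best_score") <- Inf
    attr(h, "competitor") <- FALSE
    return(h)
  }
  cand <- list()
  competitor <- FALSE
  cidx <- 0L
  for (sr in list(list(res = res_f, strand = "+"),
                  list(res = res_r, strand = "-"))) {
    res <- sr$res
    for (id in res$comp) {
      sc <- res$score[id]
      if (sc > best && sc <= best + params$mismatch_pen) competitor <- TRUE
      if (sc != best) next
      ops <- res$ops_of(id)
      cig <- ops_to_cigar(ops)
      span <- cigar_ref_span(ops)
      iv <- list(low = res$l[id] - 1L, high = res$u[id])
      pos <- locate(fwd, iv, counters)
      cidx <- cidx + 1L
      cand[[length(cand) + 1L]] <-
        data.frame(gpos = pos, strand = sr$strand, score = sc,
                   nmm = res$nmm[id], ngo = res$ngo[id], nge = res$nge[id],
                   cigar = cig, span = span, isize = length(pos),
                   comp = cidx * 100000L + seq_along(pos),
                   stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, cand)
  hits <- finalize_hits(fwd, cand, params$max_hits_reported)
  attr(hits, "best_score") <- if (nrow(hits)) best else Inf
  attr(hits, "competitor") <- competitor
  hits
}

mapq_for <- function(hits, competitor) {
  if (nrow(hits) == 0L) return(0L)
  if (nrow(hits) >= 2L || hits$interval_size[1] >= 2L) return(0L)
  if (hits$score[1] > 0L && competitor) return(23L)
  37L
}

#' Align one read (pre-pass plus fallback)
#'
#' Applies the truncation rule, reports reads that are mostly `N` as
#' unmapped without searching, runs the exact pre-pass (when the variant is
#' enabled) and falls back to the k-difference search otherwise.  The
#' two-phase output is identical to running the fallback unconditionally;
#' the pre-pass only reduces the instrumented cost.
#'
#' MAPQ scheme (deterministic, documented): unique placement 37; unique
#' inexact placement with a completed competitor within one mismatch penalty
#' 23; ambiguous placement (2+ co-optimal positions) 0; unmapped 0.
#'
#' @param index a [index_reference()] object.
#' @param read a read record (`list(id=, bases=, quals=)`).
#' @param params a [search_params()] object.
#' @param variants a [kernel_variants()] list.
#' @return `list(hits=, mapq=, truncated=, fallback_used=, cost=)` where
#'   `cost` is the deterministic instrumented work (LF steps + expansions).
#' @export
align_read <- function(index, read, params = search_params(),
                       variants = kernel_variants()) {
  counters <- new_counters()
  tr <- truncate_read(read)
  rec <- tr$record
  q <- encode_dna(rec$bases)
  out <- list(id = rec$id, hits = empty_hits(), mapq = 0L,
              truncated = tr$truncated, fallback_used = FALSE, cost = 0)
  if (length(q) == 0L || mean(q == SYM_N) > 0.5) {
    return(out)
  }
  normalize <- function(h) {
    attr(h, "best_score") <- NULL
    attr(h, "competitor") <- NULL
    row.names(h) <- NULL
    h
  }
  if (variants$prepass) {
    pp <- exact_prepass(index, rec, params, counters)
    if (!pp$needs_fallback) {
      out$hits <- normalize(pp$hits)
      out$mapq <- mapq_for(pp$hits, competitor = FALSE)
      out$cost <- counters_total(counters)
      return(out)
    }
  }
  n <- length(q)
  bound <- if (variants$use_diff_bound) NULL else
    list(fwd = integer(n), rev = integer(n))
  hits <- inexact_search(index, rec, params, bound = bound,
                         counters = counters)
  out$hits <- normalize(hits)
  out$mapq <- mapq_for(hits, isTRUE(attr(hits, "competitor")))
  out$fallback_used <- TRUE
  out$cost <- counters_total(counters)
  out
}

#' Align a batch of reads
#'
#' The `aln` stage: applies [align_read()] to each record in order.
#'
#' @param index a [index_reference()] object.
#' @param reads list of read records.
#' @inheritParams align_read
#' @return list of per-read [align_read()] results, in input order.
#' @export
aln <- function(index, reads, params = search_params(),
                variants = kernel_variants()) {
  lapply(reads, function(r) align_read(index, r, params, variants))
}
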