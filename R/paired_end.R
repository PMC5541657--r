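# Combine per-end hit streams into paired SAM: estimate the insert-size
# distribution from confident unique pairs, choose the best consistent
# combination per pair, and emit cross-consistent mate records.

#' Estimate the insert-size model from confident pairs
#'
#' Observed template lengths (leftmost start to rightmost end) from pairs
#' with the proper forward-reverse orientation are summarised after
#' discarding outliers beyond 3 interquartile ranges from the median.  The
#' standard deviation is the population sigma; acceptance bounds are
#' `mean +/- z * std`.
#'
#' @param pairs data.frame with columns `pos1`, `strand1`, `span1`, `pos2`,
#'   `strand2`, `span2` (0-based positions and reference spans of the two
#'   ends, same reference).
#' @param z half-width of the acceptance bounds in standard deviations.
#' @param default_mean,default_sd fallback model used (with a warning) when
#'   no confident pairs are available.
#' @return an `InsertModel`: `list(mean=, std=, n_used=, low=, high=)`.
#' @export
estimate_insert <- function(pairs, z = 4,
                            default_mean = 300, default_sd = 100) {
  model_from <- function(mean, std, n_used) {
    structure(list(mean = mean, std = std, n_used = n_used,
                   low = mean - z * std, high = mean + z * std),
              class = "InsertModel")
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no confident pairs; using default insert model", call. = FALSE)
    return(model_from(default_mean, default_sd, 0L))
  }
  left_fwd <- ifelse(pairs$pos1 <= pairs$pos2,
                     pairs$strand1 == "+" & pairs$strand2 == "-",
                     pairs$strand2 == "+" & pairs$strand1 == "-")
  t <- pmax(pairs$pos1 + pairs$span1, pairs$pos2 + pairs$span2) -
    pmin(pairs$pos1, pairs$pos2)
  t <- t[left_fwd]
  if (length(t) == 0L) {
    warning("no confident pairs; using default insert model", call. = FALSE)
    return(model_from(default_mean, default_sd, 0L))
  }
  med <- stats::median(t)
  iqr <- stats::IQR(t)
  keep <- abs(t - med) <= 3 * iqr
  t <- t[keep]
  m <- mean(t)
  s <- sqrt(mean((t - m)^2))            # population sigma
  model_from(m, s, length(t))
}

hit_ref_span <- function(hits) {
  vapply(hits$cigar, function(cg) cigar_lengths(cg)$ref, integer(1),
         USE.NAMES = FALSE)
}

#' Choose the best pairing of two hit lists
#'
#' Enumerates cross-combinations (each end capped at `max_occurrences`
#' placements) and selects the minimum combined-score proper pair --
#' forward-reverse orientation, leftmost end forward, template length
#' within the insert-model bounds.  If no combination is proper, the
#' independently best hits are paired with `proper = FALSE`.  Ties break on
#' lower end-1 position, then lower end-2 position.
#'
#' @param hits1,hits2 hit data.frames from [align_read()].
#' @param model an [estimate_insert()] model.
#' @param max_occurrences cap on placements considered per end.
#' @return `list(hit1=, hit2=, proper=, tlen=)`; `hit1`/`hit2` are one-row
#'   hit data.frames or `NULL` for an unmapped end; `tlen` is the observed
#'   template length (0 unless both ends map to the same reference).
#' @export
pair_hits <- function(hits1, hits2, model, max_occurrences = 64L) {
  n1 <- nrow(hits1)
  n2 <- nrow(hits2)
  if (n1 == 0L && n2 == 0L) {
    return(list(hit1 = NULL, hit2 = NULL, proper = FALSE, tlen = 0L))
  }
  if (n1 == 0L || n2 == 0L) {
    return(list(hit1 = if (n1) hits1[1, , drop = FALSE] else NULL,
                hit2 = if (n2) hits2[1, , drop = FALSE] else NULL,
                proper = FALSE, tlen = 0L))
  }
  h1 <- hits1[seq_len(min(n1, max_occurrences)), , drop = FALSE]
  h2 <- hits2[seq_len(min(n2, max_occurrences)), , drop = FALSE]
  span1 <- hit_ref_span(h1)
  span2 <- hit_ref_span(h2)
  g <- expand.grid(i = seq_len(nrow(h1)), j = seq_len(nrow(h2)))
  same <- h1$refname[g$i] == h2$refname[g$j]
  p1 <- h1$pos[g$i]
  p2 <- h2$pos[g$j]
  tl <- pmax(p1 + span1[g$i], p2 + span2[g$j]) - pmin(p1, p2)
  fr <- ifelse(p1 <= p2,
               h1$strand[g$i] == "+" & h2$strand[g$j] == "-",
               h2$strand[g$j] == "+" & h1$strand[g$i] == "-")
  proper <- same & fr & tl >= model$low & tl <= model$high
  pick_tlen <- 0L
  if (any(proper)) {
    sc <- h1$score[g$i] + h2$score[g$j]
    cand <- which(proper)
    cand <- cand[order(sc[cand], p1[cand], p2[cand])]
    k <- cand[1]
    i <- g$i[k]; j <- g$j[k]
    pick_proper <- TRUE
    pick_tlen <- tl[k]
  } else {
    i <- 1L; j <- 1L
    pick_proper <- FALSE
    if (h1$refname[1] == h2$refname[1]) {
      pick_tlen <- pmax(h1$pos[1] + span1[1], h2$pos[1] + span2[1]) -
        pmin(h1$pos[1], h2$pos[1])
    }
  }
  list(hit1 = h1[i, , drop = FALSE], hit2 = h2[j, , drop = FALSE],
       proper = pick_proper, tlen = as.integer(pick_tlen))
}

# the kernel aligns at most the first 150 bases; reported SEQ/QUAL must
# match the aligned (possibly truncated) read
apply_truncation <- function(read, hit_record) {
  if (isTRUE(hit_record$truncated)) {
    read$bases <- substr(read$bases, 1L, READ_LENGTH_LIMIT)
    if (!is.null(read$quals)) {
      read$quals <- substr(read$quals, 1L, READ_LENGTH_LIMIT)
    }
  }
  read
}

nm_of <- function(hit) {
  cg <- hit$cigar
  n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  op <- regmatches(cg, gregexpr("[MID]", cg))[[1]]
  hit$n_mismatch + sum(n[op %in% c("I", "D")])
}

strip_end_suffix <- function(id) sub("/[12]$", "", id)

pair_record <- function(qname, read, hit, mapq, end, mate_hit, proper,
                        tlen_signed) {
  fl <- SAM_FLAGS[["PAIRED"]] +
    if (end == 1L) SAM_FLAGS[["FIRST_IN_PAIR"]] else SAM_FLAGS[["SECOND_IN_PAIR"]]
  mapped <- !is.null(hit)
  mate_mapped <- !is.null(mate_hit)
  if (!mapped) fl <- fl + SAM_FLAGS[["UNMAPPED"]]
  if (!mate_mapped) fl <- fl + SAM_FLAGS[["MATE_UNMAPPED"]]
  if (mapped && hit$strand == "-") fl <- fl + SAM_FLAGS[["REVERSE"]]
  if (mate_mapped && mate_hit$strand == "-") fl <- fl + SAM_FLAGS[["MATE_REVERSE"]]
  if (proper) fl <- fl + SAM_FLAGS[["PROPER_PAIR"]]
  seq <- read$bases
  qual <- if (is.null(read$quals)) "*" else read$quals
  if (mapped && hit$strand == "-") {
    seq <- revcomp(seq)
    qual <- if (identical(qual, "*")) "*" else reverse_string(qual)
  }
  rname <- "*"; pos <- 0L; cigar <- "*"; tags <- character(0)
  if (mapped) {
    rname <- hit$refname
    pos <- hit$pos + 1L
    cigar <- hit$cigar
    tags <- sprintf("NM:i:%d", nm_of(hit))
  } else if (mate_mapped) {
    # SAM convention: place the unmapped read at its mate
    rname <- mate_hit$refname
    pos <- mate_hit$pos + 1L
  }
  rnext <- "*"; pnext <- 0L
  if (mate_mapped) {
    rnext <- if (mapped && mate_hit$refname == hit$refname) "=" else mate_hit$refname
    pnext <- mate_hit$pos + 1L
  } else if (mapped) {
    rnext <- "="                        # mate placed at this record
    pnext <- pos
  }
  sam_record(qname = qname, flag = fl, rname = rname, pos = pos,
             mapq = if (mapped) mapq else 0L, cigar = cigar,
             rnext = rnext, pnext = pnext,
             tlen = if (mapped && mate_mapped &&
                        hit$refname == mate_hit$refname) tlen_signed else 0L,
             seq = seq, qual = qual, tags = tags)
}

#' Combine paired-end hit streams into SAM records
#'
#' The `sampe` stage: reads the two per-end hit streams and the two FASTQ
#' streams (which must agree in count and order), fits the insert model
#' from confident unique pairs, selects the best consistent combination for
#' each pair and emits two cross-consistent SAM records per pair, in input
#' order.
#'
#' @param hits1,hits2 lists of per-read hit records (elements `id`, `hits`,
#'   `mapq`), as produced by [aln()] or [read_hits()]`$records`.
#' @param reads1,reads2 lists of read records.
#' @param mapq_conf minimum per-end MAPQ for a pair to inform the insert
#'   model.
#' @param z insert acceptance half-width, in standard deviations.
#' @param default_mean,default_sd fallback insert model.
#' @param max_occurrences pairing cap per end.
#' @return list of [sam_record()]s (two per pair); the fitted
#'   [estimate_insert()] model is attached as attribute `insert_model`.
#' @export
sampe <- function(hits1, hits2, reads1, reads2, mapq_conf = 20L, z = 4,
                  default_mean = 300, default_sd = 100,
                  max_occurrences = 64L) {
  n <- length(reads1)
  if (length(reads2) != n || length(hits1) != n || length(hits2) != n) {
    stop("sampe consistency error: stream lengths differ (reads1 ", n,
         ", reads2 ", length(reads2), ", hits1 ", length(hits1),
         ", hits2 ", length(hits2), ")", call. = FALSE)
  }
  for (k in seq_len(n)) {
    if (strip_end_suffix(hits1[[k]]$id) != strip_end_suffix(reads1[[k]]$id) ||
        strip_end_suffix(hits2[[k]]$id) != strip_end_suffix(reads2[[k]]$id)) {
      stop("sampe consistency error: hit/read id mismatch at pair ", k,
           " ('", hits1[[k]]$id, "' vs '", reads1[[k]]$id, "')",
           call. = FALSE)
    }
  }
  # pass 1: confident unique pairs -> insert model
  conf <- lapply(seq_len(n), function(k) {
    h1 <- hits1[[k]]; h2 <- hits2[[k]]
    if (nrow(h1$hits) != 1L || nrow(h2$hits) != 1L) return(NULL)
    if (h1$mapq < mapq_conf || h2$mapq < mapq_conf) return(NULL)
    if (h1$hits$refname != h2$hits$refname) return(NULL)
    data.frame(pos1 = h1$hits$pos, strand1 = h1$hits$strand,
               span1 = hit_ref_span(h1$hits),
               pos2 = h2$hits$pos, strand2 = h2$hits$strand,
               span2 = hit_ref_span(h2$hits), stringsAsFactors = FALSE)
  })
  conf <- do.call(rbind, conf)
  model <- estimate_insert(conf, z = z, default_mean = default_mean,
                           default_sd = default_sd)
  # pass 2: pair and emit
  out <- vector("list", 2L * n)
  for (k in seq_len(n)) {
    pr <- pair_hits(hits1[[k]]$hits, hits2[[k]]$hits, model,
                    max_occurrences = max_occurrences)
    qname <- strip_end_suffix(reads1[[k]]$id)
    t <- pr$tlen
    t1 <- t2 <- 0L
    if (t != 0L && !is.null(pr$hit1) && !is.null(pr$hit2)) {
      if (pr$hit1$pos <= pr$hit2$pos) {
        t1 <- t; t2 <- -t
      } else {
        t1 <- -t; t2 <- t
      }
    }
    out[[2L * k - 1L]] <- pair_record(qname,
                                      apply_truncation(reads1[[k]], hits1[[k]]),
                                      pr$hit1, hits1[[k]]$mapq, 1L, pr$hit2,
                                      pr$proper, t1)
    out[[2L * k]] <- pair_record(qname,
                                 apply_truncation(reads2[[k]], hits2[[k]]),
                                 pr$hit2, hits2[[k]]$mapq, 2L, pr$hit1,
                                 pr$proper, t2)
  }
  attr(out, "insert_model") <- model
  out
}

#' Single-end SAM convenience wrapper
#'
#' @param hits list of per-read hit records (`id`, `hits`, `mapq`).
#' @param reads list of read records.
#' @return list of [sam_record()]s, one per read.
#' @export
samse <- function(hits, reads) {
  n <- length(reads)
  if (length(hits) != n) {
    stop("samse consistency error: stream lengths differ", call. = FALSE)
  }
  lapply(seq_len(n), function(k) {
    h <- hits[[k]]
    r <- apply_truncation(reads[[k]], h)
    if (nrow(h$hits) == 0L) {
      return(sam_record(qname = r$id, flag = SAM_FLAGS[["UNMAPPED"]],
                        seq = r$bases,
                        qual = if (is.null(r$quals)) "*" else r$quals))
    }
    hit <- h$hits[1, , drop = FALSE]
    rev <- hit$strand == "-"
    sam_record(qname = r$id,
               flag = if (rev) SAM_FLAGS[["REVERSE"]] else 0L,
               rname = hit$refname, pos = hit$pos + 1L, mapq = h$mapq,
               cigar = hit$cigar,
               seq = if (rev) revcomp(r$bases) else r$bases,
               qual = if (is.null(r$quals)) "*" else
                 if (rev) reverse_string(r$quals) else r$quals,
               tags = sprintf("NM:i:%d", nm_of(hit)))
  })
}
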