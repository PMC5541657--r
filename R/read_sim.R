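# Synthetic data: genomes, donor variants (SNPs, 1-3 bp indels), paired-end
# reads with sequencing errors, duplicate pairs, and ground-truth records on
# the original reference coordinate frame, plus the mapped-%/accuracy-%
# scorer that consumes SAM output against that truth.

#' Simulation configuration
#'
#' Emulates the short-insert paired-end regimes the aligner targets (36 bp
#' and 100 bp ends).  Rates are per base; `dup_frac` is the fraction of
#' emitted pairs that are re-emissions of an earlier fragment (with fresh
#' sequencing errors and distinct ids), mirroring the few-percent duplicate
#' fraction typical of real short-read runs.
#'
#' @param genome_len genome length, bases.
#' @param gc GC fraction of the simulated genome.
#' @param read_len read length per end (e.g. 36 or 100).
#' @param n_pairs number of pairs emitted (duplicates included).
#' @param insert_mean,insert_std insert (template) length distribution, bases.
#' @param snp_rate,indel_rate donor variant rates per base.
#' @param err_rate per-base sequencing error rate.
#' @param dup_frac duplicated-pair fraction of emitted pairs.
#' @param rng_seed seed controlling all randomness of the simulator.
#' @param repeat_blocks,repeat_unit,repeat_copies optional planted tandem
#'   repeats (count of blocks, unit length, copies per block) to exercise
#'   repeat ambiguity.
#' @return validated `SimConfig` list.
#' @export
sim_config <- function(genome_len = 100000L, gc = 0.5, read_len = 36L,
                       n_pairs = 2000L, insert_mean = 300, insert_std = 30,
                       snp_rate = 0, indel_rate = 0, err_rate = 0,
                       dup_frac = 0, rng_seed = 1L,
                       repeat_blocks = 0L, repeat_unit = 0L,
                       repeat_copies = 0L) {
  cfg <- list(genome_len = as.integer(genome_len), gc = gc,
              read_len = as.integer(read_len), n_pairs = as.integer(n_pairs),
              insert_mean = insert_mean, insert_std = insert_std,
              snp_rate = snp_rate, indel_rate = indel_rate,
              err_rate = err_rate, dup_frac = dup_frac,
              rng_seed = as.integer(rng_seed),
              repeat_blocks = as.integer(repeat_blocks),
              repeat_unit = as.integer(repeat_unit),
              repeat_copies = as.integer(repeat_copies))
  rates <- c(cfg$gc, cfg$snp_rate, cfg$indel_rate, cfg$err_rate, cfg$dup_frac)
  if (any(rates < 0 | rates > 1)) {
    stop("sim_config: rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$read_len > cfg$insert_mean) {
    stop("sim_config: read_len must not exceed insert_mean", call. = FALSE)
  }
  if (cfg$genome_len <= cfg$insert_mean + 4 * cfg$insert_std) {
    stop("sim_config: genome_len must exceed insert_mean + 4*insert_std",
         call. = FALSE)
  }
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a reference genome
#'
#' I.i.d. bases at the configured GC fraction; optional tandem-repeat
#' blocks are stamped over the sequence (length-preserving) to create
#' ambiguous placements.  Fully determined by `rng_seed`.
#'
#' @param config a [sim_config()].
#' @param name reference name.
#' @return a reference record `list(name=, seq=)`.
#' @export
simulate_genome <- function(config, name = "simref") {
  set.seed(config$rng_seed)
  p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
         (1 - config$gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), config$genome_len, replace = TRUE,
                  prob = p)
  if (config$repeat_blocks > 0L && config$repeat_unit > 0L &&
      config$repeat_copies > 1L) {
    blk <- config$repeat_unit * config$repeat_copies
    for (b in seq_len(config$repeat_blocks)) {
      unit <- sample(c("A", "C", "G", "T"), config$repeat_unit,
                     replace = TRUE, prob = p)
      at <- sample.int(config$genome_len - blk + 1L, 1L)
      bases[at:(at + blk - 1L)] <- rep(unit, config$repeat_copies)
    }
  }
  list(name = name, seq = paste(bases, collapse = ""))
}

# Plant SNPs and 1-3 bp indels into the reference, returning the donor
# sequence, a donor->reference coordinate map (0-based; inserted bases take
# the coordinate of the leftmost unaffected reference base), and a logical
# mask of donor positions touched by a variant.
make_donor <- function(ref_bases, snp_rate, indel_rate) {
  n <- length(ref_bases)
  donor <- ref_bases
  affected <- logical(n)
  if (snp_rate > 0) {
    at <- which(stats::runif(n) < snp_rate)
    if (length(at)) {
      alt <- vapply(donor[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1), USE.NAMES = FALSE)
      donor[at] <- alt
      affected[at] <- TRUE
    }
  }
  dmap <- seq_len(n) - 1L
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    ev <- ev[ev > 3L & ev < n - 3L]
    if (length(ev)) {
      ins <- stats::runif(length(ev)) < 0.5
      lens <- sample(1:3, length(ev), replace = TRUE)
      pieces_seq <- list()
      pieces_map <- list()
      pieces_aff <- list()
      prev <- 1L
      for (k in seq_along(ev)) {
        p <- max(ev[k], prev)
        if (p > n - 3L) next
        pieces_seq[[length(pieces_seq) + 1L]] <- donor[prev:p]
        pieces_map[[length(pieces_map) + 1L]] <- dmap[prev:p]
        pieces_aff[[length(pieces_aff) + 1L]] <- affected[prev:p]
        if (ins[k]) {
          newb <- sample(c("A", "C", "G", "T"), lens[k], replace = TRUE)
          pieces_seq[[length(pieces_seq) + 1L]] <- newb
          pieces_map[[length(pieces_map) + 1L]] <- rep(dmap[p], lens[k])
          pieces_aff[[length(pieces_aff) + 1L]] <- rep(TRUE, lens[k])
          prev <- p + 1L
        } else {
          prev <- min(p + lens[k], n) + 1L   # skip deleted reference bases
        }
        if (prev > n) break
      }
      if (prev <= n) {
        pieces_seq[[length(pieces_seq) + 1L]] <- donor[prev:n]
        pieces_map[[length(pieces_map) + 1L]] <- dmap[prev:n]
        pieces_aff[[length(pieces_aff) + 1L]] <- affected[prev:n]
      }
      donor <- unlist(pieces_seq, use.names = FALSE)
      dmap <- unlist(pieces_map, use.names = FALSE)
      affected <- unlist(pieces_aff, use.names = FALSE)
      # mark the donor base right after each deletion as variant-adjacent
      gap <- c(FALSE, diff(dmap) > 1L)
      affected <- affected | gap
    }
  }
  list(donor = donor, dmap = dmap, affected = affected)
}

#' Simulate paired-end reads with ground truth
#'
#' A donor genome is derived from the reference by planting SNPs and 1-3 bp
#' indels; fragments are drawn with insert length
#' `Normal(insert_mean, insert_std)` truncated to at least `read_len`.
#' End 1 is the forward strand at the fragment start; end 2 is the reverse
#' complement of the fragment end (FR orientation).  Sequencing errors are
#' substituted per base at `err_rate` (quality downgraded at errored
#' positions); a `dup_frac` fraction of emitted pairs are duplicates of
#' earlier fragments with fresh errors and distinct ids.  Truth positions
#' are on the original reference frame.
#'
#' @param genome a reference record from [simulate_genome()] (or any
#'   `list(name=, seq=)`).
#' @param config a [sim_config()].
#' @return `list(reads1=, reads2=, truth=)`; `truth` is a data.frame with
#'   one row per read (`read_id`, `refname`, `true_pos` 0-based, `strand`,
#'   `end`, `n_planted_errors`, `is_duplicate`).
#' @export
simulate_reads <- function(genome, config) {
  set.seed(config$rng_seed + 1L)
  rl <- config$read_len
  ref_bases <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  dn <- make_donor(ref_bases, config$snp_rate, config$indel_rate)
  donor <- paste(dn$donor, collapse = "")
  dlen <- length(dn$donor)
  n_dup <- round(config$n_pairs * config$dup_frac)
  n_uni <- config$n_pairs - n_dup
  ins <- pmax(rl, pmin(dlen, round(stats::rnorm(n_uni, config$insert_mean,
                                                config$insert_std))))
  start <- vapply(ins, function(i) sample.int(dlen - i + 1L, 1L), integer(1))
  src <- seq_len(n_uni)
  if (n_dup > 0L) {
    dup_of <- sample.int(n_uni, n_dup, replace = TRUE)
    src <- c(src, dup_of)
  }
  is_dup <- c(rep(FALSE, n_uni), rep(TRUE, n_dup))
  s <- start[src]
  iv <- ins[src]
  e2s <- s + iv - rl                       # donor start of end 2 segment
  raw1 <- substring(donor, s, s + rl - 1L)
  raw2 <- vapply(substring(donor, e2s, e2s + rl - 1L), revcomp, character(1),
                 USE.NAMES = FALSE)
  ids <- sprintf("sim%06d", src)
  if (n_dup > 0L) {
    ids[is_dup] <- sprintf("%s_dup%d", ids[is_dup], seq_len(n_dup))
  }
  add_errors <- function(seqs) {
    n <- length(seqs)
    nerr <- integer(n)
    quals <- strrep("I", rl)
    quals <- rep(quals, n)
    if (config$err_rate > 0) {
      for (k in seq_len(n)) {
        at <- which(stats::runif(rl) < config$err_rate)
        if (length(at)) {
          ch <- strsplit(seqs[k], "", fixed = TRUE)[[1]]
          qv <- rep("I", rl)
          for (p in at) {
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
            qv[p] <- "#"
          }
          seqs[k] <- paste(ch, collapse = "")
          quals[k] <- paste(qv, collapse = "")
          nerr[k] <- length(at)
        }
      }
    }
    list(seqs = seqs, quals = quals, nerr = nerr)
  }
  er1 <- add_errors(raw1)
  er2 <- add_errors(raw2)
  # planted variants overlapping each read's donor interval
  aff_cum <- c(0L, cumsum(dn$affected))
  nvar <- function(from, to) aff_cum[to + 1L] - aff_cum[from]
  reads1 <- mapply(function(id, sq, qu) {
    list(id = paste0(id, "/1"), bases = sq, quals = qu)
  }, ids, er1$seqs, er1$quals, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  reads2 <- mapply(function(id, sq, qu) {
    list(id = paste0(id, "/2"), bases = sq, quals = qu)
  }, ids, er2$seqs, er2$quals, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  truth <- rbind(
    data.frame(read_id = paste0(ids, "/1"), refname = genome$name,
               true_pos = dn$dmap[s], strand = "+", end = 1L,
               n_planted_errors = er1$nerr + nvar(s, s + rl - 1L),
               is_duplicate = is_dup, stringsAsFactors = FALSE),
    data.frame(read_id = paste0(ids, "/2"), refname = genome$name,
               true_pos = dn$dmap[e2s], strand = "-", end = 2L,
               n_planted_errors = er2$nerr + nvar(e2s, e2s + rl - 1L),
               is_duplicate = is_dup, stringsAsFactors = FALSE))
  list(reads1 = reads1, reads2 = reads2, truth = truth)
}

#' Write a truth table
#' @param truth data.frame from [simulate_reads()].
#' @param file destination path or connection.
#' @export
write_truth <- function(truth, file) {
  utils::write.table(truth, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Score alignments against simulator truth
#'
#' `mapped_pct` is the percentage of truth reads with a mapped primary
#' record; `accuracy_pct` is the percentage of mapped reads whose reference
#' name and strand match the truth and whose leftmost position is within
#' `tolerance` bases of the true position (indels shift alignments, hence
#' the slack window).  A per-class breakdown by planted-error count and
#' duplicate status is included.
#'
#' @param sam SAM records as a data.frame ([read_sam()]) or a path.
#' @param truth truth data.frame from [simulate_reads()].
#' @param tolerance positional slack in bases.
#' @return `list(mapped_pct=, accuracy_pct=, n_reads=, n_mapped=,
#'   n_correct=, by_errors=, by_duplicate=)`.
#' @export
evaluate_alignments <- function(sam, truth, tolerance = 5L) {
  if (is.character(sam)) sam <- read_sam(sam)
  end <- ifelse(bitwAnd(sam$flag, SAM_FLAGS[["SECOND_IN_PAIR"]]) > 0L, 2L,
                ifelse(bitwAnd(sam$flag, SAM_FLAGS[["FIRST_IN_PAIR"]]) > 0L,
                       1L, 1L))
  paired <- bitwAnd(sam$flag, SAM_FLAGS[["PAIRED"]]) > 0L
  key <- ifelse(paired, paste0(sam$qname, "/", end), sam$qname)
  if (anyDuplicated(key)) {
    stop("evaluate_alignments: duplicate primary records in SAM",
         call. = FALSE)
  }
  idx <- match(truth$read_id, key)
  if (anyNA(idx)) {
    stop("evaluate_alignments: truth read '",
         truth$read_id[which(is.na(idx))[1]], "' missing from SAM",
         call. = FALSE)
  }
  sam <- sam[idx, , drop = FALSE]
  mapped <- bitwAnd(sam$flag, SAM_FLAGS[["UNMAPPED"]]) == 0L
  strand <- ifelse(bitwAnd(sam$flag, SAM_FLAGS[["REVERSE"]]) > 0L, "-", "+")
  correct <- mapped &
    sam$rname == truth$refname &
    strand == truth$strand &
    abs((sam$pos - 1L) - truth$true_pos) <= tolerance
  n <- nrow(truth)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  by_cls <- function(cls) {
    do.call(rbind, lapply(sort(unique(cls)), function(v) {
      sel <- cls == v
      data.frame(class = v, n = sum(sel),
                 mapped_pct = pct(sum(mapped[sel]), sum(sel)),
                 accuracy_pct = pct(sum(correct[sel]), sum(mapped[sel])))
    }))
  }
  list(mapped_pct = pct(sum(mapped), n),
       accuracy_pct = pct(sum(correct), sum(mapped)),
       n_reads = n, n_mapped = sum(mapped), n_correct = sum(correct),
       by_errors = by_cls(truth$n_planted_errors),
       by_duplicate = by_cls(truth$is_duplicate))
}
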