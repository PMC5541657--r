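mkhits <- function(pos, strand, score = 0L, refname = "g", len = 36L) {
  data.frame(refname = refname, pos = as.integer(pos), strand = strand,
             score = as.integer(score), n_mismatch = 0L, n_gap_open = 0L,
             n_gap_ext = 0L, cigar = sprintf("%dM", len),
             interval_size = 1L, stringsAsFactors = FALSE)
}

test_that("insert estimation matches direct arithmetic", {
  one <- data.frame(pos1 = 0L, strand1 = "+", span1 = 36L,
                    pos2 = 164L, strand2 = "-", span2 = 36L)
  m <- estimate_insert(one)
  expect_equal(m$mean, 200)
  expect_equal(m$std, 0)
  expect_equal(m$n_used, 1L)

  three <- data.frame(pos1 = c(0, 10, 20), strand1 = "+", span1 = 36L,
                      pos2 = c(154, 174, 194), strand2 = "-", span2 = 36L)
  m <- estimate_insert(three)
  expect_equal(m$mean, 200)
  expect_equal(m$std, sqrt(mean((c(190, 200, 210) - 200)^2)),
               tolerance = 1e-9)
  expect_equal(m$low, m$mean - 4 * m$std)
  expect_equal(m$high, m$mean + 4 * m$std)

  expect_warning(m <- estimate_insert(NULL, default_mean = 250,
                                      default_sd = 40), "default")
  expect_equal(m$mean, 250)
  expect_equal(m$n_used, 0L)
})

test_that("gross outliers beyond 3 IQR from the median are discarded", {
  tl <- c(rep(200L, 10L), rep(210L, 10L), 5000L)
  pairs <- data.frame(pos1 = 0L, strand1 = "+", span1 = 36L,
                      pos2 = tl - 36L, strand2 = "-", span2 = 36L)
  m <- estimate_insert(pairs)
  expect_equal(m$n_used, 20L)
  expect_equal(m$mean, 205)
})

test_that("insert model recovers simulator parameters", {
  cfg <- sim_config(genome_len = 20000L, read_len = 36L, n_pairs = 300L,
                    insert_mean = 300, insert_std = 30, rng_seed = 4L)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(g, cfg)
  t1 <- sim$truth[sim$truth$end == 1L, ]
  t2 <- sim$truth[sim$truth$end == 2L, ]
  pairs <- data.frame(pos1 = t1$true_pos, strand1 = t1$strand, span1 = 36L,
                      pos2 = t2$true_pos, strand2 = t2$strand, span2 = 36L)
  m <- estimate_insert(pairs)
  expect_lt(abs(m$mean - 300), 5)
  expect_lt(abs(m$std - 30), 5)
})

test_that("pair selection equals exhaustive enumeration on small instances", {
  model <- structure(list(mean = 300, std = 30, n_used = 10,
                          low = 180, high = 420), class = "InsertModel")
  # unique proper FR pair at distance 300
  pr <- pair_hits(mkhits(1000L, "+"), mkhits(1264L, "-"), model)
  expect_true(pr$proper)
  expect_equal(pr$tlen, 300L)
  # ends on different references are never proper
  pr <- pair_hits(mkhits(10L, "+", refname = "a"),
                  mkhits(300L, "-", refname = "b"), model)
  expect_false(pr$proper)
  # only one of two placements is insert-consistent
  h1 <- rbind(mkhits(500L, "+"), mkhits(5000L, "+"))
  h2 <- mkhits(5300L - 36L, "-")
  pr <- pair_hits(h1, h2, model)
  expect_true(pr$proper)
  expect_equal(pr$hit1$pos, 5000L)
  # exhaustive check over all combinations (4 x 4, scores vary)
  set.seed(9)
  h1 <- mkhits(c(100L, 400L, 700L, 4000L), "+", score = c(3L, 0L, 3L, 6L))
  h2 <- mkhits(c(364L, 664L, 964L, 7000L), "-", score = c(0L, 3L, 6L, 0L))
  pr <- pair_hits(h1, h2, model)
  span <- 36L
  best <- NULL
  for (i in 1:4) for (j in 1:4) {
    tl <- max(h1$pos[i] + span, h2$pos[j] + span) - min(h1$pos[i], h2$pos[j])
    proper <- h1$pos[i] <= h2$pos[j] && tl >= model$low && tl <= model$high
    if (!proper) next
    key <- c(h1$score[i] + h2$score[j], h1$pos[i], h2$pos[j])
    if (is.null(best) || key[1] < best$key[1] ||
        (key[1] == best$key[1] && (key[2] < best$key[2] ||
         (key[2] == best$key[2] && key[3] < best$key[3])))) {
      best <- list(key = key, i = i, j = j)
    }
  }
  expect_equal(pr$hit1$pos, h1$pos[best$i])
  expect_equal(pr$hit2$pos, h2$pos[best$j])
  # both ends unmapped
  pr <- pair_hits(gibarra:::empty_hits(), gibarra:::empty_hits(), model)
  expect_false(pr$proper)
  expect_null(pr$hit1)
})

test_that("sampe emits cross-consistent flags, mates and template lengths", {
  set.seed(17)
  cfg <- sim_config(genome_len = 30000L, read_len = 36L, n_pairs = 40L,
                    insert_mean = 300, insert_std = 30, rng_seed = 17L)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(g, cfg)
  idx <- index_reference(list(g))
  res1 <- aln(idx, sim$reads1)
  res2 <- aln(idx, sim$reads2)
  recs <- sampe(res1, res2, sim$reads1, sim$reads2)
  expect_length(recs, 80L)
  df <- sam_df_of(recs, list(g))
  f1 <- df$flag[seq(1, 80, 2)]
  f2 <- df$flag[seq(2, 80, 2)]
  # error-free unique FR pairs give the canonical 99/147 flag pair
  expect_true(all(f1 == 99L))
  expect_true(all(f2 == 147L))
  expect_equal(df$tlen[seq(1, 80, 2)], -df$tlen[seq(2, 80, 2)])
  expect_true(all(df$rnext[df$flag %in% c(99L, 147L)] == "="))
  # record order matches input order
  expect_equal(unique(df$qname), sub("/1$", "", sapply(sim$reads1, `[[`, "id")))
})

test_that("an unmapped end is placed at its mate per SAM convention", {
  g <- list(name = "g", seq = random_genome_string(2000, seed = 23))
  idx <- index_reference(list(g))
  r1 <- read_of(substr(g$seq, 501, 536), "p/1")
  r2 <- read_of(strrep("N", 36L), "p/2")       # unalignable
  res1 <- aln(idx, list(r1))
  res2 <- aln(idx, list(r2))
  # a single pair with an unmapped end cannot inform the insert model
  expect_warning(recs <- sampe(res1, res2, list(r1), list(r2)),
                 "default insert model")
  df <- sam_df_of(recs, list(g))
  expect_equal(bitwAnd(df$flag[1], 8L), 8L)     # mate unmapped
  expect_equal(bitwAnd(df$flag[2], 4L), 4L)     # unmapped
  expect_equal(df$rname[2], "g")
  expect_equal(df$pos[2], df$pos[1])            # placed at the mate
  expect_equal(df$tlen, c(0L, 0L))
})

test_that("sampe rejects streams that disagree in length or ids", {
  g <- list(name = "g", seq = random_genome_string(1000, seed = 29))
  idx <- index_reference(list(g))
  r1 <- read_of(substr(g$seq, 11, 46), "a/1")
  r2 <- read_of(substr(g$seq, 211, 246), "a/2")
  res1 <- aln(idx, list(r1))
  res2 <- aln(idx, list(r2))
  expect_error(sampe(res1, res2, list(r1), list()), "stream lengths")
  wrong <- r2
  wrong$id <- "b/2"
  expect_error(sampe(res1, res2, list(r1), list(wrong)), "id mismatch")
})

test_that("piped and file-based hit streams give identical SAM", {
  set.seed(37)
  cfg <- sim_config(genome_len = 20000L, read_len = 36L, n_pairs = 25L,
                    err_rate = 0.01, rng_seed = 37L)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(g, cfg)
  idx <- index_reference(list(g))
  res1 <- aln(idx, sim$reads1)
  res2 <- aln(idx, sim$reads2)
  t1 <- tempfile(); t2 <- tempfile()
  write_hits(res1, t1, checksum = idx$fwd$checksum)
  write_hits(res2, t2, checksum = idx$fwd$checksum)
  from_file <- sampe(read_hits(t1)$records, read_hits(t2)$records,
                     sim$reads1, sim$reads2)
  from_pipe <- sampe(read_hits(pipe(paste("cat", shQuote(t1))))$records,
                     read_hits(pipe(paste("cat", shQuote(t2))))$records,
                     sim$reads1, sim$reads2)
  s1 <- sam_df_of(from_file, list(g))
  s2 <- sam_df_of(from_pipe, list(g))
  expect_identical(s1, s2)
  # and both agree with pairing the in-memory results directly
  s0 <- sam_df_of(sampe(res1, res2, sim$reads1, sim$reads2), list(g))
  expect_identical(s0, s1)
  unlink(c(t1, t2))
})
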