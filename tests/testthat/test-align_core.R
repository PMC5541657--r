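test_that("reads over 150 bp are truncated with exactly one warning", {
  r150 <- read_of(strrep("ACGTA", 30L))          # 150 bp
  expect_silent(tr <- truncate_read(r150))
  expect_false(tr$truncated)
  expect_equal(tr$record, r150)

  r151 <- read_of(paste0(strrep("ACGTA", 30L), "G"))
  w <- capture_warnings(tr <- truncate_read(r151))
  expect_length(w, 1L)
  expect_match(w, "151 bp")
  expect_true(tr$truncated)
  expect_equal(nchar(tr$record$bases), 150L)
  expect_equal(tr$record$bases, substr(r151$bases, 1, 150))
  expect_equal(nchar(tr$record$quals), 150L)

  expect_silent(tr <- truncate_read(read_of(strrep("A", 36L))))
  expect_false(tr$truncated)
})

test_that("difference lower bound is zero on exact prefixes and monotone", {
  set.seed(21)
  g <- random_genome_string(3000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  at <- sample(nchar(g) - 40L, 1L)
  exact <- substr(g, at, at + 35L)
  d <- compute_diff_bound(idx$rev, exact)
  expect_equal(d, integer(36))

  # absent trigram needs at least one difference on its last prefix
  gat <- index_reference(list(list(name = "t", seq = "GATTACA")))
  d <- compute_diff_bound(gat$rev, "TAG")
  expect_gte(d[3], 1L)

  # validity + monotonicity on random reads: d never exceeds the true
  # minimal difference count found by the search, and is non-decreasing
  for (k in 1:100) {
    at <- sample(nchar(g) - 60L, 1L)
    rd <- plant_read(g, at, 30L, sample(0:2, 1L))
    d <- compute_diff_bound(idx$rev, rd)
    expect_true(all(diff(d) >= 0L))
    h <- inexact_search(idx, rd, oracle_params(3L))
    if (nrow(h) > 0L && any(h$strand == "+")) {
      ndiff <- with(h[h$strand == "+", ][1, ],
                    n_mismatch + n_gap_open + n_gap_ext)
      expect_lte(d[length(d)], ndiff)
    }
  }
})

test_that("exact pre-pass handles clean reads and defers everything else", {
  set.seed(31)
  g <- random_genome_string(4000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  at <- sample(nchar(g) - 40L, 1L)
  exact <- substr(g, at, at + 35L)
  pp <- exact_prepass(idx, exact)
  expect_false(pp$needs_fallback)
  expect_equal(pp$hits$pos, at - 1L)
  expect_equal(pp$hits$score, 0L)
  expect_equal(pp$hits$cigar, "36M")
  # reverse complement maps to the same forward position, minus strand
  pp <- exact_prepass(idx, revcomp(exact))
  expect_equal(pp$hits$pos, at - 1L)
  expect_equal(pp$hits$strand, "-")

  mm <- exact
  substr(mm, 18, 18) <- setdiff(c("A", "C", "G", "T"),
                                substr(mm, 18, 18))[1]
  pp <- exact_prepass(idx, mm)
  expect_true(pp$needs_fallback)
  expect_equal(nrow(pp$hits), 0L)

  pp <- exact_prepass(idx, strrep("N", 36L))
  expect_true(pp$needs_fallback)
})

test_that("inexact search agrees with hand-checked and degenerate cases", {
  gat <- index_reference(list(list(name = "t", seq = "GATTACA")))
  h <- inexact_search(gat, "TAG", search_params(max_diff = 1L, seed_len = 0L,
                                                max_hits_reported = 50L))
  expect_equal(attr(h, "best_score"), 3L)
  fwd <- h[h$strand == "+", ]
  expect_equal(fwd$pos, 3L)
  expect_equal(fwd$n_mismatch, 1L)
  expect_equal(fwd$cigar, "3M")

  # max_diff = 0 degenerates to the exact pre-pass
  set.seed(41)
  g <- random_genome_string(3000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  p0 <- search_params(max_diff = 0L, seed_len = 0L)
  for (k in 1:20) {
    at <- sample(nchar(g) - 60L, 1L)
    rd <- plant_read(g, at, 36L, sample(0:1, 1L))
    h <- inexact_search(idx, rd, p0)
    pp <- exact_prepass(idx, rd, p0)
    expect_equal(h$pos, pp$hits$pos)
    expect_equal(h$strand, pp$hits$strand)
  }
})

test_that("inexact search hit sets equal the brute-force oracle on a small batch", {
  set.seed(51)
  g <- random_genome_string(2000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  p <- oracle_params(2L)
  for (k in 1:25) {
    at <- sample(nchar(g) - 60L, 1L)
    rd <- plant_read(g, at, 36L, sample(0:2, 1L))
    if (sample(c(TRUE, FALSE), 1L)) rd <- revcomp(rd)
    kh <- inexact_search(idx, rd, p)
    oh <- oracle_hits(g, rd, 2L)
    if (!is.finite(oh$best)) {
      expect_equal(nrow(kh), 0L)
    } else {
      expect_equal(attr(kh, "best_score"), oh$best)
      expect_setequal(paste(kh$pos, kh$strand),
                      paste(oh$hits$pos, oh$hits$strand))
    }
  }
})

test_that("align_read mapping qualities follow the documented scheme", {
  set.seed(61)
  g <- random_genome_string(4000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  at <- sample(nchar(g) - 40L, 1L)
  exact <- substr(g, at, at + 35L)
  a <- align_read(idx, read_of(exact))
  expect_equal(a$mapq, 37L)
  expect_equal(nrow(a$hits), 1L)

  # a perfect tandem repeat makes the placement ambiguous
  unit <- substr(g, 101, 150)
  rep_g <- paste0(substr(g, 1, 100), unit, unit, substr(g, 201, 2000))
  ridx <- index_reference(list(list(name = "r", seq = rep_g)))
  a <- align_read(ridx, read_of(substr(unit, 1, 36)))
  expect_gte(nrow(a$hits), 2L)
  expect_equal(a$mapq, 0L)

  # mostly-N reads are reported unmapped without searching
  a <- align_read(idx, read_of(paste0(strrep("N", 20L), substr(exact, 1, 16))))
  expect_equal(nrow(a$hits), 0L)
  expect_equal(a$mapq, 0L)
  expect_false(a$fallback_used)
})

test_that("align_read is deterministic and invariant to the 150 bp rule", {
  set.seed(71)
  g <- random_genome_string(4000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  at <- sample(nchar(g) - 200L, 1L)
  rd <- plant_read(g, at, 36L, 1L)
  a1 <- align_read(idx, read_of(rd))
  a2 <- align_read(idx, read_of(rd))
  expect_identical(a1, a2)

  # a 160 bp read aligns exactly like its first 150 bases
  long <- read_of(substr(g, at, at + 159L), id = "long")
  head150 <- read_of(substr(g, at, at + 149L), id = "long")
  al <- suppressWarnings(align_read(idx, long))
  ah <- align_read(idx, head150)
  expect_equal(al$hits, ah$hits)
  expect_equal(al$mapq, ah$mapq)
  expect_true(al$truncated)
})

test_that("raising max_diff keeps previously optimal placements at equal score", {
  set.seed(81)
  g <- random_genome_string(3000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  for (k in 1:10) {
    at <- sample(nchar(g) - 60L, 1L)
    rd <- plant_read(g, at, 36L, 1L, indel_ok = FALSE)
    h1 <- inexact_search(idx, rd, search_params(max_diff = 1L, seed_len = 0L))
    h2 <- inexact_search(idx, rd, search_params(max_diff = 2L, seed_len = 0L))
    if (nrow(h1) > 0L) {
      expect_equal(attr(h2, "best_score"), attr(h1, "best_score"))
      expect_true(all(paste(h1$pos, h1$strand) %in% paste(h2$pos, h2$strand)))
    }
  }
})

test_that("the seed constraint restricts differences in the first bases", {
  set.seed(91)
  g <- random_genome_string(3000)
  idx <- index_reference(list(list(name = "g", seq = g)))
  at <- sample(nchar(g) - 60L, 1L)
  rd <- substr(g, at, at + 35L)
  # plant two substitutions inside the first 16 bases
  for (p in c(4L, 9L)) {
    substr(rd, p, p) <- setdiff(c("A", "C", "G", "T"), substr(rd, p, p))[1]
  }
  loose <- inexact_search(idx, rd, search_params(seed_len = 0L))
  strict <- inexact_search(idx, rd, search_params(seed_len = 16L,
                                                  max_seed_diff = 1L))
  expect_true((at - 1L) %in% loose$pos)
  expect_false((at - 1L) %in% strict$pos)
})

test_that("auto difference budgets follow the read-length table", {
  p <- search_params()
  expect_equal(resolve_max_diff(p, 36L), 2L)
  expect_equal(resolve_max_diff(p, 63L), 2L)
  expect_equal(resolve_max_diff(p, 64L), 4L)
  expect_equal(resolve_max_diff(p, 100L), 4L)
  expect_equal(resolve_max_diff(p, 122L), 4L)
  expect_equal(resolve_max_diff(p, 123L), 5L)
  expect_equal(resolve_max_diff(p, 150L), 5L)
  expect_equal(resolve_max_diff(search_params(max_diff = 1L), 100L), 1L)
})
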