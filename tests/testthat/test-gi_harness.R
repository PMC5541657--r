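tiny_grammar <- function() {
  build_grammar(list(
    list(id = "prepass", kind = "code_variant", values = list(TRUE, FALSE),
         default = TRUE),
    list(id = "max_diff", kind = "parameter",
         values = list("auto", 0L, 1L), default = "auto"),
    list(id = "seed_len", kind = "parameter", values = list(0L, 32L),
         default = 32L)))
}

gi_fixture <- function(n_pairs = 60L, err = 0.01, seed = 101L) {
  cfg <- sim_config(genome_len = 15000L, read_len = 36L, n_pairs = n_pairs,
                    err_rate = err, rng_seed = seed)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(g, cfg)
  list(index = index_reference(list(g)), reads = sim$reads1, genome = g)
}

test_that("grammar construction validates the site registry", {
  gr <- tiny_grammar()
  expect_s3_class(gr, "Grammar")
  expect_length(gr$sites, 3L)
  expect_error(build_grammar(list(
    list(id = "a", kind = "parameter", values = list(1L), default = 1L),
    list(id = "a", kind = "parameter", values = list(2L), default = 2L))),
    "duplicate")
  expect_error(build_grammar(list(
    list(id = "nonsense", kind = "parameter", values = list(1L),
         default = 1L))), "does not name")
  expect_error(build_grammar(list(
    list(id = "max_diff", kind = "parameter", values = list(1L, 2L),
         default = 3L))), "not among")
})

test_that("the empty assignment reproduces the reference kernel bit-exactly", {
  fx <- gi_fixture(30L)
  gr <- tiny_grammar()
  k <- instantiate_kernel(list(), gr)
  for (r in fx$reads[1:20]) {
    a <- align_read(fx$index, r, k$params, k$variants)
    b <- align_read(fx$index, r)
    expect_identical(a, b)
  }
})

test_that("every single-step mutant of the grammar instantiates cleanly", {
  gr <- build_grammar(default_site_registry())
  for (s in gr$sites) {
    for (v in s$values) {
      ind <- list()
      ind[[s$id]] <- v
      k <- instantiate_kernel(ind, gr)
      expect_s3_class(k$params, "SearchParams")
    }
  }
  expect_error(instantiate_kernel(list(bogus = 1L), gr), "unknown site")
  expect_error(instantiate_kernel(list(max_diff = 99L), gr), "illegal value")
})

test_that("mutation changes exactly one site to a legal non-default value", {
  gr <- build_grammar(list(
    list(id = "max_diff", kind = "parameter", values = list(1L, 2L),
         default = 1L)))
  set.seed(1)
  child <- mutate(list(), gr)
  expect_equal(child, list(max_diff = 2L))      # forced move
  # legality sweep over a richer grammar
  gr <- tiny_grammar()
  set.seed(2)
  ind <- list()
  for (k in 1:500) {
    ind <- mutate(ind, gr)
    expect_silent(gibarra:::check_legal(ind, gr))
  }
  # seeded reproducibility
  set.seed(99); c1 <- mutate(list(), gr)
  set.seed(99); c2 <- mutate(list(), gr)
  expect_identical(c1, c2)
  locked <- build_grammar(list(
    list(id = "max_diff", kind = "parameter", values = list(1L),
         default = 1L)))
  expect_error(mutate(list(), locked), "no alternative")
})

test_that("crossover draws every site from one of its parents", {
  gr <- tiny_grammar()
  p1 <- list(prepass = FALSE, max_diff = 1L)
  set.seed(3)
  expect_equal(crossover(p1, p1, gr), gibarra:::canonical_assignment(p1, gr))
  p2 <- list(seed_len = 0L)
  set.seed(4)
  for (k in 1:50) {
    ch <- crossover(p1, p2, gr)
    for (id in names(gr$sites)) {
      v <- gibarra:::site_value(ch, gr, id)
      expect_true(identical(v, gibarra:::site_value(p1, gr, id)) ||
                    identical(v, gibarra:::site_value(p2, gr, id)))
    }
  }
  set.seed(7); c1 <- crossover(p1, p2, gr)
  set.seed(7); c2 <- crossover(p1, p2, gr)
  expect_identical(c1, c2)
})

test_that("fitness separates equivalent from answer-changing individuals", {
  fx <- gi_fixture(40L, err = 0.02)
  gr <- tiny_grammar()
  ev <- fitness_evaluator(gr, fx$index, fx$reads)
  f0 <- ev$evaluate(list())
  expect_true(f0$equivalent)
  expect_equal(f0$speedup, 1.0)
  # max_diff = 0 cannot reproduce fallback answers on an error-bearing batch
  f1 <- ev$evaluate(list(max_diff = 0L))
  expect_false(f1$equivalent)
  # disabling the pre-pass keeps answers, costs more on an exact-heavy batch
  f2 <- ev$evaluate(list(prepass = FALSE))
  expect_true(f2$equivalent)
  expect_gt(f2$cost, f0$cost)
  expect_lt(f2$speedup, 1.0)
})

test_that("breeding takes the fastest half and conserves population size", {
  gr <- tiny_grammar()
  pop <- list(list(), list(prepass = FALSE), list(seed_len = 0L),
              list(max_diff = 1L))
  fit <- list(list(equivalent = TRUE, cost = 10),
              list(equivalent = TRUE, cost = 30),
              list(equivalent = TRUE, cost = 20),
              list(equivalent = TRUE, cost = 40))
  set.seed(5)
  bg <- breed_generation(pop, fit, gr)
  expect_length(bg$parents, 2L)
  expect_equal(bg$parents[[1]], list())          # cost 10
  expect_equal(bg$parents[[2]], list(seed_len = 0L))  # cost 20
  expect_length(bg$population, 4L)
  for (ind in bg$population) expect_silent(gibarra:::check_legal(ind, gr))
  # no eligible parents -> deterministic reseed around the reference kernel
  fit_bad <- lapply(fit, function(f) list(equivalent = FALSE, cost = Inf))
  bg <- breed_generation(pop, fit_bad, gr)
  expect_length(bg$parents, 0L)
  expect_length(bg$population, 4L)
  expect_equal(bg$population[[1]], list())
})

test_that("a fully locked grammar returns the reference kernel", {
  fx <- gi_fixture(30L)
  locked <- build_grammar(list(
    list(id = "max_diff", kind = "parameter", values = list("auto"),
         default = "auto")))
  res <- run_gi(gi_config(pop_size = 4L, generations = 2L,
                          training_reads = 20L, holdout_reads = 10L,
                          rng_seed = 8L, elitism = FALSE),
                locked, fx$index, fx$reads)
  expect_equal(res$best, list())
  expect_equal(res$report$speedup, 1.0)
})

test_that("GI runs are reproducible from the seed and never regress", {
  fx <- gi_fixture(50L, err = 0.01)
  gr <- tiny_grammar()
  cfg <- gi_config(pop_size = 8L, generations = 4L, training_reads = 30L,
                   holdout_reads = 15L, rng_seed = 12L)
  r1 <- run_gi(cfg, gr, fx$index, fx$reads)
  r2 <- run_gi(cfg, gr, fx$index, fx$reads)
  expect_identical(r1$report, r2$report)
  expect_lte(r1$report$training_cost, r1$report$reference_cost)
  expect_gte(r1$report$speedup, 1.0)
  expect_true(r1$report$holdout_equivalent)
  # best-of-generation cost never increases under elitism
  bc <- r1$report$generations$best_cost
  bc <- bc[!is.na(bc)]
  expect_true(all(diff(bc) <= 0))
})
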