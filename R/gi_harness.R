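# Genetic improvement of the search kernel: a grammar over the kernel's
# declared parameter sites and code-variant toggles, individuals as legal
# assignments, and an "equivalent answers, then faster" fitness measured in
# deterministic instrumented work units.  Selection follows the
# fastest-half / two-children scheme (one crossover child, one mutation
# child per parent), cycling for a configured number of generations with
# the final winner re-validated on a held-out read set.

#' The kernel's tunable-site registry
#'
#' One entry per genetically improvable site of the search kernel:
#' parameter sites map to [search_params()] fields, code-variant sites to
#' [kernel_variants()] toggles.  Defaults reconstruct the reference kernel
#' exactly.
#'
#' @return list of site descriptors (`id`, `kind`, `values`, `default`).
#' @export
default_site_registry <- function() {
  list(
    list(id = "prepass", kind = "code_variant",
         values = list(TRUE, FALSE), default = TRUE),
    list(id = "use_diff_bound", kind = "code_variant",
         values = list(TRUE, FALSE), default = TRUE),
    list(id = "max_diff", kind = "parameter",
         values = list("auto", 0L, 1L, 2L, 3L, 4L), default = "auto"),
    list(id = "seed_len", kind = "parameter",
         values = list(0L, 16L, 24L, 32L, 48L), default = 32L),
    list(id = "max_seed_diff", kind = "parameter",
         values = list(1L, 2L, 3L), default = 2L),
    list(id = "max_queue", kind = "parameter",
         values = list(1000L, 10000L, 100000L), default = 100000L),
    list(id = "mismatch_pen", kind = "parameter",
         values = list(3L, 5L), default = 3L),
    list(id = "max_gap_opens", kind = "parameter",
         values = list(0L, 1L, 2L), default = 1L)
  )
}

#' Build a grammar from a tunable-site registry
#'
#' Validates the registry (unique ids, defaults among the allowed values,
#' known kinds and target fields) and returns the grammar the GI operators
#' draw legal values from.  The empty assignment reproduces the reference
#' kernel bit-exactly.
#'
#' @param registry list of site descriptors as in [default_site_registry()].
#' @return object of class `Grammar`.
#' @export
build_grammar <- function(registry = default_site_registry()) {
  if (length(registry) == 0L) stop("build_grammar: empty registry", call. = FALSE)
  ids <- vapply(registry, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop("build_grammar: duplicate site id '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  }
  par_fields <- setdiff(names(formals(search_params)), character(0))
  var_fields <- names(formals(kernel_variants))
  for (s in registry) {
    if (!s$kind %in% c("parameter", "code_variant")) {
      stop("build_grammar: unknown site kind '", s$kind, "'", call. = FALSE)
    }
    tgt <- if (s$kind == "parameter") par_fields else var_fields
    if (!s$id %in% tgt) {
      stop("build_grammar: site '", s$id, "' does not name a kernel ",
           s$kind, " field", call. = FALSE)
    }
    if (!any(vapply(s$values, identical, logical(1), s$default))) {
      stop("build_grammar: default of site '", s$id,
           "' is not among its allowed values", call. = FALSE)
    }
  }
  sites <- registry
  names(sites) <- ids
  structure(list(sites = sites), class = "Grammar")
}

#' @export
print.Grammar <- function(x, ...) {
  cat("Grammar with", length(x$sites), "sites:\n")
  for (s in x$sites) {
    cat(" ", s$id, "(", s$kind, "):",
        paste(vapply(s$values, format, character(1)), collapse = " | "),
        "[default", format(s$default), "]\n")
  }
  invisible(x)
}

# canonical form: only non-default assignments, in grammar site order
canonical_assignment <- function(ind, grammar) {
  keep <- list()
  for (id in names(grammar$sites)) {
    if (!is.null(ind[[id]]) &&
        !identical(ind[[id]], grammar$sites[[id]]$default)) {
      keep[[id]] <- ind[[id]]
    }
  }
  keep
}

assignment_key <- function(ind, grammar) {
  ind <- canonical_assignment(ind, grammar)
  if (length(ind) == 0L) return("<default>")
  paste(names(ind), vapply(ind, format, character(1)),
        sep = "=", collapse = ";")
}

site_value <- function(ind, grammar, id) {
  if (!is.null(ind[[id]])) ind[[id]] else grammar$sites[[id]]$default
}

check_legal <- function(ind, grammar) {
  for (id in names(ind)) {
    s <- grammar$sites[[id]]
    if (is.null(s)) {
      stop("individual assigns unknown site '", id, "'", call. = FALSE)
    }
    if (!any(vapply(s$values, identical, logical(1), ind[[id]]))) {
      stop("individual assigns illegal value to site '", id, "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Instantiate an individual as kernel configuration
#'
#' @param ind an individual (named list assignment; sites at default may be
#'   omitted; the empty list is the reference kernel).
#' @param grammar a [build_grammar()] grammar.
#' @return `list(params=, variants=)` ready for [align_read()].
#' @export
instantiate_kernel <- function(ind, grammar) {
  check_legal(ind, grammar)
  pargs <- list()
  vargs <- list()
  for (id in names(grammar$sites)) {
    s <- grammar$sites[[id]]
    v <- site_value(ind, grammar, id)
    if (s$kind == "parameter") pargs[[id]] <- v else vargs[[id]] <- v
  }
  list(params = do.call(search_params, pargs),
       variants = do.call(kernel_variants, vargs))
}

#' GI mutation operator
#'
#' Changes exactly one site to a different grammar-legal value (site chosen
#' uniformly among sites with alternatives, value uniformly among the
#' alternatives); the parent is unmodified.  Consumes R's RNG stream, so
#' seeding makes children reproducible.
#'
#' @param ind parent individual.
#' @param grammar a [build_grammar()] grammar.
#' @return the mutated child.
#' @export
mutate <- function(ind, grammar) {
  check_legal(ind, grammar)
  movable <- Filter(function(id) {
    cur <- site_value(ind, grammar, id)
    sum(!vapply(grammar$sites[[id]]$values, identical, logical(1), cur)) > 0L
  }, names(grammar$sites))
  if (length(movable) == 0L) {
    stop("mutate: grammar offers no alternative values", call. = FALSE)
  }
  id <- movable[[sample.int(length(movable), 1L)]]
  cur <- site_value(ind, grammar, id)
  alts <- Filter(function(v) !identical(v, cur), grammar$sites[[id]]$values)
  child <- ind
  child[[id]] <- alts[[sample.int(length(alts), 1L)]]
  canonical_assignment(child, grammar)
}

#' GI crossover operator
#'
#' Uniform crossover: each site's value is drawn from one of the two
#' parents with equal probability.
#'
#' @param p1,p2 parent individuals.
#' @param grammar a [build_grammar()] grammar.
#' @return the child individual (grammar-legal by construction).
#' @export
crossover <- function(p1, p2, grammar) {
  check_legal(p1, grammar)
  check_legal(p2, grammar)
  child <- list()
  pick <- stats::runif(length(grammar$sites)) < 0.5
  for (k in seq_along(grammar$sites)) {
    id <- names(grammar$sites)[k]
    child[[id]] <- site_value(if (pick[k]) p1 else p2, grammar, id)
  }
  canonical_assignment(child, grammar)
}

#' Build a memoising fitness evaluator
#'
#' Evaluation is deterministic (instrumented work units, not wall-clock),
#' so each distinct assignment is aligned against the training batch once
#' and cached.
#'
#' @param grammar a [build_grammar()] grammar.
#' @param index a [index_reference()] object.
#' @param reads training read records.
#' @param reference precomputed [evaluate_individual()] answers of the
#'   default individual (computed internally when `NULL`).
#' @return `list(evaluate=, reference_cost=, answers=)`; `evaluate(ind)`
#'   returns a fitness record `list(equivalent=, cost=, speedup=)`.
#' @export
fitness_evaluator <- function(grammar, index, reads, reference = NULL) {
  cache <- new.env(parent = emptyenv())
  if (is.null(reference)) {
    reference <- evaluate_individual(list(), grammar, index, reads)
  }
  ref_answers <- reference$answers
  ref_cost <- reference$cost
  evaluate <- function(ind) {
    key <- assignment_key(ind, grammar)
    if (exists(key, envir = cache, inherits = FALSE)) {
      return(get(key, envir = cache))
    }
    rec <- tryCatch({
      r <- evaluate_individual(ind, grammar, index, reads)
      eq <- identical(r$answers, ref_answers)
      list(equivalent = eq, cost = r$cost,
           speedup = if (eq) ref_cost / r$cost else NA_real_)
    }, error = function(e) {
      list(equivalent = FALSE, cost = Inf, speedup = NA_real_)
    })
    assign(key, rec, envir = cache)
    rec
  }
  list(evaluate = evaluate, reference_cost = ref_cost,
       answers = ref_answers)
}

#' Run one individual's kernel over a read batch
#'
#' Answers are the per-read hit lists reduced to the equivalence-relevant
#' fields (reference, position, strand, score); cost is the summed
#' instrumented work.
#'
#' @inheritParams fitness_evaluator
#' @param ind individual to instantiate.
#' @return `list(answers=, cost=)`.
#' @export
evaluate_individual <- function(ind, grammar, index, reads) {
  k <- instantiate_kernel(ind, grammar)
  cost <- 0
  answers <- vapply(reads, function(r) {
    a <- align_read(index, r, k$params, k$variants)
    cost <<- cost + a$cost
    h <- a$hits
    paste(h$refname, h$pos, h$strand, h$score, sep = ":", collapse = ",")
  }, character(1))
  list(answers = answers, cost = max(cost, 1))
}

#' Breed the next GI generation
#'
#' Individuals with equivalent answers, ranked by cost, form the parent
#' pool; the fastest half of the population get two children each -- one by
#' crossover with another randomly chosen parent, one by mutation.  With
#' `elitism` (default), the last child slot carries the best parent forward
#' unchanged, which makes the best-of-generation cost non-increasing.  If
#' fewer than two parents are eligible the population is reseeded from the
#' reference kernel and its single-step mutants.
#'
#' @param population list of individuals.
#' @param fitness list of fitness records aligned with `population`.
#' @param grammar a [build_grammar()] grammar.
#' @param elitism carry the best parent into the next generation.
#' @return `list(parents=, population=)`; the new population has the same
#'   size as the old.
#' @export
breed_generation <- function(population, fitness, grammar, elitism = TRUE) {
  pop_size <- length(population)
  eligible <- which(vapply(fitness, function(f) isTRUE(f$equivalent),
                           logical(1)))
  if (length(eligible) < 2L) {
    return(list(parents = list(), population = reseed_population(grammar, pop_size)))
  }
  costs <- vapply(fitness[eligible], function(f) f$cost, numeric(1))
  eligible <- eligible[order(costs, eligible)]
  parents <- population[eligible[seq_len(min(length(eligible),
                                             pop_size %/% 2L))]]
  np <- length(parents)
  children <- vector("list", pop_size)
  for (k in seq_len(pop_size %/% 2L)) {
    p <- parents[[(k - 1L) %% np + 1L]]
    partner <- if (np == 1L) p else
      parents[[setdiff(seq_len(np), (k - 1L) %% np + 1L)[
        sample.int(np - 1L, 1L)]]]
    children[[2L * k - 1L]] <- crossover(p, partner, grammar)
    children[[2L * k]] <- safe_mutate(p, grammar)
  }
  if (pop_size %% 2L == 1L) {
    children[[pop_size]] <- safe_mutate(parents[[1L]], grammar)
  }
  if (elitism) children[[pop_size]] <- canonical_assignment(parents[[1L]], grammar)
  list(parents = parents, population = children)
}

# mutation that degrades to copying when the grammar is fully locked
safe_mutate <- function(ind, grammar) {
  tryCatch(mutate(ind, grammar),
           error = function(e) canonical_assignment(ind, grammar))
}

# deterministic restart: the reference kernel plus its single-step mutants,
# cycling over sites and values
reseed_population <- function(grammar, pop_size) {
  pool <- list(list())
  for (s in grammar$sites) {
    for (v in s$values) {
      if (!identical(v, s$default)) {
        ind <- list()
        ind[[s$id]] <- v
        pool[[length(pool) + 1L]] <- ind
      }
    }
  }
  pool[(seq_len(pop_size) - 1L) %% length(pool) + 1L]
}

#' GI run configuration
#'
#' Scaled-down defaults for desk-scale runs; the full-scale values
#' (population 1000, 50 generations, ~160,000 training strings) are
#' available by configuration.
#'
#' @param pop_size population size (even).
#' @param generations number of generations.
#' @param training_reads,holdout_reads read counts for the training batch
#'   and the held-out validation batch.
#' @param rng_seed seed for the whole run.
#' @param elitism see [breed_generation()].
#' @export
gi_config <- function(pop_size = 20L, generations = 10L,
                      training_reads = 2000L, holdout_reads = 500L,
                      rng_seed = 42L, elitism = TRUE) {
  cfg <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              training_reads = as.integer(training_reads),
              holdout_reads = as.integer(holdout_reads),
              rng_seed = as.integer(rng_seed),
              elitism = isTRUE(elitism))
  stopifnot(cfg$pop_size >= 2L, cfg$pop_size %% 2L == 0L,
            cfg$generations >= 1L)
  class(cfg) <- "GIConfig"
  cfg
}

# stratify reads by difficulty (exact pre-pass success vs fallback) so a
# mutant that only handles easy reads cannot win on a skewed split
split_reads <- function(index, reads, n_train, n_hold) {
  hard <- vapply(reads, function(r) {
    tr <- suppressWarnings(truncate_read(r))
    exact_prepass(index, tr$record)$needs_fallback
  }, logical(1))
  take <- function(idx, n) {
    if (length(idx) == 0L || n <= 0L) return(integer(0))
    idx[sample.int(length(idx), min(n, length(idx)))]
  }
  n <- length(reads)
  n_train <- min(n_train, n)
  n_hold <- min(n_hold, n - n_train)
  p_train <- n_train / n
  easy <- which(!hard)
  hardi <- which(hard)
  tr <- sort(c(take(easy, round(length(easy) * p_train)),
               take(hardi, n_train - round(length(easy) * p_train))))
  rest <- setdiff(seq_len(n), tr)
  ho <- sort(take(rest, n_hold))
  list(train = tr, holdout = ho)
}

#' Run the genetic-improvement loop
#'
#' Splits the reads into training and held-out batches (stratified by
#' pre-pass difficulty), evaluates the population each generation, breeds
#' by the fastest-half / two-children scheme, and finally re-validates the
#' best equivalent individual of the last generation on the held-out batch;
#' a winner that fails holdout equivalence is rejected in favour of the
#' next-best candidate, falling back to the reference kernel.  The whole
#' run is reproducible from `rng_seed`.
#'
#' @param config a [gi_config()].
#' @param grammar a [build_grammar()] grammar.
#' @param index a [index_reference()] object.
#' @param reads read records (training and holdout are drawn from these).
#' @return `list(best=, report=)`: the winning individual (guaranteed
#'   holdout-equivalent, training cost never above the reference) and a
#'   report with per-generation best/median cost, the winner's speedup and
#'   holdout verdict.
#' @export
run_gi <- function(config, grammar, index, reads) {
  set.seed(config$rng_seed)
  sp <- split_reads(index, reads, config$training_reads,
                    config$holdout_reads)
  train <- reads[sp$train]
  holdout <- reads[sp$holdout]
  ev <- fitness_evaluator(grammar, index, train)
  pop <- c(list(list()),
           lapply(seq_len(config$pop_size - 1L),
                  function(i) safe_mutate(list(), grammar)))
  gen_stats <- vector("list", config$generations)
  fit <- NULL
  for (g in seq_len(config$generations)) {
    fit <- lapply(pop, ev$evaluate)
    eq <- vapply(fit, function(f) isTRUE(f$equivalent), logical(1))
    costs <- vapply(fit, function(f) f$cost, numeric(1))
    gen_stats[[g]] <- data.frame(
      generation = g,
      n_equivalent = sum(eq),
      best_cost = if (any(eq)) min(costs[eq]) else NA_real_,
      median_cost = if (any(eq)) stats::median(costs[eq]) else NA_real_)
    if (g < config$generations) {
      pop <- breed_generation(pop, fit, grammar,
                              elitism = config$elitism)$population
    }
  }
  # rank final-generation candidates: equivalent, never slower than reference
  eq <- vapply(fit, function(f) isTRUE(f$equivalent), logical(1))
  costs <- vapply(fit, function(f) f$cost, numeric(1))
  cand <- which(eq & costs <= ev$reference_cost)
  cand <- cand[order(costs[cand], cand)]
  keys <- vapply(pop, assignment_key, character(1), grammar)
  cand <- cand[!duplicated(keys[cand])]
  ref_hold <- evaluate_individual(list(), grammar, index, holdout)
  best <- list()
  best_fit <- ev$evaluate(list())
  holdout_speedup <- 1
  rejected <- character(0)
  for (k in cand) {
    if (identical(keys[k], "<default>")) { best <- list(); break }
    hv <- tryCatch(evaluate_individual(pop[[k]], grammar, index, holdout),
                   error = function(e) NULL)
    if (!is.null(hv) && identical(hv$answers, ref_hold$answers)) {
      best <- canonical_assignment(pop[[k]], grammar)
      best_fit <- fit[[k]]
      holdout_speedup <- ref_hold$cost / hv$cost
      break
    }
    rejected <- c(rejected, keys[k])
  }
  report <- list(
    generations = do.call(rbind, gen_stats),
    winner = assignment_key(best, grammar),
    winner_assignment = best,
    training_cost = best_fit$cost,
    reference_cost = ev$reference_cost,
    speedup = ev$reference_cost / best_fit$cost,
    holdout_equivalent = TRUE,
    holdout_speedup = holdout_speedup,
    holdout_rejected = rejected,
    n_train = length(train),
    n_holdout = length(holdout),
    rng_seed = config$rng_seed)
  list(best = best, report = report)
}
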