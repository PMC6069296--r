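#' Genetic algorithm configuration
#'
#' Defaults follow the published recipe: a population of the 50 best words,
#' initialization from the all-ones word, the systematic leave-one-gene-out
#' words, and 200 random words with 2-10 inactive genes; per iteration 5
#' crossover children, 5 mutants and 5 fresh random words with fewer than 10%
#' of zeros; stop when a word scores strictly above 95 or after 200
#' iterations.
#'
#' @param pop_size population size.
#' @param n_random_init random words drawn at initialization.
#' @param init_zero_range range of the number of zeros in the random
#'   initialization words.
#' @param n_crossover,n_mutation,n_random new words per iteration from each
#'   operator.
#' @param random_max_zero_frac random-injection words carry strictly fewer
#'   than this fraction of zeros.
#' @param stop_score stop once the best score passes this value.
#' @param stop_strict if `TRUE` the comparison is strict (`score > stop`),
#'   the genetic-algorithm convention; the swarm uses `>=`.
#' @param max_iterations main-loop iteration cap.
#' @param max_evals backend-evaluation budget (cache hits do not count).
#' @param mutation_k_max_frac mutation flips `k` positions, `k` uniform in
#'   `1..max(1, ceiling(frac * n))`.
#' @param crossover_contiguous partition crossover indices into contiguous
#'   blocks (classic k-point crossover); `FALSE` assigns indices to the k
#'   subsets uniformly at random.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, n_random_init = 200,
                      init_zero_range = c(2, 10),
                      n_crossover = 5, n_mutation = 5, n_random = 5,
                      random_max_zero_frac = 0.10,
                      stop_score = 95, stop_strict = TRUE,
                      max_iterations = 200, max_evals = Inf,
                      mutation_k_max_frac = 0.05,
                      crossover_contiguous = TRUE) {
  cfg <- as.list(environment())
  stopifnot(pop_size >= 1, n_random_init >= 0,
            stop_score > 0, stop_score <= 100, max_iterations >= 0)
  class(cfg) <- "ga_config"
  cfg
}

#' k-point crossover of two subset words
#'
#' Indices `1..n` are partitioned into `k` subsets (`k` drawn uniformly in
#' `2..floor(n/2)`); the child copies the first parent on odd-numbered
#' subsets and the second parent elsewhere. The default partition uses
#' contiguous blocks cut at `k - 1` sorted distinct positions.
#'
#' @param w1,w2 parent words (equal length).
#' @param contiguous contiguous-block partition (default) or random index
#'   assignment.
#' @param subset_id optional explicit partition: an integer vector assigning
#'   each index to a subset `1..k` (overrides the random draw).
#' @return child word; every bit equals the corresponding bit of a parent.
#' @export
crossover <- function(w1, w2, contiguous = TRUE, subset_id = NULL) {
  w1 <- assert_word(w1)
  w2 <- assert_word(w2)
  n <- length(w1)
  if (length(w2) != n) stop("parents must have equal length", call. = FALSE)
  if (is.null(subset_id)) {
    k_max <- max(2L, n %/% 2L)
    k <- if (k_max > 2L) sample(2:k_max, 1L) else 2L
    subset_id <- if (contiguous) {
      cuts <- sort(sample.int(n - 1L, min(k - 1L, n - 1L)))
      findInterval(seq_len(n) - 1L, cuts) + 1L
    } else {
      sample.int(k, n, replace = TRUE)
    }
  }
  stopifnot(length(subset_id) == n)
  ifelse(subset_id %% 2L == 1L, w1, w2)
}

#' Mutate a word by flipping exactly k positions
#'
#' @param word subset word.
#' @param k number of distinct positions to flip (`1 <= k <= n`).
#' @return word at Hamming distance exactly `k` from the input.
#' @export
mutate_word <- function(word, k) {
  word <- assert_word(word)
  n <- length(word)
  if (k < 1 || k > n) stop("k must lie in 1..n", call. = FALSE)
  pos <- sample.int(n, k)
  word[pos] <- 1L - word[pos]
  word
}

random_word_with_zeros <- function(n, n_zeros) {
  word <- rep(1L, n)
  if (n_zeros > 0) word[sample.int(n, n_zeros)] <- 0L
  word
}

## evaluate new candidate words against the budget; all-zero words and words
## already in the pool are discarded (set semantics, cache-friendly)
evaluate_candidates <- function(ctx, words, pool_keys, cfg) {
  recs <- list()
  for (w in words) {
    if (ctx$state$n_evals >= cfg$max_evals) break
    if (sum(w) == 0L) next
    key <- word_to_string(w)
    if (key %in% pool_keys) next
    recs[[length(recs) + 1L]] <- evaluate_word(ctx, w)
    pool_keys <- c(pool_keys, key)
  }
  recs
}

stop_reached <- function(best, cfg) {
  if (cfg$stop_strict) best$score > cfg$stop_score else
    best$score >= cfg$stop_score
}

#' Initialize the GA population
#'
#' Evaluates the all-ones word, the systematic leave-one-out words, and the
#' random words, in that order, stopping early if a word passes the stop
#' score; keeps the `pop_size` best.
#'
#' @param ctx an [eval_context].
#' @param cfg a [ga_config].
#' @param frozen_zero optional gene indices forced to 0 in every word (used
#'   by the refinement phase).
#' @return list with `population` (evaluation records, best first),
#'   `stopped` (logical) and `terminus` (`"systematic"` or
#'   `"random-init"`, the stage reached).
#' @export
init_population <- function(ctx, cfg = ga_config(), frozen_zero = integer(0)) {
  n <- ctx$n
  if (n < 2L) stop("catalog must hold at least 2 genes", call. = FALSE)
  zr <- pmin(cfg$init_zero_range, n - 1L)
  words <- c(
    list(rep(1L, n)),
    lapply(seq_len(n), function(i) { w <- rep(1L, n); w[i] <- 0L; w }),
    lapply(seq_len(cfg$n_random_init), function(i) {
      random_word_with_zeros(n, sample(zr[1L]:zr[2L], 1L))
    })
  )
  stage_end <- c(1L, 1L + n, length(words))
  if (length(frozen_zero)) {
    words <- lapply(words, function(w) { w[frozen_zero] <- 0L; w })
  }
  seen <- character(0)
  recs <- list()
  stopped <- FALSE
  stage <- 1L
  for (i in seq_along(words)) {
    if (i > stage_end[stage]) stage <- stage + 1L
    w <- words[[i]]
    if (sum(w) == 0L) next
    key <- word_to_string(w)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (ctx$state$n_evals >= cfg$max_evals) break
    recs[[length(recs) + 1L]] <- evaluate_word(ctx, w)
    if (stop_reached(recs[[length(recs)]], cfg)) { stopped <- TRUE; break }
  }
  if (!length(recs)) stop("no word could be evaluated", call. = FALSE)
  pop <- recs[order_records(recs)]
  pop <- pop[seq_len(min(cfg$pop_size, length(pop)))]
  list(population = pop, stopped = stopped,
       terminus = if (stage <= 2L) "systematic" else "random-init")
}

#' One GA iteration
#'
#' Adds crossover children, then mutants drawn from the enlarged pool, then
#' fresh random words with fewer than 10% zeros; evaluates the new words and
#' returns the `pop_size` best of the union (elitist selection, so the best
#' score never decreases).
#'
#' @inheritParams init_population
#' @param population current population (list of evaluation records).
#' @return new population, best first.
#' @export
ga_step <- function(population, ctx, cfg = ga_config(),
                    frozen_zero = integer(0)) {
  n <- ctx$n
  freeze <- function(w) { if (length(frozen_zero)) w[frozen_zero] <- 0L; w }
  pool <- population
  pool_keys <- vapply(pool, `[[`, character(1), "word")

  children <- lapply(seq_len(cfg$n_crossover), function(i) {
    pair <- sample.int(length(pool), 2L)
    freeze(crossover(pool[[pair[1L]]]$bits, pool[[pair[2L]]]$bits,
                     contiguous = cfg$crossover_contiguous))
  })
  new_recs <- evaluate_candidates(ctx, children, pool_keys, cfg)
  pool <- c(pool, new_recs)
  pool_keys <- vapply(pool, `[[`, character(1), "word")

  k_max <- max(1L, ceiling(cfg$mutation_k_max_frac * n))
  mutants <- lapply(seq_len(cfg$n_mutation), function(i) {
    parent <- pool[[sample.int(length(pool), 1L)]]$bits
    freeze(mutate_word(parent, sample.int(k_max, 1L)))
  })
  new_recs <- evaluate_candidates(ctx, mutants, pool_keys, cfg)
  pool <- c(pool, new_recs)
  pool_keys <- vapply(pool, `[[`, character(1), "word")

  z_max <- max(0L, ceiling(cfg$random_max_zero_frac * n) - 1L)
  randoms <- lapply(seq_len(cfg$n_random), function(i) {
    freeze(random_word_with_zeros(n, sample(0:z_max, 1L)))
  })
  new_recs <- evaluate_candidates(ctx, randoms, pool_keys, cfg)
  pool <- c(pool, new_recs)

  pool <- pool[order_records(pool)]
  pool[seq_len(min(cfg$pop_size, length(pool)))]
}

#' Run the genetic algorithm
#'
#' @param ctx an [eval_context].
#' @param cfg a [ga_config].
#' @param seed seed for the search's random draws.
#' @param population optional starting population (skips initialization;
#'   used by the refinement relaunch).
#' @param frozen_zero gene indices pinned to 0 throughout.
#' @return An object of class `ga_result`: `best` (record), `population`,
#'   `history` (a `run_history`), `stop_reason` (`"score"`, `"iterations"`
#'   or `"evaluations"`), `terminus` (`"initialization"` or `"main-loop"`),
#'   `iterations`, and the context.
#' @export
run_ga <- function(ctx, cfg = ga_config(), seed = 1L, population = NULL,
                   frozen_zero = integer(0)) {
  set.seed(seed)
  terminus <- "main-loop"
  if (is.null(population)) {
    init <- init_population(ctx, cfg, frozen_zero = frozen_zero)
    population <- init$population
    if (init$stopped) {
      return(ga_result(ctx, population, "score", "initialization", 0L))
    }
  }
  iterations <- 0L
  while (iterations < cfg$max_iterations) {
    if (stop_reached(population[[1L]], cfg)) {
      return(ga_result(ctx, population, "score", terminus, iterations))
    }
    if (ctx$state$n_evals >= cfg$max_evals) {
      return(ga_result(ctx, population, "evaluations", terminus, iterations))
    }
    population <- ga_step(population, ctx, cfg, frozen_zero = frozen_zero)
    iterations <- iterations + 1L
  }
  reason <- if (stop_reached(population[[1L]], cfg)) "score" else "iterations"
  ga_result(ctx, population, reason, terminus, iterations)
}

ga_result <- function(ctx, population, stop_reason, terminus, iterations) {
  structure(list(best = population[[1L]], population = population,
                 history = run_history(ctx), stop_reason = stop_reason,
                 terminus = terminus, iterations = iterations, ctx = ctx),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA result: best score", round(x$best$score, 2),
      "(b =", round(x$best$b, 2), ", p =", round(x$best$p, 2), ")\n",
      " stop:", x$stop_reason, "| terminus:", x$terminus,
      "|", x$iterations, "iterations,", length(x$history), "evaluations\n")
  invisible(x)
}
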