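#' Geometric cooling ratio
#'
#' The tiered schedule multiplies the control parameter (temperature) by a
#' constant `C` after each Markov chain; `C = (t_f / t_i)^(1/(n_m - 1))`
#' maps the initial temperature to the final one in exactly `n_m` chains.
#'
#' @param t_init,t_final initial and final control parameter (`0 < t_final <
#'   t_init`).
#' @param n_chains maximal number of Markov chains (= temperature steps,
#'   >= 2).
#' @return the ratio `C`, so that `t_init * C^(n_chains - 1) == t_final`.
#' @export
cooling_ratio <- function(t_init, t_final, n_chains) {
  if (n_chains < 2) stop("n_chains must be >= 2", call. = FALSE)
  if (!(t_final > 0 && t_final < t_init)) {
    stop("need 0 < t_final < t_init", call. = FALSE)
  }
  (t_final / t_init)^(1 / (n_chains - 1))
}

#' Cooling schedule
#'
#' @inheritParams cooling_ratio
#' @return list of class `cooling_schedule` with the temperature of every
#'   chain (strictly decreasing, geometric).
#' @export
cooling_schedule <- function(t_init = 100, t_final = 1e-10, n_chains = 13) {
  C <- cooling_ratio(t_init, t_final, n_chains)
  structure(list(t_init = t_init, t_final = t_final, n_chains = n_chains,
                 ratio = C,
                 temperatures = t_init * C^(seq_len(n_chains) - 1)),
            class = "cooling_schedule")
}

#' Move configuration for the subset-word neighborhood
#'
#' A move draws the number of coordinates to change from a folded Gaussian
#' (capped by `move_distance_max`), picks that many distinct coordinates,
#' activates every inactive one, and inactivates an active one with
#' probability `nz/nc * alpha` (`nz` = zeros in the best word so far, `nc` =
#' catalogue size). Because the mandated all-ones start has `nz = 0`, a
#' probability floor (default `1/nc`, applied at move time) keeps 1-to-0
#' flips possible and the chain ergodic.
#'
#' @param move_distance_max maximal coordinates changed per move.
#' @param alpha scale of the inactivation probability.
#' @param prob_floor lower bound on the inactivation probability; `NULL`
#'   means `1/nc`.
#' @return list of class `move_config`.
#' @export
move_config <- function(move_distance_max = 5, alpha = 1, prob_floor = NULL) {
  stopifnot(move_distance_max >= 1, alpha > 0,
            is.null(prob_floor) || (prob_floor >= 0 && prob_floor < 1))
  structure(list(move_distance_max = move_distance_max, alpha = alpha,
                 prob_floor = prob_floor),
            class = "move_config")
}

#' Propose a neighboring word
#'
#' @param current current word.
#' @param best best word found so far (its zero count drives the
#'   inactivation probability).
#' @param cfg a [move_config].
#' @return proposed word at Hamming distance at most `move_distance_max`.
#' @export
propose_move <- function(current, best, cfg = move_config()) {
  current <- assert_word(current)
  best <- assert_word(best)
  nc <- length(current)
  if (length(best) != nc) stop("words must share the catalog", call. = FALSE)
  d_max <- min(cfg$move_distance_max, nc)
  d <- ceiling(abs(stats::rnorm(1, 0, d_max / 3)))
  d <- min(max(d, 1L), d_max)
  coords <- sample.int(nc, d)
  floor_p <- if (is.null(cfg$prob_floor)) 1 / nc else cfg$prob_floor
  p_off <- max(floor_p, (sum(best == 0L) / nc) * cfg$alpha)
  p_off <- min(p_off, 1)
  proposal <- current
  for (j in coords) {
    if (proposal[j] == 0L) {
      proposal[j] <- 1L
    } else if (stats::runif(1) < p_off) {
      proposal[j] <- 0L
    }
  }
  proposal
}

#' Tsallis acceptance probability
#'
#' Normalized generalized acceptance: for a worsening `delta > 0` the
#' probability is `base^(1/(1-q))` with
#' `base = 1 - (1-q) delta / (delta_bar * t)`, clamped to 0 when `base <= 0`;
#' improving moves are always accepted. As `q -> 1` this recovers the
#' Metropolis form `exp(-delta / (delta_bar * t))`.
#'
#' @param delta score worsening (current score minus proposal score; <= 0
#'   means improving).
#' @param delta_bar running mean of the absolute score differences observed
#'   so far (> 0).
#' @param t control parameter (temperature, > 0).
#' @param q Tsallis factor (must differ from 1).
#' @return acceptance probability in `[0, 1]`.
#' @export
tsallis_probability <- function(delta, delta_bar, t, q) {
  if (q == 1) {
    stop("q = 1 is the Metropolis limit; use exp(-delta/(delta_bar*t))",
         call. = FALSE)
  }
  stopifnot(delta_bar > 0, t > 0)
  if (delta <= 0) return(1)
  base <- 1 - (1 - q) * delta / (delta_bar * t)
  if (base <= 0) return(0)
  min(base^(1 / (1 - q)), 1)
}

#' Acceptance configuration
#'
#' @param q Tsallis factor (default 0.25).
#' @param initial_acceptance,final_acceptance target acceptance rates;
#'   stored for optional temperature calibration, not used by default.
#' @return list of class `accept_config`.
#' @export
accept_config <- function(q = 0.25, initial_acceptance = 0.7,
                          final_acceptance = 1e-5) {
  stopifnot(q != 1)
  structure(list(q = q, initial_acceptance = initial_acceptance,
                 final_acceptance = final_acceptance),
            class = "accept_config")
}

#' Run a synchronized batch of simulated-annealing clients
#'
#' Every client starts from the all-ones word. A chain is a fixed-length run
#' of propose/evaluate/accept steps at one temperature; the temperature only
#' changes between chains (geometric schedule). At each chain end a client
#' publishes its best record to a shared store and adopts the global best if
#' it is strictly better (synchronized move). A client halts after
#' `stagnation` consecutive chains that did not improve its best, and halted
#' clients are not restarted; their published bests keep seeding the others.
#'
#' @param ctx an [eval_context].
#' @param schedule a [cooling_schedule].
#' @param move_cfg a [move_config].
#' @param accept_cfg an [accept_config].
#' @param n_clients number of SA clients in the batch.
#' @param chain_length proposal steps per Markov chain (default `10 * nc`,
#'   capped by the evaluation budget).
#' @param stagnation halt a client after this many consecutive
#'   non-improving chains (default 3, deliberately small).
#' @param seed seed for the batch's random draws.
#' @param max_evals backend-evaluation budget.
#' @return An object of class `sa_result`: `best` (record), `history`,
#'   `trace` (data.frame of per-client moves: client, chain, temperature,
#'   word, score, status accepted/rejected/synchronized, hamming step),
#'   `chains_run`, and the context.
#' @export
run_sa_batch <- function(ctx, schedule = cooling_schedule(),
                         move_cfg = move_config(),
                         accept_cfg = accept_config(),
                         n_clients = 3, chain_length = NULL,
                         stagnation = 3, seed = 1L, max_evals = Inf) {
  set.seed(seed)
  n <- ctx$n
  if (is.null(chain_length)) chain_length <- 10L * n
  start <- rep(1L, n)
  start_rec <- evaluate_word(ctx, start)
  clients <- lapply(seq_len(n_clients), function(i) {
    list(current = start_rec, best = start_rec, stagnant = 0L,
         halted = FALSE, dsum = 1.0, dcount = 1L)  # running mean seeded at 1
  })
  global_best <- start_rec
  trace <- list()
  chains_run <- 0L
  for (chain in seq_len(schedule$n_chains)) {
    if (all(vapply(clients, `[[`, logical(1), "halted"))) break
    if (ctx$state$n_evals >= max_evals) break
    t <- schedule$temperatures[chain]
    chains_run <- chain
    for (ci in seq_len(n_clients)) {
      cl <- clients[[ci]]
      if (cl$halted) next
      improved <- FALSE
      for (step in seq_len(chain_length)) {
        if (ctx$state$n_evals >= max_evals) break
        prop_bits <- propose_move(cl$current$bits, cl$best$bits, move_cfg)
        if (sum(prop_bits) == 0L) next
        hstep <- hamming_distance(cl$current$bits, prop_bits)
        prop <- evaluate_word(ctx, prop_bits)
        delta <- cl$current$score - prop$score   # > 0 means worsening
        cl$dsum <- cl$dsum + abs(delta)
        cl$dcount <- cl$dcount + 1L
        dbar <- cl$dsum / cl$dcount
        accept <- delta <= 0 ||
          stats::runif(1) < tsallis_probability(delta, dbar, t, accept_cfg$q)
        if (accept) {
          cl$current <- prop
          if (prop$score > cl$best$score ||
              (prop$score == cl$best$score && prop$p > cl$best$p)) {
            cl$best <- prop
            improved <- TRUE
          }
        }
        trace[[length(trace) + 1L]] <- data.frame(
          client = ci, chain = chain, temperature = t, word = prop$word,
          score = prop$score,
          status = if (accept) "accepted" else "rejected",
          hamming = hstep, stringsAsFactors = FALSE)
      }
      ## chain end: publish to the shared store, then synchronize
      if (cl$best$score > global_best$score ||
          (cl$best$score == global_best$score && cl$best$p > global_best$p)) {
        global_best <- cl$best
      }
      if (global_best$score > cl$best$score) {
        cl$best <- global_best
        cl$current <- global_best
        improved <- TRUE
        trace[[length(trace) + 1L]] <- data.frame(
          client = ci, chain = chain, temperature = t,
          word = global_best$word, score = global_best$score,
          status = "synchronized", hamming = NA_integer_,
          stringsAsFactors = FALSE)
      }
      cl$stagnant <- if (improved) 0L else cl$stagnant + 1L
      if (cl$stagnant >= stagnation) cl$halted <- TRUE
      clients[[ci]] <- cl
    }
  }
  structure(list(best = global_best, history = run_history(ctx),
                 trace = do.call(rbind, trace), chains_run = chains_run,
                 clients = clients, ctx = ctx),
            class = "sa_result")
}

#' @export
print.sa_result <- function(x, ...) {
  cat("SA batch result: best score", round(x$best$score, 2),
      "after", x$chains_run, "chains,", length(x$history), "evaluations\n")
  invisible(x)
}

#' Greedy single-flip descent
#'
#' Repeatedly evaluates every single-bit neighbor of the current word and
#' moves to the best strictly improving one; stops at a 1-flip local
#' optimum. The returned score is never below the input's.
#'
#' @param word starting word.
#' @param ctx an [eval_context].
#' @param max_moves safety cap on descent moves.
#' @return the evaluation record of the local optimum.
#' @export
greedy_descent <- function(word, ctx, max_moves = 1000L) {
  current <- evaluate_word(ctx, assert_word(word, ctx$n))
  for (move in seq_len(max_moves)) {
    neighbors <- list()
    for (j in seq_len(ctx$n)) {
      w <- current$bits
      w[j] <- 1L - w[j]
      if (sum(w) == 0L) next
      neighbors[[length(neighbors) + 1L]] <- evaluate_word(ctx, w)
    }
    cand <- best_record(neighbors)
    if (cand$score > current$score) current <- cand else break
  }
  current
}

## --- continuous benchmark layer -------------------------------------------

#' Standard 2-D benchmark functions
#'
#' The three classical test functions used to validate the annealing
#' schedule: three-hump camel, Booth, and Levi N.13; all have global minimum
#' 0 (at the origin, (1, 3) and (1, 1) respectively).
#'
#' @param id one of `"three_hump_camel"`, `"booth"`, `"levi"`.
#' @param point numeric vector of length 2.
#' @return function value (scalar).
#' @export
benchmark_function <- function(id, point) {
  stopifnot(is.numeric(point), length(point) == 2L)
  x <- point[1L]; y <- point[2L]
  switch(id,
    three_hump_camel = 2 * x^2 - 1.05 * x^4 + x^6 / 6 + x * y + y^2,
    booth = (x + 2 * y - 7)^2 + (2 * x + y - 5)^2,
    levi = sin(3 * pi * x)^2 + (x - 1)^2 * (1 + sin(3 * pi * y)^2) +
      (y - 1)^2 * (1 + sin(2 * pi * y)^2),
    stop("unknown benchmark function: ", id, call. = FALSE)
  )
}

#' Continuous-move simulated annealing on a benchmark function
#'
#' Runs the same tiered schedule and Tsallis acceptance with a Gaussian move
#' in the plane (minimization), followed by a greedy pattern-search descent
#' with step halving.
#'
#' @param id benchmark id, see [benchmark_function()].
#' @param x0 start point (length 2).
#' @param schedule a [cooling_schedule].
#' @param accept_cfg an [accept_config].
#' @param chain_length steps per chain.
#' @param step_sd standard deviation of the Gaussian move.
#' @param descent run the final greedy descent.
#' @return list with `x` (argmin found), `value`, and `trace` (value of the
#'   current state after every chain).
#' @export
run_sa_continuous <- function(id, x0 = c(4, 4),
                              schedule = cooling_schedule(),
                              accept_cfg = accept_config(),
                              chain_length = 50, step_sd = 1,
                              descent = TRUE) {
  current <- x0
  f_cur <- benchmark_function(id, current)
  best <- current
  f_best <- f_cur
  dsum <- 1.0
  dcount <- 1L
  trace <- numeric(0)
  for (t in schedule$temperatures) {
    for (step in seq_len(chain_length)) {
      prop <- current + stats::rnorm(2, 0, step_sd)
      f_prop <- benchmark_function(id, prop)
      delta <- f_prop - f_cur            # minimization: > 0 is worsening
      dsum <- dsum + abs(delta)
      dcount <- dcount + 1L
      if (delta <= 0 ||
          stats::runif(1) < tsallis_probability(delta, dsum / dcount, t,
                                                accept_cfg$q)) {
        current <- prop
        f_cur <- f_prop
        if (f_cur < f_best) { best <- current; f_best <- f_cur }
      }
    }
    trace <- c(trace, f_cur)
  }
  if (descent) {
    step <- step_sd
    while (step > 1e-7) {
      moved <- FALSE
      for (d in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
        f_new <- benchmark_function(id, best + d)
        if (f_new < f_best) { best <- best + d; f_best <- f_new; moved <- TRUE }
      }
      if (!moved) step <- step / 2
    }
  }
  list(x = best, value = f_best, trace = trace)
}
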