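#' Binary PSO configuration
#'
#' Two velocity variants are supported. Variant `"constriction"` (version I)
#' multiplies the summed trends by the constriction coefficient of
#' [constriction_coefficient()] with `C1 = C2 = 2.05`. Variant `"inertia"`
#' (version II) uses an inertia weight that decreases linearly from
#' `w_max = 0.9` to `w_min = 0.4` over the run, with attraction weights
#' drawn uniformly from `[0.1, 0.5]` at every update.
#'
#' @param n_particles particles per swarm.
#' @param n_swarms independent swarms (run histories are merged).
#' @param variant `"constriction"`, `"inertia"`, or the numbers 1/2.
#' @param w_max,w_min inertia weight schedule endpoints.
#' @param phi_range range of the uniform attraction weights (inertia
#'   variant).
#' @param c1,c2 acceleration constants (constriction variant; `c1 + c2 >= 4`).
#' @param init_one_prob probability that an initial position bit is 1
#'   (particles start with a high share of active genes).
#' @param v_clamp velocity components are clamped to `[-v_clamp, v_clamp]`.
#' @param stop_score stop once a record scores at least this value (the
#'   swarm convention is inclusive) ...
#' @param stop_p_floor ... and retains at least this gene percentage.
#' @param max_iterations iteration cap per swarm.
#' @param max_evals shared backend-evaluation budget.
#' @return list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 10, n_swarms = 1,
                         variant = c("constriction", "inertia"),
                         w_max = 0.9, w_min = 0.4, phi_range = c(0.1, 0.5),
                         c1 = 2.05, c2 = 2.05, init_one_prob = 0.9,
                         v_clamp = 6, stop_score = 95, stop_p_floor = 90,
                         max_iterations = 100, max_evals = Inf) {
  if (is.numeric(variant)) {
    variant <- c("constriction", "inertia")[variant[1L]]
  }
  variant <- match.arg(variant)
  if (variant == "constriction" && c1 + c2 < 4) {
    stop("constriction variant requires c1 + c2 >= 4", call. = FALSE)
  }
  stopifnot(n_particles >= 1, n_swarms >= 1, w_min > 0, w_min <= w_max,
            init_one_prob > 0, init_one_prob <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "swarm_config"
  cfg
}

#' Linearly decreasing inertia weight
#'
#' @param iter current iteration (0-based).
#' @param max_iter final iteration.
#' @param w_max,w_min endpoints (defaults 0.9 and 0.4).
#' @return `w_max` at iteration 0, `w_min` at `max_iter`, affine between.
#' @export
inertia_weight <- function(iter, max_iter, w_max = 0.9, w_min = 0.4) {
  stopifnot(max_iter >= 1, iter >= 0, iter <= max_iter)
  w_max - (w_max - w_min) * iter / max_iter
}

#' Constriction coefficient
#'
#' `x = 2 k / |2 - C - sqrt(C (C - 4))|` with `C = C1 + C2 >= 4` and `k`
#' a random value in `[0, 1]`; the multiplier that contracts the velocities
#' and guarantees particle convergence.
#'
#' @param k random scalar in `[0, 1]`.
#' @param c1,c2 acceleration constants.
#' @return the coefficient (0.72984 for `k = 1`, `C = 4.1`).
#' @export
constriction_coefficient <- function(k, c1 = 2.05, c2 = 2.05) {
  C <- c1 + c2
  if (C < 4) stop("requires C = c1 + c2 >= 4", call. = FALSE)
  2 * k / abs(2 - C - sqrt(C * (C - 4)))
}

#' Velocity updates (pure forms)
#'
#' The two velocity rules with all scalars passed explicitly;
#' [update_velocity()] wraps them with the configured random draws.
#' Inertia: `v <- w v + phi1 (pbest - x) + phi2 (gbest - x)`.
#' Constriction: `v <- coef * (v + c1 (pbest - x) + c2 (gbest - x))`.
#'
#' @param v velocity vector.
#' @param x current position (0/1).
#' @param pbest,gbest personal and global best positions (0/1).
#' @param w,phi1,phi2 inertia-variant scalars.
#' @param coef,c1,c2 constriction-variant scalars.
#' @return updated velocity vector (not yet clamped).
#' @export
velocity_inertia <- function(v, x, pbest, gbest, w, phi1, phi2) {
  w * v + phi1 * (pbest - x) + phi2 * (gbest - x)
}

#' @rdname velocity_inertia
#' @export
velocity_constriction <- function(v, x, pbest, gbest, coef, c1, c2) {
  coef * (v + c1 * (pbest - x) + c2 * (gbest - x))
}

#' Velocity update with configured randomness
#'
#' Draws the variant's random scalars (`phi1`, `phi2` per update for the
#' inertia variant; `k` per update for the constriction variant), applies
#' the corresponding rule and clamps components to `[-v_clamp, v_clamp]`.
#'
#' @param v,x,pbest,gbest as in [velocity_inertia()].
#' @param cfg a [swarm_config].
#' @param iter,max_iter iteration counters for the inertia schedule.
#' @return clamped velocity vector.
#' @export
update_velocity <- function(v, x, pbest, gbest, cfg, iter, max_iter) {
  v <- if (cfg$variant == "inertia") {
    phi <- stats::runif(2, cfg$phi_range[1L], cfg$phi_range[2L])
    w <- inertia_weight(iter, max_iter, cfg$w_max, cfg$w_min)
    velocity_inertia(v, x, pbest, gbest, w, phi[1L], phi[2L])
  } else {
    coef <- constriction_coefficient(stats::runif(1), cfg$c1, cfg$c2)
    velocity_constriction(v, x, pbest, gbest, coef, cfg$c1, cfg$c2)
  }
  pmin(pmax(v, -cfg$v_clamp), cfg$v_clamp)
}

#' Sigmoid position update
#'
#' Bit `j` becomes 1 when a fresh uniform draw `r_j` does not exceed
#' `1 / (1 + exp(-v_j))`. A draw resulting in the empty word is redrawn
#' once, then a single uniformly chosen bit is activated (evaluation
#' requires at least one active gene).
#'
#' @param v velocity vector.
#' @return 0/1 position word.
#' @export
update_position <- function(v) {
  sig <- 1 / (1 + exp(-v))
  word <- as.integer(stats::runif(length(v)) <= sig)
  if (sum(word) == 0L) {
    word <- as.integer(stats::runif(length(v)) <= sig)
    if (sum(word) == 0L) word[sample.int(length(v), 1L)] <- 1L
  }
  word
}

pso_stop_reached <- function(rec, cfg) {
  rec$score >= cfg$stop_score && rec$p >= cfg$stop_p_floor
}

#' Initialize a swarm
#'
#' Draws each position bit as 1 with probability `init_one_prob` (particles
#' start near the whole core genome), sets all velocities to zero, evaluates
#' every position and sets the personal and global bests.
#'
#' @param ctx an [eval_context].
#' @param cfg a [swarm_config].
#' @return list with `positions`, `velocities`, `pbest` (records), `gbest`.
#' @export
init_swarm <- function(ctx, cfg = swarm_config()) {
  n <- ctx$n
  positions <- lapply(seq_len(cfg$n_particles), function(i) {
    w <- as.integer(stats::runif(n) <= cfg$init_one_prob)
    if (sum(w) == 0L) w[sample.int(n, 1L)] <- 1L
    w
  })
  pbest <- lapply(positions, function(w) evaluate_word(ctx, w))
  list(positions = positions,
       velocities = replicate(cfg$n_particles, numeric(n), simplify = FALSE),
       pbest = pbest, gbest = best_record(pbest))
}

#' Run the binary particle swarm optimizer
#'
#' Swarms run one after the other on the shared evaluation context (cached
#' evaluations are shared). Within a swarm each iteration follows the
#' master-worker contract: all particles are evaluated, the global best is
#' updated and broadcast, then every particle updates velocity and position.
#' Results are deterministic given the seed, independent of how evaluations
#' would be scheduled across workers (per-word resampling seeds are derived
#' from the words themselves).
#'
#' @param ctx an [eval_context].
#' @param cfg a [swarm_config].
#' @param seed seed for the search's random draws.
#' @return An object of class `bpso_result`: `best` (record), `history`,
#'   `per_swarm` (best record and iteration count per swarm), `stop_reason`
#'   and the context.
#' @export
run_bpso <- function(ctx, cfg = swarm_config(), seed = 1L) {
  set.seed(seed)
  n <- ctx$n
  best_overall <- NULL
  per_swarm <- list()
  stop_reason <- "exhausted"
  for (s in seq_len(cfg$n_swarms)) {
    swarm <- init_swarm(ctx, cfg)
    positions <- swarm$positions
    velocities <- swarm$velocities
    pbest <- swarm$pbest
    gbest <- swarm$gbest
    gbest_trace <- numeric(0)
    iter <- 0L
    swarm_stop <- FALSE
    while (iter < cfg$max_iterations && !swarm_stop &&
           ctx$state$n_evals < cfg$max_evals) {
      iter <- iter + 1L
      for (i in seq_len(cfg$n_particles)) {
        velocities[[i]] <- update_velocity(
          velocities[[i]], positions[[i]], pbest[[i]]$bits, gbest$bits,
          cfg, iter, cfg$max_iterations)
        positions[[i]] <- update_position(velocities[[i]])
      }
      for (i in seq_len(cfg$n_particles)) {
        if (ctx$state$n_evals >= cfg$max_evals) break
        rec <- evaluate_word(ctx, positions[[i]])
        if (rec$score > pbest[[i]]$score ||
            (rec$score == pbest[[i]]$score && rec$p > pbest[[i]]$p)) {
          pbest[[i]] <- rec
        }
      }
      cand <- best_record(pbest)
      if (cand$score > gbest$score ||
          (cand$score == gbest$score && cand$p > gbest$p)) gbest <- cand
      gbest_trace <- c(gbest_trace, gbest$score)
      if (pso_stop_reached(gbest, cfg)) {
        swarm_stop <- TRUE
        stop_reason <- "score"
      }
    }
    per_swarm[[s]] <- list(best = gbest, iterations = iter,
                           gbest_trace = gbest_trace)
    if (is.null(best_overall) || gbest$score > best_overall$score ||
        (gbest$score == best_overall$score && gbest$p > best_overall$p)) {
      best_overall <- gbest
    }
    if (ctx$state$n_evals >= cfg$max_evals) break
  }
  structure(list(best = best_overall, history = run_history(ctx),
                 per_swarm = per_swarm, stop_reason = stop_reason,
                 ctx = ctx),
            class = "bpso_result")
}

#' @export
print.bpso_result <- function(x, ...) {
  cat("BPSO result: best score", round(x$best$score, 2),
      "(b =", round(x$best$b, 2), ", p =", round(x$best$p, 2), ") over",
      length(x$per_swarm), "swarm(s),", length(x$history), "evaluations\n")
  invisible(x)
}
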