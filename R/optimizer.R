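#' Box-bound specification for swarm optimizers
#'
#' @param lower,upper Numeric vectors of per-dimension bounds; scalars are
#'   recycled to `dim`.
#' @param dim Number of dimensions (defaults to the longest bound vector).
#' @return An object of class `bounds_spec` with elements `lower`, `upper`,
#'   `dim`.
#' @examples
#' bounds_spec(-5, 5, dim = 10)
#' @export
bounds_spec <- function(lower, upper, dim = max(length(lower), length(upper))) {
  stopifnot(dim >= 1)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, dim = as.integer(dim)),
            class = "bounds_spec")
}

#' Optimizer configuration
#'
#' Holds every swarm constant used by the Snake Optimizer (SO), Particle Swarm
#' Optimization (PSO) and the hybrid PSSO.  Defaults follow the study setup:
#' 10 snakes/particles, 50 epochs, `K1 = 0.5`, `K2 = 0.05`, `K3 = 2`,
#' food-quantity threshold 0.25, temperature threshold 0.6, inertia `w = 0.5`,
#' cognitive `c1 = 0.8`, social `c2 = 0.9`.
#'
#' @param n_pop Population size N (>= 4).
#' @param n_iter Number of iterations T (>= 1).
#' @param k1,k2,k3 Snake constants (food-quantity scale, exploration step
#'   scale, exploitation step scale).
#' @param q_threshold Food-quantity gate between exploration and exploitation.
#' @param temp_threshold Temperature gate between food-following and
#'   fight/mate behaviour.
#' @param w,c1,c2 PSO inertia, cognitive and social coefficients.
#' @param v_max_fraction Velocity clamp as a fraction of the box width.
#' @param sign_prob Probability that the snake "diversity factor" sign is +1.
#' @param hatch_prob Probability that, after a mating iteration, the worst
#'   male and female are replaced by fresh random positions (egg hatching).
#' @param mode_split Uniform-draw threshold choosing fight (draw above) vs
#'   mate (draw at or below) when the swarm is cold.
#' @param eps_fitness Guard added to shifted fitness values so the
#'   `exp(-f_ref/f_self)` behaviour coefficients never divide by zero.
#' @param delta_so Logical; if `FALSE` the hybrid's snake displacement term is
#'   suppressed and PSSO iterations reduce exactly to PSO iterations.
#' @param seed Root seed; all randomness derives from it via independent named
#'   substreams.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(n_pop = 10L, n_iter = 50L,
                             k1 = 0.5, k2 = 0.05, k3 = 2,
                             q_threshold = 0.25, temp_threshold = 0.6,
                             w = 0.5, c1 = 0.8, c2 = 0.9,
                             v_max_fraction = 0.1,
                             sign_prob = 0.5, hatch_prob = 0.5,
                             mode_split = 0.6, eps_fitness = 1e-9,
                             delta_so = TRUE, seed = 1L) {
  if (n_pop < 4) stop("population size must be at least 4", call. = FALSE)
  if (n_iter < 1) stop("need at least one iteration", call. = FALSE)
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must lie in (0,1)", call. = FALSE)
  if (temp_threshold <= 0 || temp_threshold >= 1) stop("temp_threshold must lie in (0,1)", call. = FALSE)
  if (sign_prob < 0 || sign_prob > 1) stop("sign_prob must lie in [0,1]", call. = FALSE)
  structure(list(n_pop = as.integer(n_pop), n_iter = as.integer(n_iter),
                 k1 = k1, k2 = k2, k3 = k3,
                 q_threshold = q_threshold, temp_threshold = temp_threshold,
                 w = w, c1 = c1, c2 = c2,
                 v_max_fraction = v_max_fraction,
                 sign_prob = sign_prob, hatch_prob = hatch_prob,
                 mode_split = mode_split, eps_fitness = eps_fitness,
                 delta_so = isTRUE(delta_so), seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Environment schedule: food quantity and temperature
#'
#' `Q = K1 * exp((C - T)/T)` and `Temp = exp(-C/T)`.  Q grows and Temp decays
#' as iterations advance, moving the swarm from exploration to exploitation.
#'
#' @param iter Current iteration C, `0 <= C <= T`.
#' @param n_iter Total iterations T (>= 1).
#' @param config An [optimizer_config()] (only `k1` is used).
#' @return List with components `q` and `temp`.
#' @examples
#' swarm_environment(0, 50)   # temp = 1
#' swarm_environment(50, 50)  # q = k1 = 0.5
#' @export
swarm_environment <- function(iter, n_iter, config = optimizer_config()) {
  if (n_iter < 1) stop("invalid config: total iterations must be >= 1", call. = FALSE)
  if (iter < 0 || iter > n_iter) stop("iteration outside 0..n_iter", call. = FALSE)
  list(q = config$k1 * exp((iter - n_iter) / n_iter),
       temp = exp(-iter / n_iter))
}

#' Snake behaviour coefficient exp(-f_ref / f_self)
#'
#' Shared form of the foraging-ability (AB), fighting (FA) and mating (MA)
#' coefficients.  Inputs must already be shifted to be strictly positive; the
#' denominator is guarded by `eps_fitness`.
#'
#' @param f_ref,f_self Shifted (strictly positive) fitness values.
#' @param config An [optimizer_config()].
#' @return A scalar in `(0, 1]` for positive inputs.
#' @export
behavior_coefficient <- function(f_ref, f_self, config = optimizer_config()) {
  if (!is.finite(f_ref) || !is.finite(f_self)) {
    stop("invalid fitness: behaviour coefficients need finite inputs", call. = FALSE)
  }
  exp(-f_ref / max(f_self, config$eps_fitness))
}

# ---- pure movement kernels (unit-testable in isolation) ----------------------

# exploration step: ref +- k2 * ab * ((upper - lower) * r + lower)
so_explore_step <- function(ref_pos, ab, r, sgn, lower, upper, k2) {
  ref_pos + sgn * k2 * ab * ((upper - lower) * r + lower)
}

# food-following step: food +- k3 * temp * r * (food - pos)
so_food_step <- function(food, pos, temp, r, sgn, k3) {
  food + sgn * k3 * temp * r * (food - pos)
}

# fight step: pos +- k3 * fa * r * (opp_best - pos)
so_fight_step <- function(pos, opp_best, fa, r, sgn, k3) {
  pos + sgn * k3 * fa * r * (opp_best - pos)
}

# mating step: pos +- k3 * ma * r * (q * partner - pos)
so_mate_step <- function(pos, partner, ma, q, r, sgn, k3) {
  pos + sgn * k3 * ma * r * (q * partner - pos)
}

# PSO velocity update (pre-clamp)
pso_velocity <- function(v, x, p_best, g_best, w, c1, c2, r1, r2) {
  w * v + c1 * r1 * (p_best - x) + c2 * r2 * (g_best - x)
}

clamp_velocity <- function(v, bounds, fraction) {
  vmax <- fraction * (bounds$upper - bounds$lower)
  pmin(pmax(v, -vmax), vmax)
}

clip_position <- function(x, bounds) {
  pmin(pmax(x, bounds$lower), bounds$upper)
}

# ---- swarm state -------------------------------------------------------------

evaluate_objective <- function(objective, x) {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    stop("invalid objective: non-finite value at position [",
         paste(signif(x, 6), collapse = ", "), "]", call. = FALSE)
  }
  as.numeric(f)
}

#' Initialize a swarm population
#'
#' Positions are drawn uniformly inside the box
#' (`lower + rand * (upper - lower)`), velocities as
#' `rand * 0.1 * (upper - lower)`.  The population is split into
#' `floor(N/2)` males and `N - floor(N/2)` females; per-candidate and
#' per-gender bests and the food position (global elitist best) are set to the
#' initial minima.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param bounds A [bounds_spec()].
#' @param config An [optimizer_config()].
#' @return A `swarm_state` list (positions, velocities, fitness, roles, bests,
#'   food, RNG streams, trace).
#' @export
init_swarm <- function(objective, bounds, config) {
  n <- config$n_pop
  d <- bounds$dim
  streams <- new_rng_streams(config$seed,
                             c("init", "movement", "signs", "modes", "delta"))
  width <- bounds$upper - bounds$lower
  pos <- matrix(stream_runif(streams$init, n * d), nrow = n)
  pos <- sweep(sweep(pos, 2, width, "*"), 2, bounds$lower, "+")
  vel <- matrix(stream_runif(streams$init, n * d), nrow = n)
  vel <- sweep(vel, 2, 0.1 * width, "*")
  fitness <- vapply(seq_len(n), function(i) evaluate_objective(objective, pos[i, ]), 0)

  n_male <- n %/% 2L
  roles <- rep(c("male", "female"), c(n_male, n - n_male))

  best_i <- which.min(fitness)
  male_idx <- which(roles == "male")
  female_idx <- which(roles == "female")
  bm <- male_idx[which.min(fitness[male_idx])]
  bf <- female_idx[which.min(fitness[female_idx])]

  state <- list(
    iter = 0L,
    positions = pos, velocities = vel, fitness = fitness, roles = roles,
    pbest_positions = pos, pbest_fitness = fitness,
    food_position = pos[best_i, ], food_fitness = fitness[best_i],
    best_male = list(position = pos[bm, ], fitness = fitness[bm]),
    best_female = list(position = pos[bf, ], fitness = fitness[bf]),
    f_min_seen = min(fitness),
    evaluations = n,
    trace = numeric(0),
    streams = streams
  )
  class(state) <- "swarm_state"
  state
}

# shifted strictly positive fitness used by all exp(-a/b) coefficients
shifted_fitness <- function(f, state, config) {
  f - state$f_min_seen + config$eps_fitness
}

# re-evaluate the population at new positions and apply elitist bookkeeping
accept_positions <- function(state, new_pos, objective, bounds, config,
                             new_vel = NULL) {
  n <- nrow(new_pos)
  for (i in seq_len(n)) new_pos[i, ] <- clip_position(new_pos[i, ], bounds)
  fitness <- vapply(seq_len(n), function(i) evaluate_objective(objective, new_pos[i, ]), 0)

  improved <- fitness < state$pbest_fitness
  state$pbest_positions[improved, ] <- new_pos[improved, , drop = FALSE]
  state$pbest_fitness[improved] <- fitness[improved]

  state$positions <- new_pos
  state$fitness <- fitness
  if (!is.null(new_vel)) state$velocities <- new_vel
  state$evaluations <- state$evaluations + n
  state$f_min_seen <- min(state$f_min_seen, fitness)

  for (role in c("male", "female")) {
    idx <- which(state$roles == role)
    if (!length(idx)) next
    b <- idx[which.min(fitness[idx])]
    slot <- if (role == "male") "best_male" else "best_female"
    if (fitness[b] < state[[slot]]$fitness) {
      state[[slot]] <- list(position = new_pos[b, ], fitness = fitness[b])
    }
  }
  b <- which.min(fitness)
  if (fitness[b] < state$food_fitness) {
    state$food_position <- new_pos[b, ]
    state$food_fitness <- fitness[b]
  }
  state
}

#' One Snake Optimizer iteration
#'
#' When food is scarce (`Q < q_threshold`) every snake explores around a
#' random same-gender reference scaled by its foraging ability.  Otherwise,
#' when hot (`Temp > temp_threshold`) all snakes move toward the food
#' position; when cold, one uniform draw per iteration selects fight or
#' mating mode, and after mating the worst male and female may be replaced by
#' fresh random positions (egg hatching).
#'
#' @param state A `swarm_state`.
#' @param objective,bounds,config As in [init_swarm()].
#' @return The advanced `swarm_state`.
#' @export
so_move <- function(state, objective, bounds, config) {
  n <- config$n_pop
  d <- bounds$dim
  env <- swarm_environment(state$iter, config$n_iter, config)
  fsh <- shifted_fitness(state$fitness, state, config)
  sgn <- stream_signs(state$streams$signs, n, config$sign_prob)
  new_pos <- state$positions

  male_idx <- which(state$roles == "male")
  female_idx <- which(state$roles == "female")

  if (env$q < config$q_threshold) {
    # exploration: move around a random same-gender reference
    for (i in seq_len(n)) {
      same <- if (state$roles[i] == "male") male_idx else female_idx
      ref <- same[stream_sample_int(state$streams$movement, length(same))]
      ab <- behavior_coefficient(fsh[ref], fsh[i], config)
      r <- stream_runif(state$streams$movement, d)
      new_pos[i, ] <- so_explore_step(state$positions[ref, ], ab, r, sgn[i],
                                      bounds$lower, bounds$upper, config$k2)
    }
  } else if (env$temp > config$temp_threshold) {
    # hot: every snake follows the food
    for (i in seq_len(n)) {
      r <- stream_runif(state$streams$movement, d)
      new_pos[i, ] <- so_food_step(state$food_position, state$positions[i, ],
                                   env$temp, r, sgn[i], config$k3)
    }
  } else {
    if (!length(male_idx) || !length(female_idx)) {
      stop("degenerate population: fight/mate modes need both genders", call. = FALSE)
    }
    mode_draw <- stream_runif(state$streams$modes, 1)
    fb_m <- shifted_fitness(state$best_male$fitness, state, config)
    fb_f <- shifted_fitness(state$best_female$fitness, state, config)
    if (mode_draw > config$mode_split) {
      # fight: each snake challenges the best of the opposite gender
      for (i in seq_len(n)) {
        if (state$roles[i] == "male") {
          fa <- behavior_coefficient(fb_f, fsh[i], config)
          opp <- state$best_female$position
        } else {
          fa <- behavior_coefficient(fb_m, fsh[i], config)
          opp <- state$best_male$position
        }
        r <- stream_runif(state$streams$movement, d)
        new_pos[i, ] <- so_fight_step(state$positions[i, ], opp, fa, r, sgn[i], config$k3)
      }
    } else {
      # mating: pair the i-th male with the i-th female (recycled)
      for (i in seq_len(n)) {
        if (state$roles[i] == "male") {
          k <- match(i, male_idx)
          j <- female_idx[(k - 1L) %% length(female_idx) + 1L]
        } else {
          k <- match(i, female_idx)
          j <- male_idx[(k - 1L) %% length(male_idx) + 1L]
        }
        ma <- behavior_coefficient(fsh[j], fsh[i], config)
        r <- stream_runif(state$streams$movement, d)
        new_pos[i, ] <- so_mate_step(state$positions[i, ], state$positions[j, ],
                                     ma, env$q, r, sgn[i], config$k3)
      }
      if (stream_runif(state$streams$modes, 1) < config$hatch_prob) {
        # hatch: replace the worst snake of each gender with a random position
        wm <- male_idx[which.max(state$fitness[male_idx])]
        wf <- female_idx[which.max(state$fitness[female_idx])]
        for (idx in c(wm, wf)) {
          r <- stream_runif(state$streams$movement, d)
          new_pos[idx, ] <- bounds$lower + r * (bounds$upper - bounds$lower)
        }
      }
    }
  }

  state <- accept_positions(state, new_pos, objective, bounds, config)
  state$iter <- state$iter + 1L
  state$trace <- c(state$trace, state$food_fitness)
  state
}

#' One PSO iteration
#'
#' Standard inertia-weight velocity update with per-dimension random
#' coefficients, velocity clamped to `v_max_fraction` of the box width,
#' position clipped to the box, elitist global best.
#'
#' @inheritParams so_move
#' @return The advanced `swarm_state`.
#' @export
pso_move <- function(state, objective, bounds, config) {
  psso_step(state, objective, bounds, config, use_delta = FALSE)
}

#' One hybrid PSSO iteration
#'
#' The PSO velocity update augmented with a snake-derived environmental
#' displacement `delta_SO`: food attraction `k3 * Temp * r3 * (food - x)` when
#' food is plentiful (`Q > q_threshold`), otherwise a gendered fight-style
#' displacement `k3 * FA * r3 * (opposite_gender_best - x)`.  After each
#' iteration the snake egg-hatching behaviour fires with probability
#' `hatch_prob`: the worst male and worst female are replaced by fresh random
#' positions and velocities, which keeps the swarm sampling after the PSO
#' attractors have collapsed onto the elitist best.  With
#' `config$delta_so = FALSE` both snake components are suppressed and the
#' iteration is exactly a PSO iteration (identical RNG consumption).
#'
#' @inheritParams so_move
#' @return The advanced `swarm_state`.
#' @export
psso_move <- function(state, objective, bounds, config) {
  psso_step(state, objective, bounds, config, use_delta = config$delta_so)
}

psso_step <- function(state, objective, bounds, config, use_delta) {
  n <- config$n_pop
  d <- bounds$dim
  env <- swarm_environment(state$iter, config$n_iter, config)
  fsh <- shifted_fitness(state$fitness, state, config)
  fb_m <- shifted_fitness(state$best_male$fitness, state, config)
  fb_f <- shifted_fitness(state$best_female$fitness, state, config)

  new_pos <- state$positions
  new_vel <- state$velocities
  for (i in seq_len(n)) {
    r1 <- stream_runif(state$streams$movement, d)
    r2 <- stream_runif(state$streams$movement, d)
    v <- pso_velocity(state$velocities[i, ], state$positions[i, ],
                      state$pbest_positions[i, ], state$food_position,
                      config$w, config$c1, config$c2, r1, r2)
    if (use_delta) {
      r3 <- stream_runif(state$streams$delta, d)
      if (env$q > config$q_threshold) {
        delta <- config$k3 * env$temp * r3 * (state$food_position - state$positions[i, ])
      } else {
        if (state$roles[i] == "male") {
          fa <- behavior_coefficient(fb_f, fsh[i], config)
          opp <- state$best_female$position
        } else {
          fa <- behavior_coefficient(fb_m, fsh[i], config)
          opp <- state$best_male$position
        }
        delta <- config$k3 * fa * r3 * (opp - state$positions[i, ])
      }
      v <- v + delta
    }
    v <- clamp_velocity(v, bounds, config$v_max_fraction)
    new_vel[i, ] <- v
    new_pos[i, ] <- state$positions[i, ] + v
  }

  state <- accept_positions(state, new_pos, objective, bounds, config, new_vel)

  if (use_delta && stream_runif(state$streams$delta, 1) < config$hatch_prob) {
    # egg hatching: re-seed the worst snake of each gender
    male_idx <- which(state$roles == "male")
    female_idx <- which(state$roles == "female")
    refresh <- c(male_idx[which.max(state$fitness[male_idx])],
                 female_idx[which.max(state$fitness[female_idx])])
    width <- bounds$upper - bounds$lower
    for (idx in refresh) {
      p <- bounds$lower + stream_runif(state$streams$delta, d) * width
      f <- evaluate_objective(objective, p)
      state$positions[idx, ] <- p
      state$velocities[idx, ] <- stream_runif(state$streams$delta, d) * 0.1 * width
      state$fitness[idx] <- f
      state$evaluations <- state$evaluations + 1L
      state$f_min_seen <- min(state$f_min_seen, f)
      if (f < state$pbest_fitness[idx]) {
        state$pbest_fitness[idx] <- f
        state$pbest_positions[idx, ] <- p
      }
      slot <- if (state$roles[idx] == "male") "best_male" else "best_female"
      if (f < state[[slot]]$fitness) state[[slot]] <- list(position = p, fitness = f)
      if (f < state$food_fitness) {
        state$food_position <- p
        state$food_fitness <- f
      }
    }
  }

  state$iter <- state$iter + 1L
  state$trace <- c(state$trace, state$food_fitness)
  state
}

#' Run a bound-constrained swarm optimization
#'
#' Minimizes `objective` over the box with the selected algorithm for a fixed
#' number of iterations.  Runs are fully deterministic given
#' `config$seed`; the returned convergence trace records the elitist best
#' after each iteration and is therefore non-increasing.
#'
#' @param objective Function: numeric position vector -> finite scalar.
#' @param bounds A [bounds_spec()].
#' @param config An [optimizer_config()].
#' @param algorithm One of `"psso"`, `"so"`, `"pso"`.
#' @return An object of class `swarm_result` with `best_position`,
#'   `best_fitness`, `trace` (length `n_iter`), `evaluations`, `seed`,
#'   `algorithm`.
#' @examples
#' b <- analytic_benchmark("quadratic1d")
#' res <- optimize_swarm(b$objective, b$bounds,
#'                       optimizer_config(n_pop = 10, n_iter = 50, seed = 7))
#' res$best_position  # near 3
#' @export
optimize_swarm <- function(objective, bounds, config = optimizer_config(),
                           algorithm = c("psso", "so", "pso")) {
  algorithm <- match.arg(algorithm)
  step <- switch(algorithm, so = so_move, pso = pso_move, psso = psso_move)
  state <- init_swarm(objective, bounds, config)
  for (k in seq_len(config$n_iter)) {
    state <- step(state, objective, bounds, config)
  }
  structure(list(best_position = state$food_position,
                 best_fitness = state$food_fitness,
                 trace = state$trace,
                 evaluations = state$evaluations,
                 seed = config$seed,
                 algorithm = algorithm,
                 final_state = state),
            class = "swarm_result")
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result: %s>\n", x$algorithm))
  cat(sprintf("  best fitness: %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  cat(sprintf("  best position: [%s]\n",
              paste(signif(x$best_position, 5), collapse = ", ")))
  invisible(x)
}

#' Export a convergence trace
#'
#' @param result A `swarm_result`.
#' @param path Output file path.
#' @param format `"csv"` (iteration, best_fitness columns) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- data.frame(iteration = seq_along(result$trace),
                   best_fitness = result$trace)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA)
  }
  invisible(path)
}
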