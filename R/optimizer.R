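# Hybrid seek optimization: a crow-search ("corvid") position update and a
# sparrow-search ("gregarious") update averaged into a single proposal, with
# per-agent memory elitism and reject-infeasible bound handling. Fitness is
# MAXIMIZED.

#' Hybrid seek optimizer configuration
#'
#' @param population_size Number of search agents m (>= 2), default 25.
#' @param max_iterations Iteration budget, default 100.
#' @param flight_length Corvid flight length `a`, default 2.
#' @param awareness_probability Probability that the followed agent is
#'   "aware", sending the follower to a uniform random position; in
#'   `[0, 1]`, default 0.1.
#' @param bounds Two-column matrix of per-dimension `[lo, hi]` bounds, or a
#'   length-2 vector recycled over dimensions.
#' @param epsilon Small positive guard added to the fitness-gap denominator
#'   of the best-agent move, default 1e-12.
#' @param seed Integer seed; trajectories are bit-identical per seed.
#' @return A `hybrid_seek_config` list.
#' @export
hybrid_seek_config <- function(population_size = 25L, max_iterations = 100L,
                               flight_length = 2, awareness_probability = 0.1,
                               bounds = c(0, 1), epsilon = 1e-12, seed = 1L) {
  if (population_size < 2) stop("population_size must be at least 2")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  if (awareness_probability < 0 || awareness_probability > 1) {
    stop("awareness_probability must lie in [0, 1]")
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 flight_length = flight_length,
                 awareness_probability = awareness_probability,
                 bounds = bounds, epsilon = epsilon, seed = as.integer(seed)),
            class = "hybrid_seek_config")
}

expand_bounds <- function(bounds, dimension) {
  if (is.matrix(bounds)) {
    if (nrow(bounds) == 1L) bounds <- bounds[rep(1L, dimension), , drop = FALSE]
    if (nrow(bounds) != dimension || ncol(bounds) != 2L) {
      stop("bounds must be a dimension x 2 matrix")
    }
  } else {
    if (length(bounds) != 2L) stop("bounds must be c(lo, hi) or a matrix")
    bounds <- matrix(bounds, dimension, 2L, byrow = TRUE)
  }
  if (any(bounds[, 1] >= bounds[, 2])) stop("each lower bound must be below its upper bound")
  bounds
}

#' Initialize the swarm
#'
#' Places the agents uniformly within the bounds, sets each agent's memory
#' to its initial position (the food starts where the agent starts),
#' evaluates all fitnesses and zeroes the shared velocity. Draws from the
#' current RNG stream.
#'
#' @param config A [hybrid_seek_config()].
#' @param dimension Problem dimension (>= 1).
#' @param fitness Function mapping a position vector to a finite scalar;
#'   higher is better.
#' @return A swarm state list with `positions`, `memory` (m x d matrices),
#'   `fitness`, `memory_fitness`, `velocity`, `evaluations`.
#' @export
initialize_swarm <- function(config, dimension, fitness) {
  if (dimension < 1) stop("dimension must be at least 1")
  b <- expand_bounds(config$bounds, dimension)
  m <- config$population_size
  pos <- matrix(stats::runif(m * dimension), m, dimension)
  pos <- sweep(sweep(pos, 2, b[, 2] - b[, 1], "*"), 2, b[, 1], "+")
  fit <- apply(pos, 1, fitness)
  if (any(!is.finite(fit))) stop("fitness is non-finite at an initial position")
  list(positions = pos, memory = pos, fitness = fit, memory_fitness = fit,
       velocity = numeric(dimension), bounds = b, evaluations = m)
}

#' Corvid (crow-search) position proposal
#'
#' Agent `e` follows a uniformly drawn flock-mate `f != e`. If the mate is
#' unaware (probability `1 - awareness_probability`) the proposal is
#' `J_e + lambda1 * a * (Z_f - J_e)` toward the mate's memorized position;
#' if aware, the follower is thrown to a uniform random position within the
#' bounds. Draws from the current RNG stream.
#'
#' @param agent Index of the moving agent.
#' @param state Swarm state from [initialize_swarm()].
#' @param config A [hybrid_seek_config()].
#' @return Proposed position vector.
#' @export
corvid_step <- function(agent, state, config) {
  m <- nrow(state$positions)
  others <- setdiff(seq_len(m), agent)
  f <- others[sample.int(length(others), 1L)]
  if (stats::runif(1) < config$awareness_probability) {
    b <- state$bounds
    return(b[, 1] + stats::runif(ncol(state$positions)) * (b[, 2] - b[, 1]))
  }
  lambda1 <- stats::runif(1)
  state$positions[agent, ] +
    lambda1 * config$flight_length * (state$memory[f, ] - state$positions[agent, ])
}

#' Gregarious (sparrow-search) position proposal
#'
#' The current best agent explores relative to the worst:
#' `J_e + chi * |J_e - J_worst| / ((j_e - j_ws) + epsilon)`; every other
#' agent moves around the global best with the velocity augmentation:
#' `J_best + theta * |J_e - J_best * (1 + nu1 * w) + V|`. `theta, nu1, w`
#' are Uniform(0,1) and `chi` Uniform(-1,1), redrawn per call.
#'
#' @param agent Index of the moving agent.
#' @param state Swarm state; `best`/`worst` are taken from the memories.
#' @param config A [hybrid_seek_config()].
#' @return Proposed position vector.
#' @export
gregarious_step <- function(agent, state, config) {
  best_i <- which.max(state$memory_fitness)
  worst_i <- which.min(state$memory_fitness)
  j_best <- state$memory[best_i, ]
  pos <- state$positions[agent, ]
  if (agent == best_i) {
    chi <- stats::runif(1, -1, 1)
    gap <- (state$memory_fitness[agent] - state$memory_fitness[worst_i]) +
      config$epsilon
    pos + chi * abs(pos - state$memory[worst_i, ]) / gap
  } else {
    theta <- stats::runif(1)
    nu1 <- stats::runif(1)
    w <- stats::runif(1)
    j_best + theta * abs(pos - j_best * (1 + nu1 * w) + state$velocity)
  }
}

#' Hybrid position: midpoint of the two proposals
#'
#' @param corvid_pos,gregarious_pos Equal-length position vectors.
#' @return `0.5 * corvid_pos + 0.5 * gregarious_pos`.
#' @export
hybrid_step <- function(corvid_pos, gregarious_pos) {
  if (length(corvid_pos) != length(gregarious_pos)) {
    stop("proposals have mismatching dimensions")
  }
  0.5 * corvid_pos + 0.5 * gregarious_pos
}

#' Feasibility check for a proposed position
#'
#' The proposal is accepted only if every coordinate lies within its closed
#' bounds; otherwise the caller keeps the old position (no clipping).
#'
#' @param position Proposed position vector.
#' @param bounds Dimension x 2 bounds matrix.
#' @return List with `feasible` (logical) and `position` (the proposal).
#' @export
clamp_feasible <- function(position, bounds) {
  feasible <- all(position >= bounds[, 1] & position <= bounds[, 2])
  list(feasible = feasible, position = position)
}

#' Memory update with strict-improvement elitism
#'
#' Replaces agent `e`'s memory by its current position iff the new fitness
#' strictly exceeds the memorized fitness (ties keep the old memory).
#'
#' @param state Swarm state.
#' @param agent Agent index.
#' @param new_fitness Fitness of the agent's current position.
#' @return The updated state.
#' @export
update_memory <- function(state, agent, new_fitness) {
  state$fitness[agent] <- new_fitness
  if (new_fitness > state$memory_fitness[agent]) {
    state$memory[agent, ] <- state$positions[agent, ]
    state$memory_fitness[agent] <- new_fitness
  }
  state
}

#' Run the hybrid seek optimizer
#'
#' Each iteration proposes, per agent, a corvid and a gregarious move,
#' averages them, applies the reject-infeasible rule, re-evaluates the
#' agent, and updates its memory under strict elitism. The shared velocity
#' is advanced once per iteration as `V <- V + nu1 * w * J_best`. Returns
#' the best memory over all agents.
#'
#' @param fitness Function position -> finite scalar, maximized.
#' @param dimension Problem dimension.
#' @param config A [hybrid_seek_config()].
#' @return A list with `best_position`, `best_fitness`, `history`
#'   (best-so-far fitness per iteration, non-decreasing), `evaluations`.
#' @export
hs_optimize <- function(fitness, dimension, config = hybrid_seek_config()) {
  with_seed(config$seed, {
    state <- initialize_swarm(config, dimension, fitness)
    history <- numeric(config$max_iterations)
    for (iter in seq_len(config$max_iterations)) {
      best_i <- which.max(state$memory_fitness)
      nu1 <- stats::runif(1)
      w <- stats::runif(1)
      state$velocity <- state$velocity + nu1 * w * state$memory[best_i, ]
      for (e in seq_len(nrow(state$positions))) {
        proposal <- hybrid_step(corvid_step(e, state, config),
                                gregarious_step(e, state, config))
        chk <- clamp_feasible(proposal, state$bounds)
        if (chk$feasible) state$positions[e, ] <- chk$position
        f_new <- fitness(state$positions[e, ])
        if (!is.finite(f_new)) {
          stop("fitness returned a non-finite value at position (",
               paste(signif(state$positions[e, ], 6), collapse = ", "), ")")
        }
        state$evaluations <- state$evaluations + 1L
        state <- update_memory(state, e, f_new)
      }
      history[iter] <- max(state$memory_fitness)
    }
    best_i <- which.max(state$memory_fitness)
    list(best_position = state$memory[best_i, ],
         best_fitness = state$memory_fitness[best_i],
         history = history, evaluations = state$evaluations)
  })
}

#' Write a convergence history to CSV
#'
#' @param result Result of [hs_optimize()].
#' @param path Output CSV path with columns `iteration`, `best_fitness`.
#' @return `path`, invisibly.
#' @export
write_convergence_csv <- function(result, path) {
  utils::write.csv(data.frame(iteration = seq_along(result$history),
                              best_fitness = result$history),
                   path, row.names = FALSE)
  invisible(path)
}
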