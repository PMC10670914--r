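# Scalar-population swarm updates. One optimizer run works on one image's
# feature vector: each agent is a single scalar feature, bounds come from the
# feature vector itself, and the objective is the local-variance fitness below.

#' Local-variance fitness of one agent
#'
#' The fitness of an agent is the population variance (denominator 5) of the
#' 5-element window centred on it: the agent's own value and its four
#' index-nearest neighbours. At the edges the window shifts inward so it
#' always contains five valid elements.
#'
#' @param positions Numeric vector of at least 5 agent positions.
#' @param index 1-based agent index.
#' @return The window's population variance (a single real).
#' @examples
#' variance_fitness(c(2, 3, 4, 5, 6), 3) # 2
#' @export
variance_fitness <- function(positions, index) {
  n <- length(positions)
  if (n < 5L) stop("variance_fitness: need at least 5 positions")
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > n) {
    stop("variance_fitness: index out of range")
  }
  start <- min(max(index - 2L, 1L), n - 4L)
  w <- positions[start:(start + 4L)]
  mean((w - mean(w))^2)
}

#' Local-variance fitness of every agent
#'
#' Vectorised form of [variance_fitness()]: returns the fitness of all agents
#' in one pass.
#'
#' @param positions Numeric vector of at least 5 agent positions.
#' @return Numeric vector of the same length as `positions`.
#' @export
variance_fitness_all <- function(positions) {
  n <- length(positions)
  if (n < 5L) stop("variance_fitness_all: need at least 5 positions")
  starts <- pmin(pmax(seq_len(n) - 2L, 1L), n - 4L)
  # cumulative sums give O(n) window means and mean squares
  cs <- c(0, cumsum(positions))
  cs2 <- c(0, cumsum(positions^2))
  m <- (cs[starts + 5L] - cs[starts]) / 5
  m2 <- (cs2[starts + 5L] - cs2[starts]) / 5
  pmax(m2 - m^2, 0)
}

#' Linearly shrinking sine-cosine radius
#'
#' `rad = const - crnt_iter * (const / max_iter)`: equal to `const` at
#' iteration zero and to 0 at the final iteration.
#'
#' @param crnt_iter Current iteration, `0 <= crnt_iter <= max_iter`.
#' @param max_iter Maximum number of iterations (>= 1).
#' @param const Starting radius (default 3).
#' @return The radius, a single real.
#' @export
compute_rad <- function(crnt_iter, max_iter, const = 3) {
  if (max_iter < 1L) stop("compute_rad: max_iter must be >= 1")
  if (crnt_iter < 0 || crnt_iter > max_iter) {
    stop("compute_rad: crnt_iter must lie in [0, max_iter]")
  }
  const - crnt_iter * (const / max_iter)
}

#' Index of the silverback (best-fitness) agent
#'
#' @param fitness Non-empty numeric vector of finite fitness values.
#' @return 1-based index of the maximum; ties broken by the lowest index.
#' @export
select_silverback <- function(fitness) {
  if (length(fitness) == 0L) stop("select_silverback: empty fitness vector")
  if (!all(is.finite(fitness))) stop("select_silverback: non-finite fitness value")
  which.max(fitness)
}

#' Clamp positions into bounds
#'
#' @param positions Numeric vector.
#' @param bounds A [scalar_bounds()].
#' @return `positions` with every element clamped into
#'   `[bounds$lower, bounds$upper]`; order and length preserved.
#' @export
clip_positions <- function(positions, bounds) {
  pmin(pmax(positions, bounds$lower), bounds$upper)
}

#' Per-iteration step coefficients
#'
#' Draws the scalar random symbols shared by one iteration's position updates
#' and derives the step coefficients from them:
#' `F = cos(2 r4) + 1`, `C = F (1 - iteration / max_iter)`, `L = C l`,
#' `g = 2^L` (or `2 L` under `g_mode = "linear"`), `Q = 2 r5 - 1`,
#' `E` = a uniform draw on the position bounds or a \[0, 1\]-truncated
#' standard normal depending on a fair coin, `A = beta * E`, and the
#' sine-cosine radius from [compute_rad()]. `Z` is drawn uniformly on
#' `[-C, C]`; the per-agent coefficient `H = Z * X(t)` is formed inside the
#' exploration updates.
#'
#' When `draws` is `NULL` the symbols are taken from R's random stream in the
#' order `r4, l, Z, r5, rand_e, u_e`; a list pinning any subset of
#' `r4, l, Z, r5, rand_e, u_e` replaces those draws (used by the equation
#' oracles in the test-suite).
#'
#' @param iteration Current iteration (0-based), `<= max_iter`.
#' @param max_iter Maximum number of iterations.
#' @param params An [mgto_params()].
#' @param bounds A [scalar_bounds()] for the `E` uniform branch.
#' @param draws Optional list of pinned draws.
#' @return A list with elements `iteration, max_iter, F, C, L, l, Z, g, rad,
#'   Q, E, A, beta, const`.
#' @export
swarm_coefficients <- function(iteration, max_iter, params, bounds,
                               draws = NULL) {
  if (iteration > max_iter) stop("swarm_coefficients: iteration exceeds max_iter")
  pick <- function(name, rfun) {
    if (!is.null(draws) && !is.null(draws[[name]])) draws[[name]] else rfun()
  }
  r4 <- pick("r4", function() stats::runif(1))
  l <- pick("l", function() {
    if (params$l_mode == "integer") sample(c(-1, 0, 1), 1L) else stats::runif(1, -1, 1)
  })
  Fc <- cos(2 * r4) + 1
  C <- Fc * (1 - iteration / max_iter)
  L <- C * l
  Z <- pick("Z", function() stats::runif(1, -C, C))
  if (abs(Z) > abs(C) + 1e-12) stop("swarm_coefficients: |Z| must not exceed |C|")
  r5 <- pick("r5", function() stats::runif(1))
  rand_e <- pick("rand_e", function() stats::runif(1))
  u_e <- pick("u_e", function() stats::runif(1))
  g <- if (params$g_mode == "linear") 2 * L else 2^L
  Q <- 2 * r5 - 1
  E <- if (rand_e >= 0.5) {
    bounds$lower + (bounds$upper - bounds$lower) * u_e
  } else {
    # standard normal truncated to [0, 1], via inverse CDF so one uniform
    # advances the stream on either branch
    stats::qnorm(stats::pnorm(0) + u_e * (stats::pnorm(1) - stats::pnorm(0)))
  }
  A <- params$beta * E
  list(iteration = iteration, max_iter = max_iter, F = Fc, C = C, L = L,
       l = l, Z = Z, g = g, rad = compute_rad(iteration, max_iter, params$const),
       Q = Q, E = E, A = A, beta = params$beta, const = params$const)
}

# Vector draws for one exploration update, in the order the symbols appear in
# the governing equation; every symbol is drawn for every agent regardless of
# the branch taken so the stream is branch-independent.
exploration_draws <- function(n, modified, draws = NULL) {
  pick <- function(name, rfun) {
    if (!is.null(draws) && !is.null(draws[[name]])) draws[[name]] else rfun()
  }
  out <- list(rand = pick("rand", function() stats::runif(n)),
              r1 = pick("r1", function() stats::runif(n)),
              r2 = pick("r2", function() stats::runif(n)))
  if (!modified) out$r3 <- pick("r3", function() stats::runif(n))
  out$xr_idx <- pick("xr_idx", function() sample.int(n, n, replace = TRUE))
  out
}

#' Plain-optimizer exploration update
#'
#' Three-branch exploration move. Per agent a single uniform `rand` selects:
#' `rand < p` migrates to an unknown place (`(Ul - Ll) r1 + Ll`);
#' otherwise `rand >= 0.5` moves toward a randomly chosen other agent
#' (`(r2 - C) Xr + L H` with `H = Z X(t)`); otherwise the agent moves along a
#' known direction (`X - L (L (X - Xr) + r3 (X - Xr))`). The result is
#' clamped into bounds.
#'
#' @param positions Numeric vector of agent positions.
#' @param bounds A [scalar_bounds()].
#' @param params An [mgto_params()] (supplies `p`).
#' @param coeffs Coefficients from [swarm_coefficients()].
#' @param draws Optional pinned draws: `rand, r1, r2, r3, xr_idx`
#'   (each length `N`).
#' @return Updated positions.
#' @export
gto_update_exploration <- function(positions, bounds, params, coeffs,
                                   draws = NULL) {
  n <- length(positions)
  d <- exploration_draws(n, modified = FALSE, draws = draws)
  xr <- positions[d$xr_idx]
  H <- coeffs$Z * positions
  new <- ifelse(
    d$rand < params$p,
    (bounds$upper - bounds$lower) * d$r1 + bounds$lower,
    ifelse(
      d$rand >= 0.5,
      (d$r2 - coeffs$C) * xr + coeffs$L * H,
      positions - coeffs$L * (coeffs$L * (positions - xr) +
                                d$r3 * (positions - xr))
    )
  )
  clip_positions(new, bounds)
}

# Silverback-follow magnitude: M = (|mean(X)|^g)^(1/g); defined as 0 when the
# population mean is exactly 0 (0^g with fractional g is otherwise NaN-prone).
compute_m <- function(positions, g) {
  mu <- mean(positions)
  if (mu == 0) return(0)
  (abs(mu)^g)^(1 / g)
}

#' Plain-optimizer silverback-follow update
#'
#' `X(t+1) = L M (X(t) - Xsilverback) + X(t)`, clamped into bounds.
#'
#' @param positions Numeric vector of agent positions.
#' @param silverback_index 1-based index of the best-fitness agent.
#' @param bounds A [scalar_bounds()].
#' @param coeffs Coefficients from [swarm_coefficients()].
#' @param M Optional override of the follow magnitude (tests); computed from
#'   the population mean and `coeffs$g` when `NULL`.
#' @return Updated positions.
#' @export
gto_update_silverback <- function(positions, silverback_index, bounds, coeffs,
                                  M = NULL) {
  if (is.null(M)) M <- compute_m(positions, coeffs$g)
  sb <- positions[silverback_index]
  clip_positions(coeffs$L * M * (positions - sb) + positions, bounds)
}

#' Plain-optimizer competition update
#'
#' `X(t+1) = Xsilverback - (Xsilverback Q - X(t) Q) A`, clamped into bounds.
#'
#' @inheritParams gto_update_silverback
#' @return Updated positions.
#' @export
gto_update_competition <- function(positions, silverback_index, bounds,
                                   coeffs) {
  sb <- positions[silverback_index]
  clip_positions(sb - (sb * coeffs$Q - positions * coeffs$Q) * coeffs$A, bounds)
}

#' Sine-cosine exploration update
#'
#' As [gto_update_exploration()] but with the third branch replaced by the
#' sine-cosine move
#' `X - L rad sin(X - Xr) + rad cos(X - Xr)`.
#'
#' @inheritParams gto_update_exploration
#' @param draws Optional pinned draws: `rand, r1, r2, xr_idx`.
#' @return Updated positions.
#' @export
mgto_update_exploration <- function(positions, bounds, params, coeffs,
                                    draws = NULL) {
  n <- length(positions)
  d <- exploration_draws(n, modified = TRUE, draws = draws)
  xr <- positions[d$xr_idx]
  H <- coeffs$Z * positions
  diff <- positions - xr
  new <- ifelse(
    d$rand < params$p,
    (bounds$upper - bounds$lower) * d$r1 + bounds$lower,
    ifelse(
      d$rand >= 0.5,
      (d$r2 - coeffs$C) * xr + coeffs$L * H,
      positions - coeffs$L * coeffs$rad * sin(diff) + coeffs$rad * cos(diff)
    )
  )
  clip_positions(new, bounds)
}

#' Sine-cosine silverback-follow update
#'
#' `X(t+1) = L M rad sin(X(t) - Xsilverback) + X(t)`, clamped into bounds.
#'
#' @inheritParams gto_update_silverback
#' @return Updated positions.
#' @export
mgto_update_silverback <- function(positions, silverback_index, bounds, coeffs,
                                   M = NULL) {
  if (is.null(M)) M <- compute_m(positions, coeffs$g)
  sb <- positions[silverback_index]
  clip_positions(
    coeffs$L * M * coeffs$rad * sin(positions - sb) + positions, bounds
  )
}

#' Sine-cosine competition update
#'
#' `X(t+1) = Xsilverback - rad cos(Xsilverback Q - X(t) Q) A`, clamped into
#' bounds.
#'
#' @inheritParams gto_update_silverback
#' @return Updated positions.
#' @export
mgto_update_competition <- function(positions, silverback_index, bounds,
                                    coeffs) {
  sb <- positions[silverback_index]
  clip_positions(
    sb - coeffs$rad * cos(sb * coeffs$Q - positions * coeffs$Q) * coeffs$A,
    bounds
  )
}

#' One Particle Swarm Optimization step
#'
#' Velocities follow
#' `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`; positions are
#' `x' = x + v'`, clamped into bounds. Personal bests are replaced when the
#' new local-variance fitness strictly improves (maximization convention);
#' the global best is the personal best with maximal fitness.
#'
#' @param state List with `positions`, `velocities`, `personal_best`,
#'   `personal_best_fitness`, `global_best`, `iteration`.
#' @param params A [pso_params()].
#' @param bounds A [scalar_bounds()].
#' @param draws Optional pinned draws `r1, r2` (each length `N`).
#' @return The updated state list.
#' @export
pso_step <- function(state, params, bounds, draws = NULL) {
  n <- length(state$positions)
  pick <- function(name) {
    if (!is.null(draws) && !is.null(draws[[name]])) draws[[name]] else stats::runif(n)
  }
  r1 <- pick("r1")
  r2 <- pick("r2")
  v <- params$w * state$velocities +
    params$c1 * r1 * (state$personal_best - state$positions) +
    params$c2 * r2 * (state$global_best - state$positions)
  x <- clip_positions(state$positions + v, bounds)
  fit <- variance_fitness_all(x)
  improved <- fit > state$personal_best_fitness
  state$personal_best[improved] <- x[improved]
  state$personal_best_fitness[improved] <- fit[improved]
  gi <- select_silverback(state$personal_best_fitness)
  list(positions = x, velocities = v,
       personal_best = state$personal_best,
       personal_best_fitness = state$personal_best_fitness,
       global_best = state$personal_best[gi],
       iteration = state$iteration + 1L)
}

#' One Elephant Herding Optimization step (single clan)
#'
#' The clan centre is the mean position; the matriarch position is
#' `beta_e * centre`. Every agent moves by
#' `x' = x + alpha (xbest - x) ran` with its own uniform `ran`; the agent
#' with the lowest local-variance fitness is then replaced by
#' `xmin + (xmax - xmin + 1) rand`. Positions are clamped into bounds.
#'
#' @param positions Numeric vector of agent positions.
#' @param params An [eho_params()].
#' @param bounds A [scalar_bounds()] (also the `xmin`/`xmax` of the
#'   worst-agent replacement).
#' @param draws Optional pinned draws: `ran` (length `N`) and `rand`
#'   (length 1).
#' @return Updated positions.
#' @export
eho_step <- function(positions, params, bounds, draws = NULL) {
  n <- length(positions)
  pick <- function(name, rfun) {
    if (!is.null(draws) && !is.null(draws[[name]])) draws[[name]] else rfun()
  }
  ran <- pick("ran", function() stats::runif(n))
  xbest <- params$beta_e * mean(positions)
  new <- positions + params$alpha * (xbest - positions) * ran
  fit <- variance_fitness_all(new)
  worst <- which.min(fit)
  rand <- pick("rand", function() stats::runif(1))
  new[worst] <- bounds$lower + (bounds$upper - bounds$lower + 1) * rand
  clip_positions(new, bounds)
}

#' Transform one feature vector with a swarm optimizer
#'
#' Runs one optimizer over one image's feature vector: the population is
#' initialised at the feature values (one agent per feature), bounds are the
#' vector's min and max, and after `max_iter` iterations the final agent
#' positions are the transformed features. Iterations for the troop
#' optimizers follow the shared loop: exploration update, local-variance
#' fitness, silverback selection, then silverback-follow if `|C| >= 1` and
#' the competition update otherwise. Particle-swarm and elephant-herding runs
#' replace those stages with their own step. The iteration counter runs
#' `0 .. max_iter - 1`.
#'
#' @param features Numeric vector of length >= 5.
#' @param algorithm One of `"mgto"`, `"gto"`, `"pso"`, `"eho"`.
#' @param params Matching parameter record ([mgto_params()], [pso_params()],
#'   [eho_params()]); defaults to the algorithm's defaults.
#' @param return_trace If `TRUE`, also return per-iteration positions,
#'   fitness and silverback indices (used by the invariant tests).
#' @return The transformed feature vector (same length and order), or a list
#'   with `positions` and `trace` when `return_trace = TRUE`.
#' @examples
#' set.seed(1)
#' x <- rnorm(16)
#' y <- run_swarm_transform(x, "mgto", mgto_params(max_iter = 5))
#' range(y) # within range(x)
#' @export
run_swarm_transform <- function(features,
                                algorithm = c("mgto", "gto", "pso", "eho"),
                                params = NULL, return_trace = FALSE) {
  algorithm <- match.arg(algorithm)
  features <- as.numeric(features)
  n <- length(features)
  if (n < 5L) stop("run_swarm_transform: need at least 5 features")
  if (is.null(params)) params <- default_params_for(algorithm)
  bounds <- scalar_bounds(min(features), max(features))
  max_iter <- params$max_iter
  trace <- if (return_trace) vector("list", max_iter) else NULL
  pos <- features
  if (max_iter >= 1L) {
    if (algorithm %in% c("gto", "mgto")) {
      modified <- algorithm == "mgto"
      for (t in seq_len(max_iter) - 1L) {
        co <- swarm_coefficients(t, max_iter, params, bounds)
        pos <- if (modified) {
          mgto_update_exploration(pos, bounds, params, co)
        } else {
          gto_update_exploration(pos, bounds, params, co)
        }
        fit <- variance_fitness_all(pos)
        sb <- select_silverback(fit)
        pos <- if (abs(co$C) >= 1) {
          if (modified) mgto_update_silverback(pos, sb, bounds, co)
          else gto_update_silverback(pos, sb, bounds, co)
        } else {
          if (modified) mgto_update_competition(pos, sb, bounds, co)
          else gto_update_competition(pos, sb, bounds, co)
        }
        if (return_trace) {
          fit_end <- variance_fitness_all(pos)
          trace[[t + 1L]] <- list(positions = pos, fitness = fit_end,
                                  silverback = select_silverback(fit_end),
                                  C = co$C)
        }
      }
    } else if (algorithm == "pso") {
      fit0 <- variance_fitness_all(pos)
      state <- list(positions = pos, velocities = numeric(n),
                    personal_best = pos, personal_best_fitness = fit0,
                    global_best = pos[select_silverback(fit0)],
                    iteration = 0L)
      for (t in seq_len(max_iter)) {
        state <- pso_step(state, params, bounds)
        if (return_trace) {
          trace[[t]] <- list(positions = state$positions,
                             fitness = variance_fitness_all(state$positions),
                             global_best = state$global_best)
        }
      }
      pos <- state$positions
    } else { # eho
      for (t in seq_len(max_iter)) {
        pos <- eho_step(pos, params, bounds)
        if (return_trace) {
          fit_end <- variance_fitness_all(pos)
          trace[[t]] <- list(positions = pos, fitness = fit_end,
                             silverback = select_silverback(fit_end))
        }
      }
    }
  }
  if (return_trace) list(positions = pos, trace = trace) else pos
}
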