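# Position-update mathematics of the four optimizers, the local-variance
# fitness, and the shared iteration loop.

test_that("local-variance fitness matches a naive two-pass variance on every window", {
  expect_equal(variance_fitness(c(7, 7, 7, 7, 7, 7), 4), 0)
  expect_equal(variance_fitness(c(2, 3, 4, 5, 6), 3), 2)
  # shifted edge window covers all five elements: mean 2, sum dev^2 = 80
  expect_equal(variance_fitness(c(0, 0, 0, 0, 10), 1), 16)
  expect_error(variance_fitness(1:4, 1), "at least 5")
  expect_error(variance_fitness(1:6, 7), "out of range")

  set.seed(11)
  for (n in c(5, 6, 9, 20)) {
    x <- rnorm(n)
    expect_equal(variance_fitness_all(x),
                 vapply(seq_len(n), function(i) naive_window_variance(x, i), 0),
                 tolerance = 1e-12)
    for (i in seq_len(n)) {
      expect_equal(variance_fitness(x, i), naive_window_variance(x, i),
                   tolerance = 1e-12)
    }
  }
})

test_that("sine-cosine radius is linear from const to zero", {
  expect_equal(compute_rad(0, 11, 3), 3)
  expect_equal(compute_rad(11, 11, 3), 0)
  expect_equal(compute_rad(5, 10, 3), 1.5)
  expect_error(compute_rad(1, 0, 3), "max_iter")
  for (mi in c(1, 7, 11, 20)) {
    r <- vapply(0:mi, compute_rad, 0, max_iter = mi, const = 3)
    expect_equal(diff(r), rep(-3 / mi, mi), tolerance = 1e-12)
  }
})

test_that("silverback selection takes the max with lowest-index tie-break", {
  expect_equal(select_silverback(0.4), 1L)
  expect_equal(select_silverback(c(0.1, 0.9, 0.3)), 2L)
  expect_equal(select_silverback(c(0.5, 0.5, 0.2)), 1L)
  set.seed(2)
  for (k in 1:50) {
    f <- sample(round(runif(8), 1)) # ties likely
    expect_equal(select_silverback(f), which(f == max(f))[1])
  }
  expect_error(select_silverback(numeric(0)), "empty")
  expect_error(select_silverback(c(1, NaN)), "non-finite")
})

test_that("position clipping clamps element-wise and preserves order", {
  b <- scalar_bounds(0, 5)
  expect_equal(clip_positions(c(1, 2, 3), b), c(1, 2, 3))
  expect_equal(clip_positions(c(-1, 6), b), c(0, 5))
  bd <- scalar_bounds(2, 2)
  expect_equal(clip_positions(rep(2, 4), bd), rep(2, 4))
  expect_error(scalar_bounds(3, 1), "lower")
})

test_that("step coefficients follow their defining formulas under pinned draws", {
  p <- mgto_params(max_iter = 10)
  b <- scalar_bounds(-1, 1)
  co <- swarm_coefficients(0, 10, p, b,
                           draws = list(r4 = 0, l = 1, Z = 0, r5 = 0.5,
                                        rand_e = 0.9, u_e = 0.5))
  expect_equal(co$F, 2)
  expect_equal(co$C, 2)
  expect_equal(co$L, 2)
  expect_equal(co$g, 4)
  expect_equal(co$Q, 0) # r5 = 0.5 midpoint
  expect_equal(co$rad, 3)
  # E uniform branch: rand_e >= 0.5 -> Ll + (Ul - Ll) u = 0
  expect_equal(co$E, 0)
  expect_equal(co$A, 0.7 * co$E)

  # iteration = max_iter forces the C chain to zero regardless of draws
  for (r4 in c(0, 0.3, 0.9)) {
    co_end <- swarm_coefficients(10, 10, p, b,
                                 draws = list(r4 = r4, l = 0.5, Z = 0,
                                              r5 = 0.1, rand_e = 0.1,
                                              u_e = 0.5))
    expect_identical(co_end$C, 0)
    expect_identical(co_end$L, 0)
    expect_identical(co_end$Z, 0)
  }
  # random draws: C endpoint and Z range hold without pinning
  set.seed(4)
  for (k in 1:50) {
    co_r <- swarm_coefficients(10, 10, p, b)
    expect_identical(co_r$C, 0)
    co_r <- swarm_coefficients(sample(0:9, 1), 10, p, b)
    expect_lte(abs(co_r$Z), abs(co_r$C) + 1e-12)
    # E lies in the bounds on the uniform branch, in [0, 1] on the
    # truncated-normal branch; both are subsets of [-1, 1] here
    expect_gte(co_r$E, -1)
    expect_lte(co_r$E, 1)
  }
})

test_that("plain-optimizer exploration branches reproduce their equation", {
  p <- mgto_params(p = 0.3, max_iter = 10)
  x <- c(0.5, 2, 0.5, 0.5, 0.5)
  # branch 1 with r1 = 0 collapses to the lower bound
  y <- gto_update_exploration(x, wide_bounds, p, pin_coeffs(C = 0.1),
                              draws = list(rand = rep(0, 5), r1 = rep(0, 5),
                                           r2 = rep(0, 5), r3 = rep(0, 5),
                                           xr_idx = rep(1L, 5)))
  expect_equal(y, rep(wide_bounds$lower, 5))
  # branch 2 pinned: (r2 - C) Xr + L * (Z * X) = (0.6 - 0.1) 2 + 2 * 1 = 3
  y <- gto_update_exploration(x, wide_bounds, p,
                              pin_coeffs(C = 0.1, L = 2, Z = 2),
                              draws = list(rand = rep(0.7, 5),
                                           r1 = rep(0, 5), r2 = rep(0.6, 5),
                                           r3 = rep(0, 5), xr_idx = rep(2L, 5)))
  expect_equal(y[1], (0.6 - 0.1) * 2 + 2 * (2 * 0.5))
  expect_equal(y[1], 3.0)
  # branch 3 with X = Xr leaves the position unchanged
  y <- gto_update_exploration(x, wide_bounds, p, pin_coeffs(C = 2, L = 1),
                              draws = list(rand = rep(0.4, 5),
                                           r1 = rep(0, 5), r2 = rep(0, 5),
                                           r3 = rep(0.8, 5),
                                           xr_idx = seq_len(5)))
  expect_equal(y, x)
})

test_that("plain-optimizer silverback-follow and competition match hand evaluation", {
  x <- c(3, 1, 0, 0, 0)
  # agent at the silverback position never moves
  y <- gto_update_silverback(x, 2, wide_bounds, pin_coeffs(L = 1), M = 2)
  expect_equal(y[2], 1)
  # pinned: L M (X - Xsb) + X = 1 * 2 * (3 - 1) + 3 = 7
  expect_equal(y[1], 7)
  # L = 0 leaves all positions unchanged
  expect_equal(gto_update_silverback(x, 2, wide_bounds, pin_coeffs(L = 0),
                                     M = 5), x)
  # competition: Q = 0 sends every agent to the silverback
  y <- gto_update_competition(x, 1, wide_bounds, pin_coeffs(Q = 0, A = 0.4))
  expect_equal(y, rep(3, 5))
  # pinned: Xsb - (Xsb Q - X Q) A = 2 - (2 - 1) * 0.5 = 1.5
  x2 <- c(2, 1, 1, 1, 1)
  y <- gto_update_competition(x2, 1, wide_bounds, pin_coeffs(Q = 1, A = 0.5))
  expect_equal(y[2], 1.5)
  expect_equal(y[1], 2) # bracket vanishes at X = Xsb
})

test_that("sine-cosine exploration, follow and competition match hand evaluation", {
  p <- mgto_params(p = 0.3, max_iter = 10)
  x <- c(0.5, 2, 0.5, 0.5, 0.5)
  # branch 1 with r1 = 1 collapses to the upper bound
  y <- mgto_update_exploration(x, wide_bounds, p, pin_coeffs(C = 0.1),
                               draws = list(rand = rep(0, 5), r1 = rep(1, 5),
                                            r2 = rep(0, 5),
                                            xr_idx = rep(1L, 5)))
  expect_equal(y, rep(wide_bounds$upper, 5))
  # branch 2 has the same form as the plain optimizer's
  y <- mgto_update_exploration(x, wide_bounds, p,
                               pin_coeffs(C = 0.1, L = 2, Z = 2),
                               draws = list(rand = rep(0.7, 5),
                                            r1 = rep(0, 5), r2 = rep(0.6, 5),
                                            xr_idx = rep(2L, 5)))
  expect_equal(y[1], 3.0)
  # branch 3 with X = Xr: sin(0) = 0, cos(0) = 1 -> X + rad
  y <- mgto_update_exploration(x, wide_bounds, p,
                               pin_coeffs(C = 2, L = 1, rad = 1.5),
                               draws = list(rand = rep(0.4, 5),
                                            r1 = rep(0, 5), r2 = rep(0, 5),
                                            xr_idx = seq_len(5)))
  expect_equal(y, x + 1.5)

  # follow: agent at silverback unchanged; rad = 0 freezes everyone
  x3 <- c(0, -pi / 2, 1, 1, 1)
  y <- mgto_update_silverback(x3, 2, wide_bounds,
                              pin_coeffs(L = 2, rad = 1.5), M = 1)
  expect_equal(y[2], -pi / 2)
  # pinned: L M rad sin(X - Xsb) + X = 2 * 1 * 1.5 * sin(pi/2) + 0 = 3
  expect_equal(y[1], 3.0)
  expect_equal(mgto_update_silverback(x3, 2, wide_bounds,
                                      pin_coeffs(L = 2, rad = 0), M = 1), x3)

  # competition: rad = 0 sends every agent to the silverback
  x4 <- c(5, 1, 1, 1, 1)
  y <- mgto_update_competition(x4, 1, wide_bounds,
                               pin_coeffs(Q = 0.3, A = 2, rad = 0))
  expect_equal(y, rep(5, 5))
  # Q = 0, rad = 1, A = 1: Xsb - cos(0) = 4
  y <- mgto_update_competition(x4, 1, wide_bounds,
                               pin_coeffs(Q = 0, A = 1, rad = 1))
  expect_equal(y, rep(4, 5))
})

test_that("particle-swarm step follows the velocity equation and improves gbest", {
  prm <- pso_params(w = 0.5, c1 = 1, c2 = 1, max_iter = 5)
  # converged fixed point: v = 0 and x = pbest = gbest
  x <- c(1, 1, 1, 1, 1)
  st <- list(positions = x, velocities = rep(0, 5), personal_best = x,
             personal_best_fitness = variance_fitness_all(x),
             global_best = 1, iteration = 0L)
  st2 <- pso_step(st, prm, wide_bounds,
                  draws = list(r1 = rep(1, 5), r2 = rep(1, 5)))
  expect_equal(st2$velocities, rep(0, 5))
  expect_equal(st2$positions, x)

  # pinned: v' = 0.5 * 1 + 1 * 1 * 2 + 1 * 1 * 4 = 6.5, x' = x + 6.5
  x <- c(0, 3, -1, 2, 5)
  st <- list(positions = x, velocities = rep(1, 5),
             personal_best = x + 2, personal_best_fitness = rep(-Inf, 5),
             global_best = x[1] + 4, iteration = 0L)
  st$global_best <- NULL
  st$global_best <- 4 # gbest - x[1] = 4 for agent 1
  st2 <- pso_step(st, prm, wide_bounds,
                  draws = list(r1 = rep(1, 5), r2 = rep(1, 5)))
  expect_equal(st2$velocities[1], 0.5 * 1 + 1 * 2 + 1 * 4)
  expect_equal(st2$positions[1], x[1] + 6.5)

  # gbest fitness never decreases across steps (exhaustive recomputation)
  set.seed(5)
  for (k in 1:20) {
    x <- rnorm(7)
    f <- variance_fitness_all(x)
    st <- list(positions = x, velocities = rep(0, 7), personal_best = x,
               personal_best_fitness = f,
               global_best = x[select_silverback(f)], iteration = 0L)
    b <- scalar_bounds(min(x) - 1, max(x) + 1)
    g0 <- max(st$personal_best_fitness)
    for (it in 1:3) {
      st <- pso_step(st, prm, b)
      expect_gte(max(st$personal_best_fitness), g0)
      expect_equal(st$personal_best_fitness,
                   pmax(st$personal_best_fitness, variance_fitness_all(st$positions)))
      g0 <- max(st$personal_best_fitness)
    }
  }
})

test_that("elephant-herding step uses the clan centre and replaces the worst agent", {
  prm <- eho_params(alpha = 1, beta_e = 1, max_iter = 5)
  b <- scalar_bounds(-10, 10)
  # alpha = 1, ran = 1: every agent lands on xbest = beta_e * xcenter, the
  # clan centre being the arithmetic mean (here 2); the worst agent (all tie
  # at zero variance, lowest index) is then replaced by
  # xmin + (xmax - xmin + 1) * rand = -10 + 21 * 0.5 = 0.5
  x <- c(1, 2, 3, 2, 2)
  y <- eho_step(x, prm, b, draws = list(ran = rep(1, 5), rand = 0.5))
  expect_equal(y, c(0.5, 2, 2, 2, 2))
  # worst-replacement with rand = 0 lands exactly on the lower bound
  set.seed(6)
  x <- rnorm(6)
  y <- eho_step(x, eho_params(alpha = 0.5, beta_e = 0.8), b,
                draws = list(ran = runif(6), rand = 0))
  expect_true(any(y == b$lower))
  # hand evaluation of the move for a non-replaced agent
  x <- c(0, 4, 1, -2, 3)
  ran <- c(0.5, 0.25, 0.1, 0.9, 0.3)
  prm2 <- eho_params(alpha = 0.9, beta_e = 0.8)
  y <- eho_step(x, prm2, b, draws = list(ran = ran, rand = 0.5))
  xbest <- 0.8 * mean(x)
  manual <- x + 0.9 * (xbest - x) * ran
  worst <- which.min(variance_fitness_all(manual))
  manual[worst] <- b$lower + (b$upper - b$lower + 1) * 0.5
  expect_equal(y, pmin(pmax(manual, b$lower), b$upper))
})

# Independent transcription of the sine-cosine troop loop, consuming the
# same per-iteration stream as the implementation: scalar symbols
# r4, l, Z, r5, rand_e, u_e then vectors rand, r1, r2, xr.
mgto_loop_oracle <- function(features, prm) {
  n <- length(features)
  Ll <- min(features)
  Ul <- max(features)
  x <- features
  for (t in seq_len(prm$max_iter) - 1) {
    r4 <- runif(1); l <- runif(1, -1, 1)
    Fc <- cos(2 * r4) + 1
    C <- Fc * (1 - t / prm$max_iter)
    L <- C * l
    Z <- runif(1, -C, C)
    r5 <- runif(1); rand_e <- runif(1); u_e <- runif(1)
    g <- 2^L
    Q <- 2 * r5 - 1
    E <- if (rand_e >= 0.5) Ll + (Ul - Ll) * u_e else
      qnorm(pnorm(0) + u_e * (pnorm(1) - pnorm(0)))
    A <- prm$beta * E
    rad <- prm$const - t * (prm$const / prm$max_iter)
    rand <- runif(n); r1 <- runif(n); r2 <- runif(n)
    xr_idx <- sample.int(n, n, replace = TRUE)
    new <- numeric(n)
    for (i in seq_len(n)) {
      xr <- x[xr_idx[i]]
      new[i] <- if (rand[i] < prm$p) {
        (Ul - Ll) * r1[i] + Ll
      } else if (rand[i] >= 0.5) {
        (r2[i] - C) * xr + L * (Z * x[i])
      } else {
        x[i] - L * rad * sin(x[i] - xr) + rad * cos(x[i] - xr)
      }
    }
    x <- pmin(pmax(new, Ll), Ul)
    fit <- vapply(seq_len(n), function(i) naive_window_variance(x, i), 0)
    sb <- which.max(fit)
    mu <- mean(x)
    M <- if (mu == 0) 0 else (abs(mu)^g)^(1 / g)
    new <- if (abs(C) >= 1) {
      L * M * rad * sin(x - x[sb]) + x
    } else {
      x[sb] - rad * cos(x[sb] * Q - x * Q) * A
    }
    x <- pmin(pmax(new, Ll), Ul)
  }
  x
}

test_that("the full sine-cosine loop agrees with an independent step-by-step oracle", {
  prm <- mgto_params(p = 0.3, beta = 0.7, max_iter = 2)
  for (s in c(1, 17, 2024)) {
    set.seed(s)
    feats <- rnorm(8)
    set.seed(s + 100)
    got <- run_swarm_transform(feats, "mgto", prm)
    set.seed(s + 100)
    want <- mgto_loop_oracle(feats, prm)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # longer run, larger population
  prm3 <- mgto_params(p = 0.5, beta = 0.4, max_iter = 3)
  set.seed(31)
  feats <- runif(10, -2, 5)
  set.seed(99)
  got <- run_swarm_transform(feats, "mgto", prm3)
  set.seed(99)
  expect_equal(got, mgto_loop_oracle(feats, prm3), tolerance = 1e-10)
})

test_that("swarm transforms keep positions in bounds, deterministic, silverback optimal", {
  set.seed(123)
  algs <- c("mgto", "gto", "pso", "eho")
  for (alg in algs) {
    for (k in 1:25) {
      n <- sample(5:12, 1)
      feats <- rnorm(n, sd = runif(1, 0.5, 3))
      mi <- sample(1:4, 1)
      prm <- switch(alg,
        mgto = mgto_params(p = runif(1), beta = runif(1), max_iter = mi),
        gto = mgto_params(p = runif(1), beta = runif(1), max_iter = mi),
        pso = pso_params(w = runif(1), c1 = runif(1), c2 = runif(1),
                         max_iter = mi),
        eho = eho_params(alpha = runif(1), beta_e = runif(1), max_iter = mi))
      s <- sample.int(1e6, 1)
      set.seed(s)
      res <- run_swarm_transform(feats, alg, prm, return_trace = TRUE)
      # boundary closure after every completed iteration
      for (tr in res$trace) {
        expect_true(all(tr$positions >= min(feats) - 1e-12))
        expect_true(all(tr$positions <= max(feats) + 1e-12))
        if (!is.null(tr$silverback)) {
          expect_equal(tr$fitness[tr$silverback], max(tr$fitness))
        }
      }
      expect_length(res$positions, n)
      # bitwise determinism
      set.seed(s)
      res2 <- run_swarm_transform(feats, alg, prm)
      expect_identical(res$positions, res2)
    }
  }
  # zero iterations: output equals input exactly
  f <- rnorm(6)
  expect_identical(run_swarm_transform(f, "mgto", mgto_params(max_iter = 0)), f)
  expect_error(run_swarm_transform(rnorm(4), "mgto"), "at least 5")
})
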