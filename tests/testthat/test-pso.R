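test_that("composite objective matches its closed forms", {
  t <- ref_call_unit
  expect_equal(composite_objective(t, t), 0)
  neg <- waveform(-t$samples, t$fs)
  expect_equal(composite_objective(t, neg), 6, tolerance = 1e-12)
  half <- waveform(0.5 * t$samples, t$fs)
  expect_equal(composite_objective(t, half), 0.25, tolerance = 1e-12)
  zero <- waveform(numeric(1536), t$fs)
  expect_error(composite_objective(zero, t), "zero-energy")
  ## weights scale the two terms
  expect_equal(composite_objective(t, half, w1 = 2, w2 = 0), 0)
  expect_equal(composite_objective(t, half, w1 = 0, w2 = 2), 0.5)
})

test_that("the bare swarm update degenerates as the equations dictate", {
  cfg <- pso_config(population = 8L, max_iterations = 5L, c1 = 0, c2 = 0,
                    inertia_start = 1, inertia_end = 1,
                    velocity_clamp_fraction = 10,
                    n_components = 1L, mutate_fraction = 0,
                    canonicalize = FALSE, seed = 1)
  bounds <- search_bounds()
  objective <- function(X) rowSums(X^2)
  set.seed(1)
  st <- pso_init(objective, cfg, bounds)
  st$V <- matrix(rnorm(8 * 3), 8, 3)
  x_prev <- st$X
  v_prev <- st$V
  st2 <- pso_update(st, objective, cfg, bounds)
  ## c1 = c2 = 0, inertia 1: v unchanged, x <- x + v (within bounds)
  expect_equal(st2$V, v_prev)
  bv <- list(lo = st$lo, hi = st$hi)
  expected <- pmin(pmax(x_prev + v_prev,
                        matrix(bv$lo, 8, 3, byrow = TRUE)),
                   matrix(bv$hi, 8, 3, byrow = TRUE))
  expect_equal(st2$X, expected)

  ## a particle sitting on both bests with zero velocity stays put
  cfg2 <- pso_config(population = 2L, max_iterations = 3L,
                     n_components = 1L, mutate_fraction = 0,
                     canonicalize = FALSE, seed = 2)
  set.seed(2)
  st <- pso_init(objective, cfg2, bounds)
  st$X[1, ] <- st$Pg
  st$P[1, ] <- st$Pg
  st$Jp[1] <- st$Jg
  st$V[] <- 0
  st3 <- pso_update(st, objective, cfg2, bounds)
  expect_equal(st3$X[1, ], st$Pg)
})

test_that("the swarm solves a separable quadratic in 3 dimensions", {
  ## sphere-style oracle in the (amplitude, delay, length) box, in
  ## range-normalized coordinates so all dimensions count equally
  bounds <- search_bounds()
  ctr <- c(0.7, -40, 620)
  rng <- c(1, 200, 990)
  objective <- function(X) {
    colSums(((t(X) - ctr) / rng)^2)
  }
  cfg <- pso_config(population = 100L, max_iterations = 80L,
                    n_components = 1L, mutate_fraction = 0,
                    canonicalize = FALSE, seed = 1)
  for (seed in 1:5) {
    set.seed(seed)
    st <- pso_init(objective, cfg, bounds)
    for (i in seq_len(cfg$max_iterations)) {
      jg_before <- st$Jg
      st <- pso_update(st, objective, cfg, bounds)
      expect_lte(st$Jg, jg_before)  # global best never worsens
    }
    expect_lt(st$Jg, 1e-3)
  }
})

test_that("non-finite objective values are quarantined with a warning", {
  bounds <- search_bounds()
  objective <- function(X) {
    out <- rowSums(X^2)
    out[1] <- NaN
    out
  }
  cfg <- pso_config(population = 6L, max_iterations = 2L, n_components = 1L,
                    mutate_fraction = 0, canonicalize = FALSE, seed = 1)
  set.seed(1)
  expect_warning(st <- pso_init(objective, cfg, bounds), "non-finite")
  expect_true(is.finite(st$Jg))
})

test_that("single-component inversion beats a brute-force grid oracle", {
  comp <- wavelet_component(0.5, 10, 300)
  target <- render_component(comp, ref_mother)
  target <- waveform(target$samples / max(abs(target$samples)), 48000)

  ## brute-force oracle over a coarse (A, tau, sigma) grid
  grid <- expand.grid(A = seq(0.05, 1, by = 0.05),
                      tau = seq(-100, 100, by = 5),
                      sigma = seq(20, 1000, by = 20))
  X <- as.matrix(grid)
  J <- croaker:::cpp_swarm_objective(X, target$samples, 1536L,
                                     ref_mother$samples, ref_mother$u_peak,
                                     1, 1)
  j_grid <- min(J)
  best_grid <- X[which.min(J), ]

  res <- invert_waveform(target,
                         pso_config(population = 200L, max_iterations = 60L,
                                    n_components = 1L, seed = 1))
  expect_lte(res$final_objective, j_grid + 1e-12)
  expect_lt(res$final_objective, 1e-3)
  ## recovered delay/length close to the generating values (grid confirms
  ## the optimum is global)
  fit <- tidy(res)
  expect_lt(abs(fit$delay - 10), 5)
  expect_lt(abs(fit$length - 300) / 300, 0.05)
  expect_lt(abs(best_grid[["tau"]] - 10), 5)
})

test_that("inversion is reproducible, monotone and well-formed", {
  target <- ref_call_unit
  r1 <- invert_waveform(target, quick_pso(seed = 5))
  r2 <- invert_waveform(target, quick_pso(seed = 5))
  expect_identical(r1$best_spec, r2$best_spec)
  expect_identical(r1$objective_history, r2$objective_history)
  expect_true(all(diff(r1$objective_history) <= 1e-15))
  ## components reported sorted by delay
  expect_true(!is.unsorted(tidy(r1)$delay))
  ## final metrics recomputed from the spec
  rec <- suppressWarnings(synthesize_call(r1$best_spec, ref_mother))
  expect_equal(r1$final_correlation, cor(rec$samples, target$samples))
  expect_equal(r1$final_rmse,
               sqrt(mean((rec$samples - target$samples)^2)))

  expect_error(invert_waveform(waveform(numeric(1536), 48000), quick_pso()),
               "zero-energy")
})

test_that("tidy and glance summarize an inversion", {
  res <- invert_waveform(ref_call_unit, quick_pso(seed = 3))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("component", "amplitude", "delay", "length"))
  expect_equal(nrow(td), 5L)
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("r", "rmse", "objective", "iterations") %in% names(gl)))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("greedy mode fits components sequentially and stays reproducible", {
  target <- ref_call_unit
  cfg <- quick_pso(seed = 2, mode = "greedy")
  g1 <- invert_waveform(target, cfg)
  g2 <- invert_waveform(target, cfg)
  expect_identical(g1$best_spec, g2$best_spec)
  expect_equal(nrow(tidy(g1)), 5L)
  expect_true(g1$final_correlation > 0.5)
})
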