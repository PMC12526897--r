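#' Search bounds for wavelet-parameter inversion
#'
#' Default bounds are the standard search space for croaker-call inversion:
#' amplitude in `[0, 1]`, length in `[10, 1000]` samples, delay in
#' `[-100, 100]` samples.
#'
#' @param amplitude,length,delay Numeric length-2 intervals `c(lo, hi)`.
#' @return A `croaker_bounds`.
#' @export
search_bounds <- function(amplitude = c(0, 1),
                          length = c(10, 1000),
                          delay = c(-100, 100)) {
  for (iv in list(amplitude, length, delay)) {
    if (length(iv) != 2L || !(iv[1] < iv[2])) {
      abort("each bound must be an interval c(lo, hi) with lo < hi")
    }
  }
  structure(list(amplitude = amplitude, length = length, delay = delay),
            class = "croaker_bounds")
}

## flat bound vectors in parameter layout c(A, tau, sigma) x N
bounds_vectors <- function(bounds, n_components) {
  N <- n_components
  list(lo = c(rep(bounds$amplitude[1], N), rep(bounds$delay[1], N),
              rep(bounds$length[1], N)),
       hi = c(rep(bounds$amplitude[2], N), rep(bounds$delay[2], N),
              rep(bounds$length[2], N)))
}

#' PSO configuration
#'
#' Defaults follow the croaker inversion protocol: population 1000, 80
#' iterations, acceleration coefficients `c1 = c2 = 2`, velocities clamped
#' to 20% of each bound range. The inertia weight decreases linearly from
#' `inertia_start` to `inertia_end` across iterations (set both to the same
#' value for a constant-inertia update; the classical textbook update with
#' no inertia term corresponds to a constant 1).
#'
#' @param population Swarm size, at least 2.
#' @param max_iterations Number of update iterations, at least 1.
#' @param c1,c2 Cognitive and social acceleration coefficients (values at
#'   the first iteration).
#' @param c1_end,c2_end Optional values at the last iteration; when given,
#'   the coefficients vary linearly across iterations (time-varying
#'   acceleration), which shifts the swarm from exploration (high
#'   cognitive, low social) to exploitation. `NULL` keeps them constant.
#' @param inertia_start,inertia_end Linear inertia-weight schedule.
#' @param velocity_clamp_fraction Velocity clamp as a fraction of each
#'   dimension's bound range.
#' @param n_components Number of wavelet components fitted jointly.
#' @param final_polish Run a derivative-free simplex (Nelder-Mead) local
#'   refinement from the swarm's final global best, clipped to the bounds,
#'   and keep the result when it improves the objective. Deterministic;
#'   converts a nearly converged swarm optimum into the basin's local
#'   optimum. Set `FALSE` for the bare swarm result.
#' @param amplitude_refit Amplitudes enter the synthesis linearly, so given
#'   the global best's delays and lengths the optimal amplitudes are an
#'   ordinary least-squares solve. When `TRUE` (default) that exact solve
#'   (clipped to the bounds) is applied to the global best after each
#'   iteration and kept when it improves the objective. This leaves the
#'   swarm to search only the nonlinear (delay, length) subspace.
#' @param residual_scouts Number of residual-guided proposals evaluated per
#'   iteration: copies of the global best with one component re-placed at
#'   the current residual's peak (jittered delay, log-uniform length,
#'   residual-scaled amplitude). The residual of a nearly converged fit is
#'   dominated by whichever component is still wrong, so these proposals
#'   jump straight into the missing component's basin. Kept only when they
#'   improve the incumbent. Set 0 to disable.
#' @param mutate_fraction Fraction of the swarm re-injected each iteration
#'   as scout copies of the global best with a single randomly chosen
#'   component resampled uniformly within the bounds (velocity reset,
#'   personal best replaced). The dominant failure mode of a joint
#'   multi-component fit is a solution with all but one component correct;
#'   these scouts search the conditional one-component landscape around the
#'   incumbent and let the swarm escape such traps without any extra
#'   objective evaluations. Set 0 to disable (plain PSO).
#' @param canonicalize Sort every particle's components by delay after each
#'   position update (velocities are permuted alongside). The synthesized
#'   sum is invariant to component order, so this quotients out the
#'   `n_components!`-fold permutation symmetry of the search space without
#'   changing any candidate waveform, which markedly improves convergence
#'   for multi-component fits.
#' @param seed RNG seed for the run.
#' @param mode `"joint"` fits all components simultaneously in a
#'   `3 * n_components`-dimensional search; `"greedy"` fits them one at a
#'   time against the running residual (matching-pursuit style).
#' @param early_stop_iterations Stop when the global best has not improved
#'   for this many iterations; `Inf` (default) disables early stopping.
#' @return A `croaker_pso_config`.
#' @export
pso_config <- function(population = 1000L, max_iterations = 80L,
                       c1 = 1.494, c2 = 1.494, c1_end = NULL, c2_end = NULL,
                       inertia_start = 0.9, inertia_end = 0.4,
                       velocity_clamp_fraction = 0.2,
                       n_components = 5L, seed = 1L,
                       mutate_fraction = 0.08,
                       residual_scouts = 8L,
                       amplitude_refit = TRUE,
                       final_polish = TRUE,
                       canonicalize = TRUE,
                       mode = c("joint", "greedy"),
                       early_stop_iterations = Inf) {
  stopifnot(population >= 2L, max_iterations >= 1L, c1 >= 0, c2 >= 0,
            velocity_clamp_fraction > 0, n_components >= 1L)
  structure(list(population = as.integer(population),
                 max_iterations = as.integer(max_iterations),
                 c1 = c1, c2 = c2, c1_end = c1_end, c2_end = c2_end,
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 velocity_clamp_fraction = velocity_clamp_fraction,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed),
                 mutate_fraction = mutate_fraction,
                 residual_scouts = as.integer(residual_scouts),
                 amplitude_refit = isTRUE(amplitude_refit),
                 final_polish = isTRUE(final_polish),
                 canonicalize = isTRUE(canonicalize),
                 mode = match.arg(mode),
                 early_stop_iterations = early_stop_iterations),
            class = "croaker_pso_config")
}

#' Composite correlation + normalized-MSE objective
#'
#' `J = w1 * (1 - r) + w2 * NMSE`, where `r` is the Pearson correlation
#' between candidate and target and `NMSE = sum((target - candidate)^2) /
#' sum(target^2)`. `J >= 0`, and `J = 0` exactly when the candidate equals
#' the target. Minimized during inversion.
#'
#' @param target,candidate `croaker_waveform`s (or numeric vectors) of equal
#'   length and sampling rate; the target should be peak-normalized.
#' @param w1,w2 Objective weights (both 1 by default).
#' @return Scalar objective value.
#' @export
#' @examples
#' s <- synthesize_call(croaker_reference_spec())
#' composite_objective(s, s)  # 0
composite_objective <- function(target, candidate, w1 = 1, w2 = 1) {
  t <- if (inherits(target, "croaker_waveform")) target$samples else target
  c_ <- if (inherits(candidate, "croaker_waveform")) candidate$samples else candidate
  if (length(t) != length(c_)) abort("target and candidate must have equal length")
  if (inherits(target, "croaker_waveform") &&
      inherits(candidate, "croaker_waveform") &&
      target$fs != candidate$fs) {
    abort("target and candidate must share a sampling rate")
  }
  sst <- sum(t^2)
  if (sst == 0) abort("zero-energy target: NMSE is undefined")
  r <- if (sd(c_) == 0 || sd(t) == 0) 0 else cor(t, c_)
  w1 * (1 - r) + w2 * sum((t - c_)^2) / sst
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly within the bounds; velocities start at
#' zero. Personal and global bests are taken from the initial evaluation.
#'
#' @param objective Function mapping a position matrix (rows = particles) to
#'   a numeric vector of scores.
#' @param config A `croaker_pso_config`.
#' @param bounds A `croaker_bounds`.
#' @return A `croaker_swarm` state list.
#' @export
pso_init <- function(objective, config, bounds) {
  N <- config$n_components
  D <- 3L * N
  bv <- bounds_vectors(bounds, N)
  pop <- config$population
  X <- matrix(runif(pop * D), pop, D)
  X <- sweep(sweep(X, 2, bv$hi - bv$lo, "*"), 2, bv$lo, "+")
  if (isTRUE(config$canonicalize) && D >= 6L) {
    for (p in seq_len(pop)) {
      ord <- order(X[p, N + seq_len(N)])
      X[p, ] <- X[p, c(ord, N + ord, 2L * N + ord)]
    }
  }
  V <- matrix(0, pop, D)
  J <- sanitize_scores(objective(X))
  g <- which.min(J)
  structure(list(X = X, V = V, P = X, Jp = J,
                 Pg = X[g, ], Jg = J[g],
                 iteration = 0L, lo = bv$lo, hi = bv$hi),
            class = "croaker_swarm")
}

sanitize_scores <- function(J) {
  bad <- !is.finite(J)
  if (any(bad)) {
    warn(paste0(sum(bad), " particle(s) returned a non-finite objective; ",
                "scored as +Inf"))
    J[bad] <- Inf
  }
  J
}

#' One particle-swarm update step
#'
#' Velocity update `v <- w v + c1 r1 (p - x) + c2 r2 (g - x)` with
#' per-dimension uniform `r1, r2`, velocity clamping, position advance, and
#' clipping to the bounds; personal and global bests are refreshed. With
#' `c1 = c2 = 0` and inertia 1 the step reduces to `x <- x + v`. Ties on the
#' global best are broken toward the lower particle index, so runs are
#' deterministic given the RNG state.
#'
#' @inheritParams pso_init
#' @param state A `croaker_swarm` from [pso_init()] or a previous update.
#' @return The updated `croaker_swarm`; the global-best score never
#'   increases.
#' @export
pso_update <- function(state, objective, config, bounds) {
  stopifnot(inherits(state, "croaker_swarm"))
  pop <- nrow(state$X)
  D <- ncol(state$X)
  it <- state$iteration + 1L
  frac <- if (config$max_iterations > 1L) {
    (it - 1) / (config$max_iterations - 1)
  } else 0
  frac <- min(frac, 1)
  w <- config$inertia_start + (config$inertia_end - config$inertia_start) * frac
  c1 <- if (is.null(config$c1_end)) config$c1 else {
    config$c1 + (config$c1_end - config$c1) * frac
  }
  c2 <- if (is.null(config$c2_end)) config$c2 else {
    config$c2 + (config$c2_end - config$c2) * frac
  }
  R1 <- matrix(runif(pop * D), pop, D)
  R2 <- matrix(runif(pop * D), pop, D)
  G <- matrix(state$Pg, pop, D, byrow = TRUE)
  V <- w * state$V + c1 * R1 * (state$P - state$X) +
    c2 * R2 * (G - state$X)
  vmax <- config$velocity_clamp_fraction * (state$hi - state$lo)
  VM <- matrix(vmax, pop, D, byrow = TRUE)
  V <- pmin(pmax(V, -VM), VM)
  X <- state$X + V
  X <- pmin(pmax(X, matrix(state$lo, pop, D, byrow = TRUE)),
            matrix(state$hi, pop, D, byrow = TRUE))
  if (isTRUE(config$canonicalize) && D >= 6L) {
    N <- D %/% 3L
    for (p in seq_len(pop)) {
      ord <- order(X[p, N + seq_len(N)])
      if (is.unsorted(ord)) {
        idx <- c(ord, N + ord, 2L * N + ord)
        X[p, ] <- X[p, idx]
        V[p, ] <- V[p, idx]
      }
    }
  }
  ## scout re-injection: move the worst personal-best particles onto the
  ## global best with one component resampled uniformly in the bounds
  n_mut <- floor((config$mutate_fraction %||% 0) * pop)
  mut_idx <- integer(0)
  if (n_mut > 0L && is.finite(state$Jg)) {
    N <- D %/% 3L
    mut_idx <- order(state$Jp, decreasing = TRUE)[seq_len(n_mut)]
    for (p in mut_idx) {
      xm <- state$Pg
      u <- runif(1)
      if (u < 0.25) {
        ## fine polish: Gaussian kick of the whole vector (2% of range)
        xm <- xm + rnorm(D) * 0.02 * (state$hi - state$lo)
        xm <- pmin(pmax(xm, state$lo), state$hi)
      } else {
        nj <- if (u < 0.85) 1L else min(2L, N)
        for (j in sample.int(N, nj)) {
          cols <- c(j, N + j, 2L * N + j)
          xm[cols] <- state$lo[cols] + runif(3L) * (state$hi[cols] - state$lo[cols])
        }
      }
      X[p, ] <- xm
      V[p, ] <- 0
    }
  }
  J <- sanitize_scores(objective(X))
  upd <- J < state$Jp
  upd[mut_idx] <- TRUE       # scouts restart their personal-best history
  state$P[upd, ] <- X[upd, ]
  state$Jp[upd] <- J[upd]
  g <- which.min(state$Jp)          # which.min takes the first (lowest index)
  if (state$Jp[g] < state$Jg) {
    state$Jg <- state$Jp[g]
    state$Pg <- state$P[g, ]
  }
  state$X <- X
  state$V <- V
  state$iteration <- it
  state
}

#' Invert a target call into wavelet parameters by PSO
#'
#' Runs a particle swarm over the `3 N`-dimensional parameter space
#' (amplitude, delay, length per component), minimizing the composite
#' correlation + normalized-MSE objective between the synthesized candidate
#' and the target. The target is peak-normalized internally (with a message)
#' if it is not already. Returned components are sorted by delay; final
#' metrics are recomputed from the returned spec, not taken from cached
#' swarm values.
#'
#' @param target A `croaker_waveform` whose length will be used as the
#'   synthesis window.
#' @param config A `croaker_pso_config`.
#' @param bounds A `croaker_bounds`.
#' @param mother Optional `croaker_mother`.
#' @param w1,w2 Objective weights.
#' @return A `croaker_inversion`: list with `best_spec`,
#'   `objective_history`, `parameter_trajectories` (tibble: iteration,
#'   component, amplitude, delay, length, objective), `final_correlation`,
#'   `final_rmse` (on the peak-normalized scale), and `config`.
#' @export
invert_waveform <- function(target, config = pso_config(),
                            bounds = search_bounds(), mother = NULL,
                            w1 = 1, w2 = 1) {
  target <- as_waveform(target)
  if (is.null(mother)) mother <- mother_cache()
  if (sum(target$samples^2) == 0) abort("zero-energy target: NMSE is undefined")
  pk <- max(abs(target$samples))
  if (abs(pk - 1) > 1e-12) {
    message("target not peak-normalized; normalizing by ", signif(pk, 6))
    target <- waveform(target$samples / pk, target$fs, target$unit)
  }
  window <- length(target$samples)

  if (config$mode == "greedy") {
    return(invert_greedy(target, config, bounds, mother, w1, w2))
  }

  objective <- function(X) {
    cpp_swarm_objective(X, target$samples, window, mother$samples,
                        mother$u_peak, w1, w2)
  }

  refit_amplitudes <- function(par) {
    N <- length(par) / 3L
    U <- vapply(seq_len(N), function(i) {
      cpp_render_component(1, par[N + i], par[2L * N + i], window,
                           mother$samples, mother$u_peak)
    }, numeric(window))
    a <- tryCatch(qr.solve(U, target$samples), error = function(e) NULL)
    if (is.null(a) || any(!is.finite(a))) return(NULL)
    bv <- bounds_vectors(bounds, N)
    a <- pmin(pmax(a, bv$lo[seq_len(N)]), bv$hi[seq_len(N)])
    c(a, par[-seq_len(N)])
  }

  residual_proposals <- function(par, n_scouts) {
    N <- length(par) / 3L
    synth <- cpp_synthesize(par, window, mother$samples, mother$u_peak)
    e <- target$samples - synth
    pk <- which.max(abs(e))
    bv <- bounds_vectors(bounds, N)
    X <- matrix(par, n_scouts, length(par), byrow = TRUE)
    for (s in seq_len(n_scouts)) {
      j <- sample.int(N, 1L)
      tau <- (pk - window / 2) + runif(1, -4, 4)
      lsig <- runif(1, log(bv$lo[2L * N + 1L]), log(bv$hi[2L * N + 1L]))
      amp <- min(max(abs(e[pk]) * runif(1, 0.5, 1.5), bv$lo[1L]), bv$hi[1L])
      X[s, j] <- amp
      X[s, N + j] <- min(max(tau, bv$lo[N + 1L]), bv$hi[N + 1L])
      X[s, 2L * N + j] <- exp(lsig)
    }
    X
  }

  set.seed(config$seed)
  state <- pso_init(objective, config, bounds)
  N <- config$n_components
  hist <- numeric(0)
  traj <- vector("list", config$max_iterations)
  since_improve <- 0L
  for (it in seq_len(config$max_iterations)) {
    jg_prev <- state$Jg
    state <- pso_update(state, objective, config, bounds)
    ## residual-guided proposals only once the swarm has settled on a basin
    ## (second half of the schedule); earlier they drag the swarm into
    ## greedy-style local optima
    nrs <- config$residual_scouts %||% 0L
    if (nrs > 0L && it > config$max_iterations / 2 && is.finite(state$Jg)) {
      Xp <- residual_proposals(state$Pg, nrs)
      Jp <- sanitize_scores(objective(Xp))
      bestp <- which.min(Jp)
      cand <- refit_amplitudes(Xp[bestp, ])
      if (!is.null(cand)) {
        jc <- objective(matrix(cand, nrow = 1L))
        if (is.finite(jc) && jc < Jp[bestp]) {
          Xp[bestp, ] <- cand
          Jp[bestp] <- jc
        }
      }
      if (Jp[bestp] < state$Jg) {
        state$Jg <- Jp[bestp]
        state$Pg <- Xp[bestp, ]
      }
    }
    if (isTRUE(config$amplitude_refit)) {
      cand <- refit_amplitudes(state$Pg)
      if (!is.null(cand)) {
        jc <- objective(matrix(cand, nrow = 1L))
        if (is.finite(jc) && jc < state$Jg) {
          state$Jg <- jc
          state$Pg <- cand
        }
      }
    }
    hist <- c(hist, state$Jg)
    traj[[it]] <- tibble(iteration = it, component = seq_len(N),
                         amplitude = state$Pg[seq_len(N)],
                         delay = state$Pg[N + seq_len(N)],
                         length = state$Pg[2L * N + seq_len(N)],
                         objective = state$Jg)
    since_improve <- if (state$Jg < jg_prev) 0L else since_improve + 1L
    if (since_improve >= config$early_stop_iterations) break
  }

  if (isTRUE(config$final_polish)) {
    bv <- bounds_vectors(bounds, N)
    fn <- function(p) {
      p <- pmin(pmax(p, bv$lo), bv$hi)
      objective(matrix(p, nrow = 1L))
    }
    op <- stats::optim(state$Pg, fn, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-12))
    cand <- pmin(pmax(op$par, bv$lo), bv$hi)
    cand2 <- refit_amplitudes(cand)
    for (cc in list(cand, cand2)) {
      if (!is.null(cc)) {
        jc <- objective(matrix(cc, nrow = 1L))
        if (is.finite(jc) && jc < state$Jg) {
          state$Jg <- jc
          state$Pg <- cc
        }
      }
    }
  }

  finalize_inversion(state$Pg, target, mother, config, hist,
                     dplyr::bind_rows(traj[!vapply(traj, is.null, logical(1))]),
                     w1, w2)
}

## sequential (matching-pursuit style) fit: one component at a time against
## the running residual
invert_greedy <- function(target, config, bounds, mother, w1, w2) {
  window <- length(target$samples)
  residual <- target$samples
  par_all <- numeric(0)
  hist <- numeric(0)
  traj <- list()
  sub <- pso_config(population = config$population,
                    max_iterations = config$max_iterations,
                    c1 = config$c1, c2 = config$c2,
                    c1_end = config$c1_end, c2_end = config$c2_end,
                    inertia_start = config$inertia_start,
                    inertia_end = config$inertia_end,
                    velocity_clamp_fraction = config$velocity_clamp_fraction,
                    n_components = 1L, seed = config$seed)
  for (i in seq_len(config$n_components)) {
    sst <- sum(residual^2)
    if (sst == 0) break
    objective <- function(X) {
      cpp_swarm_objective(X, residual, window, mother$samples,
                          mother$u_peak, w1, w2)
    }
    set.seed(sub$seed + i - 1L)
    st <- pso_init(objective, sub, bounds)
    for (it in seq_len(sub$max_iterations)) st <- pso_update(st, objective, sub, bounds)
    comp <- st$Pg                        # c(A, tau, sigma)
    residual <- residual - cpp_synthesize(comp, window, mother$samples, mother$u_peak)
    par_all <- c(par_all, comp)
    hist <- c(hist, st$Jg)
    traj[[i]] <- tibble(iteration = i, component = i,
                        amplitude = comp[1], delay = comp[2],
                        length = comp[3], objective = st$Jg)
  }
  N <- length(par_all) / 3L
  par <- c(par_all[seq(1, length(par_all), by = 3)],
           par_all[seq(2, length(par_all), by = 3)],
           par_all[seq(3, length(par_all), by = 3)])
  finalize_inversion(par, target, mother, config, hist,
                     dplyr::bind_rows(traj), w1, w2)
}

finalize_inversion <- function(par, target, mother, config, hist, traj, w1, w2) {
  N <- length(par) / 3L
  spec <- par_to_spec(par, fs = target$fs,
                      window_samples = length(target$samples))
  ord <- order(vapply(spec$components, `[[`, numeric(1), "delay"))
  spec$components <- spec$components[ord]
  best <- suppressWarnings(synthesize_call(spec, mother))
  r <- cor(target$samples, best$samples)
  rmse <- sqrt(mean((target$samples - best$samples)^2))
  structure(list(best_spec = spec,
                 objective_history = hist,
                 parameter_trajectories = traj,
                 final_correlation = r,
                 final_rmse = rmse,
                 final_objective = composite_objective(target, best, w1, w2),
                 target = target,
                 reconstruction = best,
                 config = config),
            class = "croaker_inversion")
}

#' @export
print.croaker_inversion <- function(x, ...) {
  cat("<croaker_inversion> N =", length(x$best_spec$components),
      " iterations =", length(x$objective_history), "\n",
      " final r =", signif(x$final_correlation, 4),
      " rmse =", signif(x$final_rmse, 4),
      " J =", signif(x$final_objective, 4), "\n")
  invisible(x)
}

#' Tidy methods for inversion results
#'
#' `tidy()` returns the fitted component parameters (one row per component);
#' `glance()` returns a one-row summary with the final correlation, RMSE,
#' objective, and iteration count.
#'
#' @param x A `croaker_inversion`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.croaker_inversion <- function(x, ...) {
  as_tibble.croaker_spec(x$best_spec)
}

#' @rdname tidy.croaker_inversion
#' @export
glance.croaker_inversion <- function(x, ...) {
  tibble(r = x$final_correlation, rmse = x$final_rmse,
         objective = x$final_objective,
         iterations = length(x$objective_history),
         population = x$config$population,
         n_components = length(x$best_spec$components))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot PSO convergence trajectories
#'
#' Shows the global-best parameter value per component across iterations,
#' faceted by parameter, plus the objective history.
#'
#' @param object A `croaker_inversion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.croaker_inversion <- function(object, ...) {
  tr <- object$parameter_trajectories
  long <- tidyr_pivot(tr)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = factor(.data$component))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "component", y = NULL,
                  title = "PSO global-best parameter trajectories")
}

## minimal long-format helper (avoids a tidyr dependency)
tidyr_pivot <- function(tr) {
  dplyr::bind_rows(
    dplyr::mutate(tr[, c("iteration", "component")],
                  parameter = "amplitude", value = tr$amplitude),
    dplyr::mutate(tr[, c("iteration", "component")],
                  parameter = "delay", value = tr$delay),
    dplyr::mutate(tr[, c("iteration", "component")],
                  parameter = "length", value = tr$length))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
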