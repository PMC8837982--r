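#' Bald Eagle Search configuration
#'
#' Controls the three-phase (select / search / swoop) population
#' metaheuristic. Parameter ranges follow the algorithm's definition:
#' `alpha` in \[1.5, 2\] scales the move toward the population mean in
#' the select phase; `a_corner` in \[5, 10\] sets the spiral corner
#' angle and `R_cycles` in \[0.5, 2\] the number of search cycles in the
#' search phase; `c1`, `c2` in \[1, 2\] set the swoop intensity toward
#' the centre and best positions.
#'
#' @param pop_size population size; default 30.
#' @param iterations number of select-search-swoop iterations; default
#'   100.
#' @param alpha select-phase position-change control, in \[1.5, 2\].
#' @param a_corner spiral corner parameter, in \[5, 10\].
#' @param R_cycles search-cycle parameter, in \[0.5, 2\].
#' @param c1,c2 swoop intensities toward centre / best, in \[1, 2\].
#' @param lower,upper numeric bounds per dimension (equal length,
#'   `lower < upper`, finite).
#' @param seed integer seed for the whole run.
#' @return object of class `"bes_config"`.
#' @export
bes_config <- function(pop_size = 30L, iterations = 100L,
                       alpha = 2, a_corner = 10, R_cycles = 1.5,
                       c1 = 2, c2 = 2, lower, upper, seed = 1L) {
  pop_size <- as.integer(pop_size); iterations <- as.integer(iterations)
  if (pop_size < 2L) stop("`pop_size` must be >= 2", call. = FALSE)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (alpha < 1.5 || alpha > 2) stop("`alpha` must lie in [1.5, 2]",
                                     call. = FALSE)
  if (a_corner < 5 || a_corner > 10) stop("`a_corner` must lie in [5, 10]",
                                          call. = FALSE)
  if (R_cycles < 0.5 || R_cycles > 2) stop("`R_cycles` must lie in [0.5, 2]",
                                           call. = FALSE)
  if (c1 < 1 || c1 > 2 || c2 < 1 || c2 > 2)
    stop("`c1` and `c2` must lie in [1, 2]", call. = FALSE)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || !all(is.finite(c(lower, upper))) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper per dimension",
         call. = FALSE)
  structure(list(pop_size = pop_size, iterations = iterations,
                 alpha = alpha, a_corner = a_corner, R_cycles = R_cycles,
                 c1 = c1, c2 = c2, lower = lower, upper = upper,
                 seed = as.integer(seed)),
            class = "bes_config")
}

clip_bounds <- function(x, config) pmin(pmax(x, config$lower), config$upper)

# Greedy acceptance of a candidate for individual i: evaluate, reject
# non-finite fitness, replace only on improvement, and keep the running
# best and population mean current after every accepted move.
bes_accept <- function(state, i, cand, objective, config) {
  f <- tryCatch(objective(cand), error = function(e) NA_real_)
  if (!is.finite(f)) return(state)          # candidate rejected
  if (f < state$fitness[i]) {
    state$positions[i, ] <- cand
    state$fitness[i] <- f
    state$mean_pos <- colMeans(state$positions)
    if (f < state$best_fit) {
      state$best_fit <- f
      state$best_pos <- cand
    }
  }
  state
}

#' Select phase: move toward the mean-best region
#'
#' Each candidate is `P_best + alpha * gamma_i * (P_mean - P_i)` with a
#' fresh `gamma_i ~ U(0, 1)` per individual, clipped to bounds and
#' accepted only if it improves that individual's fitness.
#'
#' @param state internal BES state (positions, fitness, best, mean).
#' @param objective objective function (vector in, finite real out;
#'   minimized).
#' @param config a [bes_config()].
#' @param gamma optional vector overriding the per-individual uniform
#'   draws (used for deterministic checks).
#' @return updated state.
#' @export
bes_select_phase <- function(state, objective, config, gamma = NULL) {
  npop <- config$pop_size
  g <- if (is.null(gamma)) stats::runif(npop) else rep_len(gamma, npop)
  for (i in seq_len(npop)) {
    cand <- state$best_pos +
      config$alpha * g[i] * (state$mean_pos - state$positions[i, ])
    state <- bes_accept(state, i, clip_bounds(cand, config), objective,
                        config)
  }
  state
}

#' Spiral coordinates of the search phase
#'
#' Polar spiral: `theta_i = a * pi * rand`, `r_i = theta_i + R * rand`,
#' `xr = r * sin(theta)`, `yr = r * cos(theta)`, each max-normalized
#' over the population so `x`, `y` lie in \[-1, 1\].
#'
#' @param rand_theta,rand_r uniform draws in \[0, 1\], one per
#'   individual.
#' @param a corner parameter; R cycle parameter.
#' @param R cycle parameter.
#' @return list with components `x` and `y`.
#' @export
bes_search_coords <- function(rand_theta, rand_r, a, R) {
  theta <- a * pi * rand_theta
  r <- theta + R * rand_r
  xr <- r * sin(theta)
  yr <- r * cos(theta)
  list(x = xr / max(abs(xr)), y = yr / max(abs(yr)))
}

#' Search phase: spiral flight around the population
#'
#' Candidate `P_i + x_i (P_i - P_mean) + y_i (P_i - P_{i+1})` with the
#' spiral coordinates of [bes_search_coords()]; the neighbour index
#' wraps circularly. Greedy acceptance and clipping as in the select
#' phase.
#'
#' @inheritParams bes_select_phase
#' @param rand_theta,rand_r optional overriding draws.
#' @return updated state.
#' @export
bes_search_phase <- function(state, objective, config,
                             rand_theta = NULL, rand_r = NULL) {
  npop <- config$pop_size
  if (is.null(rand_theta)) rand_theta <- stats::runif(npop)
  if (is.null(rand_r)) rand_r <- stats::runif(npop)
  co <- bes_search_coords(rep_len(rand_theta, npop), rep_len(rand_r, npop),
                          config$a_corner, config$R_cycles)
  for (i in seq_len(npop)) {
    j <- if (i == npop) 1L else i + 1L
    pi_ <- state$positions[i, ]
    cand <- pi_ + co$x[i] * (pi_ - state$mean_pos) +
      co$y[i] * (pi_ - state$positions[j, ])
    state <- bes_accept(state, i, clip_bounds(cand, config), objective,
                        config)
  }
  state
}

#' Hyperbolic spiral coordinates of the swoop phase
#'
#' `theta_i = a * pi * rand`, `r_i = theta_i`, `xr = r * sinh(theta)`,
#' `yr = r * cosh(theta)`, max-normalized over the population.
#'
#' @param rand_theta uniform draws in \[0, 1\].
#' @param a corner parameter.
#' @return list with components `x1` and `y1`.
#' @export
bes_swoop_coords <- function(rand_theta, a) {
  theta <- a * pi * rand_theta
  r <- theta
  xr <- r * sinh(theta)
  yr <- r * cosh(theta)
  list(x1 = xr / max(abs(xr)), y1 = yr / max(abs(yr)))
}

#' Swoop phase: dive from the best position onto the prey
#'
#' Candidate `rand_i * P_best + x1_i (P_i - c1 * P_mean) +
#' y1_i (P_i - c2 * P_best)` with the hyperbolic coordinates of
#' [bes_swoop_coords()]; greedy acceptance and clipping.
#'
#' @inheritParams bes_select_phase
#' @param rand_theta,rand_scale optional overriding draws (`rand_scale`
#'   multiplies `P_best`).
#' @return updated state.
#' @export
bes_swoop_phase <- function(state, objective, config,
                            rand_theta = NULL, rand_scale = NULL) {
  npop <- config$pop_size
  if (is.null(rand_theta)) rand_theta <- stats::runif(npop)
  if (is.null(rand_scale)) rand_scale <- stats::runif(npop)
  rand_theta <- rep_len(rand_theta, npop)
  rand_scale <- rep_len(rand_scale, npop)
  co <- bes_swoop_coords(rand_theta, config$a_corner)
  for (i in seq_len(npop)) {
    pi_ <- state$positions[i, ]
    cand <- rand_scale[i] * state$best_pos +
      co$x1[i] * (pi_ - config$c1 * state$mean_pos) +
      co$y1[i] * (pi_ - config$c2 * state$best_pos)
    state <- bes_accept(state, i, clip_bounds(cand, config), objective,
                        config)
  }
  state
}

bes_init_state <- function(objective, config, init = NULL) {
  d <- length(config$lower)
  P <- matrix(stats::runif(config$pop_size * d), ncol = d)
  P <- sweep(sweep(P, 2, config$upper - config$lower, `*`), 2,
             config$lower, `+`)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), config$pop_size)
    P[seq_len(k), ] <- clip_bounds(init[seq_len(k), , drop = FALSE], config)
  }
  fitness <- apply(P, 1, function(p)
    tryCatch(objective(p), error = function(e) NA_real_))
  if (!any(is.finite(fitness)))
    stop("objective non-finite at every initial position", call. = FALSE)
  fitness[!is.finite(fitness)] <- Inf
  b <- which.min(fitness)
  list(positions = P, fitness = fitness, best_pos = P[b, ],
       best_fit = fitness[b], mean_pos = colMeans(P))
}

#' Run the Bald Eagle Search optimizer
#'
#' Initializes the population uniformly within bounds under the
#' configured seed, then iterates select, search and swoop phases with
#' greedy per-individual acceptance, so the best-so-far fitness history
#' is monotone nonincreasing. Deterministic for a fixed seed.
#'
#' @param objective function mapping a bounds-respecting numeric vector
#'   to a finite real; minimized.
#' @param config a [bes_config()].
#' @param init optional matrix of starting positions (one row per
#'   individual) overwriting the first rows of the random population --
#'   useful for warm-starting from a known default.
#' @return list with `par` (best position), `value` (best fitness) and
#'   `history` (best fitness after each iteration).
#' @export
bes_optimize <- function(objective, config, init = NULL) {
  stopifnot(inherits(config, "bes_config"))
  set.seed(config$seed)
  state <- bes_init_state(objective, config, init)
  history <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    state <- bes_select_phase(state, objective, config)
    state <- bes_search_phase(state, objective, config)
    state <- bes_swoop_phase(state, objective, config)
    history[it] <- state$best_fit
  }
  list(par = state$best_pos, value = state$best_fit, history = history,
       state = state)
}
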