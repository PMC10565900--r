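#' Density-dependence modifier of cheat fitness
#'
#' Sigmoid multiplier \eqn{1 - a + a / (1 + e^{-s_d (N_{co} - t_d)})} applied
#' to the cheat growth rate: cheats exploit cooperators better at high
#' cooperator density. Bounded in \eqn{[1 - a, 1]} and non-decreasing in
#' \code{N_co}; identically 1 when \code{a = 0}.
#'
#' @param N_co cooperator density (vectorized).
#' @param a weight in \[0, 1\].
#' @param s_d steepness per density unit.
#' @param t_d threshold density (sigmoid midpoint).
#' @return numeric multiplier(s) in \[1 - a, 1\].
#' @examples
#' density_modifier(5, a = 1, s_d = 2, t_d = 5)  # 0.5 at the midpoint
#' @export
density_modifier <- function(N_co, a, s_d, t_d) {
  check_bound(a >= 0 && a <= 1, "0 <= a <= 1")
  1 - a + a * stats::plogis(s_d * (N_co - t_d))
}

#' Frequency-dependence modifier of cheat fitness
#'
#' Sigmoid multiplier \eqn{1 - b + b / (1 + e^{-s_f (p_{co} - t_f)})} where
#' \code{p_co} is the cooperator proportion: rare cheats meet cooperators more
#' often. Bounded in \eqn{[1 - b, 1]}, non-decreasing in \code{p_co},
#' identically 1 when \code{b = 0}.
#'
#' @param p_co cooperator proportion in \[0, 1\] (vectorized).
#' @param b weight in \[0, 1\].
#' @param s_f steepness (dimensionless).
#' @param t_f threshold proportion (sigmoid midpoint).
#' @return numeric multiplier(s) in \[1 - b, 1\].
#' @examples
#' frequency_modifier(0.5, b = 1, s_f = 10, t_f = 0.5)  # 0.5 at the midpoint
#' @export
frequency_modifier <- function(p_co, b, s_f, t_f) {
  check_bound(b >= 0 && b <= 1, "0 <= b <= 1")
  if (any(p_co < 0 | p_co > 1))
    stop("p_co must lie in [0, 1]", call. = FALSE)
  1 - b + b * stats::plogis(s_f * (p_co - t_f))
}

#' Time derivatives of the two-strain system
#'
#' Right-hand side of the growth ODEs: logistic cooperator growth and cheat
#' growth rescaled by the benefit coefficient \code{h} and the two modifiers.
#' An empty population (\code{N_co + N_ch = 0}) has both derivatives zero and
#' the frequency modifier is never evaluated.
#'
#' @param state numeric \code{c(N_co, N_ch)}, non-negative.
#' @param params a [model_params()] object.
#' @return named numeric vector \code{c(dN_co, dN_ch)}.
#' @examples
#' derivatives(population_state(5, 5), model_params())  # on the K line: zero
#' @export
derivatives <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(state)) || any(state < 0))
    stop("state must be finite and non-negative", call. = FALSE)
  d <- cpp_derivs(as.numeric(state[1:2]), unclass(params))
  c(dN_co = d[1], dN_ch = d[2])
}

#' Integrate the growth dynamics of one population
#'
#' Adaptive Dormand-Prince RK5(4) integration with dense output sampled on a
#' fixed grid. Densities are clipped at zero on solver undershoot and values
#' below \code{1e-12} are floored to 0.
#'
#' @param state0 initial \code{c(N_co, N_ch)}.
#' @param params a [model_params()] object.
#' @param duration integration time (> 0).
#' @param dt output sampling interval (default 0.01 time units).
#' @param rtol,atol relative / absolute solver tolerances.
#' @return a data frame of class \code{trajectory} with columns \code{time},
#'   \code{N_co}, \code{N_ch} and \code{p_cheat} (cheat proportion, \code{NA}
#'   when the population is empty).
#' @examples
#' tr <- integrate_growth(population_state(0.1, 0), model_params(), 20)
#' tail(tr, 1)  # approaches K = 10
#' @export
integrate_growth <- function(state0, params, duration, dt = 0.01,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"))
  check_bound(duration > 0, "duration > 0")
  check_bound(dt > 0, "dt > 0")
  if (any(!is.finite(state0)) || any(state0 < 0))
    stop("state0 must be finite and non-negative", call. = FALSE)
  m <- cpp_integrate(as.numeric(state0[1:2]), unclass(params), duration,
                     dt, rtol, atol)
  as_trajectory(m[, "time"], m[, "N_co"], m[, "N_ch"])
}

as_trajectory <- function(time, N_co, N_ch) {
  tot <- N_co + N_ch
  structure(data.frame(time = time, N_co = N_co, N_ch = N_ch,
                       p_cheat = ifelse(tot > 0, N_ch / tot, NA_real_)),
            class = c("trajectory", "data.frame"))
}

#' Evaluate the vector field on a grid of population states
#'
#' Derivatives of the growth system at each supplied state, optionally
#' normalized to unit vectors (with the magnitude kept in its own column),
#' as used for phase-plane direction plots.
#'
#' @param grid data frame (or 2-column matrix) of non-negative states with
#'   columns \code{N_co}, \code{N_ch}.
#' @param params a [model_params()] object.
#' @param normalize logical; if \code{TRUE}, \code{dN_co}/\code{dN_ch} are
#'   unit-length directions (zero vectors stay zero).
#' @return data frame with columns \code{N_co}, \code{N_ch}, \code{dN_co},
#'   \code{dN_ch}, \code{magnitude}.
#' @examples
#' g <- expand.grid(N_co = 0:10, N_ch = 0:10)
#' vf <- vector_field(g, model_params())
#' @export
vector_field <- function(grid, params, normalize = FALSE) {
  stopifnot(inherits(params, "model_params"))
  grid <- as.data.frame(grid)
  if (!all(c("N_co", "N_ch") %in% names(grid)))
    names(grid)[1:2] <- c("N_co", "N_ch")
  n <- nrow(grid)
  d <- matrix(0, n, 2)
  for (i in seq_len(n))
    d[i, ] <- cpp_derivs(c(grid$N_co[i], grid$N_ch[i]), unclass(params))
  mag <- sqrt(d[, 1]^2 + d[, 2]^2)
  if (normalize) {
    nz <- mag > 0
    d[nz, ] <- d[nz, , drop = FALSE] / mag[nz]
  }
  data.frame(N_co = grid$N_co, N_ch = grid$N_ch,
             dN_co = d[, 1], dN_ch = d[, 2], magnitude = mag)
}

#' Numerically locate the growth equilibrium from a starting state
#'
#' Integrates in chunks until the derivative norm falls below \code{tol}
#' (stationarity), as used for the chemostat-limit equilibrium check where
#' all interior trajectories converge to the line \eqn{N_{co} + N_{ch} = K}.
#'
#' @param state0 initial \code{c(N_co, N_ch)}.
#' @param params a [model_params()] object.
#' @param tol stationarity tolerance on the derivative Euclidean norm.
#' @param chunk integration time per convergence check.
#' @param max_time give up (with \code{converged = FALSE}) after this time.
#' @return list with \code{state}, \code{total} (N_co + N_ch), \code{time}
#'   integrated, and logical \code{converged}.
#' @examples
#' find_equilibrium(population_state(0.1, 0.1), model_params())$total
#' @export
find_equilibrium <- function(state0, params, tol = 1e-10, chunk = 25,
                             max_time = 5000) {
  stopifnot(inherits(params, "model_params"))
  state <- as.numeric(state0[1:2])
  t_done <- 0
  repeat {
    # tight tolerances: the stationarity check probes derivative norms near
    # the solver's own error floor
    state <- cpp_integrate_end(state, unclass(params), chunk, 1e-12, 1e-14)
    t_done <- t_done + chunk
    d <- cpp_derivs(state, unclass(params))
    if (sqrt(sum(d^2)) < tol)
      return(list(state = c(N_co = state[1], N_ch = state[2]),
                  total = sum(state), time = t_done, converged = TRUE))
    if (t_done >= max_time)
      return(list(state = c(N_co = state[1], N_ch = state[2]),
                  total = sum(state), time = t_done, converged = FALSE))
  }
}
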