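#' Model parameters for cheat-cooperator growth dynamics
#'
#' Bundles and validates the parameters of the two-strain competitive
#' Lotka-Volterra system with density- and frequency-dependent cheat fitness.
#' Cooperators grow logistically at intrinsic rate \code{r} toward carrying
#' capacity \code{K}; cheats grow at \code{h} times the cooperator rate,
#' multiplied by two sigmoid modifiers: one rising with cooperator density
#' (weight \code{a}, steepness \code{s_d}, threshold \code{t_d}) and one
#' rising with cooperator frequency (weight \code{b}, steepness \code{s_f},
#' threshold \code{t_f}).
#'
#' Defaults reproduce the qualitative regimes of the serial-passage system
#' with equilibrium line \eqn{N_{co} + N_{ch} = 10}: cheats up to twice as
#' fast as cooperators when fully enabled (\code{h = 2}), a density response
#' switching on at half the typical post-bottleneck density
#' (\code{t_d = K/20} with the default dilution \code{D = 10}), and a steep
#' frequency response centred at 0.5. See the methods vignette for why the
#' density threshold must sit near the bottleneck density, not near \code{K},
#' for bottlenecks to reverse the direction of selection.
#'
#' @param r intrinsic growth rate per unit time (> 0).
#' @param K carrying capacity, density units (> 0).
#' @param alpha between-strain regulation weight relative to within-strain
#'   regulation; \code{alpha = 1} means both strains deplete the shared
#'   resource equally.
#' @param h benefit coefficient of cheating (>= 0); \code{h > 1} lets cheats
#'   out-grow cooperators when the modifiers permit.
#' @param a weight of cheat density dependence, in \[0, 1\].
#' @param b weight of cheat frequency dependence, in \[0, 1\].
#' @param s_d density sigmoid steepness (per density unit, >= 0).
#' @param t_d density sigmoid threshold (density units, >= 0).
#' @param s_f frequency sigmoid steepness (dimensionless, >= 0).
#' @param t_f frequency sigmoid threshold, in \[0, 1\].
#' @return an object of class \code{model_params} (a named list).
#' @examples
#' model_params()                  # density-dependence-only defaults
#' model_params(a = 0, b = 1)      # frequency dependence only
#' @export
model_params <- function(r = 1, K = 10, alpha = 1, h = 2, a = 1, b = 0,
                         s_d = 2, t_d = K / 20, s_f = 10, t_f = 0.5) {
  p <- list(r = r, K = K, alpha = alpha, h = h, a = a, b = b,
            s_d = s_d, t_d = t_d, s_f = s_f, t_f = t_f)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("model_params: '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  check_bound(p$r > 0, "r > 0")
  check_bound(p$K > 0, "K > 0")
  check_bound(p$h >= 0, "h >= 0")
  check_bound(p$a >= 0 && p$a <= 1, "0 <= a <= 1")
  check_bound(p$b >= 0 && p$b <= 1, "0 <= b <= 1")
  check_bound(p$s_d >= 0, "s_d >= 0")
  check_bound(p$s_f >= 0, "s_f >= 0")
  check_bound(p$t_d >= 0, "t_d >= 0")
  check_bound(p$t_f >= 0 && p$t_f <= 1, "0 <= t_f <= 1")
  structure(p, class = "model_params")
}

check_bound <- function(ok, what) {
  if (!ok) stop("parameter out of bounds: requires ", what, call. = FALSE)
  invisible(TRUE)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  growth:     r = %g, K = %g, alpha = %g, h = %g\n",
              x$r, x$K, x$alpha, x$h))
  cat(sprintf("  density:    a = %g, s_d = %g, t_d = %g\n", x$a, x$s_d, x$t_d))
  cat(sprintf("  frequency:  b = %g, s_f = %g, t_f = %g\n", x$b, x$s_f, x$t_f))
  invisible(x)
}

#' Serial-passage (growth cycle) parameters
#'
#' @param D dilution ratio applied at the end of every growth phase (>= 1);
#'   \code{D = 1} is the chemostat limit (no bottleneck).
#' @param Tgrow duration of each growth phase, time units (> 0).
#' @param n_cycles number of growth cycles to simulate (>= 1).
#' @param burn_in_cycles cycles discarded before summary statistics; must be
#'   smaller than \code{n_cycles}. Defaults to 50 (the first quarter of the
#'   standard 200-cycle run), shrinking for shorter runs.
#' @return an object of class \code{passage_params}.
#' @examples
#' passage_params()               # D = 10, Tgrow = 10, 200 cycles
#' @export
passage_params <- function(D = 10, Tgrow = 10, n_cycles = 200,
                           burn_in_cycles = min(50, n_cycles %/% 4)) {
  check_bound(D >= 1, "D >= 1")
  check_bound(Tgrow > 0, "Tgrow > 0")
  check_bound(n_cycles >= 1, "n_cycles >= 1")
  check_bound(burn_in_cycles >= 0 && burn_in_cycles < n_cycles,
              "0 <= burn_in_cycles < n_cycles")
  structure(list(D = D, Tgrow = Tgrow, n_cycles = as.integer(n_cycles),
                 burn_in_cycles = as.integer(burn_in_cycles)),
            class = "passage_params")
}

#' @export
print.passage_params <- function(x, ...) {
  cat(sprintf("<passage_params> D = %g, Tgrow = %g, %d cycles (burn-in %d)\n",
              x$D, x$Tgrow, x$n_cycles, x$burn_in_cycles))
  invisible(x)
}

#' Metapopulation (stochastic group formation) parameters
#'
#' Configures the individual-based scenario in which `M` subpopulations grow
#' deterministically, are partially mixed by `round(F * M)` random pairwise
#' events, and pass through a shared bottleneck each cycle, with densities
#' converted to whole counts at sampling, pooling and dilution. The
#' integerization at small counts is the source of demographic stochasticity.
#'
#' @param M number of subpopulations (>= 2).
#' @param K_sub per-subpopulation carrying capacity; if non-\code{NULL} it
#'   overrides \code{K} of the model parameters during subpopulation growth,
#'   rescaling \code{t_d} proportionally. The default 50 leaves roughly
#'   \code{K_sub / D = 5} individuals per subpopulation after each
#'   bottleneck, small enough for count rounding to be a real source of
#'   demographic noise.
#' @param F mixing coefficient (>= 0): \code{round(F * M)} pairwise mixing
#'   events per cycle; larger values approach global mixing.
#' @param D dilution ratio (>= 1).
#' @param Tgrow growth-phase duration (> 0).
#' @param n_cycles number of growth cycles (>= 1).
#' @param seed RNG seed for the run (integer); \code{NULL} uses the current
#'   RNG state.
#' @param integer_mode rounding rule at count-conversion points:
#'   \code{"stochastic"} (floor plus Bernoulli on the fractional part,
#'   default), \code{"round"} (deterministic half away from zero), or
#'   \code{"none"} (real-valued limit, used for cross-checks against the
#'   serial-passage engine). Stochastic rounding is the default because
#'   subpopulations start identical: under a deterministic rule they would
#'   remain identical forever and the scenario would have no demographic
#'   stochasticity at all.
#' @return an object of class \code{metapop_params}.
#' @examples
#' metapop_params(M = 50, seed = 1)
#' @export
metapop_params <- function(M = 50, K_sub = 50, F = 1, D = 10, Tgrow = 10,
                           n_cycles = 200, seed = NULL,
                           integer_mode = c("stochastic", "round", "none")) {
  integer_mode <- match.arg(integer_mode)
  check_bound(M >= 2, "M >= 2")
  check_bound(is.null(K_sub) || K_sub > 0, "K_sub > 0")
  check_bound(F >= 0, "F >= 0")
  check_bound(D >= 1, "D >= 1")
  check_bound(Tgrow > 0, "Tgrow > 0")
  check_bound(n_cycles >= 1, "n_cycles >= 1")
  structure(list(M = as.integer(M), K_sub = K_sub, F = F, D = D,
                 Tgrow = Tgrow, n_cycles = as.integer(n_cycles),
                 seed = seed, integer_mode = integer_mode),
            class = "metapop_params")
}

#' @export
print.metapop_params <- function(x, ...) {
  cat(sprintf(
    "<metapop_params> M = %d, K_sub = %s, F = %g, D = %g, Tgrow = %g, %d cycles, %s rounding\n",
    x$M, if (is.null(x$K_sub)) "model K" else format(x$K_sub), x$F, x$D,
    x$Tgrow, x$n_cycles, x$integer_mode))
  invisible(x)
}

#' Population state of one well-mixed population
#'
#' @param N_co cooperator density (>= 0, finite).
#' @param N_ch cheat density (>= 0, finite).
#' @return named numeric vector \code{c(N_co, N_ch)}.
#' @examples
#' population_state(0.1, 0.1)
#' @export
population_state <- function(N_co, N_ch) {
  if (!is.finite(N_co) || !is.finite(N_ch) || N_co < 0 || N_ch < 0)
    stop("population state must be finite and non-negative", call. = FALSE)
  c(N_co = N_co, N_ch = N_ch)
}

integer_mode_code <- function(mode) {
  match(mode, c("round", "stochastic", "none")) - 1L
}
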