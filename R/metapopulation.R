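#' Initialize a metapopulation of identical subpopulations
#'
#' @param M number of subpopulations (>= 2).
#' @param n0_co,n0_ch starting cooperator / cheat counts per subpopulation
#'   (>= 0).
#' @return an \code{M x 2} matrix with columns \code{N_co}, \code{N_ch}.
#' @examples
#' init_metapopulation(3, 5, 5)
#' @export
init_metapopulation <- function(M, n0_co = 5, n0_ch = 5) {
  check_bound(M >= 2, "M >= 2")
  check_bound(n0_co >= 0 && n0_ch >= 0, "initial counts >= 0")
  m <- cbind(N_co = rep(as.numeric(n0_co), M),
             N_ch = rep(as.numeric(n0_ch), M))
  m
}

#' Grow every subpopulation independently for one growth phase
#'
#' Each row is integrated under the same growth dynamics; results equal
#' per-subpopulation [integrate_growth()] end states to solver accuracy.
#'
#' @param subpops \code{M x 2} matrix of non-negative counts.
#' @param model a [model_params()] object.
#' @param Tgrow growth duration.
#' @param rtol,atol solver tolerances.
#' @return real-valued \code{M x 2} matrix of grown densities.
#' @export
grow_all <- function(subpops, model, Tgrow, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "model_params"))
  subpops <- as.matrix(subpops)
  out <- cpp_grow_all(subpops, unclass(model), Tgrow, rtol, atol)
  colnames(out) <- c("N_co", "N_ch")
  out
}

#' Convert real-valued counts to whole individuals
#'
#' Default rule is round-half-away-from-zero; the \code{"stochastic"} mode
#' floors and adds a Bernoulli draw on the fractional part (consuming the
#' R RNG stream); \code{"none"} passes values through for deterministic-limit
#' cross-checks. Idempotent on integers; errors on negative input.
#'
#' @param x non-negative numeric counts.
#' @param mode \code{"round"}, \code{"stochastic"} or \code{"none"}.
#' @return counts under the chosen rule.
#' @examples
#' integerize(c(4.6, 0.4, 2.5))  # 5 0 3
#' @export
integerize <- function(x, mode = c("round", "stochastic", "none")) {
  mode <- match.arg(mode)
  cpp_integerize(as.numeric(x), integer_mode_code(mode))
}

#' Random pairwise mixing of subpopulations
#'
#' Performs \code{round(F * M)} mixing events. Each event draws two distinct
#' subpopulations uniformly at random, pools their integerized counts per
#' strain, and replaces both with the integerized pooled average ("two new
#' subpopulations" per event). A subpopulation may be sampled in several
#' events within one cycle. Consumes the R RNG stream; seed upstream for
#' reproducibility.
#'
#' @param subpops \code{M x 2} count matrix.
#' @param F mixing coefficient (>= 0).
#' @param mode integerization rule (see [integerize()]).
#' @return mixed \code{M x 2} matrix.
#' @export
mix_pairs <- function(subpops, F, mode = c("round", "stochastic", "none")) {
  mode <- match.arg(mode)
  subpops <- as.matrix(subpops)
  out <- cpp_mix_pairs(subpops, F, integer_mode_code(mode))
  colnames(out) <- c("N_co", "N_ch")
  out
}

#' Apply the dilution bottleneck to every subpopulation
#'
#' Each count is divided by \code{D} and then integerized, so small
#' subpopulations can lose a strain outright (bottleneck extinction).
#'
#' @param subpops \code{M x 2} count matrix.
#' @param D dilution ratio (>= 1).
#' @param mode integerization rule (see [integerize()]).
#' @return bottlenecked \code{M x 2} matrix.
#' @examples
#' bottleneck_all(rbind(c(100, 50), c(4, 4)), D = 10)
#' @export
bottleneck_all <- function(subpops, D, mode = c("round", "stochastic", "none")) {
  mode <- match.arg(mode)
  check_bound(D >= 1, "D >= 1")
  subpops <- as.matrix(subpops)
  out <- cpp_bottleneck_all(subpops, D, integer_mode_code(mode))
  colnames(out) <- c("N_co", "N_ch")
  out
}

#' Run the stochastic metapopulation life cycle
#'
#' Per growth cycle: deterministic growth in each of the \code{M}
#' subpopulations, conversion of densities to whole counts, \code{round(F*M)}
#' random pairwise mixing events, then the dilution bottleneck (counts
#' integerized again). Records, per cycle, the post-bottleneck global cheat
#' proportion pooled over subpopulations, the mean and coefficient of
#' variation of per-subpopulation cheat relative fitness over the growth
#' phase, and the number of subpopulations where fitness is defined. Fully
#' reproducible given \code{meta$seed}.
#'
#' @param model a [model_params()] object; if \code{meta$K_sub} is set it
#'   overrides \code{model$K} (and rescales \code{t_d} by the same factor so
#'   the density threshold stays at the same fraction of capacity).
#' @param meta a [metapop_params()] object.
#' @param n0_co,n0_ch identical starting counts for every subpopulation.
#' @param rtol,atol solver tolerances.
#' @param keep_fitness also return the full \code{M x n_cycles} matrix of
#'   per-subpopulation relative fitness.
#' @return object of class \code{metapop_run}: list with \code{cycles}
#'   (data frame: cycle, p_global, mean_fitness, cv_fitness, n_fitness),
#'   \code{subpops} (final counts), \code{extinct}, \code{completed}, and
#'   the parameter objects; plus \code{fitness} if requested.
#' @examples
#' run <- run_metapopulation(model_params(), metapop_params(M = 10,
#'   n_cycles = 5, seed = 1))
#' run$cycles
#' @export
run_metapopulation <- function(model, meta, n0_co = 5, n0_ch = 5,
                               rtol = 1e-8, atol = 1e-10,
                               keep_fitness = FALSE) {
  stopifnot(inherits(model, "model_params"), inherits(meta, "metapop_params"))
  if (!is.null(meta$K_sub) && meta$K_sub != model$K) {
    scale <- meta$K_sub / model$K
    model_run <- model_params(r = model$r, K = meta$K_sub, alpha = model$alpha,
                              h = model$h, a = model$a, b = model$b,
                              s_d = model$s_d, t_d = model$t_d * scale,
                              s_f = model$s_f, t_f = model$t_f)
  } else {
    model_run <- model
  }
  if (!is.null(meta$seed)) set.seed(meta$seed)
  res <- cpp_run_metapopulation(unclass(model_run), meta$M, n0_co, n0_ch,
                                meta$F, meta$D, meta$Tgrow, meta$n_cycles,
                                integer_mode_code(meta$integer_mode),
                                rtol, atol, keep_fitness)
  cyc <- as.data.frame(res$cycles)[seq_len(res$completed), , drop = FALSE]
  sub <- res$subpops
  colnames(sub) <- c("N_co", "N_ch")
  out <- structure(list(cycles = cyc, subpops = sub, extinct = res$extinct,
                        completed = res$completed, model = model_run,
                        meta = meta, n0 = c(n0_co, n0_ch)),
                   class = "metapop_run")
  if (keep_fitness) out$fitness <- res$fitness[, seq_len(res$completed),
                                               drop = FALSE]
  out
}

#' @export
print.metapop_run <- function(x, ...) {
  cat(sprintf("<metapop_run> M = %d, %d/%d cycles%s; final global p_cheat = %s\n",
              x$meta$M, x$completed, x$meta$n_cycles,
              if (x$extinct) " (EXTINCT)" else "",
              format(utils::tail(x$cycles$p_global, 1), digits = 4)))
  invisible(x)
}

#' Cheat relative fitness over one growth phase
#'
#' Ratio of realized Malthusian growth: \eqn{\ln(ch_1/ch_0) / \ln(co_1/co_0)}.
#' Values above 1 mean cheats out-grew cooperators. Undefined (\code{NA})
#' when any count is non-positive or the cooperator log fold-change is zero;
#' undefined values are excluded from averages.
#'
#' @param start,end numeric \code{c(co, ch)} counts at phase start / end.
#' @return fitness ratio or \code{NA}.
#' @examples
#' relative_fitness(c(10, 10), c(100, 1000))  # 2
#' @export
relative_fitness <- function(start, end) {
  co0 <- start[1]; ch0 <- start[2]; co1 <- end[1]; ch1 <- end[2]
  if (any(c(co0, ch0, co1, ch1) <= 0)) return(NA_real_)
  g_co <- log(co1 / co0)
  if (abs(g_co) <= 1e-12) return(NA_real_)
  log(ch1 / ch0) / g_co
}

#' Coefficient of variation of per-subpopulation fitness
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, over
#' the defined fitness values of one growth cycle.
#'
#' @param values numeric fitness values; \code{NA}s are dropped.
#' @return CV, or \code{NA} when fewer than 2 defined values or zero mean.
#' @examples
#' fitness_cv(c(1, 3))  # sqrt(2)/2
#' @export
fitness_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  stats::sd(v) / m
}
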