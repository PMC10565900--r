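#' Harmonic regression over a grid of candidate periods
#'
#' For each candidate period \eqn{T}, fits the ordinary least squares model
#' \eqn{y_t = c + A \sin(2\pi t / T) + B \cos(2\pi t / T)} and reports the
#' amplitude \eqn{\sqrt{A^2 + B^2}} with a 95\% delta-method confidence
#' interval from the OLS coefficient covariance. The peak period is the grid
#' period of maximal amplitude (smallest period on ties). Used to quantify
#' how periodic a per-cycle cheat-proportion series is.
#'
#' @param series numeric per-cycle values (length >= 3; at least
#'   \code{2 * max(periods)} points recommended).
#' @param periods candidate periods in growth cycles (each >= 2). Default
#'   integer periods 2..75, half of the standard 150-cycle analysis window.
#' @param conf confidence level for the amplitude intervals.
#' @return object of class \code{harmonic_fit}: list with \code{fits} (data
#'   frame: period, amplitude, ci_low, ci_high), \code{peak_period},
#'   \code{degenerate} (TRUE for a constant series), \code{n}.
#' @examples
#' y <- make_sine_series(amplitude = 0.2, period = 15, noise_sd = 0,
#'                       length = 150)
#' harmonic_regression(y)$peak_period  # 15
#' @export
harmonic_regression <- function(series, periods = 2:75, conf = 0.95) {
  y <- as.numeric(series)
  y <- y[!is.na(y)]
  L <- length(y)
  if (L < 3) stop("series must have at least 3 points", call. = FALSE)
  if (any(periods < 2)) stop("candidate periods must be >= 2", call. = FALSE)
  t <- seq_len(L)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  degenerate <- stats::var(y) == 0
  fits <- lapply(periods, function(Tp) {
    X <- cbind(1, sin(2 * pi * t / Tp), cos(2 * pi * t / Tp))
    # at integer sampling a harmonic column can vanish identically (e.g. the
    # sine at period 2); drop it rather than fit a rank-deficient design
    live <- c(TRUE, colSums(X[, 2:3, drop = FALSE]^2) > L * 1e-16)
    fit <- stats::lm.fit(X[, live, drop = FALSE], y)
    coefs <- c(0, 0, 0)
    coefs[live] <- unname(fit$coefficients)
    A <- coefs[2]; B <- coefs[3]
    amp <- sqrt(A^2 + B^2)
    rss <- sum(fit$residuals^2)
    df <- L - fit$rank
    if (df > 0 && amp > 0 && fit$rank == sum(live)) {
      sigma2 <- rss / df
      XtXinv <- chol2inv(chol(crossprod(X[, live, drop = FALSE])))
      g_full <- c(A, B) / amp
      g <- g_full[live[2:3]]
      Sigma <- sigma2 * XtXinv[-1, -1, drop = FALSE]
      se <- sqrt(drop(t(g) %*% Sigma %*% g))
    } else {
      se <- NA_real_
    }
    c(amplitude = amp,
      ci_low = if (is.na(se)) NA_real_ else max(0, amp - z * se),
      ci_high = if (is.na(se)) NA_real_ else amp + z * se)
  })
  fits <- data.frame(period = periods, do.call(rbind, fits))
  if (degenerate) {  # constant series: amplitudes are exactly 0, CIs flagged
    fits$amplitude <- 0
    fits$ci_low <- NA_real_
    fits$ci_high <- NA_real_
  }
  peak <- if (all(fits$amplitude == 0)) NA_real_ else
    fits$period[which.max(fits$amplitude)]  # which.max: first (smallest) on ties
  structure(list(fits = fits, peak_period = peak, degenerate = degenerate,
                 n = L, conf = conf),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> %d points, %d candidate periods; peak period = %s%s\n",
              x$n, nrow(x$fits), format(x$peak_period),
              if (x$degenerate) " (degenerate: constant series)" else ""))
  invisible(x)
}

#' Period of maximal fitted amplitude
#'
#' @param fit a [harmonic_regression()] result.
#' @return the grid period with the largest amplitude (smallest on ties), or
#'   \code{NA} if all amplitudes are zero.
#' @examples
#' fit <- harmonic_regression(make_sine_series(0.2, 15, 0, 150))
#' peak_period(fit)
#' @export
peak_period <- function(fit) {
  stopifnot(inherits(fit, "harmonic_fit"))
  fit$peak_period
}

#' Oscillation amplitude from the discrete Fourier transform
#'
#' Mean-centers the series, takes the DFT, and returns the maximal signal
#' \eqn{\max_k 2 |X_k| / L} over nonzero frequencies. For a pure tone with an
#' integer number of periods in the window this equals the tone's amplitude.
#' Invariant to adding a constant; scales linearly with the series.
#'
#' @param series numeric per-cycle values, length >= 4.
#' @return amplitude >= 0.
#' @examples
#' dft_amplitude(0.5 + 0.25 * sin(2 * pi * (1:60) / 15))  # 0.25
#' @export
dft_amplitude <- function(series) {
  y <- as.numeric(series)
  y <- y[!is.na(y)]
  L <- length(y)
  if (L < 4) stop("series must have at least 4 points", call. = FALSE)
  X <- stats::fft(y - mean(y))
  max(2 * Mod(X[-1]) / L)
}

#' Sweep an oscillation statistic over the (a, b) dependence grid
#'
#' Runs a scenario engine for every combination of density weighting \code{a}
#' and frequency weighting \code{b}, with \code{replicates} runs per cell
#' under deterministically derived child seeds, and averages the returned
#' statistics. A failed run leaves \code{NA} in the affected cell (with a
#' warning) rather than being dropped silently.
#'
#' @param a_grid,b_grid numeric grids of dependence weightings in \[0, 1\].
#' @param runner \code{function(a, b, seed)} returning either a single
#'   amplitude or a list with elements \code{amplitude} and optionally
#'   \code{mean_fitness} and \code{cv}. See [scenario2_runner()] /
#'   [scenario3_runner()].
#' @param replicates runs averaged per cell (>= 1).
#' @param seed master seed; child seeds are drawn from it reproducibly.
#' @return object of class \code{amplitude_sweep}: list of matrices
#'   \code{amplitude}, \code{mean_fitness}, \code{cv} (rows = \code{a_grid},
#'   columns = \code{b_grid}), plus \code{long}, a long-format data frame
#'   with one row per (a, b, replicate).
#' @examples
#' sw <- amplitude_sweep(0.5, 0.5, function(a, b, seed) 0.1)
#' sw$amplitude
#' @export
amplitude_sweep <- function(a_grid, b_grid, runner, replicates = 1,
                            seed = 1) {
  check_bound(replicates >= 1, "replicates >= 1")
  na <- length(a_grid); nb <- length(b_grid)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, na * nb * replicates)
  dim(child_seeds) <- c(na, nb, replicates)
  amp <- fit <- cv <- matrix(NA_real_, na, nb,
                             dimnames = list(a = a_grid, b = b_grid))
  long <- vector("list", na * nb * replicates)
  k <- 0L
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    vals <- matrix(NA_real_, replicates, 3)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      res <- tryCatch(runner(a_grid[i], b_grid[j], child_seeds[i, j, r]),
                      error = function(e) {
                        warning(sprintf("run failed at a = %g, b = %g: %s",
                                        a_grid[i], b_grid[j],
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
      if (!is.null(res)) {
        if (is.list(res)) {
          vals[r, 1] <- res$amplitude
          vals[r, 2] <- if (!is.null(res$mean_fitness)) res$mean_fitness else NA
          vals[r, 3] <- if (!is.null(res$cv)) res$cv else NA
        } else {
          vals[r, 1] <- as.numeric(res)
        }
      }
      long[[k]] <- data.frame(a = a_grid[i], b = b_grid[j], replicate = r,
                              amplitude = vals[r, 1], mean_fitness = vals[r, 2],
                              cv = vals[r, 3])
    }
    mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    amp[i, j] <- mean_or_na(vals[, 1])
    fit[i, j] <- mean_or_na(vals[, 2])
    cv[i, j] <- mean_or_na(vals[, 3])
  }
  structure(list(amplitude = amp, mean_fitness = fit, cv = cv,
                 long = do.call(rbind, long),
                 a_grid = a_grid, b_grid = b_grid, replicates = replicates,
                 seed = seed),
            class = "amplitude_sweep")
}

#' @export
print.amplitude_sweep <- function(x, ...) {
  cat(sprintf("<amplitude_sweep> %d x %d grid, %d replicate(s)\n",
              length(x$a_grid), length(x$b_grid), x$replicates))
  print(round(x$amplitude, 4))
  invisible(x)
}

#' Sweep runner: deterministic serial passage (within-cycle amplitude)
#'
#' Returns a \code{function(a, b, seed)} for [amplitude_sweep()] that runs
#' the bottleneck engine and reports the stabilized within-cycle amplitude
#' (the seed is unused: the engine is deterministic).
#'
#' @param model base [model_params()]; \code{a}, \code{b} are overridden.
#' @param passage a [passage_params()] object.
#' @param state0 initial state.
#' @return runner function.
#' @export
scenario2_runner <- function(model = model_params(),
                             passage = passage_params(),
                             state0 = population_state(0.5, 0.5)) {
  force(model); force(passage); force(state0)
  function(a, b, seed) {
    m <- model; m$a <- a; m$b <- b
    run <- run_serial_passage(m, passage, state0)
    list(amplitude = stabilized_amplitude(run))
  }
}

#' Sweep runner: stochastic metapopulation (cross-cycle DFT amplitude)
#'
#' Returns a \code{function(a, b, seed)} for [amplitude_sweep()] that runs
#' the metapopulation engine and reports the DFT amplitude of the global
#' cheat-proportion series over the analysis window, together with the mean
#' relative fitness and the mean fitness CV over the same window.
#'
#' @param model base [model_params()]; \code{a}, \code{b} are overridden.
#' @param meta a [metapop_params()] object (its seed is replaced per run).
#' @param window cycles analyzed (default 51:200).
#' @param n0_co,n0_ch initial per-subpopulation counts.
#' @return runner function.
#' @export
scenario3_runner <- function(model = model_params(), meta = metapop_params(),
                             window = 51:200, n0_co = 5, n0_ch = 5) {
  force(model); force(meta); force(window)
  function(a, b, seed) {
    m <- model; m$a <- a; m$b <- b
    class(m) <- "model_params"
    mp <- meta; mp$seed <- seed
    class(mp) <- "metapop_params"
    run <- run_metapopulation(m, mp, n0_co = n0_co, n0_ch = n0_ch)
    cyc <- run$cycles[run$cycles$cycle %in% window, ]
    p <- cyc$p_global
    list(amplitude = if (sum(!is.na(p)) >= 4) dft_amplitude(p) else NA_real_,
         mean_fitness = weighted_mean_fitness(cyc),
         cv = if (all(is.na(cyc$cv_fitness))) NA_real_ else
           mean(cyc$cv_fitness, na.rm = TRUE))
  }
}

# mean relative fitness over all defined per-subpop values in the window,
# recovered from per-cycle means weighted by the defined-value counts
weighted_mean_fitness <- function(cycles) {
  ok <- !is.na(cycles$mean_fitness) & cycles$n_fitness > 0
  if (!any(ok)) return(NA_real_)
  sum(cycles$mean_fitness[ok] * cycles$n_fitness[ok]) / sum(cycles$n_fitness[ok])
}
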