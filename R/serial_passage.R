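#' Apply one dilution bottleneck
#'
#' Divides both densities by the dilution ratio \code{D}. Exact arithmetic:
#' the deterministic serial-passage engine never converts to whole counts
#' (integerization belongs to the metapopulation scenario).
#'
#' @param state numeric \code{c(N_co, N_ch)}.
#' @param D dilution ratio (>= 1).
#' @return diluted state.
#' @examples
#' dilute(population_state(100, 50), D = 10)
#' @export
dilute <- function(state, D) {
  check_bound(D >= 1, "D >= 1")
  state / D
}

#' Run a deterministic serial-passage experiment
#'
#' Alternates deterministic growth for \code{Tgrow} time units with an
#' instantaneous dilution of both strains by \code{D}, for \code{n_cycles}
#' growth cycles. The run is bit-reproducible given solver settings. If both
#' strains fall to zero the run terminates early and is flagged extinct.
#'
#' @param model a [model_params()] object.
#' @param passage a [passage_params()] object.
#' @param state0 initial \code{c(N_co, N_ch)} (positive).
#' @param dt within-cycle output sampling interval (default 0.01).
#' @param rtol,atol solver tolerances.
#' @param keep_trajectory keep the concatenated within-cycle trajectory
#'   (needed for the full-series amplitude statistic; default \code{TRUE}).
#' @return object of class \code{serial_passage_run}: a list with
#'   \code{cycles} (data frame: cycle, start/end densities, end-of-cycle
#'   cheat proportion \code{p_end}), \code{trajectory} (data frame: time,
#'   cycle, N_co, N_ch, p_cheat; \code{NULL} if not kept), \code{extinct},
#'   \code{completed}, \code{final} (the post-dilution state after the last
#'   completed cycle), and the parameter objects.
#' @examples
#' run <- run_serial_passage(model_params(a = 1, b = 0),
#'                           passage_params(n_cycles = 20),
#'                           population_state(0.5, 0.5))
#' stabilized_amplitude(run, burn_in_cycles = 10)
#' @export
run_serial_passage <- function(model, passage, state0 = population_state(0.5, 0.5),
                               dt = 0.01, rtol = 1e-8, atol = 1e-10,
                               keep_trajectory = TRUE) {
  stopifnot(inherits(model, "model_params"), inherits(passage, "passage_params"))
  if (any(!is.finite(state0)) || any(state0 < 0))
    stop("state0 must be finite and non-negative", call. = FALSE)
  res <- cpp_serial_passage(as.numeric(state0[1:2]), unclass(model),
                            passage$D, passage$Tgrow, passage$n_cycles,
                            dt, rtol, atol, keep_trajectory)
  cyc <- as.data.frame(res$cycles)[seq_len(res$completed), , drop = FALSE]
  traj <- NULL
  if (keep_trajectory) {
    tm <- res$trajectory
    traj <- as_trajectory(tm[, "time"], tm[, "N_co"], tm[, "N_ch"])
    traj$cycle <- tm[, "cycle"]
  }
  structure(list(cycles = cyc, trajectory = traj,
                 extinct = res$extinct, completed = res$completed,
                 final = c(N_co = res$final_co, N_ch = res$final_ch),
                 model = model, passage = passage,
                 state0 = state0, dt = dt),
            class = "serial_passage_run")
}

#' @export
print.serial_passage_run <- function(x, ...) {
  cat(sprintf("<serial_passage_run> %d/%d cycles%s; final p_cheat = %s\n",
              x$completed, x$passage$n_cycles,
              if (x$extinct) " (EXTINCT)" else "",
              format(utils::tail(x$cycles$p_end, 1), digits = 4)))
  invisible(x)
}

#' Stabilized within-cycle oscillation amplitude
#'
#' The amplitude statistic of the bottleneck scenario: the maximal difference
#' in cheat proportion (max minus min) over all retained time points after a
#' burn-in window, by which time the cycle-to-cycle dynamics have stabilized.
#' By default the full within-cycle proportion series (sampled at \code{dt})
#' is used, since the oscillation unfolds within each growth phase; cycle-end
#' points only can be requested instead.
#'
#' @param x a \code{serial_passage_run}, or a numeric proportion series with
#'   a companion \code{cycle} vector.
#' @param burn_in_cycles cycles discarded before the max-min statistic;
#'   defaults to the run's passage setting.
#' @param series \code{"full"} (within-cycle samples, default) or
#'   \code{"endpoints"} (one value per cycle).
#' @param cycle cycle index per element of \code{x} when \code{x} is numeric.
#' @return amplitude in \[0, 1\].
#' @export
stabilized_amplitude <- function(x, burn_in_cycles = NULL,
                                 series = c("full", "endpoints"),
                                 cycle = NULL) {
  series <- match.arg(series)
  if (inherits(x, "serial_passage_run")) {
    if (is.null(burn_in_cycles)) burn_in_cycles <- x$passage$burn_in_cycles
    if (series == "full") {
      if (is.null(x$trajectory))
        stop("run was created with keep_trajectory = FALSE", call. = FALSE)
      p <- x$trajectory$p_cheat
      cycle <- x$trajectory$cycle
    } else {
      p <- x$cycles$p_end
      cycle <- x$cycles$cycle
    }
  } else {
    p <- as.numeric(x)
    if (is.null(cycle)) cycle <- seq_along(p)
    if (is.null(burn_in_cycles)) burn_in_cycles <- 0L
  }
  keep <- cycle > burn_in_cycles & !is.na(p)
  if (!any(keep))
    stop("no data points remain after the burn-in window", call. = FALSE)
  max(p[keep]) - min(p[keep])
}
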