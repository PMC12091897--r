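#' One classical RK4 step
#'
#' Advances a state vector by one step of the classical fourth-order
#' Runge-Kutta scheme: increments k1..k4 with k2, k3 at half step and k4 at
#' full step, combined with weights 1/6, 1/3, 1/3, 1/6. The system is
#' autonomous, so the derivative function takes the state only.
#'
#' @param state numeric state vector.
#' @param dt step size (ms), positive.
#' @param f derivative function `f(state)` returning a vector of the same
#'   length.
#' @return The state advanced by `dt`.
#' @examples
#' rk4_step(1, 0.1, function(x) -x)  # one step of dx/dt = -x
#' @export
rk4_step <- function(state, dt, f) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  k1 <- dt * f(state)
  k2 <- dt * f(state + k1 / 2)
  k3 <- dt * f(state + k2 / 2)
  k4 <- dt * f(state + k3)
  out <- state + k1 / 6 + k2 / 3 + k3 / 3 + k4 / 6
  if (any(!is.finite(out)))
    stop("divergence: non-finite state after RK4 step", call. = FALSE)
  out
}

#' Simulate the neuron under a DC induced field
#'
#' Integrates the eight-dimensional PR system with the classical fixed-step
#' RK4 scheme, recording the full trajectory. The integration is
#' deterministic: identical inputs give bit-identical traces.
#'
#' The defaults follow the standard protocol: step `dt` = 0.1 ms, duration
#' 7000 ms (70000 steps), and the common attractor state from
#' [pr_initial_state()] as the start.
#'
#' Strong coupling makes the fixed-step scheme numerically unstable (the
#' soma-dendrite exchange rate exceeds the RK4 stability bound near
#' gc ~ 20 mS/cm2 at dt = 0.1 ms). When the state leaves the finite range
#' the integrator stops; with `on_divergence = "error"` (default) this is an
#' error reporting the failure time, with `"truncate"` the finite part of the
#' trace is returned and flagged.
#'
#' @param pars a [pr_params()] object.
#' @param Ve DC induced-field amplitude (mV).
#' @param dt time step (ms).
#' @param duration total simulated time (ms); the number of steps is
#'   `round(duration/dt)`.
#' @param init initial state (named length-8 vector).
#' @param record_stride record every `record_stride`-th step (1 = all).
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation; identical results, much slower).
#' @param on_divergence `"error"` or `"truncate"`.
#' @return A `pr_trace`: a data frame with columns `time` (ms), `Vs`, `Vd`
#'   (mV), `h`, `n`, `s`, `c`, `q`, `Ca`, and attributes `params`, `Ve`,
#'   `dt`, `duration`, `record_stride`, `diverged`, `divergence_time`.
#' @examples
#' tr <- pr_simulate(pr_params(gc = 2.1, Id = 1), duration = 500)
#' head(tr)
#' @export
pr_simulate <- function(pars = pr_params(), Ve = 0, dt = 0.1,
                        duration = 7000, init = pr_initial_state(),
                        record_stride = 1L, engine = c("cpp", "R"),
                        on_divergence = c("error", "truncate")) {
  stopifnot(inherits(pars, "pr_params"))
  engine <- match.arg(engine)
  on_divergence <- match.arg(on_divergence)
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration < dt)
    stop("'duration' must be at least one step", call. = FALSE)
  if (!is.numeric(Ve) || length(Ve) != 1L || !is.finite(Ve))
    stop("'Ve' must be a single finite number", call. = FALSE)
  record_stride <- as.integer(record_stride)
  if (is.na(record_stride) || record_stride < 1L)
    stop("'record_stride' must be a positive integer", call. = FALSE)
  init <- .check_state(init)
  nsteps <- as.integer(round(duration / dt))

  if (engine == "cpp") {
    res <- pr_integrate_cpp(init, .par_vector(pars), Ve, dt, nsteps,
                            record_stride)
    nrec <- res$n_recorded
    states <- res$states[seq_len(nrec), , drop = FALSE]
    diverged <- res$diverged
    fail_step <- res$fail_step
  } else {
    f <- function(y) unname(pr_deriv(y, pars, Ve))
    nrec_max <- nsteps %/% record_stride + 1L
    states <- matrix(NA_real_, nrec_max, 8L)
    states[1L, ] <- init
    y <- unname(init)
    nrec <- 1L
    diverged <- FALSE
    fail_step <- -1L
    for (i in seq_len(nsteps)) {
      k1 <- dt * f(y); k2 <- dt * f(y + k1 / 2)
      k3 <- dt * f(y + k2 / 2); k4 <- dt * f(y + k3)
      y <- y + k1 / 6 + k2 / 3 + k3 / 3 + k4 / 6
      if (any(!is.finite(y))) { diverged <- TRUE; fail_step <- i; break }
      if (i %% record_stride == 0L) { nrec <- nrec + 1L; states[nrec, ] <- y }
    }
    states <- states[seq_len(nrec), , drop = FALSE]
  }

  if (diverged && on_divergence == "error")
    stop(sprintf("divergence: state became non-finite at t = %.1f ms",
                 fail_step * dt), call. = FALSE)

  colnames(states) <- .state_names
  tr <- data.frame(time = seq(0, by = dt * record_stride,
                              length.out = nrow(states)),
                   states)
  structure(tr,
            class = c("pr_trace", "data.frame"),
            params = pars, Ve = Ve, dt = dt, duration = duration,
            record_stride = record_stride,
            diverged = isTRUE(diverged),
            divergence_time = if (isTRUE(diverged)) fail_step * dt else NA_real_)
}

#' @export
print.pr_trace <- function(x, ...) {
  a <- attributes(x)
  cat(sprintf(
    "PR neuron trace: %d samples, dt = %g ms, duration = %g ms, Ve = %g mV\n",
    nrow(x), a$dt, a$duration, a$Ve))
  p <- a$params
  cat(sprintf("  gc = %g, VK = %g, Is = %g, Id = %g\n", p$gc, p$VK, p$Is, p$Id))
  if (isTRUE(a$diverged))
    cat(sprintf("  ** diverged at t = %.1f ms; trace truncated **\n",
                a$divergence_time))
  cat(sprintf("  Vs range [%.2f, %.2f] mV\n", min(x$Vs), max(x$Vs)))
  invisible(x)
}

#' @export
summary.pr_trace <- function(object, criteria = pr_criteria(), ...) {
  sp <- try(pr_spikes(object, criteria), silent = TRUE)
  cat(sprintf("PR trace over %g ms (Ve = %g mV)\n",
              attr(object, "duration"), attr(object, "Ve")))
  if (!inherits(sp, "try-error")) {
    cat(sprintf("  %d somatic spikes after %g ms transient; F = %.2f Hz\n",
                length(sp$times), criteria$transient_discard,
                pr_firing_rate(sp)))
    cat("  regime:", pr_classify(object, sp, criteria), "\n")
  }
  invisible(object)
}

#' Plot a simulated trace
#'
#' Somatic (and optionally dendritic) membrane potential against time.
#'
#' @param x a `pr_trace`.
#' @param dendrite also draw Vd (dashed).
#' @param ... passed to [graphics::plot()].
#' @return The trace, invisibly.
#' @export
plot.pr_trace <- function(x, dendrite = FALSE, ...) {
  graphics::plot(x$time, x$Vs, type = "l", xlab = "time (ms)",
                 ylab = "membrane potential (mV)", ...)
  if (dendrite) graphics::lines(x$time, x$Vd, lty = 2, col = "grey40")
  invisible(x)
}
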