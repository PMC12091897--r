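#' Synthetic traces realizing each firing regime
#'
#' Builds a deterministic, simulation-free voltage trace constructed to
#' satisfy the definition of one regime label: piecewise constants and
#' sinusoids for the non-firing states, triangular spike templates grouped
#' into the required burst patterns for the firing states. These fixtures
#' exercise the classifier independently of the ODE model.
#'
#' The trace spans 7000 ms at 1 ms sampling with the first 2000 ms flat (the
#' transient that the analysis discards). Only `Vs` carries signal; the
#' other state columns are zero.
#'
#' @param label one of [pr_regime_labels()].
#' @param criteria a [pr_criteria()] object; the fixture is built relative
#'   to its thresholds.
#' @return A `pr_trace` data frame.
#' @examples
#' pr_classify(pr_fixture_trace("fast_bursting"))
#' @export
pr_fixture_trace <- function(label, criteria = pr_criteria()) {
  labels <- pr_regime_labels()
  if (!is.character(label) || length(label) != 1L || !label %in% labels)
    stop("unknown regime label '", paste(label, collapse = ","), "'",
         call. = FALSE)
  dt <- 1
  time <- seq(0, 7000, by = dt)
  n <- length(time)
  thr <- criteria$spike_threshold
  hi <- criteria$block_voltage_min
  t0 <- criteria$transient_discard
  post <- time >= t0
  v <- numeric(n)

  # triangular spike template: 0 -> 60 -> 0 over 4 ms, one upward crossing
  add_spike <- function(v, at) {
    i <- which.min(abs(time - at))
    idx <- i + (-1:2)
    ok <- idx >= 1 & idx <= n
    v[idx[ok]] <- pmax(v[idx[ok]], c(5, 60, 35, 5)[ok])
    v
  }
  add_burst <- function(v, at, nspk, isi = 10) {
    for (j in seq_len(nspk)) v <- add_spike(v, at + (j - 1) * isi)
    v
  }
  bumps <- function(amp = 8, period = 100, base = 2) {
    base + amp / 2 + amp / 2 * sin(2 * pi * time / period)
  }

  v <- switch(label,
    resting = v,
    depolarization_block = ifelse(post, hi + 5, 0) + 0,
    subthreshold_oscillation = ifelse(post, bumps(amp = 8, period = 200), 0),
    biphasic_oscillation = ifelse(
      post, (hi / 2 + 3) * sign(sin(2 * pi * time / 1000)), 0),
    periodic_spiking = {
      for (at in seq(t0 + 100, 6900, by = 100)) v <- add_spike(v, at)
      v
    },
    periodic_bursting = {
      for (at in seq(t0 + 100, 6800, by = 300)) v <- add_burst(v, at, 3)
      v
    },
    fast_bursting = {
      for (at in seq(t0 + 50, 6950, by = 80)) v <- add_burst(v, at, 2)
      v
    },
    period2_bursting = {
      at <- t0 + 100
      repeat {
        v <- add_burst(v, at, 3); at <- at + 200
        if (at > 6800) break
        v <- add_burst(v, at, 3); at <- at + 400
        if (at > 6800) break
      }
      v
    },
    burst_spike_alternating = {
      at <- t0 + 100
      single <- FALSE
      while (at < 6900) {
        v <- if (single) add_spike(v, at) else add_burst(v, at, 3)
        single <- !single
        at <- at + 200
      }
      v
    },
    mixed_mode_oscillation = {
      v <- ifelse(post, bumps(amp = 8, period = 100), 0)
      for (at in seq(t0 + 200, 6800, by = 400)) v <- add_spike(v, at)
      v
    },
    two_cycle_burst_subthreshold = {
      v <- ifelse(post, bumps(amp = 8, period = 100), 0)
      at <- t0 + 100
      repeat {
        v <- add_burst(v, at, 3); at <- at + 250
        if (at > 6800) break
        v <- add_burst(v, at, 3); at <- at + 500
        if (at > 6800) break
      }
      v
    })

  tr <- data.frame(time = time, Vs = v, Vd = 0, h = 0, n = 0, s = 0, c = 0,
                   q = 0, Ca = 0)
  structure(tr, class = c("pr_trace", "data.frame"), params = pr_params(),
            Ve = 0, dt = dt, duration = 7000, record_stride = 1L,
            diverged = FALSE, divergence_time = NA_real_,
            fixture_label = label)
}
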