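.scan_axes <- c("gc", "Vk", "Ve", "Id")

# map a scan-axis name onto a params override / field amplitude
.apply_axis <- function(pars, Ve, name, value) {
  switch(name,
    gc = list(pars = pr_modify(pars, gc = value), Ve = Ve),
    Vk = list(pars = pr_modify(pars, VK = value), Ve = Ve),
    Id = list(pars = pr_modify(pars, Id = value), Ve = Ve),
    Ve = list(pars = pars, Ve = value),
    stop("unknown scan axis '", name, "'; expected one of ",
         paste(.scan_axes, collapse = ", "), call. = FALSE))
}

# evaluate one grid point: fresh simulation from the common initial state
.scan_point <- function(pars, Ve, dt, duration, init, criteria) {
  tr <- pr_simulate(pars, Ve = Ve, dt = dt, duration = duration, init = init,
                    on_divergence = "truncate")
  diverged <- isTRUE(attr(tr, "diverged"))
  sp <- pr_spikes(tr, criteria, require_window = FALSE)
  regime <- pr_classify(tr, sp, criteria)
  Fhz <- if (regime == "diverged" && length(sp$times) == 0L) 0
         else pr_firing_rate(sp)
  list(F_hz = Fhz, regime = regime, diverged = diverged)
}

.make_scan <- function(df, axes, pars, criteria, dt, duration) {
  structure(df, class = c("pr_scan", "data.frame"), axes = axes,
            params = pars, criteria = criteria, dt = dt, duration = duration)
}

#' Sweep the DC field amplitude
#'
#' Simulates and classifies the neuron at each field amplitude of a grid,
#' holding everything else fixed. Following the weak-DC protocol used for
#' every sensitivity experiment, the injected currents default to Is = 0,
#' Id = 1 uA/cm2 (overriding whatever the parameter set carries); pass
#' `Is`/`Id` explicitly to change this. Every grid point starts from the
#' same initial state, so the result is independent of evaluation order.
#'
#' Points where the fixed-step integration diverges are recorded with regime
#' `"diverged"` and the firing rate measurable on the finite part of the
#' trace (zero when no post-transient spikes exist), rather than aborting
#' the sweep.
#'
#' @param pars a [pr_params()] object.
#' @param ve numeric grid of field amplitudes (mV).
#' @param Is,Id injected currents (uA/cm2) for the sweep.
#' @param dt,duration,init integration settings, see [pr_simulate()].
#' @param criteria a [pr_criteria()] object.
#' @return A `pr_scan`: data frame with columns `Ve`, `F_hz`, `regime`,
#'   `diverged`.
#' @examples
#' \donttest{
#' sc <- pr_sweep_field(pr_params(gc = 1), ve = c(-5, 0, 5))
#' sc
#' }
#' @export
pr_sweep_field <- function(pars = pr_params(), ve, Is = 0, Id = 1,
                           dt = 0.1, duration = 7000,
                           init = pr_initial_state(),
                           criteria = pr_criteria()) {
  stopifnot(length(ve) >= 1L, is.numeric(ve))
  pars <- pr_modify(pars, Is = Is, Id = Id)
  rows <- lapply(ve, function(a) .scan_point(pars, a, dt, duration, init,
                                             criteria))
  df <- data.frame(Ve = ve,
                   F_hz = vapply(rows, `[[`, numeric(1), "F_hz"),
                   regime = vapply(rows, `[[`, character(1), "regime"),
                   diverged = vapply(rows, `[[`, logical(1), "diverged"))
  .make_scan(df, "Ve", pars, criteria, dt, duration)
}

#' Sweep the injected dendritic current
#'
#' Firing rate and regime as a function of the dendritic drive Id (Is = 0),
#' the F-I curve of the model.
#'
#' @param pars a [pr_params()] object.
#' @param id numeric grid of dendritic currents (uA/cm2).
#' @param Ve field amplitude held fixed during the sweep (mV).
#' @inheritParams pr_sweep_field
#' @return A `pr_scan` with columns `Id`, `F_hz`, `regime`, `diverged`.
#' @export
pr_sweep_current <- function(pars = pr_params(), id, Ve = 0,
                             dt = 0.1, duration = 7000,
                             init = pr_initial_state(),
                             criteria = pr_criteria()) {
  stopifnot(length(id) >= 1L, is.numeric(id))
  pars <- pr_modify(pars, Is = 0)
  rows <- lapply(id, function(a) {
    .scan_point(pr_modify(pars, Id = a), Ve, dt, duration, init, criteria)
  })
  df <- data.frame(Id = id,
                   F_hz = vapply(rows, `[[`, numeric(1), "F_hz"),
                   regime = vapply(rows, `[[`, character(1), "regime"),
                   diverged = vapply(rows, `[[`, logical(1), "diverged"))
  .make_scan(df, "Id", pars, criteria, dt, duration)
}

#' Two-dimensional parameter-field scan
#'
#' Evaluates the full Cartesian product of two axis grids; axis names are
#' `"gc"`, `"Vk"`, `"Ve"` or `"Id"`. Rows are ordered with the first axis
#' outermost, both in the order given. Each point is an independent
#' simulation from the common initial state.
#'
#' @param pars base [pr_params()] object.
#' @param axis1,axis2 axis names.
#' @param grid1,grid2 numeric grids for the two axes.
#' @param Is,Id injected currents for the weak-DC baseline; `Id` is ignored
#'   when one of the axes is `"Id"`.
#' @inheritParams pr_sweep_field
#' @return A `pr_scan` with the two axis columns, `F_hz`, `regime`,
#'   `diverged`.
#' @export
pr_grid2d <- function(pars = pr_params(), axis1, grid1, axis2, grid2,
                      Is = 0, Id = 1, dt = 0.1, duration = 7000,
                      init = pr_initial_state(), criteria = pr_criteria()) {
  axis1 <- match.arg(axis1, .scan_axes)
  axis2 <- match.arg(axis2, .scan_axes)
  if (axis1 == axis2) stop("the two axes must differ", call. = FALSE)
  stopifnot(length(grid1) >= 1L, length(grid2) >= 1L)
  pars <- pr_modify(pars, Is = Is)
  if (axis1 != "Id" && axis2 != "Id") pars <- pr_modify(pars, Id = Id)
  grid <- expand.grid(a2 = grid2, a1 = grid1)[, c("a1", "a2")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s1 <- .apply_axis(pars, 0, axis1, grid$a1[i])
    s2 <- .apply_axis(s1$pars, s1$Ve, axis2, grid$a2[i])
    .scan_point(s2$pars, s2$Ve, dt, duration, init, criteria)
  })
  df <- data.frame(grid$a1, grid$a2,
                   F_hz = vapply(rows, `[[`, numeric(1), "F_hz"),
                   regime = vapply(rows, `[[`, character(1), "regime"),
                   diverged = vapply(rows, `[[`, logical(1), "diverged"))
  names(df)[1:2] <- c(axis1, axis2)
  .make_scan(df, c(axis1, axis2), pars, criteria, dt, duration)
}

#' Field-sensitivity interval of a scan
#'
#' The sensitivity range is the maximal contiguous run of field amplitudes
#' at which the neuron fires: grid points whose regime is one of the seven
#' spiking labels. Depolarization block, biphasic and subthreshold
#' oscillation, resting and diverged points are not sensitive. If several
#' maximal runs tie in length, the one with the smallest lower endpoint is
#' returned.
#'
#' @param scan a one-dimensional `pr_scan` over `Ve` (from
#'   [pr_sweep_field()]).
#' @return A `pr_interval`: list with `lower`, `upper` (mV) and `empty`.
#' @examples
#' \donttest{
#' sc <- pr_sweep_field(pr_params(gc = 1), ve = -20:15)
#' pr_sensitivity(sc)
#' }
#' @export
pr_sensitivity <- function(scan) {
  stopifnot(inherits(scan, "pr_scan"))
  if (!identical(attr(scan, "axes"), "Ve"))
    stop("sensitivity interval needs a one-dimensional sweep over Ve",
         call. = FALSE)
  sens <- scan$regime %in% .spiking_labels
  if (!any(sens))
    return(structure(list(lower = NA_real_, upper = NA_real_, empty = TRUE),
                     class = "pr_interval"))
  r <- rle(sens)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # ties: first (smallest lower end)
  structure(list(lower = scan$Ve[starts[best]], upper = scan$Ve[ends[best]],
                 empty = FALSE),
            class = "pr_interval")
}

#' Convenience: sweep the field and extract the sensitivity interval
#'
#' @param pars a [pr_params()] object.
#' @param ve field grid (mV); 1 mV integer steps reproduce the reference
#'   boundaries.
#' @param ... passed to [pr_sweep_field()].
#' @return A `pr_interval`.
#' @export
pr_sensitivity_range <- function(pars = pr_params(), ve = -50:50, ...) {
  pr_sensitivity(pr_sweep_field(pars, ve = ve, ...))
}

#' @export
print.pr_interval <- function(x, ...) {
  if (x$empty) cat("sensitivity interval: empty (no sustained firing)\n")
  else cat(sprintf("sensitivity interval: [%g, %g] mV\n", x$lower, x$upper))
  invisible(x)
}

#' @export
print.pr_scan <- function(x, ...) {
  axes <- attr(x, "axes")
  cat(sprintf("PR parameter scan over %s: %d points\n",
              paste(axes, collapse = " x "), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Plot a scan
#'
#' One-dimensional scans are drawn as the firing-rate curve against the
#' axis; two-dimensional scans as a firing-rate heat map.
#'
#' @param x a `pr_scan`.
#' @param ... passed to the underlying plotting function.
#' @return The scan, invisibly.
#' @export
plot.pr_scan <- function(x, ...) {
  axes <- attr(x, "axes")
  if (length(axes) == 1L) {
    graphics::plot(x[[axes]], x$F_hz, type = "b", xlab = axes,
                   ylab = "F (Hz)", ...)
  } else {
    g1 <- sort(unique(x[[axes[1]]]))
    g2 <- sort(unique(x[[axes[2]]]))
    z <- matrix(NA_real_, length(g1), length(g2))
    z[cbind(match(x[[axes[1]]], g1), match(x[[axes[2]]], g2))] <- x$F_hz
    graphics::image(g1, g2, z, xlab = axes[1], ylab = axes[2],
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
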