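#' Criteria for spike detection and regime classification
#'
#' The trace-analysis conventions. The somatic voltage convention of the
#' model puts subthreshold activity below about 15 mV and action-potential
#' overshoots far above, so 20 mV cleanly separates the two. The transient
#' discard leaves the first part of the run (settling after field onset) out
#' of every spike count; with the default 7 s run and 2 s discard the
#' analysis window is 5 s. Bursts have intra-burst inter-spike intervals of
#' a few ms and inter-burst intervals of hundreds of ms, so any cut between
#' (default 25 ms) groups them stably.
#'
#' @param spike_threshold somatic voltage (mV) whose upward crossing marks a
#'   spike.
#' @param transient_discard initial window (ms) excluded from analysis.
#' @param intra_burst_isi_max inter-spike interval (ms) at or below which
#'   consecutive spikes belong to one burst.
#' @param ibi_cv_max coefficient-of-variation tolerance for calling
#'   inter-burst intervals "regular".
#' @param fast_burst_ibi_max median inter-burst interval (ms) below which a
#'   regular bursting trace is labelled fast bursting.
#' @param resting_std_max standard deviation (mV) below which a spikeless
#'   trace counts as flat rather than oscillating.
#' @param block_voltage_min voltage (mV) above which a sustained spikeless
#'   plateau counts as depolarization block.
#' @param block_dwell_min minimum dwell (ms) above `block_voltage_min` for
#'   the block label.
#' @return An object of class `pr_criteria`.
#' @export
pr_criteria <- function(spike_threshold = 20, transient_discard = 2000,
                        intra_burst_isi_max = 25, ibi_cv_max = 0.2,
                        fast_burst_ibi_max = 100, resting_std_max = 0.5,
                        block_voltage_min = 25, block_dwell_min = 1000) {
  cr <- list(spike_threshold = spike_threshold,
             transient_discard = transient_discard,
             intra_burst_isi_max = intra_burst_isi_max,
             ibi_cv_max = ibi_cv_max,
             fast_burst_ibi_max = fast_burst_ibi_max,
             resting_std_max = resting_std_max,
             block_voltage_min = block_voltage_min,
             block_dwell_min = block_dwell_min)
  for (nm in names(cr))
    if (!is.numeric(cr[[nm]]) || length(cr[[nm]]) != 1L || !is.finite(cr[[nm]]))
      stop("criterion '", nm, "' must be a single finite number", call. = FALSE)
  if (cr$transient_discard < 0 || cr$intra_burst_isi_max <= 0 ||
      cr$ibi_cv_max <= 0 || cr$resting_std_max <= 0 ||
      cr$block_dwell_min <= 0 || cr$fast_burst_ibi_max <= 0)
    stop("criteria must be positive where applicable", call. = FALSE)
  structure(cr, class = "pr_criteria")
}

#' The firing-regime label set
#'
#' All labels the classifier can assign: four non-firing states (resting,
#' subthreshold oscillation, biphasic oscillation, depolarization block) and
#' seven firing states. A truncated, numerically diverged trace with no
#' analyzable window is reported as `"diverged"`, which is not part of this
#' set.
#'
#' @return Character vector of the eleven regime labels.
#' @export
pr_regime_labels <- function() {
  c("resting", "subthreshold_oscillation", "periodic_spiking",
    "periodic_bursting", "period2_bursting", "burst_spike_alternating",
    "mixed_mode_oscillation", "fast_bursting",
    "two_cycle_burst_subthreshold", "biphasic_oscillation",
    "depolarization_block")
}

.spiking_labels <- c("periodic_spiking", "periodic_bursting",
                     "period2_bursting", "burst_spike_alternating",
                     "mixed_mode_oscillation", "fast_bursting",
                     "two_cycle_burst_subthreshold")

#' Detect somatic spikes in a trace
#'
#' A spike is an upward crossing of the somatic voltage through
#' `spike_threshold` after the transient discard; the crossing time is
#' interpolated linearly between samples. One spike per crossing.
#'
#' @param trace a `pr_trace` (or any data frame with `time` and `Vs`).
#' @param criteria a [pr_criteria()] object.
#' @param require_window error if the trace does not cover at least
#'   `transient_discard` + 1000 ms (default). Sweeps over diverged,
#'   truncated traces set this to `FALSE` and count spikes on whatever
#'   window remains.
#' @return A `pr_spikes` object: list with `times` (ms), `window`
#'   (start, end of the analysis window, ms) and `threshold`.
#' @examples
#' tr <- pr_fixture_trace("periodic_spiking")
#' pr_spikes(tr)
#' @export
pr_spikes <- function(trace, criteria = pr_criteria(),
                      require_window = TRUE) {
  stopifnot(is.data.frame(trace), all(c("time", "Vs") %in% names(trace)))
  stopifnot(inherits(criteria, "pr_criteria"))
  t_end <- max(trace$time)
  if (require_window && t_end < criteria$transient_discard + 1000)
    stop("trace too short: need at least transient_discard + 1000 ms",
         call. = FALSE)
  keep <- trace$time >= criteria$transient_discard
  tt <- trace$time[keep]
  v <- trace$Vs[keep]
  times <- numeric(0)
  if (length(v) >= 2L) {
    thr <- criteria$spike_threshold
    i <- which(v[-length(v)] < thr & v[-1L] >= thr)
    if (length(i))
      times <- tt[i] + (tt[i + 1L] - tt[i]) * (thr - v[i]) / (v[i + 1L] - v[i])
  }
  win <- c(start = criteria$transient_discard, end = t_end)
  structure(list(times = times, window = win,
                 threshold = criteria$spike_threshold),
            class = "pr_spikes")
}

#' @export
print.pr_spikes <- function(x, ...) {
  cat(sprintf("%d somatic spikes in [%g, %g] ms (threshold %g mV); F = %.3f Hz\n",
              length(x$times), x$window[1], x$window[2], x$threshold,
              pr_firing_rate(x)))
  invisible(x)
}

#' Mean firing rate
#'
#' Spike count divided by the analysis-window length, in Hz. An empty train
#' has rate 0 regardless of the window.
#'
#' @param spikes a `pr_spikes` object.
#' @return Firing rate in Hz.
#' @examples
#' pr_firing_rate(pr_spikes(pr_fixture_trace("periodic_spiking")))
#' @export
pr_firing_rate <- function(spikes) {
  stopifnot(inherits(spikes, "pr_spikes"))
  if (length(spikes$times) == 0L) return(0)
  len <- unname(diff(spikes$window))
  if (len <= 0) stop("zero-length analysis window", call. = FALSE)
  1000 * length(spikes$times) / len
}

# group spike times into bursts: consecutive spikes closer than
# intra_burst_isi_max belong together. Returns list(starts, sizes).
.group_bursts <- function(times, isi_max) {
  if (length(times) == 0L) return(list(starts = numeric(0), sizes = integer(0)))
  brk <- c(TRUE, diff(times) > isi_max)
  id <- cumsum(brk)
  list(starts = as.numeric(tapply(times, id, min)),
       sizes = as.integer(tabulate(id)))
}

# local maxima of v below `below` with prominence >= prom, where prominence
# is measured against the lower of the two flanking minima
.subthreshold_peaks <- function(v, below, prom = 1) {
  n <- length(v)
  if (n < 3L) return(0L)
  is_pk <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]
  pk <- which(is_pk) + 1L
  pk <- pk[v[pk] < below]
  if (!length(pk)) return(0L)
  count <- 0L
  bounds <- c(1L, pk, n)
  for (j in seq_along(pk)) {
    lo1 <- min(v[bounds[j]:pk[j]])
    lo2 <- min(v[pk[j]:bounds[j + 2L]])
    if (v[pk[j]] - max(lo1, lo2) >= prom) count <- count + 1L
  }
  count
}

#' Classify the firing regime of a trace
#'
#' Assigns exactly one regime label to a simulated (or synthetic) trace,
#' using the post-transient somatic voltage and the detected spike train.
#'
#' Spikeless traces: a sustained plateau above `block_voltage_min` is
#' depolarization block when essentially flat (standard deviation below
#' `resting_std_max`) and subthreshold oscillation when it visibly
#' oscillates; away from a plateau, a flat trace is resting, two-sided
#' excursions beyond half the block voltage in both directions are biphasic
#' oscillation, and anything else that oscillates is subthreshold
#' oscillation.
#'
#' Spiking traces are grouped into bursts by `intra_burst_isi_max`. All
#' singleton groups give periodic spiking, or mixed-mode oscillation when
#' subthreshold oscillation cycles are interleaved between the spikes.
#' Alternating singleton/multi-spike groups give the burst-spike alternating
#' label. Multi-spike groups with regular inter-burst intervals are periodic
#' bursting (fast bursting below `fast_burst_ibi_max`); inter-burst
#' intervals alternating between two values give period-2 bursting, or the
#' two-cycle-with-subthreshold label when oscillation cycles appear between
#' the bursts.
#'
#' @param trace a `pr_trace` or compatible data frame.
#' @param spikes optional precomputed [pr_spikes()]; detected if `NULL`.
#' @param criteria a [pr_criteria()] object.
#' @return A single regime label (see [pr_regime_labels()]), or
#'   `"diverged"` for a truncated trace with no analyzable window.
#' @examples
#' pr_classify(pr_fixture_trace("periodic_bursting"))
#' @export
pr_classify <- function(trace, spikes = NULL, criteria = pr_criteria()) {
  stopifnot(inherits(criteria, "pr_criteria"))
  keep <- trace$time >= criteria$transient_discard
  if (sum(keep) < 10L) return("diverged")
  v <- trace$Vs[keep]
  tt <- trace$time[keep]
  if (is.null(spikes)) spikes <- pr_spikes(trace, criteria,
                                           require_window = FALSE)
  st <- spikes$times
  thr <- criteria$spike_threshold

  if (length(st) == 0L) {
    # plateau test: longest contiguous dwell above block_voltage_min
    hi <- v > criteria$block_voltage_min
    if (any(hi)) {
      r <- rle(hi)
      dt_samp <- if (length(tt) > 1L) stats::median(diff(tt)) else 0
      longest <- max(r$lengths[r$values]) * dt_samp
      if (longest >= criteria$block_dwell_min) {
        return(if (stats::sd(v) < criteria$resting_std_max)
          "depolarization_block" else "subthreshold_oscillation")
      }
    }
    if (stats::sd(v) < criteria$resting_std_max) return("resting")
    half <- criteria$block_voltage_min / 2
    if (max(v) > half && min(v) < -half) return("biphasic_oscillation")
    return("subthreshold_oscillation")
  }

  g <- .group_bursts(st, criteria$intra_burst_isi_max)
  sizes <- g$sizes
  k <- length(sizes)
  multi <- sizes > 1L

  if (!any(multi)) {
    # singleton spikes: mixed-mode needs repeated subthreshold cycles per
    # inter-spike gap; a single after-depolarization bump does not count
    npk <- .subthreshold_peaks(v, thr - 2, prom = 1)
    if (npk >= 2L * length(st)) return("mixed_mode_oscillation")
    return("periodic_spiking")
  }

  if (any(!multi) && k >= 4L) {
    alternation <- mean(multi[-1L] != multi[-k])
    if (alternation >= 0.6 && mean(multi) >= 0.25 && mean(!multi) >= 0.25)
      return("burst_spike_alternating")
  }

  ibi <- diff(g$starts)
  if (k < 3L) return("periodic_bursting")

  # period-2 test: alternating inter-burst intervals
  a <- ibi[seq(1L, length(ibi), by = 2L)]
  b <- ibi[seq(2L, length(ibi), by = 2L)]
  if (length(a) >= 2L && length(b) >= 2L) {
    sep <- abs(mean(a) - mean(b)) > 0.25 * mean(ibi)
    tight <- stats::sd(a) / mean(a) <= criteria$ibi_cv_max &&
      stats::sd(b) / mean(b) <= criteria$ibi_cv_max
    if (sep && tight) {
      gap_peaks <- .subthreshold_peaks(v, thr - 2, prom = 2)
      if (gap_peaks >= k) return("two_cycle_burst_subthreshold")
      return("period2_bursting")
    }
  }

  if (stats::median(ibi) < criteria$fast_burst_ibi_max) return("fast_bursting")
  return("periodic_bursting")
}
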