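#' Opening and closing rates of the gating variables
#'
#' Forward (alpha) and backward (beta) rate functions of the six
#' Hodgkin-Huxley-style gates of the PR model, in 1/ms. Gates m, h, n are
#' somatic and take the somatic voltage; s and c are dendritic and take the
#' dendritic voltage; q is calcium-gated and takes the calcium variable.
#'
#' The ratio forms x/(exp(x/k) - 1) appearing in alpha_m, beta_m, alpha_n and
#' beta_s have removable singularities (at Vs = 13.1, 40.1, 35.1 and
#' Vd = 51.1 respectively); within 1e-7 mV of the singular voltage they are
#' evaluated by their analytic limit k. The c gate is piecewise at
#' Vd = 50 mV, with beta_c identically zero on the upper branch.
#'
#' @param gate one of `"m"`, `"h"`, `"n"`, `"s"`, `"c"`, `"q"`.
#' @param v membrane potential in mV (gates m, h, n, s, c) or the calcium
#'   variable (gate q). Vectorised.
#' @return A list with numeric components `alpha` and `beta` (1/ms).
#' @examples
#' pr_rates("h", 17)$alpha   # 0.128: the exponent vanishes
#' pr_rates("n", 35.1)       # evaluated at the removable singularity
#' @export
pr_rates <- function(gate, v) {
  if (!is.character(gate) || length(gate) != 1L ||
      !gate %in% c("m", "h", "n", "s", "c", "q"))
    stop("unknown gate '", paste(gate, collapse = ","),
         "'; expected one of m, h, n, s, c, q", call. = FALSE)
  if (!is.numeric(v) || !all(is.finite(v)))
    stop("voltage/concentration input must be finite numeric", call. = FALSE)
  switch(gate,
    m = list(alpha = 0.32 * .expm1_ratio(13.1 - v, 4),
             beta  = 0.28 * .expm1_ratio(v - 40.1, 5)),
    h = list(alpha = 0.128 * exp((17 - v) / 18),
             beta  = 4 / (1 + exp((40 - v) / 5))),
    n = list(alpha = 0.016 * .expm1_ratio(35.1 - v, 5),
             beta  = 0.25 * exp(0.5 - 0.025 * v)),
    s = list(alpha = 1.6 / (1 + exp(-0.072 * (v - 65))),
             beta  = 0.02 * .expm1_ratio(v - 51.1, 5)),
    c = {
      a_low <- exp((v - 10) / 11 - (v - 6.5) / 27) / 18.975
      b_low <- 2 * exp((6.5 - v) / 27) - a_low
      a_hi  <- 2 * exp((6.5 - v) / 27)
      low <- v <= 50
      list(alpha = ifelse(low, a_low, a_hi),
           beta  = ifelse(low, b_low, 0))
    },
    q = {
      if (any(v < 0))
        stop("calcium variable must be non-negative", call. = FALSE)
      list(alpha = pmin(0.00002 * v, 0.01),
           beta  = rep_len(0.001, length(v)))
    })
}

# x / (exp(x/k) - 1), limit k at x = 0; vectorised
.expm1_ratio <- function(x, k) {
  out <- x / expm1(x / k)
  out[abs(x) < 1e-7] <- k
  out
}

#' Steady state and time constant of a gate
#'
#' For first-order kinetics with rates `alpha`, `beta`, the steady state is
#' alpha/(alpha+beta) and the time constant 1/(alpha+beta) ms.
#'
#' @param gate,v as in [pr_rates()].
#' @return A list with components `inf` and `tau`.
#' @examples
#' pr_gate_inf("m", 0)$inf   # instantaneous sodium activation at 0 mV
#' @export
pr_gate_inf <- function(gate, v) {
  r <- pr_rates(gate, v)
  tot <- r$alpha + r$beta
  list(inf = r$alpha / tot, tau = 1 / tot)
}

#' Time derivative of a gating variable
#'
#' First-order relaxation dx/dt = alpha (1 - x) - beta x, equivalently
#' (x_inf - x) / tau.
#'
#' @param alpha,beta rates in 1/ms, non-negative, not both zero.
#' @param x current gate value.
#' @return dx/dt in 1/ms.
#' @examples
#' pr_gate_deriv(0.3, 0.7, 0.1)  # 0.2
#' @export
pr_gate_deriv <- function(alpha, beta, x) {
  if (any(alpha < 0) || any(beta < 0))
    stop("rates must be non-negative", call. = FALSE)
  if (any(alpha + beta == 0))
    stop("singular kinetics: alpha + beta = 0", call. = FALSE)
  alpha * (1 - x) - beta * x
}

#' Calcium saturation of the fast K(Ca) current
#'
#' The fast calcium-activated potassium current scales with
#' chi(Ca) = min(Ca/250, 1), a saturating, non-decreasing function of the
#' calcium variable bounded by 1.
#'
#' @param ca calcium variable, non-negative. Vectorised.
#' @return Saturation factor in \[0, 1\].
#' @examples
#' pr_chi(c(0, 125, 500))  # 0, 0.5, 1
#' @export
pr_chi <- function(ca) {
  if (!is.numeric(ca) || any(!is.finite(ca)) || any(ca < 0))
    stop("calcium variable must be finite and non-negative", call. = FALSE)
  pmin(ca / 250, 1)
}
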