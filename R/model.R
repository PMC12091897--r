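#' Ionic and coupling currents at a given state
#'
#' Evaluates every membrane current of the two-compartment model, in uA/cm2.
#' A constant induced-field amplitude `Ve` (mV) is added to the membrane
#' potential inside each ionic driving force: somatic currents see Vs + Ve,
#' dendritic currents Vd + Ve. The electrotonic coupling current depends only
#' on the difference Vd - Vs and is therefore unaffected by the field, as are
#' the injected currents.
#'
#' Gating factors (including the instantaneous sodium activation m) are
#' evaluated at the unshifted state voltages; see the package vignette for
#' why the field must not shift the kinetics.
#'
#' @param state named numeric state vector (see [pr_initial_state()]).
#' @param pars a [pr_params()] object.
#' @param Ve DC induced-field amplitude (mV), default 0.
#' @return Named numeric vector with components `IsLeak`, `INa`, `IKDR`
#'   (somatic), `IdLeak`, `ICa`, `IKAHP`, `IKC` (dendritic), and the coupling
#'   currents `Icoup_soma` = gc (Vd - Vs) / p and
#'   `Icoup_dend` = gc (Vs - Vd) / (1 - p).
#' @examples
#' pr_currents(pr_initial_state(), pr_params())
#' @export
pr_currents <- function(state, pars = pr_params(), Ve = 0) {
  stopifnot(inherits(pars, "pr_params"))
  state <- .check_state(state)
  if (!is.numeric(Ve) || length(Ve) != 1L || !is.finite(Ve))
    stop("'Ve' must be a single finite number", call. = FALSE)
  vs <- state[["Vs"]] + Ve
  vd <- state[["Vd"]] + Ve
  minf <- pr_gate_inf("m", state[["Vs"]])$inf
  c(IsLeak = pars$gL * (vs - pars$VL),
    INa    = pars$gNa * minf^2 * state[["h"]] * (vs - pars$VNa),
    IKDR   = pars$gKDR * state[["n"]] * (vs - pars$VK),
    IdLeak = pars$gL * (vd - pars$VL),
    ICa    = pars$gCa * state[["s"]]^2 * (vd - pars$VCa),
    IKAHP  = pars$gKAHP * state[["q"]] * (vd - pars$VK),
    IKC    = pars$gKC * state[["c"]] * pr_chi(state[["Ca"]]) * (vd - pars$VK),
    Icoup_soma = pars$gc * (state[["Vd"]] - state[["Vs"]]) / pars$p,
    Icoup_dend = pars$gc * (state[["Vs"]] - state[["Vd"]]) / (1 - pars$p))
}

#' Time derivative of the full state
#'
#' The right-hand side of the eight-dimensional PR system under a DC induced
#' field: membrane equations for Vs and Vd (capacitance Cm), first-order
#' kinetics for the gates h, n, s, c, q, and calcium dynamics
#' dCa/dt = -0.13 ICa - 0.075 Ca. With `Ve = 0` this is exactly the standard
#' PR model. This is the plain-R reference implementation; the integrator
#' uses an identical compiled version which is cross-checked against this one
#' in the test suite.
#'
#' @inheritParams pr_currents
#' @return Named numeric vector of length 8: the time derivative in
#'   mV/ms (voltages), 1/ms (gates) and 1/ms (calcium).
#' @examples
#' pr_deriv(pr_initial_state(), pr_params())
#' @export
pr_deriv <- function(state, pars = pr_params(), Ve = 0) {
  state <- .check_state(state)
  I <- pr_currents(state, pars, Ve)
  rh <- pr_rates("h", state[["Vs"]])
  rn <- pr_rates("n", state[["Vs"]])
  rs <- pr_rates("s", state[["Vd"]])
  rc <- pr_rates("c", state[["Vd"]])
  rq <- pr_rates("q", state[["Ca"]])
  c(Vs = (-I[["IsLeak"]] - I[["INa"]] - I[["IKDR"]] + I[["Icoup_soma"]] +
            pars$Is / pars$p) / pars$Cm,
    Vd = (-I[["IdLeak"]] - I[["ICa"]] - I[["IKAHP"]] - I[["IKC"]] +
            I[["Icoup_dend"]] + pars$Id / (1 - pars$p)) / pars$Cm,
    h  = pr_gate_deriv(rh$alpha, rh$beta, state[["h"]]),
    n  = pr_gate_deriv(rn$alpha, rn$beta, state[["n"]]),
    s  = pr_gate_deriv(rs$alpha, rs$beta, state[["s"]]),
    c  = pr_gate_deriv(rc$alpha, rc$beta, state[["c"]]),
    q  = pr_gate_deriv(rq$alpha, rq$beta, state[["q"]]),
    Ca = -0.13 * I[["ICa"]] - 0.075 * state[["Ca"]])
}
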