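#' Biophysical parameters of the two-compartment CA3 neuron
#'
#' Constructs the full parameter set of the Pinsky-Rinzel (PR) two-compartment
#' model of a CA3 pyramidal neuron. Defaults are the standard published values
#' of the reduced model: conductances in mS/cm2, reversal potentials in mV,
#' capacitance in uF/cm2 and injected currents in uA/cm2. Voltages use the
#' model's shifted convention in which the leak reversal sits at 0 mV and the
#' sodium reversal at +120 mV.
#'
#' Two parameters are the usual knobs of interest: the electrotonic coupling
#' conductance `gc` linking soma and dendrite (scaled by the somatic area
#' fraction `p` on the soma side and `1 - p` on the dendrite side), and the
#' potassium reversal potential `VK` shared by the delayed-rectifier, the
#' fast Ca-activated and the slow afterhyperpolarization potassium currents.
#'
#' `Vsyn` is carried for completeness but enters no equation: synaptic input
#' is outside the scope of this package.
#'
#' @param p somatic membrane-area fraction (dimensionless, in (0, 1)).
#' @param Cm membrane capacitance (uF/cm2).
#' @param gc soma-dendrite coupling conductance (mS/cm2).
#' @param gL leak conductance (mS/cm2).
#' @param gNa fast sodium conductance, soma (mS/cm2).
#' @param gKDR delayed-rectifier potassium conductance, soma (mS/cm2).
#' @param gCa calcium conductance, dendrite (mS/cm2).
#' @param gKAHP afterhyperpolarization potassium conductance, dendrite (mS/cm2).
#' @param gKC fast Ca-activated potassium conductance, dendrite (mS/cm2).
#' @param VNa,VCa,VK,VL reversal potentials (mV).
#' @param Vsyn synaptic reversal potential (mV); stored, never used.
#' @param Is somatic injected current (uA/cm2), divided by `p` in the ODE.
#' @param Id dendritic injected current (uA/cm2), divided by `1 - p`.
#' @return An object of class `pr_params`: a named list of numeric scalars.
#' @examples
#' pars <- pr_params(gc = 1, VK = -15)
#' pars$gc
#' @export
pr_params <- function(p = 0.5, Cm = 3.0, gc = 2.1, gL = 0.1, gNa = 30,
                      gKDR = 15, gCa = 10, gKAHP = 0.8, gKC = 15,
                      VNa = 120, VCa = 140, VK = -15, VL = 0, Vsyn = 60,
                      Is = 0, Id = 0.7) {
  pars <- list(p = p, Cm = Cm, gc = gc, gL = gL, gNa = gNa, gKDR = gKDR,
               gCa = gCa, gKAHP = gKAHP, gKC = gKC, VNa = VNa, VCa = VCa,
               VK = VK, VL = VL, Vsyn = Vsyn, Is = Is, Id = Id)
  for (nm in names(pars)) {
    v <- pars[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (pars$p <= 0 || pars$p >= 1)
    stop("'p' must lie strictly between 0 and 1", call. = FALSE)
  if (pars$Cm <= 0) stop("'Cm' must be positive", call. = FALSE)
  for (nm in c("gc", "gL", "gNa", "gKDR", "gCa", "gKAHP", "gKC"))
    if (pars[[nm]] < 0)
      stop("conductance '", nm, "' must be non-negative", call. = FALSE)
  structure(pars, class = "pr_params")
}

#' Modify an existing parameter set
#'
#' @param pars a `pr_params` object.
#' @param ... named replacements, e.g. `gc = 1`, `VK = -38.56`.
#' @return A validated `pr_params` object.
#' @examples
#' pr_modify(pr_params(), gc = 10, Id = 1)
#' @export
pr_modify <- function(pars, ...) {
  stopifnot(inherits(pars, "pr_params"))
  upd <- list(...)
  bad <- setdiff(names(upd), names(unclass(pars)))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  merged <- utils::modifyList(unclass(pars), upd)
  do.call(pr_params, merged)
}

# fixed layout handed to the compiled integrator
.par_order <- c("p", "Cm", "gc", "gL", "gNa", "gKDR", "gCa", "gKAHP", "gKC",
                "VNa", "VCa", "VK", "VL", "Is", "Id")

.par_vector <- function(pars) {
  unlist(unclass(pars)[.par_order], use.names = TRUE)
}

#' @export
print.pr_params <- function(x, ...) {
  cat("Pinsky-Rinzel parameters\n")
  v <- unlist(unclass(x))
  cat(paste0("  ", format(names(v), width = 6), " = ", format(v)), sep = "\n")
  invisible(x)
}

.state_names <- c("Vs", "Vd", "h", "n", "s", "c", "q", "Ca")

#' Initial state of the model
#'
#' The eight-dimensional state holds the somatic and dendritic membrane
#' potentials (mV), the five gating variables h, n, s, c, q (dimensionless,
#' in \[0, 1\]) and the intracellular calcium variable Ca (dimensionless,
#' non-negative). Sodium activation m is instantaneous and is not part of
#' the state. The default vector is a point on the model's attractor used as
#' the common starting state for every simulation and sweep.
#'
#' @return A named numeric vector of length 8.
#' @examples
#' pr_initial_state()
#' @export
pr_initial_state <- function() {
  c(Vs = 8.22594127701169, Vd = 11.2873513664516, h = 0.657103951268693,
    n = 0.0575840069166615, s = 0.0586561971436294, c = 0.0328693668351334,
    q = 0.461747452058436, Ca = 46.9558464653944)
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 8L)
    stop("state must be a numeric vector of length 8 (Vs, Vd, h, n, s, c, q, Ca)",
         call. = FALSE)
  if (!all(is.finite(state)))
    stop("state contains non-finite values", call. = FALSE)
  if (is.null(names(state))) names(state) <- .state_names
  state[.state_names]
}
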