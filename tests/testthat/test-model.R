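test_that("parameter constructor validates and defaults correctly", {
  p <- pr_params()
  expect_s3_class(p, "pr_params")
  expect_equal(p$Cm, 3.0)
  expect_equal(p$VK, -15)
  expect_equal(p$Id, 0.7)
  expect_error(pr_params(p = 0), "p")
  expect_error(pr_params(Cm = -1), "Cm")
  expect_error(pr_params(gNa = -5), "gNa")
  expect_error(pr_params(gc = NA), "gc")
  expect_error(pr_modify(pr_params(), bogus = 1), "bogus")
  expect_equal(pr_modify(p, gc = 1, VK = -38.56)$gc, 1)
})

test_that("rate functions match closed forms and printed constants", {
  # alpha_h at 17 mV: the exponent vanishes
  expect_equal(pr_rates("h", 17)$alpha, 0.128)
  # beta_h at 40 mV: 4 / (1 + e^0)
  expect_equal(pr_rates("h", 40)$beta, 2)
  # q saturates at 0.01; beta_q is the constant 0.001
  expect_equal(pr_rates("q", 1000)$alpha, 0.01)
  expect_equal(pr_rates("q", 100)$alpha, 0.002)
  expect_equal(pr_rates("q", 7)$beta, 0.001)
  # frozen high-precision evaluations of the ratio forms (30-digit oracle)
  expect_equal(pr_rates("m", 0)$alpha, 0.164758984791549112, tolerance = 1e-15)
  expect_equal(pr_rates("m", 0)$beta, 11.2316932056161110, tolerance = 1e-15)
  expect_equal(pr_rates("n", 10)$alpha, 0.00267001209264086703,
               tolerance = 1e-15)
  expect_equal(pr_rates("s", 0)$beta, 1.02203723720830741, tolerance = 1e-15)
  expect_equal(pr_rates("c", 20)$alpha, 0.0793385282332589597,
               tolerance = 1e-15)
  expect_equal(pr_rates("c", 20)$beta, 1.13372279119200789, tolerance = 1e-15)
  expect_error(pr_rates("z", 0), "unknown gate")
  expect_error(pr_rates("m", NaN), "finite")
  expect_error(pr_rates("q", -1), "non-negative")
})

test_that("removable singularities evaluate to their analytic limits", {
  # limits: alpha_m -> 0.32*4 at 13.1; beta_m -> 0.28*5 at 40.1;
  # alpha_n -> 0.016*5 at 35.1; beta_s -> 0.02*5 at 51.1
  expect_equal(pr_rates("m", 13.1)$alpha, 1.28)
  expect_equal(pr_rates("m", 40.1)$beta, 1.4)
  expect_equal(pr_rates("n", 35.1)$alpha, 0.08)
  expect_equal(pr_rates("s", 51.1)$beta, 0.1)
  # continuity: values 1e-6 mV away differ from the limit only marginally
  for (eps in c(-1e-6, 1e-6)) {
    expect_equal(pr_rates("m", 13.1 + eps)$alpha, 1.28, tolerance = 1e-6)
    expect_equal(pr_rates("m", 40.1 + eps)$beta, 1.4, tolerance = 1e-6)
    expect_equal(pr_rates("n", 35.1 + eps)$alpha, 0.08, tolerance = 1e-6)
    expect_equal(pr_rates("s", 51.1 + eps)$beta, 0.1, tolerance = 1e-6)
  }
  # the c gate is continuous across its piecewise boundary at 50 mV
  lo <- pr_rates("c", 50 - 1e-9)
  hi <- pr_rates("c", 50 + 1e-9)
  expect_equal(lo$alpha + lo$beta, hi$alpha + hi$beta, tolerance = 1e-6)
})

test_that("gate kinetics and the calcium saturation behave as defined", {
  expect_equal(pr_gate_deriv(1, 1, 0.5), 0)      # steady state
  expect_equal(pr_gate_deriv(1, 0, 0), 1)        # pure activation
  expect_equal(pr_gate_deriv(0.3, 0.7, 0.1), 0.2)
  expect_error(pr_gate_deriv(0, 0, 0.5), "singular")
  expect_error(pr_gate_deriv(-1, 1, 0.5), "non-negative")
  expect_equal(pr_chi(c(0, 125, 250, 500)), c(0, 0.5, 1, 1))
  expect_error(pr_chi(-1), "non-negative")
  ca <- seq(0, 600, by = 10)
  expect_true(all(diff(pr_chi(ca)) >= 0))          # nondecreasing
  expect_true(all(pr_chi(ca) >= 0 & pr_chi(ca) <= 1))
})

test_that("currents vanish with their driving force or gate", {
  p <- pr_params()
  st <- pr_initial_state()
  # zero leak driving force at the soma
  st0 <- st; st0["Vs"] <- p$VL
  expect_equal(unname(pr_currents(st0, p)["IsLeak"]), 0)
  # closed delayed-rectifier gate
  stn <- st; stn["n"] <- 0
  expect_equal(unname(pr_currents(stn, p)["IKDR"]), 0)
  # calcium current at its reversal
  stc <- st; stc["Vd"] <- p$VCa
  expect_equal(unname(pr_currents(stc, p)["ICa"]), 0)
  # coupling currents are equal and opposite per unit area fraction
  I <- pr_currents(st, p)
  expect_equal(unname(I["Icoup_soma"] * p$p), -unname(I["Icoup_dend"] * (1 - p$p)))
})

test_that("the field shifts driving forces linearly and spares the coupling", {
  p <- pr_params(gc = 2.1)
  for (st in random_states(5, seed = 7)) {
    I0 <- pr_currents(st, p, Ve = 0)
    I5 <- pr_currents(st, p, Ve = 5)
    # each ohmic current gains exactly conductance * gating * Ve
    expect_equal(unname(I5["IsLeak"] - I0["IsLeak"]), p$gL * 5)
    expect_equal(unname(I5["IKDR"] - I0["IKDR"]), p$gKDR * st[["n"]] * 5)
    expect_equal(unname(I5["IdLeak"] - I0["IdLeak"]), p$gL * 5)
    expect_equal(unname(I5["ICa"] - I0["ICa"]), p$gCa * st[["s"]]^2 * 5)
    expect_equal(unname(I5["IKAHP"] - I0["IKAHP"]),
                 p$gKAHP * st[["q"]] * 5)
    # coupling depends only on the voltage difference: unchanged
    expect_equal(unname(I5["Icoup_soma"]), unname(I0["Icoup_soma"]))
    expect_equal(unname(I5["Icoup_dend"]), unname(I0["Icoup_dend"]))
  }
})

test_that("field-free derivative matches an independent oracle on random states", {
  p <- pr_params(gc = 1.4, VK = -22, Is = 0.3, Id = 1)
  for (st in random_states(20)) {
    expect_equal(unname(pr_deriv(st, p, Ve = 0)), pr_oracle_deriv(st, p),
                 tolerance = 1e-12)
  }
})

test_that("compiled and reference derivatives agree to rounding error", {
  p <- pr_params(gc = 3, VK = -40, Is = 0.2, Id = 0.9)
  pv <- prfield:::.par_vector(p)
  for (st in random_states(20, seed = 99)) {
    for (ve in c(-15, 0, 8)) {
      expect_equal(unname(pr_deriv(st, p, Ve = ve)),
                   as.numeric(prfield:::pr_deriv_cpp(unname(st), pv, ve)),
                   tolerance = 1e-12)
    }
  }
})

test_that("inward calcium current is a calcium source below its reversal", {
  p <- pr_params()
  for (st in random_states(10, seed = 3)) {
    st["s"] <- max(st[["s"]], 0.05)
    for (ve in c(-10, 0, 10)) {
      if (st[["Vd"]] + ve < p$VCa) {
        I <- pr_currents(st, p, Ve = ve)
        expect_lt(unname(I["ICa"]), 0)
        d <- pr_deriv(st, p, Ve = ve)
        expect_gte(-0.13 * unname(I["ICa"]), 0)
      }
    }
  }
})

test_that("initial state is the printed attractor point", {
  st <- pr_initial_state()
  expect_equal(unname(st["Vs"]), 8.22594127701169)
  expect_equal(unname(st["Ca"]), 46.9558464653944)
  expect_true(all(st[c("h", "n", "s", "c", "q")] >= 0 &
                    st[c("h", "n", "s", "c", "q")] <= 1))
})
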