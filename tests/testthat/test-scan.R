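# scans here use shortened runs (3200 ms: 2 s transient + 1.2 s window) to
# keep the suite fast; the acceptance tests use the full 7 s protocol.

test_that("a singleton field grid equals a direct simulate-and-classify", {
  p <- pr_params(gc = 2.1, VK = -15)
  sc <- pr_sweep_field(p, ve = 0, duration = 3200)
  expect_equal(nrow(sc), 1L)
  tr <- pr_simulate(pr_modify(p, Is = 0, Id = 1), Ve = 0, duration = 3200)
  sp <- pr_spikes(tr)
  expect_equal(sc$F_hz, pr_firing_rate(sp))
  expect_identical(sc$regime, pr_classify(tr, sp))
})

test_that("duplicate grid values give identical results (determinism)", {
  sc <- pr_sweep_field(pr_params(gc = 1), ve = c(0, 5, 0), duration = 3200)
  expect_equal(sc$F_hz[1], sc$F_hz[3])
  expect_identical(sc$regime[1], sc$regime[3])
})

test_that("2D grid rows match the corresponding 1D sweeps, in given order", {
  p <- pr_params(VK = -15)
  g2 <- pr_grid2d(p, "gc", c(2.1, 1), "Ve", c(3, -2), duration = 3200)
  expect_equal(nrow(g2), 4L)
  expect_equal(g2$gc, c(2.1, 2.1, 1, 1))
  expect_equal(g2$Ve, c(3, -2, 3, -2))
  for (gc in c(1, 2.1)) {
    s1 <- pr_sweep_field(pr_modify(p, gc = gc), ve = c(3, -2),
                         duration = 3200)
    rows <- g2[g2$gc == gc, ]
    expect_equal(rows$F_hz, s1$F_hz)
    expect_identical(rows$regime, s1$regime)
  }
})

test_that("grid evaluation is independent of axis order", {
  p <- pr_params()
  a <- pr_grid2d(p, "gc", c(1, 2.1), "Ve", c(0, 4), duration = 3200)
  b <- pr_grid2d(p, "Ve", c(0, 4), "gc", c(1, 2.1), duration = 3200)
  key_a <- paste(a$gc, a$Ve); key_b <- paste(b$gc, b$Ve)
  expect_setequal(key_a, key_b)
  expect_equal(a$F_hz[order(key_a)], b$F_hz[order(key_b)])
  expect_identical(a$regime[order(key_a)], b$regime[order(key_b)])
})

test_that("axis names are validated", {
  expect_error(pr_grid2d(pr_params(), "gc", 1, "gc", 2), "differ")
  expect_error(pr_grid2d(pr_params(), "foo", 1, "Ve", 0))
  expect_error(prfield:::.apply_axis(pr_params(), 0, "nope", 1), "axis")
})

test_that("sensitivity interval selects the maximal contiguous firing run", {
  # all-resting scan: empty interval
  iv <- pr_sensitivity(fake_scan(-3:3, rep("resting", 7)))
  expect_true(iv$empty)
  # single run with non-sensitive flanks: endpoints bracket it exactly
  lab <- c("depolarization_block", "fast_bursting", "periodic_bursting",
           "periodic_spiking", "resting")
  iv <- pr_sensitivity(fake_scan(-2:2, lab))
  expect_equal(c(iv$lower, iv$upper), c(-1, 1))
  # two runs: the longer wins
  lab <- c("periodic_spiking", "resting", "periodic_bursting",
           "periodic_bursting", "periodic_bursting", "resting")
  iv <- pr_sensitivity(fake_scan(0:5, lab))
  expect_equal(c(iv$lower, iv$upper), c(2, 4))
  # tie in length: smallest lower endpoint wins
  lab <- c("periodic_spiking", "periodic_spiking", "resting",
           "periodic_bursting", "periodic_bursting")
  iv <- pr_sensitivity(fake_scan(0:4, lab))
  expect_equal(c(iv$lower, iv$upper), c(0, 1))
  # subthreshold, biphasic, block and diverged points are never sensitive
  lab <- c("subthreshold_oscillation", "biphasic_oscillation",
           "depolarization_block", "diverged", "mixed_mode_oscillation")
  iv <- pr_sensitivity(fake_scan(1:5, lab))
  expect_equal(c(iv$lower, iv$upper), c(5, 5))
  # needs a Ve axis
  sc <- fake_scan(1:3, rep("resting", 3))
  attr(sc, "axes") <- "Id"
  expect_error(pr_sensitivity(sc), "Ve")
})

test_that("current sweep reproduces the weak-drive baseline behaviour", {
  # at the default coupling the F-I curve rises from a low rate at Id = 0
  sc <- pr_sweep_current(pr_params(gc = 2.1, VK = -15), id = c(0, 1),
                         duration = 3200)
  expect_lt(sc$F_hz[1], 5)          # little firing without extra drive
  expect_gt(sc$F_hz[2], sc$F_hz[1]) # the weak DC stimulus wakes it up
})

test_that("diverging grid points are marked, not fatal", {
  sc <- pr_sweep_field(pr_params(gc = 25, VK = -15), ve = c(0, 1),
                       duration = 3200)
  expect_identical(sc$regime, c("diverged", "diverged"))
  expect_true(all(sc$diverged))
  expect_equal(sc$F_hz, c(0, 0))
})
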