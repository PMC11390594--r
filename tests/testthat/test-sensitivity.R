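test_that("sensitivity is exactly zero before the perturbation event", {
  sched <- configure_condition(build_reference_model(), "DDIS", "none")
  grid <- seq(0, 100, by = 1)
  sens <- dynamic_sensitivity(sched, "kDDRF", event_time = 60,
                              species = c("DDR", "pp53", "IL6"),
                              times = grid)
  pre <- sens$S[sens$times < 60, ]
  expect_true(all(pre == 0))
  # and not merely forced to zero: the raw perturbed trajectory itself is
  # identical to the nominal one before the event
  init <- find_steady_state(sched$model)
  nom <- simulate_condition(sched, times = grid, init = init)
  pert <- simulate_condition(sched, times = grid, init = init,
                             extra_events = list(list(
                               time = 60,
                               scale_params = c(kDDRF = 1.05))))
  pre_idx <- grid < 60
  expect_equal(pert$values[pre_idx, ], nom$values[pre_idx, ],
               tolerance = 1e-10)
})

test_that("the damage input rate drives DDR after induction", {
  sched <- configure_condition(build_reference_model(), "DDIS", "none")
  sens <- dynamic_sensitivity(sched, "kDDRF", event_time = 40,
                              species = c("DDR", "pp53"),
                              times = seq(0, 100, by = 1))
  post <- sens$times > 45
  expect_gt(min(sens$S[post, "DDR"]), 0)
  expect_gt(max(sens$S[post, "pp53"]), 0)
})

test_that("Notch cleavage sensitivity respects the switch timing", {
  sched <- configure_condition(build_reference_model(), "OIS", "none")
  grid <- seq(0, 100, by = 1)
  sens <- dynamic_sensitivity(sched, "k_cleave", event_time = 60,
                              species = c("NICD", "IL6"), times = grid)
  expect_true(all(sens$S[sens$times < 60, ] == 0))
  # NICD responds immediately after T60; IL-6 disinhibition builds after
  # the switch at t = 65
  expect_gt(max(abs(sens$S[sens$times > 62 & sens$times < 65, "NICD"])),
            0.1)
  expect_gt(max(abs(sens$S[sens$times > 70, "IL6"])), 0.01)
})

test_that("forward and central differences agree at small steps", {
  sched <- configure_condition(build_reference_model(), "DDIS", "none")
  grid <- seq(0, 100, by = 2)
  fwd <- dynamic_sensitivity(sched, "b_p53", event_time = 40,
                             delta_frac = 0.01, species = "p21",
                             times = grid, method = "forward")
  ctr <- dynamic_sensitivity(sched, "b_p53", event_time = 40,
                             delta_frac = 0.01, species = "p21",
                             times = grid, method = "central")
  sel <- fwd$times > 45 & abs(ctr$S[, "p21"]) > 0.01
  rel <- abs(fwd$S[sel, "p21"] - ctr$S[sel, "p21"]) /
    abs(ctr$S[sel, "p21"])
  expect_lt(max(rel), 0.05)
})

test_that("the finite difference converges linearly in the step", {
  sched <- configure_condition(build_reference_model(), "OIS", "none")
  grid <- seq(0, 100, by = 2)
  s1 <- dynamic_sensitivity(sched, "V_NF", event_time = 40,
                            delta_frac = 0.04, species = "IL6",
                            times = grid)
  s2 <- dynamic_sensitivity(sched, "V_NF", event_time = 40,
                            delta_frac = 0.02, species = "IL6",
                            times = grid)
  sel <- grid > 45 & abs(s2$S[, "IL6"]) > 0.01
  rel <- abs(s1$S[sel, "IL6"] - s2$S[sel, "IL6"]) /
    abs(s2$S[sel, "IL6"])
  expect_lt(max(rel), 0.02)
})

test_that("input contracts and flags behave as documented", {
  sched <- configure_condition(build_reference_model(), "DDIS", "none")
  expect_error(dynamic_sensitivity(sched, "no_such_param"), "unknown")
  expect_error(dynamic_sensitivity(sched, "b_p53", delta_frac = 0.5),
               "delta_frac")
  # a pre-induction (T20) perturbation intentionally moves the system off
  # its equilibrium before induction; the simulator reports that
  expect_warning(
    sens <- dynamic_sensitivity(sched, "b_p53", event_time = 20,
                                species = "p21",
                                times = seq(0, 100, 2)),
    "equilibrium")
  expect_false(any(sens$flagged & sens$S != 0))
})
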