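test_that("no ligand, or a dead binding arm, leaves the system silent", {
  m <- fix_model()
  p <- fix_params()
  tr <- simulate_model(m, p, rtk_condition("none", 0,
                                           output_times = c(0, 5, 30, 360)))
  expect_true(all(tr$observables == 0))

  p2 <- set_params(p, kon_igf1 = 0)
  tr2 <- simulate_model(m, p2, rtk_condition("IGF1", 10,
                                             output_times = c(0, 5, 30, 360)))
  expect_true(all(abs(tr2$observables) < 1e-6))
})

test_that("symmetric two-state interconversion relaxes to the half-half point", {
  m <- fix_model()
  # only surface phosphorylation/dephosphorylation active at equal rates:
  # a closed A <-> B pair inside the receptor pool
  v <- setNames(numeric(66), m$param_info$name)
  v[c("kphos_igf1", "kdephos_igf1")] <- 1
  v["IGF1R_0"] <- 1e4
  p <- rtk_params(v, m, check = FALSE)
  tr <- simulate_model(m, p, rtk_condition("none", 0, output_times = c(0, 1000)),
                       init_state = c(IGF1R = 0, IGF1R_L = 1e4))
  end <- tr$states[2, c("IGF1R_L", "pIGF1R_L")]
  expect_equal(unname(end), c(5e3, 5e3), tolerance = 1e-6)
})

test_that("independent integrators agree along the full 48 h trajectory", {
  m <- fix_model()
  p <- fix_params()
  cond <- rtk_condition("IGF1", 10, output_times = c(0, 5, 30, 360, 1440, 2880))
  a <- simulate_model(m, p, cond)                                  # lsoda + C
  b <- simulate_model(m, p, cond, method = "radau",
                      use_compiled = FALSE, rtol = 1e-10, atol = 1e-8)
  # per-observable relative agreement, 1 mpc floor for near-zero endpoints
  rel <- abs(a$observables - b$observables) / (abs(b$observables) + 1)
  expect_lt(max(rel), 1e-4)
})

test_that("simulation is deterministic and respects conservation", {
  m <- fix_model()
  p <- fix_params()
  cond <- rtk_condition("Ins", 10)
  a <- simulate_model(m, p, cond)
  b <- simulate_model(m, p, cond)
  expect_identical(a$observables, b$observables)
  expect_lt(max(check_conservation(m, a)), 1e-6)
})

test_that("dose conversion is linear with the expected default factor", {
  expect_equal(dose_to_mpc(0), 0)
  expect_equal(dose_to_mpc(10), 6.022e5)
  expect_equal(dose_to_mpc(3, alpha = 2 * 6.022e4), 2 * dose_to_mpc(3))
  expect_error(dose_to_mpc(-1), "non-negative")
})

test_that("inhibitor emulation reduces exactly the targeted rate constants", {
  p <- fix_params()
  ly <- apply_inhibition(p, "LY")
  expect_equal(ly$values[["k_pdk1"]], 0.1 * p$values[["k_pdk1"]])
  changed <- names(p$values)[param_values(ly) != param_values(p)]
  expect_identical(changed, "k_pdk1")

  bez <- apply_inhibition(p, "BEZ")
  changed <- names(p$values)[param_values(bez) != param_values(p)]
  expect_setequal(changed, c("k_pdk1", "k_s6k"))
  expect_equal(bez$values[["k_s6k"]], 0.1 * p$values[["k_s6k"]])

  expect_identical(param_values(apply_inhibition(p, "custom")),
                   param_values(p))
  # input set not mutated
  expect_equal(p$values[["k_pdk1"]], fix_params()$values[["k_pdk1"]])
  expect_error(apply_inhibition(p, "custom", c(nope = 0.5)), "nope")
})

test_that("dose-response rows are zero at zero dose, monotone, and reproducible", {
  m <- fix_model()
  p <- fix_params()
  dr0 <- dose_response(m, p, 0)
  expect_true(all(dr0 == 0))

  doses <- c(0, 0.5, 1, 5, 10, 30, 100)
  dr <- dose_response(m, p, doses)
  # non-decreasing up to a tiny saturation-plateau wiggle
  for (ob in colnames(dr))
    expect_true(all(diff(dr[, ob]) >= -1e-4 * max(dr[, ob])),
                label = paste("monotone", ob))

  dup <- dose_response(m, p, c(10, 10))
  expect_identical(dup[1, ], dup[2, ])
})

test_that("experiment conditions validate their invariants", {
  expect_error(rtk_condition("IGF1", -1), "non-negative")
  expect_error(rtk_condition("IGF1", 10, output_times = c(5, 0, 30)), "sorted")
  expect_error(rtk_condition("IGF1", 10, output_times = c(0, 40),
                             t_end_min = 30), "sorted|within")
  expect_error(rtk_condition("IGF1", 10,
                             inhibitor_scalings = c(k_pdk1 = -2)),
               "non-negative")
})
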