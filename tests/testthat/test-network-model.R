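test_that("reference network satisfies the published structural counts", {
  m <- fix_model()
  info <- m$param_info
  expect_equal(nrow(info), 66L)
  expect_equal(sum(info$type == "abundance"), 16L)
  expect_equal(sum(info$type == "rate"), 50L)
  expect_equal(sum(info$arm == "shared" & info$type == "rate"), 34L)
  expect_equal(sum(info$arm == "IGF1"), 8L)
  expect_equal(sum(info$arm == "Ins"), 8L)
  roles <- vapply(m$pools, `[[`, "", "role")
  expect_equal(sum(roles == "ligand"), 2L)
  expect_equal(sum(roles != "ligand"), 14L)
  # the named feedback / activation parameters the scans interrogate
  expect_true(all(c("k7", "kf203", "kf208") %in% info$name))
  expect_silent(validate_model(m))
})

test_that("deleting one receptor arm disconnects its ligand from MAPK", {
  m <- fix_model()
  rx <- m$reactions[m$reactions$arm != "IGF1", ]
  m2 <- model_from_reactions(rx, check = FALSE)
  reach <- dualRTK:::.rtk_reachable(m2, "IGF1")
  expect_false("pMAPK" %in% reach)
  # and the full-count validation rejects the reduced network
  expect_error(model_from_reactions(rx), "rate parameters|arm partition|no path")
  # the insulin arm still signals
  expect_true("pMAPK" %in% dualRTK:::.rtk_reachable(m2, "Ins"))
})

test_that("protein pools are conserved by construction in the stoichiometry", {
  m <- fix_model()
  S <- stoichiometry_matrix(m)
  for (p in m$pools) {
    net <- colSums(S[p$states, , drop = FALSE])
    if (p$conserved) {
      expect_true(all(net == 0), label = paste("pool", p$name))
    } else {
      # ligand pools only lose mass: clearance and internalized-ligand
      # degradation on receptor recycling
      expect_true(all(net <= 0), label = paste("ligand pool", p$name))
      expect_true(any(net < 0), label = paste("ligand pool", p$name))
    }
  }
})

test_that("compiled RHS matches the independent flux-accumulation oracle", {
  m <- fix_model()
  p <- fix_params()
  rhs <- compile_rhs(m, p)
  set.seed(401)
  for (i in 1:100) {
    y <- setNames(10^runif(length(m$states), 0, 5), m$states)
    d1 <- rhs(0, y)
    d2 <- oracle_rhs(m, p, y)
    expect_lt(max(abs(d1 - d2) / pmax(abs(d2), 1e-300)), 1e-12)
  }
})

test_that("elementary RHS cases behave as mass action dictates", {
  m <- fix_model()
  # single reversible binding, all other rates zero:
  # d[L]/dt = -kon*L*R + koff*LR = -0.01*100*50 + 1*0 = -50
  v <- setNames(numeric(66), m$param_info$name)
  v[c("kon_igf1", "koff_igf1")] <- c(0.01, 1)
  p <- rtk_params(v, m, check = FALSE)
  rhs <- compile_rhs(m, p)
  y <- setNames(numeric(length(m$states)), m$states)
  y[c("IGF1", "IGF1R", "IGF1R_L")] <- c(100, 50, 0)
  expect_equal(rhs(0, y)[["IGF1"]], -50)

  # all rates zero -> derivative identically zero
  p0 <- rtk_params(setNames(numeric(66), m$param_info$name), m, check = FALSE)
  y2 <- setNames(10^runif(length(m$states), 0, 4), m$states)
  expect_true(all(compile_rhs(m, p0)(0, y2) == 0))

  # unknown rate parameter id is rejected at compile time
  p_bad <- fix_params()
  names(p_bad$values)[match("k7", names(p_bad$values))] <- "k_unknown"
  expect_error(compile_rhs(m, p_bad), "k7")
})

test_that("zero-activity state is a fixed point without ligand", {
  m <- fix_model()
  p <- fix_params()
  rhs <- compile_rhs(m, p)
  y0 <- setNames(numeric(length(m$states)), m$states)
  for (pool in m$pools)
    if (pool$role != "ligand")
      y0[pool$states[1]] <- param_values(p)[[pool$total_param]]
  expect_true(all(rhs(0, y0) == 0))
})

test_that("conservation drift is tiny along trajectories and flags corruption", {
  m <- fix_model()
  p <- fix_params()
  tr <- simulate_model(m, p, rtk_condition("IGF1", 10))
  drift <- check_conservation(m, tr)
  expect_lt(max(drift), 1e-6)
  # ligand total strictly non-increasing once clearance is active
  lig <- attr(drift, "ligand_totals")[, "IGF1"]
  expect_true(all(diff(lig) <= 1e-8 * lig[1]))

  # hand-corrupt one state by 10%: drift ~ 0.1 * (state share of the pool)
  tr2 <- tr
  i <- which.max(tr$states[, "pAkt"])
  tr2$states[i, "pAkt"] <- 1.1 * tr$states[i, "pAkt"]
  expected <- unname(0.1 * tr$states[i, "pAkt"] / tr$abundances$Akt_0)
  expect_equal(unname(check_conservation(m, tr2)["Akt"]), expected,
               tolerance = 1e-6)
})
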