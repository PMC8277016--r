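test_that("profiled scale minimizes the weighted least squares in closed form", {
  # y_sim=[1,2], y_data=[2,4]: scale absorbs the factor exactly
  fit <- dualRTK:::.profiled_wls(c(1, 2), c(2, 4), c(1, 1))
  expect_equal(fit$scale, 2)
  expect_equal(fit$loss, 0)
  # y_data=[2,5]: c* = sum(y d)/sum(y^2) = 12/5; loss from the closed form
  fit <- dualRTK:::.profiled_wls(c(1, 2), c(2, 5), c(1, 1))
  expect_equal(fit$scale, 12 / 5)
  expect_equal(fit$loss, (12 / 5 - 2)^2 + (24 / 5 - 5)^2)
  # all-zero simulation: scale defined as 0, loss is the data norm
  fit <- dualRTK:::.profiled_wls(c(0, 0), c(2, 5), c(1, 1))
  expect_equal(fit$scale, 0)
  expect_equal(fit$loss, 4 + 25)
})

test_that("loss is zero at truth on noise-free data and scale invariant", {
  m <- fix_model()
  truth <- fix_params()
  d0 <- generate_rppa(m, synth_config(truth, noise_sigma_log = 0,
                                      n_reps = 1, seed = 7))
  expect_lt(rppa_loss(truth, d0, m), 1e-8)

  # rescaling an observable's arbitrary units leaves the loss unchanged
  d <- generate_rppa(m, synth_config(truth, seed = 7))
  p_off <- set_params(truth, kr_mapk = truth$values[["kr_mapk"]] * 3)
  l1 <- as.numeric(rppa_loss(p_off, d, m))
  d7 <- d
  d7$value <- 7 * d7$value
  d7$sem <- 7 * d7$sem
  l7 <- as.numeric(rppa_loss(p_off, d7, m))
  expect_gt(l1, 0)
  expect_equal(l7, l1, tolerance = 1e-10)
})

test_that("single-parameter displacements from truth raise the loss", {
  # identifiability smoke test on the recovery subset
  m <- fix_model()
  truth <- fix_params()
  d0 <- generate_rppa(m, synth_config(truth, noise_sigma_log = 0,
                                      n_reps = 1, seed = 7))
  for (pid in recovery_free()) {
    up <- set_params(truth,
                     setNames(10^0.5 * truth$values[[pid]], pid))
    expect_gt(as.numeric(rppa_loss(up, d0, m)), 1e-2)
  }
})

test_that("replica-swap probability is symmetric-case exact", {
  expect_equal(pt_swap_prob(5, 5, 1, 10), 1)
  # hot chain holding the better state always swaps down
  expect_equal(pt_swap_prob(7, 3, 1, 10), 1)
  # cold chain holding the better state swaps up only occasionally
  expect_equal(pt_swap_prob(3, 7, 1, 10), exp((1 - 1 / 10) * (-4)))
})

test_that("argmin over chains and steps honors the lexicographic tie rule", {
  losses <- matrix(5, nrow = 30, ncol = 3)
  losses[17, 2] <- 1
  expect_equal(dualRTK:::.pt_argmin(losses), c(chain = 2, step = 17))
  losses[23, 1] <- 1                    # equal minimum, lower chain index
  expect_equal(dualRTK:::.pt_argmin(losses), c(chain = 1, step = 23))
  losses[9, 1] <- 1                     # equal minimum, earlier step
  expect_equal(dualRTK:::.pt_argmin(losses), c(chain = 1, step = 9))
})

test_that("single chain on a quadratic energy samples the analytic Gaussian", {
  m <- fix_model()
  p <- fix_params()
  mu <- -3; sig <- 0.1
  en <- function(pp) (log10(pp$values[["k7"]]) - mu)^2 / (2 * sig^2)
  fit <- pt_mcmc(m, NULL, pt_config(n_chains = 1, n_steps = 20000,
                                    adapt = FALSE, proposal_sigma = 0.15,
                                    seed = 5),
                 init = p, free = "k7", energy = en)
  x <- fit$samples[[1]][-(1:4000), 1]
  # autocorrelation-aware standard errors
  ac <- acf(x, plot = FALSE, lag.max = 200)$acf[-1]
  tau <- 1 + 2 * sum(ac[ac > 0.05])
  n_eff <- length(x) / tau
  expect_lt(abs(mean(x) - mu), 3 * sig / sqrt(n_eff))
  expect_lt(abs(sd(x) - sig), 3 * sig / sqrt(2 * n_eff))

  # detailed-balance smoke test: chi-square goodness of fit of the thinned
  # histogram against the analytic posterior
  xt <- x[seq(1, length(x), by = ceiling(tau))]
  br <- qnorm(seq(0.1, 0.9, by = 0.1), mu, sig)
  counts <- table(cut(xt, c(-Inf, br, Inf)))
  gof <- chisq.test(counts, p = rep(0.1, 10))
  expect_gt(gof$p.value, 0.01)
})

test_that("an effectively infinite temperature flattens the posterior", {
  m <- fix_model()
  p <- fix_params()
  # one-decade prior box so the fixed-kernel walk mixes well
  p$bounds["k7", ] <- c(1e-4, 1e-3)
  en <- function(pp) (log10(pp$values[["k7"]]) + 3.5)^2 / (2 * 0.15^2)
  fit <- pt_mcmc(m, NULL,
                 pt_config(n_chains = 2, temperatures = c(1, 1e12),
                           n_steps = 50000, adapt = FALSE,
                           proposal_sigma = 0.05, swap_interval = 1000,
                           seed = 6),
                 init = p, free = "k7", energy = en)
  # in-bounds moves are always accepted at T -> Inf
  expect_gt(fit$accept_rate[2], 0.9)
  x <- fit$samples[[2]][-(1:10000), 1]
  xt <- x[seq(1, length(x), by = 400)]
  ks <- suppressWarnings(ks.test(xt, "punif", -4, -3))
  expect_gt(ks$p.value, 0.01)
})

test_that("a short run recovers a single displaced parameter", {
  m <- fix_model()
  truth <- fix_params()
  d0 <- generate_rppa(m, synth_config(truth, noise_sigma_log = 0,
                                      n_reps = 1, seed = 9))
  init <- recovery_init(truth)
  fit <- pt_mcmc(m, d0, pt_config(n_chains = 2, n_steps = 600, seed = 11),
                 init = init, free = "kr_mapk")
  best <- select_best_fit(fit)
  err <- abs(log10(best$values[["kr_mapk"]]) -
             log10(truth$values[["kr_mapk"]]))
  expect_lt(err, 0.5)
  expect_equal(fit$best_loss, min(fit$losses))
  # running best is non-increasing by construction of the argmin
  expect_true(all(diff(cummin(fit$losses[, 1])) <= 0))
})

test_that("parallel-tempering configuration validates its ladder", {
  expect_error(pt_config(temperatures = c(2, 4, 8, 16)), "from 1")
  expect_error(pt_config(temperatures = c(1, 1, 2, 3)), "increase")
  expect_error(pt_config(n_chains = 3, temperatures = c(1, 2)), "one temperature")
  cfg <- pt_config()
  expect_equal(cfg$temperatures, 10^(0:3 / 2))
})
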