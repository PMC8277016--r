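test_that("noise-free generation reproduces the scaled trajectories exactly", {
  m <- fix_model()
  truth <- fix_params()
  cfg <- synth_config(truth, noise_sigma_log = 0, n_reps = 1, seed = 31)
  d <- generate_rppa(m, cfg)
  expect_true(all(d$sem == 0))
  sc <- attr(d, "scales")
  tr <- simulate_model(m, truth,
                       rtk_condition("IGF1", 10,
                                     output_times = sort(unique(c(0, cfg$times)))))
  for (ob in c("pAkt", "pMAPK")) {
    rows <- d[d$ligand == "IGF1" & d$observable == ob & d$time_min > 0, ]
    sim <- tr$observables[match(rows$time_min, tr$times), ob]
    expect_equal(rows$value, unname(sc[ob] * sim), tolerance = 1e-12)
  }
  # baseline records carry the small positive noise floor
  base <- d[d$time_min == 0, "value"]
  expect_true(all(base > 0))
})

test_that("replicate log-means concentrate around the scaled signal", {
  m <- fix_model()
  truth <- fix_params()
  cfg <- synth_config(truth, n_reps = 500, noise_sigma_log = 0.1, seed = 33,
                      conditions = list(rtk_condition("IGF1", 10,
                        output_times = c(0, 5, 10, 30))),
                      times = c(0, 5, 10, 30))
  d <- generate_rppa(m, cfg)
  sc <- attr(d, "scales")
  tr <- simulate_model(m, truth,
                       rtk_condition("IGF1", 10, output_times = c(0, 5, 10, 30)))
  row <- d[d$observable == "pAkt" & d$time_min == 30, ]
  mu <- sc["pAkt"] * tr$observables[tr$times == 30, "pAkt"]
  # mean of 500 lognormal replicates: relative se ~ sigma/sqrt(n)
  expect_lt(abs(log(row$value) - log(mu)), 3 * 0.1 / sqrt(500))
  expect_equal(row$sem / row$value, 0.1 / sqrt(500), tolerance = 0.2)
})

test_that("the canned fixture suite is complete and byte-reproducible", {
  m <- fix_model()
  truth <- fix_params()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- make_fixture_suite(d1, m, truth, seed = 5)
  expect_setequal(man$files, c("calib_zero_noise.csv", "calib_noisy.csv",
                               "dose_ladder.csv", "inhibitor.csv"))
  make_fixture_suite(d2, m, truth, seed = 5)
  for (f in man$files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)

  # every condition/time/observable combination is populated
  noisy <- read_rppa_csv(file.path(d1, "calib_noisy.csv"))
  tab <- table(noisy$condition, noisy$observable, noisy$time_min)
  expect_true(all(tab >= 1))
  expect_setequal(unique(noisy$observable),
                  c("pReceptor", "pAkt", "pRPS6K", "pMAPK"))

  # inhibitor fixture reflects suppressed Akt phosphorylation under PI3K
  # inhibition at 30 min
  inh <- read_rppa_csv(file.path(d1, "inhibitor.csv"))
  pakt <- function(cond) inh$value[inh$condition == cond &
                                   inh$observable == "pAkt" &
                                   inh$time_min == 30]
  expect_lt(pakt("IGF1+LY"), pakt("IGF1"))
  expect_lt(pakt("IGF1+BEZ"), pakt("IGF1"))

  # dose ladder covers the four doses
  dl <- read_rppa_csv(file.path(d1, "dose_ladder.csv"))
  expect_setequal(unique(dl$dose_nM), c(0.1, 1, 10, 100))
})

test_that("generator round-trips through the loss at truth", {
  m <- fix_model()
  truth <- fix_params()
  d0 <- generate_rppa(m, synth_config(truth, noise_sigma_log = 0,
                                      n_reps = 1, seed = 35))
  expect_lt(as.numeric(rppa_loss(truth, d0, m)), 1e-8)
  # configuration invariants
  expect_error(synth_config(truth, n_reps = 0), "n_reps")
  expect_error(synth_config(truth, noise_sigma_log = -0.1), "sigma")
  expect_error(synth_config(truth, times = c(0, 5, 10)), "fit points")
})
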