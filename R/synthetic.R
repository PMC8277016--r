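## Synthetic RPPA-like data from known ground-truth parameters, so the
## calibration, ensemble and scanning stages are testable without external
## data.

#' Configuration for the synthetic RPPA generator
#'
#' @param truth Ground-truth \code{rtk_params}.
#' @param conditions List of [rtk_condition()]s; default 10 nM IGF1 and
#'   10 nM Ins.
#' @param times Sampling times in minutes; default 0, 5, 10, 30 min and
#'   6, 24, 48 h. Must include the three fit points (5, 10, 30 min).
#' @param n_reps Biological replicates per record (>= 1; default 3).
#' @param noise_sigma_log Multiplicative lognormal noise s.d. on the natural
#'   log scale (default 0.1).
#' @param scale_range Per-observable nuisance scale factors \eqn{c_o} are
#'   drawn log-uniform from this interval (default [0.5, 2]), emulating
#'   arbitrary RPPA intensity units.
#' @param seed RNG seed.
#' @return An \code{rtk_synth_config}.
#' @export
synth_config <- function(truth,
                         conditions = list(
                           rtk_condition("IGF1", 10, output_times = c(0, 5, 10, 30, 360, 1440, 2880)),
                           rtk_condition("Ins", 10, output_times = c(0, 5, 10, 30, 360, 1440, 2880))),
                         times = c(0, 5, 10, 30, 360, 1440, 2880),
                         n_reps = 3, noise_sigma_log = 0.1,
                         scale_range = c(0.5, 2), seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (noise_sigma_log < 0) stop("noise sigma must be >= 0")
  if (!all(c(5, 10, 30) %in% times))
    stop("times must include the fit points 5, 10, 30 min")
  structure(list(truth = truth, conditions = conditions, times = times,
                 n_reps = n_reps, noise_sigma_log = noise_sigma_log,
                 scale_range = scale_range, seed = seed),
            class = "rtk_synth_config")
}

#' Generate a synthetic RPPA-style dataset
#'
#' Simulates the ground truth under each condition and emits replicate
#' records \code{value = c_o * obs(t) * exp(eta)} with
#' \code{eta ~ Normal(0, sigma_log^2)} i.i.d. per replicate, where the
#' per-observable nuisance scales \code{c_o} emulate arbitrary RPPA units.
#' Records carry the replicate mean and standard error. Baseline (t = 0)
#' records get a small noise floor (1e-3 of the observable's maximum) so
#' scale profiling never divides by zero. Fully reproducible from the seed.
#'
#' @param model The model.
#' @param cfg An [synth_config()].
#' @return Data frame in the calibration schema (\code{condition, ligand,
#'   dose_nM, observable, time_min, value, sem, n_reps}) with attributes
#'   \code{scales} and \code{seed}.
#' @export
generate_rppa <- function(model, cfg) {
  set.seed(cfg$seed)
  obs_names <- names(model$observables)
  lr <- log10(cfg$scale_range)
  c_o <- setNames(10^runif(length(obs_names), lr[1], lr[2]), obs_names)

  rows <- list()
  for (cond in cfg$conditions) {
    cond$output_times <- sort(unique(c(0, cfg$times)))
    cond$t_end_min <- max(cond$output_times)
    tr <- simulate_model(model, cfg$truth, cond)
    cid <- if (cond$ligand == "none") "unstim" else
      sprintf("%s_%gnM", cond$ligand, cond$dose_nM)
    for (ob in obs_names) {
      sig <- observables_at_times(tr, cfg$times)[, ob]
      base <- c_o[[ob]] * sig
      floor <- 1e-3 * max(base)
      for (i in seq_along(cfg$times)) {
        mu <- base[i] + if (cfg$times[i] == 0) floor else 0
        reps <- mu * exp(rnorm(cfg$n_reps, 0, cfg$noise_sigma_log))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cid, ligand = cond$ligand, dose_nM = cond$dose_nM,
          observable = ob, time_min = cfg$times[i],
          value = mean(reps),
          sem = if (cfg$n_reps > 1) sd(reps) / sqrt(cfg$n_reps) else 0,
          n_reps = cfg$n_reps, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, scales = c_o, seed = cfg$seed)
}

# observables at several grid times
observables_at_times <- function(traj, times) {
  i <- match(times, traj$times)
  if (anyNA(i)) stop("time(s) not on the trajectory grid")
  traj$observables[i, , drop = FALSE]
}

#' Write the canned synthetic fixture suite
#'
#' Emits four CSV datasets, schema-identical to real-data ingestion, plus a
#' manifest JSON recording the seed and a hash of the ground truth:
#' \describe{
#'   \item{calib_zero_noise.csv}{noise-free calibration data (both ligands)}
#'   \item{calib_noisy.csv}{3-replicate lognormal-noise calibration data}
#'   \item{dose_ladder.csv}{IGF1 doses 0.1, 1, 10, 100 nM}
#'   \item{inhibitor.csv}{control, LY, BEZ alone and combined with 10 nM
#'     IGF1 (the PI3K/mTORC1 inhibition condition grid)}
#' }
#' Regenerating with the same seed reproduces the files byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @param model The model.
#' @param truth Ground-truth parameter set (default [reference_params()]).
#' @param seed Base RNG seed.
#' @return Invisibly, the manifest list.
#' @export
make_fixture_suite <- function(dir, model = build_reference_model(),
                               truth = reference_params(model), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, df) {
    path <- file.path(dir, name)
    write_rppa_csv(df, path)
    files <<- c(files, name)
    path
  }

  emit("calib_zero_noise.csv",
       generate_rppa(model, synth_config(truth, noise_sigma_log = 0,
                                         n_reps = 1, seed = seed)))
  emit("calib_noisy.csv",
       generate_rppa(model, synth_config(truth, seed = seed + 1)))

  dose_conds <- lapply(c(0.1, 1, 10, 100), function(d)
    rtk_condition("IGF1", d, output_times = c(0, 5, 10, 30, 360, 1440, 2880)))
  emit("dose_ladder.csv",
       generate_rppa(model, synth_config(truth, conditions = dose_conds,
                                         seed = seed + 2)))

  # inhibitor grid: control, LY, BEZ, IGF1, IGF1+LY, IGF1+BEZ
  inh <- list(ctrl = list("none", identity),
              LY = list("none", function(p) apply_inhibition(p, "LY")),
              BEZ = list("none", function(p) apply_inhibition(p, "BEZ")),
              IGF1 = list("IGF1", identity),
              `IGF1+LY` = list("IGF1", function(p) apply_inhibition(p, "LY")),
              `IGF1+BEZ` = list("IGF1", function(p) apply_inhibition(p, "BEZ")))
  parts <- lapply(names(inh), function(nm) {
    lig <- inh[[nm]][[1]]
    p <- inh[[nm]][[2]](truth)
    cond <- rtk_condition(lig, dose_nM = if (lig == "none") 0 else 10,
                          output_times = c(0, 5, 10, 30, 360, 1440, 2880))
    d <- generate_rppa(model, synth_config(p, conditions = list(cond),
                                           seed = seed + 3))
    d$condition <- nm
    d
  })
  emit("inhibitor.csv", do.call(rbind, parts))

  manifest <- list(seed = seed,
                   truth_md5 = .rtk_hash(param_values(truth)),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
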