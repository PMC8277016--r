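## Perturbation scanning: single-parameter sweeps with log2 fold-change
## readouts, and two-fold local sensitivity (5-min ratio and 0-30 min AUC
## ratio).

#' Default absolute scan grid
#'
#' Realizes the "zero to infinity" sweep as \code{0} plus 21 log-spaced
#' values from 1e-6 to 1e4 (the set value, not a multiplier).
#' @return Numeric vector of absolute parameter values.
#' @export
default_scan_grid <- function() c(0, 10^seq(-6, 4, length.out = 21))

#' Sweep a single rate parameter and report log2 fold-changes
#'
#' For each grid value, re-simulates the model with only that parameter
#' replaced and reports \code{log2((obs + eps) / (obs_ref + eps))} of the
#' selected observables at the selected early time points against the
#' unperturbed model. A grid value equal to the unperturbed value runs
#' through the same code path and yields exactly zero. Integration failures
#' at a grid point are recorded as \code{NA}, not fatal.
#'
#' @param model,params Model and unperturbed parameter set.
#' @param param_id Rate parameter to sweep.
#' @param grid Absolute set values (>= 0); default [default_scan_grid()].
#' @param ligand Stimulating ligand (10 nM).
#' @param times Readout times (default 5, 10, 30 min).
#' @param observables Observables to report (default pMAPK and pAkt).
#' @param floor_eps Fold-change floor (mpc) preventing \code{log2(0)}.
#' @param dose_nM Ligand dose.
#' @return An \code{rtk_scan} with a long-format \code{entries} data frame
#'   (param, set_value, ligand, time_min, observable, log2fc) and the
#'   unperturbed reference levels.
#' @export
scan_parameter <- function(model, params, param_id, grid = default_scan_grid(),
                           ligand = "IGF1", times = c(5, 10, 30),
                           observables = c("pMAPK", "pAkt"), floor_eps = 1,
                           dose_nM = 10) {
  if (!param_id %in% names(params$values))
    stop("unknown parameter id: ", param_id)
  if (any(grid < 0)) stop("grid values must be >= 0")
  cond <- rtk_condition(ligand = ligand, dose_nM = dose_nM,
                        output_times = sort(unique(c(0, times))))
  obs_at <- function(p) {
    tr <- tryCatch(simulate_model(model, p, cond), error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    tr$observables[match(times, tr$times), , drop = FALSE]
  }
  ref <- obs_at(params)
  if (is.null(ref)) stop("unperturbed simulation failed")

  entries <- do.call(rbind, lapply(grid, function(v) {
    p_v <- params
    p_v$values[[param_id]] <- v
    ob <- obs_at(p_v)
    do.call(rbind, lapply(observables, function(o) {
      l2 <- if (is.null(ob)) NA_real_ else
        log2((ob[, o] + floor_eps) / (ref[, o] + floor_eps))
      data.frame(param = param_id, set_value = v, ligand = ligand,
                 time_min = times, observable = o, log2fc = l2,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(entries) <- NULL
  structure(list(entries = entries, floor_eps = floor_eps,
                 reference_values = ref, unperturbed = params$values[[param_id]]),
            class = "rtk_scan")
}

#' Sweep all (or selected) rate parameters under both ligands
#'
#' One [scan_parameter()] per parameter and ligand, plus a heatmap-ready
#' wide matrix: rows are grid values, columns are
#' (ligand x time x observable), one matrix per parameter.
#'
#' @param model,params Model and unperturbed parameter set.
#' @param param_ids Parameters to sweep (default: all 50 rate constants;
#'   abundances are scannable by naming them here).
#' @param grid,times,observables,floor_eps,dose_nM As [scan_parameter()].
#' @param ligands Ligands to scan under.
#' @return Named list with \code{scans} (param -> ligand -> rtk_scan) and
#'   \code{matrices} (param -> grid x condition log2fc matrix).
#' @export
scan_all <- function(model, params, param_ids = NULL,
                     grid = default_scan_grid(), ligands = c("IGF1", "Ins"),
                     times = c(5, 10, 30), observables = c("pMAPK", "pAkt"),
                     floor_eps = 1, dose_nM = 10) {
  if (is.null(param_ids)) {
    info <- model$param_info
    param_ids <- info$name[info$type == "rate"]
  }
  scans <- lapply(param_ids, function(pid) {
    per_lig <- lapply(ligands, function(lg)
      scan_parameter(model, params, pid, grid = grid, ligand = lg,
                     times = times, observables = observables,
                     floor_eps = floor_eps, dose_nM = dose_nM))
    names(per_lig) <- ligands
    per_lig
  })
  names(scans) <- param_ids
  grid_sorted <- sort(grid)
  matrices <- lapply(scans, function(per_lig) {
    cols <- list()
    for (lg in ligands) for (o in observables) for (tm in times) {
      e <- per_lig[[lg]]$entries
      sel <- e$observable == o & e$time_min == tm
      cols[[sprintf("%s_%s_t%g", lg, o, tm)]] <-
        e$log2fc[sel][order(e$set_value[sel])]
    }
    m <- do.call(cbind, cols)
    rownames(m) <- format(grid_sorted)
    m
  })
  list(scans = scans, matrices = matrices)
}

#' Trapezoidal area under an observable trajectory
#'
#' @param traj An \code{rtk_traj}.
#' @param observable Observable name.
#' @param t0,t1 Integration limits (must lie on the output grid).
#' @return Non-negative scalar (mpc * min).
#' @export
traj_auc <- function(traj, observable, t0 = 0, t1 = 30) {
  if (!observable %in% colnames(traj$observables))
    stop("unknown observable: ", observable)
  if (t0 >= t1) stop("t0 must be < t1")
  if (!all(c(t0, t1) %in% traj$times))
    stop("t0/t1 must lie on the trajectory grid")
  keep <- traj$times >= t0 & traj$times <= t1
  pracma::trapz(traj$times[keep], traj$observables[keep, observable])
}

#' Two-fold local sensitivity analysis
#'
#' Doubles and halves each rate parameter individually and reports, for all
#' four observables under the given ligand, the ratio of perturbed to
#' unperturbed level at 5 min and the ratio of trapezoidal AUC over 0-30 min.
#' A direction of 1 (control) returns all-ones metrics.
#'
#' @param model,params Model and unperturbed parameter set.
#' @param ligand Stimulating ligand (10 nM).
#' @param directions Multipliers (default x2 and x0.5).
#' @param param_ids Rate parameters to perturb (default all 50).
#' @param floor_eps Ratio floor (mpc) for zero unperturbed levels.
#' @param dose_nM Ligand dose.
#' @return An \code{rtk_sensitivity} with long-format \code{entries}
#'   (param, direction, ligand, observable, metric, value).
#' @export
sensitivity_2x <- function(model, params, ligand = "IGF1",
                           directions = c(2, 0.5), param_ids = NULL,
                           floor_eps = 1, dose_nM = 10) {
  if (is.null(param_ids)) {
    info <- model$param_info
    param_ids <- info$name[info$type == "rate"]
  }
  cond <- rtk_condition(ligand = ligand, dose_nM = dose_nM,
                        output_times = 0:30)
  obs_names <- names(model$observables)
  metric_pair <- function(tr, ref) {
    r5 <- (observables_at(tr, 5) + floor_eps) /
          (observables_at(ref, 5) + floor_eps)
    rauc <- vapply(obs_names, function(o)
      (traj_auc(tr, o, 0, 30) + floor_eps) /
      (traj_auc(ref, o, 0, 30) + floor_eps), 0)
    cbind(ratio_5min = r5, auc_ratio_0_30 = rauc)
  }
  ref <- simulate_model(model, params, cond)
  rows <- list()
  for (pid in param_ids) {
    for (dir in directions) {
      p_d <- params
      p_d$values[[pid]] <- p_d$values[[pid]] * dir
      tr <- tryCatch(simulate_model(model, p_d, cond), error = function(e) NULL)
      mp <- if (is.null(tr))
        matrix(NA_real_, length(obs_names), 2,
               dimnames = list(obs_names, c("ratio_5min", "auc_ratio_0_30")))
      else metric_pair(tr, ref)
      for (met in colnames(mp))
        rows[[length(rows) + 1L]] <- data.frame(
          param = pid, direction = dir, ligand = ligand,
          observable = obs_names, metric = met, value = unname(mp[, met]),
          stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  structure(list(entries = entries, reference = ref),
            class = "rtk_sensitivity")
}

#' @export
print.rtk_scan <- function(x, ...) {
  cat(sprintf("rtk_scan of '%s' (unperturbed %.3g): %d grid points\n",
              x$entries$param[1], x$unperturbed,
              length(unique(x$entries$set_value))))
  invisible(x)
}
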