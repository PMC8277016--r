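## Simulation: stimulation conditions, stiff integration, dose ladders and
## inhibitor emulation.

#' Default trajectory output grid (minutes)
#'
#' Dense over the early response (every minute to 30 min), then 1 h, 6 h,
#' 24 h and 48 h.
#' @return Numeric vector of minutes.
#' @export
default_output_times <- function() c(0:30, 60, 360, 1440, 2880)

#' Define a stimulation / inhibition experiment condition
#'
#' @param ligand One of \code{"IGF1"}, \code{"Ins"}, \code{"none"}.
#' @param dose_nM Ligand dose in nM (ignored for \code{"none"}).
#' @param inhibitor_scalings Named non-negative multipliers applied to rate
#'   constants (e.g. from [apply_inhibition()]'s conventions).
#' @param output_times Minutes at which to report the trajectory; sorted,
#'   non-negative.
#' @param t_end_min End of integration (defaults to the last output time).
#' @return An object of class \code{rtk_condition}.
#' @export
rtk_condition <- function(ligand = c("IGF1", "Ins", "none"), dose_nM = 10,
                          inhibitor_scalings = numeric(0),
                          output_times = default_output_times(),
                          t_end_min = max(output_times)) {
  ligand <- match.arg(ligand)
  if (dose_nM < 0) stop("dose must be non-negative")
  if (length(inhibitor_scalings) && (is.null(names(inhibitor_scalings)) ||
      any(inhibitor_scalings < 0)))
    stop("inhibitor scalings must be named and non-negative")
  if (is.unsorted(output_times, strictly = FALSE) ||
      any(output_times < 0) || max(output_times) > t_end_min)
    stop("output_times must be sorted within [0, t_end_min]")
  structure(list(ligand = ligand, dose_nM = dose_nM,
                 inhibitor_scalings = inhibitor_scalings,
                 output_times = as.numeric(output_times),
                 t_end_min = as.numeric(t_end_min)),
            class = "rtk_condition")
}

#' Convert a ligand dose to molecules per cell
#'
#' Linear conversion \code{mpc = alpha * dose_nM}. The default
#' \code{alpha = 6.022e4} mpc/nM corresponds to an effective extracellular
#' volume of 1e-13 L per cell (1 nM x Avogadro x 1e-13 L = 6.022e4
#' molecules).
#'
#' @param dose_nM Dose in nM (non-negative).
#' @param alpha mpc per nM.
#' @return Abundance in molecules per cell.
#' @export
dose_to_mpc <- function(dose_nM, alpha = 6.022e4) {
  if (any(dose_nM < 0)) stop("dose must be non-negative")
  alpha * dose_nM
}

#' Emulate kinase-inhibitor treatment as rate-constant reduction
#'
#' The PI3K inhibitor (\code{"LY"}, LY294002-like) is emulated as a 90\%
#' reduction of the rate constant controlling PI3K-mediated activation of
#' PDK1 (\code{k_pdk1}). The dual PI3K/mTORC1 inhibitor (\code{"BEZ"},
#' BEZ235-like) additionally reduces the constant controlling RPS6K
#' activation through mTORC1 (\code{k_s6k}) by 90\%. \code{"custom"} applies
#' the supplied named multipliers. The input set is not mutated.
#'
#' @param params An \code{rtk_params} set.
#' @param drug \code{"LY"}, \code{"BEZ"} or \code{"custom"}.
#' @param scalings Named multipliers for \code{drug = "custom"}.
#' @return A new \code{rtk_params} with the reductions applied.
#' @export
apply_inhibition <- function(params, drug = c("LY", "BEZ", "custom"),
                             scalings = numeric(0)) {
  drug <- match.arg(drug)
  mult <- switch(drug,
    LY = c(k_pdk1 = 0.1),
    BEZ = c(k_pdk1 = 0.1, k_s6k = 0.1),
    custom = scalings)
  if (length(mult) == 0L && drug == "custom") return(params)
  if (is.null(names(mult)) || any(mult < 0))
    stop("scalings must be named and non-negative")
  unknown <- setdiff(names(mult), names(params$values))
  if (length(unknown))
    stop("unknown rate parameter: ", paste(unknown, collapse = ", "))
  params$values[names(mult)] <- params$values[names(mult)] * mult
  params
}

# stage the compiled-C evaluator; the network topology is cached per model
# fingerprint, rates are re-staged on every call
.rtk_stage_compiled <- function(model, rates) {
  idx <- model$indices
  stamp <- paste(model$reactions$id, collapse = "|")
  if (!identical(.rtk_env$network_stamp, stamp)) {
    .Call("ma_set_network",
          as.integer(idx$f1 - 1L), as.integer(idx$f2 - 1L),
          as.integer(idx$tr_reac - 1L), as.integer(idx$tr_state - 1L),
          as.numeric(idx$tr_coef), PACKAGE = "dualRTK")
    .rtk_env$network_stamp <- stamp
  }
  .Call("ma_set_rates", as.numeric(rates), PACKAGE = "dualRTK")
  invisible(NULL)
}

#' Simulate the model under an experiment condition
#'
#' Integrates the mass-action ODE system from the serum-starved zero-activity
#' fixed point (all active/phospho states zero; proteins at their
#' initial-abundance totals; ligand set from the condition dose). Uses a
#' stiff-capable integrator at tight tolerances; results are deterministic
#' given inputs.
#'
#' @param model An \code{rtk_model}.
#' @param params An \code{rtk_params}.
#' @param cond An [rtk_condition()].
#' @param method deSolve integration method (default \code{"lsoda"};
#'   \code{"radau"} or \code{"vode"} give independent cross-checks).
#' @param use_compiled Use the compiled-C flux evaluator (default). With
#'   \code{FALSE} the portable R closure from [compile_rhs()] is used.
#' @param rtol,atol Solver tolerances; \code{atol} defaults to
#'   \code{1e-10 * max(abundances)}, comfortably below the negative-excursion
#'   abort threshold of \code{1e-9 * max(abundances)} (and far below the
#'   \code{1e-6 * max(abundances)} accuracy contract).
#' @param init_state Optional named vector overriding selected entries of the
#'   serum-starved initial state (expert option, used e.g. for reduced toy
#'   systems); pool totals for conservation checking still come from the
#'   abundance parameters.
#' @return An \code{rtk_traj}: \code{times}, \code{states} (time x species,
#'   mpc), \code{observables} (time x pReceptor/pAkt/pRPS6K/pMAPK), the
#'   condition, and the abundance totals used.
#' @export
simulate_model <- function(model, params, cond = rtk_condition(),
                           method = "lsoda", use_compiled = TRUE,
                           rtol = 1e-8, atol = NULL, init_state = NULL) {
  validate_params(params, model, bounds = FALSE)
  if (length(cond$inhibitor_scalings))
    params <- apply_inhibition(params, "custom", cond$inhibitor_scalings)
  v <- param_values(params)

  # initial state: serum-starved fixed point
  y0 <- setNames(numeric(length(model$states)), model$states)
  abund <- v[model$param_info$name[model$param_info$type == "abundance"]]
  for (p in model$pools) {
    if (p$role == "ligand") next
    y0[p$states[1]] <- v[[p$total_param]]
  }
  abund[["IGF1_0"]] <- 0; abund[["Ins_0"]] <- 0
  if (cond$ligand != "none") {
    lig_mpc <- dose_to_mpc(cond$dose_nM)
    y0[[cond$ligand]] <- lig_mpc
    abund[[paste0(cond$ligand, "_0")]] <- lig_mpc
  }

  if (!is.null(init_state)) {
    unknown <- setdiff(names(init_state), model$states)
    if (length(unknown))
      stop("unknown state(s) in init_state: ", paste(unknown, collapse = ", "))
    y0[names(init_state)] <- init_state
  }

  total_max <- max(abund, 1)
  if (is.null(atol)) atol <- 1e-10 * total_max
  times <- unique(sort(c(0, cond$output_times)))

  rates <- reaction_rates(model, params)
  if (use_compiled) {
    .rtk_stage_compiled(model, rates)
    out <- deSolve::ode(y = y0, times = times, func = "ma_derivs",
                        dllname = "dualRTK", initfunc = NULL, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
  } else {
    rhs <- compile_rhs(model, params)
    out <- deSolve::ode(y = y0, times = times,
                        func = function(t, y, p) list(unname(rhs(t, y))),
                        parms = NULL, method = method, rtol = rtol, atol = atol)
  }

  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop(rtk_integration_error(params, cond))
  states <- out[, model$states, drop = FALSE]

  # clip small negative solver excursions; abort on real blowups
  neg_floor <- -1e-9 * total_max
  if (min(states) < neg_floor)
    stop(rtk_integration_error(params, cond, "negative-state blowup"))
  states[states < 0] <- 0

  obs <- vapply(model$observables,
                function(s) rowSums(states[, s, drop = FALSE]),
                numeric(nrow(states)))
  keep <- match(cond$output_times, times)
  structure(list(times = cond$output_times,
                 states = states[keep, , drop = FALSE],
                 observables = obs[keep, , drop = FALSE],
                 condition = cond,
                 abundances = as.list(abund)),
            class = "rtk_traj")
}

# integration failure as a classed condition carrying a parameter-set hash
rtk_integration_error <- function(params, cond, what = "integration failure") {
  hash <- .rtk_hash(param_values(params))
  structure(class = c("rtk_integration_error", "error", "condition"),
            list(message = sprintf("%s (ligand=%s dose=%g nM, params md5 %s)",
                                   what, cond$ligand, cond$dose_nM, hash),
                 call = NULL))
}

.rtk_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(x), format(x, digits = 17), collapse = ";"), f)
  unname(tools::md5sum(f))
}

#' Observable levels at a single time point
#'
#' @param traj An \code{rtk_traj}.
#' @param time_min Time (must be on the trajectory's output grid).
#' @return Named vector of observable levels (mpc).
#' @export
observables_at <- function(traj, time_min) {
  i <- match(time_min, traj$times)
  if (is.na(i)) stop("time ", time_min, " not on the trajectory grid")
  traj$observables[i, ]
}

#' Dose-response of the four observables
#'
#' One simulation per dose; only the ligand input changes between runs.
#'
#' @param model,params Model and parameter set.
#' @param doses Ligand doses in nM (non-negative).
#' @param readout_time_min Readout time (default 30 min, the latest
#'   early-response point).
#' @param ligand Stimulating ligand.
#' @return Matrix dose x observable (rows ordered as \code{doses}).
#' @export
dose_response <- function(model, params, doses, readout_time_min = 30,
                          ligand = "IGF1") {
  if (any(doses < 0)) stop("doses must be non-negative")
  times <- unique(sort(c(0, readout_time_min)))
  res <- t(vapply(doses, function(d) {
    cond <- rtk_condition(ligand = ligand, dose_nM = d, output_times = times)
    observables_at(simulate_model(model, params, cond), readout_time_min)
  }, numeric(length(.rtk_observables))))
  rownames(res) <- format(doses)
  res
}

#' @export
print.rtk_traj <- function(x, ...) {
  cat(sprintf("rtk_traj: %d time points over [%g, %g] min (%s, %g nM)\n",
              length(x$times), min(x$times), max(x$times),
              x$condition$ligand, x$condition$dose_nM))
  cat("final observables (mpc):\n")
  print(round(x$observables[nrow(x$observables), ], 1))
  invisible(x)
}
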