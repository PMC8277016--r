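## Calibration: weighted least-squares loss with profiled per-observable
## scales, and parallel-tempering MCMC over log10 parameters with uniform
## priors.

.rtk_fit_times <- c(5, 10, 30)

# unique stimulation conditions present in an RPPA table
.rppa_conditions <- function(data) {
  unique(data[, c("condition", "ligand", "dose_nM")])
}

# weighted least squares with a profiled multiplicative scale:
# c = argmin_c sum(w (c y - d)^2), w = 1/sem^2, in closed form
.profiled_wls <- function(ysim, ydata, sem) {
  w <- 1 / sem^2
  denom <- sum(w * ysim^2)
  scale <- if (denom > 0) sum(w * ysim * ydata) / denom else 0
  list(scale = scale, loss = sum(w * (scale * ysim - ydata)^2))
}

#' Fitting error of a parameter set against an RPPA-style dataset
#'
#' Simulates every stimulation condition in \code{data}, then for each
#' observable profiles a free scale factor \eqn{c_o} (RPPA intensities are in
#' arbitrary units) by analytically minimizing the weighted sum of squares
#' \eqn{\sum w (c_o y_{sim} - y_{data})^2} with \eqn{w = 1/sem^2}, and
#' returns the total weighted squared residual over all conditions, fit time
#' points and observables. Only the early time points (5, 10, 30 min by
#' default) enter the loss; later points are validation-only. Integration
#' failures map to \code{Inf} (a rejected move during sampling), never to an
#' error.
#'
#' @param params Parameter set to score.
#' @param data RPPA data frame with columns \code{condition, ligand, dose_nM,
#'   observable, time_min, value, sem, n_reps}.
#' @param model The model.
#' @param fit_times Time points entering the loss (minutes).
#' @param sem_floor_frac Every entry's sem is floored at this fraction of the
#'   observable's maximum value (default 5\%). Besides handling \code{sem =
#'   0} records, the floor tames the heavy-tailed weights that
#'   replicate-estimated sems produce at small replicate numbers.
#' @return Non-negative scalar loss; attribute \code{scales} holds the
#'   profiled \eqn{c_o}.
#' @export
rppa_loss <- function(params, data, model, fit_times = .rtk_fit_times,
                      sem_floor_frac = 0.05) {
  data <- data[data$time_min %in% fit_times, , drop = FALSE]
  if (!nrow(data)) stop("no data rows at the fit time points")
  conds <- .rppa_conditions(data)
  times <- sort(unique(data$time_min))

  sim <- list()
  for (i in seq_len(nrow(conds))) {
    tr <- tryCatch(
      simulate_model(model, params,
                     rtk_condition(ligand = conds$ligand[i],
                                   dose_nM = conds$dose_nM[i],
                                   output_times = times)),
      error = function(e) NULL)
    if (is.null(tr)) return(structure(Inf, scales = NULL))
    sim[[as.character(conds$condition[i])]] <- tr
  }

  total <- 0
  scales <- c()
  for (ob in unique(data$observable)) {
    rows <- data[data$observable == ob, , drop = FALSE]
    ysim <- mapply(function(cid, tm) observables_at(sim[[as.character(cid)]], tm)[[ob]],
                   rows$condition, rows$time_min)
    sem <- rows$sem
    # floor every sem at a fraction of the observable's dynamic range:
    # replicate-estimated sems (n ~ 3) are chi-square distributed and their
    # inverse squares are heavy-tailed, so unfloored weights let single
    # records dominate the fit
    floor <- max(sem_floor_frac * max(rows$value, 0), .Machine$double.eps)
    sem <- pmax(ifelse(is.finite(sem), sem, 0), floor)
    fit <- .profiled_wls(ysim, rows$value, sem)
    total <- total + fit$loss
    scales[ob] <- fit$scale
  }
  structure(total, scales = scales)
}

#' Parallel-tempering configuration
#'
#' @param n_chains Number of chains (temperature ladder length).
#' @param temperatures Increasing ladder starting at 1; default geometric,
#'   \code{10^(seq(0, n_chains-1)/2)} (1, 3.16, 10, 31.6 for 4 chains).
#' @param n_steps Sampling steps per chain.
#' @param swap_interval Steps between adjacent-chain swap attempts.
#' @param proposal_sigma Gaussian proposal s.d. in log10 units.
#' @param adapt Scale the proposal during burn-in toward 20-40\% acceptance.
#' @param burn_frac Fraction of steps treated as burn-in (adaptation window;
#'   samples are retained regardless and flagged in the result).
#' @param seed RNG seed; the whole run is reproducible from it.
#' @return An object of class \code{rtk_pt_config}.
#' @export
pt_config <- function(n_chains = 4, temperatures = NULL, n_steps = 5000,
                      swap_interval = 10, proposal_sigma = 0.1, adapt = TRUE,
                      burn_frac = 0.2, seed = 1) {
  if (is.null(temperatures))
    temperatures <- 10^(seq(0, n_chains - 1) / 2)
  if (n_chains < 1 || length(temperatures) != n_chains)
    stop("need one temperature per chain")
  if (temperatures[1] != 1 ||
      (n_chains > 1 && any(diff(temperatures) <= 0)))
    stop("temperature ladder must increase from 1")
  structure(list(n_chains = n_chains, temperatures = temperatures,
                 n_steps = n_steps, swap_interval = swap_interval,
                 proposal_sigma = proposal_sigma, adapt = adapt,
                 burn_frac = burn_frac, seed = seed),
            class = "rtk_pt_config")
}

#' Replica-swap acceptance probability
#'
#' Metropolis acceptance for exchanging states between chains at temperatures
#' \code{t_i < t_j} with energies \code{e_i, e_j}:
#' \code{min(1, exp((1/t_i - 1/t_j) * (e_i - e_j)))}. Equal energies always
#' swap.
#'
#' @param e_i,e_j Energies (losses) of the two chains.
#' @param t_i,t_j Their temperatures.
#' @return Acceptance probability in [0, 1].
#' @export
pt_swap_prob <- function(e_i, e_j, t_i, t_j) {
  min(1, exp((1 / t_i - 1 / t_j) * (e_i - e_j)))
}

#' Parallel-tempering MCMC over log10 parameters
#'
#' Within-chain Metropolis sampling of the loss-defined posterior
#' \eqn{\propto \exp(-E/T)} with uniform priors on log10-parameter boxes:
#' Gaussian proposals in log10 space, out-of-bounds proposals rejected, and
#' adjacent-chain replica swaps every \code{swap_interval} steps
#' (see [pt_swap_prob()]). The default energy is half the weighted
#' least-squares loss, \code{0.5 * rppa_loss()}, i.e. the Gaussian negative
#' log-likelihood of the data given the parameters, so the T = 1 chain
#' samples the corresponding Bayesian posterior under the uniform
#' log10-box prior. Any other scalar function of a parameter set can be
#' supplied (used e.g. by the sampler self-tests).
#'
#' @param model,data Model and RPPA data for the default energy.
#' @param cfg An [pt_config()].
#' @param init Baseline parameter set; fixed parameters keep these values.
#' @param free Names of the parameters being sampled (default: all 50 rate
#'   constants plus the 14 protein abundances).
#' @param energy Optional \code{function(params) -> scalar} replacing
#'   [rppa_loss()].
#' @param init_retries Re-draws allowed when the initial point has non-finite
#'   energy.
#' @return An \code{rtk_pt} result: per-chain sample arrays (log10 units),
#'   losses, acceptance and swap diagnostics, and the best fit.
#' @export
pt_mcmc <- function(model, data, cfg = pt_config(), init, free = NULL,
                    energy = NULL, init_retries = 50) {
  if (is.null(free)) {
    info <- model$param_info
    free <- setdiff(info$name[info$type == "rate" | info$type == "abundance"],
                    c("IGF1_0", "Ins_0"))
  }
  if (is.null(energy))
    energy <- function(p) 0.5 * as.numeric(rppa_loss(p, data, model))
  b <- init$bounds[free, , drop = FALSE]
  if (any(!is.finite(b)) || any(b[, "lower"] <= 0))
    stop("finite positive bounds required for sampled parameters")
  lo <- log10(b[, "lower"]); hi <- log10(b[, "upper"])
  d <- length(free)

  set.seed(cfg$seed)
  nC <- cfg$n_chains
  temps <- cfg$temperatures
  nS <- cfg$n_steps
  n_burn <- floor(cfg$burn_frac * nS)

  with_free <- function(x) set_params(init, setNames(10^x, free))
  x <- matrix(NA_real_, nC, d)
  E <- rep(Inf, nC)
  for (c_ in seq_len(nC)) {
    for (try in seq_len(init_retries)) {
      cand <- lo + runif(d) * (hi - lo)
      e <- energy(with_free(cand))
      if (is.finite(e)) { x[c_, ] <- cand; E[c_] <- e; break }
    }
    if (!is.finite(E[c_])) stop("could not find a finite-loss initial point")
  }

  samples <- lapply(seq_len(nC), function(i)
    matrix(NA_real_, nS, d, dimnames = list(NULL, free)))
  losses <- matrix(NA_real_, nS, nC)
  sigma <- rep(cfg$proposal_sigma, nC)
  acc <- integer(nC); prop <- integer(nC)
  acc_win <- integer(nC); prop_win <- integer(nC)
  swap_acc <- integer(max(nC - 1, 1)); swap_try <- integer(max(nC - 1, 1))

  for (s in seq_len(nS)) {
    for (c_ in seq_len(nC)) {
      xp <- x[c_, ] + rnorm(d, 0, sigma[c_])
      prop[c_] <- prop[c_] + 1L; prop_win[c_] <- prop_win[c_] + 1L
      if (all(xp >= lo & xp <= hi)) {
        Ep <- energy(with_free(xp))
        if (is.finite(Ep) &&
            (Ep <= E[c_] || runif(1) < exp(-(Ep - E[c_]) / temps[c_]))) {
          x[c_, ] <- xp; E[c_] <- Ep
          acc[c_] <- acc[c_] + 1L; acc_win[c_] <- acc_win[c_] + 1L
        }
      }
      samples[[c_]][s, ] <- x[c_, ]
      losses[s, c_] <- E[c_]
    }
    # proposal adaptation during burn-in only (keeps the post-burn-in chain
    # a proper Markov chain)
    if (cfg$adapt && s <= n_burn && s %% 50 == 0) {
      r <- ifelse(prop_win > 0, acc_win / prop_win, 0.3)
      sigma <- pmin(pmax(sigma * exp(r - 0.3), 1e-3), 2)
      acc_win[] <- 0L; prop_win[] <- 0L
    }
    if (nC > 1 && s %% cfg$swap_interval == 0) {
      for (i in seq_len(nC - 1)) {
        swap_try[i] <- swap_try[i] + 1L
        if (runif(1) < pt_swap_prob(E[i], E[i + 1], temps[i], temps[i + 1])) {
          tmp <- x[i, ]; x[i, ] <- x[i + 1, ]; x[i + 1, ] <- tmp
          tmp <- E[i]; E[i] <- E[i + 1]; E[i + 1] <- tmp
          swap_acc[i] <- swap_acc[i] + 1L
        }
      }
    }
  }

  best <- .pt_argmin(losses)
  best_fit <- with_free(samples[[best["chain"]]][best["step"], ])
  structure(list(
    samples = samples, losses = losses,
    temperatures = temps, free = free,
    n_burn = n_burn,
    accept_rate = ifelse(prop > 0, acc / prop, NA_real_),
    swap_accept_rate = if (nC > 1) swap_acc / pmax(swap_try, 1) else numeric(0),
    proposal_sigma = sigma,
    best_fit = best_fit, best_loss = unname(losses[best["step"], best["chain"]]),
    best_index = best,
    config = cfg
  ), class = "rtk_pt")
}

# argmin over a steps x chains energy matrix; ties break to the earliest
# (chain index, step) pair, lexicographically
.pt_argmin <- function(losses) {
  e <- min(losses)
  if (!is.finite(e)) stop("no finite energy in the run")
  for (c_ in seq_len(ncol(losses))) {
    w <- which(losses[, c_] == e)
    if (length(w)) return(c(chain = c_, step = min(w)))
  }
}

#' Extract the minimum-loss parameter set from a PT run
#'
#' The best fit is the argmin of the loss over all retained samples of all
#' chains; ties break to the earliest (chain index, step).
#'
#' @param result An \code{rtk_pt} from [pt_mcmc()].
#' @return The best-fit \code{rtk_params}.
#' @export
select_best_fit <- function(result) {
  if (!is.finite(result$best_loss)) stop("no finite-loss sample in the run")
  result$best_fit
}

#' Posterior quantiles of the T=1 chain
#'
#' @param result An \code{rtk_pt}.
#' @param probs Quantile probabilities.
#' @param discard_burn Drop the burn-in samples (default).
#' @return Matrix free-parameter x quantile, in log10 units.
#' @export
pt_marginals <- function(result, probs = c(0.05, 0.5, 0.95),
                         discard_burn = TRUE) {
  s <- result$samples[[1]]
  if (discard_burn && result$n_burn > 0 && result$n_burn < nrow(s))
    s <- s[-seq_len(result$n_burn), , drop = FALSE]
  t(apply(s, 2, quantile, probs = probs, names = TRUE))
}

#' @export
print.rtk_pt <- function(x, ...) {
  cat(sprintf("rtk_pt: %d chains x %d steps, %d free parameters\n",
              length(x$samples), nrow(x$losses), length(x$free)))
  cat(sprintf("  best loss %.4g at chain %d, step %d\n",
              x$best_loss, x$best_index["chain"], x$best_index["step"]))
  cat("  acceptance:", paste(sprintf("%.2f", x$accept_rate), collapse = " "),
      "\n")
  if (length(x$swap_accept_rate))
    cat("  swap acceptance:",
        paste(sprintf("%.2f", x$swap_accept_rate), collapse = " "), "\n")
  invisible(x)
}
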