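## Virtual-cell population: Latin hypercube sampling over initial abundances
## and percentile trajectory bands.

#' Default abundance ranges for the virtual population
#'
#' Returns the per-protein (lower, upper) abundance ranges used to draw the
#' virtual-cell ensemble: the fitting bounds of the 14 protein pools. The two
#' ligand amounts are excluded because the stimulation condition sets them;
#' pass a custom range matrix to [lhs_sample()] to vary them too.
#'
#' @param model The model.
#' @return Matrix with columns \code{lower}, \code{upper}; rownames are
#'   abundance parameter names.
#' @export
population_ranges <- function(model) {
  info <- model$param_info
  keep <- info$type == "abundance" & !(info$name %in% c("IGF1_0", "Ins_0"))
  m <- cbind(lower = info$lower[keep], upper = info$upper[keep])
  rownames(m) <- info$name[keep]
  m
}

#' Latin hypercube sample of a virtual-cell population
#'
#' Draws \code{n} abundance vectors by Latin hypercube sampling with
#' log10-uniform marginals: per dimension, exactly one sample falls in each
#' of \code{n} equal-probability strata of the log10-uniform measure.
#' Reproducible from \code{seed}.
#'
#' @param ranges Range matrix as from [population_ranges()] (columns
#'   \code{lower}, \code{upper}, named rows; 0 < lower <= upper). A
#'   degenerate range (lower == upper) yields a constant column with a
#'   warning.
#' @param n Number of virtual cells (>= 1).
#' @param seed RNG seed.
#' @return An \code{rtk_ensemble}: the n x d abundance matrix (mpc) plus the
#'   ranges and seed.
#' @export
lhs_sample <- function(ranges, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  lo <- ranges[, "lower"]; hi <- ranges[, "upper"]
  if (any(lo <= 0) || any(hi < lo)) stop("ranges must satisfy 0 < lower <= upper")
  if (any(hi == lo))
    warning("degenerate range(s): ",
            paste(rownames(ranges)[hi == lo], collapse = ", "),
            " give constant columns")
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(ranges))
  m <- 10^(matrix(log10(lo), n, length(lo), byrow = TRUE) +
           u * matrix(log10(hi) - log10(lo), n, length(lo), byrow = TRUE))
  colnames(m) <- rownames(ranges)
  structure(list(abundances = m, ranges = ranges, seed = seed),
            class = "rtk_ensemble")
}

#' Percentile trajectory bands over a virtual-cell ensemble
#'
#' Simulates every ensemble member under the same condition with shared
#' (best-fit) rate constants, only the initial abundances varying, and
#' returns empirical percentiles (linear interpolation between order
#' statistics) of each observable at each output time. Failed integrations
#' are dropped and counted; more than \code{max_fail_frac} failures abort.
#'
#' @param model The model.
#' @param params Shared rate constants (and defaults for abundances not in
#'   the ensemble).
#' @param ensemble An \code{rtk_ensemble} from [lhs_sample()].
#' @param cond Stimulation condition.
#' @param percentiles Band percentiles (default 5, 15, 85, 95).
#' @param max_fail_frac Abort threshold for the integration-failure fraction.
#' @return An \code{rtk_bands}: per-observable time x percentile matrices,
#'   the time grid, and the failure count.
#' @export
ensemble_bands <- function(model, params, ensemble, cond = rtk_condition(),
                           percentiles = c(5, 15, 85, 95),
                           max_fail_frac = 0.01) {
  m <- ensemble$abundances
  n <- nrow(m)
  obs_names <- names(model$observables)
  vals <- array(NA_real_, c(n, length(cond$output_times), length(obs_names)),
                dimnames = list(NULL, NULL, obs_names))
  failed <- 0L
  for (i in seq_len(n)) {
    p_i <- set_params(params, m[i, ])
    tr <- tryCatch(simulate_model(model, p_i, cond), error = function(e) NULL)
    if (is.null(tr)) { failed <- failed + 1L; next }
    vals[i, , ] <- tr$observables
  }
  if (failed > max_fail_frac * n)
    stop(sprintf("%d/%d ensemble integrations failed (> %.1f%%)",
                 failed, n, 100 * max_fail_frac))
  bands <- lapply(obs_names, function(ob) {
    b <- t(apply(vals[, , ob, drop = FALSE], 2, quantile,
                 probs = percentiles / 100, na.rm = TRUE, type = 7))
    colnames(b) <- paste0("p", percentiles)
    b
  })
  names(bands) <- obs_names
  structure(list(bands = bands, times = cond$output_times,
                 percentiles = percentiles, n = n, n_failed = failed,
                 condition = cond),
            class = "rtk_bands")
}

#' @export
print.rtk_ensemble <- function(x, ...) {
  cat(sprintf("rtk_ensemble: %d virtual cells x %d abundances (seed %s)\n",
              nrow(x$abundances), ncol(x$abundances), format(x$seed)))
  invisible(x)
}

#' @export
print.rtk_bands <- function(x, ...) {
  cat(sprintf("rtk_bands: %s percentiles over %d cells (%d failed), %d times\n",
              paste(x$percentiles, collapse = "/"), x$n, x$n_failed,
              length(x$times)))
  invisible(x)
}
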