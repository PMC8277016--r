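## Plain-text serialization: reaction tables and trajectories as CSV,
## parameter sets and manifests as JSON, RPPA tables as CSV. Everything
## round-trips (bit-exact for strings/integers, 1e-12 relative for reals).

.rppa_columns <- c("condition", "ligand", "dose_nM", "observable",
                   "time_min", "value", "sem", "n_reps")

#' Reaction-table CSV round-trip
#'
#' Columns: \code{id, kind, reactants, products, modifier, rate_param, arm}
#' with semicolon-joined species lists, matching the model's internal table
#' exactly.
#'
#' @param model An \code{rtk_model} (write) .
#' @param path CSV path.
#' @return \code{read_model_csv} returns the reaction table (data frame);
#'   rebuild a model with [model_from_reactions()].
#' @export
write_model_csv <- function(model, path) {
  write.csv(model$reactions, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_model_csv
#' @export
read_model_csv <- function(path) {
  rx <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "kind", "reactants", "products", "modifier", "rate_param", "arm")
  missing <- setdiff(need, names(rx))
  if (length(missing))
    stop("reaction CSV is missing column(s): ", paste(missing, collapse = ", "))
  rx$modifier[is.na(rx$modifier)] <- ""
  rx$products[is.na(rx$products)] <- ""
  rx[, need]
}

#' Parameter-set JSON round-trip
#'
#' JSON object with a \code{values} map (name -> value) and a \code{bounds}
#' block (name -> [lower, upper]). Values are written at full precision.
#'
#' @param params An \code{rtk_params} (write).
#' @param path JSON path.
#' @param model Model used to validate on read.
#' @export
write_params_json <- function(params, path) {
  obj <- list(values = as.list(params$values),
              bounds = setNames(
                lapply(rownames(params$bounds), function(n)
                  unname(params$bounds[n, ])),
                rownames(params$bounds)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path, model) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  values <- unlist(obj$values)
  bounds <- do.call(rbind, obj$bounds)
  colnames(bounds) <- c("lower", "upper")
  rtk_params(values, model, bounds = bounds)
}

#' RPPA-table CSV round-trip
#'
#' Schema: \code{condition, ligand, dose_nM, observable, time_min, value,
#' sem, n_reps}. Reading validates the schema and reports missing columns by
#' name.
#'
#' @param data RPPA data frame (write).
#' @param path CSV path.
#' @export
write_rppa_csv <- function(data, path) {
  stopifnot(all(.rppa_columns %in% names(data)))
  write.csv(data[, .rppa_columns], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_rppa_csv
#' @export
read_rppa_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.rppa_columns, names(d))
  if (length(missing))
    stop("RPPA CSV is missing column(s): ", paste(missing, collapse = ", "))
  bad_obs <- setdiff(unique(d$observable),
                     c("pReceptor", "pAkt", "pRPS6K", "pMAPK"))
  if (length(bad_obs))
    stop("unknown observable(s): ", paste(bad_obs, collapse = ", "))
  if (any(d$sem < 0, na.rm = TRUE)) stop("sem must be >= 0")
  d[, .rppa_columns]
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns \code{time, name, value, kind} where kind is
#' \code{state} or \code{observable}.
#'
#' @param traj An \code{rtk_traj}.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- function(m, kind) data.frame(
    time = rep(traj$times, ncol(m)),
    name = rep(colnames(m), each = nrow(m)),
    value = as.vector(m), kind = kind, stringsAsFactors = FALSE)
  write.csv(rbind(long(traj$states, "state"),
                  long(traj$observables, "observable")),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a percentile-band table as CSV
#'
#' Columns: observable, time, then one column per percentile (p5, p15, ...).
#' @param bands An \code{rtk_bands}.
#' @param path CSV path.
#' @export
write_bands_csv <- function(bands, path) {
  rows <- do.call(rbind, lapply(names(bands$bands), function(ob)
    data.frame(observable = ob, time = bands$times, bands$bands[[ob]],
               check.names = FALSE, stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, configuration, seed, input-file hashes, output files
#' and status of a run, so that an output directory is reproducible from its
#' manifest.
#'
#' @param path Manifest JSON path.
#' @param command Command name.
#' @param config Configuration list (as parsed).
#' @param seed Seed used for any randomness (or NULL).
#' @param inputs Character vector of input file paths (hashed).
#' @param outputs Character vector of output file names.
#' @param status Integer exit status.
#' @export
write_manifest <- function(path, command, config = list(), seed = NULL,
                           inputs = character(0), outputs = character(0),
                           status = 0L) {
  inputs <- as.character(unlist(inputs))
  manifest <- list(
    command = command,
    config = config,
    config_md5 = .rtk_hash(unlist(config)),
    seed = seed,
    inputs = as.list(setNames(
      unname(tools::md5sum(inputs)), basename(inputs))),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("dualRTK")),
    status = status)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
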