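## Network model: species pools, reaction table, validation, RHS compilation.
##
## Units: time in minutes, abundances in molecules per cell (mpc).
## Unary rate constants are 1/min, binary ones 1/(mpc*min).

# canonical state ordering; receptor states: free, ligand-bound,
# phosphorylated (surface), phosphorylated internalized (ligand still bound)
.rtk_states <- c(
  "IGF1", "Ins",
  "IGF1R", "IGF1R_L", "pIGF1R_L", "pIGF1R_Li",
  "InsR", "InsR_L", "pInsR_L", "pInsR_Li",
  "IRS", "pIRS", "SOS", "aSOS", "Ras", "aRas", "Raf", "aRaf",
  "MEK", "aMEK", "MAPK", "pMAPK", "PI3K", "aPI3K", "PDK1", "aPDK1",
  "Akt", "pAkt", "TSC2", "pTSC2", "mTORC1", "amTORC1", "RPS6K", "pRPS6K"
)

.rtk_observables <- list(
  pReceptor = c("pIGF1R_L", "pIGF1R_Li", "pInsR_L", "pInsR_Li"),
  pAkt      = "pAkt",
  pRPS6K    = "pRPS6K",
  pMAPK     = "pMAPK"
)

# species pools: protein pools are conserved along any trajectory; the two
# ligand pools lose mass through clearance of free ligand and degradation of
# receptor-bound ligand on recycling
.rtk_pools <- function() {
  pool <- function(name, role, states, total_param, conserved) {
    list(name = name, role = role, states = states,
         total_param = total_param, conserved = conserved)
  }
  two <- function(name, role, inactive, active) {
    pool(name, role, c(inactive, active), paste0(name, "_0"), TRUE)
  }
  list(
    pool("IGF1", "ligand", c("IGF1", "IGF1R_L", "pIGF1R_L", "pIGF1R_Li"),
         "IGF1_0", FALSE),
    pool("Ins", "ligand", c("Ins", "InsR_L", "pInsR_L", "pInsR_Li"),
         "Ins_0", FALSE),
    pool("IGF1R", "receptor", c("IGF1R", "IGF1R_L", "pIGF1R_L", "pIGF1R_Li"),
         "IGF1R_0", TRUE),
    pool("InsR", "receptor", c("InsR", "InsR_L", "pInsR_L", "pInsR_Li"),
         "InsR_0", TRUE),
    two("IRS", "adaptor", "IRS", "pIRS"),
    two("SOS", "adaptor", "SOS", "aSOS"),
    two("Ras", "regulator", "Ras", "aRas"),
    two("Raf", "kinase", "Raf", "aRaf"),
    two("MEK", "kinase", "MEK", "aMEK"),
    two("MAPK", "kinase", "MAPK", "pMAPK"),
    two("PI3K", "kinase", "PI3K", "aPI3K"),
    two("PDK1", "kinase", "PDK1", "aPDK1"),
    two("Akt", "kinase", "Akt", "pAkt"),
    two("TSC2", "regulator", "TSC2", "pTSC2"),
    two("mTORC1", "kinase", "mTORC1", "amTORC1"),
    two("RPS6K", "kinase", "RPS6K", "pRPS6K")
  )
}

# reaction table. kind "unary": flux = k * [reactant]; kind "binary": flux =
# k * [reactant1] * ([reactant2] or [modifier]); a modifier is catalytic and
# not consumed. Empty products encode degradation (ligand clearance).
.rtk_reactions <- function() {
  rows <- list()
  rx <- function(id, kind, reactants, products, modifier, rate_param, arm) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, kind = kind,
      reactants = paste(reactants, collapse = ";"),
      products = paste(products, collapse = ";"),
      modifier = if (is.null(modifier)) "" else modifier,
      rate_param = rate_param, arm = arm,
      stringsAsFactors = FALSE)
  }
  cat_rx <- function(id, substrate, product, modifier, rate_param, arm = "shared") {
    rx(id, "binary", substrate, product, modifier, rate_param, arm)
  }

  arm <- function(tag, L, R, RL, pRL, pRLi) {
    sfx <- tolower(tag)
    rx(paste0("bind_", sfx), "binary", c(L, R), RL, NULL, paste0("kon_", sfx), tag)
    rx(paste0("unbind_", sfx), "unary", RL, c(L, R), NULL, paste0("koff_", sfx), tag)
    rx(paste0("phos_", sfx), "unary", RL, pRL, NULL, paste0("kphos_", sfx), tag)
    rx(paste0("dephos_", sfx), "unary", pRL, RL, NULL, paste0("kdephos_", sfx), tag)
    rx(paste0("int_", sfx), "unary", pRL, pRLi, NULL, paste0("kint_", sfx), tag)
    # recycling returns the receptor to the surface; the bound ligand is degraded
    rx(paste0("rec_", sfx), "unary", pRLi, R, NULL, paste0("krec_", sfx), tag)
    cat_rx(paste0("irs_", sfx), "IRS", "pIRS", pRL, paste0("kirs_", sfx), tag)
    cat_rx(paste0("sos_", sfx), "SOS", "aSOS", pRL, paste0("ksos_", sfx), tag)
  }
  arm("IGF1", "IGF1", "IGF1R", "IGF1R_L", "pIGF1R_L", "pIGF1R_Li")
  arm("Ins", "Ins", "InsR", "InsR_L", "pInsR_L", "pInsR_Li")

  # shared downstream cascades (activation/deactivation pairs)
  cat_rx("sos_irs", "SOS", "aSOS", "pIRS", "k7")
  rx("sos_off", "unary", "aSOS", "SOS", NULL, "kr_sos", "shared")
  cat_rx("ras_on", "Ras", "aRas", "aSOS", "k_ras")
  rx("ras_off", "unary", "aRas", "Ras", NULL, "kr_ras", "shared")
  cat_rx("raf_on", "Raf", "aRaf", "aRas", "k_raf")
  rx("raf_off", "unary", "aRaf", "Raf", NULL, "kr_raf", "shared")
  cat_rx("mek_on", "MEK", "aMEK", "aRaf", "k_mek")
  rx("mek_off", "unary", "aMEK", "MEK", NULL, "kr_mek", "shared")
  cat_rx("mapk_on", "MAPK", "pMAPK", "aMEK", "k_mapk")
  rx("mapk_off", "unary", "pMAPK", "MAPK", NULL, "kr_mapk", "shared")
  cat_rx("pi3k_on", "PI3K", "aPI3K", "pIRS", "k_pi3k")
  rx("pi3k_off", "unary", "aPI3K", "PI3K", NULL, "kr_pi3k", "shared")
  cat_rx("pdk1_on", "PDK1", "aPDK1", "aPI3K", "k_pdk1")   # LY294002 target
  rx("pdk1_off", "unary", "aPDK1", "PDK1", NULL, "kr_pdk1", "shared")
  cat_rx("akt_on", "Akt", "pAkt", "aPDK1", "k_akt")
  rx("akt_off", "unary", "pAkt", "Akt", NULL, "kr_akt", "shared")
  cat_rx("tsc2_on", "TSC2", "pTSC2", "pAkt", "k_tsc2")
  rx("tsc2_off", "unary", "pTSC2", "TSC2", NULL, "kr_tsc2", "shared")
  cat_rx("mtorc1_on", "mTORC1", "amTORC1", "pTSC2", "k_mtorc1")
  rx("mtorc1_off", "unary", "amTORC1", "mTORC1", NULL, "kr_mtorc1", "shared")
  cat_rx("s6k_on", "RPS6K", "pRPS6K", "amTORC1", "k_s6k") # 2nd BEZ235 target
  rx("s6k_off", "unary", "pRPS6K", "RPS6K", NULL, "kr_s6k", "shared")
  rx("irs_off", "unary", "pIRS", "IRS", NULL, "kr_irs", "shared")

  # IRS-centered negative feedback
  cat_rx("fb_s6k_irs", "pIRS", "IRS", "pRPS6K", "kf203")
  cat_rx("fb_akt_irs", "pIRS", "IRS", "pAkt", "kf208")

  # literature-motivated shared crosstalk (individually removable)
  cat_rx("fb_mapk_sos", "aSOS", "SOS", "pMAPK", "kf_mapk_sos")
  cat_rx("fb_mapk_irs", "pIRS", "IRS", "pMAPK", "kf_mapk_irs")
  cat_rx("ras_pi3k", "PI3K", "aPI3K", "aRas", "k_ras_pi3k")
  cat_rx("fb_akt_raf", "aRaf", "Raf", "pAkt", "kf_akt_raf")
  cat_rx("tsc2_mtorc1", "amTORC1", "mTORC1", "TSC2", "k_tsc2_mtorc1")
  cat_rx("pdk1_s6k", "RPS6K", "pRPS6K", "aPDK1", "k_pdk1_s6k")
  cat_rx("pi3k_ras", "Ras", "aRas", "aPI3K", "k_pi3k_ras")

  # shared free-ligand clearance and internalized-receptor
  # dephosphorylation/recycling (one rate parameter each, two instances)
  rx("clear_igf1", "unary", "IGF1", character(0), NULL, "k_lclear", "shared")
  rx("clear_ins", "unary", "Ins", character(0), NULL, "k_lclear", "shared")
  rx("rint_igf1", "unary", "pIGF1R_Li", "IGF1R", NULL, "kr_rint", "shared")
  rx("rint_ins", "unary", "pInsR_Li", "InsR", NULL, "kr_rint", "shared")

  do.call(rbind, rows)
}

#' Build the reference dual IGF1R/InsR reaction network
#'
#' Assembles the packaged network: 14 protein pools plus the two ligands
#' (16 initial-abundance parameters) and 50 rate constants, of which 34 are
#' shared between the two receptor arms and 8 are specific to each arm.
#' Each arm comprises reversible ligand binding, receptor
#' auto-phosphorylation and dephosphorylation, internalization, recycling
#' with degradation of the bound ligand, and receptor-mediated activation of
#' IRS and SOS. The shared part carries the Ras/Raf/MEK/MAPK and
#' PI3K/PDK1/Akt/TSC2/mTORC1/RPS6K cascades, IRS dephosphorylation, the
#' RPS6K-to-IRS (\code{kf203}) and Akt-to-IRS (\code{kf208}) negative
#' feedback loops, and a set of literature-motivated crosstalk edges.
#'
#' @param reactions Optional reaction table (as returned by
#'   [read_model_csv()]) replacing the packaged one; counts are re-validated.
#' @return An object of class \code{rtk_model}: pools, reaction table,
#'   parameter info with bounds, observables, and compiled flux indices.
#' @seealso [validate_model()], [compile_rhs()], [simulate_model()]
#' @export
#' @examples
#' m <- build_reference_model()
#' m$n_parameters          # 66
#' table(m$param_info$arm)
build_reference_model <- function(reactions = NULL) {
  if (is.null(reactions)) reactions <- .rtk_reactions()
  model_from_reactions(reactions)
}

#' Assemble a model object from a reaction table
#'
#' Lower-level constructor behind [build_reference_model()]: combines a
#' reaction table with the packaged species pools and observable definitions,
#' derives parameter metadata and default bounds, compiles flux indices, and
#' validates the result.
#'
#' @param reactions Reaction table with columns
#'   \code{id, kind, reactants, products, modifier, rate_param, arm}.
#' @param check If \code{TRUE} (default) run [validate_model()]; structural
#'   count checks can be skipped for deliberately reduced networks.
#' @return An \code{rtk_model} object.
#' @export
model_from_reactions <- function(reactions, check = TRUE) {
  pools <- .rtk_pools()
  states <- .rtk_states
  stopifnot(is.data.frame(reactions))
  reactions <- reactions[, c("id", "kind", "reactants", "products",
                             "modifier", "rate_param", "arm")]

  rate_ids <- unique(reactions$rate_param)
  abundance_ids <- vapply(pools, `[[`, "", "total_param")
  # a rate parameter is binary iff any of its reactions has two flux factors
  idx <- .rtk_indices(reactions, states)
  is_binary <- tapply(idx$f2 > 0, reactions$rate_param, any)[rate_ids]
  arm_of <- tapply(reactions$arm, reactions$rate_param,
                   function(a) a[[1]])[rate_ids]

  param_info <- rbind(
    data.frame(name = rate_ids, type = "rate",
               kind = ifelse(is_binary, "binary", "unary"),
               arm = unname(arm_of), stringsAsFactors = FALSE),
    data.frame(name = abundance_ids, type = "abundance", kind = "abundance",
               arm = "abundance", stringsAsFactors = FALSE)
  )
  param_info$lower <- ifelse(param_info$type == "abundance", 1e3,
                             ifelse(param_info$kind == "binary", 1e-9, 1e-6))
  param_info$upper <- ifelse(param_info$type == "abundance", 1e6,
                             ifelse(param_info$kind == "binary", 1e-1, 1e2))
  # ligand amounts are set by the stimulation condition, down to zero
  param_info$lower[param_info$name %in% c("IGF1_0", "Ins_0")] <- 0
  param_info$upper[param_info$name %in% c("IGF1_0", "Ins_0")] <- 1e7

  model <- structure(list(
    states = states,
    pools = pools,
    reactions = reactions,
    observables = .rtk_observables,
    param_info = param_info,
    n_parameters = nrow(param_info),
    indices = idx
  ), class = "rtk_model")
  if (check) validate_model(model)
  model
}

# flux/stoichiometry indices: f1/f2 are 1-based state indices of the two flux
# factors (f2 = 0 for unary), triplets give signed stoichiometry
.rtk_indices <- function(reactions, states) {
  n <- nrow(reactions)
  f1 <- integer(n); f2 <- integer(n)
  tr_reac <- integer(0); tr_state <- integer(0); tr_coef <- numeric(0)
  split_states <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  }
  lookup <- function(nm, what, id) {
    i <- match(nm, states)
    if (anyNA(i)) stop("unknown ", what, " species '", nm[is.na(i)][1],
                       "' in reaction '", id, "'")
    i
  }
  for (j in seq_len(n)) {
    re <- split_states(reactions$reactants[j])
    pr <- split_states(reactions$products[j])
    mo <- split_states(reactions$modifier[j])
    ri <- lookup(re, "reactant", reactions$id[j])
    pi <- if (length(pr)) lookup(pr, "product", reactions$id[j]) else integer(0)
    mi <- if (length(mo)) lookup(mo, "modifier", reactions$id[j]) else integer(0)
    f1[j] <- ri[1]
    f2[j] <- if (length(ri) == 2) ri[2] else if (length(mi)) mi[1] else 0L
    for (s in ri) { tr_reac <- c(tr_reac, j); tr_state <- c(tr_state, s); tr_coef <- c(tr_coef, -1) }
    for (s in pi) { tr_reac <- c(tr_reac, j); tr_state <- c(tr_state, s); tr_coef <- c(tr_coef, +1) }
  }
  list(f1 = f1, f2 = f2,
       tr_reac = tr_reac, tr_state = tr_state, tr_coef = tr_coef)
}

#' Validate the structural invariants of a model
#'
#' Checks the printed structural counts (66 parameters of which 16 are
#' initial abundances; 34 shared, 8 IGF1-arm and 8 Ins-arm rate constants;
#' 14 protein pools plus 2 ligand pools), reaction shapes (unary reactions
#' have one reactant; binary reactions have two reactants or one reactant
#' plus a catalytic modifier), per-pool mass conservation by construction,
#' and connectivity from each ligand to every observable.
#'
#' @param model An \code{rtk_model}.
#' @param counts Check the reference structural counts (disable for reduced
#'   networks built with [model_from_reactions()]).
#' @return Invisibly \code{TRUE}; a model-integrity error otherwise.
#' @export
validate_model <- function(model, counts = TRUE) {
  fail <- function(...) stop("model integrity: ", ..., call. = FALSE)
  pi_ <- model$param_info
  rx <- model$reactions
  if (anyDuplicated(model$states)) fail("duplicated state labels")
  if (anyDuplicated(rx$id)) fail("duplicated reaction ids")

  # pool bookkeeping: every pool names exactly one abundance parameter
  tp <- vapply(model$pools, `[[`, "", "total_param")
  if (anyDuplicated(tp)) fail("pools share a total-abundance parameter")
  if (!all(tp %in% pi_$name[pi_$type == "abundance"]))
    fail("pool total parameter missing from the parameter table")
  for (p in model$pools)
    if (anyDuplicated(p$states)) fail("duplicate state labels in pool ", p$name)

  if (counts) {
    n_ab <- sum(pi_$type == "abundance")
    n_rate <- sum(pi_$type == "rate")
    arm_counts <- table(pi_$arm[pi_$type == "rate"])
    if (n_ab != 16L) fail("expected 16 abundance parameters, got ", n_ab)
    if (n_rate != 50L) fail("expected 50 rate parameters, got ", n_rate)
    if (nrow(pi_) != 66L) fail("expected 66 parameters, got ", nrow(pi_))
    if (!identical(as.integer(arm_counts[c("shared", "IGF1", "Ins")]),
                   c(34L, 8L, 8L)))
      fail("rate-parameter arm partition is not 34 shared + 8 IGF1 + 8 Ins")
    n_prot <- sum(vapply(model$pools, function(p) p$role != "ligand", TRUE))
    n_lig <- sum(vapply(model$pools, function(p) p$role == "ligand", TRUE))
    if (n_prot != 14L || n_lig != 2L)
      fail("expected 14 protein pools and 2 ligand pools")
  }

  # reaction shape
  nre <- lengths(strsplit(rx$reactants, ";", fixed = TRUE))
  has_mod <- nzchar(rx$modifier)
  bad <- (rx$kind == "unary" & (nre != 1L | has_mod)) |
         (rx$kind == "binary" & !((nre == 2L & !has_mod) | (nre == 1L & has_mod)))
  if (any(bad)) fail("malformed reactions: ", paste(rx$id[bad], collapse = ", "))

  # conservation by construction: net stoichiometry of every reaction over
  # each conserved pool's states is zero
  S <- stoichiometry_matrix(model)
  for (p in model$pools) {
    if (!p$conserved) next
    net <- colSums(S[p$states, , drop = FALSE])
    if (any(net != 0))
      fail("pool ", p$name, " not conserved by reaction(s) ",
           paste(rx$id[net != 0], collapse = ", "))
  }

  # connectivity: a path must exist from each ligand to every observable
  for (lig in c("IGF1", "Ins")) {
    reach <- .rtk_reachable(model, lig)
    for (ob in names(model$observables))
      if (!any(model$observables[[ob]] %in% reach))
        fail("no path from ", lig, " to observable ", ob)
  }
  invisible(TRUE)
}

#' Signed stoichiometry matrix of a model
#'
#' @param model An \code{rtk_model}.
#' @return A states x reactions matrix of net stoichiometric coefficients
#'   (catalytic modifiers contribute zero).
#' @export
stoichiometry_matrix <- function(model) {
  idx <- model$indices
  S <- matrix(0, length(model$states), nrow(model$reactions),
              dimnames = list(model$states, model$reactions$id))
  for (m in seq_along(idx$tr_reac))
    S[idx$tr_state[m], idx$tr_reac[m]] <-
      S[idx$tr_state[m], idx$tr_reac[m]] + idx$tr_coef[m]
  S
}

# states reachable from `from` following reactant/modifier -> product edges
.rtk_reachable <- function(model, from) {
  rx <- model$reactions
  edges <- list()
  for (j in seq_len(nrow(rx))) {
    src <- c(strsplit(rx$reactants[j], ";", fixed = TRUE)[[1]],
             if (nzchar(rx$modifier[j])) rx$modifier[j])
    dst <- if (nzchar(rx$products[j]))
      strsplit(rx$products[j], ";", fixed = TRUE)[[1]] else character(0)
    for (s in src) edges[[s]] <- unique(c(edges[[s]], dst))
  }
  seen <- from
  queue <- from
  while (length(queue)) {
    nxt <- unique(unlist(edges[queue], use.names = FALSE))
    queue <- setdiff(nxt, seen)
    seen <- c(seen, queue)
  }
  seen
}

#' Compile the model to an ODE right-hand side function
#'
#' Returns an R closure evaluating the mass-action derivative vector: each
#' reaction contributes a flux \code{k * [reactant]} (unary) or
#' \code{k * [reactant] * [co-reactant or modifier]} (binary), accumulated
#' with signed stoichiometry. This is the portable reference evaluator; the
#' integrator normally uses the equivalent compiled-C evaluator
#' (see [simulate_model()]).
#'
#' @param model An \code{rtk_model}.
#' @param params An \code{rtk_params} parameter set (all rate parameters
#'   present; unknown or missing ids are an error at compile time).
#' @return \code{function(t, state)} returning the named derivative vector.
#' @export
#' @examples
#' m <- build_reference_model()
#' p <- reference_params()
#' rhs <- compile_rhs(m, p)
#' d0 <- rhs(0, setNames(numeric(length(m$states)), m$states))
#' all(d0 == 0)  # zero state is a fixed point
compile_rhs <- function(model, params) {
  k <- reaction_rates(model, params)
  idx <- model$indices
  n_state <- length(model$states)
  state_names <- model$states
  neg_floor <- -1e-6 * max(c(param_values(params)[
    model$param_info$name[model$param_info$type == "abundance"]], 1))
  function(t, state) {
    if (length(state) != n_state) stop("state vector length mismatch")
    if (min(state) < neg_floor)
      stop("negative state input (solver misconfiguration?)")
    f <- k * state[idx$f1]
    two <- idx$f2 > 0L
    f[two] <- f[two] * state[idx$f2[two]]
    d <- numeric(n_state)
    for (m in seq_along(idx$tr_reac))
      d[idx$tr_state[m]] <- d[idx$tr_state[m]] + idx$tr_coef[m] * f[idx$tr_reac[m]]
    names(d) <- state_names
    d
  }
}

# per-reaction rate constants from a parameter set
reaction_rates <- function(model, params) {
  v <- param_values(params)
  i <- match(model$reactions$rate_param, names(v))
  if (anyNA(i))
    stop("unknown rate parameter id: ",
         paste(unique(model$reactions$rate_param[is.na(i)]), collapse = ", "))
  unname(v[i])
}

#' Conservation check on a simulated trajectory
#'
#' For every conserved protein pool, reports the maximum relative drift of
#' the pool's state sum from its initial-abundance total along the
#' trajectory. Ligand pools are exempt (free-ligand clearance and
#' internalized-ligand degradation are the model's only non-conserving
#' reactions); their totals are attached as an attribute for inspection.
#'
#' @param model The \code{rtk_model} the trajectory came from.
#' @param traj An \code{rtk_traj} from [simulate_model()].
#' @return Named vector of per-pool maximum relative drifts, with attribute
#'   \code{ligand_totals} (time x ligand-pool matrix of pool sums).
#' @export
check_conservation <- function(model, traj) {
  if (!all(model$states %in% colnames(traj$states)))
    stop("trajectory state labels do not match the model")
  totals <- traj$abundances
  drift <- c()
  lig <- NULL
  for (p in model$pools) {
    s <- rowSums(traj$states[, p$states, drop = FALSE])
    if (p$conserved) {
      tot <- totals[[p$total_param]]
      drift[p$name] <- if (tot > 0) max(abs(s - tot)) / tot else max(abs(s))
    } else {
      lig <- cbind(lig, s)
      colnames(lig)[ncol(lig)] <- p$name
    }
  }
  structure(drift, ligand_totals = lig)
}

#' @export
print.rtk_model <- function(x, ...) {
  pi_ <- x$param_info
  cat("rtk_model: dual IGF1R/InsR mass-action network\n")
  cat(sprintf("  %d species states, %d reactions\n",
              length(x$states), nrow(x$reactions)))
  cat(sprintf("  %d parameters: %d abundances + %d rates (%d shared, %d IGF1, %d Ins)\n",
              nrow(pi_), sum(pi_$type == "abundance"), sum(pi_$type == "rate"),
              sum(pi_$arm == "shared"), sum(pi_$arm == "IGF1"),
              sum(pi_$arm == "Ins")))
  cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}
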