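# shared fixtures, memoised per test run (the model is a constant and the
# reference parameters ship with the package)
.fix <- new.env()

fix_model <- function() {
  if (is.null(.fix$model)) .fix$model <- build_reference_model()
  .fix$model
}

fix_params <- function() {
  if (is.null(.fix$params)) .fix$params <- reference_params(fix_model())
  .fix$params
}

early_cond <- function(ligand = "IGF1", dose = 10) {
  rtk_condition(ligand, dose, output_times = c(0, 5, 10, 30))
}

# independent flux-accumulation oracle: walks the reaction table row by row
# and accumulates signed mass-action fluxes term by term (no shared code with
# compile_rhs, which works off precompiled index vectors)
oracle_rhs <- function(model, params, y) {
  v <- param_values(params)
  d <- setNames(numeric(length(y)), names(y))
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    re <- strsplit(r$reactants, ";", fixed = TRUE)[[1]]
    flux <- v[[r$rate_param]] * prod(y[re])
    if (nzchar(r$modifier)) flux <- flux * y[[r$modifier]]
    for (s in re) d[s] <- d[s] - flux
    if (nzchar(r$products))
      for (s in strsplit(r$products, ";", fixed = TRUE)[[1]])
        d[s] <- d[s] + flux
  }
  d
}

# free-parameter subset and per-parameter priors used by the recovery tests:
# parameters with distinct kinetic signatures, bounded two decades either
# side of truth (literature-range-style per-parameter boxes)
recovery_free <- function() {
  c("kint_igf1", "kon_ins", "kirs_ins", "kr_mapk", "k_akt", "kr_s6k")
}

recovery_init <- function(truth = fix_params()) {
  free <- recovery_free()
  truth$bounds[free, "lower"] <- param_values(truth)[free] / 100
  truth$bounds[free, "upper"] <- param_values(truth)[free] * 100
  truth
}
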