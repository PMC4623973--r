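# Microstate energies of the discrete protonation Hamiltonian.
#
# G(x, c, pH) = base_energy(c)
#             + sum_i x_i * [ kT*ln10*(pH - pKa_ref_i) + shift_i(c) ]
#             + sum_{i<j} coupling_ij(c) * x_i * x_j
#
# so that the energy difference of a single deprotonated -> protonated flip is
# the transition free energy kT*ln10*(pH - pKa_ref) plus the discrete
# relative-electrostatics terms (intrinsic shift + couplings to currently
# protonated neighbours). The fully deprotonated state in a zero-base-energy
# conformer has energy 0.

#' Energy of a protonation microstate
#'
#' @param model A validated [system_model()].
#' @param state A [microstate()].
#' @param pH Solution pH (dimensionless, finite).
#' @return Energy in kcal/mol.
#' @export
microstate_energy <- function(model, state, pH) {
  model <- validate_model(model)
  .check_state(model, state)
  if (!is.finite(pH)) stop("pH must be finite")
  ci <- .conf_index(model, state$conformer)
  x <- as.numeric(state$protonation)
  e <- model$conformers$base_energy[ci] +
    sum(x * (model$thermo$kT_ln10 * (pH - model$sites$pKa_ref) + model$shift[, ci]))
  if (any(x > 0)) e <- e + 0.5 * drop(x %*% model$cmat[[ci]] %*% x)
  e
}

#' Transition free energy of a single protonation flip
#'
#' Returns the deprotonated -> protonated transition free energy for one site
#' given the rest of the microstate:
#' `kT*ln10*(pH - pKa_ref) + shift(conformer) + sum_j coupling_ij * x_j`.
#' The energy change of the move actually available from `state` is this
#' value if the site is currently deprotonated and its negative otherwise.
#'
#' @inheritParams microstate_energy
#' @param site_id Which site to flip.
#' @return A list with `cost` (deprotonated -> protonated, kcal/mol) and
#'   `delta_g` (the energy change of flipping the site from its current
#'   occupancy).
#' @export
protonation_flip_cost <- function(model, state, site_id, pH) {
  model <- validate_model(model)
  .check_state(model, state)
  i <- match(site_id, model$sites$site_id)
  if (is.na(i)) stop(sprintf("unknown site_id '%s'", site_id))
  ci <- .conf_index(model, state$conformer)
  x <- as.numeric(state$protonation)
  cost <- model$thermo$kT_ln10 * (pH - model$sites$pKa_ref[i]) +
    model$shift[i, ci] + sum(model$cmat[[ci]][i, -i] * x[-i])
  list(cost = cost, delta_g = if (x[i] > 0) -cost else cost)
}
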