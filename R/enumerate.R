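# Exact (brute-force) statistical mechanics over the enumerable microstate
# space: semi-grand-ensemble probabilities at fixed pH, per-site deprotonated
# fractions, mean bound protons, conformer populations, and the logarithm of
# the binding polynomial. These serve as the oracles the Monte Carlo engine
# is tested against.

.max_states <- 2^22

# internal: full state space at one pH.
# Returns list(bits [2^n x n], conf_idx, energy, logp) over 2^n * n_conf rows
# (protonation block repeated per conformer).
.state_space <- function(model, pH) {
  model <- validate_model(model)
  n <- nrow(model$sites)
  nc <- nrow(model$conformers)
  if (2^n * nc > .max_states) {
    stop(sprintf("state space too large to enumerate: 2^%d x %d > 2^22", n, nc))
  }
  bits <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(bits) <- model$sites$site_id
  mu <- model$thermo$kT_ln10 * (pH - model$sites$pKa_ref)
  energy <- numeric(0)
  for (ci in seq_len(nc)) {
    e <- model$conformers$base_energy[ci] +
      drop(bits %*% (mu + model$shift[, ci])) +
      0.5 * rowSums((bits %*% model$cmat[[ci]]) * bits)
    energy <- c(energy, e)
  }
  logw <- -energy / model$thermo$kT
  logz <- .logsumexp(logw)
  list(bits = bits,
       conf_idx = rep(seq_len(nc), each = 2^n),
       energy = energy,
       logp = logw - logz,
       logz = logz)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact microstate probabilities at fixed pH
#'
#' Enumerates every protonation bit-vector x conformer combination and
#' returns Boltzmann probabilities proportional to `exp(-G/kT)`. Guarded to
#' state spaces of at most 2^22 microstates.
#'
#' @param model A [system_model()].
#' @param pH Solution pH (scalar).
#' @return A data frame with columns `conformer`, `protonation` (0/1 string
#'   in canonical site order, leftmost character = first site), `energy`
#'   (kcal/mol) and `prob`; probabilities sum to 1.
#' @export
enumerate_states <- function(model, pH) {
  model <- validate_model(model)
  ss <- .state_space(model, pH)
  pat <- apply(ss$bits, 1L, paste, collapse = "")
  data.frame(
    conformer = model$conformers$conformer_id[ss$conf_idx],
    protonation = rep(pat, nrow(model$conformers)),
    energy = ss$energy,
    prob = exp(ss$logp),
    stringsAsFactors = FALSE
  )
}

#' Exact deprotonated fraction of a site
#'
#' @param model A [system_model()].
#' @param pH Numeric vector of pH values.
#' @param site_id Site to query.
#' @return Fraction of the exact ensemble with that site deprotonated, one
#'   value per element of `pH`.
#' @export
exact_site_fraction <- function(model, pH, site_id) {
  model <- validate_model(model)
  i <- match(site_id, model$sites$site_id)
  if (is.na(i)) stop(sprintf("unknown site_id '%s'", site_id))
  vapply(pH, function(p) {
    ss <- .state_space(model, p)
    sum(exp(ss$logp)[rep(ss$bits[, i] == 0, nrow(model$conformers))])
  }, numeric(1))
}

#' Exact mean number of bound titratable protons
#'
#' The proton-count curve Z(pH) entering the Wyman linkage relation; constant
#' offsets (acid vs base charge conventions) cancel in differences of Z
#' between species, so Z is reported simply as the mean count of protonated
#' sites.
#'
#' @inheritParams exact_site_fraction
#' @return Mean bound protons, one value per element of `pH`; between 0 and
#'   the number of sites.
#' @export
exact_mean_protons <- function(model, pH) {
  model <- validate_model(model)
  vapply(pH, function(p) {
    ss <- .state_space(model, p)
    pr <- exp(ss$logp)
    sum(pr * rep(rowSums(ss$bits), nrow(model$conformers)))
  }, numeric(1))
}

#' Exact conformer populations versus pH
#'
#' @inheritParams exact_site_fraction
#' @return A data frame with columns `pH`, `conformer`, `population`;
#'   populations sum to 1 at each pH.
#' @export
exact_conformer_populations <- function(model, pH) {
  model <- validate_model(model)
  nc <- nrow(model$conformers)
  out <- lapply(pH, function(p) {
    ss <- .state_space(model, p)
    pop <- vapply(seq_len(nc), function(ci) sum(exp(ss$logp)[ss$conf_idx == ci]),
                  numeric(1))
    data.frame(pH = p, conformer = model$conformers$conformer_id,
               population = pop, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log binding polynomial of a species
#'
#' `ln Q(pH) = ln sum_states exp(-(G(state, pH) - G_ref(pH)) / kT)` with the
#' reference state taken as the fully deprotonated protonation vector in the
#' lowest-base-energy conformer. Satisfies `d lnQ / d pH = -ln(10) * Z(pH)`.
#'
#' @inheritParams exact_site_fraction
#' @return `ln Q`, one value per element of `pH`.
#' @export
binding_polynomial_ln <- function(model, pH) {
  model <- validate_model(model)
  e_ref <- min(model$conformers$base_energy)
  vapply(pH, function(p) {
    ss <- .state_space(model, p)
    ss$logz + e_ref / model$thermo$kT
  }, numeric(1))
}

#' Exact titration curve of every site from enumeration
#'
#' Convenience oracle: evaluates [exact_site_fraction()] for all sites on a
#' pH grid in the long format used by the titration-analysis functions.
#'
#' @param model A [system_model()].
#' @param pH Ascending numeric pH grid.
#' @return Data frame with columns `site`, `pH`, `s` (fraction deprotonated);
#'   no sampling counts (`n_deprot`/`n_total` columns absent).
#' @export
exact_titration_curves <- function(model, pH) {
  model <- validate_model(model)
  out <- lapply(model$sites$site_id, function(sid) {
    data.frame(site = sid, pH = pH,
               s = exact_site_fraction(model, pH, sid),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
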