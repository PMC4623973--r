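# Constant-pH Monte Carlo / pH replica exchange driver. Single moves are also
# exposed as plain R functions (attempt_protonation_move, attempt_conformer_move)
# so the Metropolis semantics can be examined step by step; production runs go
# through the compiled engine, which the enumeration oracles cross-check.

#' Single Metropolis protonation attempt
#'
#' Picks a site uniformly at random, computes the transition free energy of
#' flipping its protonation (see [protonation_flip_cost()]) and accepts with
#' probability `min(1, exp(-dG/kT))`. Uses the current R RNG stream.
#'
#' @param model A validated [system_model()].
#' @param state A [microstate()].
#' @param pH Solution pH.
#' @return List with `state` (possibly updated), `accepted`, `site_id`,
#'   `delta_g`.
#' @export
attempt_protonation_move <- function(model, state, pH) {
  model <- validate_model(model)
  .check_state(model, state)
  i <- sample.int(nrow(model$sites), 1L)
  sid <- model$sites$site_id[i]
  dg <- protonation_flip_cost(model, state, sid, pH)$delta_g
  accepted <- dg <= 0 || stats::runif(1) < exp(-dg / model$thermo$kT)
  if (accepted) state$protonation[i] <- 1L - state$protonation[i]
  list(state = state, accepted = accepted, site_id = sid, delta_g = dg)
}

#' Single Metropolis conformer attempt
#'
#' Proposes a uniformly chosen different conformer and accepts on the energy
#' difference at fixed protonation. A no-op (accepted = FALSE) for
#' single-conformer models.
#'
#' @inheritParams attempt_protonation_move
#' @return List with `state`, `accepted`, `delta_g`.
#' @export
attempt_conformer_move <- function(model, state, pH) {
  model <- validate_model(model)
  .check_state(model, state)
  nc <- nrow(model$conformers)
  if (nc < 2L) return(list(state = state, accepted = FALSE, delta_g = 0))
  cur <- .conf_index(model, state$conformer)
  cand <- setdiff(seq_len(nc), cur)
  cp <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  prop <- state
  prop$conformer <- model$conformers$conformer_id[cp]
  dg <- microstate_energy(model, prop, pH) - microstate_energy(model, state, pH)
  accepted <- dg <= 0 || stats::runif(1) < exp(-dg / model$thermo$kT)
  list(state = if (accepted) prop else state, accepted = accepted, delta_g = dg)
}

#' Replica-exchange acceptance probability in the pH dimension
#'
#' `min(1, exp(ln10 * (N_i - N_j) * (pH_i - pH_j)))` for swapping the pH
#' assignments of two replicas holding `N_i` and `N_j` titratable protons,
#' evaluated with the values prior to the attempt.
#'
#' @param n_i,n_j Titratable proton counts of the two replicas.
#' @param ph_i,ph_j Their pH values.
#' @return Acceptance probability in `[0, 1]`.
#' @export
exchange_probability <- function(n_i, n_j, ph_i, ph_j) {
  pmin(1, exp(log(10) * (n_i - n_j) * (ph_i - ph_j)))
}

# internal: run the compiled engine and assemble a sample ledger
.run_engine <- function(model, ladder, schedule, exchange) {
  model <- validate_model(model)
  stopifnot(inherits(schedule, "mc_schedule"))
  if (any(!is.finite(ladder))) stop("pH ladder must be finite")
  if (length(ladder) > 1L && any(diff(ladder) <= 0)) {
    stop("pH ladder must be strictly ascending")
  }
  set.seed(schedule$seed)
  raw <- cpp_run_cphmc(
    pka = model$sites$pKa_ref,
    shift = model$shift,
    base_e = model$conformers$base_energy,
    coup = unname(model$cmat),
    kT = model$thermo$kT,
    ladder = as.numeric(ladder),
    n_attempts = schedule$n_attempts,
    conf_move_prob = schedule$conformer_move_prob,
    exchange_interval = schedule$exchange_interval,
    burn_in_fraction = schedule$burn_in_fraction,
    thin = schedule$thin,
    do_exchange = exchange)

  n <- nrow(model$sites)
  umask <- sort(unique(raw$mask))
  pat <- vapply(umask, function(m) {
    paste(as.integer(bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L)), collapse = "")
  }, character(1))
  ledger <- data.frame(
    replica = raw$replica,
    attempt = raw$attempt,
    pH = raw$pH,
    conformer = model$conformers$conformer_id[raw$conf],
    protonation = pat[match(raw$mask, umask)],
    N = raw$N,
    stringsAsFactors = FALSE)
  attr(ledger, "sites") <- model$sites$site_id
  attr(ledger, "ladder") <- as.numeric(ladder)
  attr(ledger, "label") <- model$label
  attr(ledger, "schedule") <- schedule
  attr(ledger, "exchange") <- exchange
  class(ledger) <- c("sample_ledger", "data.frame")

  ex <- NULL
  if (exchange && length(ladder) > 1L) {
    ex <- data.frame(pH_lo = ladder[-length(ladder)], pH_hi = ladder[-1],
                     attempts = raw$ex_attempts, accepts = raw$ex_accepts)
    ex$rate <- ifelse(ex$attempts > 0, ex$accepts / ex$attempts, NA_real_)
  }
  list(ledger = ledger, exchange = ex)
}

#' Constant-pH Monte Carlo at a single fixed pH
#'
#' @param model A [system_model()].
#' @param pH Single pH value.
#' @param schedule An [mc_schedule()].
#' @return A `sample_ledger` data frame with columns `replica`, `attempt`,
#'   `pH`, `conformer`, `protonation` (0/1 string in canonical site order)
#'   and `N`; the model label, site order, ladder and schedule are attached
#'   as attributes.
#' @export
run_fixed_ph <- function(model, pH, schedule = mc_schedule()) {
  stopifnot(length(pH) == 1L)
  .run_engine(model, pH, schedule, exchange = FALSE)$ledger
}

#' Constant-pH replica exchange Monte Carlo over a pH ladder
#'
#' Runs one replica per ladder pH; every `exchange_interval` attempts a sweep
#' over adjacent pH pairs (alternating even/odd pairing between sweeps)
#' proposes swapping the pH assignments with the probability of
#' [exchange_probability()], leaving protonation vectors and conformers
#' untouched.
#'
#' @param model A [system_model()].
#' @param ph_ladder Strictly ascending pH values; default 1..12 step 1.
#' @param schedule An [mc_schedule()].
#' @param exchange Set `FALSE` to run the same ladder without exchange
#'   (used for detailed-balance checks).
#' @return List with `ledger` (a `sample_ledger`) and `exchange_stats`
#'   (per adjacent pair: attempts, acceptances, rate; `NULL` when exchange
#'   is disabled).
#' @export
run_ph_remd <- function(model, ph_ladder = 1:12, schedule = mc_schedule(),
                        exchange = TRUE) {
  res <- .run_engine(model, ph_ladder, schedule, exchange = exchange)
  list(ledger = res$ledger, exchange_stats = res$exchange)
}

#' Regroup a sample ledger into per-pH streams
#'
#' Reconstructs the pH-based sample streams from a replica-exchange ledger:
#' rows are regrouped by their pH value (ordered by attempt index within each
#' stream). Row counts are conserved.
#'
#' @param ledger A `sample_ledger`.
#' @return A named list of data frames (one per ladder pH, names are the pH
#'   values), of class `ph_streams`, carrying the site order and model label
#'   as attributes.
#' @export
demultiplex <- function(ledger) {
  stopifnot(inherits(ledger, "sample_ledger"))
  ladder <- attr(ledger, "ladder")
  if (!all(ledger$pH %in% ladder)) {
    stop("ledger contains pH values absent from its ladder metadata")
  }
  streams <- lapply(ladder, function(p) {
    df <- ledger[ledger$pH == p, , drop = FALSE]
    df <- df[order(df$attempt), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- "data.frame"
    df
  })
  names(streams) <- as.character(ladder)
  structure(streams, sites = attr(ledger, "sites"),
            label = attr(ledger, "label"), class = "ph_streams")
}
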