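#' Monte Carlo schedule
#'
#' Controls a constant-pH Monte Carlo run. One attempt advances every replica
#' by one move: with probability `conformer_move_prob` a conformer move,
#' otherwise a protonation flip of a uniformly chosen site.
#'
#' @param n_attempts Protonation/conformer attempts per replica (>= 1).
#' @param conformer_move_prob Probability in `[0, 1]` that an attempt is a
#'   conformer move (ignored for single-conformer models). Default 0.1.
#' @param exchange_interval Attempts between replica-exchange sweeps.
#'   Default 100.
#' @param burn_in_fraction Fraction of attempts discarded before recording,
#'   in `[0, 1)`. Default 1/6.
#' @param thin Record every `thin`-th attempt after burn-in. Default 1.
#' @param seed Integer seed for the run's RNG stream.
#' @return An `mc_schedule` list.
#' @export
mc_schedule <- function(n_attempts = 5e4, conformer_move_prob = 0.1,
                        exchange_interval = 100, burn_in_fraction = 1 / 6,
                        thin = 1, seed = 1) {
  n_attempts <- as.integer(n_attempts)
  exchange_interval <- as.integer(exchange_interval)
  thin <- as.integer(thin)
  if (n_attempts < 1L) stop("n_attempts must be >= 1")
  if (exchange_interval < 1L) stop("exchange_interval must be >= 1")
  if (thin < 1L) stop("thin must be >= 1")
  if (conformer_move_prob < 0 || conformer_move_prob > 1) {
    stop("conformer_move_prob must be in [0, 1]")
  }
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must be in [0, 1)")
  }
  structure(list(n_attempts = n_attempts,
                 conformer_move_prob = conformer_move_prob,
                 exchange_interval = exchange_interval,
                 burn_in_fraction = burn_in_fraction,
                 thin = thin,
                 seed = as.integer(seed)),
            class = "mc_schedule")
}
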