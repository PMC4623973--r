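# Fixture builders shared across the test files. All models are built in
# code; the reference thermodynamics object is reused so expected values can
# be written in terms of kT and kT*ln10.

th <- thermo_params()

# one unshifted Asp site, one conformer
single_asp <- function() make_preset_model("single_site", "Asp")

# two Asp sites with a both-protonated coupling of +kT*ln10 (a 1 pK-unit
# penalty): the 4-state partition function at pH 4 has weights
# (DD, PD, DP, PP) = (1, 1, 1, 0.1)
pair_kTln10 <- function() {
  validate_model(system_model(
    "pair",
    list(site_spec("A", "Asp"), site_spec("B", "Asp")),
    list(conformer_spec("c1", 0)),
    list(coupling_term("A", "B", th$kT_ln10))))
}

# a random enumerable model for property-style tests: 2-4 sites, 1-2
# conformers, random shifts and couplings
random_model <- function(seed) {
  set.seed(seed)
  n <- sample(2:4, 1)
  nc <- sample(1:2, 1)
  classes <- sample(c("Asp", "Glu", "His", "Tyr", "Lys"), n, replace = TRUE)
  conf_ids <- paste0("c", seq_len(nc))
  conformers <- lapply(seq_len(nc), function(k) {
    conformer_spec(conf_ids[k], stats::runif(1, -1, 1))
  })
  sites <- lapply(seq_len(n), function(k) {
    site_spec(sprintf("s%02d", k), classes[k],
              intrinsic_shift = setNames(stats::runif(nc, -2, 2), conf_ids))
  })
  pairs <- utils::combn(n, 2)
  take <- sample(ncol(pairs), min(2, ncol(pairs)))
  couplings <- lapply(take, function(j) {
    coupling_term(sprintf("s%02d", pairs[1, j]), sprintf("s%02d", pairs[2, j]),
                  stats::runif(1, -1.5, 2.5))
  })
  validate_model(system_model(sprintf("random%d", seed), sites, conformers,
                              couplings))
}

# exact per-site deprotonated fraction computed by direct summation over an
# independently constructed state table (oracle kept separate from the
# package's .state_space internals)
brute_site_fraction <- function(model, pH, site_id) {
  model <- validate_model(model)
  n <- nrow(model$sites)
  i <- match(site_id, model$sites$site_id)
  w_tot <- 0
  w_dep <- 0
  for (ci in seq_len(nrow(model$conformers))) {
    cid <- model$conformers$conformer_id[ci]
    for (code in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(code)[seq_len(n)])
      e <- microstate_energy(model, microstate(bits, cid), pH)
      w <- exp(-e / model$thermo$kT)
      w_tot <- w_tot + w
      if (bits[i] == 0L) w_dep <- w_dep + w
    }
  }
  w_dep / w_tot
}
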