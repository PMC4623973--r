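# Preset models. These define the synthetic study conditions used throughout
# the package's tests and examples: isolated model compounds, an
# anticooperative carboxylate dyad, and a ten-site aspartyl-protease-like
# system with a two-state flap surrogate whose holo variant exhibits large
# binding-induced pKa shifts localised at the dyad.

#' Build a preset protonation model
#'
#' Available presets:
#' \describe{
#'   \item{`single_site`}{One titratable site of the requested
#'     `residue_class`, one conformer, no shifts or couplings. Titrates as an
#'     ideal model compound (Henderson-Hasselbalch, Hill n = 1).}
#'   \item{`coupled_dyad`}{Two Asp sites (`Asp32`, `Asp228`) with a
#'     both-protonated coupling of `+2 kT ln10` (a 2 pK-unit penalty on
#'     double protonation), one conformer. Each site titrates broader than a
#'     single proton (Hill n < 1), emulating a catalytic carboxylate dyad.}
#'   \item{`bace_like`}{Ten sites (5 Asp, 3 Glu, 1 His, 1 Tyr) named after
#'     the titratable set of an aspartyl protease active site, with two
#'     conformers `open` (base 0) and `closed` (base +1.5 kcal/mol). The
#'     dyad `Asp32`/`Asp228` carries the `coupled_dyad` coupling plus a
#'     -3 kcal/mol closed-conformer stabilisation per protonated dyad site,
#'     so the closed state dominates at acidic pH and the open state at
#'     basic pH. Several peripheral sites carry conformer-independent
#'     intrinsic shifts emulating buried-residue pKa upshifts.}
#'   \item{`bace_like_holo`}{The ligand-bound counterpart of `bace_like`:
#'     each dyad site gains an additional -5.5 kcal/mol intrinsic shift in
#'     every conformer (raising its apparent pKa by about 4 pK units), and
#'     the ligand's direct contacts lock the flap surrogate closed
#'     (`open` base +1.2, `closed` base 0 kcal/mol).}
#' }
#'
#' @param name One of `"single_site"`, `"coupled_dyad"`, `"bace_like"`,
#'   `"bace_like_holo"`.
#' @param residue_class Residue class for `single_site` (default `"Asp"`).
#' @param thermo Thermodynamic parameters.
#' @return A validated [system_model()].
#' @seealso [make_preset_pair()] for the apo/holo pair.
#' @export
make_preset_model <- function(name, residue_class = "Asp",
                              thermo = thermo_params()) {
  kTln10 <- thermo$kT_ln10
  model <- switch(
    name,
    single_site = {
      sid <- paste0(residue_class, "1")
      system_model(
        label = sprintf("single_site_%s", residue_class),
        sites = list(site_spec(sid, residue_class)),
        conformers = list(conformer_spec("default", 0)),
        thermo = thermo)
    },
    coupled_dyad = system_model(
      label = "coupled_dyad",
      sites = list(site_spec("Asp32", "Asp"), site_spec("Asp228", "Asp")),
      conformers = list(conformer_spec("default", 0)),
      couplings = list(coupling_term("Asp32", "Asp228", 2 * kTln10)),
      thermo = thermo),
    bace_like = .bace_like_model(holo = FALSE, thermo = thermo),
    bace_like_holo = .bace_like_model(holo = TRUE, thermo = thermo),
    stop(sprintf("unknown preset name '%s'", name))
  )
  validate_model(model)
}

#' Apo/holo preset pair
#'
#' @param name Currently `"bace_like"`.
#' @param thermo Thermodynamic parameters.
#' @return A list with validated elements `apo` and `holo`.
#' @export
make_preset_pair <- function(name = "bace_like", thermo = thermo_params()) {
  if (!identical(name, "bace_like")) stop(sprintf("unknown preset pair '%s'", name))
  list(apo = make_preset_model("bace_like", thermo = thermo),
       holo = make_preset_model("bace_like_holo", thermo = thermo))
}

.bace_like_model <- function(holo, thermo) {
  kTln10 <- thermo$kT_ln10
  # Conformer-independent intrinsic shifts for peripheral sites: buried-residue
  # upshifts of the apparent pKa, in pK units converted to kcal/mol. Identical
  # in apo and holo (binding-induced shifts are localised at the dyad).
  peripheral_pk_shift <- c(Asp138 = +2.3, Asp223 = +1.2, Glu116 = +2.8,
                           Glu339 = +2.2, His45 = -0.9)
  dyad <- c("Asp32", "Asp228")
  conformers <- if (holo) {
    list(conformer_spec("open", 1.2), conformer_spec("closed", 0))
  } else {
    list(conformer_spec("open", 0), conformer_spec("closed", 1.5))
  }
  site_tab <- data.frame(
    site_id = c("Asp32", "Asp106", "Asp138", "Asp223", "Asp228",
                "Glu116", "Glu265", "Glu339", "His45", "Tyr71"),
    residue_class = c("Asp", "Asp", "Asp", "Asp", "Asp",
                      "Glu", "Glu", "Glu", "His", "Tyr"),
    stringsAsFactors = FALSE)
  sites <- lapply(seq_len(nrow(site_tab)), function(k) {
    sid <- site_tab$site_id[k]
    sh <- c(open = 0, closed = 0)
    if (sid %in% names(peripheral_pk_shift)) {
      sh <- sh - peripheral_pk_shift[[sid]] * kTln10
    }
    if (sid %in% dyad) {
      sh[["closed"]] <- sh[["closed"]] - 3.0   # protonated dyad stabilises closed flap
      if (holo) sh <- sh - 5.5                  # ligand contacts favour protonated dyad
    }
    site_spec(sid, site_tab$residue_class[k], intrinsic_shift = sh)
  })
  system_model(
    label = if (holo) "bace_like_holo" else "bace_like",
    sites = sites,
    conformers = conformers,
    couplings = list(coupling_term("Asp32", "Asp228", 2 * kTln10)),
    thermo = thermo)
}
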