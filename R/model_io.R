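# Model configuration files. YAML or JSON with top-level keys label,
# temperature, conformers, sites, couplings; unknown keys are rejected with
# the offending key named.

.schema_top <- c("label", "temperature", "conformers", "sites", "couplings")
.schema_conformer <- c("id", "base_energy")
.schema_site <- c("id", "residue_class", "pKa_ref", "intrinsic_shift")
.schema_coupling <- c("site_a", "site_b", "conformer_scope", "energy")

.check_keys <- function(obj, allowed, where) {
  bad <- setdiff(names(obj), allowed)
  if (length(bad)) {
    stop(sprintf("unknown key '%s' in %s (allowed: %s)",
                 bad[1], where, paste(allowed, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Load a protonation model from YAML or JSON
#'
#' The schema has top-level keys `label`, `temperature` (kelvin, optional,
#' default 300), `conformers` (list of `{id, base_energy}`), `sites` (list
#' of `{id, residue_class, pKa_ref?, intrinsic_shift?}` where
#' `intrinsic_shift` maps conformer ids to kcal/mol) and optional
#' `couplings` (list of `{site_a, site_b, conformer_scope?, energy}`).
#' Unknown keys anywhere are rejected by name. The format is chosen by file
#' extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return A validated [system_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  model_from_list(raw)
}

#' Build a model from a plain list (parsed YAML/JSON)
#'
#' @param raw Nested list following the [load_model()] schema.
#' @return A validated [system_model()].
#' @export
model_from_list <- function(raw) {
  .check_keys(raw, .schema_top, "model")
  for (key in c("label", "conformers", "sites")) {
    if (is.null(raw[[key]])) stop(sprintf("model is missing required key '%s'", key))
  }
  thermo <- thermo_params(if (is.null(raw$temperature)) 300 else raw$temperature)
  conformers <- lapply(raw$conformers, function(cf) {
    .check_keys(cf, .schema_conformer, "conformer entry")
    if (is.null(cf$id)) stop("conformer entry missing 'id'")
    conformer_spec(cf$id, if (is.null(cf$base_energy)) 0 else cf$base_energy)
  })
  sites <- lapply(raw$sites, function(st) {
    .check_keys(st, .schema_site, sprintf("site entry '%s'",
                                          if (is.null(st$id)) "?" else st$id))
    if (is.null(st$id)) stop("site entry missing 'id'")
    sh <- numeric()
    if (!is.null(st$intrinsic_shift)) sh <- unlist(st$intrinsic_shift)
    site_spec(st$id,
              if (is.null(st$residue_class)) "custom" else st$residue_class,
              if (is.null(st$pKa_ref)) NA_real_ else st$pKa_ref,
              intrinsic_shift = sh)
  })
  couplings <- lapply(raw$couplings, function(cp) {
    .check_keys(cp, .schema_coupling, "coupling entry")
    for (key in c("site_a", "site_b", "energy")) {
      if (is.null(cp[[key]])) stop(sprintf("coupling entry missing '%s'", key))
    }
    coupling_term(cp$site_a, cp$site_b, cp$energy,
                  if (is.null(cp$conformer_scope)) "all" else cp$conformer_scope)
  })
  validate_model(system_model(raw$label, sites, conformers, couplings, thermo))
}

#' Serialise a model to a plain list
#'
#' Inverse of [model_from_list()]; the result round-trips through YAML or
#' JSON to an identical validated model.
#'
#' @param model A [system_model()].
#' @return Nested list following the [load_model()] schema.
#' @export
model_to_list <- function(model) {
  model <- validate_model(model)
  list(
    label = model$label,
    temperature = model$thermo$temperature,
    conformers = lapply(seq_len(nrow(model$conformers)), function(k) {
      list(id = model$conformers$conformer_id[k],
           base_energy = model$conformers$base_energy[k])
    }),
    sites = lapply(seq_len(nrow(model$sites)), function(k) {
      list(id = model$sites$site_id[k],
           residue_class = model$sites$residue_class[k],
           pKa_ref = model$sites$pKa_ref[k],
           intrinsic_shift = as.list(setNames(model$shift[k, ],
                                              colnames(model$shift))))
    }),
    couplings = lapply(seq_len(nrow(model$couplings)), function(k) {
      list(site_a = model$couplings$site_a[k],
           site_b = model$couplings$site_b[k],
           conformer_scope = model$couplings$conformer_scope[k],
           energy = model$couplings$energy[k])
    })
  )
}

#' Write a model to YAML or JSON
#'
#' @param model A [system_model()].
#' @param path Output path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  lst <- model_to_list(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}
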