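# Multi-site protonation model: titratable sites, discrete conformers, and
# pairwise couplings standing in for the relative electrostatic free energy of
# protonation changes.

.residue_pka_ref <- c(Asp = 4.0, Glu = 4.4, His = 6.5, Tyr = 9.6, Lys = 10.4)

#' Specify a titratable site
#'
#' @param site_id Unique site name, e.g. `"Asp32"`.
#' @param residue_class One of `"Asp"`, `"Glu"`, `"His"`, `"Tyr"`, `"Lys"`,
#'   `"custom"`. Determines the default model-compound reference pKa
#'   (4.0, 4.4, 6.5, 9.6, 10.4 respectively); `"custom"` requires an explicit
#'   `pKa_ref`.
#' @param pKa_ref Reference (model-compound) pKa. `NA` means "use the class
#'   default", filled by [validate_model()].
#' @param intrinsic_shift Named numeric vector, conformer_id -> kcal/mol:
#'   energy added when this site is protonated while the system is in that
#'   conformer. Missing conformers default to 0. Negative values stabilise the
#'   protonated form and raise the apparent pKa by
#'   `-shift / kT_ln10` pK units.
#' @return A `site_spec` list.
#' @export
site_spec <- function(site_id, residue_class = "custom", pKa_ref = NA_real_,
                      intrinsic_shift = numeric()) {
  if (!is.character(site_id) || length(site_id) != 1L || !nzchar(site_id)) {
    stop("site_id must be a non-empty string")
  }
  residue_class <- match.arg(residue_class,
                             c("Asp", "Glu", "His", "Tyr", "Lys", "custom"))
  if (identical(residue_class, "custom") && is.na(pKa_ref)) {
    stop(sprintf("site '%s': residue_class 'custom' requires an explicit pKa_ref",
                 site_id))
  }
  if (!is.na(pKa_ref) && !is.finite(pKa_ref)) {
    stop(sprintf("site '%s': pKa_ref must be finite", site_id))
  }
  if (length(intrinsic_shift) &&
      (is.null(names(intrinsic_shift)) || any(!nzchar(names(intrinsic_shift))))) {
    stop(sprintf("site '%s': intrinsic_shift must be named by conformer_id", site_id))
  }
  structure(list(site_id = site_id, residue_class = residue_class,
                 pKa_ref = as.numeric(pKa_ref),
                 intrinsic_shift = intrinsic_shift),
            class = "site_spec")
}

#' Specify a discrete conformer
#'
#' @param conformer_id Conformer name, e.g. `"open"` or `"closed"`.
#' @param base_energy Protonation-independent energy offset in kcal/mol.
#' @return A `conformer_spec` list.
#' @export
conformer_spec <- function(conformer_id, base_energy = 0) {
  if (!is.character(conformer_id) || length(conformer_id) != 1L ||
      !nzchar(conformer_id)) {
    stop("conformer_id must be a non-empty string")
  }
  if (!is.numeric(base_energy) || !is.finite(base_energy)) {
    stop(sprintf("conformer '%s': base_energy must be finite", conformer_id))
  }
  structure(list(conformer_id = conformer_id,
                 base_energy = as.numeric(base_energy)),
            class = "conformer_spec")
}

#' Specify a pairwise protonation coupling
#'
#' The coupling energy is added when both sites are protonated, either in
#' every conformer (`conformer_scope = "all"`) or only in a named conformer.
#' Positive values penalise double protonation and yield anticooperative
#' (Hill n < 1) titration of the pair.
#'
#' @param site_a,site_b Site ids; must differ.
#' @param energy Coupling energy in kcal/mol.
#' @param conformer_scope `"all"` or a conformer_id.
#' @return A `coupling_term` list.
#' @export
coupling_term <- function(site_a, site_b, energy, conformer_scope = "all") {
  if (identical(site_a, site_b)) stop("coupling requires site_a != site_b")
  if (!is.numeric(energy) || !is.finite(energy)) {
    stop(sprintf("coupling %s-%s: energy must be finite", site_a, site_b))
  }
  structure(list(site_a = site_a, site_b = site_b,
                 conformer_scope = conformer_scope,
                 energy = as.numeric(energy)),
            class = "coupling_term")
}

#' Assemble a multi-site protonation model
#'
#' A `system_model` describes one species (e.g. the apo protein or a
#' protein-ligand complex): its titratable sites, its discrete conformers,
#' the pairwise couplings between protonated sites, and the thermodynamic
#' parameters. The microstate space is the product of `2^n_sites` protonation
#' vectors and the conformer set. Call [validate_model()] (done automatically
#' by [load_model()] and [make_preset_model()]) before using the model in any
#' computation.
#'
#' @param label Species label, e.g. `"apo"`.
#' @param sites List of [site_spec()] entries.
#' @param conformers List of [conformer_spec()] entries (at least one).
#' @param couplings Optional list of [coupling_term()] entries.
#' @param thermo A [thermo_params()] object.
#' @return An unvalidated `system_model`.
#' @export
system_model <- function(label, sites, conformers, couplings = list(),
                         thermo = thermo_params()) {
  if (!is.character(label) || length(label) != 1L) stop("label must be a string")
  stopifnot(is.list(sites), is.list(conformers), is.list(couplings),
            inherits(thermo, "thermo_params"))
  structure(list(label = label, sites = sites, conformers = conformers,
                 couplings = couplings, thermo = thermo, validated = FALSE),
            class = "system_model")
}

#' Validate a protonation model and fill defaults
#'
#' Checks identifiers and references, fills residue-class default reference
#' pKa values and missing intrinsic-shift entries (0 kcal/mol), orders sites
#' canonically (lexicographically by site_id), and precomputes the
#' intrinsic-shift matrix and per-conformer coupling matrices used by the
#' energy functions.
#'
#' @param model A `system_model`.
#' @return The validated model: `model$sites` and `model$conformers` become
#'   data frames, `model$shift` an n_sites x n_conformers matrix, and
#'   `model$cmat` a per-conformer list of symmetric coupling matrices.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "system_model"))
  if (isTRUE(model$validated)) return(model)

  if (length(model$conformers) == 0L) stop("zero conformers: at least one required")
  conf <- do.call(rbind, lapply(model$conformers, function(cs) {
    if (!inherits(cs, "conformer_spec")) cs <- do.call(conformer_spec, cs)
    data.frame(conformer_id = cs$conformer_id, base_energy = cs$base_energy,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(conf$conformer_id)) {
    stop(sprintf("duplicate conformer_id: %s",
                 paste(unique(conf$conformer_id[duplicated(conf$conformer_id)]),
                       collapse = ", ")))
  }
  if (any(!is.finite(conf$base_energy))) stop("non-finite conformer base_energy")

  if (length(model$sites) == 0L) stop("model must contain at least one site")
  sl <- lapply(model$sites, function(ss) {
    if (!inherits(ss, "site_spec")) ss <- do.call(site_spec, ss)
    ss
  })
  ids <- vapply(sl, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate site_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ord <- order(ids, method = "radix")
  sl <- sl[ord]
  ids <- ids[ord]

  sites <- do.call(rbind, lapply(sl, function(ss) {
    pka <- ss$pKa_ref
    if (is.na(pka)) pka <- .residue_pka_ref[[ss$residue_class]]
    if (!is.finite(pka)) stop(sprintf("site '%s': pKa_ref must be finite", ss$site_id))
    data.frame(site_id = ss$site_id, residue_class = ss$residue_class,
               pKa_ref = pka, stringsAsFactors = FALSE)
  }))

  shift <- matrix(0, nrow = length(sl), ncol = nrow(conf),
                  dimnames = list(ids, conf$conformer_id))
  for (k in seq_along(sl)) {
    sh <- sl[[k]]$intrinsic_shift
    if (length(sh)) {
      bad <- setdiff(names(sh), conf$conformer_id)
      if (length(bad)) {
        stop(sprintf("site '%s': intrinsic_shift refers to unknown conformer '%s'",
                     ids[k], bad[1]))
      }
      if (any(!is.finite(sh))) {
        stop(sprintf("site '%s': non-finite intrinsic_shift", ids[k]))
      }
      shift[k, names(sh)] <- as.numeric(sh)
    }
  }

  cmat <- lapply(seq_len(nrow(conf)), function(ci) {
    matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  })
  names(cmat) <- conf$conformer_id
  coups <- list()
  seen <- character()
  for (ct in model$couplings) {
    if (!inherits(ct, "coupling_term")) ct <- do.call(coupling_term, ct)
    for (s in c(ct$site_a, ct$site_b)) {
      if (!s %in% ids) stop(sprintf("coupling to unknown site '%s'", s))
    }
    if (!(ct$conformer_scope %in% c("all", conf$conformer_id))) {
      stop(sprintf("coupling %s-%s: unknown conformer_scope '%s'",
                   ct$site_a, ct$site_b, ct$conformer_scope))
    }
    key <- paste(sort(c(ct$site_a, ct$site_b)), collapse = "|")
    key <- paste(key, ct$conformer_scope, sep = "@")
    if (key %in% seen) {
      stop(sprintf("duplicate coupling for pair %s-%s (scope '%s')",
                   ct$site_a, ct$site_b, ct$conformer_scope))
    }
    seen <- c(seen, key)
    scope <- if (identical(ct$conformer_scope, "all")) conf$conformer_id else ct$conformer_scope
    for (cid in scope) {
      cmat[[cid]][ct$site_a, ct$site_b] <- cmat[[cid]][ct$site_a, ct$site_b] + ct$energy
      cmat[[cid]][ct$site_b, ct$site_a] <- cmat[[cid]][ct$site_b, ct$site_a] + ct$energy
    }
    coups[[length(coups) + 1L]] <- data.frame(
      site_a = ct$site_a, site_b = ct$site_b,
      conformer_scope = ct$conformer_scope, energy = ct$energy,
      stringsAsFactors = FALSE)
  }

  out <- model
  out$sites <- sites
  out$conformers <- conf
  out$couplings <- if (length(coups)) do.call(rbind, coups) else
    data.frame(site_a = character(), site_b = character(),
               conformer_scope = character(), energy = numeric(),
               stringsAsFactors = FALSE)
  out$shift <- shift
  out$cmat <- cmat
  out$validated <- TRUE
  out
}

#' Number of microstates of a model
#' @param model A validated `system_model`.
#' @return `2^n_sites * n_conformers`.
#' @export
n_microstates <- function(model) {
  model <- validate_model(model)
  2^nrow(model$sites) * nrow(model$conformers)
}

#' Construct a microstate
#'
#' @param protonation Integer 0/1 vector, one bit per site in the model's
#'   canonical (lexicographic) site order; 1 = protonated.
#' @param conformer Conformer id.
#' @return A `microstate` list.
#' @export
microstate <- function(protonation, conformer) {
  if (!all(protonation %in% c(0L, 1L))) stop("protonation bits must be 0 or 1")
  structure(list(protonation = as.integer(protonation),
                 conformer = conformer),
            class = "microstate")
}

#' @export
print.system_model <- function(x, ...) {
  x <- validate_model(x)
  cat(sprintf("<system_model '%s'> %d sites, %d conformer(s), %d coupling(s), T = %g K\n",
              x$label, nrow(x$sites), nrow(x$conformers), nrow(x$couplings),
              x$thermo$temperature))
  cat("  sites: ", paste(sprintf("%s(%s, pKa_ref %.2f)", x$sites$site_id,
                                 x$sites$residue_class, x$sites$pKa_ref),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: resolve conformer id -> index
.conf_index <- function(model, conformer) {
  ci <- match(conformer, model$conformers$conformer_id)
  if (is.na(ci)) stop(sprintf("unknown conformer '%s'", conformer))
  ci
}

# internal: check a microstate against a model
.check_state <- function(model, state) {
  stopifnot(inherits(state, "microstate"))
  if (length(state$protonation) != nrow(model$sites)) {
    stop("protonation bit-vector length does not match number of sites")
  }
  invisible(TRUE)
}
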