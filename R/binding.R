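# Wyman binding-polynomial thermodynamics: proton-count curves Z(pH), their
# apo/holo difference, and pH-dependent binding free energy profiles obtained
# by integrating kT*ln10*deltaZ away from a reference binding free energy.
#
# Sign convention. With Z counting bound protons, the linkage relation
# d ln K_app / d ln[H+] = deltaZ and ln[H+] = -ln10 * pH give
#   d dG / d pH = + kT * ln10 * (Z_PL - Z_P - Z_L),
# so a complex that binds protons more tightly than the free protein
# (deltaZ > 0) binds its ligand less favourably as pH rises. This matches the
# single-site closed form and the exact binding-polynomial profile; all three
# routes are cross-checked in the test suite.

.log1p10 <- function(a) {
  # log(1 + 10^a), overflow-safe
  ifelse(a > 0, a * log(10) + log1p(10^(-a)), log1p(10^a))
}

#' Proton-count curve of one species
#'
#' `Z(pH) = sum_sites (1 - s_site(pH))`: the mean number of bound titratable
#' protons, from per-site titration curves sharing one pH grid.
#'
#' @param curves Long data frame with columns `site`, `pH`, `s` (e.g. from
#'   [titration_curves()] or [exact_titration_curves()]).
#' @param label Species label stored on the result.
#' @return Data frame (`charge_curve`) with columns `pH`, `Z`; the number of
#'   sites is attached as an attribute.
#' @export
charge_curve <- function(curves, label = "species") {
  stopifnot(all(c("site", "pH", "s") %in% names(curves)))
  sites <- unique(curves$site)
  grids <- lapply(sites, function(sid) sort(curves$pH[curves$site == sid]))
  for (g in grids) {
    if (!isTRUE(all.equal(g, grids[[1]]))) {
      stop("all sites must share the same pH grid")
    }
  }
  agg <- aggregate(I(1 - curves$s), by = list(pH = curves$pH), FUN = sum)
  out <- data.frame(pH = agg$pH, Z = as.numeric(agg$x))
  out <- out[order(out$pH), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites") <- length(sites)
  attr(out, "label") <- label
  class(out) <- c("charge_curve", "data.frame")
  out
}

#' Binding-induced change in bound protons
#'
#' `deltaZ(pH) = Z_PL - Z_P - Z_L`. A non-titrating ligand contributes a
#' constant proton count, so `z_l` may be omitted.
#'
#' @param z_pl,z_p `charge_curve` data frames for the complex and the free
#'   protein on one shared grid.
#' @param z_l Optional `charge_curve` for the ligand; `NULL` (default) means
#'   the ligand does not titrate.
#' @return Data frame (`delta_z_curve`) with columns `pH`, `deltaZ`.
#' @export
delta_z <- function(z_pl, z_p, z_l = NULL) {
  stopifnot(all(c("pH", "Z") %in% names(z_pl)), all(c("pH", "Z") %in% names(z_p)))
  if (!isTRUE(all.equal(z_pl$pH, z_p$pH))) stop("mismatched pH grids")
  dz <- z_pl$Z - z_p$Z
  if (!is.null(z_l)) {
    if (!isTRUE(all.equal(z_pl$pH, z_l$pH))) stop("mismatched pH grids")
    dz <- dz - z_l$Z
  }
  out <- data.frame(pH = z_pl$pH, deltaZ = dz)
  class(out) <- c("delta_z_curve", "data.frame")
  out
}

# internal: fine grid + cumulative Simpson integral of a function over knots.
# Each knot interval is split into `refine` uniform subintervals; the
# integral over each fine subinterval uses the three-point Simpson rule with
# a midpoint evaluation.
.cumulative_simpson <- function(f, knots, refine) {
  g <- numeric(0)
  for (k in seq_len(length(knots) - 1L)) {
    seg <- seq(knots[k], knots[k + 1L], length.out = refine + 1L)
    g <- c(g, if (k == 1L) seg else seg[-1])
  }
  fg <- f(g)
  mid <- (g[-length(g)] + g[-1]) / 2
  h <- diff(g)
  inc <- h / 6 * (fg[-length(fg)] + 4 * f(mid) + fg[-1])
  list(grid = g, fgrid = fg, cum = c(0, cumsum(inc)))
}

#' Integrate a deltaZ curve into a binding free energy profile
#'
#' `dG(pH) = dG_ref + kT*ln10 * integral from pH_ref to pH of deltaZ`.
#' deltaZ is interpolated between its knots by a shape-preserving piecewise
#' cubic (Fritsch-Carlson) and integrated by composite Simpson quadrature on
#' a grid refined `refine`-fold between knots. No extrapolation: `pH_ref`
#' must lie inside the knot span and the profile covers exactly that span.
#'
#' @param dz A `delta_z_curve` (or any data frame with columns `pH`,
#'   `deltaZ`), at least 3 points.
#' @param dg_ref Reference binding free energy in kcal/mol.
#' @param ph_ref pH at which `dg_ref` applies (inside the grid span).
#' @param refine Subintervals per knot interval for the quadrature and the
#'   output grid. Default 10.
#' @param thermo Thermodynamic parameters (kT enters the integral).
#' @return Data frame (`binding_profile`) with columns `pH` (the refined
#'   grid, knots included), `deltaZ` (interpolated) and `dG` (kcal/mol);
#'   `dG` equals `dg_ref` exactly at `ph_ref`.
#' @export
integrate_profile <- function(dz, dg_ref, ph_ref, refine = 10,
                              thermo = thermo_params()) {
  stopifnot(all(c("pH", "deltaZ") %in% names(dz)))
  knots <- as.numeric(dz$pH)
  vals <- as.numeric(dz$deltaZ)
  if (length(knots) < 3L) stop("fewer than 3 grid points")
  if (any(!is.finite(vals))) stop("deltaZ must be finite")
  o <- order(knots)
  knots <- knots[o]; vals <- vals[o]
  if (ph_ref < min(knots) || ph_ref > max(knots)) {
    stop("pH_ref outside the simulated grid span (no extrapolation)")
  }
  f <- splinefun(knots, vals, method = "monoH.FC")
  cs <- .cumulative_simpson(f, knots, refine)
  # integral from grid start to ph_ref (partial Simpson if between fine nodes)
  i0 <- findInterval(ph_ref, cs$grid)
  F_ref <- cs$cum[i0]
  if (ph_ref > cs$grid[i0]) {
    a <- cs$grid[i0]
    F_ref <- F_ref + (ph_ref - a) / 6 *
      (f(a) + 4 * f((a + ph_ref) / 2) + f(ph_ref))
  }
  out <- data.frame(pH = cs$grid, deltaZ = cs$fgrid,
                    dG = dg_ref + thermo$kT_ln10 * (cs$cum - F_ref))
  attr(out, "knots") <- knots
  attr(out, "dg_ref") <- dg_ref
  attr(out, "ph_ref") <- ph_ref
  attr(out, "thermo") <- thermo
  class(out) <- c("binding_profile", "data.frame")
  out
}

#' Closed-form single-site binding free energy profile
#'
#' For one titratable site with acid dissociation midpoints `pKa_F` in the
#' free protein and `pKa_C` in the complex:
#' `dG(pH) = dG_ref_reaction - kT * ln[(1 + 10^(pKa_C - pH)) / (1 + 10^(pKa_F - pH))]`,
#' where `dG_ref_reaction` is the binding free energy of the reference
#' reaction between fully deprotonated species. Serves as the analytic
#' oracle for [integrate_profile()].
#'
#' @param pKa_F,pKa_C Site pKa in the free and complexed protein.
#' @param dg_ref_reaction Reference-reaction binding free energy (kcal/mol).
#' @param pH Numeric vector of pH values.
#' @param thermo Thermodynamic parameters.
#' @return Data frame with columns `pH`, `dG`.
#' @export
closed_form_single_site <- function(pKa_F, pKa_C, dg_ref_reaction, pH,
                                    thermo = thermo_params()) {
  stopifnot(is.finite(pKa_F), is.finite(pKa_C))
  dg <- dg_ref_reaction -
    thermo$kT * (.log1p10(pKa_C - pH) - .log1p10(pKa_F - pH))
  data.frame(pH = pH, dG = dg)
}

#' Exact binding free energy profile from enumerable models
#'
#' Uses the binding polynomials of the two species directly:
#' `dG(pH) - dG(pH_ref) = -kT * [(lnQ_PL - lnQ_P)(pH) - (lnQ_PL - lnQ_P)(pH_ref)]`.
#' The oracle for [integrate_profile()] on enumerable systems.
#'
#' @param model_p,model_pl [system_model()]s for the free protein and the
#'   complex (both enumerable).
#' @param dg_ref,ph_ref Reference binding free energy (kcal/mol) and its pH.
#' @param pH Output pH grid.
#' @return Data frame (`binding_profile`-like) with columns `pH`, `dG`.
#' @export
exact_profile_from_models <- function(model_p, model_pl, dg_ref, ph_ref, pH) {
  model_p <- validate_model(model_p)
  model_pl <- validate_model(model_pl)
  kT <- model_pl$thermo$kT
  lnq <- function(p) binding_polynomial_ln(model_pl, p) - binding_polynomial_ln(model_p, p)
  data.frame(pH = pH, dG = dg_ref - kT * (lnq(pH) - lnq(ph_ref)))
}

#' Fixed protonation-state scenario profile
#'
#' Emulates the conventional fixed-protonation modelling assumption: the
#' chosen sites are forced to one protonation state identically in both the
#' free and bound species, so they contribute nothing to deltaZ; the
#' remaining sites keep their sampled titration curves. Returns the scenario
#' profile together with its deviation from the full (fractional-protonation)
#' profile.
#'
#' @param apo_curves,holo_curves Long per-site titration curves (columns
#'   `site`, `pH`, `s`) for the free and bound species on one grid.
#' @param fixed Named character vector, site_id -> `"protonated"` or
#'   `"deprotonated"`, applied to both species.
#' @param dg_ref,ph_ref Reference binding free energy and its pH.
#' @param refine,thermo Passed to [integrate_profile()].
#' @return List with `profile` (the fixed-state `binding_profile`), `full`
#'   (the full profile) and `deviation` (data frame `pH`,
#'   `deviation = dG_fixed - dG_full`).
#' @export
fixed_state_profile <- function(apo_curves, holo_curves, fixed, dg_ref, ph_ref,
                                refine = 10, thermo = thermo_params()) {
  stopifnot(length(fixed) > 0, !is.null(names(fixed)))
  states <- vapply(fixed, function(v) {
    match.arg(v, c("protonated", "deprotonated"))
  }, character(1))
  for (sid in names(states)) {
    if (!sid %in% apo_curves$site || !sid %in% holo_curves$site) {
      stop(sprintf("unknown site '%s' in fixed map", sid))
    }
  }
  force_states <- function(curves) {
    for (sid in names(states)) {
      curves$s[curves$site == sid] <- if (states[[sid]] == "protonated") 0 else 1
    }
    curves
  }
  profile_of <- function(apo, holo) {
    dz <- delta_z(charge_curve(holo, "holo"), charge_curve(apo, "apo"))
    integrate_profile(dz, dg_ref, ph_ref, refine = refine, thermo = thermo)
  }
  full <- profile_of(apo_curves, holo_curves)
  fixed_prof <- profile_of(force_states(apo_curves), force_states(holo_curves))
  list(profile = fixed_prof, full = full,
       deviation = data.frame(pH = full$pH,
                              deviation = fixed_prof$dG - full$dG))
}

#' Wyman linkage residual of a binding profile
#'
#' Checks the slope identity `d dG / d pH = kT * ln10 * deltaZ` by central
#' finite differences on the profile's own grid (five-point stencil where
#' the spacing is locally uniform, three-point otherwise) and returns the
#' maximum absolute residual over interior points, in kcal/mol per pH unit.
#'
#' @param profile A `binding_profile` from [integrate_profile()] (columns
#'   `pH`, `deltaZ`, `dG`).
#' @param thermo Thermodynamic parameters; defaults to those stored on the
#'   profile.
#' @return Maximum absolute residual (kcal/mol per pH unit).
#' @export
wyman_residuals <- function(profile, thermo = NULL) {
  stopifnot(all(c("pH", "deltaZ", "dG") %in% names(profile)))
  if (is.null(thermo)) thermo <- attr(profile, "thermo")
  if (is.null(thermo)) thermo <- thermo_params()
  x <- profile$pH
  y <- profile$dG
  n <- length(x)
  if (n < 5L) stop("profile grid too short for the slope check")
  res <- rep(NA_real_, n)
  h <- diff(x)
  uni <- function(i, k) all(abs(h[(i - k):(i + k - 1L)] - h[i]) < 1e-9 * max(h))
  for (i in 3:(n - 2L)) {
    if (uni(i, 2L)) {
      d <- (y[i - 2L] - 8 * y[i - 1L] + 8 * y[i + 1L] - y[i + 2L]) / (12 * h[i])
    } else {
      d <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
    }
    res[i] <- d - thermo$kT_ln10 * profile$deltaZ[i]
  }
  max(abs(res), na.rm = TRUE)
}
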