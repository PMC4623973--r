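# The sign convention checked throughout: a complex that binds protons more
# tightly than the free protein (deltaZ > 0) binds its ligand less favourably
# as pH rises, so dG(pH) = dG_ref + kT*ln10 * int_{pH_ref}^{pH} deltaZ.

test_that("proton-count curves sum protonated fractions over sites", {
  grid <- 1:12
  one <- data.frame(site = "A", pH = grid, s = 0.5)
  expect_equal(charge_curve(one)$Z, rep(0.5, 12))
  ten <- do.call(rbind, lapply(sprintf("s%02d", 1:10), function(sid) {
    data.frame(site = sid, pH = grid, s = 1)
  }))
  expect_equal(charge_curve(ten)$Z, rep(0, 12))
  dy <- make_preset_model("coupled_dyad")
  zc <- charge_curve(exact_titration_curves(dy, 4))
  expect_equal(zc$Z, exact_mean_protons(dy, 4), tolerance = 1e-12)
  bad <- rbind(data.frame(site = "A", pH = 1:3, s = 0.5),
               data.frame(site = "B", pH = 2:4, s = 0.5))
  expect_error(charge_curve(bad), "same pH grid")
})

test_that("deltaZ is the pointwise difference of proton counts", {
  grid <- seq(-20, 12, 1)
  z_p <- charge_curve(data.frame(site = "A", pH = grid, s = hill_s(grid, 5)))
  z_pl <- charge_curve(data.frame(site = "A", pH = grid, s = hill_s(grid, 9)))
  dz <- delta_z(z_pl, z_p)
  expect_equal(dz$deltaZ[grid == 7],
               1 / (1 + 10^(7 - 9)) - 1 / (1 + 10^(7 - 5)), tolerance = 1e-12)
  expect_equal(dz$deltaZ[grid == 7], 0.9802, tolerance = 1e-4)
  expect_equal(dz$deltaZ[grid == -20], 0, tolerance = 1e-12)
  expect_equal(delta_z(z_pl, z_pl)$deltaZ, rep(0, length(grid)))
  # an explicit non-titrating ligand curve subtracts cleanly
  z_l <- charge_curve(data.frame(site = "L", pH = grid, s = 1))
  expect_equal(delta_z(z_pl, z_p, z_l)$deltaZ, dz$deltaZ)
})

test_that("integration of a constant deltaZ gives the linear profile", {
  grid <- seq(4.5, 7, 0.25)
  dz <- data.frame(pH = grid, deltaZ = 1)
  prof <- integrate_profile(dz, dg_ref = -10, ph_ref = 4.5)
  expect_equal(prof$dG[abs(prof$pH - 7) < 1e-9],
               -10 + th$kT_ln10 * 2.5, tolerance = 1e-9)
  expect_equal(prof$dG[abs(prof$pH - 4.5) < 1e-9], -10)
  flat <- integrate_profile(data.frame(pH = grid, deltaZ = 0), -10, 4.5)
  expect_equal(flat$dG, rep(-10, nrow(flat)))
  expect_error(integrate_profile(dz, -10, 9), "outside")
  expect_error(integrate_profile(dz[1:2, ], -10, 4.6), "fewer than 3")
})

test_that("closed-form single-site profile has the documented limits", {
  grid <- seq(-12, 30, 0.5)
  cf <- closed_form_single_site(5, 9.7, -10.4, grid)
  # equal pKa values leave the reference reaction unchanged
  same <- closed_form_single_site(6, 6, -10.4, grid)
  expect_equal(same$dG, rep(-10.4, length(grid)))
  # acidic plateau: dG_ref - kT ln10 (pKa_C - pKa_F)
  expect_equal(cf$dG[grid == 5 - 15], -10.4 - th$kT_ln10 * (9.7 - 5),
               tolerance = 1e-6)
  # basic plateau: the reference reaction itself
  expect_equal(cf$dG[grid == 30], -10.4, tolerance = 1e-8)
})

test_that("numerical integration matches the closed form to 1e-4 kcal/mol", {
  grid <- seq(1, 12, 0.1)
  dz <- data.frame(pH = grid,
                   deltaZ = (1 - hill_s(grid, 9.7)) - (1 - hill_s(grid, 5)))
  prof <- integrate_profile(dz, dg_ref = -9.1, ph_ref = 4.5)
  cf <- closed_form_single_site(5, 9.7, 0, prof$pH)$dG -
    closed_form_single_site(5, 9.7, 0, 4.5)$dG
  expect_lt(max(abs((prof$dG - (-9.1)) - cf)), 1e-4)
  # spec-level spot value: dG(7) - dG(4.5) ~ +2.59 kcal/mol
  expect_equal(prof$dG[abs(prof$pH - 7) < 1e-9] - (-9.1), 2.586, tolerance = 1e-3)
})

test_that("independent sites integrate to the sum of closed forms", {
  pkF <- c(5.0, 6.2, 3.4)
  pkC <- c(9.7, 7.0, 3.4)
  grid <- seq(1, 12, 0.1)
  apo <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(site = sprintf("s%d", k), pH = grid, s = hill_s(grid, pkF[k]))
  }))
  holo <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(site = sprintf("s%d", k), pH = grid, s = hill_s(grid, pkC[k]))
  }))
  dz <- delta_z(charge_curve(holo), charge_curve(apo))
  prof <- integrate_profile(dz, 0, 4.5)
  cf_sum <- Reduce(`+`, lapply(1:3, function(k) {
    closed_form_single_site(pkF[k], pkC[k], 0, prof$pH)$dG -
      closed_form_single_site(pkF[k], pkC[k], 0, 4.5)$dG
  }))
  expect_lt(max(abs(prof$dG - cf_sum)), 1e-4)
})

test_that("exact binding-polynomial profiles agree with the other two routes", {
  # single-site pair: algebraic identity with the closed form
  apo <- make_preset_model("single_site", "Asp")
  holo <- validate_model(system_model(
    "holo", list(site_spec("Asp1", "Asp", intrinsic_shift = c(default = -6.45))),
    list(conformer_spec("default"))))
  grid <- seq(1, 12, 0.5)
  ex <- exact_profile_from_models(apo, holo, -9.1, 4.5, grid)
  pka_c <- 4.0 + 6.45 / th$kT_ln10
  cf <- closed_form_single_site(4.0, pka_c, 0, grid)$dG -
    closed_form_single_site(4.0, pka_c, 0, 4.5)$dG
  expect_lt(max(abs((ex$dG - (-9.1)) - cf)), 1e-10)
  # identical models give a flat profile at the reference
  flat <- exact_profile_from_models(apo, apo, -9.1, 4.5, grid)
  expect_equal(flat$dG, rep(-9.1, length(grid)))
  # multi-site pair: quadrature over exact fractions vs binding polynomials
  pair <- make_preset_pair("bace_like")
  fine <- seq(1, 12, 0.1)
  dz <- delta_z(charge_curve(exact_titration_curves(pair$holo, fine)),
                charge_curve(exact_titration_curves(pair$apo, fine)))
  prof <- integrate_profile(dz, -9.1, 4.5)
  oracle <- exact_profile_from_models(pair$apo, pair$holo, -9.1, 4.5, prof$pH)
  expect_lt(max(abs(prof$dG - oracle$dG)), 1e-3)
})

test_that("integration is path independent under re-referencing", {
  grid <- seq(1, 12, 0.1)
  dz <- data.frame(pH = grid,
                   deltaZ = (1 - hill_s(grid, 9.7)) - (1 - hill_s(grid, 5)))
  direct <- integrate_profile(dz, 0, 4.5)
  at7 <- direct$dG[abs(direct$pH - 7) < 1e-9]
  relay <- integrate_profile(dz, at7, 7)
  expect_lt(max(abs(direct$dG - relay$dG)), 1e-6)
})

test_that("deltaZ > 0 above the reference pH weakens binding monotonically", {
  pair <- make_preset_pair("bace_like")
  fine <- seq(1, 12, 0.1)
  dz <- delta_z(charge_curve(exact_titration_curves(pair$holo, fine)),
                charge_curve(exact_titration_curves(pair$apo, fine)))
  prof <- integrate_profile(dz, -9.1, 4.5)
  win <- prof$pH >= 5 & prof$pH <= 9   # the dyad-titration window
  expect_true(all(dz$deltaZ[dz$pH >= 5 & dz$pH <= 9] > 0))
  expect_true(all(diff(prof$dG[win]) > 0))
})

test_that("Wyman linkage residuals flag corrupted profiles only", {
  grid <- seq(1, 12, 0.1)
  dz <- data.frame(pH = grid,
                   deltaZ = (1 - hill_s(grid, 9.7)) - (1 - hill_s(grid, 5)))
  prof <- integrate_profile(dz, -9.1, 4.5)
  expect_lt(wyman_residuals(prof), 1e-3)
  flat <- integrate_profile(data.frame(pH = grid, deltaZ = 0), -9.1, 4.5)
  expect_lt(wyman_residuals(flat), 1e-12)
  bad <- prof
  bad$dG[600] <- bad$dG[600] + 1
  expect_gt(wyman_residuals(bad), 0.5)
})

test_that("fixing sites removes their proton-linkage contribution", {
  pair <- make_preset_pair("bace_like")
  fine <- seq(1, 12, 0.1)
  apo <- exact_titration_curves(pair$apo, fine)
  holo <- exact_titration_curves(pair$holo, fine)
  sc <- fixed_state_profile(apo, holo,
                            c(Asp32 = "protonated", Asp228 = "protonated"),
                            dg_ref = -9.1, ph_ref = 4.5)
  # only the dyad differs between species, so fixing it flattens the profile
  expect_equal(sc$profile$dG, rep(-9.1, nrow(sc$profile)), tolerance = 1e-9)
  # deviation grows in magnitude with pH above the reference
  dev <- sc$deviation$deviation[sc$deviation$pH >= 4.5]
  expect_true(all(diff(dev) <= 1e-9))
  # fixing a site identical in both species changes nothing
  sc2 <- fixed_state_profile(apo, holo, c(Glu265 = "deprotonated"),
                             dg_ref = -9.1, ph_ref = 4.5)
  expect_equal(sc2$deviation$deviation, rep(0, nrow(sc2$deviation)),
               tolerance = 1e-9)
  # fixing every site pins the profile at the reference free energy
  all_fixed <- setNames(rep("protonated", 10), pair$apo$sites$site_id)
  sc3 <- fixed_state_profile(apo, holo, all_fixed, dg_ref = -9.1, ph_ref = 4.5)
  expect_equal(sc3$profile$dG, rep(-9.1, nrow(sc3$profile)), tolerance = 1e-12)
  expect_error(fixed_state_profile(apo, holo, c(Xyz = "protonated"), -9.1, 4.5),
               "unknown site")
})
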