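test_that("validation fills residue-class defaults and canonical ordering", {
  m <- validate_model(system_model(
    "t", list(site_spec("zAsp", "Asp"), site_spec("aGlu", "Glu"),
              site_spec("mHis", "His"), site_spec("nTyr", "Tyr"),
              site_spec("kLys", "Lys")),
    list(conformer_spec("only"))))
  expect_equal(m$sites$site_id, sort(m$sites$site_id))
  expect_equal(m$sites$pKa_ref[m$sites$site_id == "zAsp"], 4.0)
  expect_equal(m$sites$pKa_ref[m$sites$site_id == "aGlu"], 4.4)
  expect_equal(m$sites$pKa_ref[m$sites$site_id == "mHis"], 6.5)
  expect_equal(m$sites$pKa_ref[m$sites$site_id == "nTyr"], 9.6)
  expect_equal(m$sites$pKa_ref[m$sites$site_id == "kLys"], 10.4)
  expect_true(all(m$shift == 0))
})

test_that("validation rejects malformed models", {
  expect_error(validate_model(system_model(
    "dup", list(site_spec("A", "Asp"), site_spec("A", "Glu")),
    list(conformer_spec("c")))), "duplicate site_id")
  expect_error(validate_model(system_model(
    "noconf", list(site_spec("A", "Asp")), list())), "zero conformers")
  expect_error(validate_model(system_model(
    "badcoup", list(site_spec("A", "Asp"), site_spec("B", "Asp")),
    list(conformer_spec("c")),
    list(coupling_term("A", "C", 1)))), "unknown site")
  expect_error(validate_model(system_model(
    "dupcoup", list(site_spec("A", "Asp"), site_spec("B", "Asp")),
    list(conformer_spec("c")),
    list(coupling_term("A", "B", 1), coupling_term("B", "A", 2)))),
    "duplicate coupling")
  expect_error(coupling_term("A", "A", 1), "site_a != site_b")
  expect_error(site_spec("X", "custom"), "requires an explicit pKa_ref")
})

test_that("microstate energies follow the transition free energy", {
  m <- single_asp()
  d0 <- microstate(0L, "default")
  d1 <- microstate(1L, "default")
  # at pH = pKa_ref the flip is free
  expect_equal(microstate_energy(m, d1, 4) - microstate_energy(m, d0, 4), 0)
  # 3 pH units above the midpoint costs 3 kT ln10
  expect_equal(microstate_energy(m, d1, 7) - microstate_energy(m, d0, 7),
               3 * th$kT_ln10, tolerance = 1e-12)
  # fully deprotonated reference state has energy zero
  expect_equal(microstate_energy(m, d0, 11.3), 0)
  # both-protonated coupling enters once
  m2 <- pair_kTln10()
  expect_equal(microstate_energy(m2, microstate(c(1L, 1L), "c1"), 4),
               th$kT_ln10, tolerance = 1e-12)
  expect_equal(protonation_flip_cost(m2, microstate(c(0L, 1L), "c1"), "A", 4)$cost,
               th$kT_ln10, tolerance = 1e-12)
})

test_that("exact enumeration reproduces hand-computed partition functions", {
  m2 <- pair_kTln10()
  es <- enumerate_states(m2, 4)
  expect_equal(sum(es$prob), 1, tolerance = 1e-12)
  probs <- setNames(es$prob, es$protonation)
  expect_equal(unname(probs[c("00", "10", "01", "11")]),
               c(1, 1, 1, 0.1) / 3.1, tolerance = 1e-9)
  # per-site deprotonated fraction and mean protons from the same 4 states
  expect_equal(exact_site_fraction(m2, 4, "A"), 2 / 3.1, tolerance = 1e-9)
  expect_equal(exact_mean_protons(m2, 4), 2.2 / 3.1, tolerance = 1e-9)
  expect_equal(binding_polynomial_ln(m2, 4), log(3.1), tolerance = 1e-9)
})

test_that("single uncoupled sites titrate as Henderson-Hasselbalch", {
  m <- single_asp()
  expect_equal(exact_site_fraction(m, 5, "Asp1"), 1 / (1 + 10^(4 - 5)),
               tolerance = 1e-12)
  expect_equal(exact_site_fraction(m, 4, "Asp1"), 0.5, tolerance = 1e-12)
  expect_lt(exact_site_fraction(m, -20, "Asp1"), 1e-10)
  expect_equal(exact_mean_protons(m, 4), 0.5, tolerance = 1e-12)
  # saturation: many uncoupled sites all bind at very low pH
  m10 <- validate_model(system_model(
    "ten", lapply(1:10, function(k) site_spec(sprintf("s%02d", k), "Asp")),
    list(conformer_spec("c"))))
  expect_equal(exact_mean_protons(m10, -20), 10, tolerance = 1e-9)
  # acid-only model fully deprotonates at very high pH
  expect_equal(binding_polynomial_ln(m10, 20), 0, tolerance = 1e-10)
})

test_that("an intrinsic shift moves the apparent pKa by -shift/kT_ln10", {
  delta <- -2.2   # kcal/mol, stabilises the protonated form
  m <- validate_model(system_model(
    "shifted", list(site_spec("A", "Asp", intrinsic_shift = c(c1 = delta))),
    list(conformer_spec("c1"))))
  pka_app <- 4.0 - delta / th$kT_ln10
  grid <- seq(-2, 14, 0.25)
  expect_equal(exact_site_fraction(m, grid, "A"), hill_s(grid, pka_app, 1),
               tolerance = 1e-10)
})

test_that("enumeration is invariant to site order and base-energy offsets", {
  for (seed in c(11, 12, 13)) {
    m <- random_model(seed)
    grid <- c(2, 5.5, 9)
    # permuting the input site list does not change per-site fractions
    perm <- rev(seq_along(m$sites$site_id))
    m_perm <- validate_model(system_model(
      m$label,
      lapply(perm, function(k) {
        site_spec(m$sites$site_id[k], m$sites$residue_class[k],
                  m$sites$pKa_ref[k],
                  intrinsic_shift = setNames(m$shift[k, ], colnames(m$shift)))
      }),
      lapply(seq_len(nrow(m$conformers)), function(k) {
        conformer_spec(m$conformers$conformer_id[k], m$conformers$base_energy[k])
      }),
      lapply(seq_len(nrow(m$couplings)), function(k) {
        coupling_term(m$couplings$site_a[k], m$couplings$site_b[k],
                      m$couplings$energy[k], m$couplings$conformer_scope[k])
      }),
      m$thermo))
    for (sid in m$sites$site_id) {
      expect_equal(exact_site_fraction(m_perm, grid, sid),
                   exact_site_fraction(m, grid, sid), tolerance = 1e-12)
    }
    # adding a constant to all conformer base energies changes nothing
    m_off <- m
    m_off$conformers$base_energy <- m$conformers$base_energy + 7.3
    expect_equal(exact_mean_protons(m_off, grid), exact_mean_protons(m, grid),
                 tolerance = 1e-10)
  }
})

test_that("enumeration matches an independent brute-force summation", {
  for (seed in c(21, 22)) {
    m <- random_model(seed)
    for (p in c(3, 7.5)) {
      for (sid in m$sites$site_id) {
        expect_equal(exact_site_fraction(m, p, sid),
                     brute_site_fraction(m, p, sid), tolerance = 1e-10)
      }
    }
  }
})

test_that("mean protons decrease with pH and lnQ obeys d lnQ/d pH = -ln10 Z", {
  grid <- seq(0, 14, 0.5)
  h <- 1e-4
  for (seed in c(31, 32, 33)) {
    m <- random_model(seed)
    z <- exact_mean_protons(m, grid)
    expect_true(all(diff(z) <= 1e-12))
    d <- (binding_polynomial_ln(m, grid + h) -
            binding_polynomial_ln(m, grid - h)) / (2 * h)
    expect_equal(d, -log(10) * z, tolerance = 1e-6)
  }
})

test_that("the state-space guard rejects unenumerable models", {
  m_big <- validate_model(system_model(
    "big", lapply(1:25, function(k) site_spec(sprintf("s%02d", k), "Asp")),
    list(conformer_spec("c"))))
  expect_error(enumerate_states(m_big, 7), "too large")
})
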