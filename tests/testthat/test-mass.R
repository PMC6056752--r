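test_that("monoisotopic masses match hand-computed references", {
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-6)
  # calibrant peptides, singly protonated, at the conventional 2 d.p.
  expect_equal(round_half_up(precursor_mz(reference_peptides[["p14r"]], 1), 2),
               1533.86)
  expect_equal(round_half_up(
    precursor_mz(reference_peptides[["bradykinin_1_7"]], 1), 2), 757.40)
  expect_equal(round_half_up(
    precursor_mz(reference_peptides[["angiotensin_ii"]], 1), 2), 1046.54)
  expect_error(monoisotopic_mass("AZA"), "'Z' at position 2")
})

test_that("concatenation additivity: mass(AB) = mass(A) + mass(B) - water", {
  set.seed(11)
  for (i in 1:50) {
    a <- random_sequence(sample(1:15, 1))
    b <- random_sequence(sample(1:15, 1))
    expect_equal(monoisotopic_mass(paste0(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b) -
                   mass_constants$water,
                 tolerance = 1e-9)
  }
})

test_that("precursor m/z is charge-consistent", {
  set.seed(12)
  for (i in 1:20) {
    p <- random_sequence(sample(5:25, 1))
    neutral <- vapply(1:4, function(z) {
      z * precursor_mz(p, z) - z * mass_constants$proton
    }, numeric(1))
    expect_equal(max(neutral) - min(neutral), 0, tolerance = 1e-9)
    expect_equal(precursor_mz(p, 1),
                 2 * precursor_mz(p, 2) - mass_constants$proton,
                 tolerance = 1e-9)
  }
  expect_error(precursor_mz("AAK", 0), "positive")
})

test_that("b/y fragments reproduce printed transition values", {
  expect_equal(round_half_up(fragment_mz("VFCTK", "y", 4), 1), 498.2)
  expect_equal(round_half_up(fragment_mz("VFCTK", "y", 3), 1), 351.2)
  expect_equal(round_half_up(precursor_mz("MHVAQPAVVLASSR", 3), 1), 489.3)
  expect_equal(round_half_up(fragment_mz("MHVAQPAVVLASSR", "y", 4), 1),
               420.2)
  expect_error(fragment_mz("VFCTK", "y", 5), "index")
  expect_error(fragment_mz("VFCTK", "b", 0), "index")
})

test_that("singly charged b_i and y_(n-i) are complementary", {
  set.seed(13)
  for (i in 1:100) {
    p <- random_sequence(sample(2:30, 1))
    n <- nchar(p)
    idx <- sample(n - 1, 1)
    expect_equal(fragment_mz(p, "b", idx) + fragment_mz(p, "y", n - idx),
                 monoisotopic_mass(p) + 2 * mass_constants$proton,
                 tolerance = 1e-9)
  }
})

test_that("disulfide homodimer species are computed from one cysteine", {
  d <- disulfide_dimer_species("VFCTK")
  expect_equal(d$dimer_mass, 1190.583, tolerance = 1e-3)
  expect_lt(d$dimer_mass, 2 * monoisotopic_mass("VFCTK"))
  expect_equal(d$dimer_mass,
               2 * monoisotopic_mass("VFCTK") - 2 * mass_constants$hydrogen)
  expect_equal(d$precursor_mz,
               (d$dimer_mass + 3 * mass_constants$proton) / 3)
  # dehydro fragment is the ordinary fragment minus one hydrogen atom
  expect_equal(d$dehydro_fragment_mz,
               fragment_mz("VFCTK", "y", 4) - mass_constants$hydrogen)
  expect_error(disulfide_dimer_species("AAAK"), "0 cysteines")
  expect_error(disulfide_dimer_species("CACK"), "2 cysteines")
})

test_that("transition tables carry roles and instrument metadata", {
  tab <- build_transition_table("VFCTK", precursor_charge = 2)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$role[tab$label == "y4+"], "quantitation")
  expect_setequal(tab$label[tab$role == "structure"], c("y3+", "y2+"))
  expect_equal(round_half_up(tab$fragment_mz[tab$label == "y4+"], 1), 498.2)

  # a dipeptide has exactly one y fragment
  expect_equal(nrow(build_transition_table("GK")), 1)

  meta <- data.frame(q1_v = -30, collision_v = -16, q3_v = -30)
  tab2 <- build_transition_table("MHVAQPAVVLASSR", precursor_charge = 3,
                                 instrument_meta = meta)
  expect_true(all(tab2$collision_v == -16))
})

test_that("observed transitions match the nearest computed ion", {
  abt <- build_transition_table("MHVAQPAVVLASSR", precursor_charge = 3)
  hit <- match_transition(489.3, 420.2, abt)
  expect_equal(hit$label, "y4+")

  vf <- build_transition_table("VFCTK", precursor_charge = 2)
  # a unit-resolution printed value resolves to y2 with ~0.26 Th deviation
  hit2 <- match_transition(299.3, 247.9, vf)
  expect_equal(hit2$label, "y2+")
  expect_equal(hit2$delta_q3, 0.26, tolerance = 0.01)

  expect_null(match_transition(0, 0, vf))
})

test_that("reported rounding is half-away-from-zero", {
  expect_equal(round_half_up(c(0.25, -0.25, 2.5, -2.5), 1),
               c(0.3, -0.3, 2.5, -2.5))
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(signif_half_up(105.54), 106)
  expect_equal(signif_half_up(3.6696), 3.67)
  expect_equal(signif_half_up(0), 0)
})
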