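test_that("kinetic energy follows E = m v^2 / 2", {
  expect_equal(kinetic_energy(5, 0), 0)
  expect_equal(kinetic_energy(2, 3), 9)
  expect_equal(kinetic_energy(33.2, 104), 179545.6)
  expect_error(kinetic_energy(0, 1), "positive")

  # quadratic in v, linear in m
  set.seed(3)
  for (i in 1:20) {
    m <- runif(1, 0.1, 100)
    v <- runif(1, 0.1, 120)
    expect_equal(kinetic_energy(m, 2 * v), 4 * kinetic_energy(m, v))
    expect_equal(kinetic_energy(2 * m, v), 2 * kinetic_energy(m, v))
  }
})

test_that("transferred energy scales by efficiency and never exceeds total", {
  expect_identical(transferred_energy(100, 1), 100)
  expect_equal(round(transferred_energy(56136, 0.85) / 1000, 3), 47.716)
  expect_equal(round(transferred_energy(162234, 0.85) / 1000, 3), 137.899)
  expect_error(transferred_energy(1, 0), "efficiency")
  expect_error(transferred_energy(1, 1.2), "efficiency")
  set.seed(4)
  for (i in 1:10) {
    e <- runif(1, 1, 1e5)
    eff <- runif(1, 0.05, 1)
    expect_lte(transferred_energy(e, eff), e)
  }
})

test_that("back-solved velocities invert the energy equation exactly", {
  set.seed(5)
  for (i in 1:20) {
    m <- runif(1, 0.1, 100)
    v <- runif(1, 0.5, 120)
    expect_equal(back_solve_velocity(kinetic_energy(m, v), m), v,
                 tolerance = 1e-12)
  }
  # velocities implied by the published whole-tail and whiplash energies
  expect_equal(back_solve_velocity(56136, 26.5), 65.1, tolerance = 1e-3)
  expect_equal(back_solve_velocity(537, 0.3), 59.8, tolerance = 1e-3)
})

test_that("scenario evaluation produces the three published scenarios", {
  masses <- list(whole = list(mass_kg = 1), whip = list(mass_kg = 0.1))
  cfg <- scenario_config("custom", v_whole_m_s = 2, v_whip_m_s = 2,
                         efficiency = 0.5)
  rep <- evaluate_scenarios(masses, cfg)
  expect_equal(rep$whole_tail_J, 2)
  expect_equal(rep$whip_transferred_J, 1)
  expect_equal(rep$quick_whiplash_J, 0.2 * 2^2 / 4)
  expect_equal(rep$whole_tail_kJ, rep$whole_tail_J / 1000)

  expect_error(evaluate_scenarios(list(whole = list(mass_kg = 1)), cfg),
               "whip")
})

test_that("implied-velocity preset regenerates the printed energy grid", {
  t1 <- printed_table1()
  masses <- lapply(seq_len(nrow(t1)), function(i) {
    list(whole = list(mass_kg = t1$tail_mass_kg[i]),
         whip = list(mass_kg = t1$whiplash_mass_kg[i]))
  })
  names(masses) <- t1$variant
  rep <- evaluate_scenarios(masses, scenario_config("as_implied"))
  # the bone-only column anchors the back-solved velocities, so it is exact
  expect_equal(rep$whole_tail_kJ[1], t1$whole_tail_energy_kJ[1],
               tolerance = 1e-6)
  expect_equal(rep$quick_whiplash_kJ[1], t1$quick_whiplash_energy_kJ[1],
               tolerance = 1e-6)
  # the whole-tail and transferred columns share one implied velocity, so the
  # remaining variants reproduce to a fraction of a percent
  expect_equal(rep$whole_tail_kJ, t1$whole_tail_energy_kJ, tolerance = 0.005)
  expect_equal(rep$whip_transferred_kJ, t1$transferred_energy_kJ,
               tolerance = 0.005)
  # the printed quick-whiplash columns imply *different* velocities
  # (59.8 to 66.6 m/s), so a single back-solved velocity cannot reproduce
  # them all: up to ~19% off, an internal inconsistency the audit reports
  rel <- abs(rep$quick_whiplash_kJ - t1$quick_whiplash_energy_kJ) /
    t1$quick_whiplash_energy_kJ
  expect_lt(rel[1], 1e-6)
  expect_gt(max(rel), 0.1)
  expect_lt(max(rel), 0.25)
})

test_that("the stated 2 m/s cannot generate the printed energies", {
  masses <- list(whole = list(mass_kg = 26.5), whip = list(mass_kg = 0.3))
  rep <- evaluate_scenarios(masses, scenario_config("as_stated"))
  expect_equal(rep$whole_tail_J, 53)   # 1/2 * 26.5 * 4
  # three orders of magnitude below the printed 56.136 kJ
  expect_lt(rep$whole_tail_kJ * 100, 56.136)
})

test_that("comparative tables reproduce published rows and tolerate gaps", {
  tab <- comparative_table(taxon_presets("diplodocus"))
  expect_equal(tab$n_caudals, 70)
  expect_equal(tab$total_tail_m, 13.26)
  expect_equal(tab$whip_length_m, 7.28)
  expect_equal(tab$whip_pct, 54.90)
  expect_equal(tab$energy_kJ, 179.55)  # round(179.5456, 2)

  # a synthetic specimen joins through the same interface
  vs <- tapering_series(20, crossing = 10)
  seg <- segment_whip(vs)
  tab2 <- comparative_table(list(list(id = "syn", series = vs,
                                      mass_kg = 1, velocity_m_s = 2)))
  expect_equal(tab2$whip_pct,
               round(100 * seg$whip_length_cm / seg$total_length_cm, 2))

  # no detectable whip -> NA columns plus a warning, the row survives
  stout <- make_series(c(5, 4, 3), c(10, 9, 8))
  expect_warning(
    tab3 <- comparative_table(list(list(id = "stout", series = stout,
                                        mass_kg = 1, velocity_m_s = 2))),
    "no whip")
  expect_true(is.na(tab3$whip_length_m))
  expect_error(comparative_table(list()), "no specimens")
})
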