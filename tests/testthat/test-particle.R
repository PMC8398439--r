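test_that("aerodynamic-to-geometric conversion follows sqrt(k/rho)", {
  expect_equal(aero_to_geometric_diameter(5, 1, 1), 5)
  expect_equal(aero_to_geometric_diameter(3.7, 1, 1.37), 3.7 / sqrt(1.37),
               tolerance = 1e-12)
  expect_equal(aero_to_geometric_diameter(3.7, 1, 1.37), 3.161,
               tolerance = 1e-3)
  # denser-than-water particles are geometrically smaller
  expect_lt(aero_to_geometric_diameter(2, 1, 2.5), 2)
  expect_error(aero_to_geometric_diameter(-1), "positive")
  expect_error(aero_to_geometric_diameter(1, 0, 1), "positive")
})

test_that("build_psd derives particle counts and rescales to delivered mass", {
  # single bin chosen so the geometric radius is exactly 1 um
  d_aero <- 2 * sqrt(1.37)  # um; converts to d_geo = 2 um, r = 1e-4 cm
  st <- data.frame(stage = 1, cutoff_um = d_aero, mass_ug = 10)
  psd <- build_psd(st, density = 1.37)
  expect_equal(psd$bins$geo_radius_cm, 1e-4, tolerance = 1e-12)
  expect_equal(psd$bins$particle_count, 1.7426e6, tolerance = 1e-4)
  g <- bin_geometry_at_mass(psd)
  expect_equal(g$surface_area_cm2, 0.21898, tolerance = 1e-4)

  # proportional rescaling preserves ratios
  st2 <- data.frame(stage = 1:2, cutoff_um = c(4, 2), mass_ug = c(1, 1))
  psd2 <- build_psd(st2, delivered_mass = 4)
  expect_equal(psd2$bins$mass_ug, c(2, 2))
  expect_equal(psd2$total_mass, 4)
  # masses already summing to the delivered amount are untouched
  psd3 <- build_psd(st2, delivered_mass = 2)
  expect_equal(psd3$bins$mass_ug, c(1, 1))

  expect_error(build_psd(data.frame(stage = 1:2, cutoff_um = c(4, 2),
                                    mass_ug = c(0, 0))), "degenerate")
  expect_error(build_psd(data.frame(stage = 1:2, cutoff_um = c(2, 4),
                                    mass_ug = c(1, 1))), "decreasing")
})

test_that("bin geometry follows cube-root shrinkage and handles exhaustion", {
  st <- data.frame(stage = 1:2, cutoff_um = c(4.46, 1.66), mass_ug = c(12, 8))
  psd <- build_psd(st)
  g0 <- bin_geometry_at_mass(psd)
  expect_equal(g0$radius_cm, psd$bins$geo_radius_cm, tolerance = 1e-12)
  gh <- bin_geometry_at_mass(psd, psd$bins$mass_ug / 2)
  expect_equal(gh$radius_cm, psd$bins$geo_radius_cm * 2^(-1 / 3),
               tolerance = 1e-12)
  gz <- bin_geometry_at_mass(psd, c(0, 0))
  expect_equal(gz$radius_cm, c(0, 0))
  expect_equal(gz$surface_area_cm2, c(0, 0))
  # arbitrary fractional dissolution matches analytic cube-root scaling
  for (f in c(0.9, 0.5, 0.1, 0.01)) {
    gf <- bin_geometry_at_mass(psd, psd$bins$mass_ug * f)
    expect_equal(gf$radius_cm, psd$bins$geo_radius_cm * f^(1 / 3),
                 tolerance = 1e-12)
  }
})

test_that("scale_psd rescales diameters and counts, conserving mass", {
  psd <- synthetic_psd(total_mass = 23)
  p2 <- scale_psd(psd, 2)
  expect_equal(p2$bins$particle_count, psd$bins$particle_count / 8,
               tolerance = 1e-12)
  expect_equal(sum(p2$bins$mass_ug), 23, tolerance = 1e-12)
  expect_equal(scale_psd(psd, 1), psd)
  back <- scale_psd(scale_psd(psd, 0.5), 2)
  expect_equal(back$bins, psd$bins, tolerance = 1e-12)
  expect_error(scale_psd(psd, 0), "> 0")
})

test_that("synthetic PSD integrates the lognormal onto stage cut-offs", {
  psd <- synthetic_psd(mmad = 3.7, gsd = 1.8, total_mass = 23)
  expect_equal(sum(psd$bins$mass_ug), 23, tolerance = 1e-12)
  expect_equal(psd_mmad(psd), 3.7, tolerance = 0.1)
  # near-degenerate GSD piles all mass into the bin containing the MMAD
  tight <- synthetic_psd(mmad = 3.7, gsd = 1.0001, total_mass = 10)
  expect_equal(tight$bins$mass_ug[tight$bins$cutoff_um == 2.82], 10,
               tolerance = 1e-6)
  # deterministic without jitter; deterministic under a fixed seed with it
  expect_identical(synthetic_psd(), synthetic_psd())
  j1 <- synthetic_psd(jitter_cv = 10, seed = 42)
  j2 <- synthetic_psd(jitter_cv = 10, seed = 42)
  expect_identical(j1, j2)
  expect_false(isTRUE(all.equal(j1$bins$mass_ug,
                                synthetic_psd()$bins$mass_ug)))
  expect_error(synthetic_psd(gsd = 1), "> 1")
  expect_error(synthetic_psd(cutoffs = c(2, 4)), "decreasing")
})

test_that("stage tables round-trip through CSV", {
  psd <- synthetic_psd(total_mass = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stage_table(psd, path)
  st <- read_stage_table(path)
  rebuilt <- build_psd(st, delivered_mass = 23)
  expect_equal(rebuilt$bins$mass_ug, psd$bins$mass_ug, tolerance = 1e-6)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,c\n1,2,3", bad)
  expect_error(read_stage_table(bad), "header")
})
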