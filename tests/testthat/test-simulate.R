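test_that("Hayduk-Laudie scaling and units are correct", {
  # unit arguments give the bare prefactor in cm^2/s
  expect_equal(hayduk_laudie_D(1, 1) / 3600, 13.26e-5, tolerance = 1e-12)
  # power-law scaling in molar volume
  expect_equal(hayduk_laudie_D(0.7, 600) / hayduk_laudie_D(0.7, 300),
               2^(-0.589), tolerance = 1e-12)
  expect_error(hayduk_laudie_D(-1, 100), "positive")
  # constructor falls back to Hayduk-Laudie when D is not given
  d <- drug_properties(diffusion_coefficient = NULL,
                       water_viscosity = 0.6913, molecular_volume = 313.5)
  expect_equal(d$diffusion_coefficient, hayduk_laudie_D(0.6913, 313.5))
})

test_that("solution runs match the piecewise closed form", {
  for (P in c(0.1, 0.289)) {
    cfg <- solution_config(P = P)
    sim <- transwell_sim(cfg)
    cf <- solution_closed_form(cfg)
    expect_equal(sim$time_min, cf$time_min)
    scale <- cfg$initial_amount
    expect_lt(max(abs(sim$receptor_amount - cf$receptor_amount)) / scale, 1e-6)
    expect_lt(max(abs(sim$donor_dissolved - cf$donor_dissolved)) / scale, 1e-6)
    expect_lt(max(abs(sim$observed$cumulative_percent -
                        cf$observed$cumulative_percent)), 1e-4)
  }
})

test_that("closed form honours the two-compartment equilibrium and rate", {
  cfg <- solution_config()
  # equilibrium receptor share of the remaining dissolved drug
  expect_equal(1.5 / (0.58 + 1.5), 0.7212, tolerance = 1e-4)
  kappa <- 0.289 * 4.52 * (1 / 0.58 + 1 / 1.5)
  expect_equal(kappa, 3.124, tolerance = 1e-3)
  cf <- solution_closed_form(cfg)
  # initial condition returned exactly
  expect_equal(cf$receptor_amount[1], 0)
  expect_equal(cf$donor_dissolved[1], cfg$initial_amount)
  # pre-first-sample trajectory is the single-exponential relaxation
  t_h <- cf$time_min[cf$time_min <= 10] / 60
  expected <- cfg$initial_amount * 0.72115 * (1 - exp(-kappa * t_h))
  expect_equal(cf$receptor_amount[cf$time_min <= 10], expected,
               tolerance = 1e-4)
})

test_that("mass is conserved and states stay physical", {
  sims <- list(
    transwell_sim(solution_config()),
    transwell_sim(particle_config()),
    transwell_sim(particle_config(Cs = 100, X0 = 50)),
    # full receptor replacement at every sample is the extreme edge case
    transwell_sim(particle_config(
      Cs = 19.12, schedule = sampling_schedule(sample_volume = 1.5)))
  )
  for (sim in sims) {
    expect_lt(mass_balance_error(sim), 1e-9)
    expect_true(all(sim$receptor_amount >= -1e-9))
    expect_true(all(diff(sim$observed$cumulative_percent) >= -1e-9))
    expect_true(all(sim$observed$cumulative_percent <= 100 + 1e-6))
  }
  # donor concentration never exceeds solubility beyond solver tolerance
  psim <- sims[[2]]
  expect_lt(max(psim$donor_concentration),
            psim$config$medium$solubility * (1 + 1e-6))
})

test_that("an impermeable membrane transfers nothing", {
  cfg <- solution_config(P = 0)
  sim <- transwell_sim(cfg)
  expect_equal(max(abs(sim$receptor_amount)), 0)
  expect_equal(max(abs(sim$removed_cumulative)), 0)
  expect_equal(sim$observed$cumulative_percent, rep(0, 9))
})

test_that("infinitely soluble particles behave like a solution", {
  pcfg <- particle_config(Cs = 1e6, F = 1)
  scfg <- pcfg; scfg$psd <- NULL
  cmp <- f1_f2(transwell_sim(scfg), transwell_sim(pcfg))
  expect_lt(cmp$f1, 1)
  expect_equal(cmp$verdict, "similar")
})

test_that("adaptive integration agrees with the fixed-step Euler oracle", {
  sch <- diffusion_schedule()
  configs <- list(
    solution_config(),
    particle_config(schedule = sch),
    particle_config(Cs = 19.12, schedule = sch)
  )
  for (cfg in configs) {
    ad <- transwell_sim(cfg)
    eu <- transwell_sim_euler(cfg, dt_min = 0.01)
    expect_lt(max(abs(ad$observed$cumulative_percent -
                        eu$observed$cumulative_percent)), 0.5)
  }
})

test_that("higher solubility never slows the observed profile", {
  base <- particle_config(Cs = 5.3,
                          schedule = diffusion_schedule())
  lo <- transwell_sim(base)
  hi_cfg <- base; hi_cfg$medium$solubility <- 19.12
  hi <- transwell_sim(hi_cfg)
  expect_true(all(hi$observed$cumulative_percent >=
                    lo$observed$cumulative_percent - 1e-9))
})

test_that("sampling jumps remove exactly the aliquot share", {
  cfg <- solution_config()
  sim <- transwell_sim(cfg)
  obs <- sim$observed
  # cumulative percent is receptor content just before the sample plus all
  # previously removed material: reconstruct the first two samples by hand
  i10 <- which(sim$time_min == 10)[1]
  expect_equal(obs$cumulative_percent[1],
               100 * sim$receptor_amount[i10] / cfg$initial_amount,
               tolerance = 1e-9)
  removed1 <- sim$receptor_amount[i10] * 0.5 / 1.5
  i20 <- which(sim$time_min == 20)[1]
  expect_equal(sim$removed_cumulative[i20], removed1, tolerance = 1e-7)
})

test_that("simulation output round-trips as a tidy data frame", {
  sim <- transwell_sim(particle_config(schedule = diffusion_schedule()))
  df <- as.data.frame(sim)
  expect_true(all(c("time_min", "donor_dissolved_ug", "receptor_ug",
                    "removed_ug", "cumulative_percent") %in% names(df)))
  expect_equal(nrow(df), length(sim$time_min))
  expect_equal(sum(grepl("^bin", names(df))), nrow(sim$config$psd$bins))
})
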