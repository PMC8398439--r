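bench_times <- c(10, 20, 30, 45, 60, 90, 120, 180, 240, 360, 480, 720, 1440)

test_that("f1/f2 reproduce hand-computed values and identity cases", {
  r <- transfer_profile(c(10, 20, 30), c(10, 20, 30))
  expect_equal(f1_f2(r, r)$f1, 0)
  expect_equal(f1_f2(r, r)$f2, 100)
  expect_equal(f1_f2(r, r)$verdict, "similar")
  s <- transfer_profile(c(10, 20, 30), c(12, 22, 32))
  cmp <- f1_f2(r, s)
  expect_equal(cmp$f1, 10.0, tolerance = 1e-12)
  expect_equal(cmp$f2, 50 * log10(100 / sqrt(5)), tolerance = 1e-12)
  expect_equal(cmp$f2, 82.53, tolerance = 1e-3)
  expect_equal(cmp$verdict, "similar")
  # the paper's decision rule needs BOTH f1 > 15 and f2 < 50
  far <- transfer_profile(c(10, 20, 30), c(40, 55, 70))
  worse <- f1_f2(r, far)
  expect_gt(worse$f1, 15); expect_lt(worse$f2, 50)
  expect_equal(worse$verdict, "different")
})

test_that("f2 decreases strictly as a constant offset grows", {
  r <- weibull_profile(bench_times, 600, 1)
  offsets <- c(1, 2, 5, 8)
  f2s <- vapply(offsets, function(d) {
    s <- transfer_profile(r$time_min, r$cumulative_percent + d)
    f1_f2(r, s)$f2
  }, numeric(1))
  expect_true(all(diff(f2s) < 0))
})

test_that("f1/f2 input contracts are enforced", {
  r <- transfer_profile(c(10, 20, 30), c(10, 20, 30))
  z <- transfer_profile(c(10, 20, 30), c(0, 0, 0))
  expect_error(f1_f2(z, r), "undefined")
  s <- transfer_profile(c(100, 200, 300), c(1, 2, 3))
  expect_error(f1_f2(r, s), "common")
  # mismatched grids are restricted to the common subset
  r2 <- transfer_profile(c(10, 20, 30, 45), c(10, 20, 30, 40))
  expect_equal(f1_f2(r, r2)$n_points, 3)
  # optional regulatory truncation one point past 85%
  ref <- transfer_profile(c(10, 20, 30, 45, 60), c(40, 70, 86, 95, 99))
  tst <- transfer_profile(c(10, 20, 30, 45, 60), c(35, 64, 80, 94, 98))
  expect_equal(f1_f2(ref, tst, truncate_after_85 = TRUE)$n_points, 3)
})

test_that("Weibull fitting recovers exact generating parameters", {
  for (par in list(c(120, 1.2), c(6, 0.5), c(3000, 3), c(35, 0.74))) {
    pr <- weibull_profile(bench_times, par[1], par[2])
    fit <- fit_weibull(pr)
    expect_equal(fit$mdt_min, par[1], tolerance = 1e-6)
    expect_equal(fit$shape, par[2], tolerance = 1e-6)
    expect_lt(fit$residual_sse, 1e-10)
  }
  # b = 1 is the exponential: MDT equals the mean time 1/lambda
  lambda <- 1 / 90
  pr <- transfer_profile(bench_times, 100 * (1 - exp(-lambda * bench_times)))
  expect_equal(fit_weibull(pr)$mdt_min, 90, tolerance = 1e-6)
})

test_that("Weibull fit rejects degenerate profiles", {
  expect_error(fit_weibull(transfer_profile(c(10, 20), c(10, 50))), "3")
  expect_error(fit_weibull(transfer_profile(c(10, 20, 30), c(50, 51, 52))),
               "flat")
})

test_that("MDT is reported in both minutes and hours", {
  fit <- fit_weibull(weibull_profile(bench_times, 120, 1.2))
  expect_equal(fit$mdt_hours, fit$mdt_min / 60)
  expect_equal(unname(coef(fit)["mdt_min"]), fit$mdt_min)
  expect_equal(predict(fit, 120), 100 * (1 - exp(-1)), tolerance = 1e-6)
})

test_that("time_to_fraction interpolates the first crossing", {
  # exact Weibull with MDT = 60 min, b = 1: 63.2% at exactly 60 min
  pr <- weibull_profile(c(10, 30, 60, 90, 240), 60, 1)
  expect_equal(time_to_fraction(pr, 1 - exp(-1)), 60, tolerance = 1e-6)
  expect_equal(time_to_fraction(pr, 0), 0)
  p <- transfer_profile(c(30, 60, 90), c(30, 60, 90))
  expect_equal(time_to_fraction(p, 0.45), 45)
  expect_error(time_to_fraction(p, 0.95), "attains")
  expect_error(time_to_fraction(p, 2), "0, 1")
})

test_that("mdt_ratio is 1 for identical runs and in the no-saturation limit", {
  sim <- transwell_sim(particle_config(schedule = diffusion_schedule()))
  expect_equal(mdt_ratio(sim, sim), 1)
  # infinite solubility: no mass effect, dose does not change kinetics
  sch <- diffusion_schedule()
  hi <- transwell_sim(particle_config(Cs = 1e6, X0 = 30, schedule = sch))
  lo <- transwell_sim(particle_config(Cs = 1e6, X0 = 10, schedule = sch))
  expect_equal(mdt_ratio(hi, lo), 1, tolerance = 1e-3)
})

test_that("profiles round-trip through CSV", {
  pr <- weibull_profile(bench_times, 120, 1.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(pr, path)
  back <- read_profile(path)
  expect_equal(back$cumulative_percent, pr$cumulative_percent,
               tolerance = 1e-6)
  expect_s3_class(back, "transfer_profile")
})
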