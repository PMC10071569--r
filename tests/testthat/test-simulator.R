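# Synthetic cultivation, VOC emission and spectrum rendering

test_that("default cultivation reaches its OD maximum between day 5 and 6", {
  traj <- simulate_cultivation(cultivation_config())
  t_max <- traj$time_h[which.max(traj$od750)]
  expect_gt(t_max, 5 * 24)
  expect_lt(t_max, 6 * 24)
  expect_equal(traj$od750[1], 0.11)
})

test_that("zero growth rate keeps OD constant and state dynamics are noise-free", {
  cc0 <- cultivation_config(growth_rate = 0, death_onset_day = 99)
  traj0 <- simulate_cultivation(cc0)
  expect_true(all(traj0$od750 == 0.11))
  # the trajectory is deterministic: the seed only affects measurement noise
  t1 <- simulate_cultivation(cultivation_config(seed = 1))
  t2 <- simulate_cultivation(cultivation_config(seed = 2))
  expect_identical(t1$od750, t2$od750)
})

test_that("phase labels are consistent with the OD dynamics and never reverse", {
  traj <- simulate_cultivation(cultivation_config())
  d_od <- diff(traj$od750)
  ph <- traj$phase
  expect_true(all(d_od[ph[-nrow(traj)] == "lag_growth"] >= 0))
  expect_true(all(d_od[ph[-1] == "death" & ph[-nrow(traj)] == "death"] < 0))
  ord <- c(lag_growth = 1, stationary = 2, death = 3)
  expect_true(all(diff(ord[ph]) >= 0))
  expect_true(all(c("lag_growth", "stationary", "death") %in% ph))
})

test_that("illumination schedule and step changes are honoured", {
  cc <- cultivation_config(illumination_level = 0.6,
                           illumination_steps = data.frame(time_h = 24,
                                                           level = 2.0))
  traj <- simulate_cultivation(cc)
  expect_true(all(traj$illumination[traj$time_h < 24] == 0.6))
  expect_true(all(traj$illumination[traj$time_h >= 24] == 2.0))
  # 16 h on / 8 h off
  expect_true(all(traj$light_on[traj$time_h %% 24 < 16]))
  expect_true(all(!traj$light_on[traj$time_h %% 24 >= 16]))
})

test_that("emission amplitudes follow growth, light and death dynamics", {
  cc <- cultivation_config()
  growth_lit <- list(od750 = 0.5, illumination = 1, light_on = TRUE,
                     phase = "lag_growth")
  growth_dark <- modifyList(growth_lit, list(light_on = FALSE))
  death <- list(od750 = 0.6, illumination = 1, light_on = TRUE,
                phase = "death")
  e_lit <- emission_profile(growth_lit, cc)
  e_dark <- emission_profile(growth_dark, cc)
  e_death <- emission_profile(death, cc)
  # growth peaks drop when the light goes off
  expect_true(all(e_dark[c("c", "d", "e")] < e_lit[c("c", "d", "e")]))
  # death marker absent during growth, present in decline
  expect_equal(unname(e_lit["g"]), 0)
  expect_gt(e_death[["g"]], e_lit[["g"]])
  # over-illumination marker
  over <- modifyList(growth_lit, list(illumination = 2.0))
  low <- modifyList(growth_lit, list(illumination = 0.6))
  expect_gt(emission_profile(over, cc)[["f"]], 0)
  expect_equal(emission_profile(low, cc)[["f"]], 0)
  # RIP dominates every profile
  expect_equal(names(which.max(e_lit)), "RIP")
  # unknown species is rejected
  bad <- cc; bad$species <- "kelp"
  expect_error(emission_profile(growth_lit, bad), "species")
})

test_that("chlorella emits a distinct pattern entirely below trel 1.2", {
  pk <- default_peak_defs("chlorella")
  expect_true(all(pk$center < 1.2))
  cc <- cultivation_config(species = "chlorella")
  e <- emission_profile(list(od750 = 0.5, illumination = 1, light_on = TRUE,
                             phase = "lag_growth"), cc)
  expect_true(all(paste0("p", 1:5) %in% names(e)))
  expect_false(any(letters[1:7] %in% names(e)))
})

test_that("rendered spectra are sums of Gaussians with seeded noise", {
  pk <- default_peak_defs()
  single <- c(d = 25, RIP = 1000)
  s <- render_spectrum(single, pk, noise_sd = 0, baseline = 0)
  td_rip <- drift_time(2.1, instrument_config())
  trel <- s$drift_time_ms / td_rip
  off_rip <- trel > 1.1
  # noiseless rendering: off-RIP maximum equals the amplitude at the center
  expect_equal(max(s$intensity[off_rip]), 25, tolerance = 1e-3)
  expect_equal(trel[off_rip][which.max(s$intensity[off_rip])],
               pk$center[pk$label == "d"], tolerance = 1e-3)
  # axis density: >= 1000 samples between trel 0.7 and 3
  expect_gte(sum(trel >= 0.7 & trel <= 3), 1000)
  # seeded determinism
  s1 <- render_spectrum(single, pk, noise_sd = 1, seed = 99)
  s2 <- render_spectrum(single, pk, noise_sd = 1, seed = 99)
  expect_identical(s1$intensity, s2$intensity)
  # non-negative after clipping
  expect_true(all(s1$intensity >= 0))
  # center outside the axis is rejected
  bad <- peak_defs("z", 5.0)
  expect_error(render_spectrum(c(z = 1, RIP = 10), bad), "outside")
})

test_that("a default series has one spectrum per 10 minutes and a dominant RIP", {
  sim <- fx_sim()
  expect_equal(length(sim$series), 8 * 24 * 6) # 1152
  expect_equal(nrow(sim$truth), 1152)
  td_rip <- drift_time(2.1, instrument_config())
  for (i in c(1, 500, 1152)) {
    sp <- sim$series$spectra[[i]]
    expect_equal(sp$drift_time_ms[which.max(sp$intensity)], td_rip,
                 tolerance = 0.01)
  }
  # ground-truth peak d reaches its maximum at or before the OD maximum
  d_amp <- sim$emissions[, "d"]
  expect_lte(sim$truth$time_h[which.max(d_amp)],
             sim$truth$time_h[which.max(sim$truth$od750)])
  # empty edge case
  sim0 <- simulate_series(cultivation_config(duration_days = 0))
  expect_equal(length(sim0$series), 0)
})

test_that("identical config and seed reproduce the series bit for bit", {
  cc <- cultivation_config(duration_days = 0.25, seed = 31)
  a <- simulate_series(cc)
  b <- simulate_series(cc)
  expect_identical(
    lapply(a$series$spectra, function(s) s$intensity),
    lapply(b$series$spectra, function(s) s$intensity)
  )
})

test_that("offline OD sampling reproduces the manual photometry protocol", {
  traj <- fx_sim()$truth
  # noiseless measurement returns the true OD
  od0 <- sample_offline_od(traj, cv = 0, seed = 5)
  truth_at <- approx(traj$time_h, traj$od750, xout = od0$time_h)$y
  expect_equal(od0$od750_mean, truth_at, tolerance = 1e-12)
  # 5 samplings/day over 8 days = 40 sampling times
  expect_equal(nrow(od0), 40)
  # replicate noise is reproducible under a fixed seed
  a <- sample_offline_od(traj, replicates = 6, cv = 0.02, seed = 7)
  b <- sample_offline_od(traj, replicates = 6, cv = 0.02, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$od750_sd > 0))
  expect_error(sample_offline_od(traj, cv = -0.1), "cv")
})
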