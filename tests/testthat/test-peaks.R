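# Peak detection, labelling, Gaussian quantification, time series

test_that("a mid-growth spectrum with the full a-g set yields exactly 7 labelled peaks", {
  pk <- default_peak_defs()
  s <- render_spectrum(fx_full_profile(), pk, noise_sd = 1, seed = 17)
  ns <- normalize_spectrum(s)
  noise <- estimate_noise(ns)
  det <- detect_peaks(ns, noise)
  m <- match_known_peaks(det, pk)
  expect_equal(nrow(det), 7)
  expect_setequal(m$label, letters[1:7])
  expect_false(any(m$novel))
})

test_that("pure-noise spectra produce (almost) no detections", {
  pk <- default_peak_defs()
  set.seed(23)
  n_det <- vapply(1:40, function(i) {
    s <- render_spectrum(c(RIP = 1000, pre_RIP = 50), pk, noise_sd = 1)
    ns <- normalize_spectrum(s)
    nrow(detect_peaks(ns, estimate_noise(ns)))
  }, numeric(1))
  # expected false-positive rate < 5% per spectrum
  expect_lt(mean(n_det > 0), 0.05)
})

test_that("detected centers agree with a brute-force oracle on rendered Gaussians", {
  pk <- peak_defs(c("p", "q", "r"), c(1.3, 1.7, 2.1), 0.015)
  prof <- c(p = 20, q = 25, r = 15, RIP = 1000) # ~5x LOD and above
  s <- render_spectrum(prof, pk, noise_sd = 1, seed = 4)
  ns <- normalize_spectrum(s)
  det <- detect_peaks(ns, estimate_noise(ns))
  expect_equal(nrow(det), 3)
  expect_equal(det$trel, pk$center, tolerance = 0.01)
  # oracle: strict local maxima of the noiseless re-render above threshold
  s0 <- render_spectrum(prof, pk, noise_sd = 0, baseline = 10)
  ns0 <- normalize_spectrum(s0)
  y <- ns0$intensity
  i <- 2:(length(y) - 1)
  oracle <- ns0$rel_axis[i][y[i] > y[i - 1] & y[i] > y[i + 1] &
                             y[i] > 13 & ns0$rel_axis[i] > 1.05]
  expect_equal(sort(det$trel), sort(oracle), tolerance = 0.01)
})

test_that("detection is invariant under joint scaling of spectrum and noise", {
  pk <- default_peak_defs()
  s <- render_spectrum(fx_full_profile(), pk, noise_sd = 1, seed = 29)
  ns <- normalize_spectrum(s)
  det1 <- detect_peaks(ns, estimate_noise(ns))
  ns5 <- make_nspec(ns$rel_axis, 5 * ns$intensity)
  det5 <- detect_peaks(ns5, estimate_noise(ns5))
  expect_equal(det5$trel, det1$trel)
  expect_equal(det5$intensity, 5 * det1$intensity, tolerance = 1e-9)
})

test_that("matching assigns nearest labels, prefers intensity, flags novelty", {
  pk <- peak_defs(c("a", "b"), c(1.3, 1.5), 0.015)
  # exact centers: one-to-one
  d <- data.frame(trel = c(1.3, 1.5), intensity = c(5, 7))
  m <- match_known_peaks(d, pk)
  expect_equal(m$label, c("a", "b"))
  # far detection is novel
  d2 <- data.frame(trel = 2.4, intensity = 9)
  expect_true(match_known_peaks(d2, pk)$novel)
  # two detections within tolerance of one center: intensity wins,
  # the loser stays unassigned (it is inside the footprint, so not novel)
  d3 <- data.frame(trel = c(1.295, 1.31), intensity = c(3, 8))
  m3 <- match_known_peaks(d3, pk)
  expect_equal(m3$label, c(NA_character_, "a"))
  expect_false(any(m3$novel))
  # brute-force check of this 2-case instance: the optimal single
  # assignment (max total matched intensity) also picks the 8
  expect_equal(m3$intensity[m3$label == "a" & !is.na(m3$label)], 8)
})

test_that("the fixed-center Gaussian model recovers amplitudes exactly when noiseless", {
  x <- seq(0.7, 3, length.out = 1150)
  pk <- peak_defs("d", 1.43, 0.015)
  ns <- make_nspec(x, gauss_mix(x, 1.43, 0.015, 10))
  fit <- fit_gaussian_model(ns, pk)
  expect_equal(unname(fit$amplitudes), 10, tolerance = 1e-9)
  expect_equal(fit$baseline, 0, tolerance = 1e-9)
  # zero spectrum: all amplitudes zero
  z <- fit_gaussian_model(make_nspec(x, rep(0, length(x))), default_peak_defs())
  expect_true(all(z$amplitudes == 0))
  # identical center/width pairs are a singular design
  dup <- structure(data.frame(label = c("u", "v"), center = c(1.4, 1.4),
                              width_sigma = 0.015),
                   class = c("peak_defs", "data.frame"))
  expect_error(fit_gaussian_model(ns, dup), "singular")
})

test_that("overlapping peaks are resolved within 5% and match the normal-equations oracle", {
  x <- seq(0.7, 3, length.out = 1150)
  pk <- peak_defs(c("p", "q"), c(1.30, 1.34), 0.02)
  set.seed(8)
  y <- gauss_mix(x, c(1.30, 1.34), c(0.02, 0.02), c(10, 5)) + rnorm(1150, 0, 0.1)
  ns <- make_nspec(x, y)
  fit <- fit_gaussian_model(ns, pk, baseline_term = FALSE)
  expect_equal(unname(fit$amplitudes), c(10, 5), tolerance = 0.05)
  # independent oracle: solve the normal equations directly
  G <- cbind(exp(-(x - 1.30)^2 / (2 * 0.02^2)),
             exp(-(x - 1.34)^2 / (2 * 0.02^2)))
  oracle <- solve(t(G) %*% G, t(G) %*% y)
  plain <- fit_gaussian_model(ns, pk, nonneg = FALSE, baseline_term = FALSE)
  expect_equal(unname(plain$amplitudes), as.numeric(oracle), tolerance = 1e-9)
})

test_that("non-negative least squares matches the oracle on random noiseless mixtures", {
  x <- seq(0.7, 3, length.out = 1150)
  set.seed(13)
  for (rep in 1:5) {
    centers <- sort(runif(10, 1.1, 2.8))
    while (min(diff(centers)) < 0.08) centers <- sort(runif(10, 1.1, 2.8))
    amps <- runif(10, 1, 50)
    pk <- peak_defs(sprintf("k%02d", 1:10), centers, 0.015)
    ns <- make_nspec(x, gauss_mix(x, centers, rep(0.015, 10), amps))
    fit <- fit_gaussian_model(ns, pk, baseline_term = FALSE)
    expect_equal(unname(fit$amplitudes), amps, tolerance = 1e-6)
  }
})

test_that("fit amplitudes equal apex intensities for well-separated noiseless peaks", {
  x <- seq(0.7, 3, length.out = 2000)
  centers <- c(1.2, 1.5, 1.9, 2.4) # separation >> 6 sigma
  amps <- c(30, 12, 50, 8)
  pk <- peak_defs(letters[1:4], centers, 0.015)
  ns <- make_nspec(x, gauss_mix(x, centers, rep(0.015, 4), amps))
  fit <- fit_gaussian_model(ns, pk)
  apex <- vapply(centers, function(cc) max(ns$intensity[abs(x - cc) < 0.02]),
                 numeric(1))
  expect_equal(unname(fit$amplitudes) / apex, rep(1, 4), tolerance = 0.01)
})

test_that("peak time series track growth, light and the OD maximum", {
  pt <- fx_peak_table()
  sim <- fx_sim()
  d <- pt[pt$label == "d", ]
  # apex-series maximum at or before the OD maximum
  t_od_max <- sim$truth$time_h[which.max(sim$truth$od750)]
  expect_lte(d$time_h[which.max(d$fitted_amplitude)], t_od_max)
  # c,d,e drop at a light-off transition (day 2, hour 16)
  cde <- pt[pt$label %in% c("c", "d", "e"), ]
  before <- cde$apex_intensity[cde$time_h == 15.5 + 24]
  after <- cde$apex_intensity[cde$time_h == 16.5 + 24]
  expect_true(all(after < before))
  # g is flagged below LOD throughout growth, present after stationary onset
  g <- pt[pt$label == "g", ]
  growth <- sim$truth$phase == "lag_growth"
  expect_gt(mean(g$below_lod[growth]), 0.99)
  expect_true(all(!g$below_lod[sim$truth$phase == "death"]))
})

test_that("a series of identical spectra yields a constant time series", {
  grid <- default_rel_grid()
  y <- gauss_mix(grid, c(1.43, 1.6), c(0.015, 0.015), c(20, 10), baseline = 5)
  nspecs <- lapply(0:3, function(t) make_nspec(grid, y, t))
  m <- to_common_axis(nspecs, grid)
  pre <- list(matrix = m, grid = grid, timestamps = 0:3,
              normalized = nspecs,
              noise = lapply(1:4, function(i) list(sigma = 0.5, lod = 1.5,
                                                   baseline = 5)))
  pt <- extract_time_series(pre, default_peak_defs())
  for (lb in unique(pt$label)) {
    vals <- pt$fitted_amplitude[pt$label == lb]
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-9)
  }
})

test_that("novel-peak flagging fires on contamination with full sensitivity when noiseless", {
  known <- default_peak_defs()
  contaminated <- peak_defs(c(known$label, "x"), c(known$center, 1.9), 0.015)
  prof <- c(fx_full_profile()[letters[1:7]], x = 25,
            RIP = 1000, pre_RIP = 50)
  for (i in 1:5) {
    s <- render_spectrum(prof, contaminated, noise_sd = 0, timestamp_h = i)
    ns <- normalize_spectrum(s)
    det <- detect_peaks(ns, list(sigma = 0, lod = 0, baseline = 10))
    m <- match_known_peaks(det, known)
    expect_true(any(m$novel & abs(m$trel - 1.9) < 0.02))
  }
  # and stays silent without the contaminant
  clean <- render_spectrum(fx_full_profile(), known, noise_sd = 0)
  ncl <- normalize_spectrum(clean)
  mcl <- match_known_peaks(detect_peaks(ncl, list(sigma = 0, lod = 0,
                                                  baseline = 10)), known)
  expect_false(any(mcl$novel))
})
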