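# Rule engine and reference analytics

# synthetic score trajectory: linear segments per component, 10-min steps
make_scores <- function(n, pc1, pc2, pc3 = rep(0, n)) {
  sc <- cbind(PC1 = pc1, PC2 = pc2, PC3 = pc3, PC4 = rep(0, n))
  attr(sc, "timestamps") <- (seq_len(n) - 1) / 6
  sc
}

test_that("each published rule fires on its canonical score pattern", {
  n <- 30
  th <- control_thresholds()
  # (1) PC1 rising, PC2 constant -> the culture grows, CONTINUE
  r1 <- classify_scores(make_scores(n, pc1 = seq(0, 15, length.out = n),
                                    pc2 = rep(0, n)), th)
  expect_true(all(r1$action[th$window:n] == "CONTINUE"))
  expect_match(r1$triggering_rule[n], "growing")
  # (3) PC2 increasing as PC1 falls off its maximum -> harvest or check
  # for contamination
  r3 <- classify_scores(make_scores(n, pc1 = seq(20, 0, length.out = n),
                                    pc2 = seq(0, 15, length.out = n)), th)
  expect_true(all(r3$action[th$window:n] == "HARVEST_OR_CHECK_CONTAMINATION"))
  # shading rule: PC3 below -5
  r5 <- classify_scores(make_scores(n, pc1 = rep(0, n), pc2 = rep(0, n),
                                    pc3 = rep(-6, n)), th)
  expect_true(all(r5$action[th$window:n] == "SHADE"))
  # (4) PC2 strongly negative -> unknown status, check the system
  r4 <- classify_scores(make_scores(n, pc1 = rep(0, n), pc2 = rep(-40, n)), th)
  expect_true(all(r4$action[th$window:n] == "CHECK_SYSTEM"))
  # safety precedence: SHADE dominates CHECK_SYSTEM
  r6 <- classify_scores(make_scores(n, pc1 = rep(0, n), pc2 = rep(-40, n),
                                    pc3 = rep(-6, n)), th)
  expect_true(all(r6$action[th$window:n] == "SHADE"))
  # warm-up period carries INSUFFICIENT_DATA
  expect_true(all(r1$action[1:(th$window - 1)] == "INSUFFICIENT_DATA"))
  expect_error(classify_scores(make_scores(0, numeric(0), numeric(0))),
               "empty")
})

test_that("classification is a pure function of its inputs", {
  sc <- fx_scores()
  a <- classify_scores(sc, control_thresholds(), peak_table = fx_peak_table(),
                       novel = fx_novel())
  b <- classify_scores(sc, control_thresholds(), peak_table = fx_peak_table(),
                       novel = fx_novel())
  expect_identical(a, b)
})

test_that("a clean default cultivation follows the narrative recommendation sequence", {
  recs <- classify_scores(fx_scores(), control_thresholds(),
                          peak_table = fx_peak_table(), novel = fx_novel())
  truth <- fx_sim()$truth
  growth <- truth$phase == "lag_growth"
  # growth: only CONTINUE (or a day/night dip while dark)
  expect_true(all(recs$action[growth] %in%
                    c("CONTINUE", "DAY_NIGHT_DIP", "INSUFFICIENT_DATA")))
  expect_equal(names(which.max(table(recs$action[growth]))), "CONTINUE")
  # day/night dips only while the light is off
  expect_true(all(!truth$light_on[recs$action == "DAY_NIGHT_DIP"]))
  # harvest-or-feed appears at the OD plateau
  hf <- recs$time_h[recs$action == "HARVEST_OR_FEED"]
  expect_gt(length(hf), 0)
  stationary_start <- min(truth$time_h[truth$phase == "stationary"])
  expect_gte(min(hf), stationary_start)
  # decline is read as harvest-or-check-contamination, after the plateau
  hc <- recs$time_h[recs$action == "HARVEST_OR_CHECK_CONTAMINATION"]
  expect_gt(length(hc), 0)
  expect_gte(min(hc), stationary_start)
  expect_lte(min(hf), min(hc))
  death_start <- min(truth$time_h[truth$phase == "death"])
  expect_gt(sum(hc >= death_start), 50) # decline dominates the death phase
  # neither shading nor the unknown-status alarm fire on a clean culture
  expect_false(any(recs$action %in% c("SHADE", "CHECK_SYSTEM")))
})

test_that("shading is recommended within 1 h of a 60% -> 200% illumination step", {
  sc3 <- transform_scores(state_matrix(fx_step_pre()$matrix), fx_model())
  recs <- classify_scores(sc3, control_thresholds())
  shade_t <- recs$time_h[recs$action == "SHADE"]
  expect_gt(length(shade_t), 0)
  expect_lte(min(shade_t) - 24, 1) # step occurs at t = 24 h
  # and never before the step
  expect_true(all(shade_t >= 24))
})

test_that("OD750 converts linearly to dry weight", {
  expect_equal(od_to_dryweight(1.0), 0.86)
  expect_equal(od_to_dryweight(0), 0)
  expect_equal(od_to_dryweight(0.11), 0.0946)
  # linear and homogeneous
  x <- c(0.2, 0.7, 1.9)
  expect_equal(od_to_dryweight(3 * x), 3 * od_to_dryweight(x))
  expect_error(od_to_dryweight(-0.1), ">= 0")
})

test_that("peak-OD correlation returns R^2 = 1 for proportional series", {
  t <- seq(0, 100, by = 2)
  od <- data.frame(time_h = seq(5, 95, by = 10),
                   od750_mean = approx(t, 0.1 * exp(0.03 * t),
                                       seq(5, 95, by = 10))$y)
  ps <- data.frame(time_h = t, intensity = 40 * 0.1 * exp(0.03 * t))
  r <- correlate_peak_with_od(ps, od, growth_only = FALSE)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$slope, 40, tolerance = 1e-6)
  # degenerate constant series is an explicit error
  flat <- data.frame(time_h = t, intensity = rep(3, length(t)))
  expect_error(correlate_peak_with_od(flat, od, growth_only = FALSE),
               "degenerate")
  expect_error(correlate_peak_with_od(ps, od[1:2, ], growth_only = FALSE),
               ">= 3")
})

test_that("uncorrelated noise gives a low R^2 against the Monte-Carlo null", {
  # null distribution of R^2 with n = 30: P(R^2 > 0.3) << 5%
  set.seed(19)
  od <- data.frame(time_h = 1:30, od750_mean = seq(0.1, 1, length.out = 30))
  r2 <- vapply(1:50, function(i) {
    ps <- data.frame(time_h = 1:30, intensity = rnorm(30))
    correlate_peak_with_od(ps, od, growth_only = FALSE)$r_squared
  }, numeric(1))
  expect_gte(mean(r2 < 0.3), 0.95)
})

test_that("Welch t-test matches the textbook oracle and flags phase changes", {
  pt_flat <- data.frame(time_h = rep(1:10, 2),
                        label = rep(c("a", "b"), each = 10),
                        apex_intensity = rep(c(2, 5), each = 10),
                        fitted_amplitude = rep(c(2, 5), each = 10),
                        below_lod = FALSE)
  # identical windows: t = 0, p = 1
  r <- growth_phase_significance(pt_flat, c(1, 5), c(6, 10))
  expect_equal(r$t_statistic, c(0, 0))
  expect_equal(r$p_value, c(1, 1))
  # N(0,1) baseline vs N(5,1) phase
  set.seed(21)
  b <- rnorm(20); p <- rnorm(20, 5)
  pt2 <- data.frame(time_h = c(1:20, 101:120), label = "a",
                    apex_intensity = c(b, p), fitted_amplitude = c(b, p),
                    below_lod = FALSE)
  r2 <- growth_phase_significance(pt2, c(1, 20), c(101, 120))
  expect_lt(r2$p_value, 0.001)
  # textbook Welch oracle computed from first principles
  se <- sqrt(var(b) / 20 + var(p) / 20)
  t_oracle <- (mean(p) - mean(b)) / se
  df_oracle <- se^4 / ((var(b) / 20)^2 / 19 + (var(p) / 20)^2 / 19)
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  expect_equal(r2$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(r2$p_value, p_oracle, tolerance = 1e-12)
})

test_that("growth and death markers change significantly over a cultivation", {
  pt <- fx_peak_table()
  res <- growth_phase_significance(pt, baseline_window = c(0, 12),
                                   phase_window = c(96, 108))
  for (lb in c("c", "d", "e")) {
    expect_lt(res$p_value[res$label == lb], 0.05)
  }
  res_g <- growth_phase_significance(pt, baseline_window = c(0, 12),
                                     phase_window = c(168, 180))
  expect_lt(res_g$p_value[res_g$label == "g"], 0.05)
})
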