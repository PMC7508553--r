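test_that("normalisation divides (or subtracts) the per-generation reference mean", {
  nc <- data.frame(line_id = rep(1:2, each = 2), generation = rep(0:1, 2),
                   pooled_f = c(0.55, 0.60, 0.65, 0.60))   # means: 0.60, 0.60
  co <- data.frame(line_id = 9, generation = 0:1, pooled_f = c(0.30, 0.24))
  expect_equal(normalize_to_noncompeted(co, nc)$value, c(0.50, 0.40))
  expect_equal(normalize_to_noncompeted(co, nc, "difference")$value,
               c(-0.30, -0.36))
  # a competed line tracking the reference exactly is flat at 1
  flat <- data.frame(line_id = 1, generation = 0:1, pooled_f = c(0.60, 0.60))
  expect_equal(normalize_to_noncompeted(flat, nc)$value, c(1, 1))
  bad <- data.frame(line_id = 1, generation = 0:3, pooled_f = rep(0.5, 4))
  expect_error(normalize_to_noncompeted(bad, nc), "cover")
})

test_that("self-normalisation identity holds to machine precision", {
  nc <- simulate_competition(8, 10, 100, preset = condition_presets("wt_live"),
                             competed = FALSE, seed = 31)
  tr <- normalize_to_noncompeted(nc, nc)
  per_gen <- as.vector(tapply(tr$value, tr$generation, mean))
  expect_equal(per_gen, rep(1, 11), tolerance = 1e-14)
  td <- normalize_to_noncompeted(nc, nc, "difference")
  expect_equal(as.vector(tapply(td$value, td$generation, mean)), rep(0, 11),
               tolerance = 1e-14)
  # and the regression slope of the self-normalised means is exactly zero
  fit <- fit_org_decline(data.frame(line_id = 1, generation = 0:10,
                                    value = per_gen),
                         n_boot = 50, seed = 1)
  expect_equal(fit$slope_hat, 0, tolerance = 1e-12)
})

test_that("organismal decline fits recover flat and geometric trajectories", {
  flat <- data.frame(line_id = rep(1:2, each = 6), generation = rep(0:5, 2),
                     value = 1)
  f0 <- fit_org_decline(flat, n_boot = 100, seed = 1)
  expect_equal(f0$slope_hat, 0)
  expect_equal(f0$s_org, 0)
  # exact geometric decline, ratio 0.9 per generation
  geo <- data.frame(line_id = 1, generation = 0:8, value = 0.9^(0:8))
  fg <- fit_org_decline(geo, n_boot = 100, seed = 1)
  expect_equal(fg$s_org, 0.1, tolerance = 1e-10)
  expect_lt(fg$slope_hat, 0)
  expect_error(fit_org_decline(data.frame(line_id = 1, generation = 0,
                                          value = 1)), "2 generations")
})

test_that("default competed lines decline relative to the non-competed reference", {
  co <- simulate_competition(8, 10, 150, preset = condition_presets("wt_live"),
                             competed = TRUE, seed = 41)
  nc <- simulate_competition(8, 10, 150, preset = condition_presets("wt_live"),
                             competed = FALSE, seed = 42)
  # lines that lose the deletion entirely produce zero frequencies, which the
  # log-linear fit drops with a warning by design
  fit <- suppressWarnings(
    fit_org_decline(normalize_to_noncompeted(co, nc), n_boot = 300, seed = 1))
  expect_lt(fit$slope_hat, 0)
  expect_lt(fit$ci[2], 0)   # interval excludes zero
})

test_that("neutral competition gives slope intervals covering zero near nominal rate", {
  p <- neutral_preset(bottleneck = 800, shift_sd = 0.035)
  cover <- vapply(1:100, function(r) {
    co <- simulate_competition(8, 6, 120, preset = p, competed = TRUE,
                               seed = 5000 + r)
    nc <- simulate_competition(4, 6, 120, preset = p, competed = FALSE,
                               seed = 6000 + r)
    fit <- fit_org_decline(normalize_to_noncompeted(co, nc), n_boot = 200,
                           seed = r)
    fit$ci[1] <= 0 && fit$ci[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.88)
})

test_that("odds-based selection coefficients follow from the fraction series", {
  fr <- data.frame(line_id = 1, generation = 0:1, het_fraction = c(0.5, 0.4))
  expect_equal(estimate_s_org(fr, n_boot = 50, seed = 1)$s_org, 1 / 3,
               tolerance = 1e-12)
  const <- data.frame(line_id = 1, generation = 0:4, het_fraction = 0.5)
  expect_equal(estimate_s_org(const, n_boot = 50, seed = 1)$s_org, 0)
  # boundary fractions are skipped, not imputed
  mixed <- data.frame(line_id = 1, generation = 0:3,
                      het_fraction = c(0.5, 0.4, 0, 0))
  est <- estimate_s_org(mixed, n_boot = 50, seed = 1)
  expect_equal(est$n_steps, 1)
  expect_equal(est$n_skipped, 2)
  allbad <- data.frame(line_id = 1, generation = 0:1, het_fraction = c(1, 0))
  expect_error(estimate_s_org(allbad), "consecutive generations")
})

test_that("s_org recovers a known flat organismal cost", {
  c_true <- 0.2
  p <- flat_cost_preset(c_true)
  est <- vapply(1:15, function(r) {
    sim <- simulate_competition(8, 10, 300, preset = p, competed = TRUE,
                                seed = 7000 + r)
    estimate_s_org(fraction_trajectory(sim), n_boot = 100, seed = r)$s_org
  }, numeric(1))
  expect_lt(abs(mean(est) - c_true) / c_true, 0.2)
})

test_that("estimated organismal cost increases with the simulated cost", {
  med <- vapply(c(0.1, 0.2, 0.3), function(cc) {
    p <- flat_cost_preset(cc)
    est <- vapply(1:8, function(r) {
      sim <- simulate_competition(6, 8, 200, preset = p, competed = TRUE,
                                  seed = 8000 + r)
      estimate_s_org(fraction_trajectory(sim), n_boot = 50, seed = r)$s_org
    }, numeric(1))
    median(est)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("fraction trajectories expose the diet-dependent endpoint contrast", {
  # with the calibrated deep costs competed fractions approach the floor by
  # generation ~6, so the informative contrast is taken at generation 4
  ec <- function(cond, ref, seed) {
    a <- simulate_competition(6, 4, 200, preset = condition_presets(cond),
                              seed = seed)
    b <- simulate_competition(6, 4, 200, preset = condition_presets(ref),
                              seed = seed + 500)
    attr(fraction_trajectory(a, fraction_trajectory(b)), "endpoint_contrast")
  }
  daf <- vapply(1:5, function(s) ec("daf16_restricted", "daf16_control", s),
                numeric(1))
  expect_lt(exp(mean(log(daf))), 0.75)   # restriction accelerates the decline
  wt <- vapply(1:5, function(s) ec("wt_restricted", "wt_control", s),
               numeric(1))
  ratio <- exp(mean(log(wt)))
  expect_gt(ratio, 0.5)                  # ... but not in wildtype hosts
  expect_lt(ratio, 2.0)
  expect_lt(exp(mean(log(daf))), ratio)  # the diet effect needs DAF-16 loss
  # identical condition: contrast is 1 for constant full fractions
  t1 <- data.frame(line_id = 1, generation = 0:2, het_fraction = 1,
                   n_genotyped = 48, competed = TRUE)
  expect_equal(attr(fraction_trajectory(t1, fraction_trajectory(t1)),
                    "endpoint_contrast"), 1)
  expect_error(fraction_trajectory(
    data.frame(line_id = 1, generation = 0, het_fraction = 1,
               n_genotyped = 10, competed = FALSE)), "competed")
})
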