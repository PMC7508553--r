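test_that("stock population has the stated mean, support and reproducibility", {
  f <- make_stock_population(1000, 0.60, 0.15, seed = 11)
  expect_true(all(f >= 0.45 & f <= 0.75))
  expect_lt(abs(mean(f) - 0.60), 0.02)
  # degenerate spread
  expect_identical(make_stock_population(1, 0.4, 0, seed = 1), 0.4)
  # bit-identical under the same seed
  expect_identical(f, make_stock_population(1000, 0.60, 0.15, seed = 11))
  expect_error(make_stock_population(10, 1.2), "mean_f")
  expect_error(make_stock_population(10, 0.9, 0.2), "support")
  expect_error(make_stock_population(0, 0.5), "n must")
})

test_that("large-sample stock mean matches the analytic truncated-normal mean", {
  # symmetric truncation about mean_f leaves the mean at exactly mean_f
  # (the analytic mean of a normal truncated to [mu - 2sd, mu + 2sd] is mu)
  f <- make_stock_population(1e5, 0.60, 0.15, seed = 2)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.60), 3 * se)
})

test_that("transmission bottleneck is binomial with a purifying shift", {
  # absorbing boundary
  expect_identical(transmit_bottleneck(0, 100, -0.05, seed = 1), 0)
  # expectation: B large
  emb <- transmit_bottleneck(rep(0.60, 2000), 1e5, -0.03, seed = 3)
  expect_lt(abs(mean(emb) - 0.57), 0.001)
  # B = Inf returns the expectation exactly
  expect_equal(transmit_bottleneck(0.6, Inf, -0.03), 0.57)
  # exact outcome distribution at B = 2 against enumeration of binomial(2, 1/2)
  x <- transmit_bottleneck(rep(0.5, 4e4), 2, 0, seed = 4)
  emp <- table(factor(x, levels = c(0, 0.5, 1))) / length(x)
  expect_equal(as.numeric(emp), c(0.25, 0.5, 0.25), tolerance = 0.02)
  expect_error(transmit_bottleneck(0.5, 0), "B must")
  expect_error(transmit_bottleneck(1.5, 10), "f_parent")
})

test_that("within-host development applies the affine gain and respects boundaries", {
  p <- condition_preset("x", shift_a = 0.155, shift_b = -0.20)
  expect_equal(develop_within_host(0.50, p), 0.555)
  # no de novo mutation: zero stays zero even with a > 0
  expect_identical(develop_within_host(0, p), 0)
  pz <- condition_preset("z", shift_a = 0, shift_b = -1e-9)
  expect_equal(develop_within_host(0, pz), 0)
  # ceiling
  expect_equal(develop_within_host(0.89, condition_preset("c", shift_a = 0.3,
                                                          shift_b = -0.1)),
               0.9)
  # expected gain of the default preset crosses zero at the calibrated
  # equilibrium: propagate a full parent -> adult generation deterministically
  wt <- condition_presets("wt_live")
  det <- wt; det$shift_sd <- 0; det$bottleneck <- Inf
  class(det) <- "condition_preset"
  fstar <- unname(compound_shift(wt)["equilibrium"])
  adult <- develop_within_host(
    transmit_bottleneck(fstar, Inf, det$delta_embryo), det)
  expect_equal(adult, fstar, tolerance = 1e-12)
  expect_true(fstar >= 0.75 && fstar <= 0.80)
})

test_that("fecundity declines monotonically above theta and vanishes at the ceiling", {
  wt <- condition_presets("wt_live")
  expect_equal(brood_rate(0, wt), wt$fecundity_base, tolerance = 1e-10)
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(brood_rate(grid, wt)) <= 1e-12))
  expect_lt(brood_rate(0.7, wt), brood_rate(0.5, wt))
  expect_identical(brood_rate(0.9, wt), 0)          # at f_max
  # lethal boundary with full cost
  lethal <- condition_preset("l", fecundity_cost = 1, f_max = 0.9,
                             shift_b = -0.1)
  expect_identical(brood_rate(0.95, lethal), 0)
})

test_that("maturation probability is a monotone unit-interval cost", {
  wt <- condition_presets("wt_live")
  expect_equal(maturation_probability(0, wt), 1)
  grid <- seq(0, 1, by = 0.05)
  p <- maturation_probability(grid, wt)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) <= 0))
  off <- neutral_preset()
  expect_true(all(maturation_probability(grid, off) == 1))
})

test_that("copy number hitchhikes: wildtype held, total strictly increasing", {
  expect_equal(copy_number(0, 100), data.frame(n_wt = 100, n_mut = 0))
  expect_equal(copy_number(0.5, 100), data.frame(n_wt = 100, n_mut = 100))
  cn <- copy_number(0.75, 100)
  expect_equal(cn$n_mut, 300)
  expect_equal(cn$n_wt + cn$n_mut, 400)
  grid <- seq(0, 0.8, by = 0.1)
  cg <- copy_number(grid, 1000)
  expect_true(all(cg$n_wt == 1000))
  expect_true(all(diff(cg$n_wt + cg$n_mut) > 0))
  expect_error(copy_number(1, 100), "f must")
})

test_that("lineage tables show proliferation under wt_live and not under restriction", {
  tab <- simulate_lineages(30, condition_presets("wt_live"), seed = 7)
  expect_s3_class(tab, "lineage_table")
  expect_equal(nrow(tab), 30)
  expect_true(all(unlist(tab[2:5]) >= 0 & unlist(tab[2:5]) <= 1))
  expect_gt(mean(tab$adult_f), mean(tab$embryo_f))
  # purifying selection at transmission
  expect_lt(mean(tab$embryo_f), mean(tab$parent_f))
  # restricted diet: no mean rise from embryo at any stage
  tabr <- simulate_lineages(30, condition_presets("wt_restricted"), seed = 7)
  expect_lt(mean(tabr$adult_f) - mean(tabr$embryo_f), 0.01)
  expect_lt(mean(tabr$l4_f) - mean(tabr$embryo_f), 0.01)
  # neutral dynamics with a huge bottleneck: progeny trace the parent
  nt <- simulate_lineages(10, neutral_preset(bottleneck = 1e6), seed = 3)
  expect_equal(nt$adult_f, nt$parent_f, tolerance = 0.005)
  expect_equal(nt$embryo_f, nt$parent_f, tolerance = 0.005)
  # reproducibility and hierarchical seeding: first lineages unchanged when more
  # are added
  again <- simulate_lineages(30, condition_presets("wt_live"), seed = 7)
  expect_identical(tab, again)
  more <- simulate_lineages(35, condition_presets("wt_live"), seed = 7)
  expect_equal(more[1:30, ], as.data.frame(tab)[1:30, ], ignore_attr = TRUE)
})

test_that("pooled lysate values lie between pool member extremes", {
  tab <- simulate_lineages(20, condition_presets("wt_live"), seed = 9,
                           pool_size = 1)
  expect_true(all(tab$adult_f <= condition_presets("wt_live")$f_max))
  tabw <- simulate_lineages(5, condition_presets("wt_live"), seed = 9,
                            weighted_pool = TRUE)
  expect_true(all(tabw$adult_f >= 0 & tabw$adult_f <= 1))
})

test_that("competition lines lose heteroplasmic animals; controls do not", {
  co <- simulate_competition(8, 10, 100, preset = condition_presets("wt_live"),
                             competed = TRUE, seed = 21)
  expect_s3_class(co, "competition_table")
  expect_equal(sort(unique(co$generation)), 0:10)
  for (l in unique(co$line_id)) {
    d <- co[co$line_id == l, ]
    expect_lt(d$het_fraction[d$generation == 10],
              d$het_fraction[d$generation == 0])
  }
  nc <- simulate_competition(4, 5, 100, preset = condition_presets("wt_live"),
                             competed = FALSE, seed = 21)
  expect_true(all(nc$het_fraction == 1))   # heteroplasmic-only by construction
  expect_true(all(nc$pooled_f >= 0 & nc$pooled_f <= 1))
  # same seed, same table, bit for bit
  expect_identical(co, simulate_competition(8, 10, 100,
                                            preset = condition_presets("wt_live"),
                                            competed = TRUE, seed = 21))
})

test_that("neutral competition conserves the mean frequency in expectation", {
  p <- neutral_preset(bottleneck = 2000)
  means <- vapply(1:60, function(r) {
    sim <- simulate_competition(1, 5, 60, preset = p, competed = FALSE,
                                seed = r, genotype_sample = 5)
    mean(sim$pooled_f[sim$generation == 5])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.60), 3 * se + 1e-4)
})

test_that("tiny-census expected heteroplasmic fraction matches exhaustive enumeration", {
  # 6 heteroplasmic members at f = 0.6 and 4 wildtype, one generation:
  # offspring pick parents ~ multinomial with probs prop. to census weight;
  # E[het fraction] = sum_k dbinom(k; 10, p_het) * k / 10 = p_het
  p <- flat_cost_preset(0.3, bottleneck = 5000)
  w_het <- brood_rate(0.6, p) * maturation_probability(0.6, p)
  w_wt <- brood_rate(0, p) * maturation_probability(0, p)
  p_het <- 6 * w_het / (6 * w_het + 4 * w_wt)
  expected <- sum(dbinom(0:10, 10, p_het) * (0:10) / 10)   # enumeration oracle
  sims <- vapply(1:400, function(r) {
    set.seed(r)
    f <- c(rep(0.6, 6), rep(0, 4))
    w <- brood_rate(f, p) * maturation_probability(f, p)
    par_f <- f[sample.int(10, 10, replace = TRUE, prob = w)]
    adult <- develop_within_host(
      transmit_bottleneck(par_f, p$bottleneck, p$delta_embryo), p)
    mean(adult > 0)
  }, numeric(1))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected), 3 * se)
})

test_that("a line whose members cannot reproduce terminates and is flagged", {
  doomed <- condition_preset("doomed", shift_a = 0, shift_b = -1e-9,
                             fecundity_cost = 1, fecundity_theta = 0,
                             f_max = 0.95)
  # all members near 0.9: brood rate ~ 0 everywhere above theta = 0
  sim <- simulate_competition(1, 5, 20, preset = doomed, competed = FALSE,
                              seed = 1, mean_f = 0.9, spread = 0.02)
  expect_true(any(sim$terminated))
  expect_lt(max(sim$generation), 5)
})
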