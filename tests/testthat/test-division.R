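# daughter pairing, delta-MOB mixture classification, inheritance,
# dynamics, condition screening

test_that("micropattern pairing finds divisions and flags crowded sites", {
  sites <- data.frame(site = 1:3, x = c(0, 100, 200), y = 0)
  pre <- data.frame(cell_id = 1:3, x = c(2, 101, 199), y = c(1, -2, 0),
                    score = c(1, 2, 3))
  post <- data.frame(cell_id = 1:6,
                     x = c(1, 3, 99, 198, 201, 203),
                     y = c(-1, 2, 1, 1, -1, 2),
                     score = c(1.1, 0.9, 2.0, 2.8, 3.1, 3.3))
  pd <- pair_daughters(pre, post, sites, site_radius = 15)
  # site 1 divided (2 cells), site 2 did not (1 cell), site 3 has 3 cells
  expect_equal(nrow(pd$records), 1)
  expect_equal(pd$records$site, 1)
  expect_equal(pd$records$delta_mob, abs(1.1 - 0.9))
  expect_equal(pd$flagged$site, 3)
})

test_that("jittered synthetic positions pair perfectly against ground truth", {
  ds <- simulate_division_dataset(division_spec(n_pairs = 100, seed = 17))
  pd <- pair_daughters(ds$pre, ds$post, ds$sites, site_radius = 15)
  expect_equal(nrow(pd$records), 100)
  ord <- order(pd$records$site)
  expect_equal(pd$records$parent_score[ord], ds$pairs$parent_score)
  expect_equal(pd$records$delta_mob[ord], ds$pairs$delta_mob)
})

test_that("equal-variance equal-weight delta modes give the midpoint threshold", {
  x <- rep(c(0.3, 2.0), each = 100)
  mix <- fit_delta_mixture(x)
  expect_equal(mix$threshold, 1.15, tolerance = 1e-6)
  expect_true(all(mix$pattern[x == 0.3] == "M-symmetric"))
  expect_true(all(mix$pattern[x == 2.0] == "M-asymmetric"))
})

test_that("the division benchmark is classified accurately with a sane threshold", {
  ds <- simulate_division_dataset(
    division_spec(n_pairs = 500, inheritance_r = 0.8, asym_fraction = 0.3,
                  delta_mean_sym = 0.3, delta_mean_asym = 2.0,
                  delta_sd = 0.2, seed = 19))
  mix <- fit_delta_mixture(ds$pairs$delta_mob)
  expect_gte(mix$threshold, 0.8)
  expect_lte(mix$threshold, 1.5)
  acc <- mean(as.character(mix$pattern) == ds$pairs$true_pattern)
  expect_gte(acc, 0.95)
  # classification is symmetric in daughter order
  swapped <- abs(ds$pairs$daughter2 - ds$pairs$daughter1)
  expect_equal(swapped, ds$pairs$delta_mob)
})

test_that("unimodal delta data collapses: no threshold, pairs unclassified", {
  set.seed(23)
  mix <- suppressWarnings(fit_delta_mixture(abs(rnorm(300, 0.3, 0.2))))
  expect_true(mix$collapsed)
  expect_true(all(is.na(mix$pattern)))
})

test_that("threshold recovery: median error < 0.15 over 100 seeded draws", {
  # independent oracle: grid intersection of the two true delta densities
  oracle <- local({
    xs <- seq(0.31, 1.99, by = 1e-4)
    d <- 0.8 * dnorm(xs, 0.3, 0.2) - 0.2 * dnorm(xs, 2.0, 0.2)
    xs[which.min(abs(d))]
  })
  errs <- vapply(1:100, function(s) {
    ds <- simulate_division_dataset(division_spec(n_pairs = 200, seed = s))
    abs(fit_delta_mixture(ds$pairs$delta_mob)$threshold - oracle)
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("inheritance correlation: identity, null, and generator recovery", {
  rec <- data.frame(parent_score = rnorm(50))
  rec$daughter1 <- rec$parent_score
  rec$daughter2 <- rec$parent_score
  expect_equal(inheritance_correlation(rec)$r, 1)

  set.seed(25)
  null <- data.frame(parent_score = rnorm(200), daughter1 = rnorm(200),
                     daughter2 = rnorm(200))
  expect_lt(abs(inheritance_correlation(null)$r), 0.15)

  ds <- simulate_division_dataset(
    division_spec(n_pairs = 300, inheritance_r = 0.8, seed = 27))
  ic <- inheritance_correlation(ds$pairs)
  ci <- cor.test(ds$pairs$parent_score,
                 (ds$pairs$daughter1 + ds$pairs$daughter2) / 2)$conf.int
  expect_gte(0.8, ci[1]); expect_lte(0.8, ci[2])
  expect_equal(ic$r[ic$group == "all"], unname(cor.test(
    ds$pairs$parent_score,
    (ds$pairs$daughter1 + ds$pairs$daughter2) / 2)$estimate))

  degen <- data.frame(parent_score = rep(1, 5), daughter1 = rnorm(5),
                      daughter2 = rnorm(5))
  expect_true(is.na(inheritance_correlation(degen)$r))
})

test_that("score dynamics reproduce constructed trajectories exactly", {
  # symmetric daughters decay below threshold; asymmetric stem-like stay up
  tr <- expand.grid(pair_id = 1:20, timepoint = c(0, 8))
  tr$pattern <- ifelse(tr$pair_id <= 12, "M-symmetric", "M-asymmetric")
  tr$score <- ifelse(tr$pattern == "M-symmetric",
                     ifelse(tr$timepoint == 0, 1, -1), 2)
  dyn <- score_dynamics(tr, threshold = 0)
  tj <- dyn$trajectories
  expect_equal(tj$fraction_above[tj$pattern == "M-symmetric" &
                                   tj$timepoint == 0], 1)
  expect_equal(tj$fraction_above[tj$pattern == "M-symmetric" &
                                   tj$timepoint == 8], 0)
  expect_true(all(tj$fraction_above[tj$pattern == "M-asymmetric"] == 1))
  expect_equal(nrow(dyn$tests), 2)

  # single timepoint: summary only
  one <- tr[tr$timepoint == 0, ]
  dyn1 <- score_dynamics(one, threshold = 0)
  expect_equal(unique(dyn1$trajectories$timepoint), 0)
})

test_that("identical null conditions are rejected at the nominal ANOVA rate", {
  set.seed(33)
  hits <- vapply(1:60, function(i) {
    rec <- data.frame(condition = rep(c("ctrl", "mock"), each = 40),
                      delta_mob = abs(rnorm(80, 0.8, 0.4)),
                      daughter1 = rnorm(80), daughter2 = rnorm(80))
    suppressWarnings(condition_screen(rec, threshold = 1.15)$anova_p) < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.15)   # ~5% nominal, binomial slack at 60 draws
})

test_that("an induced asymmetry shift is detected in the right direction", {
  ds_lo <- simulate_division_dataset(
    division_spec(n_pairs = 150, asym_fraction = 0.15, seed = 35))
  ds_hi <- simulate_division_dataset(
    division_spec(n_pairs = 150, asym_fraction = 0.45, seed = 36))
  rec <- rbind(cbind(ds_lo$pairs, condition = "ctrl"),
               cbind(ds_hi$pairs, condition = "drug"))
  scr <- condition_screen(rec)
  s <- scr$summary
  expect_gt(s$asym_fraction[s$condition == "drug"],
            s$asym_fraction[s$condition == "ctrl"])
  expect_lt(scr$anova_p, 0.05)

  # single condition: summaries only, no omnibus test
  scr1 <- condition_screen(rec[rec$condition == "ctrl", ])
  expect_true(is.na(scr1$anova_p))

  expect_warning(condition_screen(rbind(rec,
    data.frame(ds_lo$pairs[1:2, ], condition = "tiny"))), "excluding")
})
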