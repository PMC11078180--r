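# phasor transform, smoothing, free/bound decomposition, ORR

test_that("mono-exponential phasor matches the closed form and inverts", {
  # 2.5 ns calibration-dye lifetime at 80 MHz, noise-free, 4096 bins
  sc <- single_cell_scene(alpha = 1, tau = 2.5, n_bins = 4096L)
  ph <- phasor_transform(sc$nadph)
  px <- which(sc$truth$cell_labels == 1)[1]
  cf <- phasor_of_lifetime(2.5, OMEGA80)   # g = 1/(1+(wt)^2), s = wt*g
  expect_equal(ph$g[px], cf$g, tolerance = 1e-5)
  expect_equal(ph$s[px], cf$s, tolerance = 1e-5)
  expect_lt(abs((ph$g[px] - 0.5)^2 + ph$s[px]^2 - 0.25), 1e-4)
  expect_equal(phasor_to_lifetime(ph$g[px], ph$s[px], OMEGA80), 2.5,
               tolerance = 5e-4)
})

test_that("zero-lifetime limit sits at the (1, 0) corner", {
  counts <- array(0, dim = c(1, 1, 4096))
  counts[1, 1, 1] <- 100   # all photons in the first bin
  ph <- phasor_transform(decay_image(counts))
  expect_equal(ph$g[1, 1], 1, tolerance = 1e-5)
  expect_lt(ph$s[1, 1], 1e-3)
})

test_that("the transform is linear: 50/50 mixtures land at the midpoint", {
  nb <- 512L
  pmf <- function(tau) mobflim:::.decay_pmf(tau, nb, 12.5)
  one <- function(p) {
    ph <- phasor_transform(decay_image(array(p, dim = c(1, 1, nb))))
    c(ph$g[1, 1], ph$s[1, 1])
  }
  a <- one(pmf(0.45)); b <- one(pmf(3.4))
  mix <- one((pmf(0.45) + pmf(3.4)) / 2)
  expect_equal(mix, (a + b) / 2, tolerance = 1e-12)
})

test_that("zero-photon pixels are invalid and an all-zero image warns", {
  counts <- array(0, dim = c(2, 2, 8))
  counts[1, 1, ] <- 1
  ph <- phasor_transform(decay_image(counts))
  expect_true(ph$valid[1, 1])
  expect_false(ph$valid[2, 2])
  expect_true(is.na(ph$g[2, 2]))
  expect_warning(phasor_transform(decay_image(array(0, dim = c(2, 2, 8)))),
                 "all-invalid")
})

test_that("median filter handles constants, outliers, and matches a brute-force oracle", {
  const <- point_phasor(0.5, 0.3)
  const$g <- matrix(0.5, 5, 5); const$s <- matrix(0.3, 5, 5)
  const$valid <- matrix(TRUE, 5, 5)
  f <- median_filter_phasor(const)
  expect_equal(f$g, matrix(0.5, 5, 5))

  out <- const
  out$g[3, 3] <- 99
  expect_equal(median_filter_phasor(out)$g[3, 3], 0.5)

  # checkerboard vs direct per-pixel enumeration (reduced borders)
  set.seed(7)
  x <- matrix((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2, 6, 6) +
    matrix(runif(36, 0, 0.01), 6, 6)
  p <- const; p$g <- x; p$s <- x; p$valid <- matrix(TRUE, 6, 6)
  got <- median_filter_phasor(p)$g
  want <- x
  for (i in 1:6) for (j in 1:6) {
    ii <- max(1, i - 1):min(6, i + 1); jj <- max(1, j - 1):min(6, j + 1)
    want[i, j] <- median(x[ii, jj])
  }
  expect_equal(got, want)

  # invalid pixels are excluded from neighborhoods and stay invalid
  p$g[2, 2] <- NA; p$valid[2, 2] <- FALSE; p$s[2, 2] <- NA
  fg <- median_filter_phasor(p)$g
  expect_true(is.na(fg[2, 2]))
  expect_equal(fg[1, 1], median(x[1:2, 1:2][-4]))
  expect_error(median_filter_phasor(p, window = 2), "odd")
})

test_that("free/bound decomposition recovers the chord geometry", {
  fa <- phasor_of_lifetime(0.45, OMEGA80)
  expect_equal(c(fa$g, fa$s), c(0.9513, 0.2152), tolerance = 1e-4)

  # at the free anchor: alpha = 0
  lt <- resolve_bound_fraction(point_phasor(fa$g, fa$s))
  expect_equal(lt$alpha_bound[1, 1], 0)
  expect_equal(lt$qc[1, 1], 0L)

  # pure bound species at 3.4 ns: alpha = 1, tau recovered
  b <- phasor_of_lifetime(3.4, OMEGA80)
  lt <- resolve_bound_fraction(point_phasor(b$g, b$s))
  expect_equal(lt$alpha_bound[1, 1], 1, tolerance = 1e-9)
  expect_equal(lt$tau_bound[1, 1], 3.4, tolerance = 1e-9)

  # chord midpoint: alpha = 0.5, tau_bound = 3.4 ns
  lt <- resolve_bound_fraction(point_phasor((fa$g + b$g) / 2, (fa$s + b$s) / 2))
  expect_equal(lt$alpha_bound[1, 1], 0.5, tolerance = 1e-9)
  expect_equal(lt$tau_bound[1, 1], 3.4, tolerance = 1e-9)

  # beyond the bound intersection: clamped to 1 and flagged
  beyond <- list(g = fa$g + 1.05 * (b$g - fa$g), s = fa$s + 1.05 * (b$s - fa$s))
  lt <- resolve_bound_fraction(point_phasor(beyond$g, beyond$s))
  expect_equal(lt$alpha_bound[1, 1], 1)
  expect_equal(lt$qc[1, 1], 1L)

  # short-lifetime side of the anchor: no valid bound intersection
  sh <- phasor_of_lifetime(0.1, OMEGA80)
  lt <- resolve_bound_fraction(point_phasor(sh$g, sh$s))
  expect_equal(lt$qc[1, 1], 2L)
})

test_that("alpha_bound is monotone and exact on forward-constructed mixtures", {
  fa <- phasor_of_lifetime(0.45, OMEGA80)
  b <- phasor_of_lifetime(3.4, OMEGA80)
  alphas <- seq(0, 1, by = 0.05)
  rec <- vapply(alphas, function(a) {
    p <- point_phasor(fa$g + a * (b$g - fa$g), fa$s + a * (b$s - fa$s))
    resolve_bound_fraction(p)$alpha_bound[1, 1]
  }, numeric(1))
  expect_equal(rec, alphas, tolerance = 1e-9)
  expect_true(all(diff(rec) > 0))
})

test_that("phasors of exponential mixtures stay inside the universal semicircle", {
  set.seed(42)
  nb <- 256L
  for (i in 1:100) {
    taus <- runif(3, 0.2, 6)
    w <- runif(3); w <- w / sum(w)
    p <- w[1] * mobflim:::.decay_pmf(taus[1], nb, 12.5) +
      w[2] * mobflim:::.decay_pmf(taus[2], nb, 12.5) +
      w[3] * mobflim:::.decay_pmf(taus[3], nb, 12.5)
    ph <- phasor_transform(decay_image(array(p, dim = c(1, 1, nb))))
    expect_lt((ph$g[1, 1] - 0.5)^2 + ph$s[1, 1]^2, 0.25 + 1e-4)
    expect_gt(ph$s[1, 1], -1e-12)
  }
})

test_that("corrected ORR removes an additive cytoplasmic baseline exactly", {
  set.seed(3)
  nadph <- matrix(runif(100, 5, 20), 10, 10)
  mito <- matrix(FALSE, 10, 10); mito[3:5, 3:5] <- TRUE
  cyto <- !mito
  fad_true <- matrix(0, 10, 10)
  fad_true[mito] <- 0.8 * nadph[mito]            # true mito ratio = 0.8
  fad_obs <- fad_true + 0.3 * nadph              # additive baseline alpha=0.3
  orr <- compute_orr(fad_obs, nadph, mito, cyto)
  expect_lt(abs(orr$orr_corrected - 0.8), 1e-12)
  expect_equal(orr$baseline_alpha, 0.3, tolerance = 1e-12)

  # no FAD anywhere: corrected ORR = 0
  expect_equal(compute_orr(fad_true * 0, nadph, mito, cyto)$orr_corrected, 0)

  # printed arithmetic: mito ratio 0.8, cyto ratio 0.3 -> 0.5
  fad <- matrix(0.3, 10, 10); fad[mito] <- 0.8
  orr <- compute_orr(fad, matrix(1, 10, 10), mito, cyto)
  expect_equal(orr$orr_corrected, 0.5, tolerance = 1e-12)

  # degenerate inputs
  expect_false(compute_orr(fad, nadph, matrix(FALSE, 10, 10), cyto)$ok)
  expect_error(compute_orr(fad, nadph, mito, mito), "disjoint")
})
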