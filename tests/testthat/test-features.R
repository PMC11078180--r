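# the MOB feature library: registry, morphology, region statistics,
# compartmentalization, full extraction

test_that("the registry is complete, unique, and spans every family", {
  reg <- mob_registry()
  expect_false(anyDuplicated(reg$feature_id) > 0)
  expect_setequal(unique(reg$family),
                  c("signal", "distribution", "texture",
                    "compartmentalization", "morphology", "orr"))
  # both compartments covered for the three per-pixel channels
  for (ch in c("NADPH_intensity", "alpha_bound", "tau_bound"))
    expect_setequal(unique(reg$region[reg$channel == ch]),
                    c("mito", "cyto", "compartmentalization"))
  # ORR is quantified in mitochondria only (plus its corrected cell value)
  expect_setequal(unique(reg$region[reg$channel == "ORR"]), c("mito", "cell"))
  expect_equal(nrow(reg), 205)
})

test_that("morphology: disk circularity, printed-area arithmetic, partition", {
  disk <- mobflim:::.disk_mask(41, 41, c(21, 21), 15)
  mo <- morphology_features(disk, pixel_size_um = 0.18)
  expect_gt(mo["circularity"], 0.85)
  expect_equal(unname(mo["major_axis_length"] / mo["minor_axis_length"]), 1,
               tolerance = 0.02)

  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  mo <- morphology_features(sq, pixel_size_um = 0.18)
  expect_equal(unname(mo["size"]), 100 * 0.0324)  # 3.24 um^2

  mito <- sq & (row(sq) %% 2 == 0)
  cyto <- sq & !mito
  mo <- morphology_features(sq, mito, cyto, pixel_size_um = 0.18)
  expect_equal(unname(mo["mito_size"] + mo["cyto_size"]), unname(mo["size"]))
  # dispersity = components per mito pixel
  expect_equal(unname(mo["mito_dispersity"]),
               unname(mo["mito_count"]) / (sum(mito)))
})

test_that("region statistics match direct oracles and handle degenerate input", {
  rs <- region_statistics(rep(7, 50))
  expect_equal(unname(rs[c("sd", "variance", "entropy")]), c(0, 0, 0))
  expect_equal(unname(rs["uniformity"]), 1)

  v <- as.numeric(1:100)
  rs <- region_statistics(v)
  expect_equal(unname(rs["median"]), 50.5)
  expect_equal(unname(rs["p10"]), quantile(v, 0.1, names = FALSE))
  expect_equal(unname(rs["p90"]), quantile(v, 0.9, names = FALSE))
  expect_equal(unname(rs["iqr"]),
               quantile(v, .75, names = FALSE) - quantile(v, .25, names = FALSE))
  expect_equal(unname(rs["average"]), mean(v))

  set.seed(2)
  sym <- c(rnorm(4000), -rnorm(4000))
  expect_lt(abs(region_statistics(sym)["skewness"]), 0.05)

  # higher moments undefined below 3 pixels
  expect_true(is.na(region_statistics(c(1, 2))["skewness"]))
})

test_that("compartmentalization follows the printed formula and conventions", {
  expect_equal(compartmentalization(5, 5), 0)
  expect_equal(compartmentalization(3, 0), 1)
  expect_equal(compartmentalization(3, 1), 0.5)
  expect_equal(compartmentalization(0, 0), 0)      # documented convention
  expect_true(is.na(compartmentalization(1, -1)))  # vanishing denominator
  expect_true(all(abs(compartmentalization(runif(50), runif(50))) <= 1))
})

test_that("full extraction matches per-statistic oracles on a constructed cell", {
  # deterministic two-level cell, uniform lifetime maps
  h <- 40
  cellm <- mobflim:::.disk_mask(h, h, c(20, 20), 12)
  set.seed(5)
  nadph <- matrix(0.2, h, h); nadph[cellm] <- 20 + runif(sum(cellm), -2, 2)
  fad <- matrix(0.1, h, h); fad[cellm] <- 2
  bright <- cellm & mobflim:::.disk_mask(h, h, c(17, 17), 5)
  fad[bright] <- 12
  seg <- segment_cells(nadph, fad, photon_threshold = 2, min_size_px = 100,
                       max_size_px = 5000)
  expect_length(seg$cells, 1)
  lt <- structure(list(alpha_bound = matrix(0.5, h, h),
                       tau_bound = matrix(3.4, h, h),
                       qc = matrix(0L, h, h), tau_free = 0.45,
                       omega = OMEGA80), class = "lifetime_map")
  ft <- extract_features(seg, nadph, fad, lt)
  expect_equal(nrow(ft), 1)

  cell <- seg$cells[[1]]
  expect_equal(ft$mito_NADPH_intensity_average, mean(nadph[cell$mito_mask]))
  expect_equal(ft$cyto_NADPH_intensity_median, median(nadph[cell$cyto_mask]))
  expect_equal(ft$mito_alpha_bound_average, 0.5)
  expect_equal(ft$comp_tau_bound_average, 0)   # same tau both compartments
  orr <- compute_orr(fad, nadph, cell$mito_mask, cell$cyto_mask)
  expect_equal(ft$cell_ORR_corrected, orr$orr_corrected)

  # no silent missing values in a clean cell: the only NAs are the GLCM
  # correlations of the constant lifetime channels, which are undefined
  reg <- mob_registry()
  vals <- unlist(ft[1, reg$feature_id])
  undefined <- names(vals)[is.na(vals)]
  expect_setequal(undefined,
                  c("mito_alpha_bound_glcm_correlation",
                    "cyto_alpha_bound_glcm_correlation",
                    "mito_tau_bound_glcm_correlation",
                    "cyto_tau_bound_glcm_correlation"))
})

test_that("a failed subregion split flags compartment features, keeps morphology", {
  h <- 30
  cellm <- mobflim:::.disk_mask(h, h, c(15, 15), 9)
  nadph <- matrix(0, h, h); nadph[cellm] <- 10
  fad <- matrix(0, h, h); fad[cellm] <- 3   # constant FAD: split fails
  seg <- segment_cells(nadph, fad, 2, min_size_px = 50, max_size_px = 5000)
  expect_false(seg$cells[[1]]$split_ok)
  ft <- extract_features(seg, nadph, fad, NULL)
  expect_true(ft$flag_split[1])
  expect_true(is.na(ft$comp_NADPH_intensity_average[1]))
  expect_true(is.na(ft$mito_NADPH_intensity_average[1]))
  expect_false(is.na(ft$morph_size[1]))
})

test_that("non-spatial statistics are invariant to pixel permutation", {
  set.seed(8)
  v <- rnorm(400, 10, 2)
  rs1 <- region_statistics(v)
  rs2 <- region_statistics(sample(v))
  expect_equal(rs1, rs2)
})
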