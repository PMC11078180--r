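# Synthetic FLIM data with known ground truth: decay-image scenes, staged
# population feature tables, and parent/daughter division datasets. These
# generators define the benchmark conditions every downstream stage is tested
# against, so their defaults are fixed, documented choices.

#' Construct a decay image
#'
#' @param counts numeric H x W x T array of per-pixel photon counts per time
#'   bin (T planes over one laser period). Counts may be non-integer for
#'   noise-free expected histograms.
#' @param laser_period_ns laser repetition period in ns.
#' @param channel channel name, e.g. "NADPH" or "FAD".
#' @return a \code{decay_image}.
#' @export
decay_image <- function(counts, laser_period_ns = 12.5, channel = "NADPH") {
  stopifnot(length(dim(counts)) == 3, dim(counts)[3] >= 2, laser_period_ns > 0)
  if (any(counts < 0)) stop("photon counts must be nonnegative")
  structure(list(counts = counts, n_time_bins = dim(counts)[3],
                 laser_period_ns = laser_period_ns, channel = channel),
            class = "decay_image")
}

#' Total-intensity image of a decay stack
#' @param decay a \code{decay_image}.
#' @return matrix of per-pixel total photon counts.
#' @export
decay_intensity <- function(decay) {
  stopifnot(inherits(decay, "decay_image"))
  rowSums(decay$counts, dims = 2)
}

#' Scene specification for synthetic FLIM images
#'
#' Describes disk-shaped cells with punctate mitochondrial subregions on a
#' dark background. Defaults reproduce the low-photon live-cell regime
#' (about 20-30 photons per pixel inside cells) at 0.18 um pixels, 256 time
#' bins over a 12.5 ns period (80 MHz).
#'
#' @param image_size c(height, width) in pixels.
#' @param cells list of cells; each a list with \code{center} (row, col),
#'   \code{radius_px}, \code{true_alpha_bound} in [0,1], \code{true_tau_bound}
#'   (ns, > tau_free), \code{nadph_rate} and \code{fad_rate} (mean
#'   photons/pixel), \code{mito_fraction} in (0,1), \code{mito_contrast} >= 1.
#' @param pixel_size_um pixel size in micrometers.
#' @param background_rate mean background photons/pixel (time-uniform dark
#'   counts, added in both channels).
#' @param n_time_bins time bins per laser period.
#' @param laser_period_ns laser period in ns.
#' @param tau_free free-NAD(P)H lifetime in ns.
#' @param fad_tau_ns mono-exponential lifetime used for the FAD channel decay
#'   (FAD is consumed as intensity only; its decay shape is inert).
#' @param seed integer RNG seed.
#' @return a validated \code{scene_spec}.
#' @export
scene_spec <- function(image_size = c(128L, 128L), cells, pixel_size_um = 0.18,
                       background_rate = 0.5, n_time_bins = 256L,
                       laser_period_ns = 12.5, tau_free = 0.45,
                       fad_tau_ns = 2.3, seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8),
            background_rate >= 0, n_time_bins >= 2, laser_period_ns > 0)
  for (cl in cells) {
    if (cl$radius_px <= 0) stop("cell radii must be > 0")
    if (cl$true_alpha_bound < 0 || cl$true_alpha_bound > 1)
      stop("true_alpha_bound must be in [0,1]")
    if (cl$true_tau_bound <= tau_free)
      stop("true_tau_bound must exceed tau_free")
    if (cl$nadph_rate < 0 || cl$fad_rate < 0) stop("rates must be >= 0")
    if (cl$mito_fraction <= 0 || cl$mito_fraction >= 1)
      stop("mito_fraction must be in (0,1)")
    if (cl$mito_contrast < 1) stop("mito_contrast must be >= 1")
  }
  structure(list(image_size = as.integer(image_size), cells = cells,
                 pixel_size_um = pixel_size_um,
                 background_rate = background_rate,
                 n_time_bins = as.integer(n_time_bins),
                 laser_period_ns = laser_period_ns, tau_free = tau_free,
                 fad_tau_ns = fad_tau_ns, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Lay out identical cells on a jittered grid
#'
#' Convenience builder for multi-cell scenes: one cell per grid site, with
#' per-cell parameters drawn (seeded) from the supplied ranges so the
#' population carries real metabolic variation.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing_px center-to-center spacing.
#' @param radius_px cell radius range (length-2) sampled uniformly.
#' @param alpha_bound,tau_bound,nadph_rate,fad_rate ranges sampled uniformly.
#' @param mito_fraction,mito_contrast scalars shared by all cells.
#' @param jitter_px positional jitter.
#' @param seed RNG seed.
#' @return list of cell descriptions for \code{\link{scene_spec}}.
#' @export
grid_cells <- function(n_rows, n_cols, spacing_px = 40, radius_px = c(10, 12),
                       alpha_bound = c(0.3, 0.7), tau_bound = c(2.5, 3.8),
                       nadph_rate = c(20, 30), fad_rate = c(8, 14),
                       mito_fraction = 0.25, mito_contrast = 5,
                       jitter_px = 2, seed = 1L) {
  set.seed(seed)
  cells <- list()
  for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
    cells[[length(cells) + 1L]] <- list(
      center = c(spacing_px * (i - 0.5) + runif(1, -jitter_px, jitter_px),
                 spacing_px * (j - 0.5) + runif(1, -jitter_px, jitter_px)),
      radius_px = runif(1, radius_px[1], radius_px[2]),
      true_alpha_bound = runif(1, alpha_bound[1], alpha_bound[2]),
      true_tau_bound = runif(1, tau_bound[1], tau_bound[2]),
      nadph_rate = runif(1, nadph_rate[1], nadph_rate[2]),
      fad_rate = runif(1, fad_rate[1], fad_rate[2]),
      mito_fraction = mito_fraction, mito_contrast = mito_contrast)
  }
  cells
}

# normalized per-bin photon probability of a periodized mono-exponential,
# evaluated at bin centers (the periodization factor is constant and cancels)
.decay_pmf <- function(tau, n_bins, period) {
  tc <- (seq_len(n_bins) - 0.5) * period / n_bins
  p <- exp(-tc / tau)
  p / sum(p)
}

# disk mask on an H x W grid
.disk_mask <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  rr^2 + cc^2 <= radius^2
}

#' Simulate a two-channel FLIM acquisition with ground truth
#'
#' Renders each cell as a disk whose NAD(P)H decay is the two-species
#' intensity mixture \code{(1-alpha) * free + alpha * bound} (normalized
#' per-species decays at tau_free and the cell's tau_bound), so the per-pixel
#' phasor sits exactly at the chord position alpha_bound along the
#' free-to-bound chord. Photon counts are Poisson-sampled per time bin;
#' background counts are time-uniform dark counts. Punctate mitochondrial
#' disks cover \code{mito_fraction} of each cell and carry
#' \code{mito_contrast}-fold FAD intensity.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param noise if FALSE, return the noise-free expected histograms
#'   (non-integer counts) instead of Poisson samples.
#' @return a \code{flim_scene}: list with \code{nadph} and \code{fad} decay
#'   images, and \code{truth} (cell label matrix, mito mask, per-pixel
#'   alpha/tau/rate maps, per-cell parameter table).
#' @export
simulate_decay_image <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  nb <- spec$n_time_bins; period <- spec$laser_period_ns

  labels <- matrix(0L, h, w)
  mito <- matrix(FALSE, h, w)
  alpha_map <- matrix(NA_real_, h, w)
  tau_map <- matrix(NA_real_, h, w)
  nadph_rate <- matrix(0, h, w)
  fad_rate <- matrix(0, h, w)

  cell_tab <- data.frame(cell_id = integer(), center_row = numeric(),
                         center_col = numeric(), radius_px = numeric(),
                         true_alpha_bound = numeric(), true_tau_bound = numeric(),
                         nadph_rate = numeric(), fad_rate = numeric())
  for (k in seq_along(spec$cells)) {
    cl <- spec$cells[[k]]
    dm <- .disk_mask(h, w, cl$center, cl$radius_px)
    if (!any(dm)) stop("cell ", k, " has zero area on the image grid")
    labels[dm] <- k
    alpha_map[dm] <- cl$true_alpha_bound
    tau_map[dm] <- cl$true_tau_bound
    nadph_rate[dm] <- cl$nadph_rate
    fad_rate[dm] <- cl$fad_rate
    # punctate mitochondria: seeded small disks until area coverage is reached
    target <- cl$mito_fraction * sum(dm)
    cm <- matrix(FALSE, h, w)
    guard <- 0L
    while (sum(cm & dm) < target && guard < 4000L) {
      guard <- guard + 1L
      ctr <- cl$center + runif(2, -cl$radius_px, cl$radius_px)
      cm <- cm | .disk_mask(h, w, ctr, runif(1, 1.2, 2.6))
    }
    mito <- mito | (cm & dm)
    fad_rate[cm & dm] <- cl$fad_rate * cl$mito_contrast
    cell_tab[k, ] <- list(k, cl$center[1], cl$center[2], cl$radius_px,
                          cl$true_alpha_bound, cl$true_tau_bound,
                          cl$nadph_rate, cl$fad_rate)
  }

  pmf_free <- .decay_pmf(spec$tau_free, nb, period)
  pmf_fad <- .decay_pmf(spec$fad_tau_ns, nb, period)

  # per-pixel NADPH decay pmf: mixture class per cell (+ background uniform)
  mix_pmf <- matrix(1 / nb, nrow = nb, ncol = length(spec$cells) + 1L)
  for (k in seq_along(spec$cells)) {
    cl <- spec$cells[[k]]
    pmf_b <- .decay_pmf(cl$true_tau_bound, nb, period)
    mix_pmf[, k + 1L] <- (1 - cl$true_alpha_bound) * pmf_free +
      cl$true_alpha_bound * pmf_b
  }
  cls <- labels + 1L  # class 1 = background

  n_px <- h * w
  bg <- spec$background_rate
  expected_channel <- function(rate_map, pmf_by_class) {
    # E[count in bin t] = cell_rate * pmf[t, class] + bg / nb
    arr <- array(0, dim = c(h, w, nb))
    rate_v <- as.vector(rate_map); cls_v <- as.vector(cls)
    for (t in seq_len(nb)) {
      arr[, , t] <- matrix(rate_v * pmf_by_class[t, cls_v] + bg / nb, h, w)
    }
    arr
  }
  # FAD: single decay shape for all cells
  fad_pmf_by_class <- matrix(pmf_fad, nrow = nb,
                             ncol = length(spec$cells) + 1L)
  fad_pmf_by_class[, 1L] <- 1 / nb

  e_nadph <- expected_channel(nadph_rate, mix_pmf)
  e_fad <- expected_channel(fad_rate, fad_pmf_by_class)
  if (noise) {
    e_nadph <- array(rpois(n_px * nb, as.vector(e_nadph)), dim = c(h, w, nb))
    e_fad <- array(rpois(n_px * nb, as.vector(e_fad)), dim = c(h, w, nb))
  }

  structure(list(
    nadph = decay_image(e_nadph, period, "NADPH"),
    fad = decay_image(e_fad, period, "FAD"),
    truth = list(cell_labels = labels, mito_mask = mito,
                 alpha_map = alpha_map, tau_map = tau_map,
                 nadph_rate_map = nadph_rate, fad_rate_map = fad_rate,
                 cells = cell_tab),
    spec = spec), class = "flim_scene")
}

#' Spatially bin a decay image
#'
#' Sums photon counts over \code{factor} x \code{factor} pixel blocks
#' (quadrupling photons per pixel at factor 2), the standard trick to trade
#' resolution for photon statistics. Trailing rows/columns that do not fill a
#' block are dropped.
#'
#' @param decay a \code{decay_image}.
#' @param factor integer binning factor, default 2.
#' @return the binned \code{decay_image}.
#' @export
bin_decay_image <- function(decay, factor = 2L) {
  stopifnot(inherits(decay, "decay_image"), factor >= 1)
  if (factor == 1) return(decay)
  d <- dim(decay$counts)
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  x <- decay$counts[seq_len(h2 * factor), seq_len(w2 * factor), , drop = FALSE]
  out <- array(0, dim = c(h2, w2, d[3]))
  for (a in seq_len(factor)) for (b in seq_len(factor)) {
    out <- out + x[seq(a, by = factor, length.out = h2),
                   seq(b, by = factor, length.out = w2), , drop = FALSE]
  }
  decay_image(out, decay$laser_period_ns, decay$channel)
}

#' Population specification for staged feature tables
#'
#' @param n_stages number of differentiation stages (stage 0 is the stem
#'   population and carries the positive "HSC" label downstream).
#' @param cells_per_stage cells per stage.
#' @param feature_means n_stages x n_features matrix of stage means.
#' @param monotone_mask logical vector marking features whose stage means must
#'   be strictly ordered (the ground-truth "informative" set).
#' @param noise_sd per-feature Gaussian noise SD (recycled).
#' @param seed RNG seed.
#' @return a \code{population_spec}.
#' @export
population_spec <- function(n_stages, cells_per_stage, feature_means,
                            monotone_mask, noise_sd = 1, seed = 1L) {
  feature_means <- as.matrix(feature_means)
  stopifnot(nrow(feature_means) == n_stages,
            length(monotone_mask) == ncol(feature_means))
  noise_sd <- rep_len(noise_sd, ncol(feature_means))
  for (j in which(monotone_mask)) {
    d <- diff(feature_means[, j])
    if (!(all(d > 0) || all(d < 0)))
      stop("monotone feature ", j, " does not have strictly ordered stage means")
  }
  structure(list(n_stages = n_stages, cells_per_stage = cells_per_stage,
                 feature_means = feature_means, monotone_mask = monotone_mask,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "population_spec")
}

#' Simulate a staged population feature table
#'
#' Draws Gaussian features around the specified stage means, emulating
#' populations whose informative features trend monotonically across
#' differentiation stages while the rest fluctuate.
#'
#' @param spec a \code{\link{population_spec}}.
#' @return data.frame with \code{stage} (0-based), \code{label} ("HSC" for
#'   stage 0, "diff" otherwise) and one column per feature.
#' @export
simulate_population_features <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  p <- ncol(spec$feature_means)
  nm <- colnames(spec$feature_means)
  if (is.null(nm)) nm <- sprintf("feat_%02d", seq_len(p))
  rows <- vector("list", spec$n_stages)
  for (st in seq_len(spec$n_stages)) {
    n <- spec$cells_per_stage
    x <- matrix(rnorm(n * p), n, p) %*% diag(spec$noise_sd, p) +
      matrix(spec$feature_means[st, ], n, p, byrow = TRUE)
    colnames(x) <- nm
    rows[[st]] <- data.frame(stage = st - 1L,
                             label = if (st == 1) "HSC" else "diff", x)
  }
  do.call(rbind, rows)
}

#' Simulate features driven by one latent stemness factor
#'
#' Draws \code{x = z w' + e} with a standard-normal latent \code{z},
#' per-feature loadings sampled uniformly from \code{loading_range} with
#' random sign, and isotropic Gaussian noise — the parameter-recovery
#' benchmark for the latent MOB model. Defaults (11 features, loadings
#' 0.6-1, noise SD 0.3) emulate a representative-feature panel dominated by
#' one metabolic-stemness axis.
#'
#' @param n cells.
#' @param p features.
#' @param loading_range absolute loading range.
#' @param noise_sd isotropic noise SD.
#' @param seed RNG seed.
#' @return list with \code{features} (data.frame f01..fp), \code{latent}
#'   (the true factor), \code{loadings}.
#' @export
simulate_latent_features <- function(n = 500L, p = 11L,
                                     loading_range = c(0.6, 1),
                                     noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  z <- rnorm(n)
  w <- runif(p, loading_range[1], loading_range[2]) *
    sample(c(-1, 1), p, replace = TRUE)
  x <- outer(z, w) + matrix(rnorm(n * p, 0, noise_sd), n, p)
  df <- as.data.frame(x)
  names(df) <- sprintf("f%02d", seq_len(p))
  list(features = df, latent = z, loadings = w)
}

#' Division-experiment specification
#'
#' @param n_pairs number of parent/daughter-pair records.
#' @param inheritance_r target Pearson correlation between the parent score
#'   and the daughter-pair mean score, in [0,1].
#' @param asym_fraction fraction of metabolically asymmetric divisions.
#' @param delta_mean_sym,delta_mean_asym mean |score| difference between the
#'   two daughters for symmetric vs asymmetric divisions (score units);
#'   asym > sym >= 0 is required.
#' @param delta_sd SD of the daughter score difference.
#' @param parent_mean,parent_sd parent MOB score distribution.
#' @param site_spacing_um micropattern site spacing (positions for pairing).
#' @param seed RNG seed.
#' @return a \code{division_spec}.
#' @export
division_spec <- function(n_pairs = 200L, inheritance_r = 0.8,
                          asym_fraction = 0.2, delta_mean_sym = 0.3,
                          delta_mean_asym = 2.0, delta_sd = 0.2,
                          parent_mean = 1, parent_sd = 1,
                          site_spacing_um = 40, seed = 1L) {
  if (inheritance_r < 0 || inheritance_r > 1) stop("inheritance_r must be in [0,1]")
  if (asym_fraction < 0 || asym_fraction > 1) stop("asym_fraction must be in [0,1]")
  if (!(delta_mean_asym > delta_mean_sym && delta_mean_sym >= 0))
    stop("need delta_mean_asym > delta_mean_sym >= 0")
  structure(list(n_pairs = as.integer(n_pairs), inheritance_r = inheritance_r,
                 asym_fraction = asym_fraction, delta_mean_sym = delta_mean_sym,
                 delta_mean_asym = delta_mean_asym, delta_sd = delta_sd,
                 parent_mean = parent_mean, parent_sd = parent_sd,
                 site_spacing_um = site_spacing_um, seed = as.integer(seed)),
            class = "division_spec")
}

#' Simulate a parent/paired-daughter division dataset
#'
#' Parent scores are Gaussian; the daughter-pair mean inherits the parent
#' score with correlation \code{inheritance_r}; the two daughters split
#' symmetrically about that mean by a signed difference whose magnitude is
#' Gaussian around the symmetric or asymmetric mode, giving the bimodal
#' |delta-MOB| structure. Site positions on a jittered micropattern grid are
#' included so centroid-based pairing can be exercised.
#'
#' @param spec a \code{\link{division_spec}}.
#' @return list with \code{pairs} (pair_id, site, positions, parent_score,
#'   daughter scores, delta_mob, true_pattern), and long-format \code{pre}
#'   and \code{post} cell tables (site positions + scores) for
#'   \code{\link{pair_daughters}}.
#' @export
simulate_division_dataset <- function(spec) {
  stopifnot(inherits(spec, "division_spec"))
  set.seed(spec$seed)
  n <- spec$n_pairs
  r <- spec$inheritance_r
  parent <- rnorm(n, spec$parent_mean, spec$parent_sd)
  mid <- spec$parent_mean + r * (parent - spec$parent_mean) +
    sqrt(max(0, 1 - r^2)) * spec$parent_sd * rnorm(n)
  asym <- runif(n) < spec$asym_fraction
  dmean <- ifelse(asym, spec$delta_mean_asym, spec$delta_mean_sym)
  delta <- abs(rnorm(n, dmean, spec$delta_sd))
  side <- sample(c(-1, 1), n, replace = TRUE)
  d1 <- mid + side * delta / 2
  d2 <- mid - side * delta / 2

  ns <- ceiling(sqrt(n))
  site_xy <- expand.grid(x = seq_len(ns), y = seq_len(ns))[seq_len(n), ] *
    spec$site_spacing_um
  jit <- function(k, a = spec$site_spacing_um * 0.15) runif(k, -a, a)
  pairs <- data.frame(pair_id = seq_len(n), site = seq_len(n),
                      site_x = site_xy$x, site_y = site_xy$y,
                      parent_score = parent, daughter1 = d1, daughter2 = d2,
                      delta_mob = abs(d1 - d2),
                      true_pattern = ifelse(asym, "M-asymmetric", "M-symmetric"))
  pre <- data.frame(cell_id = seq_len(n), x = site_xy$x + jit(n),
                    y = site_xy$y + jit(n), score = parent)
  post <- data.frame(cell_id = seq_len(2 * n),
                     x = rep(site_xy$x, each = 2) + jit(2 * n),
                     y = rep(site_xy$y, each = 2) + jit(2 * n),
                     score = as.vector(rbind(d1, d2)))
  list(pairs = pairs, pre = pre, post = post,
       sites = data.frame(site = seq_len(n), x = site_xy$x, y = site_xy$y),
       spec = spec)
}
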