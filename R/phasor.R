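# Phasor-domain FLIM analysis: transform, smoothing, free/bound decomposition,
# and the baseline-corrected optical redox ratio.

#' Closed-form phasor coordinates of a mono-exponential decay
#'
#' For a single-exponential decay with lifetime \code{tau} the first-harmonic
#' phasor lies on the universal semicircle: g = 1/(1+(omega*tau)^2),
#' s = omega*tau*g.
#'
#' @param tau lifetime in ns (vectorised).
#' @param omega angular modulation frequency in rad/ns
#'   (\code{2*pi*harmonic/laser_period_ns}).
#' @return a list with numeric \code{g} and \code{s}.
#' @examples
#' phasor_of_lifetime(2.5, omega_from_period(12.5))
#' @export
phasor_of_lifetime <- function(tau, omega) {
  wt <- omega * tau
  g <- 1 / (1 + wt^2)
  list(g = g, s = wt * g)
}

#' Angular frequency of a harmonic of the laser repetition period
#'
#' @param laser_period_ns repetition period in ns (12.5 ns for an 80 MHz
#'   Ti:Sapphire source).
#' @param harmonic harmonic number (the pipeline uses the first harmonic).
#' @return omega in rad/ns.
#' @export
omega_from_period <- function(laser_period_ns, harmonic = 1L) {
  stopifnot(laser_period_ns > 0, harmonic >= 1)
  2 * pi * harmonic / laser_period_ns
}

#' Invert on-semicircle phasor coordinates to a lifetime
#'
#' @param g,s phasor coordinates.
#' @param omega angular frequency in rad/ns.
#' @return lifetime in ns (\code{s/(omega*g)}).
#' @export
phasor_to_lifetime <- function(g, s, omega) s / (omega * g)

#' Phasor transform of a decay image
#'
#' Computes per-pixel first-harmonic (or higher) phasor coordinates from a
#' photon decay histogram stack. Time is taken at bin centers:
#' g = sum_t I(t) cos(omega t) / sum_t I(t) and likewise with sin for s.
#' Pixels with zero total photons are flagged invalid (g = s = NA).
#'
#' @param decay a \code{decay_image} (see \code{\link{decay_image}}).
#' @param harmonic harmonic number, default 1.
#' @return a \code{phasor_map}: list with matrices \code{g}, \code{s},
#'   \code{total_photons}, logical \code{valid}, plus \code{omega} (rad/ns),
#'   \code{harmonic} and \code{laser_period_ns}.
#' @export
phasor_transform <- function(decay, harmonic = 1L) {
  stopifnot(inherits(decay, "decay_image"))
  counts <- decay$counts
  nb <- dim(counts)[3]
  if (nb < 2) stop("decay image must have at least 2 time bins")
  period <- decay$laser_period_ns
  omega <- omega_from_period(period, harmonic)
  dt <- period / nb
  tc <- (seq_len(nb) - 0.5) * dt
  h <- dim(counts)[1]; w <- dim(counts)[2]
  flat <- matrix(counts, nrow = h * w, ncol = nb)
  tot <- rowSums(flat)
  num <- flat %*% cbind(cos(omega * tc), sin(omega * tc))
  g <- matrix(num[, 1] / tot, h, w)
  s <- matrix(num[, 2] / tot, h, w)
  valid <- matrix(tot > 0, h, w)
  g[!valid] <- NA_real_
  s[!valid] <- NA_real_
  if (!any(valid)) warning("all pixels have zero photons; phasor map is all-invalid")
  structure(
    list(g = g, s = s, total_photons = matrix(tot, h, w), valid = valid,
         harmonic = as.integer(harmonic), omega = omega,
         laser_period_ns = period),
    class = "phasor_map")
}

#' Median-filter a phasor map
#'
#' Applies an odd-window median filter to the g and s matrices independently,
#' the standard noise-reduction step before free/bound decomposition. Invalid
#' pixels are excluded from every neighborhood; border pixels use the reduced
#' neighborhood that fits inside the image.
#'
#' @param p a \code{phasor_map}.
#' @param window odd window size, default 3 (a 3x3 filter).
#' @return a filtered \code{phasor_map}.
#' @export
median_filter_phasor <- function(p, window = 3L) {
  stopifnot(inherits(p, "phasor_map"))
  if (window < 1 || window %% 2 == 0) stop("window must be a positive odd integer")
  if (window == 1) return(p)
  p$g <- .median_filter_na(p$g, window)
  p$s <- .median_filter_na(p$s, window)
  p
}

# NA-aware median filter with reduced neighborhoods at borders.
.median_filter_na <- function(x, window) {
  h <- nrow(x); w <- ncol(x)
  r <- (window - 1L) %/% 2L
  offs <- expand.grid(di = -r:r, dj = -r:r)
  n_off <- nrow(offs)
  # stack shifted copies, then take a per-pixel median over the stack
  stack <- array(NA_real_, dim = c(h, w, n_off))
  for (k in seq_len(n_off)) {
    di <- offs$di[k]; dj <- offs$dj[k]
    si <- seq_len(h) + di; sj <- seq_len(w) + dj
    oki <- si >= 1 & si <= h; okj <- sj >= 1 & sj <= w
    stack[oki, okj, k] <- x[si[oki], sj[okj], drop = FALSE]
  }
  out <- apply(stack, c(1, 2), median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out[is.na(x)] <- NA_real_   # invalid pixels stay invalid
  out
}

# qc codes shared by lifetime maps
QC_OK <- 0L; QC_CLAMPED <- 1L; QC_INVALID <- 2L

#' Decompose a phasor map into free/bound NAD(P)H components
#'
#' Fixes the free-NAD(P)H anchor F on the universal semicircle at
#' \code{tau_free} (0.45 ns by default), draws the line from F through each
#' pixel's phasor P, and extends it to its second intersection B with the
#' semicircle \eqn{(g-0.5)^2 + s^2 = 0.25}. The bound lifetime is the
#' lifetime at B (\code{tau = s/(omega g)}) and the bound fraction is the
#' chord ratio \code{alpha_bound = |P-F| / |B-F|}.
#'
#' Pixels whose phasor falls outside the semicircle or beyond the chord are
#' clamped into range and flagged \code{"clamped"}; pixels where the geometry
#' is degenerate (no second intersection on the long-lifetime side, or an
#' invalid phasor) are flagged \code{"invalid"}.
#'
#' @param p a \code{phasor_map} (typically median-filtered).
#' @param tau_free free-NAD(P)H lifetime in ns, default 0.45.
#' @param omega angular frequency in rad/ns; defaults to the map's own.
#' @return a \code{lifetime_map}: matrices \code{alpha_bound},
#'   \code{tau_bound}, integer \code{qc} (0 ok, 1 clamped, 2 invalid), and
#'   scalars \code{tau_free}, \code{omega}.
#' @export
resolve_bound_fraction <- function(p, tau_free = 0.45, omega = p$omega) {
  stopifnot(inherits(p, "phasor_map"), tau_free > 0)
  fa <- phasor_of_lifetime(tau_free, omega)
  gF <- fa$g; sF <- fa$s
  g <- p$g; s <- p$s
  h <- nrow(g); w <- ncol(g)
  alpha <- matrix(NA_real_, h, w)
  taub  <- matrix(NA_real_, h, w)
  qc    <- matrix(QC_INVALID, h, w)

  ok <- p$valid & is.finite(g) & is.finite(s)
  dg <- g[ok] - gF; ds <- s[ok] - sF
  d2 <- dg^2 + ds^2
  tol <- 1e-12

  a <- rep(NA_real_, sum(ok)); tb <- a; q <- rep(QC_INVALID, sum(ok))

  at_anchor <- d2 < tol
  a[at_anchor] <- 0; tb[at_anchor] <- NA_real_; q[at_anchor] <- QC_OK

  idx <- which(!at_anchor)
  if (length(idx)) {
    dgi <- dg[idx]; dsi <- ds[idx]
    # F is on the circle (center c=(0.5,0), r=0.5); parametrize X = F + u*d.
    # |X-c|^2 = r^2  =>  u * (u*|d|^2 + 2 (F-c).d) = 0; second root:
    u2 <- -2 * ((gF - 0.5) * dgi + sF * dsi) / (dgi^2 + dsi^2)
    gB <- gF + u2 * dgi
    sB <- sF + u2 * dsi
    tB <- sB / (omega * gB)
    # the valid branch exits on the long-lifetime side (tau_B > tau_free)
    good <- is.finite(u2) & u2 > tol & is.finite(tB) & tB > tau_free
    ii <- idx[good]
    av <- 1 / u2[good]                     # |P-F|/|B-F|
    clamped <- av > 1 | av < 0
    av <- pmin(pmax(av, 0), 1)
    a[ii] <- av
    tb[ii] <- tB[good]
    q[ii] <- ifelse(clamped, QC_CLAMPED, QC_OK)
  }

  alpha[ok] <- a; taub[ok] <- tb; qc[ok] <- q
  structure(
    list(alpha_bound = alpha, tau_bound = taub, qc = qc,
         tau_free = tau_free, omega = omega),
    class = "lifetime_map")
}

#' QC summary of a lifetime map
#'
#' @param lm a \code{lifetime_map}.
#' @return named fractions of ok / clamped / invalid pixels.
#' @export
qc_fractions <- function(lm) {
  stopifnot(inherits(lm, "lifetime_map"))
  n <- length(lm$qc)
  c(ok = mean(lm$qc == QC_OK), clamped = mean(lm$qc == QC_CLAMPED),
    invalid = mean(lm$qc == QC_INVALID))
}

#' Baseline-corrected optical redox ratio per cell
#'
#' The observed FAD/NAD(P)H ratio in mitochondria is the true mitochondrial
#' redox ratio plus a constant additive baseline contributed by diffuse
#' cytoplasmic/nuclear signal; subtracting the cytoplasmic/nuclear ratio
#' removes that baseline:
#' \code{orr_corrected = (sum FAD / sum NADPH)_mito - (sum FAD / sum NADPH)_cyto}.
#'
#' @param fad_intensity,nadph_intensity intensity matrices (same shape).
#' @param mito_mask,cyto_mask disjoint logical masks of the two compartments
#'   of one cell.
#' @return a list with \code{orr_corrected}, \code{mito_ratio},
#'   \code{baseline_alpha} (the cytoplasmic ratio) and logical \code{ok}
#'   (FALSE when either region is empty or has zero NAD(P)H signal).
#' @export
compute_orr <- function(fad_intensity, nadph_intensity, mito_mask, cyto_mask) {
  stopifnot(all(dim(fad_intensity) == dim(nadph_intensity)),
            all(dim(mito_mask) == dim(fad_intensity)))
  if (any(mito_mask & cyto_mask)) stop("mito and cyto masks must be disjoint")
  nm <- sum(nadph_intensity[mito_mask]); nc <- sum(nadph_intensity[cyto_mask])
  if (!any(mito_mask) || !any(cyto_mask) || nm <= 0 || nc <= 0) {
    return(list(orr_corrected = NA_real_, mito_ratio = NA_real_,
                baseline_alpha = NA_real_, ok = FALSE))
  }
  rm_ <- sum(fad_intensity[mito_mask]) / nm
  rc <- sum(fad_intensity[cyto_mask]) / nc
  list(orr_corrected = rm_ - rc, mito_ratio = rm_, baseline_alpha = rc, ok = TRUE)
}
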