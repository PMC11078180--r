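# Single-cell segmentation from NAD(P)H intensity and the mitochondria vs
# cytoplasm/nucleus split from FAD intensity. EBImage provides the
# morphological primitives (erosion, hole filling, distance transform,
# marker propagation, labelling); this module fixes the pipeline around them.

#' Threshold NAD(P)H intensity into a cell mask
#'
#' Cells are much brighter than the low photon-count background, so a photon
#' threshold of 1-2 counts/pixel separates them; holes inside cells are
#' filled.
#'
#' @param nadph_intensity photon-count matrix.
#' @param photon_threshold counts/pixel; pixels strictly above it are
#'   foreground. Default 2.
#' @return logical matrix.
#' @export
mask_cells <- function(nadph_intensity, photon_threshold = 2) {
  stopifnot(photon_threshold >= 0)
  mask <- nadph_intensity > photon_threshold
  if (!any(mask)) {
    warning("cell mask is empty at this photon threshold")
    return(mask)
  }
  EBImage::fillHull(mask) > 0
}

#' Pixel-area window for plausible cell sizes
#'
#' @param pixel_size_um pixel size in micrometers.
#' @param diameter_um_range plausible cell diameter range in micrometers;
#'   default 6-20 um covers hematopoietic cells while excluding debris and
#'   unsegregated clumps.
#' @return c(min_px, max_px) disk-equivalent pixel areas.
#' @export
size_window_px <- function(pixel_size_um = 0.18, diameter_um_range = c(6, 20)) {
  a <- pi * (diameter_um_range / 2)^2 / pixel_size_um^2
  c(floor(a[1]), ceiling(a[2]))
}

#' Split a cell mask into labelled single cells
#'
#' Erodes the mask to seed markers (separating touching cells), assigns every
#' mask pixel to its marker by watershed-style propagation on the distance
#' transform, and removes components outside the size window.
#'
#' @param mask logical cell mask.
#' @param min_size_px,max_size_px retained component area bounds (pixels);
#'   defaults from \code{\link{size_window_px}} at 0.18 um pixels.
#' @param erode_iter erosion iterations with a 3x3 cross, default 1.
#' @return integer label matrix (0 = background), labels consecutive from 1.
#' @export
split_cells <- function(mask, min_size_px = size_window_px()[1],
                        max_size_px = size_window_px()[2], erode_iter = 1L) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  kern <- EBImage::makeBrush(3, shape = "diamond")  # 3x3 cross
  seeds <- mask
  for (i in seq_len(erode_iter)) seeds <- EBImage::erode(seeds, kern) > 0
  seed_lab <- EBImage::bwlabel(seeds)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::propagate(dm, seeds = seed_lab, mask = mask, lambda = 100)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  # components that lost every seed to erosion are specks; recover them so
  # the size filter (not the erosion depth) decides their fate
  orphan <- mask & lab == 0L
  if (any(orphan)) {
    extra <- EBImage::bwlabel(orphan)
    extra <- matrix(as.integer(EBImage::imageData(extra)), nrow(mask), ncol(mask))
    extra[extra > 0L] <- extra[extra > 0L] + max(lab)
    lab <- lab + extra
  }
  .filter_relabel(lab, min_size_px, max_size_px)
}

.filter_relabel <- function(lab, min_size_px, max_size_px) {
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size_px & sizes <= max_size_px)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Split one cell into mitochondrial and cytoplasmic/nuclear submasks
#'
#' After background subtraction, FAD intensity inside the cell is thresholded
#' with Otsu's method: pixels above the threshold are mitochondria (punctate,
#' FAD-bright), the rest is the pooled cytoplasm/nucleus compartment.
#'
#' @param fad_intensity FAD intensity matrix.
#' @param cell_mask logical mask of one cell.
#' @param background_estimate additive FAD background to subtract (e.g. mean
#'   FAD outside the global cell mask). Default 0.
#' @param levels histogram levels for the Otsu search.
#' @return list with \code{mito_mask}, \code{cyto_mask}, \code{threshold}
#'   (on the background-subtracted scale) and \code{ok}; \code{ok = FALSE}
#'   with empty masks when FAD is constant within the cell or one compartment
#'   would be empty (degenerate threshold).
#' @export
segment_subregions <- function(fad_intensity, cell_mask,
                               background_estimate = 0, levels = 256L) {
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) stop("cell mask is empty")
  vals <- pmax(fad_intensity[cell_mask] - background_estimate, 0)
  rng <- range(vals)
  bad <- list(mito_mask = cell_mask & FALSE, cyto_mask = cell_mask & FALSE,
              threshold = NA_real_, ok = FALSE)
  if (diff(rng) <= 0) return(bad)
  thr <- .otsu_threshold(vals, levels)
  sub <- pmax(fad_intensity - background_estimate, 0)
  mito <- cell_mask & sub > thr
  cyto <- cell_mask & !mito
  if (!any(mito) || !any(cyto)) return(bad)
  list(mito_mask = mito, cyto_mask = cyto, threshold = thr, ok = TRUE)
}

# Otsu's threshold (maximum between-class variance) on an equal-width
# histogram; returns a threshold on the value scale.
.otsu_threshold <- function(vals, levels = 256L) {
  rng <- range(vals)
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  cnt <- tabulate(findInterval(vals, br, rightmost.closed = TRUE), levels)
  p <- cnt / sum(cnt)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-levels])
  br[k + 1L]
}

#' Full single-cell segmentation of a two-channel acquisition
#'
#' Chains \code{\link{mask_cells}}, \code{\link{split_cells}} and per-cell
#' \code{\link{segment_subregions}}. The FAD background estimate is the mean
#' FAD intensity outside the global cell mask.
#'
#' @param nadph_intensity,fad_intensity intensity matrices.
#' @param photon_threshold see \code{\link{mask_cells}}.
#' @param min_size_px,max_size_px see \code{\link{split_cells}}.
#' @param erode_iter see \code{\link{split_cells}}.
#' @return a \code{cell_segmentation}: \code{label_image} plus a per-cell
#'   list (\code{cell_id}, \code{pixel_count}, \code{centroid},
#'   \code{mito_mask}, \code{cyto_mask}, \code{split_ok}) and the
#'   \code{fad_background} used.
#' @export
segment_cells <- function(nadph_intensity, fad_intensity, photon_threshold = 2,
                          min_size_px = size_window_px()[1],
                          max_size_px = size_window_px()[2], erode_iter = 1L) {
  stopifnot(all(dim(nadph_intensity) == dim(fad_intensity)))
  mask <- mask_cells(nadph_intensity, photon_threshold)
  lab <- split_cells(mask, min_size_px, max_size_px, erode_iter)
  bg <- if (any(!mask)) mean(fad_intensity[!mask]) else 0
  n <- max(lab)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cm <- lab == i
    idx <- which(cm, arr.ind = TRUE)
    sub <- segment_subregions(fad_intensity, cm, background_estimate = bg)
    cells[[i]] <- list(cell_id = i, pixel_count = nrow(idx),
                       centroid = colMeans(idx),  # (row, col), 1-based centers
                       mito_mask = sub$mito_mask, cyto_mask = sub$cyto_mask,
                       split_ok = sub$ok, fad_threshold = sub$threshold)
  }
  structure(list(label_image = lab, cells = cells, fad_background = bg,
                 photon_threshold = photon_threshold),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  n <- length(x$cells)
  ok <- sum(vapply(x$cells, function(c) c$split_ok, logical(1)))
  cat("cell_segmentation:", n, "cells (", ok, "with mito/cyto split),",
      "FAD background", signif(x$fad_background, 3), "\n")
  invisible(x)
}
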