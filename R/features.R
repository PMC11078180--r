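# The MOB feature library: a declarative registry of per-cell features over
# the four MOB channels (NAD(P)H intensity, alpha_bound, tau_bound, ORR) and
# the two subcellular compartments, plus morphology and mito<->cyto
# compartmentalization.

REGISTRY_VERSION <- "1.0"

.signal_stats <- c("average", "median", "p10", "p90")
.dist_stats <- c("sd", "variance", "skewness", "kurtosis", "entropy",
                 "iqr", "uniformity")
.texture_stats <- c("glcm_contrast", "glcm_homogeneity", "glcm_energy",
                    "glcm_entropy", "glcm_correlation",
                    "glcm_difference_variance", "glrlm_sre", "glrlm_lre",
                    "glrlm_gln", "glrlm_rln", "glrlm_rp", "glrlm_glv")
.morph_stats <- c("size", "major_axis_length", "minor_axis_length",
                  "eccentricity", "perimeter", "circularity", "mito_size",
                  "mito_count", "mito_dispersity", "cyto_size")

#' The MOB feature registry
#'
#' Enumerates the full feature library as a declarative table: per-region
#' signal-strength, distribution and texture statistics of the NAD(P)H
#' intensity, alpha_bound and tau_bound channels in both compartments, the
#' same statistics of the per-pixel ORR in mitochondria only, mito-vs-cyto
#' compartmentalization of every non-texture statistic, whole-cell
#' morphology, and the baseline-corrected per-cell ORR. The registry is
#' data-driven so subsets can be passed to \code{\link{extract_features}}.
#'
#' @return data.frame with \code{feature_id}, \code{channel}, \code{region},
#'   \code{statistic}, \code{family}; registry version in
#'   \code{attr(, "version")}.
#' @export
mob_registry <- function() {
  rows <- list()
  add <- function(channel, region, statistic, family) {
    id <- if (region == "compartmentalization") {
      paste("comp", channel, statistic, sep = "_")
    } else if (channel == "morphology") {
      paste("morph", statistic, sep = "_")
    } else paste(region, channel, statistic, sep = "_")
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = id, channel = channel, region = region,
      statistic = statistic, family = family)
  }
  per_region <- c(.signal_stats, .dist_stats, .texture_stats)
  fam <- c(rep("signal", 4), rep("distribution", 7), rep("texture", 12))
  for (ch in c("NADPH_intensity", "alpha_bound", "tau_bound")) {
    for (rg in c("mito", "cyto")) {
      for (k in seq_along(per_region)) add(ch, rg, per_region[k], fam[k])
    }
    for (st in c(.signal_stats, .dist_stats))
      add(ch, "compartmentalization", st, "compartmentalization")
  }
  for (k in seq_along(per_region)) add("ORR", "mito", per_region[k], fam[k])
  for (st in .morph_stats) add("morphology", "whole", st, "morphology")
  add("ORR", "cell", "corrected", "orr")
  reg <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(reg$feature_id))
  attr(reg, "version") <- REGISTRY_VERSION
  reg
}

#' Compartmentalization of a feature between mitochondria and cytoplasm
#'
#' \code{(m - c) / (m + c)}, the normalized mito-vs-cytoplasm contrast of a
#' per-region feature value; 0 when both values are 0 (documented
#' convention), NA (flagged) when opposite-signed inputs make the
#' denominator vanish.
#'
#' @param m,c finite per-region feature values (vectorised).
#' @return values in [-1, 1] for same-signed inputs.
#' @export
compartmentalization <- function(m, c) {
  out <- rep(NA_real_, length(m))
  both0 <- !is.na(m) & !is.na(c) & m == 0 & c == 0
  out[both0] <- 0
  den <- m + c
  ok <- !both0 & is.finite(m) & is.finite(c) &
    abs(den) > 1e-12 * pmax(abs(m), abs(c), 1)
  out[ok] <- (m[ok] - c[ok]) / den[ok]
  out
}

#' Signal-strength and distribution statistics of a region
#'
#' Average, median, 10th/90th percentile (linear-interpolation convention),
#' SD, variance, skewness, excess kurtosis, Shannon entropy and uniformity
#' on a fixed-bin histogram, and interquartile range. Regions with fewer
#' than 3 pixels get NA higher moments.
#'
#' @param values numeric vector of in-region pixel values (NAs dropped).
#' @param hist_bins histogram bins for entropy/uniformity, default 16.
#' @return named numeric vector over the 11 statistics.
#' @export
region_statistics <- function(values, hist_bins = 16L) {
  v <- values[is.finite(values)]
  out <- setNames(rep(NA_real_, 11), c(.signal_stats, .dist_stats))
  n <- length(v)
  if (n == 0) return(out)
  out["average"] <- mean(v)
  out["median"] <- median(v)
  out["p10"] <- quantile(v, 0.10, names = FALSE)
  out["p90"] <- quantile(v, 0.90, names = FALSE)
  out["iqr"] <- quantile(v, 0.75, names = FALSE) - quantile(v, 0.25, names = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  out["sd"] <- sqrt(m2)
  out["variance"] <- m2
  if (n >= 3) {
    if (m2 > 0) {
      out["skewness"] <- mean((v - m)^3) / m2^1.5
      out["kurtosis"] <- mean((v - m)^4) / m2^2 - 3
    } else {
      out["skewness"] <- 0; out["kurtosis"] <- 0
    }
  }
  rng <- range(v)
  if (diff(rng) <= 0) {
    out["entropy"] <- 0; out["uniformity"] <- 1
  } else {
    br <- seq(rng[1], rng[2], length.out = hist_bins + 1L)
    p <- tabulate(findInterval(v, br, rightmost.closed = TRUE), hist_bins) / n
    nz <- p > 0
    out["entropy"] <- -sum(p[nz] * log2(p[nz]))
    out["uniformity"] <- sum(p^2)
  }
  out
}

#' Morphological features of one segmented cell
#'
#' Areas in um^2 from the pixel size, ellipse axis lengths and eccentricity
#' from the mask's second moments, contour perimeter and circularity
#' (4*pi*A/P^2), and the mitochondrial fragmentation summary (component
#' count, and dispersity = components per mito pixel).
#'
#' @param cell one cell entry of a \code{\link{segment_cells}} result (needs
#'   \code{mito_mask}/\code{cyto_mask} and the label image context).
#' @param cell_mask logical mask of the cell.
#' @param pixel_size_um pixel size in micrometers.
#' @return named numeric vector over the morphology statistics.
#' @export
morphology_features <- function(cell_mask, mito_mask = NULL, cyto_mask = NULL,
                                pixel_size_um = 0.18) {
  out <- setNames(rep(NA_real_, length(.morph_stats)), .morph_stats)
  idx <- which(cell_mask, arr.ind = TRUE)
  n <- nrow(idx)
  pa <- pixel_size_um^2
  out["size"] <- n * pa
  if (n >= 3) {
    cv <- cov(idx) * (n - 1) / n     # population moments of pixel coords
    ev <- eigen(cv, symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    out["major_axis_length"] <- 4 * sqrt(ev[1]) * pixel_size_um
    out["minor_axis_length"] <- 4 * sqrt(ev[2]) * pixel_size_um
    out["eccentricity"] <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
    per <- .contour_perimeter(cell_mask) * pixel_size_um
    out["perimeter"] <- per
    out["circularity"] <- if (per > 0) min(4 * pi * out["size"] / per^2, 1) else NA_real_
  }
  if (!is.null(mito_mask)) {
    nm <- sum(mito_mask)
    out["mito_size"] <- nm * pa
    if (nm > 0) {
      lab <- EBImage::bwlabel(mito_mask)
      ncomp <- max(lab)
      out["mito_count"] <- ncomp
      out["mito_dispersity"] <- ncomp / nm
    } else {
      out["mito_count"] <- 0; out["mito_dispersity"] <- NA_real_
    }
  }
  if (!is.null(cyto_mask)) out["cyto_size"] <- sum(cyto_mask) * pa
  out
}

# 8-connected contour-chain perimeter (diagonal steps count sqrt(2))
.contour_perimeter <- function(mask) {
  oc <- tryCatch(EBImage::ocontour(EBImage::bwlabel(mask)),
                 error = function(e) NULL)
  if (is.null(oc) || !length(oc)) {
    # fallback: 4-neighbor boundary edge count
    m <- mask > 0
    h <- nrow(m); w <- ncol(m)
    pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- m
    edges <- sum(pad[2:(h + 1), 2:(w + 1)] & !pad[1:h, 2:(w + 1)]) +
      sum(pad[2:(h + 1), 2:(w + 1)] & !pad[3:(h + 2), 2:(w + 1)]) +
      sum(pad[2:(h + 1), 2:(w + 1)] & !pad[2:(h + 1), 1:w]) +
      sum(pad[2:(h + 1), 2:(w + 1)] & !pad[2:(h + 1), 3:(w + 2)])
    return(edges)
  }
  tot <- 0
  for (ct in oc) {
    d <- diff(rbind(ct, ct[1, , drop = FALSE]))
    tot <- tot + sum(sqrt(rowSums(d^2)))
  }
  tot
}

#' Extract the MOB feature table from a segmented acquisition
#'
#' Computes one value (or NA flag) per registry entry per cell. Lifetime
#' channels use only pixels with valid phasor decomposition; the per-pixel
#' ORR channel (FAD/NAD(P)H) is quantified in mitochondria only, and the
#' baseline-corrected per-cell ORR subtracts the cytoplasmic ratio. Cells
#' whose mito/cyto split failed keep whole-cell morphology but carry NA for
#' all compartment-dependent entries (flagged in \code{flag_split}).
#'
#' @param seg a \code{\link{segment_cells}} result.
#' @param nadph_intensity,fad_intensity intensity matrices.
#' @param lifetime a \code{lifetime_map} from
#'   \code{\link{resolve_bound_fraction}} (or NULL to skip those channels).
#' @param pixel_size_um pixel size in micrometers.
#' @param registry registry table (default full \code{\link{mob_registry}});
#'   pass a subset for fast targeted extraction.
#' @param texture_levels gray levels for texture quantization.
#' @return data.frame: one row per cell with \code{cell_id}, centroid,
#'   \code{flag_split}, then one column per registry feature_id.
#' @export
extract_features <- function(seg, nadph_intensity, fad_intensity,
                             lifetime = NULL, pixel_size_um = 0.18,
                             registry = mob_registry(), texture_levels = 16L) {
  stopifnot(inherits(seg, "cell_segmentation"))
  n <- length(seg$cells)
  ids <- registry$feature_id
  mat <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  meta <- data.frame(cell_id = integer(n), centroid_row = numeric(n),
                     centroid_col = numeric(n), area_px = numeric(n),
                     flag_split = logical(n))
  if (n == 0) return(cbind(meta, as.data.frame(mat)))

  chan_maps <- list(NADPH_intensity = nadph_intensity)
  if (!is.null(lifetime)) {
    a <- lifetime$alpha_bound; a[lifetime$qc == 2L] <- NA
    tb <- lifetime$tau_bound; tb[lifetime$qc != 0L] <- NA
    chan_maps$alpha_bound <- a
    chan_maps$tau_bound <- tb
  }
  orr_map <- fad_intensity / ifelse(nadph_intensity > 0, nadph_intensity, NA)

  need_region <- unique(registry[registry$region %in% c("mito", "cyto"),
                                 c("channel", "region", "family")])
  comp_chans <- unique(registry$channel[registry$region == "compartmentalization"])

  for (ci in seq_len(n)) {
    cell <- seg$cells[[ci]]
    cm <- seg$label_image == cell$cell_id
    meta$cell_id[ci] <- cell$cell_id
    meta$centroid_row[ci] <- cell$centroid[1]
    meta$centroid_col[ci] <- cell$centroid[2]
    meta$area_px[ci] <- cell$pixel_count
    meta$flag_split[ci] <- !cell$split_ok

    if (any(registry$channel == "morphology")) {
      mo <- morphology_features(cm,
                                if (cell$split_ok) cell$mito_mask,
                                if (cell$split_ok) cell$cyto_mask,
                                pixel_size_um)
      sel <- registry$channel == "morphology"
      mat[ci, registry$feature_id[sel]] <- mo[registry$statistic[sel]]
    }

    if (cell$split_ok) {
      masks <- list(mito = cell$mito_mask, cyto = cell$cyto_mask)
      # cache per (channel, region) statistics for compartmentalization reuse
      stat_cache <- list()
      for (ch in setdiff(unique(registry$channel), c("morphology"))) {
        if (ch == "ORR") next
        if (is.null(chan_maps[[ch]])) next
        for (rg in c("mito", "cyto")) {
          rows <- registry$channel == ch & registry$region == rg
          comp_need <- ch %in% comp_chans
          if (!any(rows) && !comp_need) next
          vals_mat <- chan_maps[[ch]]
          vm <- vals_mat; vm[!masks[[rg]]] <- NA
          rs <- region_statistics(vm[!is.na(vm)])
          stat_cache[[paste(ch, rg)]] <- rs
          if (any(rows)) {
            nontex <- rows & registry$family != "texture"
            mat[ci, registry$feature_id[nontex]] <- rs[registry$statistic[nontex]]
            tex_rows <- rows & registry$family == "texture"
            if (any(tex_rows)) {
              tx <- texture_features(.crop_region(vm), texture_levels)
              mat[ci, registry$feature_id[tex_rows]] <- tx[registry$statistic[tex_rows]]
            }
          }
        }
      }
      # ORR: per-pixel ratio, mitochondria only
      orows <- registry$channel == "ORR" & registry$region == "mito"
      if (any(orows)) {
        vm <- orr_map; vm[!masks$mito] <- NA
        rs <- region_statistics(vm[!is.na(vm)])
        nontex <- orows & registry$family != "texture"
        mat[ci, registry$feature_id[nontex]] <- rs[registry$statistic[nontex]]
        tex_rows <- orows & registry$family == "texture"
        if (any(tex_rows) && sum(!is.na(vm)) >= 9) {
          tx <- texture_features(.crop_region(vm), texture_levels)
          mat[ci, registry$feature_id[tex_rows]] <- tx[registry$statistic[tex_rows]]
        }
      }
      crow <- registry$channel == "ORR" & registry$region == "cell"
      if (any(crow)) {
        orr <- compute_orr(fad_intensity, nadph_intensity,
                           masks$mito, masks$cyto)
        mat[ci, registry$feature_id[crow]] <- orr$orr_corrected
      }
      crows <- registry$region == "compartmentalization"
      if (any(crows)) {
        for (ch in intersect(comp_chans, names(chan_maps))) {
          rr <- crows & registry$channel == ch
          if (!any(rr)) next
          sm <- stat_cache[[paste(ch, "mito")]]
          sc <- stat_cache[[paste(ch, "cyto")]]
          if (is.null(sm)) {
            vm <- chan_maps[[ch]]; vm[!masks$mito] <- NA
            sm <- region_statistics(vm[!is.na(vm)])
          }
          if (is.null(sc)) {
            vm <- chan_maps[[ch]]; vm[!masks$cyto] <- NA
            sc <- region_statistics(vm[!is.na(vm)])
          }
          st <- registry$statistic[rr]
          mat[ci, registry$feature_id[rr]] <-
            compartmentalization(sm[st], sc[st])
        }
      }
    }
  }
  cbind(meta, as.data.frame(mat))
}

# crop a NA-masked matrix to its region bounding box (texture speed)
.crop_region <- function(vm) {
  idx <- which(!is.na(vm), arr.ind = TRUE)
  vm[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
}

#' Default representative MOB feature set
#'
#' A fixed, documented set of 11 representative features spanning the
#' categories the selection stage typically retains: cell size, mitochondrial
#' NAD(P)H level, corrected ORR, alpha_bound and tau_bound levels,
#' mitochondrial spatial variances, and the alpha_bound/tau_bound
#' compartmentalization.
#'
#' @return character vector of registry feature ids.
#' @export
mob_representatives_default <- function() {
  c("morph_size",
    "mito_NADPH_intensity_average",
    "cell_ORR_corrected",
    "mito_alpha_bound_average",
    "mito_tau_bound_average",
    "mito_NADPH_intensity_glcm_difference_variance",
    "mito_alpha_bound_glrlm_glv",
    "mito_tau_bound_glcm_contrast",
    "comp_alpha_bound_average",
    "comp_tau_bound_average",
    "cyto_NADPH_intensity_average")
}
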