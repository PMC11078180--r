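# File formats: TIFF decay stacks (one plane per time bin) and map images,
# CSV feature tables with a registry manifest, JSON configs. Each TIFF
# carries a JSON sidecar (same path + ".json") with the value encoding and
# acquisition metadata; vendor formats (.ptu/.lif) are not supported — the
# conversion contract is: export per-bin photon counts as a multi-plane TIFF
# plus the laser period in the sidecar.

.sidecar <- function(path) paste0(path, ".json")

# tiff stores [0,1] scaled integers; encode with an explicit range so
# integer photon counts round-trip exactly at 16 bits
.write_planes <- function(planes, path, meta, bits) {
  vals <- unlist(lapply(planes, range))
  lo <- min(vals); hi <- max(vals)
  if (bits == 16) {
    # integer data: k/65535 encoding stores each count verbatim
    lo <- 0; scale <- 65535
  } else {
    scale <- if (hi > lo) hi - lo else 1
  }
  enc <- lapply(planes, function(m) (m - lo) / scale)
  suppressWarnings(tiff::writeTIFF(enc, path, bits.per.sample = bits,
                                   reduce = FALSE))
  meta$encoding <- list(lo = lo, scale = scale, bits = bits)
  jsonlite::write_json(meta, .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_planes <- function(path) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  if (!file.exists(.sidecar(path)))
    stop("missing sidecar ", .sidecar(path), " (encoding metadata)")
  meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  enc <- meta$encoding
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(m) {
    if (enc$bits == 16) {
      m <- round(m * 65535) / 65535   # undo 16-bit quantization exactly
    }
    m * enc$scale + enc$lo
  })
  list(planes = planes, meta = meta)
}

#' Write / read a decay image as a multi-plane TIFF
#'
#' Planes are time bins. Integer photon counts up to 65535 round-trip
#' bit-exactly (16-bit storage); non-integer (noise-free expected) stacks
#' use 32-bit storage with ~1e-9 relative precision.
#'
#' @param decay a \code{decay_image}.
#' @param path output TIFF path (a \code{.json} sidecar is written next to
#'   it).
#' @return \code{read_decay_tiff} returns the restored \code{decay_image}.
#' @export
write_decay_tiff <- function(decay, path) {
  stopifnot(inherits(decay, "decay_image"))
  nb <- decay$n_time_bins
  planes <- lapply(seq_len(nb), function(t) decay$counts[, , t])
  int_ok <- max(decay$counts) <= 65535 &&
    all(decay$counts == round(decay$counts))
  .write_planes(planes, path,
                list(kind = "decay", channel = decay$channel,
                     laser_period_ns = decay$laser_period_ns,
                     n_time_bins = nb),
                bits = if (int_ok) 16L else 32L)
}

#' @rdname write_decay_tiff
#' @export
read_decay_tiff <- function(path) {
  r <- .read_planes(path)
  if (!identical(r$meta$kind, "decay"))
    stop(path, " is not a decay stack (kind = ", r$meta$kind, ")")
  nb <- length(r$planes)
  if (nb != r$meta$n_time_bins)
    stop("plane count ", nb, " does not match sidecar n_time_bins ",
         r$meta$n_time_bins)
  arr <- array(0, dim = c(dim(r$planes[[1]]), nb))
  for (t in seq_len(nb)) arr[, , t] <- r$planes[[t]]
  if (identical(r$meta$encoding$bits, 16L) ||
      identical(r$meta$encoding$bits, 16)) {
    arr <- round(arr)
    storage.mode(arr) <- "integer"   # photon counts are integers
  }
  decay_image(arr, r$meta$laser_period_ns, r$meta$channel)
}

#' Write / read named map images (g, s, alpha_bound, ...) as one TIFF
#'
#' @param maps named list of equally sized matrices.
#' @param path output TIFF path.
#' @return \code{read_maps_tiff} returns the named list of matrices.
#' @export
write_maps_tiff <- function(maps, path) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  dims <- vapply(maps, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1)
    stop("mismatched map shapes: ", paste(unique(dims), collapse = " vs "))
  clean <- lapply(maps, function(m) { m[!is.finite(m)] <- 0; m })
  nas <- lapply(maps, function(m) !is.finite(m))
  .write_planes(c(clean, lapply(nas, function(m) m * 1)), path,
                list(kind = "maps", names = names(maps)), bits = 32L)
}

#' @rdname write_maps_tiff
#' @export
read_maps_tiff <- function(path) {
  r <- .read_planes(path)
  if (!identical(r$meta$kind, "maps")) stop(path, " is not a maps TIFF")
  nm <- r$meta$names
  k <- length(nm)
  out <- r$planes[seq_len(k)]
  for (i in seq_len(k)) out[[i]][r$planes[[k + i]] > 0.5] <- NA_real_
  names(out) <- nm
  out
}

#' Write / read a feature table with its registry manifest
#'
#' The CSV is accompanied by a JSON manifest (same path + ".json") recording
#' the registry feature definitions and version; reading validates the CSV
#' header against the manifest and names any missing column.
#'
#' @param table feature data.frame.
#' @param path CSV path.
#' @param registry the registry the feature columns come from.
#' @return \code{read_feature_csv} returns the table (manifest in
#'   \code{attr(, "manifest")}).
#' @export
write_feature_csv <- function(table, path, registry = mob_registry()) {
  write.csv(table, path, row.names = FALSE)
  manifest <- list(registry_version = attr(registry, "version"),
                   features = registry$feature_id[
                     registry$feature_id %in% names(table)],
                   n_rows = nrow(table))
  jsonlite::write_json(manifest, .sidecar(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tb <- read.csv(path, check.names = FALSE)
  man_path <- .sidecar(path)
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    miss <- setdiff(man$features, names(tb))
    if (length(miss))
      stop("feature CSV is missing registry column(s): ",
           paste(miss, collapse = ", "))
    attr(tb, "manifest") <- man
  }
  tb
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default: the printed
#' method constants (tau_free 0.45 ns, F1 cut 0.6, TI cut 0.5, 3 latent
#' dimensions, photon threshold 2 counts) and the documented package
#' defaults (80 MHz first-harmonic phasor geometry, 3x3 median filter,
#' 16-level texture quantization, size window from 6-20 um diameters).
#' Serializes losslessly through JSON.
#'
#' @param ... overrides of the defaults.
#' @return a \code{mob_config} list.
#' @export
mob_config <- function(...) {
  cfg <- list(
    laser_period_ns = 12.5, harmonic = 1L, tau_free = 0.45,
    median_window = 3L, photon_threshold = 2,
    pixel_size_um = 0.18,
    min_size_px = size_window_px()[1], max_size_px = size_window_px()[2],
    erode_iter = 1L, texture_levels = 16L,
    f1_cut = 0.6, ti_cut = 0.5, node_fraction_cut = 0.5,
    n_latent = 3L, dbscan_min_samples = 5L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "mob_config")
}

#' @rdname mob_config
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mob_config
#' @export
read_config <- function(path) {
  do.call(mob_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
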