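# Data conditioning before the latent model: density-based outlier removal,
# per-condition trimming/shuffling, and robust quartile scaling.

#' Fit a robust scaler on a training reference
#'
#' Centers at the training median and divides by half the interquartile
#' range, so the training median maps to 0, the first quartile to -1 and the
#' third quartile to +1 exactly. Quartiles use the linear-interpolation
#' convention. The alternative full-IQR convention (quartiles to +/-0.5) is
#' available via \code{convention = "iqr"}.
#'
#' @param train numeric vector, or data.frame/matrix (per-column scalers).
#' @param convention "half_iqr" (default) or "iqr".
#' @return a \code{robust_scaler} with anchors (median, q1, q3) per feature.
#' @export
robust_scale <- function(train, convention = c("half_iqr", "iqr")) {
  convention <- match.arg(convention)
  tr <- as.data.frame(train)
  anchors <- lapply(tr, function(v) {
    v <- v[is.finite(v)]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    if (q[3] <= q[1]) stop("zero interquartile spread; feature rejected")
    list(median = q[2], q1 = q[1], q3 = q[3])
  })
  structure(list(anchors = anchors, convention = convention,
                 features = names(tr)),
            class = "robust_scaler")
}

#' Apply a fitted robust scaler
#'
#' @param object a \code{robust_scaler}.
#' @param newdata vector (single-feature scaler) or data.frame with the
#'   scaler's feature columns.
#' @param ... unused.
#' @return scaled values of the same shape.
#' @export
predict.robust_scaler <- function(object, newdata, ...) {
  tf <- function(v, a) {
    half <- (a$q3 - a$q1) / if (object$convention == "half_iqr") 2 else 1
    (v - a$median) / half
  }
  if (is.null(dim(newdata)) && length(object$anchors) == 1)
    return(tf(newdata, object$anchors[[1]]))
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(nd))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  for (f in object$features) nd[[f]] <- tf(nd[[f]], object$anchors[[f]])
  nd
}

#' @export
print.robust_scaler <- function(x, ...) {
  cat("robust_scaler (", x$convention, ") over", length(x$anchors),
      "feature(s)\n")
  invisible(x)
}

#' Shuffle and trim condition tables to equal size
#'
#' Randomizes row order within each condition (seeded) and downsamples every
#' condition without replacement to the smallest condition's n, removing
#' sample-size bias between conditions.
#'
#' @param tables named list of data.frames (one per condition).
#' @param seed RNG seed.
#' @return list of equally sized, shuffled data.frames.
#' @export
trim_and_shuffle <- function(tables, seed = 1L) {
  ns <- vapply(tables, nrow, integer(1))
  if (any(ns == 0)) stop("a condition has zero cells")
  n <- min(ns)
  set.seed(seed)
  lapply(tables, function(tb) tb[sample(nrow(tb), n), , drop = FALSE])
}

#' Density-based outlier removal (DBSCAN)
#'
#' Standardizes the given feature columns (median/MAD) and runs DBSCAN with
#' Euclidean distances; rows labelled noise (reachable from no core point)
#' are removed. When \code{eps} is NULL it is set by a k-distance heuristic:
#' three times the median distance to the \code{min_samples}-th nearest
#' neighbor, which keeps the bulk of a single cluster connected while
#' isolating far outliers.
#'
#' @param table data.frame of cells.
#' @param features feature columns to cluster on (default: all numeric).
#' @param eps neighborhood radius; NULL for the k-distance heuristic.
#' @param min_samples minimum neighborhood size for a core point, default 5.
#' @return list with \code{table} (inliers), \code{outliers} (row indices),
#'   \code{fraction_removed}, and the \code{eps} used.
#' @export
remove_outliers <- function(table, features = NULL, eps = NULL,
                            min_samples = 5L) {
  if (is.null(features))
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- as.matrix(table[, features, drop = FALSE])
  if (nrow(x) < min_samples) stop("fewer rows than min_samples")
  x <- apply(x, 2, function(v) {
    s <- mad(v); if (s == 0) s <- sd(v); if (s == 0) return(v * 0)
    (v - median(v)) / s
  })
  d <- as.matrix(dist(x))
  if (is.null(eps)) {
    kd <- apply(d, 1, function(r) sort(r)[min_samples + 1L])
    eps <- 3 * median(kd)
  }
  lab <- .dbscan_labels(d, eps, min_samples)
  out_idx <- which(lab == 0L)
  if (length(out_idx) == nrow(table))
    stop("all rows flagged as noise (eps = ", signif(eps, 3),
         "); adjust eps/min_samples")
  list(table = table[lab != 0L, , drop = FALSE], outliers = out_idx,
       fraction_removed = length(out_idx) / nrow(table), eps = eps)
}

# classic DBSCAN on a precomputed distance matrix; label 0 = noise
.dbscan_labels <- function(d, eps, min_samples) {
  n <- nrow(d)
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_samples
  lab <- rep(-1L, n)   # -1 unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != -1L || !core[i]) next
    cl <- cl + 1L
    lab[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (lab[j] == 0L) lab[j] <- cl          # border, previously noise
      if (lab[j] != -1L) next
      lab[j] <- cl
      if (core[j]) queue <- c(queue, setdiff(nbrs[[j]], j))
    }
  }
  lab[lab == -1L] <- 0L
  lab
}
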