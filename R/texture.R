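# Gray-level co-occurrence (GLCM) and run-length (GLRLM) texture statistics
# on masked regions, per standard radiomics definitions: min-max quantization
# to a fixed number of gray levels, distance-1 offsets in 4 directions,
# symmetrized and aggregated.

#' Quantize region values to discrete gray levels
#'
#' Min-max quantization to \code{n_levels} equal-width bins; values outside
#' the region (NA) stay NA.
#'
#' @param x numeric matrix with NA outside the region of interest.
#' @param n_levels number of gray levels, default 16.
#' @return integer matrix of levels in 1..n_levels (NA preserved).
#' @export
quantize_levels <- function(x, n_levels = 16L) {
  v <- x[!is.na(x)]
  if (!length(v)) stop("empty region")
  rng <- range(v)
  q <- x
  if (diff(rng) <= 0) {
    q[!is.na(q)] <- 1L
    return(q)
  }
  q <- floor((x - rng[1]) / diff(rng) * n_levels) + 1L
  q[q > n_levels] <- n_levels
  q
}

# the four distance-1 direction offsets (dr, dc): 0deg, 90deg, 45deg, 135deg
.tex_offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

#' Gray-level co-occurrence matrix of a masked region
#'
#' Counts level pairs at distance 1 along the four directions (both pixels
#' inside the region), symmetrized and normalized to a joint probability.
#'
#' @param q integer level matrix (NA outside region), e.g. from
#'   \code{\link{quantize_levels}}.
#' @param n_levels number of gray levels.
#' @return n_levels x n_levels probability matrix, or NULL when the region
#'   has no valid pixel pair.
#' @export
glcm_matrix <- function(q, n_levels = max(q, na.rm = TRUE)) {
  h <- nrow(q); w <- ncol(q)
  cm <- matrix(0, n_levels, n_levels)
  for (off in .tex_offsets) {
    dr <- off[1]; dc <- off[2]
    if (max(1, 1 - dr) > min(h, h - dr) ||
        max(1, 1 - dc) > min(w, w - dc)) next
    r1 <- max(1, 1 - dr):min(h, h - dr)
    c1 <- max(1, 1 - dc):min(w, w - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- cbind(a[ok], b[ok])
    for (k in seq_len(nrow(idx))) {
      cm[idx[k, 1], idx[k, 2]] <- cm[idx[k, 1], idx[k, 2]] + 1
      cm[idx[k, 2], idx[k, 1]] <- cm[idx[k, 2], idx[k, 1]] + 1
    }
  }
  tot <- sum(cm)
  if (tot == 0) return(NULL)
  cm / tot
}

#' Gray-level run-length matrix of a masked region
#'
#' Maximal runs of equal gray level along the four directions (region
#' boundaries break runs), aggregated into one matrix.
#'
#' @inheritParams glcm_matrix
#' @return n_levels x max_run_length count matrix.
#' @export
glrlm_matrix <- function(q, n_levels = max(q, na.rm = TRUE)) {
  h <- nrow(q); w <- ncol(q)
  runs_i <- integer(0); runs_l <- integer(0)
  collect <- function(v) {
    r <- rle(ifelse(is.na(v), 0L, v))
    keep <- r$values > 0L
    runs_i <<- c(runs_i, r$values[keep])
    runs_l <<- c(runs_l, r$lengths[keep])
  }
  for (i in seq_len(h)) collect(q[i, ])
  for (j in seq_len(w)) collect(q[, j])
  for (d in seq(-(h - 1L), w - 1L)) {           # diagonals (dr = dc = 1)
    i0 <- max(1L, 1L - d); j0 <- i0 + d
    n <- min(h - i0, w - j0) + 1L
    collect(q[cbind(i0 + 0:(n - 1L), j0 + 0:(n - 1L))])
  }
  for (d in seq(2L, h + w)) {                    # anti-diagonals (dr=1, dc=-1)
    i0 <- max(1L, d - w); j0 <- d - i0
    n <- min(h - i0, j0 - 1L) + 1L
    collect(q[cbind(i0 + 0:(n - 1L), j0 - 0:(n - 1L))])
  }
  if (!length(runs_l)) return(matrix(0, n_levels, 1))
  R <- matrix(0, n_levels, max(runs_l))
  for (k in seq_along(runs_l)) R[runs_i[k], runs_l[k]] <- R[runs_i[k], runs_l[k]] + 1
  R
}

#' Texture statistics of a masked region
#'
#' GLCM statistics (contrast, homogeneity, energy, entropy, correlation,
#' difference variance) and GLRLM statistics (short/long run emphasis,
#' gray-level and run-length nonuniformity, run percentage, gray level
#' variance) after quantization to \code{n_levels} gray levels.
#'
#' @param x numeric matrix with NA outside the region.
#' @param n_levels gray levels for quantization, default 16.
#' @param min_pixels minimum region size; smaller regions are degenerate.
#' @return named numeric vector (all NA when the region is too small). A
#'   constant region is a defined limit — zero contrast/difference variance,
#'   unit energy — except the GLCM correlation, which is undefined (NA).
#' @export
texture_features <- function(x, n_levels = 16L, min_pixels = 9L) {
  stats_names <- c("glcm_contrast", "glcm_homogeneity", "glcm_energy",
                   "glcm_entropy", "glcm_correlation", "glcm_difference_variance",
                   "glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln",
                   "glrlm_rp", "glrlm_glv")
  out <- setNames(rep(NA_real_, length(stats_names)), stats_names)
  np <- sum(!is.na(x))
  if (np < min_pixels) return(out)
  q <- quantize_levels(x, n_levels)
  P <- glcm_matrix(q, n_levels)
  if (!is.null(P)) {
    i <- matrix(seq_len(n_levels), n_levels, n_levels)
    j <- t(i)
    out["glcm_contrast"] <- sum(P * (i - j)^2)
    out["glcm_homogeneity"] <- sum(P / (1 + (i - j)^2))
    out["glcm_energy"] <- sum(P^2)
    nz <- P > 0
    out["glcm_entropy"] <- -sum(P[nz] * log2(P[nz]))
    px <- rowSums(P)
    mu <- sum(seq_len(n_levels) * px)
    sg2 <- sum((seq_len(n_levels) - mu)^2 * px)
    out["glcm_correlation"] <-
      if (sg2 > 0) (sum(i * j * P) - mu^2) / sg2 else NA_real_
    # difference distribution p_{|i-j|}
    k <- abs(i - j)
    pd <- vapply(0:(n_levels - 1L), function(d) sum(P[k == d]), numeric(1))
    mud <- sum((0:(n_levels - 1L)) * pd)
    out["glcm_difference_variance"] <- sum(((0:(n_levels - 1L)) - mud)^2 * pd)
  }

  R <- glrlm_matrix(q, n_levels)
  nr <- sum(R)
  if (nr > 0) {
    l <- matrix(seq_len(ncol(R)), n_levels, ncol(R), byrow = TRUE)
    out["glrlm_sre"] <- sum(R / l^2) / nr
    out["glrlm_lre"] <- sum(R * l^2) / nr
    out["glrlm_gln"] <- sum(rowSums(R)^2) / nr
    out["glrlm_rln"] <- sum(colSums(R)^2) / nr
    out["glrlm_rp"] <- nr / (4 * np)   # runs per pixel over the 4 directions
    pr <- R / nr
    gi <- matrix(seq_len(n_levels), n_levels, ncol(R))
    mug <- sum(pr * gi)
    out["glrlm_glv"] <- sum(pr * (gi - mug)^2)
  }
  out
}
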