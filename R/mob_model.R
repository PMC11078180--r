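# The latent-variable MOB score: a maximum-likelihood linear factor model
# over the robust-scaled representative features. The primary latent
# variable (LV1) is the MOB score of metabolic stemness; per-feature weights
# are the correlations between LV1 and each feature.

#' Fit the latent-variable MOB model
#'
#' Fits a 3-dimensional maximum-likelihood factor model to the scaled
#' representative features; LV1 (the first factor, largest shared variance)
#' is the MOB score. Because a factor's sign is arbitrary, LV1 is oriented
#' so the designated stemness anchor feature has a positive weight; the
#' default anchor is the mitochondrial tau_bound average, which is elevated
#' in stem cells.
#'
#' @param x data.frame/matrix of scaled representative features (rows =
#'   cells; needs at least \code{min_rows_per_feature} rows per feature).
#' @param n_latent latent dimensionality, default 3.
#' @param anchor feature (column) name anchoring the score's sign; defaults
#'   to \code{"mito_tau_bound_average"} when present, else the first column.
#' @param min_rows_per_feature row requirement multiplier, default 5.
#' @return a \code{mob_model}: per-feature standardization (center, scale),
#'   loadings, uniquenesses, LV1 weights (correlations), sign orientation,
#'   and the training scores.
#' @export
fit_mob_model <- function(x, n_latent = 3L, anchor = NULL,
                          min_rows_per_feature = 5L) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  p <- ncol(x); n <- nrow(x)
  if (n < min_rows_per_feature * p)
    stop("need at least ", min_rows_per_feature * p, " complete rows for ",
         p, " features (got ", n, ")")
  if (is.null(anchor))
    anchor <- if ("mito_tau_bound_average" %in% names(x))
      "mito_tau_bound_average" else names(x)[1]
  stopifnot(anchor %in% names(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) stop("constant feature(s): ",
                          paste(names(x)[scl == 0], collapse = ", "))
  xs <- scale(as.matrix(x), center = ctr, scale = scl)
  R <- cor(as.matrix(x))
  if (!all(is.finite(R)))
    stop("non-finite feature correlations; check inputs")
  fa <- .fa_em(R, n_latent)
  if (!fa$converged)
    warning("factor EM hit the iteration cap (", fa$n_iter,
            "); loadings may not be at the ML optimum (delta loglik ",
            signif(fa$delta, 3), ")")
  L <- fa$loadings
  dimnames(L) <- list(names(x), paste0("LV", seq_len(n_latent)))
  psi <- fa$uniquenesses
  model <- structure(list(features = names(x), center = ctr, scale = scl,
                          loadings = L, uniquenesses = psi,
                          n_latent = n_latent, anchor = anchor,
                          sign_orientation = 1, n_train = n),
                     class = "mob_model")
  lv1 <- .mob_lv_scores(model, xs)[, 1]
  w <- cor(lv1, as.matrix(x))[1, ]
  if (is.finite(w[anchor]) && w[anchor] < 0) {
    model$sign_orientation <- -1
    lv1 <- -lv1
    w <- -w
  }
  model$weights <- w
  model$train_scores <- as.numeric(lv1)
  model
}

# Maximum-likelihood factor analysis of a correlation matrix by EM.
# Monotone-likelihood, so it converges from the near-zero noise-variance
# initialization even where gradient optimizers fail on ill-conditioned
# panels. Loadings are initialized from the principal eigenvectors; factors
# are returned ordered by explained variance (column sum of squares).
.fa_em <- function(R, k, max_iter = 5000L, tol = 1e-7, psi_init = 1e-3) {
  p <- nrow(R)
  stopifnot(k >= 1, k < p)
  ei <- eigen(R, symmetric = TRUE)
  L <- ei$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ei$values[seq_len(k)], 1e-8)), k)
  psi <- pmax(rep(psi_init, p), 1e-6)
  ll_old <- -Inf
  delta <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Sigma <- L %*% t(L) + diag(psi)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) { psi <- psi + 1e-8; next }
    Sinv <- chol2inv(ch)
    ll <- -(sum(2 * log(diag(ch))) + sum(Sinv * R)) / 2
    delta <- abs(ll - ll_old)
    if (delta < tol) { converged <- TRUE; break }
    ll_old <- ll
    beta <- t(L) %*% Sinv                       # k x p
    M <- diag(k) - beta %*% L + beta %*% R %*% t(beta)
    C <- R %*% t(beta)                          # p x k
    L <- C %*% solve(M)
    psi <- pmax(diag(R - L %*% t(C)), 1e-6)
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  list(loadings = L[, ord, drop = FALSE], uniquenesses = psi,
       loglik = ll_old, n_iter = it, converged = converged, delta = delta)
}

# Thomson/regression factor scores from standardized data:
# F = Xs R^{-1} L  with R = LL' + Psi (the model-implied correlation)
.mob_lv_scores <- function(model, xs) {
  L <- model$loadings
  Rhat <- L %*% t(L) + diag(model$uniquenesses)
  xs %*% solve(Rhat, L)
}

#' Score cells with a fitted MOB model
#'
#' Deterministic linear scoring: rows are standardized with the training
#' center/scale and projected onto LV1 by the regression score formula.
#' Rows with any missing representative feature are flagged and returned as
#' NA rather than scored.
#'
#' @param model a \code{mob_model}.
#' @param x data.frame with the model's feature columns (on the same robust
#'   scale as the training data).
#' @return numeric MOB scores (NA for flagged rows).
#' @export
score_cells <- function(model, x) {
  stopifnot(inherits(model, "mob_model"))
  x <- as.data.frame(x)
  miss <- setdiff(model$features, names(x))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  xm <- as.matrix(x[, model$features, drop = FALSE])
  ok <- stats::complete.cases(xm)
  out <- rep(NA_real_, nrow(xm))
  if (any(ok)) {
    xs <- scale(xm[ok, , drop = FALSE], center = model$center,
                scale = model$scale)
    out[ok] <- model$sign_orientation * .mob_lv_scores(model, xs)[, 1]
  }
  out
}

#' @export
predict.mob_model <- function(object, newdata, ...) score_cells(object, newdata)

#' @export
coef.mob_model <- function(object, ...) object$weights

#' @export
print.mob_model <- function(x, ...) {
  cat("mob_model:", length(x$features), "features,", x$n_latent,
      "latent dims, fitted on", x$n_train, "cells\n")
  cat("  anchor:", x$anchor,
      if (x$sign_orientation < 0) "(LV1 sign flipped)\n" else "\n")
  invisible(x)
}

#' @export
summary.mob_model <- function(object, ...) {
  cat("MOB score model (LV1 of a", object$n_latent, "-factor ML model)\n")
  cat("Feature weights (correlation of LV1 with each scaled feature):\n")
  print(round(sort(object$weights, decreasing = TRUE), 3))
  invisible(object)
}

#' Stem/differentiated threshold on MOB scores
#'
#' Maximum-likelihood two-component Gaussian mixture on the scores; the
#' threshold is the equal-posterior point between the component means.
#' Scores above the threshold are metabolically stem-like.
#'
#' @param scores numeric MOB scores.
#' @param ... passed to \code{\link{fit_gauss2}}.
#' @return list with \code{threshold} (NA and \code{collapsed = TRUE} for
#'   unimodal data) and the mixture \code{fit}.
#' @export
stemness_threshold <- function(scores, ...) {
  fit <- fit_gauss2(scores, ...)
  list(threshold = fit$threshold, collapsed = fit$collapsed, fit = fit)
}

#' Serialize / restore a MOB model
#'
#' @param model a \code{mob_model}.
#' @param path JSON file path.
#' @return \code{read_mob_model} returns the restored \code{mob_model}.
#' @export
write_mob_model <- function(model, path) {
  stopifnot(inherits(model, "mob_model"))
  obj <- list(features = model$features, center = as.list(model$center),
              scale = as.list(model$scale),
              loadings = apply(model$loadings, 2, as.numeric, simplify = FALSE),
              uniquenesses = as.list(model$uniquenesses),
              n_latent = model$n_latent, anchor = model$anchor,
              sign_orientation = model$sign_orientation,
              weights = as.list(model$weights), n_train = model$n_train,
              registry_version = REGISTRY_VERSION)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mob_model
#' @export
read_mob_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$features)
  L <- matrix(unlist(obj$loadings), nrow = p)
  dimnames(L) <- list(obj$features, paste0("LV", seq_len(ncol(L))))
  structure(list(features = obj$features,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 loadings = L, uniquenesses = unlist(obj$uniquenesses),
                 n_latent = obj$n_latent, anchor = obj$anchor,
                 sign_orientation = obj$sign_orientation,
                 weights = unlist(obj$weights), n_train = obj$n_train),
            class = "mob_model")
}
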