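# Two-component univariate Gaussian mixture by EM, with the equal-posterior
# threshold between the component means. Shared by the delta-MOB division
# classifier and the stem/differentiated score threshold.

#' Fit a two-component Gaussian mixture to a 1-D sample
#'
#' Deterministic EM initialized at the sample's 25th/75th percentiles with a
#' common initial SD, run to convergence of the log-likelihood. Components
#' are returned ordered by mean. When the fitted means are separated by
#' fewer than \code{collapse_tol} pooled SDs (default 2, the usual
#' bimodality criterion; EM splits of genuinely unimodal samples stay below
#' it) the fit is flagged unimodal and no threshold is defined.
#'
#' @param x numeric sample (n >= 20 recommended).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param collapse_tol minimum |mu2 - mu1| in pooled-SD units.
#' @return a \code{gauss2_fit}: means, sds, weights, loglik, n_iter,
#'   \code{collapsed}, and \code{threshold} (NA when collapsed).
#' @export
fit_gauss2 <- function(x, max_iter = 500L, tol = 1e-8, collapse_tol = 2) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("too few observations for a two-component mixture")
  mu <- quantile(x, c(0.25, 0.75), names = FALSE)
  sg <- rep(max(sd(x) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sg <- sqrt(c(sum(r * (x - mu[1])^2) / n1,
                 sum((1 - r) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-6)
    w <- c(n1, n2) / n
  }
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  pooled <- sqrt(w[1] * sg[1]^2 + w[2] * sg[2]^2)
  collapsed <- (mu[2] - mu[1]) < collapse_tol * pooled
  thr <- if (collapsed) NA_real_ else
    .gauss2_threshold(mu, sg, w)
  structure(list(means = mu, sds = sg, weights = w, loglik = ll_old,
                 n_iter = it, collapsed = collapsed, threshold = thr),
            class = "gauss2_fit")
}

# equal-posterior (density-intersection) point between the two means;
# falls back to the midpoint when variances are (numerically) equal
.gauss2_threshold <- function(mu, sg, w) {
  if (abs(sg[1] - sg[2]) < 1e-9 * mean(sg)) {
    if (abs(w[1] - w[2]) < 1e-12) return(mean(mu))
    # equal variances, unequal weights: linear equation
    s2 <- mean(sg)^2
    return((mu[1] + mu[2]) / 2 + s2 * log(w[1] / w[2]) / (mu[2] - mu[1]))
  }
  # w1 N(x; mu1, s1) = w2 N(x; mu2, s2): quadratic a x^2 + b x + c = 0
  a <- 1 / sg[2]^2 - 1 / sg[1]^2
  b <- 2 * (mu[1] / sg[1]^2 - mu[2] / sg[2]^2)
  cc <- mu[2]^2 / sg[2]^2 - mu[1]^2 / sg[1]^2 +
    2 * log((w[1] * sg[2]) / (w[2] * sg[1]))
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(mean(mu))
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside)) inside[1] else mean(mu)
}

#' @export
print.gauss2_fit <- function(x, ...) {
  cat(sprintf(
    "gauss2_fit: mu = (%.3f, %.3f), sd = (%.3f, %.3f), w = (%.2f, %.2f)\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2]))
  if (x$collapsed) cat("  components collapsed; no threshold\n")
  else cat(sprintf("  threshold = %.4f (%d EM iterations)\n",
                   x$threshold, x$n_iter))
  invisible(x)
}
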