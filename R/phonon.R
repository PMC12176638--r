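#' Per-pixel phonon-microscopy map
#'
#' Rectangular raster of relative Brillouin frequency shift (dfb, GHz) and
#' acoustic attenuation (alpha, arbitrary units), the first data product of
#' time-resolved phonon microscopy after FFT / wavelet extraction.
#'
#' @param dfb,alpha numeric matrices of identical dimensions, finite.
#' @param truth optional matrix of latent component labels (1/2) for
#'   simulated maps.
#' @return object of class \code{phonon_map}.
#' @export
phonon_map <- function(dfb, alpha, truth = NULL) {
  if (!identical(dim(dfb), dim(alpha))) stopf("dfb and alpha grids differ in shape")
  if (any(!is.finite(dfb)) || any(!is.finite(alpha))) stopf("map values must be finite")
  structure(list(dfb = dfb, alpha = alpha, truth = truth), class = "phonon_map")
}

#' @export
print.phonon_map <- function(x, ...) {
  cat(sprintf("phonon_map: %d x %d pixels\n", nrow(x$dfb), ncol(x$dfb)))
  invisible(x)
}

#' Brillouin frequency shift from acoustic and optical parameters
#'
#' f_B = 2 n v / lambda_probe for normal optical incidence: the frequency
#' offset of probe light backscattered by a coherent acoustic phonon.
#'
#' @param n refractive index (dimensionless, > 0).
#' @param v sound velocity, m/s.
#' @param lambda_probe optical probing wavelength, m.
#' @return frequency shift in Hz.
#' @export
brillouin_shift <- function(n, v, lambda_probe) {
  if (n <= 0 || v <= 0 || lambda_probe <= 0) stopf("all parameters must be positive")
  2 * n * v / lambda_probe
}

#' Longitudinal elastic modulus
#'
#' M = rho v^2, the GHz-frequency elastic modulus probed by Brillouin
#' scattering (not comparable to a quasi-static Young's modulus).
#'
#' @param rho mass density, kg/m^3.
#' @param v sound velocity, m/s.
#' @return modulus in Pa.
#' @export
longitudinal_modulus <- function(rho, v) {
  if (rho <= 0 || v <= 0) stopf("all parameters must be positive")
  rho * v^2
}

mvn_logdens <- function(x, mean, cov) {
  ch <- chol(cov)
  z <- forwardsolve(t(ch), t(x) - mean)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Two-component Gaussian-mixture segmentation of a phonon map
#'
#' Fits a bivariate two-component Gaussian mixture to the per-pixel
#' (dfb, alpha) cloud by expectation-maximization, initialized by 2-means on
#' standardized coordinates. The log-likelihood is checked to be
#' non-decreasing at every iteration. The component with the higher mean
#' dfb is labelled "cell_wall" (the stiffer phase), the other "background";
#' components are returned in (background, cell_wall) order.
#'
#' @param map a \code{\link{phonon_map}} with >= 10 pixels.
#' @param seed seed for the k-means initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return object of class \code{gmm2}: weights, means (list of 2-vectors),
#'   covs (list of 2x2 matrices), responsibilities (pixels x 2), assignment
#'   (1 = background, 2 = cell_wall), loglik trace, component labels.
#' @export
fit_gmm2 <- function(map, seed = 1L, tol = 1e-8, max_iter = 500L) {
  x <- cbind(as.vector(map$dfb), as.vector(map$alpha))
  npx <- nrow(x)
  if (npx < 10) stopf("need >= 10 pixels to fit a mixture")
  if (any(apply(x, 2, sd) == 0)) stopf("degenerate map: a channel is constant")

  set.seed(seed)
  xs <- scale(x)
  km <- kmeans(xs, centers = 2, nstart = 10, iter.max = 100)
  ridge <- diag(1e-6 * apply(x, 2, var) + 1e-12, 2)

  w <- pmax(tabulate(km$cluster, 2) / npx, 1e-6); w <- w / sum(w)
  mu <- lapply(1:2, function(k) colMeans(x[km$cluster == k, , drop = FALSE]))
  S <- lapply(1:2, function(k) {
    xk <- x[km$cluster == k, , drop = FALSE]
    if (nrow(xk) < 3) return(stats::cov(x) + ridge)
    stats::cov(xk) + ridge
  })

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    ld <- vapply(1:2, function(k) log(w[k]) + mvn_logdens(x, mu[[k]], S[[k]]),
                 numeric(npx))
    m <- pmax(ld[, 1], ld[, 2])
    ll <- sum(m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m)))
    if (length(ll_trace) && ll < ll_prev - 1e-8 * abs(ll_prev))
      stopf("EM log-likelihood decreased (iteration %d): internal error", iter)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - m - log(exp(ld[, 1] - m) + exp(ld[, 2] - m)))
    converged <- is.finite(ll_prev) && abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1e-12)
    ll_prev <- ll
    if (converged) break
    nk <- colSums(resp)
    if (any(nk < 1e-8)) {  # a component collapsed to zero weight
      nk <- pmax(nk, 1e-8)
    }
    w <- nk / npx
    for (k in 1:2) {
      mu[[k]] <- colSums(resp[, k] * x) / nk[k]
      xc <- sweep(x, 2, mu[[k]])
      Sk <- crossprod(xc * resp[, k], xc) / nk[k] + ridge
      S[[k]] <- (Sk + t(Sk)) / 2
    }
  }

  ## order components so 1 = background (lower mean dfb), 2 = cell wall
  ord <- order(vapply(mu, `[`, numeric(1), 1))
  w <- w[ord]; mu <- mu[ord]; S <- S[ord]; resp <- resp[, ord, drop = FALSE]
  structure(list(weights = w, means = mu, covs = S,
                 responsibilities = resp,
                 assignment = max.col(resp, ties.method = "first"),
                 loglik = ll_prev, loglik_trace = ll_trace,
                 labels = c("background", "cell_wall"),
                 data = x, grid = dim(map$dfb)),
            class = "gmm2")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf("gmm2: weights %.3f/%.3f; background dfb %.3g, cell_wall dfb %.3g; loglik %.4g\n",
              x$weights[1], x$weights[2], x$means[[1]][1], x$means[[2]][1], x$loglik))
  invisible(x)
}

#' Confidence-region membership and trimmed component means
#'
#' A pixel belongs to a component's confidence region iff it is assigned to
#' that component by maximum responsibility AND its squared Mahalanobis
#' distance to the component mean is within the chi-squared (2 d.f.)
#' quantile at \code{level} — the "roughly 70 percent confidence" interval
#' used to summarize cell-wall vs background (dfb, alpha) values.
#'
#' @param gmm a fitted \code{\link{fit_gmm2}} object.
#' @param level confidence level in (0, 1\]; default 0.70.
#' @return list with logical masks and per-component means of dfb and alpha
#'   over region members (NA with a warning for an empty region).
#' @export
confidence_membership <- function(gmm, level = 0.70) {
  if (level <= 0 || level > 1) stopf("level must lie in (0, 1]")
  q <- qchisq(level, df = 2)
  x <- gmm$data
  masks <- lapply(1:2, function(k) {
    d2 <- mahalanobis(x, gmm$means[[k]], gmm$covs[[k]])
    gmm$assignment == k & d2 <= q
  })
  names(masks) <- gmm$labels
  means <- lapply(masks, function(m) {
    if (!any(m)) {
      warnf("empty confidence region; means undefined")
      return(c(dfb = NA_real_, alpha = NA_real_))
    }
    c(dfb = mean(x[m, 1]), alpha = mean(x[m, 2]))
  })
  list(masks = masks, means = means, level = level, chisq_quantile = q)
}

#' Yuen's trimmed-mean t-test
#'
#' Robust two-sample comparison of trimmed means with winsorized variances
#' and Welch–Satterthwaite degrees of freedom. With \code{trim = 0} it
#' reduces exactly to Welch's t-test.
#'
#' @param x,y numeric samples.
#' @param trim trim fraction in \[0, 0.5); default 0.2.
#' @param alternative "two.sided" (default), "less" or "greater" (refers to
#'   trimmed mean of x minus trimmed mean of y).
#' @return list with statistic, df, p.value, estimate (difference of
#'   trimmed means), trim and alternative.
#' @export
yuen_test <- function(x, y, trim = 0.2, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (trim < 0 || trim >= 0.5) stopf("trim must lie in [0, 0.5)")
  one <- function(v) {
    n <- length(v)
    g <- floor(trim * n)
    h <- n - 2 * g
    if (h < 2) stopf("over-trimming: fewer than 2 values retained")
    sv <- sort(v)
    win <- pmin(pmax(sv, sv[g + 1]), sv[n - g])
    list(tm = mean(sv[(g + 1):(n - g)]),
         d = var(win) * (n - 1) / (h * (h - 1)), h = h)
  }
  a <- one(x); b <- one(y)
  se <- sqrt(a$d + b$d)
  stat <- if (se == 0) 0 else (a$tm - b$tm) / se
  df <- if (se == 0) a$h + b$h - 2 else
    (a$d + b$d)^2 / (a$d^2 / (a$h - 1) + b$d^2 / (b$h - 1))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(stat), df),
              less = pt(stat, df),
              greater = pt(stat, df, lower.tail = FALSE))
  list(statistic = stat, df = df, p.value = p, estimate = a$tm - b$tm,
       trim = trim, alternative = alternative)
}
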