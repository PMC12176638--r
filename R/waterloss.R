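#' Cumulative radial water-loss series
#'
#' Gravimetric time series of an excised root segment drying in a
#' low-humidity chamber: cumulative water loss as a percentage of the
#' segment's total water content (fresh mass minus dry mass), plus the
#' geometry needed to convert mass-loss rates into area-normalized radial
#' flux over the lateral root surface.
#'
#' @param times minutes, strictly increasing.
#' @param cumulative_loss percent of total water content, same length.
#' @param root_length,root_diameter segment geometry in metres.
#' @param total_water grams of water in the fresh segment.
#' @param strict if TRUE enforce loss in \[0, 100\] exactly; measured (noisy)
#'   series may drift slightly outside and are clamped-checked loosely.
#' @return object of class \code{water_loss_series}.
#' @export
water_loss_series <- function(times, cumulative_loss, root_length = NA_real_,
                              root_diameter = NA_real_, total_water = NA_real_,
                              strict = TRUE) {
  if (length(times) != length(cumulative_loss)) stopf("times and loss differ in length")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  lo <- if (strict) 0 else -5
  hi <- if (strict) 100 else 105
  if (any(cumulative_loss < lo | cumulative_loss > hi))
    stopf("cumulative_loss must lie in [0, 100] percent")
  for (g in c("root_length", "root_diameter", "total_water")) {
    v <- get(g)
    if (!is.na(v) && v <= 0) stopf("%s must be positive", g)
  }
  structure(list(times = as.numeric(times), cumulative_loss = as.numeric(cumulative_loss),
                 root_length = root_length, root_diameter = root_diameter,
                 total_water = total_water),
            class = "water_loss_series")
}

check_decay_params <- function(p) {
  need <- c("plateau", "span_fast", "span_slow", "k_fast", "k_slow")
  miss <- setdiff(need, names(p))
  if (length(miss)) stopf("decay parameters missing: %s", paste(miss, collapse = ", "))
  if (p$plateau < 0 || p$span_fast < 0 || p$span_slow < 0)
    stopf("plateau and spans must be non-negative")
  if (p$k_fast <= 0 || p$k_slow < 0) stopf("rate constants must be positive")
  if (p$k_slow > p$k_fast) stopf("k_fast must be >= k_slow")
  invisible(p)
}

## remaining water W(t) = plateau + span_fast e^(-k_fast t) + span_slow e^(-k_slow t)
two_phase_remaining <- function(t, p) {
  p$plateau + p$span_fast * exp(-p$k_fast * t) + p$span_slow * exp(-p$k_slow * t)
}

#' Two-phase decay fit object
#'
#' @param plateau,span_fast,span_slow,k_fast,k_slow model parameters of the
#'   remaining-water curve W(t) = plateau + span_fast e^(-k_fast t) +
#'   span_slow e^(-k_slow t); rates per minute, amplitudes in percent.
#' @param rss residual sum of squares of the fit.
#' @param converged logical convergence flag.
#' @return object of class \code{decay_fit}.
#' @export
decay_fit <- function(plateau, span_fast, span_slow, k_fast, k_slow,
                      rss = NA_real_, converged = NA) {
  p <- list(plateau = plateau, span_fast = span_fast, span_slow = span_slow,
            k_fast = k_fast, k_slow = k_slow, rss = rss, converged = converged)
  check_decay_params(p)
  structure(p, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(paste0("two-phase decay: plateau %.3f + %.3f exp(-%.4g t) + ",
                     "%.3f exp(-%.4g t)  [rss %.4g]\n"),
              x$plateau, x$span_fast, x$k_fast, x$span_slow, x$k_slow, x$rss))
  invisible(x)
}

#' Fit the two-phase exponential decay to a water-loss series
#'
#' Constrained nonlinear least squares on remaining water
#' (100 - cumulative loss): W(t) = plateau + span_fast e^(-k_fast t) +
#' span_slow e^(-k_slow t), all amplitudes non-negative and the rate
#' ordering k_fast > k_slow enforced by construction. Multistart from a grid
#' of rate guesses (3 fast-rate scalings x 3 slow/fast ratios around a crude
#' single-exponential estimate); the lowest-RSS converged start wins.
#' Deterministic for a fixed series.
#'
#' @param series a \code{\link{water_loss_series}} with >= 6 points.
#' @return a \code{\link{decay_fit}}.
#' @export
fit_two_phase_decay <- function(series) {
  t <- series$times
  y <- 100 - series$cumulative_loss  # remaining water, percent
  if (length(t) < 6) stopf("need >= 6 points to fit 5 parameters")

  ## crude initial rate: time at which half the observed loss has occurred
  total_drop <- max(y[1] - min(y), 1e-6)
  half_t <- t[which(y <= y[1] - total_drop / 2)[1]]
  if (is.na(half_t) || half_t <= 0) half_t <- max(t) / 4
  k0 <- log(2) / half_t

  plateau0 <- max(min(y), 0)
  span0 <- max(y[1] - plateau0, 1e-3)
  rss_of <- function(p) sum((y - (p[1] + p[2] * exp(-p[4] * t) + p[3] * exp(-p[5] * t)))^2)
  best <- NULL
  for (kf in k0 * c(1, 3, 10)) for (ratio in c(0.02, 0.1, 0.3)) {
    start <- c(plateau = plateau0, span_fast = 0.6 * span0, span_slow = 0.4 * span0,
               k_fast = kf, k_slow = kf * ratio)
    fit <- tryCatch(suppressWarnings(
      nls(y ~ plateau + span_fast * exp(-k_fast * t) + span_slow * exp(-k_slow * t),
          start = as.list(start), algorithm = "port",
          lower = c(0, 0, 0, 1e-8, 1e-10),
          control = list(maxiter = 500, warnOnly = TRUE))),
      error = function(e) NULL)
    cf <- if (!is.null(fit)) coef(fit) else {
      ## gradient-free fallback when the least-squares solver errors outright
      op <- tryCatch(optim(start, rss_of, method = "L-BFGS-B",
                           lower = c(0, 0, 0, 1e-8, 1e-10),
                           control = list(maxit = 2000)),
                     error = function(e) NULL)
      if (is.null(op)) next
      op$par
    }
    rss <- rss_of(unname(cf[c("plateau", "span_fast", "span_slow", "k_fast", "k_slow")]))
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(coef = cf, rss = rss)
  }
  if (is.null(best)) stopf("two-phase decay fit failed to converge from all starts")
  cf <- as.list(best$coef)
  if (cf$k_fast < cf$k_slow) {  # enforce ordering by swapping phases
    cf[c("span_fast", "span_slow")] <- cf[c("span_slow", "span_fast")]
    cf[c("k_fast", "k_slow")] <- cf[c("k_slow", "k_fast")]
  }
  decay_fit(plateau = cf$plateau, span_fast = cf$span_fast, span_slow = cf$span_slow,
            k_fast = cf$k_fast, k_slow = max(cf$k_slow, 1e-10), rss = best$rss,
            converged = TRUE)
}

#' Time at which half of the water is lost
#'
#' Solves W(t) = W(0)/2 on the fitted, strictly decreasing two-phase model
#' by bisection (tolerance in minutes). The model must asymptotically lose
#' at least half of its initial water (plateau < W(0)/2).
#'
#' @param fit a \code{\link{decay_fit}}.
#' @param tol bisection tolerance in minutes.
#' @return t50 in minutes.
#' @export
time_to_half_loss <- function(fit, tol = 1e-6) {
  w0 <- fit$plateau + fit$span_fast + fit$span_slow
  target <- w0 / 2
  if (fit$plateau >= target)
    stopf("model never reaches 50%% loss (plateau %.3f >= W(0)/2 = %.3f)", fit$plateau, target)
  hi <- 1
  while (two_phase_remaining(hi, fit) > target) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (two_phase_remaining(mid, fit) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Half-loss time by linear interpolation of the raw series
#'
#' Flagged alternative to the model-based \code{\link{time_to_half_loss}}:
#' linear interpolation of the measured cumulative-loss curve at 50%.
#'
#' @param series a \code{\link{water_loss_series}}.
#' @return t50 in minutes.
#' @export
t50_interpolate <- function(series) {
  loss <- series$cumulative_loss
  i <- which(loss >= 50)[1]
  if (is.na(i)) stopf("series never reaches 50%% loss")
  if (i == 1) return(series$times[1])
  t0 <- series$times[i - 1]; t1 <- series$times[i]
  l0 <- loss[i - 1]; l1 <- loss[i]
  t0 + (50 - l0) / (l1 - l0) * (t1 - t0)
}

#' Area-normalized radial water flux
#'
#' Converts a gravimetric mass-loss rate into a molar flux over the lateral
#' root surface (a cylinder of the measured length and diameter):
#' flux = (rate / 18.015 g mol^-1 x 10^6 umol mol^-1) / (pi d L).
#'
#' @param mass_loss_rate grams of water per second.
#' @param length,diameter root segment geometry in metres.
#' @return flux in umol m^-2 s^-1.
#' @export
radial_flux <- function(mass_loss_rate, length, diameter) {
  if (length <= 0 || diameter <= 0) stopf("length and diameter must be positive")
  molar_mass_water <- 18.015  # g / mol
  area <- pi * diameter * length
  (mass_loss_rate / molar_mass_water * 1e6) / area
}
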