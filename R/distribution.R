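#' Parenchymal attenuation distribution
#'
#' Two-component mixture model for the attenuation histogram of aerated lung
#' parenchyma: a Gaussian bulk of aerated tissue plus a rightward
#' shifted-exponential tail of denser voxels (vessels, airway walls,
#' juxta-mediastinal parenchyma). The tail starts at the bulk mean and decays
#' with scale `tail_scale` toward higher HU:
#' \deqn{f(x) = (1-w)\,\phi\!\left(\frac{x-\mu}{\sigma}\right)/\sigma +
#'       \frac{w}{s} e^{-(x-\mu)/s}\,[x \ge \mu]}
#'
#' The mixture reproduces the empirical asymmetry of pediatric inspiratory
#' lung histograms, where the mass below (mean - 1 SD) is far smaller than
#' the 15.87% a Gaussian would give while the mass above (mean + 1 SD) stays
#' near it: the dense tail inflates the overall SD, pushing the low threshold
#' deep below the narrow aerated bulk.
#'
#' @param bulk_mean Gaussian bulk mean (HU).
#' @param bulk_sd Gaussian bulk SD (HU), > 0.
#' @param tail_weight mixture weight of the dense tail, in \[0, 0.5\].
#' @param tail_scale exponential tail scale (HU), > 0.
#'
#' @return Object of class `parenchyma_distribution` with the four parameters
#'   plus `achieved_mean`, `achieved_sd`, `achieved_frac_low`,
#'   `achieved_frac_high` — the analytic moments and one-SD tail fractions of
#'   the mixture.
#' @seealso [calibrate_distribution()], [sample_parenchyma()]
#' @export
parenchyma_distribution <- function(bulk_mean, bulk_sd, tail_weight,
                                    tail_scale) {
  if (bulk_sd <= 0) stop_pedct("bulk_sd must be > 0", "pedct_bad_distribution")
  if (tail_weight < 0 || tail_weight > 0.5)
    stop_pedct("tail_weight must lie in [0, 0.5]", "pedct_bad_distribution")
  if (tail_scale <= 0)
    stop_pedct("tail_scale must be > 0", "pedct_bad_distribution")
  st <- mixture_moments(bulk_mean, bulk_sd, tail_weight, tail_scale)
  fr <- mixture_tail_fractions(bulk_mean, bulk_sd, tail_weight, tail_scale)
  structure(list(bulk_mean = bulk_mean, bulk_sd = bulk_sd,
                 tail_weight = tail_weight, tail_scale = tail_scale,
                 achieved_mean = st$mean, achieved_sd = st$sd,
                 achieved_frac_low = fr[["low"]],
                 achieved_frac_high = fr[["high"]]),
            class = "parenchyma_distribution")
}

#' @export
print.parenchyma_distribution <- function(x, ...) {
  cat(sprintf(paste0(
    "<parenchyma_distribution> bulk N(%.1f, %.1f^2) + %.3f * Exp(scale %.1f)\n",
    "  mean %.1f HU, sd %.1f HU, frac<mean-1SD %.4f, frac>mean+1SD %.4f\n"),
    x$bulk_mean, x$bulk_sd, x$tail_weight, x$tail_scale,
    x$achieved_mean, x$achieved_sd, x$achieved_frac_low, x$achieved_frac_high))
  invisible(x)
}

# Closed-form mean and SD of the mixture. The tail component has mean
# mu + s and variance s^2, so
#   E[X]  = mu + w s
#   Var X = (1-w) sigma^2 + w s^2 (2 - w)
mixture_moments <- function(mu, sigma, w, s) {
  list(mean = mu + w * s,
       sd = sqrt((1 - w) * sigma^2 + w * s^2 * (2 - w)))
}

# P(X < mean - SD) and P(X > mean + SD) for the mixture's own mean/SD.
mixture_tail_fractions <- function(mu, sigma, w, s) {
  st <- mixture_moments(mu, sigma, w, s)
  lo <- st$mean - st$sd
  hi <- st$mean + st$sd
  p_low <- (1 - w) * pnorm((lo - mu) / sigma) +
    w * (if (lo > mu) 1 - exp(-(lo - mu) / s) else 0)
  p_high <- (1 - w) * pnorm((hi - mu) / sigma, lower.tail = FALSE) +
    w * (if (hi > mu) exp(-(hi - mu) / s) else 1)
  c(low = p_low, high = p_high)
}

#' Calibrate the parenchymal mixture to target histogram statistics
#'
#' Finds mixture parameters whose analytic mean, SD and one-SD tail fractions
#' match the requested targets. Given tail weight `w` and tail scale `s`, the
#' bulk parameters are determined exactly by moment matching:
#' \eqn{\mu = m - ws}, \eqn{\sigma^2 = (V - w s^2 (2-w)) / (1-w)}; the
#' remaining two tail-fraction equations are solved for `(w, s)` by
#' deterministic Nelder-Mead minimisation of the squared residuals from
#' several fixed starting points (no sampling involved).
#'
#' @param target_mean,target_sd target mixture mean and SD (HU), `target_sd > 0`.
#' @param target_frac_low,target_frac_high target fractions below
#'   (mean - 1 SD) and above (mean + 1 SD);
#'   `0 < target_frac_low <= target_frac_high < 0.5`.
#' @param tol_frac maximum absolute deviation of the achieved tail fractions
#'   from their targets (default 0.003, i.e. 0.3 percentage points).
#'
#' @return A [parenchyma_distribution()] whose `achieved_*` fields match the
#'   targets: mean/SD to numerical precision (moment matching is exact) and
#'   fractions within `tol_frac`.
#' @export
#' @examples
#' d <- calibrate_distribution(-803, 147.3, 0.0053, 0.1020)
#' c(d$achieved_mean, d$achieved_sd)
calibrate_distribution <- function(target_mean, target_sd,
                                   target_frac_low, target_frac_high,
                                   tol_frac = 0.003) {
  if (target_sd <= 0) stop_pedct("target_sd must be > 0", "pedct_calibration")
  if (!(target_frac_low > 0 && target_frac_low <= target_frac_high &&
        target_frac_high < 0.5))
    stop_pedct("need 0 < target_frac_low <= target_frac_high < 0.5",
               "pedct_calibration")
  V <- target_sd^2

  unpack <- function(p) {
    w <- 0.5 / (1 + exp(-p[1]))             # w in (0, 0.5)
    s <- exp(p[2])
    c(w = w, s = s)
  }
  bulk_for <- function(w, s) {
    v_bulk <- (V - w * s^2 * (2 - w)) / (1 - w)
    if (v_bulk <= 0) return(NULL)           # tail alone exceeds target variance
    list(mu = target_mean - w * s, sigma = sqrt(v_bulk))
  }
  objective <- function(p) {
    q <- unpack(p)
    b <- bulk_for(q[["w"]], q[["s"]])
    if (is.null(b)) return(1e8 * (1 + abs(p[2])))
    fr <- mixture_tail_fractions(b$mu, b$sigma, q[["w"]], q[["s"]])
    sum(((fr - c(target_frac_low, target_frac_high)) / 1e-3)^2)
  }

  starts <- list(c(-1, log(target_sd)), c(-2, log(1.5 * target_sd)),
                 c(0, log(0.5 * target_sd)), c(-1.5, log(2 * target_sd)),
                 c(-6, log(0.1 * target_sd)))
  best <- NULL
  for (p0 in starts) {
    fit <- optim(p0, objective, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  q <- unpack(best$par)
  b <- bulk_for(q[["w"]], q[["s"]])
  if (is.null(b))
    stop_pedct("calibration infeasible: target SD too small for tail",
               "pedct_calibration")
  fr <- mixture_tail_fractions(b$mu, b$sigma, q[["w"]], q[["s"]])
  err <- abs(fr - c(target_frac_low, target_frac_high))
  if (any(err > tol_frac)) {
    which_bad <- if (err[1] > err[2]) "target_frac_low" else "target_frac_high"
    stop_pedct(sprintf(
      "calibration did not converge: %s missed by %.4f (tolerance %.4f)",
      which_bad, max(err), tol_frac), "pedct_calibration")
  }
  parenchyma_distribution(b$mu, b$sigma, q[["w"]], q[["s"]])
}

#' Sample voxel attenuation values from a parenchymal distribution
#'
#' Draws `n` independent HU values from the mixture and rounds them to
#' integer HU (half away from zero), the form in which a CT volume stores
#' them.
#'
#' @param dist a [parenchyma_distribution()].
#' @param n number of voxels.
#' @param seed integer seed; sampling never touches the global RNG state.
#' @return integer vector of length `n`, clamped to \[-1024, 3071\].
#' @export
sample_parenchyma <- function(dist, n, seed) {
  stopifnot(inherits(dist, "parenchyma_distribution"))
  withr::with_seed(as.integer(seed), {
    from_tail <- runif(n) < dist$tail_weight
    x <- numeric(n)
    n_tail <- sum(from_tail)
    x[!from_tail] <- rnorm(n - n_tail, dist$bulk_mean, dist$bulk_sd)
    if (n_tail > 0)
      x[from_tail] <- dist$bulk_mean + rexp(n_tail, rate = 1 / dist$tail_scale)
    as.integer(pmin(3071, pmax(-1024, round_half_away(x))))
  })
}
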