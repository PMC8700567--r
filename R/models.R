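#' Reference equation
#'
#' A fitted or stored regression of one densitometry metric on one predictor.
#' Two forms are supported, matching how pediatric CT reference values behave:
#' `linear` (`y = a + b x`, e.g. CT lung volume rising with age) and
#' `inverse` (`y = a + b / x`, a hyperbola, e.g. mean lung attenuation and
#' both attenuation thresholds falling with age toward an asymptote `a`).
#'
#' @param form `"linear"` or `"inverse"`.
#' @param a intercept, in response units. For the inverse form this is the
#'   large-`x` asymptote.
#' @param b coefficient: response units per predictor unit (linear), or
#'   response units times predictor units (inverse).
#' @param response,predictor metric names (e.g. `"mean_hu"`, `"age_years"`).
#' @param r_squared coefficient of determination on the response scale.
#' @param n number of observations behind the fit.
#' @param se_a,se_b standard errors of the coefficients (NA for stored
#'   equations, filled in by the fitting functions).
#' @return Object of class `reference_equation`.
#' @export
reference_equation <- function(form, a, b, response = NA_character_,
                               predictor = NA_character_,
                               r_squared = NA_real_, n = NA_integer_,
                               se_a = NA_real_, se_b = NA_real_) {
  form <- match.arg(form, c("linear", "inverse"))
  structure(list(form = form, a = as.numeric(a), b = as.numeric(b),
                 response = response, predictor = predictor,
                 r_squared = as.numeric(r_squared), n = as.integer(n),
                 se_a = as.numeric(se_a), se_b = as.numeric(se_b)),
            class = "reference_equation")
}

#' @export
print.reference_equation <- function(x, ...) {
  rhs <- if (x$form == "linear")
    sprintf("%.6g + (%.6g * %s)", x$a, x$b, x$predictor)
  else
    sprintf("%.6g + (%.6g / %s)", x$a, x$b, x$predictor)
  cat(sprintf("<reference_equation> %s = %s", x$response %||% "y", rhs))
  if (!is.na(x$r_squared)) cat(sprintf("  (r^2 = %.2f, n = %d)",
                                       x$r_squared, x$n))
  cat("\n")
  invisible(x)
}

#' Fit a linear reference model by ordinary least squares
#'
#' @param x predictor values (length >= 3, not constant).
#' @param y response values, same length.
#' @param response,predictor metric names recorded on the result.
#' @return A [reference_equation()] with `form = "linear"`; `r_squared` is
#'   computed on the response scale (`1 - SS_res / SS_tot`, defined as 0 when
#'   the response is constant).
#' @export
fit_linear <- function(x, y, response = NA_character_,
                       predictor = NA_character_) {
  check_fit_input(x, y)
  if (diff(range(x)) == 0)
    stop_pedct("degenerate fit: predictor is constant", "pedct_degenerate_fit")
  fit <- lm(y ~ x)
  se <- coef_standard_errors(cbind(1, x), residuals(fit))
  reference_equation("linear", coef(fit)[[1]], coef(fit)[[2]],
                     response, predictor,
                     r_squared_of(y, fitted(fit)), length(x),
                     se_a = se[[1]], se_b = se[[2]])
}

#' Fit an inverse (hyperbola) reference model
#'
#' Fits `y = a + b / x` by ordinary least squares on the transformed
#' predictor `1/x`; for this model family the transformed-predictor OLS
#' solution is the least-squares hyperbola, and `r_squared` on the original
#' response scale coincides with the transformed-scale value.
#'
#' @inheritParams fit_linear
#' @return A [reference_equation()] with `form = "inverse"`.
#' @export
fit_inverse <- function(x, y, response = NA_character_,
                        predictor = NA_character_) {
  check_fit_input(x, y)
  if (any(x <= 0))
    stop_pedct("inverse fit requires all predictor values > 0",
               "pedct_bad_predictor")
  inv <- 1 / x
  if (diff(range(inv)) == 0)
    stop_pedct("degenerate fit: 1/x is constant", "pedct_degenerate_fit")
  fit <- lm(y ~ inv)
  se <- coef_standard_errors(cbind(1, inv), residuals(fit))
  reference_equation("inverse", coef(fit)[[1]], coef(fit)[[2]],
                     response, predictor,
                     r_squared_of(y, fitted(fit)), length(x),
                     se_a = se[[1]], se_b = se[[2]])
}

# OLS coefficient SEs computed directly (sigma^2 (X'X)^-1); unlike
# summary.lm this stays silent on perfect fits, where the SEs are simply 0.
coef_standard_errors <- function(X, resid) {
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  sqrt(pmax(0, diag(chol2inv(chol(crossprod(X)))) * s2))
}

check_fit_input <- function(x, y) {
  if (length(x) != length(y))
    stop_pedct("x and y lengths differ", "pedct_bad_fit_input")
  if (length(x) < 3)
    stop_pedct("need at least 3 observations", "pedct_bad_fit_input")
  if (anyNA(x) || anyNA(y))
    stop_pedct("NA values in fit input", "pedct_bad_fit_input")
  invisible(TRUE)
}

r_squared_of <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Predict from a reference equation
#'
#' @param object a [reference_equation()].
#' @param x predictor value(s); must be > 0 for the inverse form.
#' @param ... unused.
#' @return Predicted response value(s), unrounded. Use [predict_rounded()]
#'   for presentation values.
#' @export
predict.reference_equation <- function(object, x, ...) {
  if (object$form == "inverse") {
    if (any(x <= 0))
      stop_pedct("inverse-form prediction requires x > 0",
                 "pedct_bad_predictor")
    object$a + object$b / x
  } else {
    object$a + object$b * x
  }
}

#' Presentation rounding for predicted values
#'
#' Rounds a prediction to the nearest multiple of `nearest` (half away from
#' zero), e.g. integer HU for attenuation values or tens of HU for threshold
#' summaries.
#'
#' @param eq a [reference_equation()].
#' @param x predictor value(s).
#' @param nearest rounding grain in response units (default 1).
#' @return Rounded predicted value(s).
#' @export
#' @examples
#' eqs <- reference_set()
#' predict_rounded(eqs[["mean_hu~age_years"]], 6)   # -699 HU
predict_rounded <- function(eq, x, nearest = 1) {
  round_to(predict(eq, x), nearest)
}

#' Built-in pediatric reference equation set
#'
#' The package's stored reference equations mapping age (years) or CT lung
#' volume (mL) to densitometry metrics in children aged 6-17: CT total lung
#' capacity (linear in age), mean lung attenuation, low/high attenuation
#' thresholds and percent high-attenuation volume (inverse in age), and
#' percent low/high-attenuation volume (inverse in TLC_CT). Shipped as a
#' versioned JSON resource.
#'
#' @param path JSON file to load; defaults to the installed resource.
#' @return Named list of [reference_equation()] objects keyed by
#'   `"response~predictor"`, with the resource `version`, `source` and the
#'   stored rank `correlations` attached as attributes.
#' @export
#' @examples
#' names(reference_set())
reference_set <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_equations.json",
                                package = "pedlungct", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  eqs <- lapply(seq_len(nrow(raw$equations)), function(i) {
    e <- raw$equations[i, ]
    reference_equation(e$form, e$a, e$b, e$response, e$predictor,
                       e$r_squared, e$n)
  })
  names(eqs) <- raw$equations$key
  attr(eqs, "version") <- raw$version
  attr(eqs, "source") <- raw$source
  attr(eqs, "correlations") <- raw$correlations
  eqs
}

#' Spearman rank correlation with large-sample p-value
#'
#' Ranks with average ties, computes the Pearson correlation of the ranks,
#' and derives a two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees of freedom
#' (p = 0 when `|rho| = 1`).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Object of class `correlation_result` with fields `rho`, `n`,
#'   `p_value`.
#' @export
#' @examples
#' spearman_cor(1:10, (1:10)^3)$rho   # 1: rank correlation ignores curvature
spearman_cor <- function(x, y) {
  check_fit_input(x, y)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop_pedct("correlation undefined: constant input", "pedct_degenerate_fit")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  structure(list(rho = rho, n = n, p_value = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.3f (n = %d, p = %.3g)\n",
              x$rho, x$n, x$p_value))
  invisible(x)
}
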