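# Quadratic bias calibration.
#
# Control mixtures with known (flow-cytometry-determined) allele ratios let
# systematic bias of the sequencing-based estimate be modelled as
# observed = a*expected^2 + b*expected + c, fit per locus by least squares.
# Simple SNPs and small in-dels show almost no bias (a ~ 0, b ~ 1, c ~ 0);
# larger deletions can deviate and benefit from correction.  Correction
# inverts the fitted map, which requires it to be monotone non-decreasing
# on [0, 1].

#' Fit a quadratic calibration model
#'
#' Unconstrained degree-2 least squares of observed on expected frequency.
#' Monotonicity of the fitted curve on `[0, 1]` (derivative `2ax + b >= 0`
#' at both endpoints) is checked; a violating fit is kept but flagged with a
#' warning, and cannot be inverted.
#'
#' @param expected Numeric vector of expected (control) frequencies in
#'   `[0, 1]`; at least 3 distinct values.
#' @param observed Numeric vector of observed (sequencing-derived)
#'   frequencies, same length.
#' @param locus Optional locus name attached to the model.
#' @param constrain_endpoints If `TRUE`, the fit is constrained through
#'   (0,0) and (1,1), leaving curvature as the single free parameter.
#' @return An object of class `freq_calibration` with `coefficients`
#'   (named `a`, `b`, `c`), `locus`, `monotone`, `rmse`, `fitted`,
#'   `residuals` and `data`.
#' @examples
#' x <- seq(0, 1, 0.1)
#' fit_calibration(x, 0.2 * x^2 + 0.8 * x)$coefficients
#' @export
fit_calibration <- function(expected, observed, locus = NULL,
                            constrain_endpoints = FALSE) {
  stopifnot(is.numeric(expected), is.numeric(observed),
            length(expected) == length(observed))
  if (length(unique(expected)) < 3L) {
    stop("need >= 3 distinct expected values for a quadratic fit",
         call. = FALSE)
  }
  if (any(expected < 0 | expected > 1 | observed < 0 | observed > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (constrain_endpoints) {
    # observed = a x^2 + (1 - a) x  <=>  observed - x = a (x^2 - x)
    z <- expected^2 - expected
    a <- sum((observed - expected) * z) / sum(z^2)
    co <- c(a = a, b = 1 - a, c = 0)
    fitted <- co["a"] * expected^2 + co["b"] * expected
    fit <- NULL
  } else {
    fit <- lm(observed ~ expected + I(expected^2))
    co <- c(a = unname(coef(fit)[3]), b = unname(coef(fit)[2]),
            c = unname(coef(fit)[1]))
    fitted <- unname(predict(fit))
  }
  res <- observed - fitted
  monotone <- co["b"] >= -1e-9 && 2 * co["a"] + co["b"] >= -1e-9
  if (!monotone) {
    warning("fitted calibration is not monotone on [0, 1]; it cannot be ",
            "inverted - refit (consider constrain_endpoints = TRUE)",
            call. = FALSE)
  }
  structure(list(
    coefficients = co,
    locus = locus,
    monotone = unname(monotone),
    rmse = sqrt(mean(res^2)),
    fitted = fitted,
    residuals = res,
    data = data.frame(expected = expected, observed = observed),
    lm = fit
  ), class = "freq_calibration")
}

#' @export
print.freq_calibration <- function(x, digits = 4, ...) {
  cat("Quadratic calibration",
      if (!is.null(x$locus)) paste0("for locus ", x$locus), "\n")
  cat("  observed =", signif(x$coefficients["a"], digits), "* expected^2 +",
      signif(x$coefficients["b"], digits), "* expected +",
      signif(x$coefficients["c"], digits), "\n")
  cat("  n =", nrow(x$data), " residual RMS =", signif(x$rmse, digits),
      " monotone on [0,1]:", x$monotone, "\n")
  invisible(x)
}

#' @export
coef.freq_calibration <- function(object, ...) object$coefficients

#' @export
residuals.freq_calibration <- function(object, ...) object$residuals

#' @export
#' @rdname fit_calibration
#' @param object,newdata For the `predict` method: the model and the
#'   expected frequencies at which to evaluate the forward (bias) map.
#' @param ... Unused.
predict.freq_calibration <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$expected
       else if (is.data.frame(newdata)) newdata$expected
       else newdata
  co <- object$coefficients
  unname(co["a"] * x^2 + co["b"] * x + co["c"])
}

#' @export
plot.freq_calibration <- function(x, ...) {
  plot(x$data$expected, x$data$observed, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "expected frequency", ylab = "observed frequency",
       main = if (is.null(x$locus)) "Calibration" else
         paste("Calibration:", x$locus), ...)
  grid_x <- seq(0, 1, length.out = 200)
  graphics::lines(grid_x, predict(x, grid_x), col = "steelblue", lwd = 2)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Invert a calibration model
#'
#' Maps an observed frequency back to the underlying expected frequency: the
#' unique root in `[0, 1]` of `a x^2 + b x + c = observed`, chosen by the
#' monotone branch (closed form; bisection fallback when the quadratic term
#' is numerically degenerate).  Observations outside the model's range on
#' `[0, 1]` are clamped to the nearest endpoint and flagged in the
#' `"clamped"` attribute.
#'
#' @param model A monotone `freq_calibration`.
#' @param observed Numeric vector of observed frequencies in `[0, 1]`.
#' @return Numeric vector of corrected frequencies in `[0, 1]`, with a
#'   logical attribute `clamped`.
#' @examples
#' x <- seq(0, 1, 0.1)
#' m <- fit_calibration(x, 0.2 * x^2 + 0.8 * x)
#' apply_calibration(m, 1.0) # 1
#' @export
apply_calibration <- function(model, observed) {
  stopifnot(inherits(model, "freq_calibration"))
  if (!model$monotone) {
    stop("calibration model is not monotone on [0, 1]; refit before ",
         "inverting", call. = FALSE)
  }
  if (any(observed < 0 | observed > 1, na.rm = TRUE)) {
    stop("observed frequencies must lie in [0, 1]", call. = FALSE)
  }
  co <- model$coefficients
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]
  lo <- cc                 # value at x = 0
  hi <- a + b + cc         # value at x = 1
  out <- numeric(length(observed))
  clamped <- logical(length(observed))
  for (i in seq_along(observed)) {
    y <- observed[i]
    if (is.na(y)) { out[i] <- NA_real_; next }
    if (y <= lo) { out[i] <- 0; clamped[i] <- y < lo - 1e-12; next }
    if (y >= hi) { out[i] <- 1; clamped[i] <- y > hi + 1e-12; next }
    if (abs(a) < 1e-10) {
      out[i] <- (y - cc) / b
    } else {
      disc <- b^2 - 4 * a * (cc - y)
      if (disc < 0) { # numerically degenerate: fall back to bisection
        out[i] <- uniroot(function(x) a * x^2 + b * x + cc - y, c(0, 1),
                          tol = 1e-12)$root
      } else {
        # monotone non-decreasing branch: root where derivative 2ax+b >= 0
        r <- (-b + sqrt(disc)) / (2 * a)
        if (r < -1e-9 || r > 1 + 1e-9) {
          r <- (-b - sqrt(disc)) / (2 * a)
        }
        out[i] <- min(max(r, 0), 1)
      }
    }
  }
  attr(out, "clamped") <- clamped
  out
}
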