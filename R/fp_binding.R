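# Fluorescence polarisation and the four-parameter-logistic (unit-slope)
# binding isotherm.

#' Fluorescence polarisation from channel intensities
#'
#' \eqn{P = (I_\parallel - I_\perp)/(I_\parallel + I_\perp)}.
#'
#' @param i_par parallel-channel intensity.
#' @param i_perp perpendicular-channel intensity.
#' @return polarisation, in \eqn{[-1, 1]} for non-negative intensities.
#' @examples
#' polarisation(2, 1)  # 1/3
#' @export
polarisation <- function(i_par, i_perp) {
  den <- i_par + i_perp
  if (any(den == 0)) stop("i_par + i_perp must be non-zero", call. = FALSE)
  (i_par - i_perp) / den
}

#' Fit a unit-slope binding isotherm to polarisation data
#'
#' \eqn{y = b + (t - b)/(1 + K_d/x)}: a rectangular hyperbola whose
#' inflection on a log-concentration axis sits at \eqn{x = K_d} with
#' \eqn{y(K_d) = (b + t)/2}, assuming 1:1 binding. The Hill slope is fixed
#' at 1 exactly; an optional free slope is available behind
#' \code{free_slope} for diagnostic use.
#'
#' @param x titrant concentrations (M), > 0; at least 4 points spanning the
#'   inflection.
#' @param y polarisation (or any saturating signal) at each concentration.
#' @param weights optional fit weights.
#' @param free_slope allow a free Hill exponent (default FALSE).
#' @return list with \code{b}, \code{t}, \code{kd}, standard errors,
#'   \code{slope} (1 unless freed), \code{fitted}, \code{converged} and
#'   \code{flags} (contains \code{"non_identifiable"} when the data show no
#'   usable curvature).
#' @export
fit_4pl <- function(x, y, weights = NULL, free_slope = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 4, all(x > 0))
  if (is.null(weights)) weights <- rep(1, length(x))
  flags <- character(0)
  b0 <- min(y); t0 <- max(y)
  kd0 <- stats::approx(y, x, xout = (b0 + t0) / 2, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(x)
  fml <- if (free_slope)
    y ~ b + (t - b) / (1 + (kd / x)^h)
  else
    y ~ b + (t - b) / (1 + kd / x)
  start <- if (free_slope) list(b = b0, t = t0, kd = kd0, h = 1)
           else list(b = b0, t = t0, kd = kd0)
  fit <- try(minpack.lm::nlsLM(fml, start = start, weights = weights,
                               lower = c(-Inf, -Inf, .Machine$double.xmin,
                                         if (free_slope) 0.1),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(b = NA_real_, t = NA_real_, kd = NA_real_,
                se = c(b = NA, t = NA, kd = NA), slope = NA_real_,
                fitted = rep(NA_real_, length(x)), converged = FALSE,
                flags = "not_converged"))
  }
  cf <- stats::coef(fit)
  se <- try(sqrt(diag(stats::vcov(fit))), silent = TRUE)
  if (inherits(se, "try-error")) se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  # no curvature: asymptotes indistinguishable or Kd undetermined
  if (!is.finite(se[["kd"]]) || se[["kd"]] > 10 * cf[["kd"]] ||
      abs(cf[["t"]] - cf[["b"]]) < 4 * stats::sd(y - stats::fitted(fit)))
    flags <- c(flags, "non_identifiable")
  list(b = unname(cf["b"]), t = unname(cf["t"]), kd = unname(cf["kd"]),
       se = se, slope = if (free_slope) unname(cf["h"]) else 1,
       fitted = stats::fitted(fit), converged = TRUE, flags = flags)
}

#' Polarisation binding curve from a plate-reader intensity table
#'
#' @param df data.frame with columns \code{conc} (M), \code{i_par},
#'   \code{i_perp}.
#' @param ... passed to \code{\link{fit_4pl}}.
#' @return the \code{\link{fit_4pl}} result with the polarisation table
#'   attached as \code{$data}.
#' @export
fit_fp_curve <- function(df, ...) {
  stopifnot(all(c("conc", "i_par", "i_perp") %in% names(df)))
  p <- polarisation(df$i_par, df$i_perp)
  out <- fit_4pl(df$conc, p, ...)
  out$data <- data.frame(conc = df$conc, p = p)
  out
}
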