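# R1 / R1rho / hetNOE extraction from intensity series.

#' Fit a single-exponential decay
#'
#' Least-squares fit of \eqn{I(t) = A e^{-Rt}} to an intensity series; the
#' rate uncertainty comes from the covariance matrix of the fit. Replicate
#' points are averaged per delay before fitting; negative tail intensities
#' are retained (no truncation).
#'
#' @param delays relaxation delays (s), at least 3 distinct values.
#' @param intensities matching intensities (arbitrary units).
#' @param replicate optional replicate flags; points sharing (delay,
#'   replicate-averaged) are pooled by delay.
#' @return list with \code{rate}, \code{rate_se}, \code{amplitude},
#'   \code{fitted}, \code{converged}.
#' @examples
#' t <- seq(0, 1, length.out = 8)
#' fit_exponential(t, 3 * exp(-2 * t))$rate  # 2
#' @export
fit_exponential <- function(delays, intensities, replicate = NULL) {
  stopifnot(length(delays) == length(intensities))
  d <- tapply(intensities, delays, mean)
  t <- as.numeric(names(d))
  y <- as.numeric(d)
  if (length(t) < 3) stop("need at least 3 distinct delays", call. = FALSE)
  # log-linear start from the positive points
  pos <- y > 0
  st <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    list(A = exp(cf[[1]]), R = max(-cf[[2]], 1e-3))
  } else list(A = max(abs(y)), R = 1)
  fit <- try(minpack.lm::nlsLM(y ~ A * exp(-R * t),
                               start = list(A = st$A, R = st$R),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(rate = NA_real_, rate_se = NA_real_, amplitude = NA_real_,
                fitted = rep(NA_real_, length(t)), converged = FALSE))
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(rate = unname(cf["R"]), rate_se = unname(se["R"]),
       amplitude = unname(cf["A"]), fitted = stats::fitted(fit),
       converged = TRUE)
}

#' Spin-lock tilt angle from resonance offset
#'
#' \eqn{\theta = \arctan(\nu_1 / \Omega)} mapped into \eqn{(0, \pi/2]}: on
#' resonance (zero offset) the effective field is perpendicular to B0.
#'
#' @param spinlock_hz spin-lock field strength \eqn{\nu_1} (Hz).
#' @param offset_hz resonance offset from the carrier (Hz).
#' @return tilt angle (rad) in \eqn{(0, \pi/2]}.
#' @export
spinlock_theta <- function(spinlock_hz, offset_hz) {
  stopifnot(all(spinlock_hz > 0))
  ifelse(offset_hz == 0, pi / 2, atan(spinlock_hz / abs(offset_hz)))
}

#' Transverse rate from rotating-frame relaxation
#'
#' \eqn{R_2 = (R_{1\rho} - R_1 \cos^2\theta) / \sin^2\theta}, the exact
#' inverse of composing \eqn{R_{1\rho}} from \eqn{(R_1, R_2, \theta)}.
#'
#' @param r1rho rotating-frame rate (s^-1).
#' @param r1 longitudinal rate (s^-1).
#' @param theta tilt angle between effective spin-lock field and B0 (rad),
#'   in \eqn{(0, \pi/2]}.
#' @return transverse rate (s^-1).
#' @examples
#' r2_from_r1rho(10, 2, pi / 3)  # (10 - 0.5)/0.75 = 12.667
#' @export
r2_from_r1rho <- function(r1rho, r1, theta) {
  if (any(theta <= 0) || any(theta > pi / 2))
    stop("theta must lie in (0, pi/2]", call. = FALSE)
  (r1rho - r1 * cos(theta)^2) / sin(theta)^2
}

#' Steady-state heteronuclear NOE with propagated error
#'
#' \eqn{NOE = I_{sat}/I_{ref}} with first-order error propagation.
#'
#' @param i_sat intensity with 1H saturation.
#' @param i_ref reference intensity (non-zero).
#' @param sigma_sat,sigma_ref intensity uncertainties.
#' @return list with \code{noe} and \code{noe_se}.
#' @export
het_noe <- function(i_sat, i_ref, sigma_sat = 0, sigma_ref = 0) {
  if (any(i_ref == 0)) stop("reference intensity must be non-zero",
                            call. = FALSE)
  noe <- i_sat / i_ref
  se <- sqrt((sigma_sat / i_ref)^2 + (i_sat * sigma_ref / i_ref^2)^2)
  list(noe = noe, noe_se = se)
}

#' Fit a table of relaxation decay series
#'
#' Convenience wrapper: one exponential fit per residue on a long-format
#' table (replicates averaged per delay).
#'
#' @param df data.frame with columns \code{residue}, \code{delay_s},
#'   \code{intensity} and optionally \code{replicate}.
#' @return data.frame with columns \code{residue}, \code{rate},
#'   \code{rate_se}, \code{converged}.
#' @export
fit_relaxation_table <- function(df) {
  stopifnot(all(c("residue", "delay_s", "intensity") %in% names(df)))
  out <- lapply(split(df, df$residue), function(g) {
    f <- fit_exponential(g$delay_s, g$intensity)
    data.frame(residue = g$residue[1], rate = f$rate, rate_se = f$rate_se,
               converged = f$converged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$residue), ]
}
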