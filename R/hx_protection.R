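# Water-exchange (WEX) buildup fitting and hydrogen-exchange protection
# factors. The buildup of amide signal after water inversion follows the
# two-pool transfer solution
#   I(T) = A k_obs [exp(-R1w T) - exp(-(R1a + k_obs) T)] / (R1a + k_obs - R1w)
# with R1w the water longitudinal rate (shared across residues) and R1a the
# amide longitudinal rate.

#' WEX buildup model
#'
#' @param T water inversion intervals (s).
#' @param amp amplitude A (arbitrary units).
#' @param k_obs amide-water exchange rate (s^-1).
#' @param r1a amide longitudinal relaxation rate (s^-1).
#' @param r1w water longitudinal relaxation rate (s^-1).
#' @return intensities; \code{I(0) = 0} for any parameters. The
#'   rate-degenerate case \code{r1a + k_obs == r1w} is evaluated through its
#'   analytic limit \eqn{A k_{obs} T e^{-R_{1w} T}}.
#' @export
wex_buildup <- function(T, amp, k_obs, r1a, r1w) {
  den <- r1a + k_obs - r1w
  if (abs(den) < 1e-8 * max(r1w, r1a + k_obs, 1)) {
    amp * k_obs * T * exp(-r1w * T)
  } else {
    amp * k_obs * (exp(-r1w * T) - exp(-(r1a + k_obs) * T)) / den
  }
}

#' Fit a WEX buildup curve for the amide exchange rate
#'
#' Fits \code{\link{wex_buildup}} for \code{(k_obs, r1a)} at fixed water
#' rate, with the amplitude pinned to the reference intensity (the fully
#' recovered amide magnetisation). The buildup shape determines only the
#' products \code{amp * k_obs} and \code{r1a + k_obs}, so a free amplitude
#' would leave the exchange rate undetermined — the reference experiment is
#' what makes \code{k_obs} identifiable.
#'
#' @param T water inversion intervals (s), strictly increasing, >= 4 points.
#' @param intensity matching buildup intensities.
#' @param r1w water longitudinal rate (s^-1), supplied (shared across
#'   residues; single water pool).
#' @param i_ref reference (equilibrium) amide intensity fixing the
#'   amplitude; default 1 for normalised data.
#' @param start optional named list (\code{k_obs}, \code{r1a}) overriding
#'   the automatic start values.
#' @return list with \code{k_obs}, \code{k_obs_se}, \code{amp}, \code{r1a},
#'   \code{fitted}, \code{converged}.
#' @export
fit_wex_buildup <- function(T, intensity, r1w, i_ref = 1, start = NULL) {
  stopifnot(length(T) == length(intensity), length(T) >= 4,
            all(diff(T) > 0), r1w > 0, i_ref > 0)
  starts <- if (!is.null(start)) {
    list(c(start$k_obs, start$r1a))
  } else {
    t_peak <- T[which.max(abs(intensity))]
    list(c(max(1 / max(t_peak, 1e-3), 1), 2), c(5, 2), c(40, 2))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      p0, fn = function(p) wex_buildup(T, i_ref, p[1], p[2], r1w) -
        intensity,
      lower = c(1e-4, 1e-3), upper = c(1e4, 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 300))),
      silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    return(list(k_obs = NA_real_, k_obs_se = NA_real_, amp = i_ref,
                r1a = NA_real_, fitted = rep(NA_real_, length(T)),
                converged = FALSE))
  }
  # rate uncertainty from the fit covariance (forward-difference Jacobian)
  s2 <- best$deviance / max(length(T) - 2, 1)
  J <- vapply(1:2, function(j) {
    h <- 1e-6 * max(abs(best$par[j]), 1e-3)
    p <- best$par; p[j] <- p[j] + h
    (wex_buildup(T, i_ref, p[1], p[2], r1w) -
       wex_buildup(T, i_ref, best$par[1], best$par[2], r1w)) / h
  }, numeric(length(T)))
  vc <- try(s2 * solve(crossprod(J)), silent = TRUE)
  k_se <- if (!inherits(vc, "try-error") && vc[1, 1] >= 0)
    sqrt(vc[1, 1]) else NA_real_
  list(k_obs = best$par[1], k_obs_se = k_se, amp = i_ref,
       r1a = best$par[2],
       fitted = wex_buildup(T, i_ref, best$par[1], best$par[2], r1w),
       converged = best$info %in% 1:4)
}

#' Log protection factor from observed and intrinsic exchange rates
#'
#' \eqn{\log P = \log_{10}(s\,k_{int}/k_{obs})} with a scaling factor
#' \eqn{s} (default 1.5) applied to the intrinsic random-coil rates so that
#' fully exposed amides do not fall below zero.
#'
#' @param k_obs observed amide exchange rate (s^-1), > 0.
#' @param k_int intrinsic random-coil exchange rate (s^-1), > 0 (supplied
#'   from sequence-based reference tables).
#' @param scale multiplier on \code{k_int}, default 1.5.
#' @return log10 protection factor.
#' @examples
#' protection_factor(0.15, 10)  # 2
#' @export
protection_factor <- function(k_obs, k_int, scale = 1.5) {
  if (any(k_obs <= 0) || any(k_int <= 0))
    stop("rates must be positive", call. = FALSE)
  log10(scale * k_int / k_obs)
}

#' Fit a table of WEX buildup series
#'
#' @param df data.frame with columns \code{residue}, \code{T_s},
#'   \code{intensity} and optionally \code{i_ref} (per-residue reference
#'   intensity; defaults to 1 for normalised data).
#' @param r1w water longitudinal rate (s^-1).
#' @param k_int optional data.frame (\code{residue}, \code{k_int}); when
#'   given, log protection factors are appended.
#' @return data.frame with columns \code{residue}, \code{k_obs},
#'   \code{k_obs_se} and optionally \code{logP}.
#' @export
fit_hx_table <- function(df, r1w, k_int = NULL) {
  stopifnot(all(c("residue", "T_s", "intensity") %in% names(df)))
  out <- lapply(split(df, df$residue), function(g) {
    o <- g[order(g$T_s), ]
    f <- fit_wex_buildup(o$T_s, o$intensity, r1w,
                         i_ref = if (!is.null(o$i_ref)) o$i_ref[1] else 1)
    data.frame(residue = g$residue[1], k_obs = f$k_obs,
               k_obs_se = f$k_obs_se, converged = f$converged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$residue), ]
  if (!is.null(k_int)) {
    stopifnot(all(c("residue", "k_int") %in% names(k_int)))
    out$logP <- protection_factor(
      out$k_obs, k_int$k_int[match(out$residue, k_int$residue)])
  }
  out
}
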