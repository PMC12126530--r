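# Chemical-shift perturbation significance, open-state populations from
# fast-exchange peak positions, and the fast-limit exchange-rate estimate.

#' Combined 1H/15N chemical shift perturbation
#'
#' \eqn{\Delta\delta_{comb} = \sqrt{\Delta\delta_H^2 +
#' (0.2\,\Delta\delta_N)^2}}.
#'
#' @param d_h 1H shift difference (ppm).
#' @param d_n 15N shift difference (ppm).
#' @return combined perturbation (ppm), >= 0.
#' @examples
#' combined_csp(0.1, 0.5)  # 0.1414
#' @export
combined_csp <- function(d_h, d_n) {
  sqrt(d_h^2 + (0.2 * d_n)^2)
}

#' Iterative corrected-standard-deviation significance cutoff
#'
#' Establishes a CSP significance threshold by iterative outlier trimming:
#' values more than 3 standard deviations above the mean of the surviving
#' set are removed, and the procedure repeats until the set is stable (it
#' shrinks monotonically, so it terminates). The final corrected standard
#' deviation is computed about zero by default — CSPs are magnitudes — and
#' the significance cutoff is twice that value. Both the trimming reference
#' and the final-deviation reference are exposed because the two conventions
#' coexist in the literature.
#'
#' @param csps vector of combined CSPs (ppm), at least 5 values.
#' @param n_sd trimming threshold in standard deviations (default 3).
#' @param cutoff_factor multiplier on the corrected SD for significance
#'   (default 2).
#' @param final_about reference for the final corrected SD: \code{"zero"}
#'   (root mean square, default) or \code{"mean"} (ordinary SD).
#' @param trim_about reference for the trimming test: \code{"mean"}
#'   (default) or \code{"zero"}.
#' @return list with \code{sigma_corr}, \code{cutoff}, \code{significant}
#'   (logical per input value), \code{kept} (values surviving the trim),
#'   \code{n_iter}, \code{degenerate} (TRUE when all values are identical).
#' @export
corrected_sd_cutoff <- function(csps, n_sd = 3, cutoff_factor = 2,
                                final_about = c("zero", "mean"),
                                trim_about = c("mean", "zero")) {
  final_about <- match.arg(final_about)
  trim_about <- match.arg(trim_about)
  stopifnot(is.numeric(csps), length(csps) >= 5, all(is.finite(csps)))
  keep <- rep(TRUE, length(csps))
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    x <- csps[keep]
    mu <- if (trim_about == "mean") mean(x) else 0
    s <- if (trim_about == "mean") stats::sd(x) else sqrt(mean(x^2))
    if (!is.finite(s) || s == 0) break
    drop <- keep & (csps > mu + n_sd * s)
    if (!any(drop[keep])) break
    keep <- keep & !drop
    if (sum(keep) < 2) break
  }
  x <- csps[keep]
  # no spread at all (identical values): the cutoff is undefined
  degenerate <- length(x) < 2 || isTRUE(stats::sd(x) == 0)
  sigma <- if (degenerate) 0
           else if (final_about == "zero") sqrt(mean(x^2))
           else stats::sd(x)
  if (!is.finite(sigma)) { sigma <- 0; degenerate <- TRUE }
  cutoff <- cutoff_factor * sigma
  list(sigma_corr = sigma, cutoff = cutoff,
       significant = csps > cutoff & !degenerate,
       kept = x, n_iter = n_iter, degenerate = degenerate)
}

#' CSP table with significance flags
#'
#' @param df data.frame with columns \code{residue}, \code{d_h}, \code{d_n}
#'   (ppm shift differences).
#' @param ... passed to \code{\link{corrected_sd_cutoff}}.
#' @return the input with \code{csp} and \code{significant} columns; the
#'   cutoff object is attached as attribute \code{"cutoff"}.
#' @export
csp_table <- function(df, ...) {
  stopifnot(all(c("residue", "d_h", "d_n") %in% names(df)))
  df$csp <- combined_csp(df$d_h, df$d_n)
  cs <- corrected_sd_cutoff(df$csp, ...)
  df$significant <- cs$significant
  attr(df, "cutoff") <- cs
  df
}

#' Open-state population from fast-exchange peak positions
#'
#' In fast exchange the observed resonance sits at the population-weighted
#' average of the closed and open positions, so per residue
#' \eqn{p_{open} = (\delta_{obs} - \delta_{closed}) / (\delta_{open} -
#' \delta_{closed})}, clipped to \eqn{[0, 1]}. Residues whose reference
#' separation is below the noise floor are excluded. The aggregate is an
#' inverse-variance-weighted mean with per-residue variance
#' \eqn{\sigma_\delta^2 (1 + p^2 + (1-p)^2) / (\delta_{open} -
#' \delta_{closed})^2} from first-order propagation of the three peak
#' positions.
#'
#' @param df data.frame with columns \code{residue}, \code{delta_closed},
#'   \code{delta_open}, \code{delta_obs} (ppm peak positions; 15N by
#'   default usage).
#' @param sigma_delta peak-position uncertainty (ppm), default 0.02.
#' @param floor minimum usable reference separation (ppm), default 5x
#'   \code{sigma_delta}.
#' @return list with \code{p_open} (aggregate), \code{p_se}, and
#'   \code{per_residue} (data.frame with p, weight, used flag).
#' @export
open_population <- function(df, sigma_delta = 0.02,
                            floor = 5 * sigma_delta) {
  stopifnot(all(c("residue", "delta_closed", "delta_open", "delta_obs")
                %in% names(df)))
  sep <- df$delta_open - df$delta_closed
  used <- abs(sep) >= floor
  if (!any(used))
    stop("no residue with reference separation above the noise floor",
         call. = FALSE)
  if (any(!used))
    message(sum(!used), " residue(s) excluded: reference separation below ",
            floor, " ppm")
  p <- (df$delta_obs - df$delta_closed) / sep
  p <- pmin(pmax(p, 0), 1)
  var_p <- sigma_delta^2 * (1 + p^2 + (1 - p)^2) / sep^2
  w <- ifelse(used, 1 / var_p, 0)
  agg <- sum(w * p) / sum(w)
  se <- sqrt(1 / sum(w))
  list(p_open = agg, p_se = se,
       per_residue = data.frame(residue = df$residue, p = p,
                                weight = w, used = used))
}

#' Fast-limit exchange rate from an exchange contribution
#'
#' In the fast-exchange limit \eqn{R_{ex} = p(1-p)\Delta\omega^2/k_{ex}},
#' so \eqn{k_{ex} = p(1-p)\Delta\omega^2/R_{ex}}. The caller is responsible
#' for verifying the fast-exchange assumption (e.g. from field scaling of
#' R_ex or exchange-averaged peak positions).
#'
#' @param p_open population of the minor/open state (fraction).
#' @param dw_rad chemical-shift difference between the states (rad/s).
#' @param rex exchange contribution to R2 (s^-1), > 0.
#' @return exchange rate (s^-1).
#' @examples
#' kex_from_rex(0.7, 1000, 10)  # 21000
#' @export
kex_from_rex <- function(p_open, dw_rad, rex) {
  stopifnot(p_open >= 0, p_open <= 1)
  if (any(rex <= 0)) stop("rex must be positive", call. = FALSE)
  p_open * (1 - p_open) * dw_rad^2 / rex
}
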