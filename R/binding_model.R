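# Stoichiometric layer of the two-state binding model:
#   JDP + Hsc <=> JDPHsc   (k_on, k_off; Kd = k_off/k_on)
# All concentrations are molar internally; micromolar only at file/user
# boundaries (see uM_to_M).

#' Kinetic parameters of a two-state binding equilibrium
#'
#' Bundles the bimolecular association rate and the dissociation rate of a
#' simple 1:1 binding reaction. The equilibrium dissociation constant is
#' derived, never stored independently, so \code{k_d == k_off/k_on} holds to
#' machine precision.
#'
#' @param k_on bimolecular association rate constant (M^-1 s^-1), > 0.
#' @param k_off dissociation rate constant (s^-1), >= 0.
#' @return An object of class \code{"exchange_params"}: a list with elements
#'   \code{k_on}, \code{k_off} and the derived \code{k_d} (M).
#' @examples
#' exchange_params(k_on = 580 / 380e-6, k_off = 580)
#' @export
exchange_params <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L, is.numeric(k_off),
            length(k_off) == 1L)
  if (!is.finite(k_on) || k_on <= 0)
    stop("k_on must be a positive finite rate (M^-1 s^-1)", call. = FALSE)
  if (!is.finite(k_off) || k_off < 0)
    stop("k_off must be a non-negative finite rate (s^-1)", call. = FALSE)
  structure(list(k_on = k_on, k_off = k_off, k_d = k_off / k_on),
            class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf("Two-state exchange parameters:\n  k_on  = %.4g M^-1 s^-1\n  k_off = %.4g s^-1\n  K_d   = %.4g M (%.4g uM)\n",
              x$k_on, x$k_off, x$k_d, x$k_d * 1e6))
  invisible(x)
}

#' Sample composition of a titration point
#'
#' Total concentrations of the NMR-visible species (the JDP construct) and of
#' the unlabelled binding partner (ligand, here Hsc70). Together with a
#' dissociation constant these define the bound population via material
#' balance.
#'
#' @param jdp_total total concentration of the NMR-visible species (M).
#' @param hsc_total total ligand concentration (M).
#' @return An object of class \code{"titration_condition"}.
#' @export
titration_condition <- function(jdp_total, hsc_total) {
  stopifnot(is.numeric(jdp_total), length(jdp_total) == 1L,
            is.numeric(hsc_total), length(hsc_total) == 1L)
  if (!is.finite(jdp_total) || jdp_total < 0)
    stop("jdp_total must be a non-negative concentration (M)", call. = FALSE)
  if (!is.finite(hsc_total) || hsc_total < 0)
    stop("hsc_total must be a non-negative concentration (M)", call. = FALSE)
  structure(list(jdp_total = jdp_total, hsc_total = hsc_total),
            class = "titration_condition")
}

#' Convert micromolar to molar
#'
#' @param x concentration(s) in micromolar.
#' @return concentration(s) in molar.
#' @export
uM_to_M <- function(x) x * 1e-6

#' Bound fraction of the observed species under ligand depletion
#'
#' Solves the material-balance quadratic for the population of the bound
#' NMR-visible species at a given dissociation constant,
#' \deqn{p_B = \{J + H + K_d - \sqrt{(J + H + K_d)^2 - 4JH}\} / 2J,}
#' with \eqn{J} and \eqn{H} the total concentrations. The subtracting root is
#' evaluated in the numerically stable rationalised form
#' \eqn{p_B = 2H / (J + H + K_d + \sqrt{\cdot})} to avoid cancellation when
#' the bound population is small. The limit \eqn{J \to 0} is handled
#' analytically as \eqn{p_B = H/(H + K_d)} (no depletion).
#'
#' @param cond a \code{\link{titration_condition}}.
#' @param kd dissociation constant (M), > 0.
#' @return bound fraction in \eqn{[0, 1]}.
#' @examples
#' cond <- titration_condition(uM_to_M(200), uM_to_M(20))
#' bound_fraction(cond, uM_to_M(380))  # ~0.0337
#' @export
bound_fraction <- function(cond, kd) {
  stopifnot(inherits(cond, "titration_condition"))
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("kd must be a positive dissociation constant (M)", call. = FALSE)
  j <- cond$jdp_total
  h <- cond$hsc_total
  if (h == 0) return(0)
  if (j == 0) return(h / (h + kd))
  b <- j + h + kd
  disc <- b^2 - 4 * j * h
  # clamp tiny negative discriminants from rounding (stoichiometric point)
  if (disc < 0 && disc > -1e-12 * b^2) disc <- 0
  if (disc < 0)
    stop("negative discriminant in material-balance quadratic", call. = FALSE)
  p <- 2 * h / (b + sqrt(disc))
  min(max(p, 0), 1)
}

#' Full kinetic state of a titration point
#'
#' Combines the material-balance bound fraction with the kinetic constants to
#' give the free-ligand concentration, the pseudo-first-order on-rate
#' \eqn{k_{on}^{app} = k_{on}[Hsc]_{free}} and the exchange rate
#' \eqn{k_{ex} = k_{on}^{app} + k_{off}} that enter the exchange matrix.
#' Detailed balance \eqn{(1 - p_B) k_{on}^{app} = p_B k_{off}} is guaranteed
#' by construction.
#'
#' @param cond a \code{\link{titration_condition}}.
#' @param params an \code{\link{exchange_params}}.
#' @return An object of class \code{"binding_state"}: list with
#'   \code{p_bound}, \code{hsc_free} (M), \code{k_on_app}, \code{k_off} and
#'   \code{k_ex} (all s^-1 where rates).
#' @examples
#' cond <- titration_condition(uM_to_M(200), uM_to_M(20))
#' binding_state(cond, exchange_params(580 / 380e-6, 580))  # k_ex ~ 600 s^-1
#' @export
binding_state <- function(cond, params) {
  stopifnot(inherits(cond, "titration_condition"),
            inherits(params, "exchange_params"))
  if (params$k_off == 0 && cond$hsc_total > 0) {
    # irreversible limit: all ligand consumed or all protein bound
    p <- min(cond$hsc_total / max(cond$jdp_total, .Machine$double.xmin), 1)
    hf <- max(cond$hsc_total - p * cond$jdp_total, 0)
  } else if (cond$hsc_total == 0) {
    p <- 0
    hf <- 0
  } else {
    p <- bound_fraction(cond, params$k_d)
    hf <- max(cond$hsc_total - p * cond$jdp_total, 0)
  }
  k_on_app <- params$k_on * hf
  structure(list(p_bound = p, hsc_free = hf, k_on_app = k_on_app,
                 k_off = params$k_off, k_ex = k_on_app + params$k_off),
            class = "binding_state")
}

#' @export
print.binding_state <- function(x, ...) {
  cat(sprintf("Binding state:\n  p_bound  = %.4g\n  hsc_free = %.4g M\n  k_on_app = %.4g s^-1\n  k_off    = %.4g s^-1\n  k_ex     = %.4g s^-1\n",
              x$p_bound, x$hsc_free, x$k_on_app, x$k_off, x$k_ex))
  invisible(x)
}

#' Dissociation rate implied by an exchange rate at fixed Kd
#'
#' Given a dissociation constant and the exchange rate measured at a known
#' sample composition, returns the dissociation rate consistent with the
#' material-balance model: \eqn{k_{off} = k_{ex} / (1 + [Hsc]_{free}/K_d)}.
#'
#' @param cond a \code{\link{titration_condition}}.
#' @param kd dissociation constant (M).
#' @param kex exchange rate (s^-1).
#' @return dissociation rate (s^-1).
#' @export
koff_from_kex <- function(cond, kd, kex) {
  p <- bound_fraction(cond, kd)
  hf <- max(cond$hsc_total - p * cond$jdp_total, 0)
  kex / (1 + hf / kd)
}

#' Dissociation constant implied by (k_off, k_ex) at a composition
#'
#' Root-finds the Kd at which the material-balance model returns the stated
#' exchange rate for the stated dissociation rate. Requires
#' \code{kex > koff} (some association must be present).
#'
#' @param cond a \code{\link{titration_condition}}.
#' @param koff dissociation rate (s^-1).
#' @param kex exchange rate (s^-1), > koff.
#' @param interval search interval for Kd (M).
#' @return dissociation constant (M).
#' @export
kd_from_kex <- function(cond, koff, kex, interval = c(1e-9, 1)) {
  stopifnot(kex > koff, koff > 0)
  f <- function(log_kd) {
    kd <- 10^log_kd
    binding_state(cond, exchange_params(koff / kd, koff))$k_ex - kex
  }
  r <- stats::uniroot(f, log10(interval), tol = 1e-12)
  10^r$root
}
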