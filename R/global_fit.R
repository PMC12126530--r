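# Joint weighted least-squares fit of multi-field CPMG dispersion curves and
# exchange-induced shifts to the two-state binding model. Global parameters
# are (k_on, k_off), optimised on a log10 scale because rates span decades;
# nuisance parameters are a shared (across fields, in ppm) shift difference
# per residue and an intrinsic apo rate per curve, with R2_bound tied to
# r2_bound_scale * R2_apo.

#' Extract R2,eff from peak intensities
#'
#' \eqn{R_{2,eff} = -\ln(I/I_0)/T_{relax}}, with the reference intensity
#' taken from the experiment recorded without the relaxation period.
#' Non-positive intensities cannot be converted and are returned as NA with
#' a message.
#'
#' @param intensity peak intensity at each CPMG field strength.
#' @param i0 reference intensity (relaxation period omitted); recycled.
#' @param t_relax constant-time relaxation delay (s).
#' @return vector of effective rates (s^-1).
#' @examples
#' r2eff_from_intensities(0.5, 1, 0.04)  # ln(2)/0.04 = 17.33 s^-1
#' @export
r2eff_from_intensities <- function(intensity, i0, t_relax) {
  stopifnot(t_relax > 0)
  if (any(i0 <= 0)) stop("reference intensity must be positive", call. = FALSE)
  out <- suppressWarnings(-log(intensity / i0) / t_relax)
  bad <- !is.finite(out) | intensity <= 0
  if (any(bad)) {
    message(sum(bad), " non-positive intensities dropped (returned as NA)")
    out[bad] <- NA_real_
  }
  out
}

#' Pooled R2,eff uncertainty from duplicate measurements
#'
#' Standard duplicate-difference estimator: for m duplicated CPMG field
#' strengths with rate differences d, \eqn{\sigma = \sqrt{\sum d^2 / 2m}}.
#' The pooled value is applied to every point of the curve.
#'
#' @param r2eff effective rates of one dispersion curve.
#' @param nu_cpmg matching CPMG field strengths; duplicated values identify
#'   the replicate pairs.
#' @return pooled standard deviation (s^-1), or NA if no duplicates.
#' @export
sigma_from_duplicates <- function(r2eff, nu_cpmg) {
  stopifnot(length(r2eff) == length(nu_cpmg))
  ok <- is.finite(r2eff)
  d <- tapply(r2eff[ok], nu_cpmg[ok], function(x)
    if (length(x) >= 2) diff(x[1:2]) else NA_real_)
  d <- d[is.finite(d)]
  if (length(d) == 0) return(NA_real_)
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Convert an intensity table to dispersion curves
#'
#' Groups rows by (dataset, residue, field), converts intensities to R2,eff,
#' estimates a per-curve uncertainty from the duplicated CPMG field
#' strengths, and averages duplicates into one point per field strength.
#'
#' @param df data.frame with columns \code{dataset}, \code{residue},
#'   \code{field_mhz}, \code{nu_cpmg}, \code{intensity}, \code{i0}.
#' @param t_relax constant-time relaxation delay (s).
#' @return data.frame with columns \code{dataset}, \code{residue},
#'   \code{field_mhz}, \code{nu_cpmg}, \code{r2eff}, \code{sigma},
#'   \code{t_relax}.
#' @export
dispersion_from_intensities <- function(df, t_relax) {
  need <- c("dataset", "residue", "field_mhz", "nu_cpmg", "intensity", "i0")
  stopifnot(all(need %in% names(df)))
  key <- interaction(df$dataset, df$residue, df$field_mhz, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    r2 <- r2eff_from_intensities(g$intensity, g$i0, t_relax)
    sig <- sigma_from_duplicates(r2, g$nu_cpmg)
    if (!is.finite(sig) || sig == 0)
      stop("no usable duplicate pair for curve (residue ", g$residue[1],
           ", field ", g$field_mhz[1], ")", call. = FALSE)
    agg <- tapply(r2, g$nu_cpmg, mean, na.rm = TRUE)
    data.frame(dataset = g$dataset[1], residue = g$residue[1],
               field_mhz = g$field_mhz[1],
               nu_cpmg = as.numeric(names(agg)),
               r2eff = as.numeric(agg), sigma = sig, t_relax = t_relax,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[is.finite(out$r2eff), ]
}

#' Assemble a global fit problem
#'
#' @param cpmg data.frame of dispersion points with columns \code{dataset},
#'   \code{residue}, \code{field_mhz}, \code{nu_cpmg}, \code{r2eff},
#'   \code{sigma}, \code{t_relax} (see
#'   \code{\link{dispersion_from_intensities}}).
#' @param conditions a \code{\link{titration_condition}} (single dataset) or
#'   a named list of them keyed by dataset name.
#' @param dex optional data.frame of exchange-induced shifts with columns
#'   \code{dataset}, \code{residue}, \code{field_mhz}, \code{dex_ppm} and
#'   optionally \code{sigma} (ppm).
#' @param r2_bound_scale multiplier tying the bound-state rate to the apo
#'   rate (default 5).
#' @param use_delta_ex include the shift term in the target function;
#'   defaults to TRUE when \code{dex} is supplied.
#' @param dex_sigma_floor uncertainty floor (ppm) applied to shifts without a
#'   stated sigma; default 0.002.
#' @return An object of class \code{"fit_problem"}.
#' @export
fit_problem <- function(cpmg, conditions, dex = NULL, r2_bound_scale = 5,
                        use_delta_ex = !is.null(dex),
                        dex_sigma_floor = 0.002) {
  need <- c("dataset", "residue", "field_mhz", "nu_cpmg", "r2eff", "sigma",
            "t_relax")
  stopifnot(is.data.frame(cpmg), all(need %in% names(cpmg)))
  if (inherits(conditions, "titration_condition"))
    conditions <- stats::setNames(list(conditions), unique(cpmg$dataset)[1])
  stopifnot(is.list(conditions), !is.null(names(conditions)))
  if (!all(unique(cpmg$dataset) %in% names(conditions)))
    stop("every dataset needs a titration condition", call. = FALSE)
  if (any(!is.finite(cpmg$sigma) | cpmg$sigma <= 0))
    stop("every CPMG point needs a positive sigma", call. = FALSE)
  key <- interaction(cpmg$dataset, cpmg$residue, cpmg$field_mhz, drop = TRUE)
  if (any(table(key) < 2))
    stop("each dispersion curve needs at least 2 nu_cpmg points",
         call. = FALSE)
  if (!is.null(dex)) {
    stopifnot(all(c("dataset", "residue", "field_mhz", "dex_ppm") %in%
                    names(dex)))
    if (is.null(dex$sigma)) dex$sigma <- dex_sigma_floor
    dex$sigma <- pmax(dex$sigma, dex_sigma_floor)
    if (!all(dex$dataset %in% names(conditions)))
      stop("delta_ex rows reference unknown datasets", call. = FALSE)
  }
  structure(list(cpmg = cpmg, dex = dex, conditions = conditions,
                 r2_bound_scale = r2_bound_scale,
                 use_delta_ex = use_delta_ex && !is.null(dex)),
            class = "fit_problem")
}

# ---- internal fit machinery ------------------------------------------------

# index structure: curves (list), spin table, parameter packing
.build_index <- function(prob) {
  cpmg <- prob$cpmg
  key <- interaction(cpmg$dataset, cpmg$residue, cpmg$field_mhz, drop = TRUE)
  curves <- lapply(split(cpmg, key), function(g)
    list(dataset = as.character(g$dataset[1]), residue = g$residue[1],
         field = g$field_mhz[1], nu = g$nu_cpmg, obs = g$r2eff,
         sig = g$sigma, t_relax = g$t_relax[1]))
  curves <- unname(curves)
  spins <- sort(unique(cpmg$residue))
  n_cp <- sum(vapply(curves, function(cv) length(cv$nu), 1L))
  # residual row ranges
  pos <- 1L
  for (i in seq_along(curves)) {
    n <- length(curves[[i]]$nu)
    curves[[i]]$rows <- seq.int(pos, pos + n - 1L)
    pos <- pos + n
  }
  dexi <- NULL
  if (prob$use_delta_ex) {
    dx <- prob$dex
    dexi <- data.frame(dataset = as.character(dx$dataset),
                       residue = dx$residue, field = dx$field_mhz,
                       obs = dx$dex_ppm, sig = dx$sigma,
                       row = seq.int(pos, pos + nrow(dx) - 1L),
                       stringsAsFactors = FALSE)
  }
  list(curves = curves, spins = spins, dex = dexi,
       n_resid = n_cp + if (is.null(dexi)) 0L else nrow(dexi),
       n_par = 2L + length(spins) + length(curves),
       scale = prob$r2_bound_scale, conditions = prob$conditions)
}

.unpack <- function(theta, idx) {
  s <- length(idx$spins)
  list(lkon = theta[1], lkoff = theta[2],
       dw = theta[2 + seq_len(s)],
       r2a = theta[2 + s + seq_along(idx$curves)])
}

.states_at <- function(idx, lkon, lkoff) {
  ep <- exchange_params(10^lkon, 10^lkoff)
  lapply(idx$conditions, binding_state, params = ep)
}

# residuals for a subset of curves/dex rows; cv_sel/dx_sel are indices or NULL
# for all. Returns full-length vector when full = TRUE, else the subset rows.
.resid_eval <- function(theta, idx, cv_sel = NULL, dx_sel = NULL,
                        states = NULL) {
  p <- .unpack(theta, idx)
  if (is.null(states)) states <- .states_at(idx, p$lkon, p$lkoff)
  spin_of <- match(vapply(idx$curves, `[[`, 1, "residue"), idx$spins)
  cvs <- if (is.null(cv_sel)) seq_along(idx$curves) else cv_sel
  out <- numeric(0)
  rows <- integer(0)
  for (i in cvs) {
    cv <- idx$curves[[i]]
    st <- states[[cv$dataset]]
    r2a <- p$r2a[i]
    dw <- ppm_to_rads(p$dw[spin_of[i]], cv$field)
    calc <- .bm_r2eff(cv$nu, cv$t_relax, st$k_on_app, st$k_off, st$p_bound,
                      r2a, idx$scale * r2a, dw)
    out <- c(out, (calc - cv$obs) / cv$sig)
    rows <- c(rows, cv$rows)
  }
  if (!is.null(idx$dex)) {
    dxs <- if (is.null(dx_sel)) seq_len(nrow(idx$dex)) else dx_sel
    if (length(dxs)) {
      dx <- idx$dex[dxs, , drop = FALSE]
      spin_dx <- match(dx$residue, idx$spins)
      # r2a of the matching curve (same dataset/residue/field), else median
      cv_res <- vapply(idx$curves, `[[`, 1, "residue")
      cv_fld <- vapply(idx$curves, `[[`, 1, "field")
      cv_ds <- vapply(idx$curves, `[[`, "", "dataset")
      calc <- vapply(seq_len(nrow(dx)), function(k) {
        st <- states[[dx$dataset[k]]]
        j <- which(cv_res == dx$residue[k] & cv_fld == dx$field[k] &
                     cv_ds == dx$dataset[k])
        r2a <- if (length(j)) p$r2a[j[1]] else stats::median(p$r2a)
        rads <- .delta_ex_rads(st$k_on_app, st$k_off, r2a, idx$scale * r2a,
                               ppm_to_rads(p$dw[spin_dx[k]], dx$field[k]))
        rads_to_ppm(rads, dx$field[k])
      }, 1)
      out <- c(out, (calc - dx$obs) / dx$sig)
      rows <- c(rows, dx$row)
    }
  }
  list(resid = out, rows = rows)
}

.resid_full <- function(theta, idx) {
  r <- .resid_eval(theta, idx)
  out <- numeric(idx$n_resid)
  out[r$rows] <- r$resid
  out
}

# block-structured forward-difference Jacobian: global columns need a full
# recomputation, per-spin and per-curve columns only their own rows
.jac_full <- function(theta, idx, r0 = NULL) {
  if (is.null(r0)) r0 <- .resid_full(theta, idx)
  n <- idx$n_resid
  p <- length(theta)
  J <- matrix(0, n, p)
  s <- length(idx$spins)
  cv_res <- vapply(idx$curves, `[[`, 1, "residue")
  h_g <- 1e-6
  for (j in 1:2) {
    th <- theta; th[j] <- th[j] + h_g
    J[, j] <- (.resid_full(th, idx) - r0) / h_g
  }
  states <- .states_at(idx, theta[1], theta[2])
  for (k in seq_len(s)) {
    j <- 2L + k
    h <- 1e-6 * max(abs(theta[j]), 0.01)
    th <- theta; th[j] <- th[j] + h
    sel_cv <- which(cv_res == idx$spins[k])
    sel_dx <- if (!is.null(idx$dex)) which(idx$dex$residue == idx$spins[k])
              else NULL
    r <- .resid_eval(th, idx, cv_sel = sel_cv, dx_sel = sel_dx,
                     states = states)
    J[r$rows, j] <- (r$resid - r0[r$rows]) / h
  }
  for (k in seq_along(idx$curves)) {
    j <- 2L + s + k
    h <- 1e-6 * max(abs(theta[j]), 1)
    th <- theta; th[j] <- th[j] + h
    cv <- idx$curves[[k]]
    sel_dx <- if (!is.null(idx$dex))
      which(idx$dex$residue == cv$residue & idx$dex$field == cv$field &
              idx$dex$dataset == cv$dataset) else NULL
    r <- .resid_eval(th, idx, cv_sel = k, dx_sel = sel_dx, states = states)
    J[r$rows, j] <- (r$resid - r0[r$rows]) / h
  }
  J
}

# heuristic nuisance start values at fixed globals
.nuisance_start <- function(idx, lkon, lkoff) {
  states <- .states_at(idx, lkon, lkoff)
  s <- length(idx$spins)
  dw0 <- numeric(s)
  r2a0 <- vapply(idx$curves, function(cv) max(min(cv$obs), 0.5), 1)
  for (k in seq_len(s)) {
    est <- c()
    for (i in seq_along(idx$curves)) {
      cv <- idx$curves[[i]]
      if (cv$residue != idx$spins[k]) next
      st <- states[[cv$dataset]]
      pb <- st$p_bound
      if (pb <= 0 || pb >= 1) next
      rex <- max(cv$obs[which.min(cv$nu)] - cv$obs[which.max(cv$nu)], 0.05)
      dw_rad <- sqrt(rex * max(st$k_ex, 1) / (pb * (1 - pb)))
      est <- c(est, rads_to_ppm(dw_rad, cv$field))
    }
    dw0[k] <- if (length(est)) min(stats::median(est), 10) else 1
  }
  list(dw = dw0, r2a = r2a0)
}

# re-optimise nuisance parameters at fixed (lkon, lkoff); returns chi2 and
# the refined nuisances
.profile_chi2 <- function(idx, lkon, lkoff, dw0, r2a0, maxiter = 25) {
  states <- .states_at(idx, lkon, lkoff)
  cv_res <- vapply(idx$curves, `[[`, 1, "residue")
  s <- length(idx$spins)
  dw <- dw0; r2a <- r2a0
  chi2 <- 0
  for (k in seq_len(s)) {
    sel_cv <- which(cv_res == idx$spins[k])
    sel_dx <- if (!is.null(idx$dex)) which(idx$dex$residue == idx$spins[k])
              else NULL
    par0 <- c(dw[k], r2a[sel_cv])
    fn <- function(par) {
      th <- numeric(idx$n_par)
      th[1] <- lkon; th[2] <- lkoff
      th[2 + seq_len(s)] <- dw
      th[2 + k] <- par[1]
      th[2 + s + seq_along(idx$curves)] <- r2a
      th[2 + s + sel_cv] <- par[-1]
      .resid_eval(th, idx, cv_sel = sel_cv, dx_sel = sel_dx,
                  states = states)$resid
    }
    fit <- try(suppressWarnings(
      minpack.lm::nls.lm(par0, fn = fn,
                         lower = c(-50, rep(1e-3, length(sel_cv))),
                         upper = c(50, rep(1e4, length(sel_cv))),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter))), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      dw[k] <- fit$par[1]
      r2a[sel_cv] <- fit$par[-1]
      chi2 <- chi2 + fit$deviance
    } else {
      chi2 <- chi2 + sum(fn(par0)^2)
    }
  }
  list(chi2 = chi2, dw = dw, r2a = r2a)
}

#' Global fit of CPMG and exchange-induced-shift data
#'
#' Minimises
#' \deqn{\chi^2 = \sum \left(\frac{R_{2,eff}^{obs} - R_{2,eff}^{calc}}
#'   {\sigma}\right)^2 + \sum \left(\frac{\delta_{ex}^{obs} -
#'   \delta_{ex}^{calc}}{\sigma_\delta}\right)^2}
#' over global \eqn{(k_{on}, k_{off})} (log10-parameterised) and per-residue
#' nuisance parameters (shift difference in ppm shared across fields, apo
#' R2 per curve). The bound fraction is recomputed from material balance at
#' every iteration, so the reported exchange rate satisfies
#' \code{binding_state(cond, params)$k_ex} exactly. Initialisation is a
#' coarse multi-start grid over the rate constants unless \code{init} is
#' given; the procedure is deterministic.
#'
#' @param problem a \code{\link{fit_problem}}.
#' @param init optional list with elements \code{k_on}, \code{k_off} used as
#'   the single starting point (skips the multi-start grid).
#' @param seed integer; fixed for reproducibility of any randomised choices
#'   (the default pipeline is fully deterministic).
#' @param grid_kon,grid_koff multi-start grid nodes for the rate constants
#'   (defaults: 5 log-spaced values each).
#' @param maxiter maximum Levenberg-Marquardt iterations for the joint fit.
#' @return An object of class \code{"cpmg_fit"} with elements \code{params}
#'   (rates, Kd and standard errors), \code{per_spin}, \code{r2a},
#'   \code{states} (one \code{\link{binding_state}} per dataset),
#'   \code{chi2}, \code{dof}, \code{converged} and \code{flags}.
#' @export
fit_global <- function(problem, init = NULL, seed = 0,
                       grid_kon = 10^seq(4, 9, length.out = 5),
                       grid_koff = 10^seq(0.5, 4.5, length.out = 5),
                       maxiter = 200) {
  stopifnot(inherits(problem, "fit_problem"))
  set.seed(seed)
  idx <- .build_index(problem)
  s <- length(idx$spins)
  flags <- character(0)

  if (!is.null(init)) {
    starts <- list(c(log10(init$k_on), log10(init$k_off)))
  } else {
    nodes <- expand.grid(lkon = log10(grid_kon), lkoff = log10(grid_koff))
    node_chi2 <- numeric(nrow(nodes))
    node_nuis <- vector("list", nrow(nodes))
    for (i in seq_len(nrow(nodes))) {
      st0 <- .nuisance_start(idx, nodes$lkon[i], nodes$lkoff[i])
      pr <- .profile_chi2(idx, nodes$lkon[i], nodes$lkoff[i],
                          st0$dw, st0$r2a, maxiter = 15)
      node_chi2[i] <- pr$chi2
      node_nuis[[i]] <- pr
    }
    best <- order(node_chi2)[1]
    starts <- list(c(nodes$lkon[best], nodes$lkoff[best]))
    attr(starts, "nuis") <- node_nuis[[best]]
  }

  nuis <- attr(starts, "nuis")
  if (is.null(nuis)) {
    st0 <- .nuisance_start(idx, starts[[1]][1], starts[[1]][2])
    nuis <- .profile_chi2(idx, starts[[1]][1], starts[[1]][2],
                          st0$dw, st0$r2a, maxiter = 25)
  }
  theta0 <- c(starts[[1]], nuis$dw, nuis$r2a)

  lower <- c(-2, -2, rep(-50, s), rep(1e-3, length(idx$curves)))
  upper <- c(10, 6, rep(50, s), rep(1e4, length(idx$curves)))
  fit <- minpack.lm::nls.lm(theta0, fn = .resid_full, jac = .jac_full,
                            idx = idx, lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-12,
                              ptol = 1e-10))
  converged <- fit$info %in% 1:4
  if (!converged) flags <- c(flags, "not_converged")

  theta <- fit$par
  p <- .unpack(theta, idx)
  params <- exchange_params(10^p$lkon, 10^p$lkoff)
  states <- lapply(idx$conditions, binding_state, params = params)

  # covariance of the weighted problem: (J'J)^-1 at the optimum
  J <- .jac_full(theta, idx)
  se <- rep(NA_real_, length(theta))
  vc <- try(solve(crossprod(J)), silent = TRUE)
  kd_se <- NA_real_
  if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
      all(diag(vc) >= 0)) {
    se <- sqrt(diag(vc))
    kd_se <- log(10) * params$k_d *
      sqrt(max(vc[1, 1] + vc[2, 2] - 2 * vc[1, 2], 0))
  } else {
    flags <- c(flags, "singular_covariance")
  }
  res <- .resid_full(theta, idx)
  # flatness probe: re-optimise nuisances half a decade away from the
  # optimum in each rate; a chi2 surface that does not rise carries no
  # exchange information (e.g. all shift differences zero)
  chi2_min <- sum(res^2)
  probe <- rbind(c(0.5, 0), c(-0.5, 0), c(0, 0.5), c(0, -0.5))
  rise <- vapply(seq_len(nrow(probe)), function(i)
    .profile_chi2(idx, p$lkon + probe[i, 1], p$lkoff + probe[i, 2],
                  p$dw, p$r2a, maxiter = 25)$chi2 - chi2_min, 1)
  if (!all(is.finite(se[1:2])) || max(abs(p$dw)) < 1e-3 ||
      min(rise) < max(0.01 * chi2_min, 2)) {
    flags <- c(flags, "non_identifiable")
  }
  per_spin <- data.frame(residue = idx$spins, dw_ppm = p$dw,
                         dw_se = se[2 + seq_len(s)])
  r2a_tab <- data.frame(
    dataset = vapply(idx$curves, `[[`, "", "dataset"),
    residue = vapply(idx$curves, `[[`, 1, "residue"),
    field_mhz = vapply(idx$curves, `[[`, 1, "field"),
    r2a = p$r2a, r2a_se = se[2 + s + seq_along(idx$curves)])

  structure(list(
    params = list(k_on = params$k_on, k_off = params$k_off,
                  k_d = params$k_d,
                  se = c(k_on = log(10) * params$k_on * se[1],
                         k_off = log(10) * params$k_off * se[2],
                         k_d = kd_se)),
    exchange = params,
    per_spin = per_spin, r2a = r2a_tab, states = states,
    chi2 = sum(res^2), dof = idx$n_resid - length(theta),
    residuals = res, converged = converged, flags = flags,
    info = fit$info, seed = seed, problem = problem),
    class = "cpmg_fit")
}

#' @export
print.cpmg_fit <- function(x, ...) {
  cat("Global two-state binding fit\n")
  cat(sprintf("  k_on  = %.4g +/- %.2g M^-1 s^-1\n", x$params$k_on,
              x$params$se["k_on"]))
  cat(sprintf("  k_off = %.4g +/- %.2g s^-1\n", x$params$k_off,
              x$params$se["k_off"]))
  cat(sprintf("  K_d   = %.4g +/- %.2g uM\n", x$params$k_d * 1e6,
              x$params$se["k_d"] * 1e6))
  for (nm in names(x$states))
    cat(sprintf("  [%s] p_bound = %.4g, k_ex = %.4g s^-1\n", nm,
                x$states[[nm]]$p_bound, x$states[[nm]]$k_ex))
  cat(sprintf("  chi2 = %.4g (%d dof)%s\n", x$chi2, x$dof,
              if (length(x$flags)) paste0("  [", paste(x$flags,
                collapse = ", "), "]") else ""))
  invisible(x)
}

#' Chi-square surface around the fitted rate constants
#'
#' Grid search used to assess convergence: at every (k_on, k_off) node the
#' per-residue nuisance parameters are re-optimised and the resulting
#' chi-square recorded. For a well-determined fit the surface minimum lies
#' within one grid cell of the reported optimum.
#'
#' @param problem the \code{\link{fit_problem}} that was fitted.
#' @param result the \code{\link{fit_global}} result.
#' @param span half-width of the grid in log10 units around the optimum.
#' @param steps number of nodes per axis (odd keeps the optimum on-grid).
#' @return data.frame with columns \code{k_on}, \code{k_off}, \code{chi2},
#'   with the chi2 matrix and axis values as attributes.
#' @export
convergence_grid <- function(problem, result, span = 0.3, steps = 7) {
  stopifnot(inherits(problem, "fit_problem"), inherits(result, "cpmg_fit"))
  idx <- .build_index(problem)
  lkon0 <- log10(result$params$k_on)
  lkoff0 <- log10(result$params$k_off)
  lkon <- if (span == 0 || steps == 1) lkon0 else
    seq(lkon0 - span, lkon0 + span, length.out = steps)
  lkoff <- if (span == 0 || steps == 1) lkoff0 else
    seq(lkoff0 - span, lkoff0 + span, length.out = steps)
  dw0 <- result$per_spin$dw_ppm
  r2a0 <- result$r2a$r2a
  grid <- expand.grid(lkon = lkon, lkoff = lkoff)
  chi2 <- vapply(seq_len(nrow(grid)), function(i)
    .profile_chi2(idx, grid$lkon[i], grid$lkoff[i], dw0, r2a0,
                  maxiter = 25)$chi2, 1)
  out <- data.frame(k_on = 10^grid$lkon, k_off = 10^grid$lkoff, chi2 = chi2)
  attr(out, "chi2_matrix") <- matrix(chi2, nrow = length(lkon),
                                     dimnames = list(signif(10^lkon, 4),
                                                     signif(10^lkoff, 4)))
  attr(out, "k_on_axis") <- 10^lkon
  attr(out, "k_off_axis") <- 10^lkoff
  out
}
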