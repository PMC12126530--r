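# Seeded ground-truth generators for every observable the package analyses.
# Defaults emulate the DNAJB6 JD-GF / Hsc70 titration: k_off = 580 s^-1,
# Kd = 380 uM, 200 uM labelled protein with ligand at molar ratio 0.1,
# CPMG at 600/800/950 MHz with a 40 ms constant-time element, duplicate
# measurements at two CPMG field strengths, and 2% fractional intensity
# noise. Noise is applied at the intensity level so the duplicate-based
# error estimator is exercised by the same route as measured data.

#' Specification for the CPMG titration generator
#'
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @param k_off,kd_uM,jdp_uM,hsc_uM truth kinetics and composition
#'   (k_on is kd-derived).
#' @param n_spins number of residues with dispersion curves.
#' @param fields_mhz spectrometer 1H frequencies (MHz).
#' @param t_relax constant-time relaxation delay (s).
#' @param nu_cpmg CPMG field strengths (Hz); snapped to the delay.
#' @param noise fractional Gaussian intensity noise (default 0.02).
#' @param n_duplicates how many CPMG field strengths are measured twice.
#' @param dw_range,r2a_range uniform sampling ranges for the per-residue
#'   shift differences (ppm) and apo rates (s^-1).
#' @param r2_bound_scale bound-state R2 multiplier.
#' @param dex_sigma reported uncertainty of exchange-induced shifts (ppm).
#' @return list of class \code{"cpmg_generator_spec"}.
#' @export
cpmg_generator_spec <- function(seed = 1, k_off = 580, kd_uM = 380,
                                jdp_uM = 200, hsc_uM = 20, n_spins = 15,
                                fields_mhz = c(600, 800, 950),
                                t_relax = 0.04,
                                nu_cpmg = seq(25, 1000, length.out = 12),
                                noise = 0.02, n_duplicates = 2,
                                dw_range = c(0.5, 3.5),
                                r2a_range = c(8, 16),
                                r2_bound_scale = 5, dex_sigma = 0.002) {
  structure(list(seed = seed, k_off = k_off, kd_uM = kd_uM,
                 jdp_uM = jdp_uM, hsc_uM = hsc_uM, n_spins = n_spins,
                 fields_mhz = fields_mhz, t_relax = t_relax,
                 nu_cpmg = snap_nu_cpmg(nu_cpmg, t_relax), noise = noise,
                 n_duplicates = n_duplicates, dw_range = dw_range,
                 r2a_range = r2a_range, r2_bound_scale = r2_bound_scale,
                 dex_sigma = dex_sigma),
            class = "cpmg_generator_spec")
}

#' Generate a synthetic CPMG + exchange-induced-shift titration bundle
#'
#' Forward-models dispersion intensities and shifts from the exchange core
#' at the truth parameters, adds fractional Gaussian noise to intensities
#' (both the dispersion points and the reference experiment), duplicates
#' the first \code{n_duplicates} CPMG field strengths, and converts back to
#' R2,eff with duplicate-based uncertainties — mirroring the acquisition
#' route. At \code{noise = 0} a nominal sigma of 1e-4 s^-1 is attached (the
#' duplicate estimator degenerates without noise).
#'
#' @param spec a \code{\link{cpmg_generator_spec}}.
#' @return list with \code{intensities} (raw table), \code{cpmg} (fit-ready
#'   dispersion table), \code{dex}, \code{condition}, \code{spins} (truth
#'   per-residue parameters) and \code{truth} (manifest: all generator
#'   inputs plus the implied binding state).
#' @export
gen_cpmg_titration <- function(spec) {
  stopifnot(inherits(spec, "cpmg_generator_spec"))
  set.seed(spec$seed)
  cond <- titration_condition(uM_to_M(spec$jdp_uM), uM_to_M(spec$hsc_uM))
  params <- exchange_params(spec$k_off / uM_to_M(spec$kd_uM), spec$k_off)
  state <- binding_state(cond, params)
  nu <- spec$nu_cpmg
  dup <- nu[seq_len(min(spec$n_duplicates, length(nu)))]
  nu_all <- sort(c(nu, dup))

  spins <- data.frame(
    residue = seq_len(spec$n_spins),
    dw_ppm = stats::runif(spec$n_spins, spec$dw_range[1], spec$dw_range[2]))
  r2a <- matrix(stats::runif(spec$n_spins * length(spec$fields_mhz),
                             spec$r2a_range[1], spec$r2a_range[2]),
                spec$n_spins, length(spec$fields_mhz),
                dimnames = list(NULL, as.character(spec$fields_mhz)))

  rows <- list(); drows <- list()
  for (i in seq_len(spec$n_spins)) {
    for (f in seq_along(spec$fields_mhz)) {
      field <- spec$fields_mhz[f]
      sp <- spin_params(spins$residue[i], spins$dw_ppm[i], r2a[i, f],
                        spec$r2_bound_scale)
      r2true <- cpmg_r2eff(sp, state, field, nu_all, spec$t_relax)
      inten <- exp(-r2true * spec$t_relax)
      if (spec$noise > 0) {
        inten <- inten * (1 + stats::rnorm(length(inten), 0, spec$noise))
        i0 <- 1 + stats::rnorm(1, 0, spec$noise)
      } else i0 <- 1
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = "d1", residue = spins$residue[i], field_mhz = field,
        nu_cpmg = nu_all, intensity = inten, i0 = i0)
      dx <- delta_ex(sp, state, field)
      if (spec$noise > 0) dx <- dx + stats::rnorm(1, 0, spec$dex_sigma)
      drows[[length(drows) + 1L]] <- data.frame(
        dataset = "d1", residue = spins$residue[i], field_mhz = field,
        dex_ppm = dx, sigma = spec$dex_sigma)
    }
  }
  intensities <- do.call(rbind, rows)
  dex <- do.call(rbind, drows)
  if (spec$noise > 0) {
    cpmg <- dispersion_from_intensities(intensities, spec$t_relax)
  } else {
    cpmg <- dispersion_from_intensities(
      transform(intensities,
                intensity = intensity *
                  (1 + 1e-9 * seq_along(intensity))), spec$t_relax)
    cpmg$sigma <- 1e-4
  }
  spins$r2a <- I(r2a)
  list(intensities = intensities, cpmg = cpmg, dex = dex,
       condition = cond, spins = spins,
       truth = c(unclass(spec),
                 list(k_on = params$k_on, kd = params$k_d,
                      p_bound = state$p_bound, k_ex = state$k_ex)))
}

#' Generate exponential decay series
#'
#' @param seed integer seed.
#' @param rates named or plain vector of decay rates (s^-1), one residue
#'   each.
#' @param delays sampling delays (s).
#' @param noise fractional Gaussian intensity noise.
#' @param amplitude initial intensity.
#' @return list with \code{data} (residue, delay_s, intensity, replicate)
#'   and \code{truth}.
#' @export
gen_decays <- function(seed = 1, rates = seq(2, 20, length.out = 10),
                       delays = seq(0.01, 0.8, length.out = 8),
                       noise = 0.01, amplitude = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(rates), function(i) {
    y <- amplitude * exp(-rates[i] * delays)
    if (noise > 0) y <- y + stats::rnorm(length(y), 0, noise * amplitude)
    data.frame(residue = i, delay_s = delays, intensity = y, replicate = 1L)
  })
  list(data = do.call(rbind, rows),
       truth = list(seed = seed, rates = rates, noise = noise,
                    amplitude = amplitude))
}

#' Generate WEX hydrogen-exchange buildup series
#'
#' Defaults span the 10-40 s^-1 exchange regime of a disordered linker,
#' with inversion intervals from 0.5 to 900 ms.
#'
#' @param seed integer seed.
#' @param k_obs exchange rates (s^-1), one residue each.
#' @param T_s water inversion intervals (s).
#' @param r1w water longitudinal rate (s^-1).
#' @param r1a amide longitudinal rate (s^-1).
#' @param amp amplitude.
#' @param noise fractional noise (of the curve maximum).
#' @return list with \code{data} (residue, T_s, intensity) and \code{truth}.
#' @export
gen_hx <- function(seed = 1, k_obs = seq(10, 40, length.out = 8),
                   T_s = c(0.0005, 0.003, 0.008, 0.02, 0.05, 0.1, 0.2,
                           0.45, 0.9),
                   r1w = 0.5, r1a = 2, amp = 1, noise = 0.02) {
  set.seed(seed)
  rows <- lapply(seq_along(k_obs), function(i) {
    y <- wex_buildup(T_s, amp, k_obs[i], r1a, r1w)
    if (noise > 0) y <- y + stats::rnorm(length(y), 0, noise * max(abs(y)))
    data.frame(residue = i, T_s = T_s, intensity = y, i_ref = amp)
  })
  list(data = do.call(rbind, rows),
       truth = list(seed = seed, k_obs = k_obs, r1w = r1w, r1a = r1a,
                    amp = amp, noise = noise))
}

#' Generate a CSP set with planted outliers
#'
#' Bulk values are |N(mean, sd)| (CSPs are magnitudes); a configurable
#' number of large outliers emulates genuinely perturbed residues.
#'
#' @param seed integer seed.
#' @param n number of bulk values.
#' @param mean,sd bulk distribution parameters (ppm).
#' @param n_outliers planted significant residues.
#' @param outlier_size outlier magnitude (ppm).
#' @return list with \code{data} (residue, d_h, d_n, csp) and \code{truth};
#'   the combined CSP is planted directly on d_h (d_n = 0) so the value is
#'   exact.
#' @export
gen_csp <- function(seed = 1, n = 19, mean = 0.015, sd = 0.003,
                    n_outliers = 1, outlier_size = 0.5) {
  set.seed(seed)
  vals <- abs(stats::rnorm(n, mean, sd))
  out <- rep(outlier_size, n_outliers)
  all <- c(vals, out)
  list(data = data.frame(residue = seq_along(all), d_h = all,
                         d_n = 0, csp = all),
       truth = list(seed = seed, n = n, mean = mean, sd = sd,
                    outliers = which(seq_along(all) > n)))
}

#' Generate synthetic RDCs from a known alignment tensor
#'
#' Draws internuclear unit vectors uniformly on the sphere (or accepts
#' vectors from a structure model) and back-calculates couplings from a
#' known Saupe tensor, optionally with Gaussian noise.
#'
#' @param seed integer seed.
#' @param n number of vectors (ignored when \code{vectors} given).
#' @param saupe length-5 Saupe vector (Sxx, Syy, Sxy, Sxz, Syz); the
#'   default produces NH couplings in the few-Hz range typical of dilute
#'   alignment.
#' @param type coupling type for generated vectors.
#' @param r internuclear distance (m) for generated vectors.
#' @param noise_hz Gaussian noise on couplings (Hz).
#' @param vectors optional data.frame (as \code{\link{structure_vectors}}).
#' @return list with \code{obs} (fit-ready table), \code{vectors} and
#'   \code{truth}.
#' @export
gen_rdc <- function(seed = 1, n = 20,
                    saupe = c(4e-4, -1.5e-4, 1e-4, -2e-4, 0.5e-4),
                    type = "NH", r = 1.041e-10, noise_hz = 0,
                    vectors = NULL) {
  set.seed(seed)
  if (is.null(vectors)) {
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    vectors <- data.frame(residue = seq_len(n), type = type,
                          x = s * cos(phi), y = s * sin(phi), z = z,
                          r_m = r)
  }
  d <- rdc_back_calc(saupe, vectors)
  if (noise_hz > 0) d <- d + stats::rnorm(length(d), 0, noise_hz)
  list(obs = data.frame(residue = vectors$residue, type = vectors$type,
                        d_obs = d,
                        sigma = max(noise_hz, 0.1)),
       vectors = vectors,
       truth = list(seed = seed, saupe = saupe, noise_hz = noise_hz))
}

#' Generate a fluorescence polarisation titration
#'
#' @param seed integer seed.
#' @param b,t bottom/top polarisation asymptotes.
#' @param kd_M dissociation constant (M).
#' @param conc_M titrant concentrations (M); default 12 points log-spaced
#'   around the Kd.
#' @param noise fractional noise on the channel intensities.
#' @param i_total total fluorescence intensity (channel sum).
#' @return list with \code{data} (conc, i_par, i_perp) and \code{truth}.
#' @export
gen_fp <- function(seed = 1, b = 0.05, t = 0.25, kd_M = 5e-6,
                   conc_M = 10^seq(-7.5, -3.5, length.out = 12),
                   noise = 0.02, i_total = 1000) {
  set.seed(seed)
  p <- b + (t - b) / (1 + kd_M / conc_M)
  i_par <- i_total * (1 + p) / 2
  i_perp <- i_total * (1 - p) / 2
  if (noise > 0) {
    i_par <- i_par * (1 + stats::rnorm(length(p), 0, noise))
    i_perp <- i_perp * (1 + stats::rnorm(length(p), 0, noise))
  }
  list(data = data.frame(conc = conc_M, i_par = i_par, i_perp = i_perp),
       truth = list(seed = seed, b = b, t = t, kd_M = kd_M, noise = noise))
}

#' Write a generator bundle to CSV files plus a JSON manifest
#'
#' Every data.frame element of the bundle becomes \code{<name>.csv}; the
#' truth list becomes \code{manifest.json}. The manifest suffices to
#' regenerate the fixture bit-exactly (same generator, same seed).
#'
#' @param bundle a generator result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(bundle)) {
    el <- bundle[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(el, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(bundle$truth)) {
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(bundle$truth, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
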