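make_state <- function(p_b, kex) {
  structure(list(p_bound = p_b, hsc_free = NA, k_on_app = p_b * kex,
                 k_off = (1 - p_b) * kex, k_ex = kex),
            class = "binding_state")
}

test_that("dispersion is flat without ligand", {
  sp <- spin_params(1, 2, 10)
  st <- binding_state(titration_condition(200e-6, 0),
                      exchange_params(1e6, 580))
  nu <- snap_nu_cpmg(seq(25, 1000, length.out = 12), 0.04)
  r2 <- cpmg_r2eff(sp, st, 600, nu)
  expect_lt(diff(range(r2)), 1e-10)
  expect_equal(r2[1], 10)
  expect_equal(carver_richards_r2eff(sp, st, 600, nu), rep(10, 12))
})

test_that("propagator matches brute-force ODE integration everywhere", {
  skip_if_not_installed("deSolve")
  nu <- c(25, 125, 500, 1000)
  dw <- ppm_to_rads(2, 600)
  cases <- list(c(ratio = 0.9, pb = 0.5),    # coalescence corner
                c(ratio = 0.1, pb = 0.3),    # slow exchange
                c(ratio = 6, pb = 0.05),     # fast exchange
                c(ratio = 0.8, pb = 0.034))  # study-like conditions
  for (cs in cases) {
    kex <- cs[["ratio"]] * dw
    st <- make_state(cs[["pb"]], kex)
    sp <- spin_params(1, 2, 10)
    bm <- cpmg_r2eff(sp, st, 600, nu)
    oracle <- ode_cpmg_r2eff(nu, 0.04, st$k_on_app, st$k_off, st$p_bound,
                             10, 50, dw)
    expect_equal(bm, oracle, tolerance = 1e-6)
  }
})

test_that("Carver-Richards agrees with propagation away from coalescence", {
  # a single-mode closed form describes the finite-T amplitude decay only
  # where one eigenmode dominates: skewed populations and kex not ~ dw
  # the finite-T amplitude correction scales as ~ pB (dw/kex)^2, so the
  # two routes coincide for skewed populations in fast exchange
  nu <- snap_nu_cpmg(seq(25, 1000, length.out = 12), 0.04)
  dw <- ppm_to_rads(2, 600)
  sp <- spin_params(1, 2, 10)
  grid <- rbind(expand.grid(ratio = c(4, 8, 12, 20), pb = c(0.01, 0.03)),
                data.frame(ratio = c(6, 8, 20), pb = 0.05))
  for (i in seq_len(nrow(grid))) {
    st <- make_state(grid$pb[i], grid$ratio[i] * dw)
    expect_lt(max(abs(cpmg_r2eff(sp, st, 600, nu) -
                        carver_richards_r2eff(sp, st, 600, nu))), 0.1)
  }
})

test_that("fast exchange reproduces the Luz-Meiboom closed form", {
  # equal intrinsic rates isolate the exchange contribution the closed
  # form describes
  kex <- 6000; dw <- 300; pb <- 0.05
  st <- make_state(pb, kex)
  sp <- spin_params(1, rads_to_ppm(dw, 600), 10, r2_bound_scale = 1)
  nu <- snap_nu_cpmg(seq(25, 1000, length.out = 15), 0.04)
  lm <- luz_meiboom_r2(nu, 10, pb, dw, kex)
  expect_lt(max(abs(cpmg_r2eff(sp, st, 600, nu) - lm)), 0.05)
})

test_that("no shift difference gives a flat population-averaged rate", {
  st <- make_state(0.05, 1000)
  sp <- spin_params(1, 0, 10)
  nu <- snap_nu_cpmg(c(50, 200, 800), 0.04)
  expect_equal(carver_richards_r2eff(sp, st, 600, nu),
               rep(0.95 * 10 + 0.05 * 50, 3))
  r2 <- cpmg_r2eff(sp, st, 600, nu)
  expect_lt(diff(range(r2)), 1e-6)
})

test_that("high-pulsing limit approaches the population average", {
  # fast exchange: R2,eff(nu -> inf) -> (1-pB) R2A + pB R2B
  st <- make_state(0.05, 6000)
  sp <- spin_params(1, 1, 10)
  r2_inf <- cpmg_r2eff(sp, st, 600, 4000, 0.04)
  expect_equal(r2_inf, 0.95 * 10 + 0.05 * 50, tolerance = 0.02)
})

test_that("exchange contribution is non-negative and vanishes correctly", {
  nu_lo <- 25; nu_hi <- 2000
  dw600 <- ppm_to_rads(2, 600)
  for (ratio in c(0.2, 1, 5, 15)) {
    for (pb in c(0.02, 0.1, 0.4)) {
      st <- make_state(pb, ratio * dw600)
      sp <- spin_params(1, 2, 10)
      r2 <- cpmg_r2eff(sp, st, 600, c(nu_lo, nu_hi), 0.04)
      expect_gte(r2[1] - r2[2], -1e-8)
    }
  }
  st <- make_state(0, 600)
  sp <- spin_params(1, 2, 10)
  expect_equal(diff(cpmg_r2eff(sp, st, 600, c(nu_lo, nu_hi), 0.04)), 0)
})

test_that("low-nu exchange contribution scales with the square of the field", {
  # fast limit, dw fixed in ppm: R_ex ~ pA pB dw_rad^2 / kex ~ field^2
  pb <- 0.03; kex <- 30000
  st <- make_state(pb, kex)
  sp <- spin_params(1, 2, 10)
  rex <- vapply(c(600, 800), function(f) {
    r2 <- cpmg_r2eff(sp, st, f, c(25, 2000), 0.04)
    r2[1] - r2[2]
  }, 1)
  expect_equal(rex[2] / rex[1], (800 / 600)^2, tolerance = 0.02)
})

test_that("nu_cpmg snapping enforces the even-echo constraint", {
  nu <- snap_nu_cpmg(c(33, 100.2, 999), 0.04)
  expect_true(all(abs(nu * 0.04 - round(nu * 0.04)) < 1e-9))
  sp <- spin_params(1, 2, 10)
  st <- make_state(0.03, 600)
  expect_error(cpmg_r2eff(sp, st, 600, 33, 0.04), "nearest valid")
})

test_that("exchange-induced shift obeys its limits", {
  sp <- spin_params(1, 2, 10)
  # no bound state, no shift
  expect_equal(delta_ex(sp, make_state(0, 600), 600), 0)
  # fast limit: population-weighted average pB * dw
  dw <- ppm_to_rads(2, 600)
  st_fast <- make_state(0.05, 40 * dw)
  expect_equal(delta_ex(sp, st_fast, 600), 0.05 * 2, tolerance = 0.01)
  # sign follows the sign of dw
  sp_neg <- spin_params(1, -2, 10)
  expect_lt(delta_ex(sp_neg, st_fast, 600), 0)
  # bounded by |pB dw| in the fast regime, approached monotonically
  ratios <- c(2, 4, 8, 16, 32, 64)
  dex <- vapply(ratios, function(r)
    delta_ex(sp, make_state(0.05, r * dw), 600), 1)
  expect_true(all(dex <= 0.05 * 2 + 1e-12))
  expect_true(all(diff(dex) > 0))
})

test_that("exchange-induced shift matches the FID lineshape oracle", {
  dw <- ppm_to_rads(2, 600)
  # study-like intermediate point plus a sweep over the dilute-bound
  # regime in which an exchange-induced shift is the relevant observable
  cases <- rbind(c(600.2, 0.0337), expand.grid(kex = dw * c(1.5, 3, 8, 20),
                                               pb = c(0.02, 0.06, 0.1)))
  for (i in seq_len(nrow(cases))) {
    kex <- cases[i, 1]; pb <- cases[i, 2]
    st <- make_state(pb, kex)
    sp <- spin_params(1, 2, 10)
    dex <- delta_ex(sp, st, 600)
    oracle <- rads_to_ppm(
      fid_delta_ex(st$k_on_app, st$k_off, pb, 10, 50, dw), 600)
    expect_equal(dex, oracle, tolerance = 5e-3)
    expect_gt(dex, 0)
    expect_lt(dex, pb * 2)
  }
})

test_that("ppm/rad conversion is self-consistent and field-linear", {
  expect_equal(rads_to_ppm(ppm_to_rads(3.2, 800), 800), 3.2)
  expect_equal(ppm_to_rads(1, 800) / ppm_to_rads(1, 600), 800 / 600)
})
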