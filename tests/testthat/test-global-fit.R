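test_that("R2,eff extraction from intensities is exact", {
  expect_equal(r2eff_from_intensities(0.5, 1, 0.04), log(2) / 0.04)
  expect_equal(r2eff_from_intensities(1, 1, 0.04), 0)
  expect_message(out <- r2eff_from_intensities(c(0.5, -0.1), 1, 0.04),
                 "dropped")
  expect_true(is.na(out[2]) && is.finite(out[1]))
  expect_error(r2eff_from_intensities(0.5, 0, 0.04), "positive")
})

test_that("duplicate-difference sigma matches the pooled estimator", {
  nu <- c(50, 50, 100, 100, 200)
  r2 <- c(10.2, 10.6, 9.1, 8.9, 8.0)
  d <- c(10.6 - 10.2, 8.9 - 9.1)
  expect_equal(sigma_from_duplicates(r2, nu), sqrt(sum(d^2) / 4))
  expect_true(is.na(sigma_from_duplicates(c(1, 2), c(50, 100))))
})

test_that("intensity tables convert to fit-ready dispersion curves", {
  g <- gen_cpmg_titration(cpmg_generator_spec(seed = 3, n_spins = 2,
                                              fields_mhz = 600))
  curves <- dispersion_from_intensities(g$intensities, 0.04)
  expect_true(all(c("r2eff", "sigma") %in% names(curves)))
  expect_true(all(curves$sigma > 0))
  # duplicates averaged away: one row per nu per curve
  key <- paste(curves$residue, curves$field_mhz)
  expect_true(all(tapply(curves$nu_cpmg, key,
                         function(x) !any(duplicated(x)))))
})

test_that("noiseless data are refit to the generating truth", {
  sf <- small_fit_problem(seed = 7, n_spins = 5, fields = c(600, 800),
                          noise = 0)
  fit <- fit_global(sf$prob, init = list(k_on = 1e6, k_off = 500))
  expect_true(fit$converged)
  expect_equal(fit$params$k_off, 580, tolerance = 1e-3)
  expect_equal(fit$params$k_d, 380e-6, tolerance = 1e-3)
  # per-residue shift differences recovered too
  expect_equal(fit$per_spin$dw_ppm, sf$gen$spins$dw_ppm, tolerance = 1e-3)
})

test_that("reported k_ex is exactly the binding-state value", {
  sf <- small_fit_problem(seed = 5, n_spins = 3, fields = 600, noise = 0)
  fit <- fit_global(sf$prob, init = list(k_on = 1e6, k_off = 500))
  st <- binding_state(sf$prob$conditions$d1, fit$exchange)
  expect_identical(fit$states$d1$k_ex, st$k_ex)
  expect_identical(fit$params$k_d, fit$params$k_off / fit$params$k_on)
})

test_that("fit is invariant to the ordering of the input rows", {
  sf <- small_fit_problem(seed = 9, n_spins = 3, fields = 600,
                          noise = 0.02)
  fit1 <- fit_global(sf$prob, init = list(k_on = 1e6, k_off = 500))
  perm <- sample(nrow(sf$gen$cpmg))
  prob2 <- fit_problem(sf$gen$cpmg[perm, ], sf$gen$condition,
                       dex = sf$gen$dex)
  fit2 <- fit_global(prob2, init = list(k_on = 1e6, k_off = 500))
  expect_equal(fit1$params$k_off, fit2$params$k_off, tolerance = 1e-6)
  expect_equal(fit1$params$k_on, fit2$params$k_on, tolerance = 1e-6)
})

test_that("a problem with no shift differences is flagged non-identifiable", {
  g <- gen_cpmg_titration(cpmg_generator_spec(
    seed = 2, n_spins = 3, fields_mhz = 600, noise = 0.01,
    dw_range = c(0, 0)))
  prob <- fit_problem(g$cpmg, g$condition, dex = g$dex)
  fit <- fit_global(prob, init = list(k_on = 1e6, k_off = 500))
  expect_true("non_identifiable" %in% fit$flags)
})

test_that("convergence grid brackets the optimum", {
  sf <- small_fit_problem(seed = 13, n_spins = 4, fields = c(600, 800),
                          noise = 0.02)
  fit <- fit_global(sf$prob, init = list(k_on = 1e6, k_off = 500))
  # degenerate single-node grid reproduces the best chi2
  g0 <- convergence_grid(sf$prob, fit, span = 0, steps = 1)
  expect_equal(nrow(g0), 1L)
  expect_equal(g0$chi2, fit$chi2, tolerance = 1e-3)
  # small surface: minimum at (or adjacent to) the central node
  g1 <- convergence_grid(sf$prob, fit, span = 0.2, steps = 3)
  expect_equal(nrow(g1), 9L)
  centre <- which(abs(log10(g1$k_on / fit$params$k_on)) < 1e-9 &
                    abs(log10(g1$k_off / fit$params$k_off)) < 1e-9)
  expect_lte(g1$chi2[centre], min(g1$chi2) + 0.05 * abs(min(g1$chi2)) + 1)
})

test_that("fit problems are validated on assembly", {
  g <- gen_cpmg_titration(cpmg_generator_spec(seed = 1, n_spins = 2,
                                              fields_mhz = 600))
  bad <- g$cpmg
  bad$sigma[1] <- -1
  expect_error(fit_problem(bad, g$condition), "positive sigma")
  one_pt <- g$cpmg[!duplicated(paste(g$cpmg$residue, g$cpmg$field_mhz)), ]
  expect_error(fit_problem(one_pt, g$condition), "at least 2")
  expect_error(fit_problem(g$cpmg, list(other = g$condition)),
               "condition")
})
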