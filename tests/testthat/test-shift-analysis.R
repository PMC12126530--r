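test_that("combined CSP follows the weighted quadrature formula", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(0.1, 0.5), sqrt(0.01 + 0.01))
  expect_equal(combined_csp(0, 1), 0.2)
  expect_true(all(combined_csp(rnorm(10), rnorm(10)) >= 0))
})

test_that("iterative trimming removes planted outliers", {
  g <- gen_csp(seed = 21, n = 19, mean = 0.015, sd = 0.003,
               n_outliers = 1, outlier_size = 0.5)
  vals <- g$data$csp
  cs <- corrected_sd_cutoff(vals)
  # the 0.5 ppm outlier is trimmed in the first pass
  expect_false(0.5 %in% cs$kept)
  expect_true(cs$significant[g$truth$outliers])
  # brute-force replication of the iterative procedure
  keep <- vals
  repeat {
    drop <- keep > mean(keep) + 3 * sd(keep)
    if (!any(drop)) break
    keep <- keep[!drop]
  }
  expect_equal(sort(cs$kept), sort(keep))
  expect_equal(cs$sigma_corr, sqrt(mean(keep^2)))
  expect_equal(cs$cutoff, 2 * sqrt(mean(keep^2)))
})

test_that("a clean set is returned unchanged in one pass", {
  g <- gen_csp(seed = 8, n = 20, n_outliers = 0)
  vals <- g$data$csp
  cs <- corrected_sd_cutoff(vals)
  expect_equal(length(cs$kept), length(vals))
  expect_equal(cs$n_iter, 1L)
  expect_equal(cs$sigma_corr, sqrt(mean(vals^2)))
  # about-mean convention gives the plain standard deviation
  cs_m <- corrected_sd_cutoff(vals, final_about = "mean")
  expect_equal(cs_m$sigma_corr, sd(vals))
})

test_that("the cutoff is idempotent and permutation invariant", {
  g <- gen_csp(seed = 5, n = 25, n_outliers = 2)
  vals <- g$data$csp
  cs <- corrected_sd_cutoff(vals)
  again <- corrected_sd_cutoff(cs$kept)
  expect_equal(again$sigma_corr, cs$sigma_corr)
  expect_equal(length(again$kept), length(cs$kept))

  perm <- sample(seq_along(vals))
  cs_p <- corrected_sd_cutoff(vals[perm])
  expect_setequal(perm[which(cs_p$significant)], which(cs$significant))
})

test_that("degenerate identical values are flagged", {
  cs <- corrected_sd_cutoff(rep(0.02, 6))
  expect_true(cs$degenerate)
  expect_equal(cs$cutoff, 0)
  expect_false(any(cs$significant))
})

test_that("csp_table flags residues above twice the corrected SD", {
  g <- gen_csp(seed = 12, n = 19, n_outliers = 1)
  tab <- csp_table(data.frame(residue = g$data$residue, d_h = g$data$d_h,
                              d_n = g$data$d_n))
  expect_true(tab$significant[g$truth$outliers])
  expect_equal(attr(tab, "cutoff")$cutoff,
               corrected_sd_cutoff(tab$csp)$cutoff)
})

test_that("open-state populations interpolate peak positions", {
  df <- data.frame(residue = 1, delta_closed = 120, delta_open = 118,
                   delta_obs = 119.2)
  expect_equal(open_population(df)$p_open, 0.4, tolerance = 1e-10)
  df$delta_obs <- 120
  expect_equal(open_population(df)$p_open, 0)
  df$delta_obs <- 118
  expect_equal(open_population(df)$p_open, 1)
})

test_that("populations are exact on noiseless two-state shifts", {
  set.seed(31)
  p_true <- 0.7
  closed <- runif(6, 110, 125)
  open <- closed + runif(6, 0.5, 2.5) * sample(c(-1, 1), 6, TRUE)
  df <- data.frame(residue = 1:6, delta_closed = closed,
                   delta_open = open,
                   delta_obs = closed + p_true * (open - closed))
  out <- open_population(df)
  expect_equal(out$p_open, p_true, tolerance = 1e-10)
  expect_true(all(out$per_residue$used))
})

test_that("residues below the separation floor are excluded", {
  df <- data.frame(residue = 1:2, delta_closed = c(120, 120),
                   delta_open = c(118, 120.01),
                   delta_obs = c(119.2, 120.005))
  expect_message(out <- open_population(df), "excluded")
  expect_false(out$per_residue$used[2])
  expect_equal(out$p_open, 0.4, tolerance = 1e-10)
  expect_error(open_population(df[2, ]), "noise floor")
})

test_that("fast-limit exchange rates follow p(1-p) dw^2 / Rex", {
  expect_equal(kex_from_rex(0.7, 1000, 10), 21000)
  expect_error(kex_from_rex(0.5, 1000, 0), "positive")
  expect_error(kex_from_rex(0.5, 1000, -3), "positive")
  # Rex -> large drives the estimate towards zero
  expect_lt(kex_from_rex(0.5, 1000, 1e6), 1)
})

test_that("simulated fast-exchange Rex round-trips the generating k_ex", {
  kex_true <- 20000; p <- 0.3
  dw <- ppm_to_rads(2.5, 600)
  st <- structure(list(p_bound = p, k_on_app = p * kex_true,
                       k_off = (1 - p) * kex_true, k_ex = kex_true),
                  class = "binding_state")
  sp <- spin_params(1, 2.5, 10, r2_bound_scale = 1)
  # exchange contribution: low-pulsing rate minus the exchange-free
  # population average (here R2A = R2B = 10)
  rex <- cpmg_r2eff(sp, st, 600, 25, 0.04) - 10
  expect_equal(kex_from_rex(p, dw, rex), kex_true, tolerance = 0.1)
})
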