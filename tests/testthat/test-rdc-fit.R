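test_that("a known tensor is recovered exactly from noiseless couplings", {
  g <- gen_rdc(seed = 3, n = 12)
  fit <- svd_fit_tensor(g$obs, vectors = g$vectors)
  expect_equal(fit$tensor$saupe, g$truth$saupe, tolerance = 1e-10)
  expect_lt(fit$r_factor, 1e-8)
  expect_equal(fit$table$d_calc, fit$table$d_obs, tolerance = 1e-10)
  # residuals orthogonal to the design by construction
  expect_equal(sum(fit$table$residual * fit$table$d_calc), 0,
               tolerance = 1e-8)
})

test_that("a zero tensor back-calculates zero everywhere", {
  g <- gen_rdc(seed = 4, n = 8, saupe = rep(0, 5))
  expect_equal(rdc_back_calc(rep(0, 5), g$vectors), rep(0, 8))
})

test_that("the tensor matrix is symmetric and traceless", {
  g <- gen_rdc(seed = 10, n = 15)
  fit <- svd_fit_tensor(g$obs, vectors = g$vectors)
  S <- fit$tensor$matrix
  expect_equal(S, t(S))
  expect_equal(sum(diag(S)), 0, tolerance = 1e-15)
  expect_equal(sum(fit$tensor$eigenvalues), 0, tolerance = 1e-12)
})

test_that("noisy couplings recover the axial component within Monte-Carlo error", {
  truth <- gen_rdc(seed = 1, n = 40)$truth$saupe
  ax <- replicate(60, {
    g <- gen_rdc(seed = sample.int(1e6, 1), n = 40, saupe = truth,
                 noise_hz = 1)
    svd_fit_tensor(g$obs, vectors = g$vectors)$tensor$axial
  })
  ax_true <- svd_fit_tensor(gen_rdc(seed = 2, n = 40, saupe = truth)$obs,
                            vectors = gen_rdc(seed = 2, n = 40,
                                              saupe = truth)$vectors
                            )$tensor$axial
  expect_lt(abs(mean(ax) - ax_true), 3 * sd(ax) / sqrt(length(ax)) +
              0.02 * abs(ax_true))
  # couplings in the few-Hz range imply weak alignment
  expect_lt(abs(ax_true), 1e-2)
})

test_that("the fit is invariant under a global rotation", {
  g <- gen_rdc(seed = 6, n = 20)
  th <- 0.7; ph <- 1.2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  R <- Rx %*% Rz
  v <- as.matrix(g$vectors[, c("x", "y", "z")]) %*% t(R)
  vr <- g$vectors
  vr$x <- v[, 1]; vr$y <- v[, 2]; vr$z <- v[, 3]
  f0 <- svd_fit_tensor(g$obs, vectors = g$vectors)
  f1 <- svd_fit_tensor(g$obs, vectors = vr)
  expect_equal(f1$r_factor, f0$r_factor, tolerance = 1e-8)
  expect_equal(f1$tensor$eigenvalues, f0$tensor$eigenvalues,
               tolerance = 1e-8)
})

test_that("degenerate designs are rejected with a condition number", {
  v <- data.frame(residue = 1:6, type = "NH", x = 1, y = 0, z = 0,
                  r_m = 1.041e-10)
  obs <- data.frame(residue = 1:6, type = "NH", d_obs = rnorm(6))
  expect_error(svd_fit_tensor(obs, vectors = v), "ill-conditioned")
  expect_error(svd_fit_tensor(obs[1:4, ],
                              vectors = gen_rdc(seed = 1, n = 6)$vectors),
               "at least 5")
})

test_that("the Clore-Garrett R-factor has its closed-form landmarks", {
  d <- c(-5, 2, 8, -3, 11)
  expect_equal(r_factor(d, d), 0)
  expect_equal(r_factor(d, rep(0, 5)), 100 / sqrt(2))
  expect_equal(r_factor(3 * d, 3 * d * 0.9), r_factor(d, d * 0.9))
  expect_error(r_factor(rep(0, 4), rep(0, 4)), "zero mean-square")
  # supplied expected mean-square changes only the normalisation
  expect_equal(r_factor(d, d * 0.9, ms_expected = 2 * mean(d^2)),
               r_factor(d, d * 0.9) / sqrt(2))
})

test_that("selection strings expand ranges and exclusions", {
  expect_equal(parse_selection("1-5"), 1:5)
  expect_equal(parse_selection("1-75,100-105!48,57,58,68,69"),
               setdiff(c(1:75, 100:105), c(48, 57, 58, 68, 69)))
  expect_null(parse_selection(NULL))
})

test_that("vectors and couplings come from PDB coordinates", {
  pdb <- file.path(tempdir(), "mini.pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       0.000   0.000   1.020  1.00  0.00           H",
    "ATOM      3  C   ALA A   1       1.400   0.000   0.500  1.00  0.00           C",
    "ATOM      4  N   ALA A   2       2.000   1.000   0.000  1.00  0.00           N",
    "ATOM      5  H   ALA A   2       2.000   2.020   0.000  1.00  0.00           H",
    "ATOM      6  C   ALA A   2       3.400   1.000   0.500  1.00  0.00           C",
    "ATOM      7  N   ALA A   3       4.000   2.000   0.000  1.00  0.00           N",
    "ATOM      8  H   ALA A   3       5.020   2.000   0.000  1.00  0.00           H",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1      99.000  99.000  99.000  1.00  0.00           N",
    "ENDMDL",
    "END"), pdb)
  model <- read_structure(pdb)
  # first model only
  expect_equal(model$atoms$x[1], 0)
  v <- structure_vectors(model, "NH")
  expect_equal(nrow(v), 3)
  expect_equal(v$x^2 + v$y^2 + v$z^2, rep(1, 3), tolerance = 1e-12)
  expect_equal(v$r_m, rep(1.02e-10, 3), tolerance = 1e-6)
  # two-bond vectors need the preceding carbonyl
  v2 <- structure_vectors(model, "CH")
  expect_equal(v2$residue, 2:3)
  # distance override
  v3 <- structure_vectors(model, "NH", r_override = 1.041e-10)
  expect_equal(v3$r_m, rep(1.041e-10, 3))
  # residue selection
  expect_equal(structure_vectors(model, "NH", residues = c(1, 3))$residue,
               c(1, 3))
})
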