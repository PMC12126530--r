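# Independent oracles used to cross-check the analytic implementations.

# mass-action equilibrium bound fraction by fixed-point iteration of
# p = hsc_free / (kd + hsc_free)
fixed_point_pbound <- function(jdp, hsc, kd, tol = 1e-14, maxit = 200000) {
  # step size chosen from the worst-case map slope ~ jdp/kd so the damped
  # iteration contracts even for tight binding
  alpha <- 1 / (1 + jdp / kd)
  p <- 0
  for (i in seq_len(maxit)) {
    hf <- max(hsc - p * jdp, 0)
    step <- hf / (kd + hf) - p
    if (abs(step) < tol) return(p)
    p <- p + alpha * step
  }
  p
}

# Luz-Meiboom fast-exchange closed form (single intrinsic R2)
luz_meiboom_r2 <- function(nu, r2bar, p_b, dw, kex) {
  p_a <- 1 - p_b
  r2bar + (p_a * p_b * dw^2 / kex) *
    (1 - (4 * nu / kex) * tanh(kex / (4 * nu)))
}

# brute-force CPMG R2,eff: numerical ODE integration of the two-site
# Bloch-McConnell equations with explicit conjugation at each 180 pulse
ode_cpmg_r2eff <- function(nu, t_relax, kon_app, koff, pb, r2a, r2b, dw) {
  sapply(nu, function(v) {
    tau <- 1 / (4 * v)
    n_units <- round(2 * t_relax * v)
    deriv <- function(t, y, p) {
      A <- complex(real = y[1], imaginary = y[2])
      B <- complex(real = y[3], imaginary = y[4])
      dA <- (-r2a - kon_app) * A + koff * B
      dB <- kon_app * A + (-r2b - koff + 1i * dw) * B
      list(c(Re(dA), Im(dA), Re(dB), Im(dB)))
    }
    y <- c(1 - pb, 0, pb, 0)
    for (k in seq_len(n_units)) {
      y <- deSolve::ode(y, c(0, tau), deriv, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)[2, -1]
      y[c(2, 4)] <- -y[c(2, 4)]
      y <- deSolve::ode(y, c(0, tau), deriv, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)[2, -1]
    }
    unname(-log(sqrt(y[1]^2 + y[2]^2) / (1 - pb)) / t_relax)
  }, USE.NAMES = FALSE)
}

# dense FID simulation of the free-precession signal followed by Fourier
# peak picking (parabolic interpolation); returns the observed-line shift
# from the apo frequency in rad/s
fid_delta_ex <- function(kon_app, koff, pb, r2a, r2b, dw,
                         n = 2^17, sw_factor = 8) {
  L <- matrix(c(complex(real = -r2a - kon_app), complex(real = kon_app),
                complex(real = koff),
                complex(real = -r2b - koff, imaginary = dw)), 2, 2)
  m0 <- c(1 - pb, pb)
  eg <- eigen(L)
  amp <- colSums(eg$vectors) * solve(eg$vectors, m0)
  sw <- max((abs(dw) + kon_app + koff) / (2 * pi), 50) * sw_factor
  dt <- 1 / sw
  t <- (0:(n - 1)) * dt
  s <- amp[1] * exp(eg$values[1] * t) + amp[2] * exp(eg$values[2] * t)
  S <- Mod(stats::fft(s))
  i <- which.max(S)
  ip <- if (i == n) 1 else i + 1
  im <- if (i == 1) n else i - 1
  denom <- S[im] - 2 * S[i] + S[ip]
  frac <- if (denom != 0) 0.5 * (S[im] - S[ip]) / denom else 0
  k <- (i - 1) + frac
  f <- k / (n * dt)
  if (f > sw / 2) f <- f - sw
  2 * pi * f
}

# shared quick generator for small fit problems
small_fit_problem <- function(seed = 7, n_spins = 5,
                              fields = c(600, 800), noise = 0) {
  g <- gen_cpmg_titration(cpmg_generator_spec(
    seed = seed, n_spins = n_spins, fields_mhz = fields, noise = noise))
  list(gen = g, prob = fit_problem(g$cpmg, g$condition, dex = g$dex))
}
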