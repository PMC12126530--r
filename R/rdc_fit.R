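# Alignment-tensor fitting of residual dipolar couplings by singular value
# decomposition. Observed couplings are linear in the five independent
# Saupe components:
#   D = Dmax(r) * [ Sxx (x^2 - z^2) + Syy (y^2 - z^2)
#                   + 2 Sxy xy + 2 Sxz xz + 2 Syz yz ]
# with (x, y, z) the internuclear unit vector in the molecular frame and
# Dmax(r) = -mu0 h gamma_i gamma_j / (16 pi^3 r^3) in Hz.

.mu0 <- 4e-7 * pi
.h_planck <- 6.62607015e-34
.gyro <- c(H = 2.6752218744e8, N = -2.71261804e7, C = 6.728284e7)

#' Maximum dipolar coupling for a nuclear pair
#'
#' @param pair two-letter code of the coupled nuclei: \code{"NH"} (amide
#'   one-bond) or \code{"CH"} (two-bond C'(i-1)-HN(i)).
#' @param r internuclear distance (m).
#' @return static dipolar coupling constant (Hz) in the Saupe convention
#'   \eqn{D = D_{max} \sum S_{ij} c_i c_j}.
#' @export
rdc_dmax <- function(pair = c("NH", "CH"), r) {
  pair <- match.arg(pair)
  g <- if (pair == "NH") .gyro["N"] * .gyro["H"] else .gyro["C"] * .gyro["H"]
  unname(-.mu0 * .h_planck * g / (16 * pi^3 * r^3))
}

# n x 5 design matrix from unit-vector components
.rdc_design <- function(x, y, z) {
  cbind(x^2 - z^2, y^2 - z^2, 2 * x * y, 2 * x * z, 2 * y * z)
}

#' Parse a residue-selection string
#'
#' Format: comma-separated ranges, with exclusions after \code{"!"}, e.g.
#' \code{"1-75,100-105!48,57,58,68,69"}.
#'
#' @param sel selection string, or NULL for no restriction.
#' @return integer vector of selected residues, or NULL.
#' @export
parse_selection <- function(sel) {
  if (is.null(sel) || !nzchar(sel)) return(NULL)
  parts <- strsplit(sel, "!", fixed = TRUE)[[1]]
  expand <- function(s) {
    unlist(lapply(strsplit(s, ",")[[1]], function(tok) {
      tok <- trimws(tok)
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        seq(ab[1], ab[2])
      } else as.integer(tok)
    }))
  }
  inc <- expand(parts[1])
  if (length(parts) > 1) inc <- setdiff(inc, expand(parts[2]))
  sort(unique(inc))
}

#' Internuclear vectors for RDC back-calculation from coordinates
#'
#' Extracts per-residue unit vectors and distances from a structure model:
#' N-H(N) for one-bond amide couplings, C'(i-1)-H(N)(i) for the two-bond
#' carbonyl-proton coupling.
#'
#' @param model a structure model from \code{\link{read_structure}}.
#' @param type \code{"NH"} or \code{"CH"}.
#' @param residues optional integer vector restricting the residues.
#' @param r_override optional fixed internuclear distance (m) replacing the
#'   coordinate-derived one (e.g. the effective 1.041 Angstrom N-H length).
#' @return data.frame with columns \code{residue}, \code{type}, \code{x},
#'   \code{y}, \code{z} (unit-vector components), \code{r_m}.
#' @export
structure_vectors <- function(model, type = c("NH", "CH"), residues = NULL,
                              r_override = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  h_names <- c("H", "HN")
  pick <- function(resno, elety) {
    i <- which(at$resno == resno & at$elety %in% elety)
    if (!length(i)) return(NULL)
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  res <- sort(unique(at$resno))
  if (!is.null(residues)) res <- intersect(res, residues)
  rows <- lapply(res, function(rn) {
    h <- pick(rn, h_names)
    a <- if (type == "NH") pick(rn, "N") else pick(rn - 1, "C")
    if (is.null(h) || is.null(a)) return(NULL)
    v <- h - a
    r_ang <- sqrt(sum(v^2))
    if (r_ang < 1e-6) return(NULL)
    u <- v / r_ang
    r_m <- if (is.null(r_override)) r_ang * 1e-10 else r_override
    data.frame(residue = rn, type = type, x = u[1], y = u[2], z = u[3],
               r_m = r_m)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("no usable ", type, " vectors found in the model", call. = FALSE)
  rownames(out) <- NULL
  out
}

.tensor_from_saupe <- function(s) {
  S <- matrix(c(s[1], s[3], s[4],
                s[3], s[2], s[5],
                s[4], s[5], -s[1] - s[2]), 3, 3)
  e <- eigen(S, symmetric = TRUE)
  o <- order(abs(e$values))          # |Sxx'| <= |Syy'| <= |Szz'|
  vals <- e$values[o]
  vecs <- e$vectors[, o]
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  axial <- vals[3]
  rhombic <- (2 / 3) * (vals[1] - vals[2])
  # ZYZ Euler angles of the principal-axis frame
  beta <- acos(pmin(pmax(vecs[3, 3], -1), 1))
  alpha <- atan2(vecs[2, 3], vecs[1, 3])
  gamma <- atan2(vecs[3, 2], -vecs[3, 1])
  structure(list(saupe = s, matrix = S, eigenvalues = vals,
                 eigenvectors = vecs, axial = axial, rhombic = rhombic,
                 rhombicity = if (axial != 0) rhombic / axial else NA_real_,
                 euler_deg = c(alpha = alpha, beta = beta, gamma = gamma) *
                   180 / pi),
            class = "alignment_tensor")
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat("Alignment tensor (Saupe):\n")
  cat(sprintf("  eigenvalues: %s\n",
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  cat(sprintf("  axial = %.4g, rhombic = %.4g (rhombicity %.3g)\n",
              x$axial, x$rhombic, x$rhombicity))
  cat(sprintf("  Euler ZYZ (deg): %s\n",
              paste(signif(x$euler_deg, 4), collapse = ", ")))
  invisible(x)
}

#' Fit the alignment tensor to observed RDCs by SVD
#'
#' Linear least-squares solution (via singular value decomposition, with
#' optional error weighting) of the five Saupe components from observed
#' couplings and internuclear vectors, either coordinate-derived or supplied
#' directly. Residuals are orthogonal to the design columns by construction.
#'
#' @param obs data.frame with columns \code{residue}, \code{type}
#'   (\code{"NH"}/\code{"CH"}), \code{d_obs} (Hz) and optionally
#'   \code{sigma} (Hz).
#' @param model a structure model (see \code{\link{read_structure}});
#'   ignored when \code{vectors} is given.
#' @param vectors optional data.frame as returned by
#'   \code{\link{structure_vectors}}.
#' @param selection optional selection string (see
#'   \code{\link{parse_selection}}).
#' @param weighted use 1/sigma weights in the least squares (default FALSE,
#'   plain least squares).
#' @param r_nh optional effective N-H distance override (m), e.g.
#'   \code{1.041e-10}.
#' @param max_condition condition-number limit of the design matrix beyond
#'   which the problem is declared ill-conditioned.
#' @return list of class \code{"rdc_fit"}: \code{tensor}
#'   (\code{alignment_tensor}), \code{table} (per-observation d_obs/d_calc),
#'   \code{r_factor} (percent, all observations), \code{r_factor_by_type},
#'   \code{condition}, \code{n}.
#' @export
svd_fit_tensor <- function(obs, model = NULL, vectors = NULL,
                           selection = NULL, weighted = FALSE, r_nh = NULL,
                           max_condition = 1e8) {
  stopifnot(all(c("residue", "type", "d_obs") %in% names(obs)))
  sel <- if (is.character(selection)) parse_selection(selection) else
    selection
  if (is.null(vectors)) {
    if (is.null(model)) stop("supply either a model or vectors",
                             call. = FALSE)
    vecs <- list()
    for (tp in unique(obs$type))
      vecs[[tp]] <- structure_vectors(model, tp, residues = sel,
                                      r_override = if (tp == "NH") r_nh)
    vectors <- do.call(rbind, vecs)
  }
  if (!is.null(sel)) obs <- obs[obs$residue %in% sel, ]
  key_o <- paste(obs$residue, obs$type)
  key_v <- paste(vectors$residue, vectors$type)
  m <- match(key_o, key_v)
  missing <- is.na(m)
  if (any(missing))
    stop("no vector for observation(s): ",
         paste(key_o[missing], collapse = "; "), call. = FALSE)
  v <- vectors[m, ]
  if (nrow(obs) < 5)
    stop("need at least 5 observations to determine the tensor",
         call. = FALSE)
  dmax <- vapply(seq_len(nrow(v)), function(i)
    rdc_dmax(v$type[i], v$r_m[i]), 1)
  A <- .rdc_design(v$x, v$y, v$z) * dmax
  b <- obs$d_obs
  w <- if (weighted) {
    if (is.null(obs$sigma) || any(obs$sigma <= 0))
      stop("weighted fit needs positive sigma for every observation",
           call. = FALSE)
    1 / obs$sigma
  } else rep(1, length(b))
  sv <- svd(A * w)
  cond <- sv$d[1] / sv$d[length(sv$d)]
  if (!is.finite(cond) || cond > max_condition)
    stop(sprintf(
      "ill-conditioned RDC design (condition number %.3g): vectors are too collinear",
      cond), call. = FALSE)
  s <- sv$v %*% (crossprod(sv$u, b * w) / sv$d)
  d_calc <- as.numeric(A %*% s)
  tab <- data.frame(residue = obs$residue, type = obs$type,
                    d_obs = b, d_calc = d_calc, residual = b - d_calc)
  rby <- vapply(split(tab, tab$type), function(g)
    r_factor(g$d_obs, g$d_calc), 1)
  structure(list(tensor = .tensor_from_saupe(as.numeric(s)), table = tab,
                 r_factor = r_factor(b, d_calc), r_factor_by_type = rby,
                 condition = cond, n = nrow(obs)),
            class = "rdc_fit")
}

#' Back-calculate RDCs from a tensor and vectors
#'
#' @param tensor an \code{alignment_tensor} or a length-5 Saupe vector.
#' @param vectors data.frame as from \code{\link{structure_vectors}}.
#' @return back-calculated couplings (Hz).
#' @export
rdc_back_calc <- function(tensor, vectors) {
  s <- if (inherits(tensor, "alignment_tensor")) tensor$saupe else tensor
  stopifnot(length(s) == 5)
  dmax <- vapply(seq_len(nrow(vectors)), function(i)
    rdc_dmax(vectors$type[i], vectors$r_m[i]), 1)
  as.numeric(.rdc_design(vectors$x, vectors$y, vectors$z) %*% s * dmax)
}

#' Clore-Garrett R-factor
#'
#' \eqn{R = 100\sqrt{\langle(D_{obs} - D_{calc})^2\rangle /
#' (2\langle D_{obs}^2\rangle)}} (percent). The denominator may optionally
#' be replaced by a supplied expected mean-square coupling (e.g. the powder
#' average implied by the fitted tensor).
#'
#' @param d_obs observed couplings (Hz).
#' @param d_calc back-calculated couplings (Hz).
#' @param ms_expected optional expected mean-square coupling replacing
#'   \eqn{\langle D_{obs}^2\rangle}.
#' @return R-factor in percent; 0 for a perfect fit, \eqn{100/\sqrt{2}} for
#'   \code{d_calc = 0}.
#' @export
r_factor <- function(d_obs, d_calc, ms_expected = NULL) {
  stopifnot(length(d_obs) == length(d_calc), length(d_obs) > 0)
  ms <- if (is.null(ms_expected)) mean(d_obs^2) else ms_expected
  if (ms <= 0) stop("cannot normalise R-factor: zero mean-square coupling",
                    call. = FALSE)
  100 * sqrt(mean((d_obs - d_calc)^2) / (2 * ms))
}
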